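#' Prolyl peptide-bond torsion potential
#'
#' Physical torsion energy of one prolyl peptide bond as a function of its
#' omega dihedral angle. Four dihedral terms surround the peptide bond
#' (Ca-C-N-Ca, O-C-N-Ca, O-C-N-H, Ca-C-N-H); under rigid co-rotation of the
#' planar peptide unit they sit at omega + offset with offsets
#' {0, 180, 180, 0} degrees. Each term is
#' `V * (1 + cos(2 * Phi - 180))` so, with multiplicity 2, all four terms
#' coincide and the profile reduces to `4 V (1 + cos(2 omega - 180))`:
#' equal minima of zero at omega = 0 and 180 degrees and a barrier of `8 V`
#' at +/-90 degrees (20 kcal mol^-1 at the physical V = 2.5 kcal mol^-1).
#'
#' @param omega Omega dihedral angle(s) in degrees (treated periodically).
#' @param force_constant Per-term force constant V in kcal mol^-1
#'   (the replica-ladder level; 2.5 for the physical potential).
#' @return Torsion energy in kcal mol^-1, same length as `omega`.
#' @examples
#' eval_physical_torsion(90, 2.5)   # barrier: 20 kcal/mol
#' eval_physical_torsion(c(0, 180), 2.5)  # both wells at 0
#' @export
eval_physical_torsion <- function(omega, force_constant) {
  if (!is.numeric(force_constant) || length(force_constant) != 1L ||
      force_constant < 0) {
    abort("`force_constant` must be a single non-negative energy.")
  }
  w <- omega * pi / 180
  # sum over the four co-rotating dihedrals: offsets 0/180 leave the
  # multiplicity-2 cosine unchanged, so all four terms coincide
  4 * force_constant * (1 + cos(2 * w - pi))
}

#' One-fold trans-destabilizing bias potential
#'
#' The balancing bias added to every replica: a multiplicity-1 cosine with
#' phase 180 degrees on each of the three omega angles,
#' `sum_i V (1 + cos(omega_i - 180))`. It is maximal (`2 V` per residue) in
#' the trans well and zero in the cis well, flattening the otherwise
#' dominant all-trans state.
#'
#' @param omegas Angle triple (omega2, omega3, omega7) in degrees, or an
#'   n x 3 matrix / data frame with columns omega2, omega3, omega7.
#' @param bias_force_constant Force constant V_omega in kcal mol^-1
#'   (default 1).
#' @return Bias energy in kcal mol^-1 (one value per row).
#' @examples
#' eval_bias_potential(c(180, 180, 180), 1)  # 6: fully penalized
#' eval_bias_potential(c(0, 0, 0), 1)        # 0: cis untouched
#' @export
eval_bias_potential <- function(omegas, bias_force_constant = 1) {
  if (!is.numeric(bias_force_constant) || length(bias_force_constant) != 1L ||
      bias_force_constant < 0) {
    abort("`bias_force_constant` must be a single non-negative energy.")
  }
  m <- .as_omega_matrix(omegas) * pi / 180
  bias_force_constant * rowSums(1 + cos(m - pi))
}

# smooth cis weight on the circle: 1 at omega = 0, 0 at omega = 180,
# period 360 degrees
.w_cis <- function(omega) (1 + cos(omega * pi / 180)) / 2

# n x 8 matrix of smooth octant weights (product of per-axis factors);
# rows sum to 1
.state_weights <- function(m) {
  wc <- .w_cis(m)
  sm <- .state_matrix()
  out <- matrix(1, nrow(m), 8L)
  for (s in 1:8) {
    for (j in 1:3) {
      w <- if (sm[s, j]) 1 - wc[, j] else wc[, j]
      out[, s] <- out[, s] * w
    }
  }
  out
}

#' Reduced three-dihedral model potential
#'
#' Builds the toy Hamiltonian used throughout the package: three
#' independent physical prolyl torsion potentials (one per Pro residue
#' analogue) plus a smooth state-coupling term that makes the eight
#' cis/trans octant states energetically inequivalent. The coupling adds,
#' for each octant state s, an offset `e_s` weighted by a smooth periodic
#' switching function (products of `cos^2(omega/2)`-type factors) that is
#' ~1 deep inside octant s and partitions unity over the eight states.
#' The offsets stand in for the peptide-environment effects that
#' differentiate the states in the solvated peptide.
#'
#' @param coupling_offsets Eight energies (kcal mol^-1) named by
#'   [state_labels()] (TTT must be 0: it is the reference state).
#' @param force_constants Torsion force constants for the three residues
#'   (kcal mol^-1); default the physical 2.5 each.
#' @param temperature Temperature in Kelvin (default 300).
#' @return A `model_potential` object.
#' @export
model_potential <- function(coupling_offsets = setNames(numeric(8), state_labels()),
                            force_constants = c(2.5, 2.5, 2.5),
                            temperature = 300) {
  if (length(coupling_offsets) != 8L || !all(is.finite(coupling_offsets))) {
    abort("`coupling_offsets` must be eight finite energies.")
  }
  if (is.null(names(coupling_offsets))) {
    names(coupling_offsets) <- state_labels()
  }
  if (!setequal(names(coupling_offsets), state_labels())) {
    abort("`coupling_offsets` must be named by the eight state labels.")
  }
  coupling_offsets <- coupling_offsets[state_labels()]
  if (abs(coupling_offsets[["TTT"]]) > 1e-12) {
    abort("the TTT coupling offset must be 0 (reference state).")
  }
  if (length(force_constants) != 3L || any(force_constants < 0)) {
    abort("`force_constants` must be three non-negative energies.")
  }
  if (temperature <= 0) abort("`temperature` must be positive.")
  structure(
    list(
      coupling_offsets = coupling_offsets,
      force_constants = as.numeric(force_constants),
      temperature = temperature
    ),
    class = "model_potential"
  )
}

#' @export
print.model_potential <- function(x, ...) {
  cat("<model_potential>\n")
  cat("  torsion force constants:",
      paste(format(x$force_constants), collapse = ", "),
      "kcal/mol (barriers",
      paste(format(8 * x$force_constants), collapse = ", "), ")\n")
  cat("  temperature:", x$temperature, "K\n")
  cat("  coupling offsets (kcal/mol):\n")
  print(round(x$coupling_offsets, 4))
  invisible(x)
}

#' Total model energy
#'
#' Sum of the three physical torsion potentials and the smooth
#' state-coupling term; periodic in each angle with period 360 degrees.
#'
#' @inheritParams eval_bias_potential
#' @param model A [model_potential()].
#' @param bias_force_constant Optional bias force constant; if positive the
#'   one-fold trans-destabilizing bias is added (default 0 = physical
#'   Hamiltonian).
#' @param force_constants Optional override of the torsion force constants
#'   (used for replica-ladder levels).
#' @return Energy in kcal mol^-1, one value per row of `omegas`.
#' @export
eval_model_energy <- function(omegas, model, bias_force_constant = 0,
                              force_constants = NULL) {
  stopifnot(inherits(model, "model_potential"))
  m <- .as_omega_matrix(omegas)
  fc <- force_constants %||% model$force_constants
  u <- eval_physical_torsion(m[, 1], fc[1]) +
    eval_physical_torsion(m[, 2], fc[2]) +
    eval_physical_torsion(m[, 3], fc[3])
  off <- model$coupling_offsets
  if (any(off != 0)) {
    u <- u + drop(.state_weights(m) %*% off)
  }
  if (bias_force_constant > 0) {
    u <- u + eval_bias_potential(m, bias_force_constant)
  }
  u
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# midpoint grid over [-180, 180); grid_points must be a multiple of 4 so
# that no node falls exactly on an octant boundary (+/-90)
.quad_axis <- function(grid_points) {
  if (grid_points < 8 || grid_points %% 4 != 0) {
    abort("`grid_points` must be a multiple of 4 (>= 8).")
  }
  h <- 360 / grid_points
  -180 + (seq_len(grid_points) - 0.5) * h
}

# unnormalized Boltzmann factor exp(-U/kT) tabulated on the midpoint grid;
# returns list(axis, values (3d array))
.quad_density <- function(model, grid_points = 120, bias_force_constant = 0,
                          force_constants = NULL, temperature = NULL) {
  ax <- .quad_axis(grid_points)
  n <- length(ax)
  fc <- force_constants %||% model$force_constants
  temp <- temperature %||% model$temperature
  beta <- 1 / kT(temp)
  t1 <- eval_physical_torsion(ax, fc[1])
  t2 <- eval_physical_torsion(ax, fc[2])
  t3 <- eval_physical_torsion(ax, fc[3])
  u <- outer(outer(t1, t2, "+"), t3, "+")
  off <- model$coupling_offsets
  if (any(off != 0)) {
    wc <- .w_cis(ax)
    sm <- .state_matrix()
    for (s in 1:8) {
      w1 <- if (sm[s, 1]) 1 - wc else wc
      w2 <- if (sm[s, 2]) 1 - wc else wc
      w3 <- if (sm[s, 3]) 1 - wc else wc
      u <- u + off[s] * outer(outer(w1, w2), w3)
    }
  }
  if (bias_force_constant > 0) {
    b <- bias_force_constant * (1 + cos(ax * pi / 180 - pi))
    u <- u + outer(outer(b, b, "+"), b, "+")
  }
  list(axis = ax, values = exp(-beta * (u - min(u))))
}

#' Exact state probabilities by quadrature
#'
#' Independent brute-force oracle for the eight octant-state
#' probabilities: integrates `exp(-U/kT)` on a regular midpoint grid over
#' the three-torus and sums each +/-90-degree octant. Used to calibrate
#' the model and to validate every sampled/unbiased estimate.
#'
#' @param model A [model_potential()].
#' @param temperature Temperature in Kelvin; defaults to the model's.
#' @param grid_points Grid points per axis (multiple of 4; >= 100
#'   recommended).
#' @param bias_force_constant If positive, probabilities of the biased
#'   Hamiltonian (model + one-fold bias) are returned instead.
#' @param force_constants Optional torsion force-constant override.
#' @return A tibble with columns `state`, `probability` and
#'   `free_energy` (`-kT log P`, shifted so TTT = 0).
#' @export
quadrature_state_probabilities <- function(model, temperature = NULL,
                                           grid_points = 120,
                                           bias_force_constant = 0,
                                           force_constants = NULL) {
  stopifnot(inherits(model, "model_potential"))
  q <- .quad_density(model, grid_points, bias_force_constant,
                     force_constants, temperature)
  trans <- abs(q$axis) > 90
  p <- numeric(8)
  sm <- .state_matrix()
  for (s in 1:8) {
    m1 <- if (sm[s, 1]) trans else !trans
    m2 <- if (sm[s, 2]) trans else !trans
    m3 <- if (sm[s, 3]) trans else !trans
    p[s] <- sum(q$values[m1, m2, m3])
  }
  p <- p / sum(q$values)
  temp <- temperature %||% model$temperature
  g <- -kT(temp) * log(p)
  tibble(
    state = state_labels(),
    probability = p,
    free_energy = g - g[1]
  )
}

#' Calibrate the model to target state free energies
#'
#' Chooses coupling offsets so that the quadrature state free energies of
#' the model reproduce a target table (relative to TTT = 0). Because the
#' smooth switching function leaks slightly across octant boundaries, the
#' offsets are found iteratively: each offset is corrected by the current
#' free-energy residual until the largest residual is below `tol`.
#'
#' @param target_free_energies Eight target free energies (kcal mol^-1,
#'   relative to TTT = 0), named by [state_labels()] or in canonical
#'   order. See [bk_state_table()] for the bradykinin reference targets.
#' @param temperature Temperature in Kelvin (default 300).
#' @param grid_points Quadrature grid points per axis (default 120).
#' @param tol Convergence tolerance on the largest free-energy residual
#'   (kcal mol^-1, default 0.005 -- comfortably inside the 0.01
#'   calibration contract).
#' @param max_iter Iteration cap (default 60).
#' @return A calibrated [model_potential()].
#' @export
calibrate_model <- function(target_free_energies, temperature = 300,
                            grid_points = 120, tol = 0.005, max_iter = 60) {
  tgt <- target_free_energies
  if (is.data.frame(tgt)) tgt <- setNames(tgt$free_energy, tgt$state)
  if (length(tgt) != 8L || !all(is.finite(tgt))) {
    abort("`target_free_energies` must be eight finite energies.")
  }
  if (is.null(names(tgt))) names(tgt) <- state_labels()
  tgt <- tgt[state_labels()]
  if (abs(tgt[["TTT"]]) > 1e-9) {
    abort("the TTT target must be 0 (reference state).")
  }
  off <- tgt  # offsets ~ targets is an excellent starting point
  model <- model_potential(off, temperature = temperature)
  for (it in seq_len(max_iter)) {
    g <- quadrature_state_probabilities(model, grid_points = grid_points)
    resid <- tgt - g$free_energy
    if (max(abs(resid)) < tol) {
      attr(model, "calibration") <- list(
        iterations = it, max_residual = max(abs(resid)), targets = tgt
      )
      return(model)
    }
    off <- off + resid
    off[1] <- 0
    model <- model_potential(off, temperature = temperature)
  }
  abort(paste0(
    "calibration did not converge after ", max_iter, " iterations; ",
    "largest residual ", format(max(abs(resid)), digits = 3), " kcal/mol."
  ))
}

#' Write / read a model definition file
#'
#' The model (and optionally a replica-ladder block) is stored as a YAML
#' config with keys `temperature`, `force_constants`, `coupling_offsets`,
#' and optional `ladder` (n_replicas, v_max, bias_force_constant) and
#' `seed` entries.
#'
#' @param model A [model_potential()].
#' @param path File path.
#' @param ladder Optional [replica_ladder()] to store alongside.
#' @param seed Optional integer seed to record.
#' @return `write_model_config()` returns `path` invisibly;
#'   `read_model_config()` returns a list with elements `model` and
#'   (if present) `ladder` and `seed`.
#' @export
write_model_config <- function(model, path, ladder = NULL, seed = NULL) {
  stopifnot(inherits(model, "model_potential"))
  cfg <- list(
    temperature = model$temperature,
    force_constants = model$force_constants,
    coupling_offsets = as.list(model$coupling_offsets)
  )
  if (!is.null(ladder)) {
    cfg$ladder <- list(
      n_replicas = ladder$n_replicas,
      v_max = ladder$v_max,
      bias_force_constant = ladder$bias_force_constant
    )
  }
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  yaml::write_yaml(cfg, path, precision = 12)
  invisible(path)
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  for (key in c("temperature", "coupling_offsets", "force_constants")) {
    if (is.null(cfg[[key]])) {
      abort(paste0("model config is missing required key `", key, "`."))
    }
  }
  model <- model_potential(
    coupling_offsets = unlist(cfg$coupling_offsets),
    force_constants = unlist(cfg$force_constants),
    temperature = cfg$temperature
  )
  out <- list(model = model)
  if (!is.null(cfg$ladder)) {
    out$ladder <- replica_ladder(
      n_replicas = cfg$ladder$n_replicas,
      v_max = cfg$ladder$v_max,
      bias_force_constant = cfg$ladder$bias_force_constant
    )
  }
  if (!is.null(cfg$seed)) out$seed <- cfg$seed
  out
}
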