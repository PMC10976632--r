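#' Replica ladder of torsion force constants
#'
#' Defines the Hamiltonian ladder: equidistant torsion force constants
#' from `v_max` in replica 1 (the physical potential, barrier `8 v_max`)
#' down to 0 in the last replica (free cis/trans interconversion). The
#' one-fold trans-destabilizing bias (multiplicity 1, phase 180 degrees)
#' is present with the same force constant in every replica.
#'
#' @param n_replicas Number of replicas (default 12).
#' @param v_max Torsion force constant of replica 1 in kcal mol^-1
#'   (default 2.5).
#' @param bias_force_constant Bias force constant V_omega in kcal mol^-1,
#'   identical in all replicas (default 1).
#' @return A `replica_ladder` object with element `force_constants`
#'   (strictly decreasing, last value 0).
#' @export
replica_ladder <- function(n_replicas = 12, v_max = 2.5,
                           bias_force_constant = 1) {
  if (n_replicas < 2) abort("`n_replicas` must be at least 2.")
  if (v_max <= 0) abort("`v_max` must be positive.")
  if (bias_force_constant < 0) abort("`bias_force_constant` must be >= 0.")
  structure(
    list(
      n_replicas = as.integer(n_replicas),
      v_max = v_max,
      bias_force_constant = bias_force_constant,
      force_constants = seq(v_max, 0, length.out = n_replicas)
    ),
    class = "replica_ladder"
  )
}

#' @export
print.replica_ladder <- function(x, ...) {
  cat("<replica_ladder>", x$n_replicas, "replicas, V =",
      format(x$v_max), "-> 0 kcal/mol, bias V =",
      format(x$bias_force_constant), "kcal/mol\n")
  invisible(x)
}

.as_traj_tibble <- function(frames, step, replica_index, save_stride, seed) {
  out <- tibble(
    step = step,
    omega2 = frames[, 1],
    omega3 = frames[, 2],
    omega7 = frames[, 3]
  )
  attr(out, "replica_index") <- replica_index
  attr(out, "save_stride") <- save_stride
  attr(out, "seed") <- seed
  class(out) <- c("omega_traj", class(out))
  out
}

#' Metropolis Monte Carlo propagation of the model
#'
#' Random-walk Metropolis sampling of the three omega angles with
#' wrapped-Gaussian proposals (one sweep proposes one move per angle).
#' The chain satisfies detailed balance with respect to
#' `exp(-U/kT)` for the model Hamiltonian at the requested ladder level,
#' plus the one-fold bias when `bias_force_constant > 0`. Deterministic
#' given `seed`.
#'
#' @param model A [model_potential()].
#' @param n_sweeps Number of MC sweeps (> 0).
#' @param start Starting angle triple in degrees (default all-trans).
#' @param ladder_force_constant Torsion force constant of this replica
#'   level (default the model's physical value).
#' @param bias_force_constant Bias force constant (default 0 = unbiased).
#' @param step_sigma Proposal standard deviation in degrees (default 20).
#' @param save_stride Save every this many sweeps (default 1).
#' @param n_burn Burn-in sweeps discarded before saving (default 0).
#' @param seed Integer seed (required).
#' @return An `omega_traj` tibble with columns `step`, `omega2`,
#'   `omega3`, `omega7` (degrees in `[-180, 180)`).
#' @export
mc_propagate <- function(model, n_sweeps, start = c(180, 180, 180),
                         ladder_force_constant = NULL,
                         bias_force_constant = 0, step_sigma = 20,
                         save_stride = 1, n_burn = 0, seed) {
  stopifnot(inherits(model, "model_potential"))
  if (n_sweeps <= 0) abort("`n_sweeps` must be positive.")
  if (step_sigma <= 0) abort("`step_sigma` must be positive.")
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  v <- ladder_force_constant %||% model$force_constants[1]
  if (v < 0) abort("`ladder_force_constant` must be >= 0.")
  set.seed(seed)
  res <- .run_remd_cpp(
    force_constants = v,
    offsets = unname(model$coupling_offsets),
    state_trans = .state_matrix(),
    bias_force_constant = bias_force_constant,
    temperature = model$temperature,
    n_sweeps = as.integer(n_sweeps),
    n_burn = as.integer(n_burn),
    exchange_every = 0L,
    save_stride = as.integer(save_stride),
    step_sigma_deg = step_sigma,
    start = matrix(wrap_angle(start), nrow = 1)
  )
  .as_traj_tibble(res$frames[[1]], res$step, 1L, save_stride, seed)
}

#' Metropolis exchange probability between two replicas
#'
#' Probability of accepting a configuration swap between two replicas at
#' the same temperature:
#' `min(1, exp(-beta * (H_a(x_b) + H_b(x_a) - H_a(x_a) - H_b(x_b))))`.
#'
#' @param config_a,config_b Angle triples (degrees) currently held by the
#'   two replicas.
#' @param hamiltonian_a,hamiltonian_b Functions mapping an angle triple to
#'   a potential energy in kcal mol^-1.
#' @param temperature Temperature in Kelvin.
#' @return Acceptance probability in `[0, 1]`.
#' @export
exchange_probability <- function(config_a, config_b, hamiltonian_a,
                                 hamiltonian_b, temperature = 300) {
  delta <- hamiltonian_a(config_b) + hamiltonian_b(config_a) -
    hamiltonian_a(config_a) - hamiltonian_b(config_b)
  min(1, exp(-delta / kT(temperature)))
}

#' Run a bias-potential replica-exchange simulation
#'
#' Propagates every replica of the ladder by Metropolis MC under its own
#' Hamiltonian (torsions scaled to the ladder level + state coupling +
#' the one-fold bias, which is present in all replicas) and attempts
#' Metropolis configuration swaps between neighboring replicas every
#' `exchange_every` sweeps, alternating even and odd pairs. Replica 1
#' carries the physical torsion barrier and is the analysis input; its
#' sampled density is biased and must be reweighted (see
#' [unbias_density()]).
#'
#' @param model A [model_potential()].
#' @param ladder A [replica_ladder()].
#' @param n_sweeps MC sweeps per replica (after burn-in).
#' @param exchange_every Sweeps between exchange attempts (default 250).
#' @param save_stride Save every this many sweeps (default 10).
#' @param step_sigma Proposal standard deviation in degrees (default 20).
#' @param n_burn Burn-in sweeps discarded before saving (default 2000).
#' @param seed Integer seed (required).
#' @return A `wbp_remd` object: list with `trajectories` (one
#'   `omega_traj` per replica), `exchange_stats` (tibble of per-pair
#'   attempts, acceptances and acceptance fractions) and the run
#'   parameters. `tidy()` returns the exchange statistics and `glance()`
#'   a one-row run summary.
#' @export
run_wbp_remd <- function(model, ladder = replica_ladder(), n_sweeps,
                         exchange_every = 250, save_stride = 10,
                         step_sigma = 20, n_burn = 2000, seed) {
  stopifnot(inherits(model, "model_potential"),
            inherits(ladder, "replica_ladder"))
  if (exchange_every < 1) abort("`exchange_every` must be >= 1.")
  if (ladder$n_replicas < 2) {
    abort("replica exchange needs at least 2 replicas.")
  }
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  set.seed(seed)
  start <- matrix(180, nrow = ladder$n_replicas, ncol = 3)
  res <- .run_remd_cpp(
    force_constants = ladder$force_constants,
    offsets = unname(model$coupling_offsets),
    state_trans = .state_matrix(),
    bias_force_constant = ladder$bias_force_constant,
    temperature = model$temperature,
    n_sweeps = as.integer(n_sweeps),
    n_burn = as.integer(n_burn),
    exchange_every = as.integer(exchange_every),
    save_stride = as.integer(save_stride),
    step_sigma_deg = step_sigma,
    start = start
  )
  trajectories <- purrr::map(seq_len(ladder$n_replicas), function(r) {
    .as_traj_tibble(res$frames[[r]], res$step, r, save_stride, seed)
  })
  stats <- tibble(
    pair = paste0(seq_len(ladder$n_replicas - 1), "-",
                  2:ladder$n_replicas),
    attempts = as.integer(res$attempts),
    accepts = as.integer(res$accepts),
    acceptance = ifelse(res$attempts > 0, res$accepts / res$attempts, NA_real_)
  )
  structure(
    list(
      trajectories = trajectories,
      exchange_stats = stats,
      model = model,
      ladder = ladder,
      n_sweeps = n_sweeps,
      exchange_every = exchange_every,
      save_stride = save_stride,
      seed = seed
    ),
    class = "wbp_remd"
  )
}

#' @export
print.wbp_remd <- function(x, ...) {
  cat("<wbp_remd>", x$ladder$n_replicas, "replicas,",
      format(x$n_sweeps, big.mark = ","), "sweeps,",
      nrow(x$trajectories[[1]]), "saved frames per replica\n")
  acc <- x$exchange_stats$acceptance
  if (any(!is.na(acc))) {
    cat("  neighbor exchange acceptance:",
        paste0(round(100 * range(acc, na.rm = TRUE)), collapse = "-"), "%\n")
  }
  invisible(x)
}

#' @rdname run_wbp_remd
#' @param x A `wbp_remd` object.
#' @param ... Unused.
#' @export
tidy.wbp_remd <- function(x, ...) {
  x$exchange_stats
}

#' @rdname run_wbp_remd
#' @export
glance.wbp_remd <- function(x, ...) {
  acc <- x$exchange_stats$acceptance
  tibble(
    n_replicas = x$ladder$n_replicas,
    n_sweeps = x$n_sweeps,
    n_frames = nrow(x$trajectories[[1]]),
    exchange_every = x$exchange_every,
    min_acceptance = min(acc, na.rm = TRUE),
    max_acceptance = max(acc, na.rm = TRUE),
    seed = x$seed
  )
}

#' Extract the analysis trajectory (replica 1)
#'
#' @param run A `wbp_remd` object.
#' @return The replica-1 `omega_traj` tibble (biased sampling of the
#'   physical Hamiltonian).
#' @export
replica1 <- function(run) {
  stopifnot(inherits(run, "wbp_remd"))
  run$trajectories[[1]]
}

#' Read / write omega trajectories as tabular text
#'
#' Plain whitespace-separated text with columns
#' `step omega2 omega3 omega7` (degrees) and `#`-prefixed header lines.
#'
#' @param traj An `omega_traj` tibble (or any data frame with those
#'   columns).
#' @param path File path.
#' @param ... Header comment lines to record (`name = value`).
#' @return `write_omega_traj()` returns `path` invisibly;
#'   `read_omega_traj()` returns an `omega_traj` tibble.
#' @export
write_omega_traj <- function(traj, path, ...) {
  meta <- c(
    list(package = paste0("wbpremd ", utils::packageVersion("wbpremd"))),
    list(...)
  )
  hdr <- paste0("# ", names(meta), ": ", unlist(meta))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(
    as.data.frame(traj)[c("step", "omega2", "omega3", "omega7")],
    con, row.names = FALSE, quote = FALSE, sep = "\t"
  )
  invisible(path)
}

#' @rdname write_omega_traj
#' @export
read_omega_traj <- function(path) {
  df <- utils::read.table(path, header = TRUE, comment.char = "#")
  out <- as_tibble(df)
  class(out) <- c("omega_traj", class(out))
  out
}
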