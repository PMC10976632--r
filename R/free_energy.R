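# Composite Simpson weights for k equally spaced nodes, spacing h.
# Odd interval counts use Simpson 3/8 on the last three intervals.
.simpson_weights <- function(k, h) {
  m <- k - 1
  w <- numeric(k)
  if (m < 2) abort("Simpson integration needs at least 3 nodes.")
  if (m %% 2 == 0) {
    w[1] <- 1
    w[k] <- 1
    w[seq(2, k - 1, by = 2)] <- 4
    if (k > 3) w[seq(3, k - 2, by = 2)] <- 2
    w * h / 3
  } else {
    k1 <- k - 3
    if (k1 >= 3) w[seq_len(k1)] <- .simpson_weights(k1, h)
    w[(k - 3):k] <- w[(k - 3):k] + h * 3 / 8 * c(1, 3, 3, 1)
    w
  }
}

# Node indices and Simpson weights for the cis half [-90, 90] and the
# trans half [90, 270] of one omega axis. The octant boundaries must fall
# exactly on bin centres, which requires n_bins == 2 (mod 4); the shared
# boundary ordinates then serve as endpoints of both composite ranges, so
# the two halves partition the circle exactly.
.half_nodes <- function(n_bins, bin_width) {
  if (n_bins %% 4 != 2) {
    abort(paste0(
      "state integration requires the octant boundaries (+/-90 deg) to ",
      "fall on bin centres: use n_bins = 2 (mod 4), e.g. 50."
    ))
  }
  i_lo <- n_bins / 4 + 0.5   # centre at -90
  i_hi <- 3 * n_bins / 4 + 0.5  # centre at +90
  cis_idx <- i_lo:i_hi
  trans_idx <- c(i_hi:n_bins, 1:i_lo)
  w <- .simpson_weights(length(cis_idx), bin_width)
  list(
    cis = list(idx = as.integer(cis_idx), w = w),
    trans = list(idx = as.integer(trans_idx), w = w)
  )
}

# Simpson integrals of a 3D density over the eight octants (unnormalized)
.octant_integrals <- function(density) {
  h <- .half_nodes(density$n_bins, density$bin_width)
  sm <- .state_matrix()
  p <- numeric(8)
  for (s in 1:8) {
    h1 <- if (sm[s, 1]) h$trans else h$cis
    h2 <- if (sm[s, 2]) h$trans else h$cis
    h3 <- if (sm[s, 3]) h$trans else h$cis
    sub <- density$values[h1$idx, h2$idx, h3$idx]
    p[s] <- sum(sub * outer(outer(h1$w, h2$w), h3$w))
  }
  p
}

#' Isomerization-state probabilities of a density
#'
#' Integrates the (unbiased) 3D probability density over the eight
#' +/-90-degree octants by composite Simpson's rule on the bin-centre
#' ordinates (trans: omega in 180 +/- 90, cis: omega in 0 +/- 90;
#' boundary ordinates are shared between the adjacent halves). The eight
#' probabilities are normalized over the octant partition, so they sum to
#' one exactly.
#'
#' @param density A `density3d` (normalized; unbias first if it came from
#'   biased sampling).
#' @return A tibble with columns `state` and `probability`.
#' @export
state_probabilities <- function(density) {
  stopifnot(inherits(density, "density3d"))
  p <- .octant_integrals(density)
  tibble(state = state_labels(), probability = p / sum(p))
}

#' @rdname state_probabilities
#' @param state A three-letter state label over \{T, C\} (positions Pro2,
#'   Pro3, Pro7), e.g. `"TTC"`.
#' @return `state_probability()` returns a single probability.
#' @export
state_probability <- function(density, state) {
  if (!is.character(state) || length(state) != 1L ||
      !state %in% state_labels()) {
    abort("`state` must be one of the eight three-letter labels over {T, C}.")
  }
  p <- state_probabilities(density)
  p$probability[match(state, p$state)]
}

#' Boltzmann-inversion free-energy table
#'
#' Converts the eight state probabilities of an unbiased density into
#' relative free energies `G(state) = -kT log P(state)`, shifted so that
#' the all-trans state TTT is zero. Empty octants get `G = +Inf` with a
#' warning.
#'
#' @param density An unbiased `density3d`.
#' @param temperature Temperature in Kelvin (default 300).
#' @return An `fe_report` object; `tidy()` gives the state table
#'   (`state`, `probability`, `probability_sem`, `free_energy`,
#'   `free_energy_sem`), `glance()` a one-row summary. SEM columns are
#'   `NA` unless filled in by [analyze_replica1()].
#' @export
free_energy_table <- function(density, temperature = 300) {
  p <- state_probabilities(density)
  if (any(p$probability == 0)) {
    warn(paste(
      "empty isomerization-state octant(s):",
      paste(p$state[p$probability == 0], collapse = ", "),
      "- free energy set to +Inf."
    ))
  }
  g <- -kT(temperature) * log(p$probability)
  # reference: TTT, falling back to the lowest sampled state if TTT is empty
  ref <- if (is.finite(g[1])) g[1] else min(g[is.finite(g)])
  states <- tibble(
    state = p$state,
    probability = p$probability,
    probability_sem = NA_real_,
    free_energy = g - ref,
    free_energy_sem = NA_real_
  )
  structure(
    list(states = states, temperature = temperature,
         n_frames = density$n_frames),
    class = "fe_report"
  )
}

#' @export
print.fe_report <- function(x, ...) {
  cat("<fe_report> isomerization-state free energies at",
      x$temperature, "K",
      if (!is.na(x$n_frames)) paste0("(", x$n_frames, " frames)"), "\n")
  df <- x$states
  df$probability <- sprintf("%.4f", df$probability)
  df$free_energy <- sprintf("%.3f", df$free_energy)
  print(as.data.frame(df), row.names = FALSE)
  invisible(x)
}

#' @rdname free_energy_table
#' @param x An `fe_report`.
#' @param ... Unused.
#' @export
tidy.fe_report <- function(x, ...) {
  x$states
}

#' @rdname free_energy_table
#' @export
glance.fe_report <- function(x, ...) {
  tibble(
    temperature = x$temperature,
    n_frames = x$n_frames,
    p_all_trans = x$states$probability[1],
    n_states_sampled = sum(x$states$probability > 0),
    fe_range = max(x$states$free_energy[is.finite(x$states$free_energy)]) -
      min(x$states$free_energy[is.finite(x$states$free_energy)])
  )
}

#' Potential of mean force along one omega angle
#'
#' Boltzmann inversion of a 1D marginal density:
#' `G(omega) = -kT log P(omega)`, shifted so the minimum is zero. Empty
#' bins give `+Inf`.
#'
#' @param marginal A `density1d` from [project_density()].
#' @param temperature Temperature in Kelvin (default 300).
#' @return A tibble with columns `omega` (bin centres, degrees) and
#'   `free_energy` (kcal mol^-1).
#' @export
pmf_1d <- function(marginal, temperature = 300) {
  stopifnot(inherits(marginal, "density1d"))
  g <- -kT(temperature) * log(marginal$values)
  g <- g - min(g[is.finite(g)])
  tibble(omega = marginal$axis, free_energy = g)
}

# Simpson half-circle integrals of a 1D marginal: c(cis, trans)
.half_integrals <- function(marginal) {
  h <- .half_nodes(length(marginal$axis), marginal$bin_width)
  c(
    cis = sum(marginal$values[h$cis$idx] * h$cis$w),
    trans = sum(marginal$values[h$trans$idx] * h$trans$w)
  )
}

#' Marginal cis-to-trans isomerization free energy
#'
#' `dG_cis_to_trans = -kT log(P_trans / P_cis)` for one omega angle,
#' where the halves are 180 +/- 90 (trans) and 0 +/- 90 (cis) degrees and
#' the marginal averages over the isomerization states of the other
#' residues. Negative values mean trans is favored.
#'
#' @inheritParams pmf_1d
#' @return Free energy in kcal mol^-1.
#' @export
isomerization_dG <- function(marginal, temperature = 300) {
  p <- .half_integrals(marginal)
  -kT(temperature) * log(p[["trans"]] / p[["cis"]])
}

#' Conditional cis-to-trans isomerization free energy
#'
#' Free energy of switching residue `residue` from cis to trans while the
#' other two Pro residues are held in prescribed isomerization states:
#' `dG = -kT log(P(i = trans, j = s_j, k = s_k) /
#' P(i = cis, j = s_j, k = s_k))`, i.e. the free-energy difference of the
#' two involved octants. Negative values mean trans is favored under that
#' condition.
#'
#' @param density An unbiased `density3d`.
#' @param residue Residue of interest: 2, 3 or 7.
#' @param condition Length-2 character vector of `"T"`/`"C"` for the
#'   other two residues in ascending residue order (e.g. for
#'   `residue = 7`, `condition = c("C", "T")` means Pro2 cis, Pro3
#'   trans).
#' @param temperature Temperature in Kelvin (default 300).
#' @return A one-row tibble: `residue`, `condition` (e.g. `"2C,3T"`),
#'   `dG_cis_to_trans`, `dG_sem` (`NA` here; filled by
#'   [analyze_replica1()]).
#' @export
conditional_dG <- function(density, residue, condition, temperature = 300) {
  residue <- as.integer(residue)
  if (!residue %in% .residues) abort("`residue` must be 2, 3 or 7.")
  if (length(condition) != 2L || !all(condition %in% c("T", "C"))) {
    abort('`condition` must be two letters from {"T", "C"}.')
  }
  others <- setdiff(.residues, residue)
  pos_i <- match(residue, .residues)
  pos_o <- match(others, .residues)
  lab <- function(s_i) {
    l <- character(3)
    l[pos_i] <- s_i
    l[pos_o] <- condition
    paste(l, collapse = "")
  }
  p <- state_probabilities(density)
  pt <- p$probability[match(lab("T"), p$state)]
  pc <- p$probability[match(lab("C"), p$state)]
  if (pt == 0 || pc == 0) {
    warn("empty conditioned octant: conditional free energy is infinite.")
  }
  tibble(
    residue = residue,
    condition = paste0(others, condition, collapse = ","),
    dG_cis_to_trans = -kT(temperature) * log(pt / pc),
    dG_sem = NA_real_
  )
}

#' All conditional isomerization free energies
#'
#' The twelve conditional cis-to-trans free energies (each residue
#' conditioned on the four T/C combinations of the other two), plus the
#' coupling shift `ddG` relative to the both-trans condition.
#'
#' @inheritParams conditional_dG
#' @return A tibble with columns `residue`, `condition`,
#'   `dG_cis_to_trans`, `dG_sem`, `ddG`.
#' @export
conditional_dG_table <- function(density, temperature = 300) {
  combos <- expand.grid(s1 = c("T", "C"), s2 = c("T", "C"),
                        stringsAsFactors = FALSE)
  out <- purrr::map(
    .residues,
    function(r) {
      purrr::map(seq_len(nrow(combos)), function(i) {
        conditional_dG(density, r, c(combos$s1[i], combos$s2[i]), temperature)
      }) |> bind_rows()
    }
  ) |> bind_rows()
  out |>
    group_by(.data$residue) |>
    mutate(ddG = .data$dG_cis_to_trans - .data$dG_cis_to_trans[1]) |>
    ungroup()
}

#' Block standard error of the mean
#'
#' Splits a frame stream into `n_blocks` contiguous, equally sized
#' subsets (trailing remainder frames are dropped), evaluates a statistic
#' on each block and returns the standard error of the mean of the block
#' values, `sd(blocks) / sqrt(n_blocks)`.
#'
#' @param x Per-frame data: a vector, matrix or data frame (rows =
#'   frames).
#' @param statistic Function applied to each block; may return a scalar
#'   or a numeric vector (SEMs are computed elementwise).
#' @param n_blocks Number of blocks (default 5).
#' @return Numeric SEM(s), same shape as the statistic's output; `NA`
#'   where block values are not finite.
#' @export
block_sem <- function(x, statistic = mean, n_blocks = 5) {
  n <- if (is.null(dim(x))) length(x) else nrow(x)
  if (n < n_blocks) abort("need at least `n_blocks` frames.")
  size <- n %/% n_blocks
  vals <- purrr::map(seq_len(n_blocks), function(b) {
    idx <- ((b - 1) * size + 1):(b * size)
    block <- if (is.null(dim(x))) x[idx] else x[idx, , drop = FALSE]
    as.numeric(statistic(block))
  })
  m <- do.call(rbind, vals)
  sems <- apply(m, 2, function(v) {
    if (all(is.finite(v))) sd(v) / sqrt(n_blocks) else NA_real_
  })
  if (length(sems) == 1) unname(sems) else sems
}

#' Full replica-1 unbiasing analysis
#'
#' The standard analysis of the biased replica-1 trajectory: histogram
#' into the 50^3 density, reweight out the one-fold bias, and derive the
#' state free-energy table and all conditional isomerization free
#' energies, with 5-subset block standard errors computed by repeating
#' the whole analysis on contiguous fifths of the trajectory.
#'
#' @param traj Replica-1 trajectory (`omega_traj` or data frame with
#'   `omega2`, `omega3`, `omega7`).
#' @param bias_force_constant Bias force constant used in the run
#'   (default 1).
#' @param temperature Temperature in Kelvin (default 300).
#' @param n_bins Histogram bins per axis (default 50).
#' @param n_blocks Error-analysis subsets (default 5).
#' @return An `isomer_analysis` list: `fe` (an `fe_report` with SEMs),
#'   `conditionals` (tibble with SEMs and `ddG`), `density` (unbiased
#'   `density3d`) and `biased_density`.
#' @export
analyze_replica1 <- function(traj, bias_force_constant = 1,
                             temperature = 300, n_bins = 50, n_blocks = 5) {
  m <- .as_omega_matrix(traj)
  biased <- histogram3d(m, n_bins = n_bins, biased = TRUE)
  unb <- unbias_density(biased, bias_force_constant, temperature)
  fe <- free_energy_table(unb, temperature)
  cond <- conditional_dG_table(unb, temperature)

  per_block <- function(block) {
    d <- unbias_density(histogram3d(block, n_bins = n_bins),
                        bias_force_constant, temperature)
    ftab <- suppressWarnings(free_energy_table(d, temperature))
    ctab <- suppressWarnings(conditional_dG_table(d, temperature))
    c(ftab$states$probability, ftab$states$free_energy,
      ctab$dG_cis_to_trans)
  }
  sems <- block_sem(m, per_block, n_blocks = n_blocks)
  fe$states$probability_sem <- sems[1:8]
  fe$states$free_energy_sem <- sems[9:16]
  cond$dG_sem <- sems[17:28]

  structure(
    list(fe = fe, conditionals = cond, density = unb,
         biased_density = biased, temperature = temperature,
         bias_force_constant = bias_force_constant, n_blocks = n_blocks),
    class = "isomer_analysis"
  )
}

#' @export
print.isomer_analysis <- function(x, ...) {
  print(x$fe)
  cat("\nconditional cis->trans free energies (kcal/mol):\n")
  df <- x$conditionals
  df$dG_cis_to_trans <- sprintf("%.3f", df$dG_cis_to_trans)
  df$ddG <- sprintf("%.3f", df$ddG)
  print(as.data.frame(df), row.names = FALSE)
  invisible(x)
}
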