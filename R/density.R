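#' Binned probability density over the three-torus
#'
#' Internal constructor for the 3D density container: a cubic array of
#' non-negative bin values over `[-180, 180)^3` with bin edges at
#' `-180 + k * 360/n_bins`, normalized so that
#' `sum(values) * bin_width^3 = 1`.
#'
#' @param values `n_bins^3` array of non-negative values.
#' @param biased Flag: does the density still contain the one-fold bias?
#' @param n_frames Number of frames the density was estimated from
#'   (NA for analytic densities).
#' @return A `density3d` object.
#' @keywords internal
new_density3d <- function(values, biased = FALSE, n_frames = NA_integer_) {
  n_bins <- dim(values)[1]
  bw <- 360 / n_bins
  total <- sum(values) * bw^3
  if (total <= 0) abort("density has zero total weight.")
  structure(
    list(
      values = values / total,
      axis = -180 + (seq_len(n_bins) - 0.5) * bw,
      bin_width = bw,
      n_bins = n_bins,
      biased = biased,
      n_frames = n_frames
    ),
    class = "density3d"
  )
}

#' @export
print.density3d <- function(x, ...) {
  cat("<density3d>", x$n_bins, "^3 bins,", format(x$bin_width),
      "deg bin width,", if (x$biased) "biased" else "unbiased", "\n")
  if (!is.na(x$n_frames)) cat("  estimated from", x$n_frames, "frames\n")
  invisible(x)
}

#' Histogram a trajectory into a 3D density
#'
#' Bins the (omega2, omega3, omega7) frames into a cube with `n_bins`
#' bins along each axis (edges at `-180 + k * 360/n_bins`) and normalizes
#' the counts to a probability density. Sampling from the biased replica
#' yields the biased density; pass the result to [unbias_density()].
#'
#' @param series Trajectory: data frame with columns `omega2`, `omega3`,
#'   `omega7` (degrees), or an n x 3 matrix.
#' @param n_bins Bins per axis (default 50).
#' @param biased Flag recorded on the result (default TRUE: replica-1
#'   sampling is biased).
#' @return A `density3d` object.
#' @export
histogram3d <- function(series, n_bins = 50, biased = TRUE) {
  m <- .as_omega_matrix(series)
  if (nrow(m) == 0) abort("`series` is empty.")
  bw <- 360 / n_bins
  idx <- floor((wrap_angle(m) + 180) / bw) + 1L
  idx[idx > n_bins] <- n_bins  # guard against rounding at the upper edge
  counts <- array(
    tabulate(
      (idx[, 3] - 1L) * n_bins^2 + (idx[, 2] - 1L) * n_bins + idx[, 1],
      nbins = n_bins^3
    ),
    dim = rep(n_bins, 3)
  )
  new_density3d(counts, biased = biased, n_frames = nrow(m))
}

#' Analytic model density on the histogram grid
#'
#' Tabulates `exp(-U/kT)` of the model (optionally including the
#' one-fold bias) at the bin centres of the standard histogram grid and
#' normalizes it. This is the quadrature reference against which sampled
#' and unbiased histograms are validated.
#'
#' @param model A [model_potential()].
#' @param n_bins Bins per axis (default 50).
#' @param bias_force_constant If positive, the biased density (model +
#'   bias Hamiltonian) is returned.
#' @param temperature Temperature in Kelvin; defaults to the model's.
#' @param supersample Subcells per bin and axis used to bin-average the
#'   Boltzmann factor (default 1 = evaluate at bin centres; use 3-5 when
#'   the reference must match bin averages of sampled histograms).
#' @return A `density3d` object.
#' @export
density_from_model <- function(model, n_bins = 50, bias_force_constant = 0,
                               temperature = NULL, supersample = 1) {
  stopifnot(inherits(model, "model_potential"))
  s <- as.integer(supersample)
  if (s < 1) abort("`supersample` must be >= 1.")
  if (s > 1) {
    fine <- density_from_model(model, n_bins * s, bias_force_constant,
                               temperature, supersample = 1)
    v <- fine$values
    # aggregate s^3 subcells per bin, one axis at a time
    for (axis in 1:3) {
      dim(v) <- c(s, length(v) / s)
      v <- colSums(v)
      dim(v) <- c(n_bins, length(v) / n_bins)
      v <- t(v)
    }
    dim(v) <- rep(n_bins, 3)
    return(new_density3d(v, biased = bias_force_constant > 0))
  }
  bw <- 360 / n_bins
  ax <- -180 + (seq_len(n_bins) - 0.5) * bw
  temp <- temperature %||% model$temperature
  beta <- 1 / kT(temp)
  t1 <- eval_physical_torsion(ax, model$force_constants[1])
  t2 <- eval_physical_torsion(ax, model$force_constants[2])
  t3 <- eval_physical_torsion(ax, model$force_constants[3])
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
  new_density3d(exp(-beta * (u - min(u))), biased = bias_force_constant > 0)
}

#' Reweight a biased density to the unbiased ensemble
#'
#' Removes the one-fold trans-destabilizing bias from a sampled density:
#' each bin is multiplied by `exp(+ bias(bin centre) / kT)` and the
#' result is renormalized, which absorbs the additive free-energy
#' constants of the biased and unbiased ensembles.
#'
#' @param biased A `density3d` from biased sampling.
#' @param bias_force_constant Bias force constant used in the simulation
#'   (kcal mol^-1).
#' @param temperature Temperature in Kelvin (default 300).
#' @return An unbiased `density3d`.
#' @export
unbias_density <- function(biased, bias_force_constant, temperature = 300) {
  stopifnot(inherits(biased, "density3d"))
  if (bias_force_constant < 0) abort("`bias_force_constant` must be >= 0.")
  if (bias_force_constant == 0) {
    out <- biased
    out$biased <- FALSE
    return(out)
  }
  beta <- 1 / kT(temperature)
  b <- bias_force_constant * (1 + cos(biased$axis * pi / 180 - pi))
  w <- exp(beta * outer(outer(b, b, "+"), b, "+"))
  values <- biased$values * w
  if (sum(values) <= 0) abort("reweighted density has zero total weight.")
  out <- new_density3d(values, biased = FALSE, n_frames = biased$n_frames)
  out
}

#' Project a 3D density onto one or two omega axes
#'
#' Marginalizes the density by summing over the dropped axes times the
#' bin width; the projection is renormalized over the kept axes.
#'
#' @param density A `density3d`.
#' @param keep_axes Residues to keep: subset of `c(2, 3, 7)` of size 1
#'   or 2.
#' @return A `density1d` (tibble-backed profile) or `density2d` object.
#' @export
project_density <- function(density, keep_axes) {
  stopifnot(inherits(density, "density3d"))
  keep_axes <- sort(as.integer(keep_axes))
  if (length(keep_axes) < 1 || length(keep_axes) > 2 ||
      !all(keep_axes %in% .residues)) {
    abort("`keep_axes` must be a subset of c(2, 3, 7) of size 1 or 2.")
  }
  dims <- match(keep_axes, .residues)
  vals <- apply(density$values, dims, sum) * density$bin_width^(3 - length(dims))
  if (length(dims) == 1) {
    structure(
      list(
        values = as.numeric(vals), axis = density$axis,
        bin_width = density$bin_width, residue = keep_axes,
        n_frames = density$n_frames
      ),
      class = "density1d"
    )
  } else {
    structure(
      list(
        values = vals, axis = density$axis,
        bin_width = density$bin_width, residues = keep_axes,
        n_frames = density$n_frames
      ),
      class = "density2d"
    )
  }
}

#' @export
print.density1d <- function(x, ...) {
  cat("<density1d> omega", x$residue, ",", length(x$axis), "bins\n")
  invisible(x)
}

#' @export
print.density2d <- function(x, ...) {
  cat("<density2d> omega", paste(x$residues, collapse = " x "), ",",
      length(x$axis), "^2 bins\n")
  invisible(x)
}

#' @rdname histogram3d
#' @param x A `density3d`.
#' @param ... Unused.
#' @export
tidy.density3d <- function(x, ...) {
  grid <- expand.grid(omega2 = x$axis, omega3 = x$axis, omega7 = x$axis)
  out <- as_tibble(grid)
  out$density <- as.numeric(x$values)
  out
}
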