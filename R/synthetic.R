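#' Draw i.i.d. samples from the model density
#'
#' Samples frames directly from the quadrature-tabulated Boltzmann
#' density of the model (inverse-CDF on the flattened grid with uniform
#' in-bin jitter), bypassing the Monte Carlo dynamics. This isolates the
#' unbiasing estimators from sampler mixing: the empirical octant
#' frequencies converge to the quadrature state probabilities by
#' construction.
#'
#' @param model A [model_potential()].
#' @param n Number of frames.
#' @param bias_force_constant If positive, sample the biased density
#'   (model + one-fold bias), as replica 1 would produce.
#' @param n_grid Tabulation grid points per axis (multiple of 4,
#'   default 120).
#' @param seed Integer seed (required).
#' @return An `omega_traj` tibble with columns `step`, `omega2`,
#'   `omega3`, `omega7`.
#' @export
sample_iid_density <- function(model, n, bias_force_constant = 0,
                               n_grid = 120, seed) {
  stopifnot(inherits(model, "model_potential"))
  if (n <= 0) abort("`n` must be positive.")
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  q <- .quad_density(model, n_grid, bias_force_constant)
  h <- 360 / n_grid
  set.seed(seed)
  flat <- as.numeric(q$values)
  cell <- sample.int(length(flat), n, replace = TRUE, prob = flat)
  i <- (cell - 1L) %% n_grid + 1L
  j <- ((cell - 1L) %/% n_grid) %% n_grid + 1L
  k <- (cell - 1L) %/% (n_grid^2) + 1L
  jit <- function(idx) {
    wrap_angle(q$axis[idx] + runif(n, -h / 2, h / 2))
  }
  .as_traj_tibble(
    cbind(jit(i), jit(j), jit(k)),
    step = seq_len(n), replica_index = 1L, save_stride = 1L, seed = seed
  )
}

#' Synthetic geometric time series with planted ground truth
#'
#' Generates the inputs for the structural-observable analyses with
#' every planted quantity recorded for oracle tests: hydrogen-bond
#' geometry with exact per-state contact occupancies, constant-distance
#' NOE channels, a labeled feature matrix with a controlled number of
#' informative columns, and well-separated feature-space blobs for
#' clustering. All draws are reproducible from `seed`.
#'
#' @param n_frames Frames per isomerization state for the hydrogen-bond
#'   series (default 500).
#' @param states States to include (default all eight).
#' @param hbond_occupancy Tibble with columns `bond`, `state`,
#'   `occupancy`: planted contact fractions. Non-contact frames are
#'   drawn with donor-acceptor distances above 3.8 Angstrom, so the
#'   planted occupancy is recovered exactly under both the 3.0 and the
#'   looser 3.5 Angstrom criterion.
#' @param noe_distances Tibble with columns `pair`, `r`: constant
#'   interproton distance channels (Angstrom).
#' @param n_informative,n_noise Informative / pure-noise columns of the
#'   classification feature matrix (defaults 2 and 20).
#' @param n_clusters,cluster_size Number and size of planted
#'   feature-space blobs (defaults 3 and 1000).
#' @param cluster_noise Number of uniform background points added to the
#'   cluster fixture (default 0).
#' @param seed Integer seed (required).
#' @return A list with elements `hbond_geom` (long tibble: `frame`,
#'   `state`, `bond`, `dist`, `angle`), `noe_geom` (long tibble:
#'   `frame`, `state`, `pair`, `r`), `features` + `feature_states`
#'   (classification fixture), `cluster_features` + `cluster_truth`, and
#'   `truth` (every planted quantity).
#' @export
make_geometry_fixture <- function(n_frames = 500,
                                  states = state_labels(),
                                  hbond_occupancy = NULL,
                                  noe_distances = NULL,
                                  n_informative = 2, n_noise = 20,
                                  n_clusters = 3, cluster_size = 1000,
                                  cluster_noise = 0,
                                  seed) {
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  set.seed(seed)
  frame_states <- rep(states, each = n_frames)
  n_tot <- length(frame_states)

  if (is.null(hbond_occupancy)) {
    hbond_occupancy <- tibble(
      bond = "Ser6O-Arg9H", state = states,
      occupancy = rep(c(0.308, 0), length.out = length(states))
    )
  }
  hbond_geom <- purrr::map(seq_len(nrow(hbond_occupancy)), function(i) {
    st <- hbond_occupancy$state[i]
    idx <- which(frame_states == st)
    n_on <- round(hbond_occupancy$occupancy[i] * length(idx))
    on <- seq_len(length(idx)) <= n_on
    tibble(
      frame = idx,
      state = st,
      bond = hbond_occupancy$bond[i],
      dist = ifelse(on, runif(length(idx), 2.2, 2.9),
                    runif(length(idx), 3.8, 5.0)),
      angle = ifelse(on, runif(length(idx), 145, 175),
                     runif(length(idx), 95, 175))
    )
  }) |> bind_rows()

  if (is.null(noe_distances)) {
    noe_distances <- tibble(pair = c("Phe5H-Pro3HA", "Arg9H-Pro7HA"),
                            r = c(3.5, 4.2))
  }
  noe_geom <- purrr::map(seq_len(nrow(noe_distances)), function(i) {
    tibble(frame = seq_len(n_tot), state = frame_states,
           pair = noe_distances$pair[i], r = noe_distances$r[i])
  }) |> bind_rows()

  # classification fixture: informative columns separate the classes,
  # the rest is pure noise
  class_id <- as.integer(factor(frame_states, levels = states))
  centers <- seq_along(states) * 3
  informative <- sapply(seq_len(n_informative), function(j) {
    centers[class_id] * (1 + 0.1 * j) + rnorm(n_tot, sd = 0.5)
  })
  noise <- matrix(rnorm(n_tot * n_noise), n_tot, n_noise)
  features <- as.data.frame(cbind(informative, noise))
  names(features) <- c(paste0("info", seq_len(n_informative)),
                       paste0("noise", seq_len(n_noise)))

  # clustering fixture: well-separated Gaussian blobs in 4 dimensions,
  # centered on scaled unit vectors
  blob_centers <- matrix(0, n_clusters, 4)
  for (i in seq_len(n_clusters)) {
    blob_centers[i, (i - 1) %% 4 + 1] <- 10 * ceiling(i / 4)
  }
  blob_id <- rep(seq_len(n_clusters), each = cluster_size)
  cluster_features <- blob_centers[blob_id, , drop = FALSE] +
    matrix(rnorm(length(blob_id) * 4, sd = 0.5), ncol = 4)
  if (cluster_noise > 0) {
    lim <- max(abs(cluster_features)) + 2
    cluster_features <- rbind(
      cluster_features,
      matrix(runif(cluster_noise * 4, -lim, lim), ncol = 4)
    )
    blob_id <- c(blob_id, rep(0L, cluster_noise))
  }

  list(
    hbond_geom = hbond_geom,
    noe_geom = noe_geom,
    features = features,
    feature_states = frame_states,
    cluster_features = cluster_features,
    cluster_truth = blob_id,
    truth = list(
      hbond_occupancy = mutate(
        hbond_occupancy,
        occupancy_exact = round(.data$occupancy * n_frames) / n_frames
      ),
      noe_distances = noe_distances,
      informative_features = paste0("info", seq_len(n_informative)),
      n_clusters = n_clusters,
      seed = seed
    )
  )
}

#' Markov binary-state series with a planted flip rate
#'
#' Two-state (cis/trans) Markov chain fixture for the transition-rate
#' diagnostic: each frame flips state with probability `p_flip`.
#'
#' @param n Number of frames.
#' @param p_flip Per-frame flip probability.
#' @param seed Integer seed (required).
#' @return Integer vector of 0/1 states.
#' @export
make_markov_states <- function(n, p_flip, seed) {
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  set.seed(seed)
  flips <- runif(n - 1) < p_flip
  c(0L, cumsum(flips) %% 2L)
}

#' Correlated binary-state series with a planted phi coefficient
#'
#' Draws two Bernoulli(0.5) series whose Pearson (phi) correlation is
#' `phi`, for the state-correlation diagnostic.
#'
#' @param n Number of frames.
#' @param phi Target phi coefficient in `[-1, 1]`.
#' @param seed Integer seed (required).
#' @return A two-column 0/1 matrix.
#' @export
make_correlated_states <- function(n, phi, seed) {
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  if (abs(phi) > 1) abort("`phi` must be in [-1, 1].")
  set.seed(seed)
  # joint cell probabilities of a symmetric 2x2 table with correlation phi
  p11 <- (1 + phi) / 4
  p10 <- (1 - phi) / 4
  u <- runif(n)
  a <- integer(n)
  b <- integer(n)
  both <- u < p11
  only_a <- u >= p11 & u < p11 + p10
  only_b <- u >= p11 + p10 & u < p11 + 2 * p10
  a[both | only_a] <- 1L
  b[both | only_b] <- 1L
  cbind(a, b)
}
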