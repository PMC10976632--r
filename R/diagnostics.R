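#' Label frames with cis/trans isomerization states
#'
#' Assigns each residue's omega angle to trans (`"T"`, 180 +/- halfwidth
#' degrees) or cis (`"C"`, 0 +/- halfwidth). With `halfwidth = 90` every
#' frame is labeled (the convention used for replica-1 state
#' integration); with the stricter `halfwidth = 45` used for trajectory
#' filtering, intermediate frames are left `NA` (unassigned).
#'
#' @param series Trajectory data frame with columns `omega2`, `omega3`,
#'   `omega7` (degrees).
#' @param halfwidth Half-width of the assignment windows in degrees
#'   (default 90).
#' @return The input as a tibble with added columns `s2`, `s3`, `s7`
#'   (`"T"`, `"C"` or `NA`) and `state` (three-letter label or `NA`);
#'   attribute `halfwidth` records the convention.
#' @export
label_states <- function(series, halfwidth = 90) {
  if (halfwidth <= 0 || halfwidth > 90) {
    abort("`halfwidth` must be in (0, 90] degrees.")
  }
  m <- .as_omega_matrix(series)
  lab1 <- function(w) {
    out <- rep(NA_character_, length(w))
    out[abs(wrap_angle(w)) <= halfwidth] <- "C"
    out[abs(wrap_angle(w - 180)) <= halfwidth] <- "T"
    out
  }
  out <- as_tibble(as.data.frame(series))
  out$s2 <- lab1(m[, 1])
  out$s3 <- lab1(m[, 2])
  out$s7 <- lab1(m[, 3])
  st <- paste0(out$s2, out$s3, out$s7)
  st[is.na(out$s2) | is.na(out$s3) | is.na(out$s7)] <- NA_character_
  out$state <- st
  attr(out, "halfwidth") <- halfwidth
  out
}

# 0/1/NA series per residue from a labeled trajectory
.binary_states <- function(labeled) {
  cols <- c("s2", "s3", "s7")
  if (!all(cols %in% names(labeled))) {
    abort("input must come from `label_states()` (columns s2, s3, s7).")
  }
  sapply(cols, function(cl) {
    v <- labeled[[cl]]
    ifelse(is.na(v), NA_real_, as.numeric(v == "T"))
  })
}

#' Running mean of isomerization states
#'
#' Centered running mean of the binary state series (trans = 1, cis = 0)
#' over `window` consecutive frames; values near 0.5 indicate balanced
#' cis/trans sampling. Windows at the series edges are truncated to the
#' available frames; unassigned frames are excluded from the mean.
#'
#' @param labeled Output of [label_states()].
#' @param window Window length in frames (default 100).
#' @return A tidy tibble with columns `frame`, `residue` (2, 3, 7) and
#'   `running_mean`.
#' @export
running_mean_states <- function(labeled, window = 100) {
  if (window < 1) abort("`window` must be >= 1.")
  b <- .binary_states(labeled)
  n <- nrow(b)
  before <- floor((window - 1) / 2)
  after <- window - 1 - before
  run1 <- function(x) {
    ok <- !is.na(x)
    v <- ifelse(ok, x, 0)
    cs_v <- cumsum(v)
    cs_n <- cumsum(as.numeric(ok))
    i <- seq_len(n)
    lo <- pmax(i - before, 1L)
    hi <- pmin(i + after, n)
    tot <- cs_v[hi] - ifelse(lo > 1, cs_v[lo - 1], 0)
    cnt <- cs_n[hi] - ifelse(lo > 1, cs_n[lo - 1], 0)
    ifelse(cnt > 0, tot / cnt, NA_real_)
  }
  purrr::map(1:3, function(j) {
    tibble(frame = seq_len(n), residue = .residues[j],
           running_mean = run1(b[, j]))
  }) |> bind_rows()
}

#' Cis/trans transition rates
#'
#' Counts isomerization-state changes between consecutive assigned
#' frames of each residue and divides by the time spanned by the series.
#' By default no transition is scored across an unassigned gap (the
#' stricter 45-degree labeling leaves barrier-top frames unassigned);
#' set `count_across_gaps = TRUE` to score a transition whenever the
#' labels flanking a gap differ.
#'
#' @param labeled Output of [label_states()].
#' @param time_per_frame Simulated time per saved frame (default 1, so
#'   the rate is per frame; pass e.g. 0.04 for 40 ps frames and ns^-1
#'   rates).
#' @param count_across_gaps Score a transition when the labels flanking
#'   an unassigned gap differ (default FALSE).
#' @return A tibble with columns `residue`, `n_transitions`, `rate`.
#' @export
transition_rate <- function(labeled, time_per_frame = 1,
                            count_across_gaps = FALSE) {
  b <- .binary_states(labeled)
  n <- nrow(b)
  if (n < 2) abort("need at least two frames.")
  span <- (n - 1) * time_per_frame
  if (count_across_gaps) {
    counts <- apply(b, 2, function(x) {
      x <- x[!is.na(x)]
      if (length(x) < 2) return(0L)
      sum(diff(x) != 0)
    })
  } else {
    # only transitions between directly consecutive assigned frames
    counts <- apply(b, 2, function(x) {
      d <- diff(x)
      sum(d != 0, na.rm = TRUE)
    })
  }
  counts <- unname(counts)
  tibble(
    residue = .residues,
    n_transitions = as.integer(counts),
    rate = counts / span
  )
}

#' Pearson correlation of residue isomerization states
#'
#' Correlation matrix of the three binary (trans = 1, cis = 0) state
#' series over the frames where all residues are assigned. Values near
#' zero indicate independent isomerization sampling; +/-1 would mean the
#' residues always switch together.
#'
#' @param labeled Output of [label_states()].
#' @return A 3 x 3 correlation matrix with dimnames `Pro2`, `Pro3`,
#'   `Pro7` (diagonal 1).
#' @export
state_correlation <- function(labeled) {
  b <- .binary_states(labeled)
  keep <- stats::complete.cases(b)
  if (sum(keep) < 3) abort("too few commonly assigned frames.")
  r <- cor(b[keep, , drop = FALSE])
  dimnames(r) <- list(paste0("Pro", .residues), paste0("Pro", .residues))
  r
}
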