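#' NOE upper-bound mapping
#'
#' Experimental upper bounds for NOE intensity classes: strong 3.0,
#' medium 3.5, weak 4.0, very weak 4.5 Angstrom.
#'
#' @param class Character vector over `c("s", "m", "w", "vw")`.
#' @return Upper bounds in Angstrom.
#' @export
noe_bound <- function(class) {
  map <- c(s = 3.0, m = 3.5, w = 4.0, vw = 4.5)
  if (!all(class %in% names(map))) {
    abort('NOE intensity class must be one of "s", "m", "w", "vw".')
  }
  unname(map[class])
}

#' NOE upper-bound violation
#'
#' Violation of one distance restraint over an ensemble of frames:
#' the inverse-6th-power averaged proton-proton distance minus the
#' experimental upper bound, `Delta = <r^-6>^(-1/6) - bound`. Positive
#' values mean the ensemble is inconsistent with the NOE.
#'
#' @param distances Instantaneous proton-proton distances in Angstrom
#'   (one per frame).
#' @param bound Experimental upper bound in Angstrom (see [noe_bound()]).
#' @return The violation Delta in Angstrom (negative = satisfied).
#' @examples
#' noe_violation(rep(3.5, 100), 3.0)   # +0.5: violated
#' noe_violation(c(2.5, 5.0), 3.0)     # r^-6 averaging favors the short frame
#' @export
noe_violation <- function(distances, bound) {
  if (length(distances) == 0) abort("`distances` is empty.")
  if (any(distances <= 0)) abort("distances must be positive.")
  mean(distances^-6)^(-1 / 6) - bound
}

#' Per-state NOE violation report
#'
#' Evaluates every restraint against the frames of each isomerization
#' state.
#'
#' @param distances Long tibble of per-frame distances: columns `pair`,
#'   `r` (Angstrom) and optionally `state`.
#' @param restraints Restraint table: columns `pair` and `class`
#'   (intensity class, see [noe_bound()]).
#' @param by_state Split by the `state` column if present (default TRUE).
#' @return A tibble with columns (`state`,) `pair`, `class`, `bound`,
#'   `violation`, `violated`.
#' @export
noe_report <- function(distances, restraints, by_state = TRUE) {
  if (!all(c("pair", "r") %in% names(distances))) {
    abort("`distances` needs columns `pair` and `r`.")
  }
  if (!all(c("pair", "class") %in% names(restraints))) {
    abort("`restraints` needs columns `pair` and `class`.")
  }
  restraints <- mutate(restraints, bound = noe_bound(.data$class))
  grouping <- if (by_state && "state" %in% names(distances)) {
    c("state", "pair")
  } else {
    "pair"
  }
  distances |>
    dplyr::inner_join(restraints, by = "pair") |>
    group_by(across(dplyr::all_of(c(grouping, "class", "bound")))) |>
    summarise(violation = noe_violation(.data$r, .data$bound[1]),
              .groups = "drop") |>
    mutate(violated = .data$violation > 0)
}

#' Hydrogen-bond detection
#'
#' A donor-H-acceptor contact is counted when the donor-hydrogen-acceptor
#' angle is at least `angle_min` and the donor-acceptor distance is below
#' `dist_max` (3.0 Angstrom by default; 3.5 is the looser criterion used
#' for occupancy bookkeeping of weak contacts).
#'
#' @param geom Long tibble of per-frame hydrogen-bond geometry: columns
#'   `bond`, `dist` (donor-acceptor distance, Angstrom), `angle`
#'   (donor-H-acceptor angle, degrees) and optionally `frame`, `state`.
#' @param angle_min Minimum angle in degrees (default 135).
#' @param dist_max Maximum donor-acceptor distance in Angstrom
#'   (default 3.0).
#' @return `detect_hbonds()`: the input with a logical `contact` column.
#' @export
detect_hbonds <- function(geom, angle_min = 135, dist_max = 3.0) {
  if (!all(c("bond", "dist", "angle") %in% names(geom))) {
    abort("`geom` needs columns `bond`, `dist`, `angle`.")
  }
  if (any(geom$dist <= 0)) abort("distances must be positive.")
  if (any(geom$angle < 0 | geom$angle > 180)) {
    abort("angles must be within [0, 180] degrees.")
  }
  mutate(geom, contact = .data$angle >= angle_min & .data$dist < dist_max)
}

#' @rdname detect_hbonds
#' @param by_state Split occupancies by the `state` column if present
#'   (default TRUE).
#' @return `hbond_occupancy()`: a tibble of occupancy fractions per bond
#'   (and state).
#' @export
hbond_occupancy <- function(geom, angle_min = 135, dist_max = 3.0,
                            by_state = TRUE) {
  flagged <- detect_hbonds(geom, angle_min, dist_max)
  grouping <- if (by_state && "state" %in% names(geom)) {
    c("bond", "state")
  } else {
    "bond"
  }
  flagged |>
    group_by(across(dplyr::all_of(grouping))) |>
    summarise(n_frames = n(), occupancy = mean(.data$contact),
              .groups = "drop")
}

#' Scale donor-acceptor distances into cluster features
#'
#' `d_scaled = (d - 1.8)^2` (Angstrom): short contacts get high weight
#' and the density of long-distance noise is compressed, which improves
#' the subsequent density-based clustering.
#'
#' @param d Distances in Angstrom.
#' @return Scaled feature values.
#' @export
scale_distances <- function(d) {
  (d - 1.8)^2
}

#' Rank features by discriminative importance
#'
#' Trains a random-forest classifier of the isomerization-state labels
#' on the feature matrix (classes weighted inversely to their frequency)
#' and returns the features ordered by impurity-based importance. Used
#' to pick the hydrogen-bond distances best suited to discriminate the
#' eight states before clustering.
#'
#' @param features Frame x feature data frame or matrix.
#' @param labels Per-frame state labels (character or factor; frames with
#'   `NA` labels are dropped).
#' @param num_trees Number of trees (default 200).
#' @param seed Integer seed (required: the forest is stochastic).
#' @return A tibble with columns `feature`, `importance`, sorted by
#'   decreasing importance.
#' @export
rank_features <- function(features, labels, num_trees = 200, seed) {
  if (missing(seed)) abort("`seed` is required for reproducibility.")
  features <- as.data.frame(features)
  keep <- !is.na(labels)
  features <- features[keep, , drop = FALSE]
  labels <- factor(labels[keep])
  if (nlevels(droplevels(labels)) < 2) {
    abort("need at least 2 classes present to rank features.")
  }
  labels <- droplevels(labels)
  w <- 1 / table(labels)
  w <- as.numeric(w / sum(w))
  dat <- cbind(features, .state = labels)
  set.seed(seed)
  fit <- ranger::ranger(
    dependent.variable.name = ".state", data = dat,
    num.trees = num_trees, importance = "impurity",
    class.weights = w, seed = seed, num.threads = 1
  )
  imp <- fit$variable.importance
  tibble(feature = names(imp), importance = unname(imp)) |>
    arrange(desc(.data$importance))
}

#' Density-based conformational clustering
#'
#' Hierarchical density-based clustering (mutual-reachability single
#' linkage with excess-of-mass cluster selection) of the frames in
#' feature space. Points in no dense region are labeled 0 (outliers);
#' clusters smaller than `min_cluster_size` are never reported, and a
#' single all-encompassing cluster is not reported either (pure noise
#' yields no clusters).
#'
#' @param features Frame x feature data frame or matrix (typically the
#'   top-ranked scaled distances from [rank_features()] /
#'   [scale_distances()]).
#' @param min_cluster_size Smallest reportable cluster (default 500).
#' @param min_samples Neighborhood size for the core-distance estimate
#'   (default 10).
#' @return An integer vector of cluster labels (0 = outlier), with
#'   attribute `n_clusters`.
#' @export
cluster_conformations <- function(features, min_cluster_size = 500,
                                  min_samples = 10) {
  x <- as.matrix(features)
  if (min_cluster_size < 2) abort("`min_cluster_size` must be >= 2.")
  if (nrow(x) < min_cluster_size) {
    out <- rep(0L, nrow(x))
    attr(out, "n_clusters") <- 0L
    return(out)
  }
  .hdbscan(x, min_cluster_size, min_samples)
}

#' Cluster on the most discriminative features
#'
#' The combined workflow used for conformational analysis: rank the
#' (scaled-distance) features by their power to discriminate the
#' isomerization states ([rank_features()]), keep the `k` best, and run
#' the density-based clustering on those.
#'
#' @inheritParams rank_features
#' @inheritParams cluster_conformations
#' @param k Number of top-ranked features passed to the clustering
#'   (default 20, capped at the number of available features).
#' @return As [cluster_conformations()], with attribute `features_used`
#'   naming the selected columns.
#' @export
cluster_by_ranked_features <- function(features, labels, k = 20,
                                       min_cluster_size = 500,
                                       min_samples = 10, num_trees = 200,
                                       seed) {
  rk <- rank_features(features, labels, num_trees = num_trees, seed = seed)
  keep <- rk$feature[seq_len(min(k, nrow(rk)))]
  labels_out <- cluster_conformations(
    as.data.frame(features)[keep],
    min_cluster_size = min_cluster_size, min_samples = min_samples
  )
  attr(labels_out, "features_used") <- keep
  labels_out
}
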