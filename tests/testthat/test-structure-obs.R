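test_that("NOE violations use inverse-6th-power averaging", {
  expect_equal(noe_violation(rep(3.0, 10), 4.5), -1.5)
  expect_equal(noe_violation(rep(3.5, 10), 3.0), 0.5)
  # hand-computed two-value series: <r^-6> = 2.080e-3 -> r_eff = 2.799
  d <- rep(c(2.5, 5.0), 50)
  r_eff <- mean(d^-6)^(-1 / 6)
  expect_equal(r_eff, 2.799, tolerance = 1e-3)
  expect_equal(noe_violation(d, 3.0), r_eff - 3.0)
  expect_lt(noe_violation(d, 3.0), 0)

  # r^-6 averaging equals r for constant series and is monotone in r
  expect_equal(noe_violation(rep(4.2, 5), 0), 4.2)
  base <- runif(100, 2, 6)
  up <- base
  up[17] <- up[17] + 0.5
  expect_gt(noe_violation(up, 3), noe_violation(base, 3))
  expect_error(noe_violation(numeric(0), 3), "empty")
  expect_error(noe_bound("x"))
  expect_equal(noe_bound(c("s", "m", "w", "vw")), c(3, 3.5, 4, 4.5))
})

test_that("per-state NOE report flags violated restraints", {
  fix <- make_geometry_fixture(n_frames = 50, states = c("TTT", "TCT"),
                               noe_distances = tibble::tibble(
                                 pair = c("a", "b"), r = c(3.5, 2.0)
                               ),
                               seed = 2)
  restr <- tibble::tibble(pair = c("a", "b"), class = c("s", "s"))
  rep <- noe_report(fix$noe_geom, restr)
  expect_equal(nrow(rep), 4)  # 2 states x 2 pairs
  expect_true(all(rep$violated[rep$pair == "a"]))   # 3.5 > bound 3.0
  expect_false(any(rep$violated[rep$pair == "b"]))  # 2.0 < 3.0
  expect_equal(rep$violation[rep$pair == "a"][1], 0.5, tolerance = 1e-12)
})

test_that("hydrogen-bond detection applies both geometric criteria", {
  g <- tibble::tibble(
    bond = "x",
    dist = c(2.9, 2.5, 3.2, 2.8),
    angle = c(140, 130, 160, 134.9)
  )
  flags <- detect_hbonds(g)$contact
  expect_equal(flags, c(TRUE, FALSE, FALSE, FALSE))
  # looser distance criterion admits the 3.2 A contact
  expect_equal(detect_hbonds(g, dist_max = 3.5)$contact,
               c(TRUE, FALSE, TRUE, FALSE))
  expect_error(detect_hbonds(tibble::tibble(bond = "x", dist = -1,
                                            angle = 140)))
})

test_that("planted hydrogen-bond occupancies are recovered exactly", {
  occ <- tibble::tibble(
    bond = "Ser6O-Arg9H",
    state = c("TTT", "TCT", "CTT", "CCT"),
    occupancy = c(0.308, 0.072, 0.043, 0.107)
  )
  fix <- make_geometry_fixture(n_frames = 1000, hbond_occupancy = occ,
                               seed = 6)
  got <- hbond_occupancy(fix$hbond_geom, dist_max = 3.5)
  for (i in seq_len(nrow(occ))) {
    expect_equal(got$occupancy[got$state == occ$state[i]],
                 occ$occupancy[i])
  }
  # identical under the strict 3.0 A criterion by fixture construction
  strict <- hbond_occupancy(fix$hbond_geom, dist_max = 3.0)
  expect_equal(strict$occupancy, got$occupancy)
})

test_that("distance scaling is the squared offset from contact range", {
  expect_equal(scale_distances(1.8), 0)
  expect_equal(scale_distances(2.8), 1)
  expect_equal(scale_distances(3.8), 4)
  expect_equal(scale_distances(c(2.3, 4.8)), c(0.25, 9))
})

test_that("feature ranking puts informative features on top, deterministically", {
  fix <- make_geometry_fixture(n_frames = 120, n_informative = 2,
                               n_noise = 20, seed = 14)
  rk <- rank_features(fix$features, fix$feature_states, seed = 14)
  expect_equal(nrow(rk), 22)
  expect_true(all(fix$truth$informative_features %in% rk$feature[1:3]))
  # informative features dominate across seeds
  for (s in c(1, 2, 3)) {
    rks <- rank_features(fix$features, fix$feature_states, seed = s)
    expect_true(all(fix$truth$informative_features %in% rks$feature[1:3]))
  }
  # same seed -> identical ranking
  rk2 <- rank_features(fix$features, fix$feature_states, seed = 14)
  expect_identical(rk, rk2)
  expect_error(
    rank_features(fix$features, rep("TTT", nrow(fix$features)), seed = 1),
    "2 classes"
  )
})

test_that("density-based clustering finds planted blobs and rejects noise", {
  fix <- make_geometry_fixture(n_frames = 10, n_clusters = 3,
                               cluster_size = 1000, seed = 23)
  labels <- cluster_conformations(fix$cluster_features,
                                  min_cluster_size = 500)
  expect_equal(attr(labels, "n_clusters"), 3)
  expect_lt(mean(labels == 0), 0.05)
  # membership counts plus outliers account for every frame
  expect_equal(sum(table(labels)), nrow(fix$cluster_features))
  # each planted blob maps to one found cluster
  purity <- sapply(1:3, function(b) {
    found <- labels[fix$cluster_truth == b]
    max(table(found)) / length(found)
  })
  expect_true(all(purity > 0.95))

  # pure uniform noise yields no clusters
  set.seed(31)
  noise <- matrix(runif(1500 * 4, -10, 10), ncol = 4)
  ln <- cluster_conformations(noise, min_cluster_size = 500)
  expect_equal(attr(ln, "n_clusters"), 0)
  expect_true(all(ln == 0))

  # a blob below the minimum cluster size is never reported
  small <- matrix(rnorm(300 * 4, sd = 0.3), ncol = 4)
  ls <- cluster_conformations(small, min_cluster_size = 500)
  expect_equal(attr(ls, "n_clusters"), 0)
})

test_that("ranked-feature clustering selects informative columns first", {
  fix <- make_geometry_fixture(n_frames = 150, n_informative = 2,
                               n_noise = 8, seed = 41)
  # separable classes concentrate in feature space along the
  # informative axes; noise-only clustering would find nothing
  lab <- cluster_by_ranked_features(fix$features, fix$feature_states,
                                    k = 2, min_cluster_size = 100,
                                    seed = 41)
  expect_true(all(fix$truth$informative_features %in%
                    attr(lab, "features_used")))
  expect_gt(attr(lab, "n_clusters"), 1)
  expect_equal(length(lab), nrow(fix$features))
})
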