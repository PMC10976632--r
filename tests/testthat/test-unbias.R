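test_that("histogramming bins frames correctly and normalizes", {
  d <- histogram3d(matrix(c(0, 0, 0), 1), n_bins = 50)
  expect_equal(sum(d$values > 0), 1)
  expect_equal(sum(d$values) * d$bin_width^3, 1, tolerance = 1e-10)
  expect_error(histogram3d(matrix(numeric(0), ncol = 3)), "empty")

  # uniform samples give a flat histogram within counting noise
  set.seed(1)
  n <- 1e5
  u <- matrix(runif(3 * n, -180, 180), ncol = 3)
  du <- histogram3d(u, n_bins = 10)
  counts <- du$values * n * du$bin_width^3
  lambda <- n / 10^3
  expect_lt(max(abs(counts - lambda)) / sqrt(lambda), 5)
})

test_that("unbiasing at zero bias is the identity", {
  cal <- bk_model()
  s <- sample_iid_density(cal, 2e4, seed = 4)
  d <- histogram3d(s)
  d0 <- unbias_density(d, 0, 300)
  expect_equal(d0$values, d$values)
  expect_false(d0$biased)
})

test_that("unbiasing biased samples recovers the model density (oracle round trip)", {
  cal <- bk_model()
  s <- sample_iid_density(cal, 1e6, bias_force_constant = 1, seed = 8)
  unb <- unbias_density(histogram3d(s), 1, 300)
  # bin-averaged reference, comparable to a histogram estimate
  ref <- density_from_model(cal, 50, supersample = 3)
  # compare well-populated bins (expected count >= 1e4) bin-for-bin
  n_eff <- histogram3d(s)$values * 1e6 * unb$bin_width^3
  sel <- n_eff >= 1e4
  expect_gt(sum(sel), 5)
  rel <- abs(unb$values[sel] - ref$values[sel]) / ref$values[sel]
  expect_lt(max(rel), 0.05)
  # and the recovered state free energies match the calibration targets
  fe <- free_energy_table(unb)
  expect_equal(tidy(fe)$free_energy, bk_state_table()$free_energy,
               tolerance = 0.08)
})

test_that("unbiasing a uniform density yields the inverse-bias profile", {
  d <- uniform_density3d(50)
  out <- unbias_density(d, 1, 300)
  # along one axis the profile is proportional to exp(+beta bias)
  b <- 1 + cos((out$axis - 180) * pi / 180)
  prof <- out$values[, 1, 1]
  expected <- exp(b / KT300)
  expect_equal(prof / max(prof), expected / max(expected), tolerance = 1e-10)
  # global maximum sits at the all-trans corner
  peak <- which(out$values == max(out$values), arr.ind = TRUE)[1, ]
  expect_true(all(abs(abs(out$axis[peak]) - 176.4) < 1e-9))
})

test_that("state probabilities integrate octants and sum to one", {
  u <- uniform_density3d(50)
  p <- state_probabilities(u)
  expect_equal(p$probability, rep(0.125, 8), tolerance = 1e-12)
  expect_equal(state_probability(u, "TCT"), 0.125, tolerance = 1e-12)
  expect_error(state_probability(u, "TTX"), "labels")

  # density concentrated in a single octant
  one <- histogram3d(matrix(c(170, 175, -5), 1))
  p1 <- state_probabilities(one)
  expect_equal(p1$probability[p1$state == "TTC"], 1)
  expect_equal(sum(p1$probability), 1)

  cal <- bk_model()
  ref <- density_from_model(cal, 50)
  expect_equal(state_probability(ref, "TTT"), 0.9032, tolerance = 2e-3)
})

test_that("Boltzmann inversion gives the closed-form free energies", {
  u <- uniform_density3d(50)
  fe0 <- free_energy_table(u)
  expect_equal(tidy(fe0)$free_energy, rep(0, 8), tolerance = 1e-12)

  cal <- bk_model()
  fe <- free_energy_table(density_from_model(cal, 50))
  g <- tidy(fe)$free_energy
  expect_equal(g, bk_state_table()$free_energy, tolerance = 0.02)
  # two-state closed form on the same table: P ratio 88:12 <-> 1.188
  p <- tidy(fe)$probability
  expect_equal(-KT300 * log(0.12 / 0.88), 1.188, tolerance = 1e-3)

  # empty octants warn and go to +Inf
  one <- histogram3d(matrix(c(0, 0, 0), 1))
  expect_warning(fe1 <- free_energy_table(one), "Inf")
  expect_true(is.infinite(tidy(fe1)$free_energy[2]))
})

test_that("projections conserve normalization and factor for product densities", {
  m <- model_potential(force_constants = c(0.5, 1.0, 1.5))
  d <- density_from_model(m, 50)
  m1 <- project_density(d, 2)
  expect_equal(sum(m1$values) * m1$bin_width, 1, tolerance = 1e-10)
  m2 <- project_density(d, c(2, 7))
  expect_equal(sum(m2$values) * m2$bin_width^2, 1, tolerance = 1e-10)
  # independent torsions: the 2D projection is the product of marginals
  a <- project_density(d, 2)$values
  b <- project_density(d, 7)$values
  expect_lt(max(abs(m2$values - outer(a, b))), 1e-10)
  expect_error(project_density(d, integer(0)))
  expect_error(project_density(d, c(2, 3, 7)))
})

test_that("1D PMF recovers the torsion profile by Boltzmann inversion", {
  m <- model_potential(force_constants = c(1.2, 1.2, 1.2))
  marg <- project_density(density_from_model(m, 50), 3)
  pmf <- pmf_1d(marg, 300)
  ref <- eval_physical_torsion(pmf$omega, 1.2)
  expect_equal(pmf$free_energy, ref - min(ref), tolerance = 1e-9)
  # flat marginal -> flat profile at zero
  flat <- project_density(uniform_density3d(50), 2)
  expect_equal(pmf_1d(flat, 300)$free_energy, rep(0, 50), tolerance = 1e-12)
})

test_that("marginal isomerization free energy follows its sign convention", {
  # symmetric double well -> zero
  m <- model_potential(force_constants = c(1, 1, 1))
  marg <- project_density(density_from_model(m, 50), 2)
  expect_equal(isomerization_dG(marg, 300), 0, tolerance = 1e-10)

  # trans:cis = 88:12 -> -1.188 kcal/mol (trans favored -> negative)
  tg <- setNames(numeric(8), state_labels())
  tg[c("CTT", "CTC", "CCT", "CCC")] <- 1.1877  # Pro2 cis costs 1.1877
  m2 <- calibrate_model(tg)
  marg2 <- project_density(density_from_model(m2, 50), 2)
  expect_equal(isomerization_dG(marg2, 300), -1.1877, tolerance = 5e-3)

  # mixture identity: marginal split equals the octant-sum split
  cal <- bk_model()
  d <- density_from_model(cal, 50)
  p <- state_probabilities(d)
  pt <- sum(p$probability[substr(p$state, 1, 1) == "T"])
  dg_marg <- isomerization_dG(project_density(d, 2), 300)
  dg_oct <- -KT300 * log(pt / (1 - pt))
  expect_equal(dg_marg, dg_oct, tolerance = 1e-3)
})

test_that("conditional free energies reproduce the octant differences", {
  cal <- bk_model()
  d <- density_from_model(cal, 50)
  # Pro7 prefers cis when Pro2 is cis and Pro3 trans: +0.89
  c7 <- conditional_dG(d, 7, c("C", "T"))
  expect_equal(c7$dG_cis_to_trans, 0.89, tolerance = 0.02)
  # Pro2 with both others trans: cis costs 4.09
  c2 <- conditional_dG(d, 2, c("T", "T"))
  expect_equal(c2$dG_cis_to_trans, -4.09, tolerance = 0.02)
  # coupling shift when Pro7 switches to cis at Pro3 trans
  tab <- conditional_dG_table(d)
  dd <- tab$ddG[tab$residue == 2 & tab$condition == "3T,7C"]
  expect_equal(dd, 2.51, tolerance = 0.03)

  # independent residues: all four conditions give the same dG
  tg <- setNames(numeric(8), state_labels())
  tg[c("CTT", "CTC", "CCT", "CCC")] <- 0.8
  mi <- calibrate_model(tg)
  ti <- conditional_dG_table(density_from_model(mi, 50))
  for (r in c(3, 7)) {
    vals <- ti$dG_cis_to_trans[ti$residue == r]
    expect_lt(max(vals) - min(vals), 0.02)
  }
})

test_that("conditional free energies close the thermodynamic cycle", {
  cal <- bk_model()
  d <- density_from_model(cal, 50)
  tab <- conditional_dG_table(d)
  dg <- function(r, cond) {
    tab$dG_cis_to_trans[tab$residue == r & tab$condition == cond]
  }
  # for each pair (i, j), third residue fixed:
  # dG_i(j=T) - dG_i(j=C) == dG_j(i=T) - dG_j(i=C)
  closures <- c(
    (dg(2, "3T,7T") - dg(2, "3C,7T")) - (dg(3, "2T,7T") - dg(3, "2C,7T")),
    (dg(2, "3T,7C") - dg(2, "3C,7C")) - (dg(3, "2T,7C") - dg(3, "2C,7C")),
    (dg(2, "3T,7T") - dg(2, "3T,7C")) - (dg(7, "2T,3T") - dg(7, "2C,3T")),
    (dg(3, "2T,7T") - dg(3, "2T,7C")) - (dg(7, "2T,3T") - dg(7, "2T,3C"))
  )
  expect_lt(max(abs(closures)), 1e-8)
  # octant free energies and conditionals are mutually consistent
  g <- tidy(free_energy_table(d))$free_energy
  names(g) <- state_labels()
  expect_equal(dg(2, "3T,7T"), g[["TTT"]] - g[["CTT"]], tolerance = 1e-10)
  expect_equal(dg(7, "2C,3T"), g[["CTT"]] - g[["CTC"]], tolerance = 1e-10)
})

test_that("block SEM matches sampling theory and handles edge cases", {
  expect_equal(block_sem(rep(3.2, 1000)), 0)
  set.seed(2)
  x <- rnorm(5000)
  sem <- block_sem(x)
  # five blocks of 1000: SEM of the grand mean ~ 1/sqrt(5000)
  expect_gt(sem, 1 / sqrt(5000) / 2)
  expect_lt(sem, 2 / sqrt(5000))
  # definition: sd of block means over sqrt(n_blocks)
  bm <- sapply(1:5, function(b) mean(x[((b - 1) * 1000 + 1):(b * 1000)]))
  expect_equal(sem, sd(bm) / sqrt(5))
  # vector statistics are handled elementwise
  sems <- block_sem(cbind(x, 2 * x), statistic = colMeans)
  expect_equal(sems[2], 2 * sems[1], tolerance = 1e-12)
  expect_error(block_sem(1:3, n_blocks = 5))
})

test_that("the full replica-1 analysis attaches block errors", {
  cal <- bk_model()
  s <- sample_iid_density(cal, 1e5, bias_force_constant = 1, seed = 12)
  a <- analyze_replica1(s)
  st <- tidy(a$fe)
  expect_equal(sum(st$probability), 1, tolerance = 1e-8)
  expect_true(all(is.finite(st$probability_sem)))
  expect_equal(st$free_energy_sem[1], 0)  # TTT is the reference
  expect_equal(st$probability[1], 0.903, tolerance = 3 * st$probability_sem[1] + 0.01)
  expect_equal(nrow(a$conditionals), 12)
  expect_false(a$density$biased)
  expect_true(a$biased_density$biased)
})
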