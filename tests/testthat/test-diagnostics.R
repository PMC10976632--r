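test_that("state labeling respects the halfwidth convention", {
  traj <- tibble::tibble(
    omega2 = c(170, 100, -5, 50),
    omega3 = c(-170, 0, 130, -130),
    omega7 = c(10, 44, -46, 91)
  )
  wide <- label_states(traj, halfwidth = 90)
  expect_equal(wide$s2, c("T", "T", "C", "C"))
  expect_equal(wide$s3, c("T", "C", "T", "T"))
  expect_equal(wide$s7, c("C", "C", "C", "T"))
  expect_false(anyNA(wide$state))

  strict <- label_states(traj, halfwidth = 45)
  expect_equal(strict$s2, c("T", NA, "C", NA))
  expect_equal(strict$s7, c("C", "C", NA, NA))
  expect_true(is.na(strict$state[2]))

  # planted counts on a synthetic composition
  n <- c(TTT = 30, TTC = 20, CCC = 7)
  w <- do.call(rbind, purrr::map2(names(n), n, function(s, k) {
    ang <- ifelse(strsplit(s, "")[[1]] == "T", 180, 0)
    matrix(rep(ang, k), ncol = 3, byrow = TRUE)
  }))
  colnames(w) <- c("omega2", "omega3", "omega7")
  lab <- label_states(as.data.frame(w), halfwidth = 45)
  expect_equal(as.numeric(table(lab$state)[names(n)]), as.numeric(n))
})

test_that("running mean of states tracks the trans fraction", {
  all_trans <- tibble::tibble(omega2 = rep(180, 200), omega3 = 180,
                              omega7 = 180)
  rm1 <- running_mean_states(label_states(all_trans), window = 100)
  expect_true(all(rm1$running_mean == 1))

  # strict alternation hovers at 0.5
  alt <- tibble::tibble(omega2 = rep(c(180, 0), 150), omega3 = 180,
                        omega7 = 0)
  rm2 <- running_mean_states(label_states(alt), window = 100)
  v <- rm2$running_mean[rm2$residue == 2]
  expect_lt(max(abs(v - 0.5)), 0.01)
  expect_true(all(rm2$running_mean >= 0 & rm2$running_mean <= 1))

  # 75 trans + 25 cis in a window -> 0.75 at its centre
  mix <- tibble::tibble(
    omega2 = c(rep(180, 75), rep(0, 25)), omega3 = 180, omega7 = 180
  )
  rm3 <- running_mean_states(label_states(mix), window = 100)
  centre <- rm3$running_mean[rm3$residue == 2][50]
  expect_equal(centre, 0.75)

  # long-run average equals the trans fraction
  set.seed(7)
  rnd <- tibble::tibble(omega2 = ifelse(runif(5000) < 0.3, 180, 0),
                        omega3 = 180, omega7 = 0)
  rm4 <- running_mean_states(label_states(rnd), window = 100)
  frac <- mean(label_states(rnd)$s2 == "T")
  expect_equal(mean(rm4$running_mean[rm4$residue == 2]), frac,
               tolerance = 0.01)
})

test_that("transition rates count state changes per unit time", {
  const <- tibble::tibble(omega2 = rep(180, 100), omega3 = 180, omega7 = 0)
  expect_equal(transition_rate(label_states(const))$n_transitions,
               c(0L, 0L, 0L))

  alt <- tibble::tibble(omega2 = rep(c(180, 0), 50), omega3 = 180,
                        omega7 = 180)
  tr <- transition_rate(label_states(alt))
  expect_equal(tr$n_transitions[tr$residue == 2], 99L)
  expect_equal(tr$rate[tr$residue == 2], 1)

  # Markov fixture: flips with probability p per frame
  p <- 0.05
  n <- 2e4
  st <- make_markov_states(n, p, seed = 5)
  traj <- tibble::tibble(omega2 = ifelse(st == 1, 180, 0), omega3 = 180,
                         omega7 = 0)
  rate <- transition_rate(label_states(traj))$rate[1]
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(rate - p), 3 * se)

  # invariance under global cis/trans relabeling
  flipped <- tibble::tibble(omega2 = ifelse(st == 1, 0, 180), omega3 = 0,
                            omega7 = 180)
  expect_equal(transition_rate(label_states(flipped))$rate[1], rate)

  # no transition scored across an unassigned gap by default
  gap <- tibble::tibble(omega2 = c(180, 180, 100, 0, 0), omega3 = 180,
                        omega7 = 180)
  lab45 <- label_states(gap, halfwidth = 45)
  expect_equal(transition_rate(lab45)$n_transitions[1], 0L)
  expect_equal(
    transition_rate(lab45, count_across_gaps = TRUE)$n_transitions[1], 1L
  )

  # time units: 0.04 ns per frame turns counts into ns^-1
  tr_ns <- transition_rate(label_states(alt), time_per_frame = 0.04)
  expect_equal(tr_ns$rate[1], 99 / (99 * 0.04))
})

test_that("state correlations recover planted dependence", {
  # identical series -> R = 1
  same <- tibble::tibble(omega2 = rep(c(180, 0), 50),
                         omega3 = rep(c(180, 0), 50),
                         omega7 = rep(c(0, 180), 50))
  r <- state_correlation(label_states(same))
  expect_equal(unname(diag(r)), c(1, 1, 1))
  expect_equal(r["Pro2", "Pro3"], 1)
  expect_equal(r["Pro2", "Pro7"], -1)

  # independent series -> |R| below 3/sqrt(n)
  set.seed(9)
  n <- 5000
  ind <- tibble::tibble(
    omega2 = sample(c(180, 0), n, replace = TRUE),
    omega3 = sample(c(180, 0), n, replace = TRUE),
    omega7 = sample(c(180, 0), n, replace = TRUE)
  )
  ri <- state_correlation(label_states(ind))
  expect_lt(max(abs(ri[upper.tri(ri)])), 3 / sqrt(n))

  # planted phi coefficient 0.3
  ab <- make_correlated_states(2e4, 0.3, seed = 3)
  tr <- tibble::tibble(omega2 = ifelse(ab[, 1] == 1, 180, 0),
                       omega3 = ifelse(ab[, 2] == 1, 180, 0),
                       omega7 = sample(c(180, 0), 2e4, replace = TRUE))
  rp <- state_correlation(label_states(tr))
  se <- (1 - 0.3^2) / sqrt(2e4)
  expect_lt(abs(rp["Pro2", "Pro3"] - 0.3), 3 * se)
})
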