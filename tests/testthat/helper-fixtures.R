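# shared fixtures, built once per test run

# model calibrated to the bradykinin reference state table
bk_model <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_model(bk_state_table())
    cache
  }
})

# kT at 300 K
KT300 <- 0.0019872 * 300

# SEM of a log-ratio free energy, propagated from the probability SEMs of
# the two octants (usable even when one block misses a rare state)
propagated_dG_sem <- function(fe, state_hi, state_lo) {
  st <- tidy(fe)
  a <- st[st$state == state_hi, ]
  b <- st[st$state == state_lo, ]
  KT300 * sqrt((a$probability_sem / a$probability)^2 +
                 (b$probability_sem / b$probability)^2)
}

# uniform density3d (all bins equal)
uniform_density3d <- function(n_bins = 50) {
  wbpremd:::new_density3d(array(1, rep(n_bins, 3)), biased = FALSE)
}
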