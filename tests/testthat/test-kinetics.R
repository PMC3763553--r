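ideal_from_path <- function(states, starts, durations, means_by_state,
                            id = "t") {
  total <- sum(durations)
  seg <- data.frame(state = states, start = starts, duration = durations,
                    mean_E = unname(means_by_state[states]))
  attr(seg, "trace_id") <- id
  attr(seg, "model_means") <- sort(unname(means_by_state))
  class(seg) <- c("idealized_trace", "data.frame")
  seg
}

test_that("extract_dwells censors first/last segments and partitions time", {
  means <- c(`1` = 0.7, `2` = 0.5)
  ideal <- ideal_from_path(c(1, 2, 1), c(0, 5, 8), c(5, 3, 4), means)
  d <- extract_dwells(ideal)
  expect_equal(nrow(d), 3)
  expect_equal(d$censored, c(TRUE, FALSE, TRUE))
  expect_equal(d$duration[!d$censored], 3)
  expect_equal(sum(d$duration), 12)  # partition of the trace
  # empty idealization -> empty set
  empty <- structure(data.frame(state = integer(0), start = numeric(0),
                                duration = numeric(0), mean_E = numeric(0)),
                     class = c("idealized_trace", "data.frame"))
  expect_equal(nrow(extract_dwells(empty)), 0)
})

test_that("uncensored dwell means match the generator", {
  m <- build_end_dynamics_model(0.25, 0.5, 1)  # M2 exit rate 0.5 -> mean 2 s
  set.seed(60)
  paths <- lapply(1:200, function(i)
    simulate_state_path(m, 150, initial_state = "stationary"))
  dwells <- extract_dwells_all(paths)
  d2 <- dwells[dwells$state == "M2" & !dwells$censored, "duration"]
  expect_gt(length(d2), 1000)
  expect_lt(abs(mean(d2) - 2), 0.2)
})

test_that("exponential dwell MLE is the sample mean with tau/sqrt(n) error", {
  fit <- fit_exponential_dwell(c(1, 2, 3), min_n = 3)
  expect_identical(fit$tau, 2)
  expect_equal(fit$stderr, 2 / sqrt(3))
  set.seed(61)
  x <- rexp(1000, 1 / 5)
  fit2 <- fit_exponential_dwell(x)
  expect_lt(abs(fit2$tau - 5), 0.5)
  expect_equal(fit2$n, 1000)
  expect_error(fit_exponential_dwell(numeric(0)), ">= 5")
  # censored dwells are excluded by default
  means <- c(`1` = 0.7, `2` = 0.5)
  ideal <- ideal_from_path(c(1, 2, 1, 2, 1, 2, 1), c(0, 1, 3, 6, 10, 15, 21),
                           c(1, 2, 3, 4, 5, 6, 7), means)
  fit3 <- fit_exponential_dwell(extract_dwells(ideal), state = "2", min_n = 3)
  expect_equal(fit3$tau, mean(c(2, 4, 6)))
})

test_that("nucleation kinetics recover frequency and lifetime", {
  # zero events
  quiet <- ideal_from_path("2", 0, 100, c(`2` = 0.7))
  attr(quiet, "model_means") <- c(0.2, 0.7)
  st0 <- nucleation_kinetics(list(quiet))
  expect_equal(st0$f_nuc, 0)
  expect_true(is.na(st0$tau))
  # generator oracle on ground-truth paths: k_nuc = 0.01, k_dis = 0.05
  m <- build_nucleation_model(0.01, 0.05)
  set.seed(62)
  paths <- lapply(1:100, function(i)
    simulate_state_path(m, 100, initial_state = "unbound"))
  st <- nucleation_kinetics(paths)
  expect_lt(abs(st$f_nuc - 0.01) / 0.01, 0.30)
  expect_lt(abs(st$tau - 20) / 20, 0.30)
  expect_gt(st$n_events, 0)
})

test_that("TDPs are empty for single-state traces and 4-peaked for the chain", {
  means <- c(`1` = 0.7)
  single <- ideal_from_path("1", 0, 50, means)
  tdp0 <- build_tdp(collect_transitions(list(single)))
  expect_equal(tdp0$n_transitions, 0)
  expect_equal(nrow(tdp_peaks(tdp0)), 0)
  expect_true(all(diag(tdp0$counts) == 0))

  # decoded end-dynamics chain: exactly 4 off-diagonal clusters
  means3 <- c(`1` = 0.3, `2` = 0.5, `3` = 0.7)
  set.seed(63)
  ideals <- lapply(1:30, function(i) {
    s <- 3; states <- integer(40)
    states[1] <- 3
    for (t in 2:40) {
      states[t] <- max(1, min(3, states[t - 1] + sample(c(-1, 1), 1)))
      if (states[t] == states[t - 1]) states[t] <- states[t - 1] +
          if (states[t - 1] == 3) -1 else 1
    }
    r <- rle(states)
    ideal_from_path(r$values, cumsum(c(0, head(r$lengths, -1))), r$lengths,
                    means3, id = paste0("t", i))
  })
  tr <- collect_transitions(ideals)
  expect_true(all(tr$state_before != tr$state_after))
  tdp <- build_tdp(tr)
  pk <- tdp_peaks(tdp)
  expect_equal(nrow(pk), 4)
  expect_true(all(diag(tdp$counts) == 0))
})

test_that("nucleation TDP has the two clusters of the two-state scheme", {
  m <- build_nucleation_model(0.05, 0.05)
  model <- hmm_model(c(0.2, 0.7), c(0.05, 0.05),
                     matrix(c(0.99, 0.01, 0.01, 0.99), 2, 2, byrow = TRUE),
                     c(0.5, 0.5))
  em <- nucleation_emission(bleach_rate = 0)
  set.seed(64)
  ideals <- lapply(1:40, function(i) {
    p <- simulate_state_path(m, 100, initial_state = "unbound")
    idealize(model, compute_fret(render_intensities(p, em)))
  })
  pk <- tdp_peaks(build_tdp(collect_transitions(ideals)))
  expect_equal(nrow(pk), 2)
  pk <- pk[order(pk$E_before), ]
  expect_equal(pk$E_before, c(0.2, 0.7), tolerance = 0.05)
  expect_equal(pk$E_after, c(0.7, 0.2), tolerance = 0.05)
})

test_that("rate estimator is unbiased on ground-truth paths", {
  k_on <- 0.2; k_off <- 0.1; conc <- 1
  m <- build_end_dynamics_model(k_on, k_off, conc)
  set.seed(65)
  paths <- lapply(1:150, function(i)
    simulate_state_path(m, 150, initial_state = "stationary"))
  r <- estimate_rates(paths, sequence_condition("truth", conc))
  expect_lt(abs(r$k_on - k_on), 3 * r$k_on_stderr)
  expect_lt(abs(r$k_off - k_off), 3 * r$k_off_stderr)
  expect_equal(r$n_skipped, 0)
})

test_that("k_on estimates agree across concentrations after division", {
  k_on <- 0.2; k_off <- 0.15
  set.seed(66)
  ests <- lapply(c(0.5, 1, 2), function(conc) {
    m <- build_end_dynamics_model(k_on, k_off, conc)
    paths <- lapply(1:120, function(i)
      simulate_state_path(m, 150, initial_state = "stationary"))
    estimate_rates(paths, sequence_condition(paste0("c", conc), conc))
  })
  for (r in ests) {
    expect_lt(abs(r$k_on - k_on), 3 * r$k_on_stderr)
    expect_lt(abs(r$k_off - k_off), 3 * r$k_off_stderr)
  }
})

test_that("estimate_rates refuses degenerate inputs", {
  means <- c(`1` = 0.7)
  single <- ideal_from_path("1", 0, 50, means)
  attr(single, "model_means") <- c(0.3, 0.5, 0.7)
  expect_error(estimate_rates(list(single), sequence_condition("x", 1)),
               "undefined")
  expect_error(estimate_rates(list(), sequence_condition("x", 1)), "no traces")
})

test_that("growth rate crosses zero at the critical concentration", {
  rates <- list(k_on = 1, k_off = 1)
  expect_identical(growth_rate(rates, 1), 0)      # critical concentration
  expect_identical(growth_rate(list(k_on = 0.5, k_off = 1), 2), 0)
  expect_identical(growth_rate(list(k_on = 0.3, k_off = 0), 2), 0.6)
  expect_error(growth_rate(rates, -1), ">= 0")
  # strictly increasing in concentration, zero exactly at k_off/k_on
  r <- list(k_on = 0.21, k_off = 0.084)
  cc <- seq(0, 3, by = 0.1)
  g <- growth_rate(r, cc)
  expect_true(all(diff(g) > 0))
  expect_equal(growth_rate(r, r$k_off / r$k_on), 0)
})
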