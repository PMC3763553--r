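test_that("rate model constructors validate and build the documented schemes", {
  m <- build_end_dynamics_model(0.2, 0.1, 2)
  expect_equal(m$states, c("M0", "M1", "M2"))
  expect_equal(unname(m$rates["M0", "M1"]), 0.4)  # k_on * [RecA]
  expect_equal(unname(m$rates["M1", "M2"]), 0.4)
  expect_equal(unname(m$rates["M1", "M0"]), 0.1)
  expect_equal(unname(m$rates["M2", "M1"]), 0.1)
  expect_equal(unname(m$rates["M0", "M2"]), 0)    # no double-monomer jumps
  expect_equal(unname(m$rates["M2", "M0"]), 0)

  n <- build_nucleation_model(0.01, 0.05)
  expect_equal(n$states, c("unbound", "nucleated"))
  expect_equal(unname(n$rates["unbound", "nucleated"]), 0.01)

  expect_error(rate_model("A", matrix(-1, 1, 1)), "finite and >= 0")
  expect_error(build_nucleation_model(-1, 0.1))
  expect_error(rate_model(c("A", "B"), matrix(1, 2, 2)), "diagonal")
})

test_that("an absorbing state yields a single full-length segment", {
  m <- rate_model(c("A", "B"), matrix(0, 2, 2))
  p <- simulate_state_path(m, 10, seed = 1)
  expect_equal(nrow(p), 1L)
  expect_equal(p$state, "A")
  expect_equal(p$duration, 10)
  # k_nuc = 0: traces never leave the unbound state
  p2 <- simulate_state_path(build_nucleation_model(0, 0.05), 50, seed = 2)
  expect_equal(p2$state, "unbound")
})

test_that("Gillespie paths satisfy the state-path invariants", {
  m <- build_end_dynamics_model(0.2, 0.2, 1)
  for (s in 1:20) {
    p <- simulate_state_path(m, 50, seed = s, initial_state = "stationary")
    expect_true(all(p$duration > 0))
    expect_equal(sum(p$duration), 50)
    if (nrow(p) > 1) {
      expect_equal(p$start[-1], (p$start + p$duration)[-nrow(p)])
      expect_true(all(p$state[-1] != p$state[-nrow(p)]))
    }
  }
})

test_that("symmetric two-state chain spends half its time in each state", {
  m <- rate_model(c("A", "B"), matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE))
  expect_equal(unname(stationary_distribution(m)), c(0.5, 0.5))
  set.seed(11)
  frac <- vapply(1:100, function(i) {
    p <- simulate_state_path(m, 100, initial_state = "stationary")
    sum(p$duration[p$state == "A"]) / 100
  }, numeric(1))
  se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 0.5), 3 * se)
})

test_that("dwell times are exponential with the state's total exit rate", {
  m <- build_end_dynamics_model(0.2, 0.2, 1)  # exit rates: M0 .2, M1 .4, M2 .2
  set.seed(42)
  paths <- lapply(1:120, function(i)
    simulate_state_path(m, 250, initial_state = "stationary"))
  exit <- c(M0 = 0.2, M1 = 0.4, M2 = 0.2)
  for (s in names(exit)) {
    d <- truth_dwells(paths, s)
    expect_gt(length(d), 1000)
    expect_gt(ks.test(d, pexp, rate = exit[[s]])$p.value, 0.01)
  }
  # mean M2 dwell = 1 / exit rate: build chain with rate(M2->M1) = 0.5
  m2 <- build_end_dynamics_model(0.3, 0.5, 1)
  set.seed(43)
  paths2 <- lapply(1:150, function(i)
    simulate_state_path(m2, 200, initial_state = "stationary"))
  d2 <- truth_dwells(paths2, "M2")
  expect_gt(length(d2), 1000)
  expect_lt(abs(mean(d2) - 2), 3 * 2 / sqrt(length(d2)))
})

test_that("nucleation event count follows the Poisson expectation", {
  # fast disassembly so nearly all time is unbound: E[events] ~ k_nuc * T_unbound
  m <- build_nucleation_model(0.01, 2)
  set.seed(5)
  events <- 0
  t_unbound <- 0
  for (i in 1:100) {
    p <- simulate_state_path(m, 100, initial_state = "unbound")
    events <- events + sum(p$state[-1] == "nucleated")
    t_unbound <- t_unbound + sum(p$duration[p$state == "unbound"])
  }
  lambda <- 0.01 * t_unbound
  expect_lt(abs(events - lambda), 3 * sqrt(lambda))
  # mean nucleated dwell = 1 / k_disassembly
  m2 <- build_nucleation_model(0.05, 0.05)
  set.seed(6)
  paths <- lapply(1:60, function(i) simulate_state_path(m2, 400))
  d <- truth_dwells(paths, "nucleated")
  expect_lt(abs(mean(d) - 20), 3 * 20 / sqrt(length(d)))
})

test_that("zero concentration permits only dissociation", {
  m <- build_end_dynamics_model(0.2, 0.3, 0)
  p <- simulate_state_path(m, 100, seed = 3, initial_state = "M2")
  expect_equal(p$state, c("M2", "M1", "M0"))
})

test_that("linear-chain path parity holds per trace", {
  m <- build_end_dynamics_model(0.2, 0.2, 1)
  for (s in 1:10) {
    p <- simulate_state_path(m, 300, seed = 100 + s, initial_state = "stationary")
    from <- p$state[-nrow(p)]
    to <- p$state[-1]
    expect_lte(abs(sum(from == "M0" & to == "M1") - sum(from == "M1" & to == "M0")), 1)
    expect_lte(abs(sum(from == "M1" & to == "M2") - sum(from == "M2" & to == "M1")), 1)
    expect_equal(sum(abs(match(to, m$states) - match(from, m$states)) > 1), 0)
  }
})

test_that("noiseless rendering reproduces exact time-weighted frame FRET", {
  em <- emission_model(c(M0 = 0.7, M1 = 0.5, M2 = 0.3), total_intensity = 100,
                       noise_sd = 0, bleach_rate = 0)
  # single state: every frame donor 30 / acceptor 70
  p1 <- state_path("M0", 0, 1, 1)
  tr1 <- render_intensities(p1, em, frame_time = 0.1)
  expect_equal(tr1$donor, rep(30, 10))
  expect_equal(tr1$acceptor, rep(70, 10))
  # switch at a frame midpoint: that frame reads the average level
  p2 <- state_path(c("M0", "M1"), c(0, 0.15), c(0.15, 0.25), 0.4)
  tr2 <- render_intensities(p2, em, frame_time = 0.1)
  E <- tr2$acceptor / (tr2$acceptor + tr2$donor)
  expect_equal(E, c(0.7, 0.6, 0.5, 0.5))
  # property: random paths match the brute-force overlap oracle exactly
  m <- build_end_dynamics_model(0.5, 0.5, 1)
  for (s in 1:10) {
    p <- simulate_state_path(m, 10, seed = 200 + s, initial_state = "stationary")
    tr <- render_intensities(p, em, frame_time = 0.1)
    E <- tr$acceptor / (tr$acceptor + tr$donor)
    expect_equal(E, frame_fret_oracle(p, em$mean_fret, 0.1), tolerance = 1e-10)
  }
})

test_that("acceptor bleaching darkens the trace from the bleach time on", {
  em <- emission_model(c(M0 = 0.7), total_intensity = 100, noise_sd = 0,
                       bleach_rate = 0.05)
  p <- state_path("M0", 0, 10, 10)
  tr <- render_intensities(p, em, frame_time = 0.1, bleach_time = 2.0)
  E <- tr$acceptor / (tr$acceptor + tr$donor)
  expect_true(all(E[tr$time >= 2.0] == 0))
  expect_equal(E[tr$time < 1.9], rep(0.7, sum(tr$time < 1.9)))
  expect_error(render_intensities(p, em, frame_time = -1), "frame_time")
})

test_that("simulation batches are bit-identical for a fixed seed", {
  m <- build_end_dynamics_model(0.2, 0.2, 1)
  params <- simulation_params(m, end_dynamics_emission(), n_molecules = 5,
                              trace_duration = 20, seed = 99)
  a <- simulate_experiment(params)
  b <- simulate_experiment(params)
  expect_identical(a, b)
  params2 <- simulation_params(m, end_dynamics_emission(), n_molecules = 5,
                               trace_duration = 20, seed = 100)
  expect_false(identical(simulate_experiment(params2), a))
})

test_that("trace CSV round-trips through write_traces/read_traces", {
  m <- build_nucleation_model(0.05, 0.1)
  params <- simulation_params(m, nucleation_emission(), n_molecules = 3,
                              trace_duration = 10, seed = 4,
                              donor_only_fraction = 0,
                              initial_state = "unbound")
  traces <- simulate_experiment(params)
  tf <- tempfile(fileext = ".csv")
  gf <- tempfile(fileext = ".csv")
  write_traces(traces, tf, gf)
  back <- read_traces(tf)
  expect_length(back, 3)
  orig <- traces[[1]]
  got <- back[[orig$trace_id]]
  expect_equal(got$donor, orig$donor)
  expect_equal(got$acceptor, orig$acceptor)
  expect_equal(got$frame_time, 0.1)
  gt <- read.csv(gf)
  expect_true(all(c("trace_id", "state", "start_s", "duration_s") %in% names(gt)))
})
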