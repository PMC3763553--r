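#' Latent state path of a single molecule
#'
#' Ordered, contiguous segments of a continuous-time Markov realization:
#' `state`, `start` (s), `duration` (s). Durations are positive, segments
#' tile `[0, total_duration]`, and consecutive segments have distinct states.
#'
#' @param state character vector of segment state labels.
#' @param start numeric segment start times (s).
#' @param duration numeric segment durations (s).
#' @param total_duration total observation time (s).
#' @return data.frame of class `state_path` with attribute `total_duration`.
#' @export
state_path <- function(state, start, duration, total_duration) {
  df <- data.frame(state = as.character(state), start = start,
                   duration = duration, stringsAsFactors = FALSE)
  validate_state_path(df, total_duration)
  attr(df, "total_duration") <- total_duration
  class(df) <- c("state_path", "data.frame")
  df
}

validate_state_path <- function(df, total_duration) {
  if (nrow(df) == 0) stop("state path must have at least one segment")
  if (any(df$duration <= 0)) stop("segment durations must be > 0")
  if (abs(df$start[1]) > 1e-9) stop("first segment must start at 0")
  if (nrow(df) > 1) {
    ends <- df$start + df$duration
    if (max(abs(df$start[-1] - ends[-nrow(df)])) > 1e-9)
      stop("segments must be contiguous and non-overlapping")
    if (any(df$state[-1] == df$state[-nrow(df)]))
      stop("consecutive segments must have distinct states")
  }
  if (abs(sum(df$duration) - total_duration) > 1e-6 * max(1, total_duration))
    stop("segment durations must sum to total_duration")
  invisible(df)
}

#' Simulate a state path by the Gillespie algorithm
#'
#' Exact stochastic realization of the continuous-time Markov chain: the dwell
#' in state `s` is exponential with rate equal to the total exit rate of `s`,
#' and the next state is chosen with probability proportional to its rate.
#' A state with zero exit rate is absorbing. The final segment is truncated at
#' `duration` (its observed dwell is right-censored).
#'
#' @param model a [rate_model()].
#' @param duration finite observation time in s (> 0).
#' @param seed optional integer seed for reproducibility; when `NULL` the
#'   current RNG stream is consumed.
#' @param initial_state label of the starting state, or `"stationary"` to draw
#'   it from [stationary_distribution()]. Default: the model's first state
#'   (the unbound / M0 state by construction).
#' @return a [state_path()].
#' @export
simulate_state_path <- function(model, duration, seed = NULL,
                                initial_state = NULL) {
  stopifnot(inherits(model, "rate_model"))
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be finite and > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))

  states <- model$states
  R <- model$rates
  if (is.null(initial_state)) initial_state <- states[1]
  if (identical(initial_state, "stationary")) {
    p <- stationary_distribution(model)
    cur <- sample.int(length(states), 1, prob = p)
  } else {
    cur <- match(initial_state, states)
    if (is.na(cur)) stop("unknown initial state: ", initial_state)
  }

  seg_state <- integer(0)
  seg_start <- numeric(0)
  seg_dur <- numeric(0)
  t <- 0
  repeat {
    exit <- R[cur, ]
    total <- sum(exit)
    dwell <- if (total > 0) rexp(1, total) else Inf
    if (t + dwell >= duration) {
      seg_state <- c(seg_state, cur)
      seg_start <- c(seg_start, t)
      seg_dur <- c(seg_dur, duration - t)
      break
    }
    seg_state <- c(seg_state, cur)
    seg_start <- c(seg_start, t)
    seg_dur <- c(seg_dur, dwell)
    t <- t + dwell
    cur <- sample.int(length(states), 1, prob = exit)
  }
  state_path(states[seg_state], seg_start, seg_dur, duration)
}

#' Camera emission model for a dye pair
#'
#' Maps a latent state path to donor/acceptor photon counts per frame. Each
#' state has a mean FRET efficiency; the camera integrates over the frame, so
#' the noiseless per-frame FRET is the time-weighted mean of the state levels.
#' The acceptor photobleaches after an exponentially distributed time, after
#' which it emits only `background` and the trace shows an apparent E ~ 0
#' dark state (donor recovers the full intensity).
#'
#' @param mean_fret named numeric vector of mean FRET efficiencies per state,
#'   each in `[0, 1]`.
#' @param total_intensity total (donor + acceptor) counts per frame (> 0).
#' @param noise_sd Gaussian shot-noise s.d. per channel, counts.
#' @param bleach_rate acceptor photobleaching rate, s^-1.
#' @param background constant acceptor background, counts.
#' @return object of class `emission_model`.
#' @export
emission_model <- function(mean_fret, total_intensity = 500, noise_sd = 25,
                           bleach_rate = 0.005, background = 0) {
  stopifnot(all(mean_fret >= 0 & mean_fret <= 1), total_intensity > 0,
            noise_sd >= 0, bleach_rate >= 0)
  if (is.null(names(mean_fret))) stop("mean_fret must be named by state")
  structure(list(mean_fret = mean_fret, total_intensity = total_intensity,
                 noise_sd = noise_sd, bleach_rate = bleach_rate,
                 background = background),
            class = "emission_model")
}

#' Render donor/acceptor intensity frames from a state path
#'
#' Per frame the true FRET efficiency is the exact time-weighted mean of the
#' state FRET levels over that frame (frame integration, not point sampling).
#' Before bleaching, acceptor counts are `I * E` and donor counts
#' `I * (1 - E)` plus the constant acceptor background; after the acceptor
#' bleach time, the acceptor emits background only and the donor emits the
#' full intensity. The frame containing the bleach instant is blended in
#' proportion to its pre-bleach fraction. Gaussian noise of s.d. `noise_sd`
#' is added to both channels. The ground-truth path and bleach time are
#' attached to the returned trace.
#'
#' @param path a [state_path()].
#' @param emission an [emission_model()]; `emission$mean_fret` must cover all
#'   states in `path`.
#' @param frame_time frame integration time in s (> 0; default 0.1).
#' @param seed optional integer seed.
#' @param trace_id identifier stored in the trace.
#' @param bleach_time override the drawn acceptor bleach time (s); `0` makes a
#'   donor-only molecule, `Inf` disables bleaching.
#' @return object of class `time_trace`: list with `trace_id`, `time`
#'   (frame start times), `donor`, `acceptor`, `frame_time`, `ground_truth`
#'   (the path), `bleach_time`.
#' @export
render_intensities <- function(path, emission, frame_time = 0.1, seed = NULL,
                               trace_id = "trace", bleach_time = NULL) {
  stopifnot(inherits(path, "state_path"), inherits(emission, "emission_model"))
  if (!is.finite(frame_time) || frame_time <= 0)
    stop("frame_time must be > 0")
  if (!is.null(seed)) set.seed(as.integer(seed))

  total <- attr(path, "total_duration")
  n_frames <- floor(total / frame_time + 1e-9)
  if (n_frames < 1) stop("trace duration shorter than one frame")

  m <- unname(emission$mean_fret[path$state])
  if (anyNA(m)) stop("emission model lacks FRET levels for some states")

  ## cumulative integral of the piecewise-constant E(t) evaluated at frame edges
  bounds <- c(path$start, total)
  cum <- c(0, cumsum(path$duration * m))
  edges <- seq(0, by = frame_time, length.out = n_frames + 1)
  j <- findInterval(edges, bounds, rightmost.closed = TRUE)
  j <- .clamp(j, 1, nrow(path))
  Ecum <- cum[j] + (edges - bounds[j]) * m[j]
  E_frame <- diff(Ecum) / frame_time

  if (is.null(bleach_time)) {
    bleach_time <- if (emission$bleach_rate > 0) rexp(1, emission$bleach_rate) else Inf
  }
  t0 <- edges[-(n_frames + 1)]
  pre_frac <- .clamp((bleach_time - t0) / frame_time, 0, 1)

  I <- emission$total_intensity
  acc_mean <- I * E_frame * pre_frac + emission$background
  don_mean <- I * (1 - E_frame * pre_frac)
  ns <- emission$noise_sd
  donor <- don_mean + if (ns > 0) rnorm(n_frames, 0, ns) else 0
  acceptor <- acc_mean + if (ns > 0) rnorm(n_frames, 0, ns) else 0

  structure(list(trace_id = as.character(trace_id), time = t0, donor = donor,
                 acceptor = acceptor, frame_time = frame_time,
                 ground_truth = path, bleach_time = bleach_time),
            class = "time_trace")
}

#' @export
print.time_trace <- function(x, ...) {
  cat("<time_trace> ", x$trace_id, ": ", length(x$time), " frames @ ",
      x$frame_time, " s\n", sep = "")
  invisible(x)
}

#' Simulation parameters for one synthetic experiment
#'
#' Bundles the kinetic scheme, emission model and acquisition settings for a
#' batch of molecules. `donor_only_fraction` molecules carry no active
#' acceptor (bleach time 0), producing the E ~ 0 population of real smFRET
#' histograms.
#'
#' @param rate_model a [rate_model()].
#' @param emission_model an [emission_model()].
#' @param reca_concentration RecA concentration in uM (metadata; the
#'   concentration is already baked into the rate model).
#' @param frame_time frame time in s (default 0.1).
#' @param n_molecules number of traces to generate (>= 1).
#' @param trace_duration duration of each trace in s (>= frame_time).
#' @param seed master integer seed; per-trace substreams are derived from it.
#' @param donor_only_fraction fraction of donor-only molecules in `[0, 1]`.
#' @param initial_state initial state label, or `"stationary"` (default) to
#'   draw each molecule's starting state from the stationary distribution
#'   (molecules are at steady state when acquisition starts).
#' @return object of class `simulation_params`.
#' @export
simulation_params <- function(rate_model, emission_model,
                              reca_concentration = 1, frame_time = 0.1,
                              n_molecules = 100, trace_duration = 100,
                              seed = 1, donor_only_fraction = 0.1,
                              initial_state = "stationary") {
  stopifnot(inherits(rate_model, "rate_model"),
            inherits(emission_model, "emission_model"),
            frame_time > 0, trace_duration >= frame_time, n_molecules >= 1,
            donor_only_fraction >= 0, donor_only_fraction <= 1)
  structure(list(rate_model = rate_model, emission_model = emission_model,
                 reca_concentration = reca_concentration,
                 frame_time = frame_time, n_molecules = n_molecules,
                 trace_duration = trace_duration, seed = as.integer(seed),
                 donor_only_fraction = donor_only_fraction,
                 initial_state = initial_state),
            class = "simulation_params")
}

#' Simulate a batch of ground-truth-labeled traces
#'
#' For a fixed seed the output is bit-identical across runs: one seeded master
#' stream assigns each trace an independent substream derived from
#' `(seed, trace index)`.
#'
#' @param params a [simulation_params()].
#' @return list of [render_intensities()] `time_trace` objects, one per
#'   molecule, each with ground truth attached.
#' @export
simulate_experiment <- function(params) {
  stopifnot(inherits(params, "simulation_params"))
  n <- params$n_molecules
  sub <- derive_seeds(params$seed, 2L * n + 1L)
  set.seed(sub[2L * n + 1L])
  donor_only <- runif(n) < params$donor_only_fraction

  lapply(seq_len(n), function(i) {
    path <- simulate_state_path(params$rate_model, params$trace_duration,
                                seed = sub[2L * i - 1L],
                                initial_state = params$initial_state)
    render_intensities(path, params$emission_model, params$frame_time,
                       seed = sub[2L * i],
                       trace_id = sprintf("trace%04d", i),
                       bleach_time = if (donor_only[i]) 0 else NULL)
  })
}

#' Default emission model for 5'-end monomer-occupancy simulations
#'
#' FRET levels 0.7 / 0.5 / 0.3 for zero, one, two bound monomers between the
#' dye pair (Delta E ~ 0.2 per monomer step).
#' @inheritParams emission_model
#' @return an [emission_model()].
#' @export
end_dynamics_emission <- function(total_intensity = 500, noise_sd = 25,
                                  bleach_rate = 0.005, background = 0) {
  emission_model(c(M0 = 0.7, M1 = 0.5, M2 = 0.3), total_intensity, noise_sd,
                 bleach_rate, background)
}

#' Default emission model for nucleation simulations
#'
#' FRET levels 0.7 (bare ssDNA, compact coil) and 0.2 (tail stretched by the
#' nucleated cluster).
#' @inheritParams emission_model
#' @return an [emission_model()].
#' @export
nucleation_emission <- function(total_intensity = 500, noise_sd = 25,
                                bleach_rate = 0.005, background = 0) {
  emission_model(c(unbound = 0.7, nucleated = 0.2), total_intensity, noise_sd,
                 bleach_rate, background)
}

#' Write / read trace batches as long-format CSV
#'
#' Columns `trace_id,time_s,donor,acceptor`; the optional companion
#' ground-truth file has `trace_id,state,start_s,duration_s`.
#'
#' @param traces list of `time_trace` objects.
#' @param file path of the trace CSV.
#' @param truth_file optional path for the ground-truth CSV.
#' @return `file`, invisibly.
#' @export
write_traces <- function(traces, file, truth_file = NULL) {
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(trace_id = tr$trace_id, time_s = tr$time, donor = tr$donor,
               acceptor = tr$acceptor)))
  write.csv(df, file, row.names = FALSE)
  if (!is.null(truth_file)) {
    gt <- do.call(rbind, lapply(traces, function(tr) {
      if (is.null(tr$ground_truth)) return(NULL)
      data.frame(trace_id = tr$trace_id, state = tr$ground_truth$state,
                 start_s = tr$ground_truth$start,
                 duration_s = tr$ground_truth$duration)
    }))
    write.csv(gt, truth_file, row.names = FALSE)
  }
  invisible(file)
}

#' @rdname write_traces
#' @param frame_time frame time (s) of the stored traces.
#' @return `read_traces()`: list of `time_trace` objects (no ground truth).
#' @export
read_traces <- function(file, frame_time = NULL) {
  df <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("trace_id", "time_s", "donor", "acceptor")
  if (!all(need %in% names(df)))
    stop("trace CSV must have columns ", paste(need, collapse = ","))
  lapply(split(df, df$trace_id), function(d) {
    d <- d[order(d$time_s), ]
    ft <- if (is.null(frame_time)) {
      if (nrow(d) > 1) stats::median(diff(d$time_s)) else NA_real_
    } else frame_time
    structure(list(trace_id = d$trace_id[1], time = d$time_s, donor = d$donor,
                   acceptor = d$acceptor, frame_time = ft,
                   ground_truth = NULL, bleach_time = NA_real_),
              class = "time_trace")
  })
}
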