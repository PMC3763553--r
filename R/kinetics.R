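#' Extract dwell times from an idealized trace
#'
#' One dwell per decoded segment. The first and last segments of every trace
#' are flagged censored: their true durations are cut by the start of
#' observation, the end of the recording, or photobleach truncation. Censored
#' dwells are excluded from exponential fits by default.
#'
#' @param ideal an [idealize()] result, or a ground-truth [state_path()]
#'   (useful to isolate estimator bias from decoder bias).
#' @param condition optional condition label attached to every dwell.
#' @return data.frame of class `dwell_set`: `condition`, `trace_id`, `state`,
#'   `duration`, `start`, `censored`.
#' @export
extract_dwells <- function(ideal, condition = NA_character_) {
  if (inherits(ideal, "state_path")) {
    seg <- data.frame(state = ideal$state, start = ideal$start,
                      duration = ideal$duration)
    id <- "truth"
  } else if (inherits(ideal, "idealized_trace")) {
    seg <- as.data.frame(ideal)[c("state", "start", "duration")]
    id <- attr(ideal, "trace_id")
  } else stop("ideal must be an idealized_trace or state_path")
  n <- nrow(seg)
  if (n == 0)
    return(structure(data.frame(condition = character(0), trace_id = character(0),
                                state = character(0), duration = numeric(0),
                                start = numeric(0), censored = logical(0)),
                     class = c("dwell_set", "data.frame")))
  censored <- rep(FALSE, n)
  censored[c(1, n)] <- TRUE
  out <- data.frame(condition = condition, trace_id = id,
                    state = as.character(seg$state), duration = seg$duration,
                    start = seg$start, censored = censored,
                    stringsAsFactors = FALSE)
  class(out) <- c("dwell_set", "data.frame")
  out
}

#' @rdname extract_dwells
#' @param ideals list of idealized traces.
#' @export
extract_dwells_all <- function(ideals, condition = NA_character_) {
  out <- do.call(rbind, lapply(ideals, extract_dwells, condition = condition))
  class(out) <- c("dwell_set", "data.frame")
  out
}

#' Exponential dwell-time fit
#'
#' Maximum-likelihood single-exponential lifetime of a dwell set: the sample
#' mean of the uncensored dwells, with standard error `tau / sqrt(n)`.
#' Optionally corrects for left truncation at the frame time (dwells shorter
#' than one frame are unobservable): `tau = mean(x) - t_min`.
#'
#' @param dwells a `dwell_set` (uncensored rows are used), or a bare numeric
#'   vector of dwell times.
#' @param state restrict to this state label (ignored for numeric input).
#' @param min_n minimum number of dwells required (default 5).
#' @param t_min left-truncation time in s (default 0 = no correction).
#' @return list `tau` (s), `stderr` (s), `n`.
#' @export
fit_exponential_dwell <- function(dwells, state = NULL, min_n = 5, t_min = 0) {
  if (is.numeric(dwells)) {
    x <- dwells
  } else {
    stopifnot(inherits(dwells, "dwell_set"))
    d <- dwells[!dwells$censored, ]
    if (!is.null(state)) d <- d[d$state == state, ]
    x <- d$duration
  }
  x <- x[is.finite(x) & x > 0]
  if (length(x) < min_n)
    stop("need >= ", min_n, " uncensored dwells, got ", length(x))
  tau <- mean(x) - t_min
  list(tau = tau, stderr = tau / sqrt(length(x)), n = length(x))
}

#' Nucleation frequency and nucleated-filament lifetime
#'
#' From idealized two-state (unbound/nucleated) trajectories: the nucleation
#' frequency `f_nuc` is the number of unbound-to-nucleated transitions divided
#' by the total observed unbound time, pooled over molecules (events per
#' molecule per second of unbound time); the lifetime `tau` is the
#' exponential fit of the uncensored nucleated-state dwells.
#'
#' @param ideals list of [idealize()] results (or [state_path()]s). For
#'   idealized traces the unbound state is the one with the higher emission
#'   mean (bare ssDNA E ~ 0.7 vs nucleated E ~ 0.2).
#' @param condition condition label.
#' @param min_n minimum dwells for the lifetime fit.
#' @return list of class `nucleation_stats`: `condition`, `tau`, `tau_stderr`,
#'   `f_nuc`, `f_nuc_stderr`, `n_events`, `n_dwells`, `unbound_time`,
#'   `n_molecules`.
#' @export
nucleation_kinetics <- function(ideals, condition = NA_character_, min_n = 5) {
  lab <- nucleation_labels(ideals)
  n_events <- 0L
  unbound_time <- 0
  nuc_dwells <- numeric(0)
  for (ideal in ideals) {
    seg <- segment_frame(ideal)
    s <- lab(seg)
    unbound_time <- unbound_time + sum(seg$duration[s == "unbound"])
    if (nrow(seg) > 1) {
      from <- s[-nrow(seg)]; to <- s[-1]
      n_events <- n_events + sum(from == "unbound" & to == "nucleated")
      interior <- setdiff(which(s == "nucleated"), c(1, nrow(seg)))
      nuc_dwells <- c(nuc_dwells, seg$duration[interior])
    }
  }
  f_nuc <- if (unbound_time > 0) n_events / unbound_time else 0
  tau <- tau_se <- NA_real_
  if (length(nuc_dwells) >= min_n) {
    fit <- fit_exponential_dwell(nuc_dwells, min_n = min_n)
    tau <- fit$tau; tau_se <- fit$stderr
  }
  structure(list(condition = condition, tau = tau, tau_stderr = tau_se,
                 f_nuc = f_nuc,
                 f_nuc_stderr = if (n_events > 0) f_nuc / sqrt(n_events) else NA_real_,
                 n_events = n_events, n_dwells = length(nuc_dwells),
                 unbound_time = unbound_time, n_molecules = length(ideals)),
            class = "nucleation_stats")
}

segment_frame <- function(ideal) {
  if (inherits(ideal, "state_path")) {
    data.frame(state = ideal$state, duration = ideal$duration,
               mean_E = NA_real_)
  } else {
    data.frame(state = ideal$state, duration = ideal$duration,
               mean_E = ideal$mean_E)
  }
}

## classify two-state segments as unbound (high E) / nucleated (low E)
nucleation_labels <- function(ideals) {
  first <- ideals[[1]]
  if (inherits(first, "state_path")) {
    function(seg) ifelse(seg$state == "unbound", "unbound", "nucleated")
  } else {
    means <- attr(first, "model_means")
    hi <- which.max(means)
    function(seg) ifelse(as.integer(seg$state) == hi, "unbound", "nucleated")
  }
}

#' Transitions of idealized traces
#'
#' One record per decoded state change: `(trace_id, time, E_before, E_after,
#' state_before, state_after)`. E values are the decoded states' emission
#' means, not raw frame values, which is what gives transition density plots
#' their sharp peak structure.
#'
#' @param ideals list of [idealize()] results.
#' @return data.frame of class `transition_set`.
#' @export
collect_transitions <- function(ideals) {
  rows <- lapply(ideals, function(seg) {
    n <- nrow(seg)
    if (n < 2) return(NULL)
    data.frame(trace_id = attr(seg, "trace_id"),
               time = seg$start[-1],
               E_before = seg$mean_E[-n], E_after = seg$mean_E[-1],
               state_before = seg$state[-n], state_after = seg$state[-1])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(trace_id = character(0), time = numeric(0),
                      E_before = numeric(0), E_after = numeric(0),
                      state_before = integer(0), state_after = integer(0))
  attr(out, "n_molecules") <- length(ideals)
  class(out) <- c("transition_set", "data.frame")
  out
}

#' Transition density plot (TDP)
#'
#' 2D histogram of `(E_before, E_after)` over `[0,1]^2` for all decoded
#' transitions; diagonal bins are empty by construction because a transition
#' requires a state change.
#'
#' @param transitions a [collect_transitions()] result.
#' @param bin_width bin width on each axis (default 0.02).
#' @return object of class `tdp`: `counts` (matrix, rows = E_before),
#'   `breaks`, `mids`, `n_transitions`, `n_molecules`.
#' @export
build_tdp <- function(transitions, bin_width = 0.02) {
  stopifnot(inherits(transitions, "transition_set"), bin_width > 0)
  breaks <- seq(0, 1, by = bin_width)
  if (abs(breaks[length(breaks)] - 1) > 1e-12) breaks <- c(breaks, 1)
  nb <- length(breaks) - 1
  counts <- matrix(0L, nb, nb)
  if (nrow(transitions) > 0) {
    i <- .clamp(findInterval(.clamp(transitions$E_before, 0, 1), breaks,
                             rightmost.closed = TRUE), 1, nb)
    j <- .clamp(findInterval(.clamp(transitions$E_after, 0, 1), breaks,
                             rightmost.closed = TRUE), 1, nb)
    for (k in seq_along(i)) counts[i[k], j[k]] <- counts[i[k], j[k]] + 1L
  }
  structure(list(counts = counts, breaks = breaks,
                 mids = (breaks[-1] + breaks[-(nb + 1)]) / 2,
                 bin_width = bin_width, n_transitions = nrow(transitions),
                 n_molecules = attr(transitions, "n_molecules")),
            class = "tdp")
}

#' @export
print.tdp <- function(x, ...) {
  cat("<tdp> ", x$n_transitions, " transitions from ", x$n_molecules,
      " molecules; ", sum(x$counts > 0), " occupied bins\n", sep = "")
  invisible(x)
}

#' TDP peak clusters
#'
#' Groups occupied TDP bins into clusters by 8-neighbour grid adjacency and
#' keeps clusters holding at least `min_fraction` of all transitions. For
#' clean idealized data each cluster is one transition class (e.g. the four
#' binding/dissociation peaks of the M0-M1-M2 chain).
#'
#' @param tdp a [build_tdp()] result.
#' @param min_fraction minimum share of transitions per reported cluster.
#' @return data.frame `E_before`, `E_after` (count-weighted cluster centres),
#'   `count`, sorted by count descending.
#' @export
tdp_peaks <- function(tdp, min_fraction = 0.02) {
  stopifnot(inherits(tdp, "tdp"))
  occ <- which(tdp$counts > 0, arr.ind = TRUE)
  if (nrow(occ) == 0)
    return(data.frame(E_before = numeric(0), E_after = numeric(0),
                      count = numeric(0)))
  ## union-find over occupied cells
  comp <- seq_len(nrow(occ))
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  for (a in seq_len(nrow(occ))) {
    for (b in seq_len(nrow(occ))) {
      if (b >= a) break
      if (abs(occ[a, 1] - occ[b, 1]) <= 1 && abs(occ[a, 2] - occ[b, 2]) <= 1) {
        ra <- find(a); rb <- find(b)
        if (ra != rb) comp[ra] <- rb
      }
    }
  }
  roots <- vapply(seq_len(nrow(occ)), find, integer(1))
  cnt <- tdp$counts[occ]
  agg <- lapply(split(seq_len(nrow(occ)), roots), function(idx) {
    w <- cnt[idx]
    data.frame(E_before = sum(tdp$mids[occ[idx, 1]] * w) / sum(w),
               E_after = sum(tdp$mids[occ[idx, 2]] * w) / sum(w),
               count = sum(w))
  })
  out <- do.call(rbind, agg)
  out <- out[out$count >= min_fraction * tdp$n_transitions, , drop = FALSE]
  out <- out[order(-out$count), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sequence experimental condition
#'
#' @param label sequence repeat label (e.g. `"TGG"`, `"TTT"`, `"Chi"`).
#' @param reca_uM RecA concentration in uM.
#' @param atpase_rate ATP hydrolysis rate in arbitrary consistent units
#'   (>= 0; measured externally and consumed as an input).
#' @return list of class `sequence_condition`.
#' @export
sequence_condition <- function(label, reca_uM = 1, atpase_rate = NA_real_) {
  stopifnot(is.na(atpase_rate) || atpase_rate >= 0, reca_uM >= 0)
  structure(list(label = label, reca_uM = reca_uM, atpase_rate = atpase_rate),
            class = "sequence_condition")
}

#' Monomer binding and dissociation rates from idealized traces
#'
#' Exact continuous-time Markov estimator on the M0-M1-M2 occupancy chain:
#' each transition class contributes `rate = N(class) / T(source state)`.
#' Binding classes (M0->M1, M1->M2) are pooled and divided by the RecA
#' concentration to give the single `k_on` (uM^-1 s^-1); dissociation classes
#' (M1->M0, M2->M1) are pooled to give `k_off` (s^-1). States are identified
#' by their emission means in descending order (highest E = empty probe
#' window, M0). The dark E ~ 0 state must already be removed by
#' [truncate_photobleach()]. Standard errors are counting statistics
#' (`rate / sqrt(N)`).
#'
#' @param ideals list of [idealize()] results, or ground-truth [state_path()]s
#'   (states `M0`,`M1`,`M2`) to bypass the decoder.
#' @param condition a [sequence_condition()] supplying `[RecA]`.
#' @return list of class `kinetic_rates`: `condition`, `k_on`, `k_on_stderr`,
#'   `k_off`, `k_off_stderr`, `reca_uM`, `n_bind`, `n_dissoc`, `n_skipped`
#'   (decoded non-adjacent jumps, excluded), `time_bindable`, `time_dissociable`.
#' @export
estimate_rates <- function(ideals, condition) {
  stopifnot(inherits(condition, "sequence_condition"))
  if (length(ideals) == 0) stop("no traces supplied")
  occ_of <- occupancy_map(ideals)

  n_bind <- n_dissoc <- n_skip <- 0L
  t_bind <- t_dissoc <- 0
  for (ideal in ideals) {
    seg <- segment_frame(ideal)
    occ <- occ_of(seg)
    ## occupancy time: M0 and M1 can bind, M1 and M2 can dissociate
    t_bind <- t_bind + sum(seg$duration[occ <= 1])
    t_dissoc <- t_dissoc + sum(seg$duration[occ >= 1])
    if (nrow(seg) > 1) {
      d <- diff(occ)
      n_bind <- n_bind + sum(d == 1)
      n_dissoc <- n_dissoc + sum(d == -1)
      n_skip <- n_skip + sum(abs(d) > 1)
    }
  }
  if (t_bind <= 0 || t_dissoc <= 0)
    stop("zero occupancy time in a source state; rates undefined")
  if (n_bind + n_dissoc == 0) stop("no transitions observed; rates undefined")

  conc <- condition$reca_uM
  if (conc <= 0) stop("k_on undefined at zero RecA concentration")
  k_on <- n_bind / t_bind / conc
  k_off <- n_dissoc / t_dissoc
  structure(list(condition = condition$label,
                 k_on = k_on,
                 k_on_stderr = if (n_bind > 0) k_on / sqrt(n_bind) else NA_real_,
                 k_off = k_off,
                 k_off_stderr = if (n_dissoc > 0) k_off / sqrt(n_dissoc) else NA_real_,
                 reca_uM = conc, n_bind = n_bind, n_dissoc = n_dissoc,
                 n_skipped = n_skip, time_bindable = t_bind,
                 time_dissociable = t_dissoc),
            class = "kinetic_rates")
}

#' @export
print.kinetic_rates <- function(x, ...) {
  cat("<kinetic_rates> ", x$condition, ": k_on = ", signif(x$k_on, 4),
      " +/- ", signif(x$k_on_stderr, 2), " uM^-1 s^-1; k_off = ",
      signif(x$k_off, 4), " +/- ", signif(x$k_off_stderr, 2), " s^-1 (",
      x$n_bind, " binding / ", x$n_dissoc, " dissociation events)\n", sep = "")
  invisible(x)
}

## map decoded/true states to monomer occupancy 0/1/2
occupancy_map <- function(ideals) {
  first <- ideals[[1]]
  if (inherits(first, "state_path")) {
    function(seg) match(seg$state, c("M0", "M1", "M2")) - 1L
  } else {
    means <- attr(first, "model_means")
    occ_by_state <- rank(-means) - 1L  # highest mean -> occupancy 0
    function(seg) occ_by_state[as.integer(seg$state)]
  }
}

#' Filament growth rate at the 5' end
#'
#' Net elongation rate `k_on * [RecA] - k_off` in monomers s^-1: positive
#' means net growth, negative net shrinkage (the same difference is often
#' quoted with opposite sign as a shrinkage rate). Strictly increasing in
#' concentration for `k_on > 0`, crossing zero exactly at the critical
#' concentration `k_off / k_on`.
#'
#' @param rates a [estimate_rates()] result, or a list with `k_on`, `k_off`.
#' @param concentration RecA concentration in uM (>= 0).
#' @return net growth rate, s^-1.
#' @export
growth_rate <- function(rates, concentration) {
  if (any(concentration < 0)) stop("concentration must be >= 0")
  stopifnot(is.numeric(rates$k_on), is.numeric(rates$k_off))
  rates$k_on * concentration - rates$k_off
}
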