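# Independent oracles used across tests. These deliberately use naive
# implementations (full enumeration, brute-force overlap loops) so they share
# no code with the package internals they check.

# Exhaustive most-likely-path search over all K^T state paths.
brute_viterbi <- function(x, means, sds, trans, init_prob) {
  K <- length(means)
  T_ <- length(x)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T_)))
  lA <- log(trans)
  lpi <- log(init_prob)
  em <- matrix(NA_real_, T_, K)
  for (k in seq_len(K)) em[, k] <- dnorm(x, means[k], sds[k], log = TRUE)
  em[is.na(x), ] <- 0
  lp <- lpi[paths[, 1]] + em[cbind(1, paths[, 1])]
  if (T_ > 1) {
    for (t in 2:T_) {
      lp <- lp + lA[cbind(paths[, t - 1], paths[, t])] +
        em[cbind(t, paths[, t])]
    }
  }
  best <- which.max(lp)
  list(path = unname(paths[best, ]), logprob = max(lp))
}

# Brute-force time-weighted frame FRET: loop over frames and segments,
# accumulating overlap durations.
frame_fret_oracle <- function(path, levels, frame_time) {
  total <- attr(path, "total_duration")
  n <- floor(total / frame_time + 1e-9)
  out <- numeric(n)
  for (i in seq_len(n)) {
    t0 <- (i - 1) * frame_time
    t1 <- i * frame_time
    acc <- 0
    for (j in seq_len(nrow(path))) {
      s0 <- path$start[j]
      s1 <- path$start[j] + path$duration[j]
      ov <- max(0, min(t1, s1) - max(t0, s0))
      acc <- acc + ov * levels[[path$state[j]]]
    }
    out[i] <- acc / frame_time
  }
  out
}

# Sample a discrete-time Gaussian HMM (observations + true states).
rhmm <- function(n, means, sds, trans, init_prob) {
  K <- length(means)
  s <- integer(n)
  s[1] <- sample.int(K, 1, prob = init_prob)
  if (n > 1) for (t in 2:n) s[t] <- sample.int(K, 1, prob = trans[s[t - 1], ])
  list(x = rnorm(n, means[s], sds[s]), states = s)
}

# Quick fret_trace constructor for synthetic observation vectors.
as_fret <- function(E, frame_time = 0.1, trace_id = "t") {
  structure(list(trace_id = trace_id,
                 time = (seq_along(E) - 1) * frame_time,
                 E = E, valid = !is.na(E), frame_time = frame_time,
                 ground_truth = NULL, bleach_time = NA_real_),
            class = "fret_trace")
}

# Uncensored ground-truth dwells of one state pooled over paths.
truth_dwells <- function(paths, state) {
  unlist(lapply(paths, function(p) {
    n <- nrow(p)
    idx <- setdiff(which(p$state == state), c(1, n))
    p$duration[idx]
  }))
}
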