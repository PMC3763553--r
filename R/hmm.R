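#' Gaussian-emission hidden Markov model
#'
#' Container for a discrete-time HMM with Gaussian emissions on the FRET
#' scale: per-state emission `means` and `sds`, a per-frame transition
#' probability matrix `trans` (rows sum to 1), an initial distribution
#' `init_prob`, and the training log-likelihood.
#'
#' @param means,sds numeric emission parameters, one per state (`sds > 0`).
#' @param trans K x K transition matrix.
#' @param init_prob initial state distribution.
#' @param loglik training log-likelihood (optional).
#' @return object of class `hmm_model`.
#' @export
hmm_model <- function(means, sds, trans, init_prob, loglik = NA_real_) {
  K <- length(means)
  stopifnot(length(sds) == K, all(sds > 0), all(dim(trans) == K),
            length(init_prob) == K)
  if (max(abs(rowSums(trans) - 1)) > 1e-6) stop("transition rows must sum to 1")
  if (abs(sum(init_prob) - 1) > 1e-6) stop("initial distribution must sum to 1")
  structure(list(n_states = K, means = as.numeric(means),
                 sds = as.numeric(sds), trans = unname(as.matrix(trans)),
                 init_prob = as.numeric(init_prob), loglik = loglik),
            class = "hmm_model")
}

#' @export
print.hmm_model <- function(x, ...) {
  cat("<hmm_model> ", x$n_states, " states; loglik = ",
      format(x$loglik), "\n", sep = "")
  cat("  means:", paste(round(x$means, 3), collapse = " "), "\n")
  cat("  sds:  ", paste(round(x$sds, 3), collapse = " "), "\n")
  invisible(x)
}

trace_observations <- function(tr) {
  if (inherits(tr, "fret_trace")) {
    x <- tr$E
    x[!tr$valid] <- NA_real_
    x
  } else if (is.numeric(tr)) {
    as.numeric(tr)
  } else stop("traces must be fret_trace objects or numeric vectors")
}

#' Fit an HMM to pooled FRET traces by Baum-Welch
#'
#' Maximum-likelihood expectation-maximization with Gaussian emissions over a
#' pool of trajectories (one model per experimental condition). The
#' log-likelihood is non-decreasing across iterations (asserted); iteration
#' stops at relative tolerance `tol` or `max_iter`. Given the same
#' initialization the fit is fully deterministic. Emission s.d.s are floored
#' at 10^-3 and flagged when the floor binds. After convergence states are
#' relabelled in ascending order of emission mean.
#'
#' @param traces list of `fret_trace` objects (or numeric FRET vectors; `NA` =
#'   missing frame).
#' @param n_states number of states (>= 2).
#' @param init optional `hmm_model` (or list with `means`, `sds`, `trans`,
#'   `init_prob`) used as the starting point. Default seeding: means at the
#'   `(k - 1/2)/K` quantiles of the pooled data (or a supplied `init_means`
#'   vector, e.g. a [fit_fret_populations()] result), s.d. 0.05, sticky
#'   transitions (0.95 self), uniform initial distribution.
#' @param init_means optional starting emission means (overrides quantiles).
#' @param tol relative log-likelihood tolerance (default 1e-6).
#' @param max_iter maximum EM iterations (default 100).
#' @return an [hmm_model()] with extra fields `n_iter`, `converged`,
#'   `loglik_trace`, `sd_floored`.
#' @export
fit_hmm <- function(traces, n_states, init = NULL, init_means = NULL,
                    tol = 1e-6, max_iter = 100L) {
  stopifnot(n_states >= 2)
  if (inherits(traces, "fret_trace") || is.numeric(traces)) traces <- list(traces)
  obs <- lapply(traces, trace_observations)
  obs <- lapply(obs, function(x) x[seq_along(x)])
  pooled <- unlist(obs, use.names = FALSE)
  pooled <- pooled[!is.na(pooled)]
  if (length(pooled) < 10 * n_states)
    stop("need at least ", 10 * n_states, " observed frames to fit ",
         n_states, " states")

  K <- n_states
  if (!is.null(init)) {
    means <- init$means; sds <- init$sds
    trans <- init$trans; init_prob <- init$init_prob
  } else {
    means <- if (!is.null(init_means)) {
      stopifnot(length(init_means) == K)
      as.numeric(init_means)
    } else {
      as.numeric(quantile(pooled, probs = (seq_len(K) - 0.5) / K, names = FALSE))
    }
    sds <- rep(0.05, K)
    trans <- matrix(0.05 / (K - 1), K, K)
    diag(trans) <- 0.95
    init_prob <- rep(1 / K, K)
  }

  sd_floor <- 1e-3
  floored <- FALSE
  ll_trace <- numeric(0)
  ll_prev <- -Inf
  converged <- FALSE
  iter <- 0L

  while (iter < max_iter) {
    iter <- iter + 1L
    gamma1 <- numeric(K); gsum <- numeric(K)
    gx <- numeric(K); gx2 <- numeric(K)
    xi <- matrix(0, K, K)
    ll <- 0
    n_tr <- 0L
    for (x in obs) {
      es <- hmm_estep(x, means, sds, trans, init_prob)
      ll <- ll + es$loglik
      gamma1 <- gamma1 + es$gamma1
      gsum <- gsum + es$gamma_sum
      gx <- gx + es$gamma_x
      gx2 <- gx2 + es$gamma_x2
      xi <- xi + es$xi
      n_tr <- n_tr + 1L
    }
    if (ll + 1e-8 * max(1, abs(ll)) < ll_prev)
      stop("Baum-Welch log-likelihood decreased (", ll_prev, " -> ", ll, ")")
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) &&
        abs(ll - ll_prev) <= tol * max(1, abs(ll_prev))) {
      converged <- TRUE
      break
    }
    ll_prev <- ll

    ## M-step
    init_prob <- gamma1 / n_tr
    rs <- rowSums(xi)
    for (i in seq_len(K)) {
      trans[i, ] <- if (rs[i] > 0) xi[i, ] / rs[i] else
        replace(rep(0, K), i, 1)
    }
    nz <- gsum > 0
    means[nz] <- gx[nz] / gsum[nz]
    v <- pmax(gx2[nz] / gsum[nz] - means[nz]^2, 0)
    new_sd <- sqrt(v)
    if (any(new_sd < sd_floor)) floored <- TRUE
    sds[nz] <- pmax(new_sd, sd_floor)
  }

  ord <- order(means)
  model <- hmm_model(means[ord], sds[ord], trans[ord, ord, drop = FALSE],
                     init_prob[ord], loglik = ll_trace[length(ll_trace)])
  model$n_iter <- iter
  model$converged <- converged
  model$loglik_trace <- ll_trace
  model$sd_floored <- floored
  model
}

#' Idealize a FRET trace by Viterbi decoding
#'
#' Most-likely discrete state path under a fitted [hmm_model()], with ties
#' broken toward the lower state index. Invalid frames (flagged by
#' [compute_fret()]) are bridged: their emission term is skipped so the
#' decoder interpolates through them. Consecutive equal states are merged
#' into segments; single-frame segments are retained.
#'
#' @param model an [hmm_model()].
#' @param fret a `fret_trace` (or numeric FRET vector).
#' @return object of class `idealized_trace`: data.frame `state` (1-based
#'   index), `start` (s), `duration` (s), `mean_E` (model emission mean of the
#'   state), with attributes `trace_id`, `logprob`, `frame_time`, `model_means`
#'   and, when the input carries it, `ground_truth`. Also stores the per-frame
#'   decoded path as attribute `path`.
#' @export
idealize <- function(model, fret) {
  stopifnot(inherits(model, "hmm_model"))
  x <- trace_observations(fret)
  ft <- if (inherits(fret, "fret_trace")) fret$frame_time else 1
  t0 <- if (inherits(fret, "fret_trace")) fret$time[1] else 0
  id <- if (inherits(fret, "fret_trace")) fret$trace_id else "trace"
  if (length(x) == 0) stop("empty trace")

  vit <- hmm_viterbi(x, model$means, model$sds, model$trans, model$init_prob)
  path <- vit$path
  r <- rle(path)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  seg <- data.frame(state = r$values,
                    start = t0 + starts * ft,
                    duration = r$lengths * ft,
                    mean_E = model$means[r$values])
  attr(seg, "trace_id") <- id
  attr(seg, "logprob") <- vit$logprob
  attr(seg, "frame_time") <- ft
  attr(seg, "model_means") <- model$means
  attr(seg, "path") <- path
  if (inherits(fret, "fret_trace")) attr(seg, "ground_truth") <- fret$ground_truth
  class(seg) <- c("idealized_trace", "data.frame")
  seg
}

#' Truncate a FRET trace at acceptor photobleaching
#'
#' The apparent E ~ 0 dark state produced by acceptor photo-inactivation must
#' be excluded before kinetic analysis. The trace is cut at the first run of
#' at least `min_dark_frames` consecutive frames below `dark_threshold`;
#' everything from the start of that run on is dropped and the truncation
#' time recorded.
#'
#' @param fret a `fret_trace`.
#' @param dark_threshold FRET level below which a frame counts as dark
#'   (default 0.1).
#' @param min_dark_frames minimum run length that triggers truncation
#'   (default 5). Shorter dark excursions are kept.
#' @return the (possibly truncated) `fret_trace`, with attributes `truncated`
#'   (logical) and `truncated_at` (s, `NA` if untouched). A trace that is dark
#'   from the first frame returns zero frames and is flagged.
#' @export
truncate_photobleach <- function(fret, dark_threshold = 0.1,
                                 min_dark_frames = 5) {
  stopifnot(inherits(fret, "fret_trace"), min_dark_frames >= 1)
  dark <- !is.na(fret$E) & fret$E < dark_threshold
  r <- rle(dark)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  hit <- which(r$values & r$lengths >= min_dark_frames)
  cut_at <- if (length(hit)) starts[hit[1]] else NA_integer_

  out <- fret
  if (!is.na(cut_at)) {
    keep <- seq_len(cut_at - 1)
    out$time <- fret$time[keep]
    out$E <- fret$E[keep]
    out$valid <- fret$valid[keep]
    attr(out, "truncated") <- TRUE
    attr(out, "truncated_at") <- fret$time[cut_at]
  } else {
    attr(out, "truncated") <- FALSE
    attr(out, "truncated_at") <- NA_real_
  }
  out
}

#' Serialize / deserialize an HMM model as JSON
#'
#' @param model an [hmm_model()].
#' @param file output path.
#' @return `file` (write) or an `hmm_model` (read).
#' @export
write_hmm_model <- function(model, file) {
  stopifnot(inherits(model, "hmm_model"))
  jsonlite::write_json(
    list(n_states = model$n_states, means = model$means, sds = model$sds,
         trans = model$trans, init_prob = model$init_prob,
         loglik = model$loglik),
    file, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(file)
}

#' @rdname write_hmm_model
#' @export
read_hmm_model <- function(file) {
  j <- jsonlite::read_json(file, simplifyVector = TRUE)
  trans <- if (is.matrix(j$trans)) j$trans else
    matrix(unlist(j$trans), j$n_states, j$n_states, byrow = TRUE)
  hmm_model(j$means, j$sds, trans, j$init_prob, loglik = j$loglik)
}

#' Write idealized traces as CSV
#'
#' Columns `trace_id,state,start_s,duration_s,mean_E`.
#' @param ideals list of [idealize()] results.
#' @param file output path.
#' @export
write_idealized <- function(ideals, file) {
  df <- do.call(rbind, lapply(ideals, function(seg)
    data.frame(trace_id = attr(seg, "trace_id"), state = seg$state,
               start_s = seg$start, duration_s = seg$duration,
               mean_E = seg$mean_E)))
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}
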