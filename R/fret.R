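#' FRET efficiency from donor/acceptor intensities
#'
#' Computes the proximity ratio `E = acceptor / (acceptor + donor)` per frame
#' (apparent FRET, no gamma or crosstalk correction). Frames with non-positive
#' total intensity are flagged invalid (`NA` efficiency); downstream decoders
#' bridge them. Values are clamped to `[-0.1, 1.1]` to tame noise outliers.
#'
#' @param trace a `time_trace` (see [render_intensities()]).
#' @return object of class `fret_trace`: list with `trace_id`, `time`, `E`,
#'   `valid`, `frame_time`, and the trace's `ground_truth`/`bleach_time`
#'   carried through when present.
#' @export
compute_fret <- function(trace) {
  stopifnot(inherits(trace, "time_trace"))
  n <- length(trace$time)
  if (n == 0) stop("empty trace")
  total <- trace$donor + trace$acceptor
  valid <- is.finite(total) & total > 0
  if (!any(valid)) stop("no frame with positive total intensity")
  E <- rep(NA_real_, n)
  E[valid] <- .clamp(trace$acceptor[valid] / total[valid], -0.1, 1.1)
  structure(list(trace_id = trace$trace_id, time = trace$time, E = E,
                 valid = valid, frame_time = trace$frame_time,
                 ground_truth = trace$ground_truth,
                 bleach_time = trace$bleach_time),
            class = "fret_trace")
}

#' @export
print.fret_trace <- function(x, ...) {
  cat("<fret_trace> ", x$trace_id, ": ", length(x$E), " frames @ ",
      x$frame_time, " s; mean E = ",
      round(mean(x$E, na.rm = TRUE), 3), "\n", sep = "")
  invisible(x)
}

#' Per-molecule FRET value
#'
#' One FRET value per molecule for histogram building: the arithmetic mean of
#' the first `n_first` valid frames (default 10).
#'
#' @param fret a [compute_fret()] trace.
#' @param n_first number of initial frames to average.
#' @return scalar E, or `NA` with a warning if the trace has fewer than
#'   `n_first` valid frames (the molecule is excluded from histograms).
#' @export
summarize_molecule <- function(fret, n_first = 10) {
  stopifnot(inherits(fret, "fret_trace"), n_first >= 1)
  vals <- fret$E[fret$valid]
  if (length(vals) < n_first) {
    warning("trace ", fret$trace_id, " has ", length(vals),
            " valid frames (< ", n_first, "); excluded")
    return(NA_real_)
  }
  mean(vals[seq_len(n_first)])
}

#' FRET histogram over the unit efficiency range
#'
#' Fixed-width bins on `[0, 1]`; out-of-range values are clipped into the edge
#' bins, `NA` values (excluded molecules) are dropped.
#'
#' @param values numeric vector of per-molecule FRET values.
#' @param bin_width bin width (default 0.02, i.e. 50 bins).
#' @return object of class `fret_histogram`: `breaks`, `mids`, `counts`,
#'   `bin_width`, `n_molecules` (= sum of counts).
#' @export
build_fret_histogram <- function(values, bin_width = 0.02) {
  stopifnot(bin_width > 0, bin_width <= 1)
  values <- values[!is.na(values)]
  breaks <- seq(0, 1, by = bin_width)
  if (abs(breaks[length(breaks)] - 1) > 1e-12) breaks <- c(breaks, 1)
  nb <- length(breaks) - 1
  if (length(values) == 0) {
    counts <- integer(nb)
  } else {
    v <- .clamp(values, 0, 1)
    idx <- .clamp(findInterval(v, breaks, rightmost.closed = TRUE), 1, nb)
    counts <- tabulate(idx, nbins = nb)
  }
  structure(list(breaks = breaks, mids = (breaks[-1] + breaks[-(nb + 1)]) / 2,
                 counts = counts, bin_width = bin_width,
                 n_molecules = sum(counts)),
            class = "fret_histogram")
}

#' @export
print.fret_histogram <- function(x, ...) {
  cat("<fret_histogram> ", x$n_molecules, " molecules in ",
      length(x$counts), " bins of width ", x$bin_width, "\n", sep = "")
  invisible(x)
}

#' Local maxima of a FRET histogram
#'
#' Peaks of the (lightly smoothed) bin counts: bins strictly greater than both
#' neighbours after a 3-bin running mean, keeping peaks of at least
#' `min_fraction` of the maximum count.
#'
#' @param hist a [build_fret_histogram()] result.
#' @param min_fraction prominence threshold relative to the tallest bin.
#' @param exclude_below ignore peaks with centre below this E (e.g. 0.15 to
#'   skip the donor-only zero peak).
#' @return data.frame with columns `E` (bin centre) and `count`.
#' @export
histogram_peaks <- function(hist, min_fraction = 0.1, exclude_below = 0) {
  stopifnot(inherits(hist, "fret_histogram"))
  y <- as.numeric(hist$counts)
  n <- length(y)
  if (n < 3) return(data.frame(E = numeric(0), count = numeric(0)))
  sm <- (c(y[1], y[-n]) + y + c(y[-1], y[n])) / 3
  is_peak <- c(FALSE, sm[2:(n - 1)] > sm[1:(n - 2)] &
                 sm[2:(n - 1)] >= sm[3:n], FALSE)
  keep <- is_peak & sm >= min_fraction * max(sm) & hist$mids >= exclude_below
  data.frame(E = hist$mids[keep], count = y[keep])
}

gaussian_sum <- function(x, amp, mean, sd) {
  y <- numeric(length(x))
  for (k in seq_along(amp))
    y <- y + amp[k] * exp(-0.5 * ((x - mean[k]) / sd[k])^2)
  y
}

#' Gaussian mixture fit of a FRET histogram
#'
#' Nonlinear least-squares fit of a sum of Gaussian peaks to the bin counts,
#' optionally with an extra donor-only peak pinned at E = 0, mirroring how
#' smFRET population histograms are routinely decomposed. The fit is
#' deterministic: unless `init_means` is supplied, component means initialize
#' at the histogram's `n_components` tallest local maxima (above E = 0.15
#' when a zero peak is included), falling back to equal spacing over the
#' occupied data range when fewer maxima exist.
#'
#' @param hist a [build_fret_histogram()] result with at least one count.
#' @param n_components number of Gaussian populations (>= 1), zero peak
#'   excluded.
#' @param include_zero_peak add a donor-only peak at E = 0 (mean fixed at
#'   `zero_mean`).
#' @param init_means optional numeric vector of starting means.
#' @param zero_mean fixed centre of the zero peak (default 0).
#' @return object of class `mixture_fit`: `components` (data.frame
#'   `mean,sd,weight,amplitude`, sorted by mean), `zero_peak` (one-row
#'   data.frame or `NULL`), `goodness` (list `rss`, `r_squared`), `fitted`
#'   (per-bin model counts), plus the input histogram.
#' @export
fit_fret_populations <- function(hist, n_components = 3,
                                 include_zero_peak = TRUE, init_means = NULL,
                                 zero_mean = 0) {
  stopifnot(inherits(hist, "fret_histogram"), n_components >= 1)
  x <- hist$mids
  y <- as.numeric(hist$counts)
  if (sum(y) == 0) stop("cannot fit an empty histogram")

  occupied <- x[y > 0]
  lo_range <- if (include_zero_peak) occupied[occupied > 0.15] else occupied
  if (length(lo_range) == 0) lo_range <- occupied
  rng <- range(lo_range)
  if (is.null(init_means)) {
    ## deterministic seeding: histogram local maxima when they pin down
    ## exactly n_components populations, otherwise equal spacing over the
    ## occupied range
    pk <- histogram_peaks(hist, min_fraction = 0.1,
                          exclude_below = if (include_zero_peak) 0.15 else 0)
    if (nrow(pk) >= n_components) {
      pk <- pk[order(-pk$count)[seq_len(n_components)], ]
      init_means <- sort(pk$E)
    } else {
      init_means <- seq(rng[1], rng[2], length.out = n_components + 2)
      init_means <- init_means[2:(n_components + 1)]
    }
  }
  stopifnot(length(init_means) == n_components)

  ## fit on counts normalized to max 1 so amplitude and location parameters
  ## share a scale (keeps the box-constrained quasi-Newton well conditioned)
  yscale <- max(y)
  yn <- y / yscale
  a0 <- rep(0.8, n_components)
  s0 <- rep(0.05, n_components)
  par0 <- c(a0, init_means, s0)
  lower <- c(rep(0, n_components), rep(0, n_components), rep(0.005, n_components))
  upper <- c(rep(10, n_components), rep(1, n_components), rep(0.5, n_components))
  if (include_zero_peak) {
    par0 <- c(par0, max(yn[x < 0.1], 0.01), 0.03)
    lower <- c(lower, 0, 0.005)
    upper <- c(upper, 10, 0.2)
  }

  K <- n_components
  resid_fun <- function(p) {
    amp <- p[1:K]; mu <- p[(K + 1):(2 * K)]; sg <- p[(2 * K + 1):(3 * K)]
    yhat <- gaussian_sum(x, amp, mu, sg)
    if (include_zero_peak)
      yhat <- yhat + p[3 * K + 1] * exp(-0.5 * ((x - zero_mean) / p[3 * K + 2])^2)
    yn - yhat
  }
  sse <- function(p) sum(resid_fun(p)^2)
  sse_grad <- function(p) {
    amp <- p[1:K]; mu <- p[(K + 1):(2 * K)]; sg <- p[(2 * K + 1):(3 * K)]
    r <- resid_fun(p)
    g <- numeric(length(p))
    for (k in seq_len(K)) {
      z <- (x - mu[k]) / sg[k]
      e <- exp(-0.5 * z^2)
      g[k] <- sum(-2 * r * e)
      g[K + k] <- sum(-2 * r * amp[k] * e * z / sg[k])
      g[2 * K + k] <- sum(-2 * r * amp[k] * e * z^2 / sg[k])
    }
    if (include_zero_peak) {
      z <- (x - zero_mean) / p[3 * K + 2]
      e <- exp(-0.5 * z^2)
      g[3 * K + 1] <- sum(-2 * r * e)
      g[3 * K + 2] <- sum(-2 * r * p[3 * K + 1] * e * z^2 / p[3 * K + 2])
    }
    g
  }
  opt <- stats::nlminb(par0, sse, gradient = sse_grad,
                       lower = lower, upper = upper,
                       control = list(iter.max = 5000, eval.max = 10000))
  ## "false/singular convergence" at a box constraint still delivers a usable
  ## minimum and is flagged; anything else is a hard failure, no fallback
  weak <- opt$convergence != 0 &&
    grepl("false convergence|singular convergence", opt$message)
  if (opt$convergence != 0 && !weak)
    stop("mixture fit did not converge (code ", opt$convergence, "): ",
         opt$message)

  p <- opt$par
  p[1:K] <- p[1:K] * yscale
  if (include_zero_peak) p[3 * K + 1] <- p[3 * K + 1] * yscale
  amp <- p[1:K]; mu <- p[(K + 1):(2 * K)]; sg <- p[(2 * K + 1):(3 * K)]
  yhat <- gaussian_sum(x, amp, mu, sg)
  zero <- NULL
  ## weights: each component's area restricted to the observable E range
  ## [0, 1] (matters for the zero peak, which is half-truncated at 0)
  trunc_area <- function(a, m, s)
    a * s * sqrt(2 * pi) * (stats::pnorm(1, m, s) - stats::pnorm(0, m, s))
  areas <- trunc_area(amp, mu, sg)
  if (include_zero_peak) {
    z_amp <- p[3 * K + 1]; z_sd <- p[3 * K + 2]
    yhat <- yhat + z_amp * exp(-0.5 * ((x - zero_mean) / z_sd)^2)
    zero <- data.frame(mean = zero_mean, sd = z_sd, amplitude = z_amp,
                       weight = NA_real_)
    areas <- c(areas, trunc_area(z_amp, zero_mean, z_sd))
  }
  w <- areas / sum(areas)
  ord <- order(mu)
  comps <- data.frame(mean = mu[ord], sd = sg[ord], weight = w[seq_len(K)][ord],
                      amplitude = amp[ord])
  if (!is.null(zero)) zero$weight <- w[K + 1]
  rss <- sum((y - yhat)^2)
  tss <- sum((y - mean(y))^2)
  structure(list(components = comps, zero_peak = zero,
                 goodness = list(rss = rss,
                                 r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
                                 weak_convergence = weak),
                 fitted = yhat, histogram = hist),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  cat("<mixture_fit> ", nrow(x$components), " components",
      if (!is.null(x$zero_peak)) " + zero peak", "; R^2 = ",
      round(x$goodness$r_squared, 4), "\n", sep = "")
  print(round(x$components, 4))
  if (!is.null(x$zero_peak)) {
    cat("zero peak:\n")
    print(round(x$zero_peak, 4))
  }
  invisible(x)
}

#' Collect per-molecule FRET values from traces
#'
#' Convenience wrapper: [compute_fret()] + [summarize_molecule()] over a batch
#' of traces, reporting how many molecules were excluded as too short.
#'
#' @param traces list of `time_trace` objects.
#' @param n_first frames averaged per molecule.
#' @return numeric vector (`NA`s removed) with attribute `n_excluded`.
#' @export
molecule_fret_values <- function(traces, n_first = 10) {
  vals <- vapply(traces, function(tr) {
    suppressWarnings(summarize_molecule(compute_fret(tr), n_first))
  }, numeric(1))
  out <- vals[!is.na(vals)]
  attr(out, "n_excluded") <- sum(is.na(vals))
  out
}
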