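#' Concatenated intra-burst ISI series for one condition
#'
#' Builds the ISI vector of one (arrangement, delay) condition by
#' concatenating, trial after trial, the successive intra-burst ISIs of the
#' somatic response, and recording the trial boundaries so that windows of
#' downstream analyses never straddle trials.
#'
#' @param trial_isis List of per-trial ISI vectors (already restricted to
#'   intra-burst intervals, in temporal order).
#' @return An object of class `isi_series`: `values`, `trial` (trial index
#'   per value), `boundaries` (first index of each trial).
#' @export
isi_series <- function(trial_isis) {
  trial_isis <- trial_isis[lengths(trial_isis) > 0]
  values <- unlist(trial_isis, use.names = FALSE)
  if (length(values) && any(values <= 0))
    stop("ISI values must be > 0", call. = FALSE)
  lens <- lengths(trial_isis)
  structure(list(
    values = as.numeric(values),
    trial = rep(seq_along(trial_isis), lens),
    boundaries = cumsum(c(1L, lens[-length(lens)]))
  ), class = "isi_series")
}

#' Intra-burst ISIs of one trial, in temporal order
#'
#' @param spikes Spike times (ms).
#' @param max_intra_isi Burst segmentation threshold (ms).
#' @return Numeric vector of intra-burst ISIs.
#' @export
trial_isis <- function(spikes, max_intra_isi = 50) {
  unlist(segment_bursts(spikes, max_intra_isi)$intra_isis,
         use.names = FALSE)
}

#' Three-dimensional return map of an ISI series
#'
#' Embeds the series as points `(ISI_{i-1}, ISI_i, ISI_{i+1})`, using only
#' windows fully contained within one trial.
#'
#' @param series An [isi_series()] object.
#' @param dim Embedding length of each window (default 3).
#' @return Numeric matrix with `dim` columns; one row per window.
#' @export
build_return_map <- function(series, dim = 3) {
  stopifnot(inherits(series, "isi_series"))
  v <- series$values
  if (length(v) < dim)
    stop("series shorter than the embedding dimension", call. = FALSE)
  rows <- list()
  for (tr in unique(series$trial)) {
    x <- v[series$trial == tr]
    if (length(x) < dim) next
    idx <- seq_len(length(x) - dim + 1L)
    rows[[length(rows) + 1L]] <-
      vapply(seq_len(dim), function(k) x[idx + k - 1L],
             numeric(length(idx)))
  }
  if (!length(rows))
    return(matrix(numeric(0), ncol = dim))
  out <- do.call(rbind, lapply(rows, function(m)
    matrix(m, ncol = dim)))
  colnames(out) <- paste0("isi", seq_len(dim) - 2L)
  out
}

#' Normalized entropy of a binned point cloud
#'
#' Shannon entropy of the d-dimensional histogram of the points (equal
#' bins over the bounding box along each axis), divided by the maximal
#' entropy `log(bins^d)`.  0 for a fully concentrated cloud, 1 for exactly
#' uniform occupancy.  Axes with zero range collapse to a single bin.
#'
#' @param points Numeric matrix (rows = points) or vector (1-D).
#' @param bins Bins per axis (>= 2).
#' @return Normalized entropy in `[0, 1]`.
#' @export
normalized_entropy <- function(points, bins = 10) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 1)
  if (!nrow(points)) stop("no points", call. = FALSE)
  if (bins < 2) stop("'bins' must be >= 2", call. = FALSE)
  d <- ncol(points)
  cell <- rep(1L, nrow(points))
  mult <- 1L
  n_bins_total <- 1
  for (k in seq_len(d)) {
    x <- points[, k]
    rng <- range(x)
    if (rng[1] == rng[2]) next  # degenerate axis: single bin
    b <- pmin(pmax(ceiling((x - rng[1]) / diff(rng) * bins), 1L), bins)
    cell <- cell + (b - 1L) * mult
    mult <- mult * bins
    n_bins_total <- n_bins_total * bins
  }
  if (n_bins_total == 1) return(0)
  p <- tabulate(cell, nbins = mult)
  p <- p[p > 0] / sum(p)
  h <- -sum(p * log(p))
  h / log(n_bins_total)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' Standard two-sample KS test between the empirical distributions of two
#' ISI samples (e.g. the flattened ISI vectors underlying two return
#' maps).  Ties are handled with the asymptotic approximation.
#'
#' @param a,b Non-empty numeric samples.
#' @return List with elements `D` (statistic) and `p` (p-value).
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  res <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(res$statistic), p = unname(res$p.value))
}

#' Nonlinear prediction error of an ISI series
#'
#' Local-constant (zeroth-order) nonlinear prediction in delay-embedding
#' space, after Kantz & Schreiber.  Each value is embedded as
#' `(s_i, s_{i-tau}, ..., s_{i-(m-1)tau})`; for every reference point the
#' `k` nearest embedded neighbours (temporally adjacent indices within
#' `tau` excluded) predict each future step as the mean of the neighbours'
#' futures.  The error per step is the root-mean-square prediction error
#' normalized by the series standard deviation, so an unpredictable series
#' scores about 1 and a perfectly predictable one 0.
#'
#' @param series An [isi_series()] object or numeric vector.
#' @param time_delay Embedding delay (samples).
#' @param embed_dim Embedding dimension.
#' @param k_neighbors Minimum number of neighbours used per prediction.
#' @param steps Prediction horizon (steps ahead).
#' @return Object of class `isi_prediction`: `error` (length `steps`),
#'   the settings, and `n_reference` points used.
#' @export
predict_isi_series <- function(series, time_delay = 6, embed_dim = 10,
                               k_neighbors = 8, steps = 10) {
  v <- if (inherits(series, "isi_series")) series$values else as.numeric(series)
  stopifnot(time_delay >= 1, embed_dim >= 1, k_neighbors >= 1, steps >= 1)
  n <- length(v)
  span <- (embed_dim - 1L) * time_delay
  if (n <= span + steps + k_neighbors)
    stop("series too short for the requested embedding", call. = FALSE)
  idx <- seq.int(span + 1L, n - steps)   # embedding end-points
  m <- length(idx)
  emb <- vapply(seq_len(embed_dim) - 1L,
                function(j) v[idx - j * time_delay], numeric(m))
  sdv <- sd(v)
  sq_err <- matrix(0, nrow = m, ncol = steps)
  for (i in seq_len(m)) {
    d2 <- rowSums((emb - matrix(emb[i, ], m, embed_dim, byrow = TRUE))^2)
    d2[abs(idx - idx[i]) <= time_delay] <- Inf
    nb <- order(d2)[seq_len(min(k_neighbors, sum(is.finite(d2))))]
    for (h in seq_len(steps)) {
      pred <- mean(v[idx[nb] + h])
      sq_err[i, h] <- (pred - v[idx[i] + h])^2
    }
  }
  rms <- sqrt(colMeans(sq_err))
  err <- if (sdv > 0) rms / sdv else ifelse(rms > 0, Inf, 0)
  structure(list(error = as.numeric(err), time_delay = time_delay,
                 embed_dim = embed_dim, k_neighbors = k_neighbors,
                 steps = steps, n_reference = m),
            class = "isi_prediction")
}

#' @export
print.isi_prediction <- function(x, ...) {
  cat("Nonlinear prediction (delay", x$time_delay, ", dim", x$embed_dim,
      ",", x$k_neighbors, "neighbours,", x$n_reference,
      "reference points)\n")
  cat("  normalized error by step:",
      paste(round(x$error, 3), collapse = " "), "\n")
  invisible(x)
}

#' Fit a sigmoid delay-response curve
#'
#' Least-squares fit of `F(x) = base + max / (1 + exp(-(x - xhalf)/rate))`
#' to a delay-response curve (average firing frequency or mean burst ISI
#' versus delay).  With this parameterization `F(0)` is close to `base`
#' and the late-delay asymptote is `base + max`; a falling firing-rate
#' curve therefore has negative `max`.
#'
#' @param x Delays (ms).
#' @param y Responses (Hz or ms).
#' @return Object of class `sigmoid_fit` with `coefficients`
#'   (`base`, `max`, `xhalf`, `rate`), `residual` (RMS), `vcov`,
#'   `converged`, and the data.
#' @export
fit_sigmoid <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 5)
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  n <- length(x)
  lo <- mean(head(y, 3)); hi <- mean(tail(y, 3))
  start <- list(base = lo, max = hi - lo,
                xhalf = x[which.min(abs(y - (lo + hi) / 2))],
                rate = diff(range(x)) / 10)
  dat <- data.frame(x = x, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ base + max / (1 + exp(-(x - xhalf) / rate)),
                      data = dat, start = start,
                      lower = c(-Inf, -Inf, min(x) - diff(range(x)), 1e-3),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    cf <- c(base = mean(y), max = 0, xhalf = median(x),
            rate = diff(range(x)) / 4)
    return(structure(list(coefficients = cf, vcov = NULL,
                          residual = sqrt(mean((y - mean(y))^2)),
                          converged = FALSE, x = x, y = y),
                     class = "sigmoid_fit"))
  }
  cf <- coef(fit)
  structure(list(coefficients = cf,
                 vcov = tryCatch(vcov(fit), error = function(e) NULL),
                 residual = sqrt(mean(residuals(fit)^2)),
                 converged = TRUE, x = x, y = y),
            class = "sigmoid_fit")
}

#' @export
coef.sigmoid_fit <- function(object, ...) object$coefficients

#' @export
predict.sigmoid_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x
       else if (is.list(newdata)) newdata$x else newdata
  cf <- object$coefficients
  cf["base"] + cf["max"] / (1 + exp(-(x - cf["xhalf"]) / cf["rate"]))
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat("Sigmoid fit: F(x) = base + max / (1 + exp(-(x - xhalf)/rate))\n")
  print(round(x$coefficients, 4))
  cat("RMS residual:", signif(x$residual, 4),
      if (!x$converged) "(did not converge; flat fallback)" else "", "\n")
  invisible(x)
}

#' @export
summary.sigmoid_fit <- function(object, ...) {
  se <- if (!is.null(object$vcov)) sqrt(diag(object$vcov)) else
    rep(NA_real_, 4)
  out <- cbind(estimate = object$coefficients, std_error = se)
  structure(list(table = out, residual = object$residual,
                 converged = object$converged), class = "summary.sigmoid_fit")
}

#' @export
print.summary.sigmoid_fit <- function(x, ...) {
  print(round(x$table, 4))
  cat("RMS residual:", signif(x$residual, 4), "\n")
  invisible(x)
}
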