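#' Detect pseudo-events in a standardized resting-state series
#'
#' Spontaneous supra-threshold local maxima act as pseudo-events from which a
#' hemodynamic response can be estimated blindly, in the spirit of
#' point-process characterizations of resting-state BOLD. Maxima within one
#' kernel length of either end are discarded.
#'
#' @param x standardized numeric series (length >= 50).
#' @param threshold event threshold in SD units (default 1.0).
#' @param margin samples excluded at each end (default: 24 s worth given
#'   `TR`, see `margin_samples`).
#' @param min_events below this count the result is flagged low-confidence
#'   (attribute `low_confidence`), not an error.
#' @return integer vector of event indices (strictly increasing) with
#'   attribute `low_confidence`.
#' @export
detect_pseudo_events <- function(x, threshold = 1.0, margin = 33L,
                                 min_events = 5L) {
  if (length(x) < 50) stop("series too short for event detection (T < 50)")
  T <- length(x)
  idx <- which(x > threshold)
  idx <- idx[idx > 1 & idx < T]
  idx <- idx[x[idx] > x[idx - 1] & x[idx] >= x[idx + 1]]
  idx <- idx[idx > margin & idx <= T - margin]
  structure(as.integer(idx), low_confidence = length(idx) < min_events)
}

# canonical basis: double-gamma + temporal derivative + dispersion derivative
hrf_basis <- function(TR, span = 24, peak = 6) {
  h0 <- hrf_double_gamma(TR, peak = peak, span = span)
  dt <- 0.1
  hshift <- hrf_double_gamma_at(TR, peak = peak, span = span, shift = dt)
  td <- (h0 - hshift) / dt
  wide <- {
    t <- seq(0, span, by = TR)
    w <- stats::dgamma(t * 0.95, shape = peak + 1, rate = 1) -
      (1 / 6) * stats::dgamma(t, shape = 17, rate = 1)
    w / max(w)
  }
  dd <- (h0 - wide) / 0.05
  cbind(canonical = h0, temporal = td, dispersion = dd)
}

# canonical kernel evaluated on a time grid shifted by `shift` seconds
hrf_double_gamma_at <- function(TR, peak = 6, span = 24, shift = 0) {
  t <- pmax(seq(0, span, by = TR) - shift, 0)
  h <- stats::dgamma(t, shape = peak + 1, rate = 1) -
    (1 / 6) * stats::dgamma(t, shape = 17, rate = 1)
  h / max(h)
}

# smoothed FIR basis: cubic B-ish bumps over the kernel support
fir_basis <- function(TR, span = 24, n_basis = 8L) {
  t <- seq(0, span, by = TR)
  centers <- seq(0, span, length.out = n_basis)
  width <- (span / (n_basis - 1)) * 1.2
  B <- sapply(centers, function(cn) exp(-((t - cn)^2) / (2 * (width / 2)^2)))
  B
}

#' Blind HRF estimation from pseudo-events
#'
#' For each candidate event-to-response lag `delta` in `lag_grid`, the series
#' is regressed on basis kernels (canonical double-gamma plus temporal and
#' dispersion derivatives, or a smoothed FIR set) convolved with a stick
#' train placed at `event - delta`; the lag minimizing the residual sum of
#' squares is selected and the fitted kernel returned, normalized to unit
#' peak. With no usable events, a rank-deficient design, or a best fit whose
#' R-squared stays below `min_r2` (no event-locked hemodynamic structure,
#' e.g. white noise), the canonical kernel is returned with
#' `flag = "canonical_fallback"`.
#'
#' @param x standardized series.
#' @param TR sampling interval (s).
#' @param lag_grid candidate lags in samples (default `0:9`).
#' @param basis `"canonical"` (3 regressors) or `"fir"`.
#' @param threshold event threshold passed to [detect_pseudo_events()].
#' @param events optional precomputed event indices.
#' @param span kernel support (s), default 24.
#' @param min_r2 minimum variance fraction the event regression must explain
#'   before its kernel is trusted (default 0.2).
#' @return object of class `"hrf_model"`: list with `kernel` (unit-peak
#'   samples over `[0, span]`), `TR`, `peak_latency` (s), `lag` (selected
#'   delta, samples), `rss`, `flag` (`"ok"`, `"low_confidence"` or
#'   `"canonical_fallback"`), `n_events`.
#' @export
estimate_hrf_blind <- function(x, TR, lag_grid = 0:9, basis = "canonical",
                               threshold = 1.0, events = NULL, span = 24,
                               min_r2 = 0.2) {
  margin <- length(seq(0, span, by = TR))
  user_events <- !is.null(events)
  if (is.null(events)) {
    events <- detect_pseudo_events(x, threshold = threshold, margin = margin)
  }
  low <- isTRUE(attr(events, "low_confidence")) || length(events) < 5
  canonical <- hrf_double_gamma(TR, span = span)
  fallback <- function(flag) {
    structure(list(kernel = canonical, TR = TR,
                   peak_latency = (which.max(canonical) - 1) * TR,
                   lag = NA_integer_, rss = NA_real_, flag = flag,
                   n_events = length(events)),
              class = "hrf_model")
  }
  if (length(events) < 2) return(fallback("canonical_fallback"))
  T <- length(x)
  scan_one <- function(delta, pk) {
    onsets <- events - delta
    onsets <- onsets[onsets >= 1]
    if (length(onsets) < 2) return(NULL)
    stick <- numeric(T)
    stick[onsets] <- 1
    r <- causal_convolve(stick, hrf_double_gamma(TR, peak = pk, span = span))
    fit <- stats::lm.fit(cbind(1, r), x)
    list(rss = sum(fit$residuals^2), delta = delta, stick = stick, peak = pk)
  }
  # stage 1: lag and latency selection. Internally detected events sit at
  # response peaks, so the lag and the kernel peak are the same quantity:
  # a fine latency family is scanned with the lag tied (within one sample)
  # to each candidate peak, and the residual compares kernel shapes.
  # Caller-supplied events are onset markers of unknown offset: the lag
  # grid is scanned freely against the canonical kernel. A free lag scan
  # with a free latency family would be degenerate (a kernel shift can
  # absorb any lag).
  best <- NULL
  cand <- if (user_events) {
    cbind(delta = lag_grid, pk = 6)
  } else {
    pk <- seq(2.5, min(10, span / 2), by = 0.25)
    d0 <- round(pk / TR)
    unique(do.call(rbind, lapply(-1:1, function(o)
      cbind(delta = pmax(d0 + o, 0), pk = pk))))
  }
  for (k in seq_len(nrow(cand))) {
    res <- scan_one(cand[k, "delta"], cand[k, "pk"])
    if (!is.null(res) && (is.null(best) || res$rss < best$rss)) best <- res
  }
  if (is.null(best)) return(fallback("canonical_fallback"))
  # stage 2: shape refinement with the full basis centred at the selected
  # latency
  B <- switch(match.arg(basis, c("canonical", "fir")),
              canonical = hrf_basis(TR, span = span, peak = best$peak),
              fir = fir_basis(TR, span = span))
  X <- apply(B, 2, function(b) causal_convolve(best$stick, b))
  fit <- stats::lm.fit(cbind(1, X), x)
  if (fit$rank < ncol(X) + 1) return(fallback("canonical_fallback"))
  best$rss <- sum(fit$residuals^2)
  best$beta <- fit$coefficients[-1]
  # fine-grid version of the basis for sub-sample peak readout
  B_fine <- switch(match.arg(basis, c("canonical", "fir")),
                   canonical = hrf_basis(0.1, span = span, peak = best$peak),
                   fir = fir_basis(0.1, span = span))
  if (1 - best$rss / sum((x - mean(x))^2) < min_r2) {
    return(fallback("canonical_fallback"))
  }
  kernel <- drop(B %*% best$beta)
  fine <- drop(B_fine %*% best$beta)
  if (abs(min(kernel)) > max(kernel)) {
    kernel <- -kernel
    fine <- -fine
  }
  if (max(kernel) <= 0) return(fallback("canonical_fallback"))
  kernel <- kernel / max(kernel)
  structure(list(kernel = kernel, TR = TR,
                 peak_latency = (which.max(fine) - 1) * 0.1,
                 lag = as.integer(best$delta), rss = best$rss,
                 flag = if (low) "low_confidence" else "ok",
                 n_events = length(events)),
            class = "hrf_model")
}

#' @export
print.hrf_model <- function(x, ...) {
  cat("HRF model: peak latency", round(x$peak_latency, 2), "s, lag",
      x$lag, "samples,", x$n_events, "events [", x$flag, "]\n")
  invisible(x)
}

#' Pooled blind HRF estimation across sessions of one node
#'
#' The hemodynamic kernel is a property of a subject-node pair, so all of a
#' node's sessions inform one estimate (mirroring the session pooling of the
#' connectivity stage). A one-parameter family of double-gamma kernels
#' (candidate peak latencies `peak_grid`) is scanned, and the peak latency
#' is selected by a minimum-entropy criterion: the candidate whose Wiener
#' inverse (at light regularization `selection_lambda * max |H|^2`) yields
#' the most positively skewed neural proxy, averaged over sessions, wins.
#' Spontaneous neural activity is sparse and positively skewed, so the
#' correct kernel concentrates the deconvolved signal back into sharp
#' events, whereas a mis-specified kernel smears them; skewness uses every
#' sample and, unlike derivative-basis regression, does not shrink latency
#' estimates toward the canonical peak. The selected kernel is then
#' anchored by the pseudo-event regression: the event-to-response lag
#' minimizing the pooled residual is reported, and a pooled R-squared below
#' `min_r2` (no event-locked structure) triggers the canonical fallback.
#'
#' @param xs list of standardized series (the node's sessions).
#' @param TR sampling interval (s).
#' @param peak_grid candidate peak latencies (s).
#' @param lag_grid candidate event-to-response lags (samples).
#' @param threshold event threshold (SD units).
#' @param span kernel support (s).
#' @param selection_lambda relative Wiener ridge used during kernel
#'   selection (default 0.01; light, to keep the proxy sharp).
#' @param min_r2 pooled variance fraction below which the canonical kernel
#'   is substituted (`flag = "canonical_fallback"`).
#' @return an `"hrf_model"` (see [estimate_hrf_blind()]).
#' @export
estimate_hrf_pooled <- function(xs, TR, peak_grid = seq(3, 10, by = 0.25),
                                lag_grid = 0:14, threshold = 1.0,
                                span = 24, selection_lambda = 0.01,
                                min_r2 = 0.2) {
  if (!is.list(xs)) xs <- list(xs)
  margin <- length(seq(0, span, by = TR))
  evs <- lapply(xs, function(x)
    detect_pseudo_events(x, threshold = threshold, margin = margin))
  n_events <- sum(lengths(evs))
  canonical <- hrf_double_gamma(TR, span = span)
  fallback <- function(flag) {
    structure(list(kernel = canonical, TR = TR,
                   peak_latency = (which.max(canonical) - 1) * TR,
                   lag = NA_integer_, rss = NA_real_, flag = flag,
                   n_events = n_events),
              class = "hrf_model")
  }
  if (n_events < 5) return(fallback("canonical_fallback"))
  # kernel selection: maximize proxy skewness across the latency family
  sk <- vapply(peak_grid, function(p) {
    h <- hrf_double_gamma(TR, peak = p, span = span)
    lam <- selection_lambda * hrf_spectrum_max(h, length(xs[[1]]))
    mean(vapply(xs, function(b)
      mean(as.numeric(wiener_deconvolve(b, h, lambda = lam))^3), 0))
  }, 0)
  kernel <- hrf_double_gamma(TR, peak = peak_grid[which.max(sk)], span = span)
  # anchor: pooled event regression at the selected kernel
  dmax <- max(lag_grid)
  rss_d <- rep(0, length(lag_grid))
  tss <- 0
  for (k in seq_along(xs)) {
    x <- xs[[k]]
    T <- length(x)
    stick <- numeric(T + 2 * dmax)
    stick[evs[[k]] + dmax] <- 1
    r0 <- causal_convolve(stick, kernel)
    xc <- x - mean(x)
    tss <- tss + sum(xc^2)
    for (di in seq_along(lag_grid)) {
      # onsets at event - lag: slice the padded zero-lag regressor
      r <- r0[(dmax + lag_grid[di]) + seq_len(T)]
      rc <- r - mean(r)
      vr <- sum(rc^2)
      rss_d[di] <- rss_d[di] +
        if (vr > 0) sum(xc^2) - sum(rc * xc)^2 / vr else sum(xc^2)
    }
  }
  di <- which.min(rss_d)
  if (1 - rss_d[di] / tss < min_r2) return(fallback("canonical_fallback"))
  structure(list(kernel = kernel, TR = TR,
                 peak_latency = (which.max(kernel) - 1) * TR,
                 lag = as.integer(lag_grid[di]), rss = rss_d[di],
                 flag = "ok", n_events = n_events),
            class = "hrf_model")
}

# peak power of the kernel spectrum at the padded FFT length used by
# wiener_deconvolve for a series of length T
hrf_spectrum_max <- function(kernel, T) {
  pad <- min(T - 1L, max(8L * length(kernel), 256L))
  L <- T + 2L * pad
  max(Mod(stats::fft(c(kernel, numeric(L - length(kernel)))))^2)
}

#' Wiener deconvolution of a BOLD-like series
#'
#' Recovers a neural-activity proxy by regularized inverse filtering in the
#' frequency domain: `N(w) = Conj(H(w)) B(w) / (|H(w)|^2 + lambda)`. The
#' series is padded by odd reflection before the FFT to avoid wrap-around
#' artefacts and the output is standardized, so the estimate is
#' scale-equivariant.
#'
#' @param x numeric series.
#' @param hrf an `"hrf_model"` or a raw numeric kernel.
#' @param lambda ridge regularization (>= 0); default
#'   `0.1 * max(|H(w)|^2)`. `lambda = 0` is rejected when the kernel
#'   spectrum has near-zero bins (ill-posed inversion).
#' @return standardized numeric series of the same length, with the model
#'   and `lambda` attached as attributes `hrf` and `lambda`.
#' @export
wiener_deconvolve <- function(x, hrf, lambda = NULL) {
  kernel <- if (inherits(hrf, "hrf_model")) hrf$kernel else as.numeric(hrf)
  if (all(kernel == 0)) stop("HRF kernel is identically zero")
  T <- length(x)
  # anti-symmetric (odd) reflection keeps both value and trend continuous at
  # the junctions; discontinuities there would be amplified globally by the
  # near-inverse filter
  pad <- min(T - 1L, max(8L * length(kernel), 256L))
  xp <- c(2 * x[1] - rev(x[2:(pad + 1)]), x,
          2 * x[T] - rev(x[(T - pad):(T - 1)]))
  L <- length(xp)
  H <- stats::fft(c(kernel, numeric(L - length(kernel))))
  P <- Mod(H)^2
  if (is.null(lambda)) lambda <- 0.1 * max(P)
  if (lambda < 0) stop("lambda must be >= 0")
  if (lambda == 0 && min(P) < 1e-6 * max(P)) {
    stop("lambda = 0 with near-zero HRF spectrum bins: ill-posed; ",
         "pass lambda > 0")
  }
  Bf <- stats::fft(xp)
  nf <- Re(stats::fft(Conj(H) * Bf / (P + lambda), inverse = TRUE)) / L
  out <- nf[pad + seq_len(T)]
  s <- stats::sd(out)
  out <- if (s > 0) (out - mean(out)) / s else out - mean(out)
  attr(out, "hrf") <- if (inherits(hrf, "hrf_model")) hrf else NULL
  attr(out, "lambda") <- lambda
  out
}

#' Deconvolve every series of a time-series set
#'
#' Per subject, session and node: estimate the HRF blindly and apply Wiener
#' deconvolution, yielding neural-activity proxies on which directed
#' connectivity is then computed. Each session's series is handled
#' independently, matching per-signal deconvolution.
#'
#' @param nts an `"nts_set"`.
#' @param pool_sessions if `TRUE` (default) estimate one kernel per
#'   subject-node from all sessions via [estimate_hrf_pooled()]; otherwise
#'   estimate per session with [estimate_hrf_blind()].
#' @param lag_grid,threshold passed to the estimator.
#' @param basis per-session basis (`pool_sessions = FALSE` only).
#' @param lambda passed to [wiener_deconvolve()] (`NULL` = default ridge).
#' @return list: `nts` (deconvolved `"nts_set"`) and `hrf_table` (data frame
#'   `subject,session,node,peak_latency_s,lag_samples,flag`).
#' @export
deconvolve_set <- function(nts, pool_sessions = TRUE, lag_grid = 0:14,
                           basis = "canonical", threshold = 1.0,
                           lambda = NULL) {
  stopifnot(inherits(nts, "nts_set"))
  rows <- list()
  out <- nts
  for (sid in names(nts$subjects)) {
    sess <- nts$subjects[[sid]]
    nsx <- length(sess)
    for (j in seq_len(ncol(sess[[1]]))) {
      hms <- if (pool_sessions) {
        hm <- estimate_hrf_pooled(lapply(sess, function(S) S[, j]), nts$TR,
                                  lag_grid = lag_grid, threshold = threshold)
        rep(list(hm), nsx)
      } else {
        lapply(sess, function(S)
          estimate_hrf_blind(S[, j], nts$TR, lag_grid = lag_grid,
                             basis = basis, threshold = threshold))
      }
      for (se in seq_len(nsx)) {
        out$subjects[[sid]][[se]][, j] <- as.numeric(
          wiener_deconvolve(sess[[se]][, j], hms[[se]], lambda = lambda))
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sid, session = se, node = nts$labels[j],
          peak_latency_s = hms[[se]]$peak_latency,
          lag_samples = hms[[se]]$lag, flag = hms[[se]]$flag)
      }
    }
  }
  rows <- do.call(rbind, rows)
  rows <- rows[order(rows$subject, rows$session, rows$node), ]
  rownames(rows) <- NULL
  list(nts = out, hrf_table = rows)
}
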