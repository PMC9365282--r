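#' Detrend a luminescence trace
#'
#' Removes slow baseline drift before rhythmicity testing. The default
#' subtracts an ordinary least-squares line fit over (time, signal); the
#' \code{"movavg"} method subtracts a centered moving-average baseline with
#' a 24 h window, shrinking the window at the edges.
#'
#' @param trace a \code{\link{new_trace}} object with at least 3 points.
#' @param method \code{"linear"} (default) or \code{"movavg"}.
#' @param window_h moving-average window in hours (movavg only).
#' @return detrended \code{chrono_trace}.
#' @export
detrend_trace <- function(trace, method = c("linear", "movavg"),
                          window_h = 24) {
  stopifnot(inherits(trace, "chrono_trace"))
  method <- tryCatch(match.arg(method),
                     error = function(e) stopf("unknown detrend method '%s'",
                                               method[1]))
  if (length(trace$times) < 3) stopf("detrending needs at least 3 points")
  baseline <- switch(method,
    linear = {
      fit <- stats::lm.fit(cbind(1, trace$times), trace$values)
      drop(cbind(1, trace$times) %*% fit$coefficients)
    },
    movavg = {
      half <- window_h / 2
      vapply(seq_along(trace$times), function(i) {
        sel <- abs(trace$times - trace$times[i]) <= half
        mean(trace$values[sel])
      }, numeric(1))
    })
  out <- trace
  out$values <- trace$values - baseline
  out
}

#' Exact two-sided p-value for Kendall's S statistic
#'
#' Computes \eqn{P(|S_{null}| \ge |S|)} under the uniform-permutation null
#' using the inversion-count recursion (the number of permutations of n
#' items with k inversions): a permutation with k inversions has
#' \eqn{S = n(n-1)/2 - 2k}. For \eqn{n > 50} the normal approximation with
#' variance \eqn{n(n-1)(2n+5)/18} is used.
#'
#' @param n number of observations (at least 3).
#' @param S Kendall score, concordant minus discordant pairs;
#'   \eqn{|S| \le n(n-1)/2}.
#' @return two-sided p-value.
#' @export
kendall_exact_pvalue <- function(n, S) {
  n <- check_count(n, "n", min = 3)
  max_s <- n * (n - 1) / 2
  if (abs(S) > max_s) stopf("|S| = %g exceeds the maximum %g", abs(S), max_s)
  if (n > 50) {
    sd_s <- sqrt(n * (n - 1) * (2 * n + 5) / 18)
    return(min(1, 2 * stats::pnorm(-abs(S) / sd_s)))
  }
  pmf <- kendall_inversion_pmf(n)
  k <- 0:max_s
  in_tail <- abs(max_s - 2 * k) >= abs(S)
  if (all(in_tail)) return(1)
  min(1, sum(pmf[in_tail]))
}

# pmf of the inversion count of a uniform random permutation of n items:
# successive convolution of Uniform{0..i-1} pmfs
kendall_inversion_pmf <- function(n) {
  pmf <- 1
  for (i in 2:n) {
    new <- numeric(length(pmf) + i - 1)
    for (j in 0:(i - 1)) {
      idx <- seq_along(pmf) + j
      new[idx] <- new[idx] + pmf / i
    }
    pmf <- new
  }
  pmf
}

# Kendall S between x and y over pairs non-tied in both
kendall_S <- function(x, y) {
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  up <- upper.tri(sx)
  sum(sx[up] * sy[up])
}

#' JTK_CYCLE rhythmicity test
#'
#' Nonparametric test of circadian rhythmicity: the (detrended) trace is
#' rank-correlated via Kendall's S against cosine reference curves of the
#' preset period at every candidate phase; the best \eqn{|S|} is converted
#' to a p-value with the exact permutation null
#' (\code{\link{kendall_exact_pvalue}}) and Bonferroni-corrected for the
#' number of phase (and period, if scanned) alternatives.
#'
#' @param trace detrended \code{chrono_trace} with at least 12 points.
#' @param period_preset_h reference period in hours (default 24).
#' @param phase_step_h candidate-phase spacing; defaults to the sampling
#'   interval.
#' @param period_scan_h optional numeric vector of periods to scan instead
#'   of the single preset (e.g. \code{seq(20, 28, by = 1)}).
#' @return object of class \code{jtk_result}: list with \code{p_value}
#'   (Bonferroni-corrected, capped at 1), \code{best_phase_h},
#'   \code{best_period_h}, \code{tau}, \code{S} and \code{n_alternatives}.
#' @export
jtk_cycle <- function(trace, period_preset_h = 24, phase_step_h = NULL,
                      period_scan_h = NULL) {
  stopifnot(inherits(trace, "chrono_trace"))
  t <- trace$times
  v <- trace$values
  if (length(v) < 12) stopf("jtk_cycle needs at least 12 points")
  periods <- if (is.null(period_scan_h)) period_preset_h else period_scan_h
  step <- phase_step_h %||% stats::median(diff(t))
  n <- length(v)
  max_pairs <- n * (n - 1) / 2

  sv <- sign(outer(v, v, "-"))
  up <- upper.tri(sv)
  sv_up <- sv[up]
  if (all(sv_up == 0)) {
    return(structure(list(p_value = 1, best_phase_h = 0,
                          best_period_h = periods[1], tau = 0, S = 0L,
                          n_alternatives = 0L),
                     class = "jtk_result"))
  }

  best <- list(S = 0, phase = 0, period = periods[1])
  n_alt <- 0L
  for (T_h in periods) {
    phases <- seq(0, T_h - step, by = step)
    for (ph in phases) {
      ref <- cos(2 * pi * (t - ph) / T_h)
      sr <- sign(outer(ref, ref, "-"))
      S <- sum(sv_up * sr[up])
      n_alt <- n_alt + 1L
      if (abs(S) > abs(best$S)) best <- list(S = S, phase = ph, period = T_h)
    }
  }
  p_raw <- kendall_exact_pvalue(n, best$S)
  structure(list(p_value = min(1, p_raw * n_alt),
                 best_phase_h = best$phase,
                 best_period_h = best$period,
                 tau = best$S / max_pairs,
                 S = best$S,
                 n_alternatives = n_alt),
            class = "jtk_result")
}

#' FFT-NLLS damped-cosine fit
#'
#' Estimates period and amplitude by fitting
#' \deqn{y(t) = A e^{-d (t - t_0)} \cos(2\pi (t - \phi)/T) + c}
#' with nonlinear least squares (Levenberg-Marquardt), initialized from the
#' dominant discrete-Fourier component inside the period band. The reported
#' amplitude is the fitted envelope at the start of the recording; the
#' relative amplitude error (RAE) is the half-width of the amplitude's
#' asymptotic 95\% confidence interval divided by the amplitude.
#'
#' @param trace detrended \code{chrono_trace} with at least 12 points.
#' @param period_band_h allowed period range in hours for the Fourier
#'   initialization (default \code{c(18, 34)}).
#' @return object of class \code{rhythm_fit}: list with \code{period_h},
#'   \code{amplitude}, \code{damping_per_h}, \code{phase_h}, \code{rae} and
#'   \code{rss}. A fit with no usable Fourier component (or a failed
#'   optimization) carries \code{period_h = 0}.
#' @export
fft_nlls_fit <- function(trace, period_band_h = c(18, 34)) {
  stopifnot(inherits(trace, "chrono_trace"))
  t0 <- trace$times[1]
  t <- trace$times - t0
  v <- trace$values
  n <- length(v)
  if (n < 12) stopf("fft_nlls_fit needs at least 12 points")

  dt <- stats::median(diff(t))
  span <- n * dt
  ft <- stats::fft(v - mean(v))
  k <- seq_len(floor(n / 2))
  periods_k <- span / k
  in_band <- periods_k >= period_band_h[1] & periods_k <= period_band_h[2]
  unusable <- structure(list(period_h = 0, amplitude = 0,
                             damping_per_h = 0, phase_h = 0, rae = Inf,
                             rss = sum((v - mean(v))^2)),
                        class = "rhythm_fit")
  if (!any(in_band)) return(unusable)
  kk <- k[in_band][which.max(Mod(ft[k + 1][in_band]))]
  A0 <- 2 * Mod(ft[kk + 1]) / n
  T0 <- span / kk
  phi0 <- ((-Arg(ft[kk + 1]) / (2 * pi)) * T0) %% T0

  resid_fn <- function(par) {
    v - (par[1] * exp(-par[2] * t) * cos(2 * pi * (t - par[3]) / par[4]) +
           par[5])
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(A = A0, d = 0, phi = phi0, T = T0,
                               c = mean(v)),
                       fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$deviance)) return(unusable)

  par <- fit$par
  if (par["T"] <= 0) return(unusable)
  if (par["A"] < 0) {   # fold the sign into the phase
    par["A"] <- -par["A"]
    par["phi"] <- par["phi"] + par["T"] / 2
  }
  par["phi"] <- par["phi"] %% par["T"]

  df <- n - length(par)
  rae <- Inf
  # asymptotic covariance from a finite-difference Jacobian at the optimum
  se_A <- tryCatch({
    jac <- vapply(seq_along(par), function(p) {
      h <- 1e-6 * max(1, abs(par[p]))
      hi <- par; hi[p] <- hi[p] + h
      lo <- par; lo[p] <- lo[p] - h
      (resid_fn(lo) - resid_fn(hi)) / (2 * h)
    }, numeric(n))
    covm <- fit$deviance / df * chol2inv(chol(crossprod(jac)))
    sqrt(covm[1, 1])
  }, error = function(e) NA_real_)
  if (is.finite(se_A) && par["A"] > 0) {
    rae <- stats::qt(0.975, df) * se_A / par["A"]
  }
  structure(list(period_h = unname(par["T"]),
                 amplitude = unname(par["A"]),
                 damping_per_h = unname(par["d"]),
                 phase_h = unname(par["phi"]) + t0,
                 rae = unname(rae),
                 rss = fit$deviance),
            class = "rhythm_fit")
}

#' Classify a trace as rhythmic or nonrhythmic
#'
#' A trace is called rhythmic only if the JTK_CYCLE p-value is below the
#' threshold (default \eqn{P < 0.001}) \emph{and} the FFT-NLLS period lies
#' inside the circadian gate (default 22--30 h, strict bounds: a period
#' shorter than 22 h or longer than 30 h is nonrhythmic, NR).
#'
#' @param jtk a \code{\link{jtk_cycle}} result.
#' @param fit a \code{\link{fft_nlls_fit}} result on the same trace.
#' @param p_threshold rhythmicity p-value cutoff (default 0.001).
#' @param period_lo,period_hi period gate in hours (defaults 22 and 30).
#' @return object of class \code{rhythm_call}: list with \code{rhythmic},
#'   \code{reason} (\code{"ok"}, \code{"p_above_threshold"},
#'   \code{"period_short"} or \code{"period_long"}), \code{p_value},
#'   \code{period_h} and \code{amplitude} (the latter two \code{NA} for NR
#'   calls).
#' @export
classify_rhythm <- function(jtk, fit, p_threshold = 0.001,
                            period_lo = 22, period_hi = 30) {
  stopifnot(inherits(jtk, "jtk_result"), inherits(fit, "rhythm_fit"))
  reason <- if (!(jtk$p_value < p_threshold)) "p_above_threshold"
            else if (fit$period_h < period_lo) "period_short"
            else if (fit$period_h > period_hi) "period_long"
            else "ok"
  rhythmic <- reason == "ok"
  structure(list(rhythmic = rhythmic, reason = reason,
                 p_value = jtk$p_value,
                 period_h = if (rhythmic) fit$period_h else NA_real_,
                 amplitude = if (rhythmic) fit$amplitude else NA_real_),
            class = "rhythm_call")
}

#' Tumor/normal amplitude ratios for matched organoid pairs
#'
#' For each patient the tumor amplitude is normalized to the matched normal
#' amplitude. A tumor called NR but with a usable fit still contributes its
#' fitted amplitude (flagged); an unusable tumor fit yields a missing
#' ratio. Patients without a normal partner are skipped with a warning.
#'
#' @param fits named list of \code{\link{fft_nlls_fit}} results keyed by
#'   sample id.
#' @param calls named list of \code{\link{classify_rhythm}} results keyed by
#'   sample id.
#' @param pairing data frame with columns \code{patient_id},
#'   \code{normal_sample}, \code{tumor_sample}.
#' @return data frame with columns \code{patient_id}, \code{normal_amp},
#'   \code{tumor_amp}, \code{ratio}, \code{tumor_nr} (flag: ratio taken
#'   from an NR tumor fit).
#' @export
amplitude_ratio <- function(fits, calls, pairing) {
  out <- lapply(seq_len(nrow(pairing)), function(i) {
    pid <- pairing$patient_id[i]
    nid <- pairing$normal_sample[i]
    tid <- pairing$tumor_sample[i]
    if (!nid %in% names(fits)) {
      warnf("patient %s skipped: no normal partner '%s'", pid, nid)
      return(NULL)
    }
    nfit <- fits[[nid]]
    if (nfit$period_h == 0 || nfit$amplitude <= 0) {
      warnf("patient %s skipped: normal fit unusable", pid)
      return(NULL)
    }
    tfit <- fits[[tid]]
    tumor_nr <- !isTRUE(calls[[tid]]$rhythmic)
    tumor_amp <- if (!is.null(tfit) && tfit$period_h > 0) tfit$amplitude
                 else NA_real_
    data.frame(patient_id = pid, normal_amp = nfit$amplitude,
               tumor_amp = tumor_amp, ratio = tumor_amp / nfit$amplitude,
               tumor_nr = tumor_nr, stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), out))
}

#' Wilcoxon matched-pair signed-rank test
#'
#' Two-sided one-sample signed-rank test of paired ratios against a null
#' value. For \eqn{n \le 25} non-zero differences the null distribution is
#' exact, enumerating all \eqn{2^n} sign assignments (ties mid-ranked, via
#' a convolution over doubled ranks); above that a normal approximation
#' with continuity correction and tie-corrected variance is used. Zero
#' differences are dropped.
#'
#' @param x observed values (e.g. tumor/normal amplitude ratios).
#' @param null_value hypothesized center (default 1).
#' @return list of class \code{chrono_test} with \code{statistic} (V, the
#'   positive-rank sum), \code{p_value} and \code{n} (non-zero differences).
#' @export
wilcoxon_signed_rank <- function(x, null_value = 1) {
  d <- x[!is.na(x)] - null_value
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(structure(list(statistic = 0, p_value = 1, n = 0L),
                     class = "chrono_test"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= 25) {
    w <- as.integer(round(2 * r))     # doubled mid-ranks are integers
    f <- 1
    for (wk in w) f <- (c(f, rep(0, wk)) + c(rep(0, wk), f)) / 2
    v2 <- as.integer(round(2 * V))
    cdf_lo <- sum(f[seq_len(v2 + 1)])
    cdf_hi <- sum(f[(v2 + 1):length(f)])
    p <- min(1, 2 * min(cdf_lo, cdf_hi))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  structure(list(statistic = V, p_value = p, n = n), class = "chrono_test")
}

#' Run the full rhythm pipeline on a trace set
#'
#' Detrends every trace, applies \code{\link{jtk_cycle}} and
#' \code{\link{fft_nlls_fit}}, and classifies each sample with
#' \code{\link{classify_rhythm}}.
#'
#' @param trace_set long trace table (see \code{\link{generate_traces}}).
#' @param detrend_method passed to \code{\link{detrend_trace}}.
#' @param p_threshold,period_lo,period_hi gates passed to
#'   \code{\link{classify_rhythm}}.
#' @param period_preset_h,period_scan_h passed to \code{\link{jtk_cycle}}.
#' @return list with \code{report} (one row per sample: p, period,
#'   amplitude, rae, verdict, reason; NR periods/amplitudes are \code{NA}),
#'   \code{fits}, \code{calls} and \code{detrended} traces.
#' @export
rhythm_pipeline <- function(trace_set, detrend_method = "linear",
                            p_threshold = 0.001, period_lo = 22,
                            period_hi = 30, period_preset_h = 24,
                            period_scan_h = NULL) {
  traces <- split_traces(trace_set)
  det <- lapply(traces, detrend_trace, method = detrend_method)
  jtks <- lapply(det, jtk_cycle, period_preset_h = period_preset_h,
                 period_scan_h = period_scan_h)
  fits <- lapply(det, fft_nlls_fit)
  calls <- Map(classify_rhythm, jtks, fits,
               MoreArgs = list(p_threshold = p_threshold,
                               period_lo = period_lo,
                               period_hi = period_hi))
  report <- data.frame(
    sample_id = names(det),
    patient_id = vapply(traces, function(x) x$patient_id, character(1)),
    p_value = vapply(jtks, function(x) x$p_value, numeric(1)),
    period_h = vapply(calls, function(x) x$period_h, numeric(1)),
    amplitude = vapply(calls, function(x) x$amplitude, numeric(1)),
    rae = vapply(fits, function(x) x$rae, numeric(1)),
    verdict = vapply(calls, function(x)
      if (x$rhythmic) "rhythmic" else "NR", character(1)),
    reason = vapply(calls, function(x) x$reason, character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  list(report = report, fits = fits, calls = calls, detrended = det)
}

#' Z-scored trace matrix for rhythm heatmaps
#'
#' Builds the matrix behind per-sample rhythmicity heatmaps: each detrended
#' trace is z-scored and laid out as one row over time bins.
#'
#' @param detrended named list of detrended \code{chrono_trace} objects on a
#'   common time grid.
#' @return numeric matrix, rows = samples, columns = time points (hours).
#' @export
rhythm_heatmap_matrix <- function(detrended) {
  mat <- do.call(rbind, lapply(detrended, function(tr) {
    s <- stats::sd(tr$values)
    if (s == 0) rep(0, length(tr$values))
    else (tr$values - mean(tr$values)) / s
  }))
  colnames(mat) <- detrended[[1]]$times
  mat
}
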