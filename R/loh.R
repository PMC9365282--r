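#' Normalize depth tracks to the largest data store
#'
#' Scales every sample's counts so all totals equal the largest sample's
#' total (the largest "data store"), absorbing library-size differences.
#'
#' @param tracks a \code{depth_track_set}
#'   (see \code{\link{generate_depth_tracks}} / \code{\link{read_depth}}).
#' @return the track set with scaled (no longer integer) counts; per-sample
#'   scale factors are attached as attribute \code{"offsets"} on the counts.
#' @export
normalize_depth <- function(tracks) {
  stopifnot(inherits(tracks, "depth_track_set"))
  totals <- colSums(tracks$counts)
  if (any(totals == 0)) {
    stopf("sample(s) with zero total depth: %s",
          paste(colnames(tracks$counts)[totals == 0], collapse = ", "))
  }
  scale <- max(totals) / totals
  tracks$counts <- sweep(tracks$counts, 2, scale, "*")
  attr(tracks$counts, "offsets") <- scale
  tracks
}

#' Length-corrected log2 interval quantification
#'
#' \eqn{value = \log_2((count + pseudocount) / length_{kb})}, with interval
#' length taken from the BED coordinates (end - start).
#'
#' @param tracks normalized \code{depth_track_set}.
#' @param pseudocount added before the log (default 1).
#' @return object of class \code{interval_matrix}: list with
#'   \code{log2_values} (intervals x samples), \code{intervals},
#'   \code{groups} and \code{offsets}.
#' @export
quantify_intervals <- function(tracks, pseudocount = 1) {
  stopifnot(inherits(tracks, "depth_track_set"))
  len_kb <- (tracks$intervals$end - tracks$intervals$start) / 1000
  if (any(len_kb <= 0)) stopf("zero-length interval in input")
  vals <- log2((tracks$counts + pseudocount) / len_kb)
  structure(list(log2_values = vals,
                 intervals = tracks$intervals,
                 groups = tracks$groups,
                 offsets = attr(tracks$counts, "offsets")),
            class = "interval_matrix")
}

# moment-matching fit of the scaled inverse-chi-square variance prior:
# matches the mean and variance of log s^2 across intervals
# (digamma/trigamma moments of the log chi-square distribution)
estimate_moderation_prior <- function(s2, d) {
  z <- log(s2)
  z <- z[is.finite(z)]
  if (length(z) < 2) return(list(d0 = 0, s0_sq = mean(s2)))
  excess <- stats::var(z) - psigamma(d / 2, 1)
  if (excess <= 0) {
    d0 <- Inf
    log_s0 <- mean(z) - digamma(d / 2) + log(d / 2)
  } else {
    # invert trigamma(d0/2) = excess by Newton iteration
    x <- 0.5 + 1 / excess
    for (i in 1:60) {
      step <- (psigamma(x, 1) - excess) / psigamma(x, 2)
      x <- x - step
      if (x <= 0) x <- 1e-8
      if (abs(step) < 1e-10 * x) break
    }
    d0 <- 2 * x
    log_s0 <- mean(z) - digamma(d / 2) + log(d / 2) +
      digamma(d0 / 2) - log(d0 / 2)
  }
  list(d0 = d0, s0_sq = exp(log_s0))
}

#' Empirical-Bayes moderated two-group test per interval
#'
#' For each interval the late-vs-early mean difference is tested with a
#' moderated t statistic: the pooled residual variance \eqn{s^2} (d degrees
#' of freedom) is shrunk toward a prior \eqn{s_0^2} with prior degrees of
#' freedom \eqn{d_0},
#' \deqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d),}
#' and \eqn{t = \Delta / (\tilde s \sqrt{1/n_1 + 1/n_2})} is referred to a
#' t distribution on \eqn{d_0 + d} df. With \code{prior = "estimate"} the
#' prior is fit by matching the first two moments of \eqn{\log s^2} across
#' intervals. \code{d0 = 0} recovers the ordinary pooled t;
#' \code{d0 = Inf} a fixed-variance z-like statistic.
#'
#' @param im an \code{\link{quantify_intervals}} result.
#' @param groups per-sample labels (\code{"early"}/\code{"late"}); defaults
#'   to the labels carried by \code{im}. At least 2 samples per group.
#' @param prior \code{"estimate"} or a list with elements \code{d0} and
#'   \code{s0_sq}.
#' @return data frame with one row per interval: BED coordinates,
#'   \code{mean_early}, \code{mean_late}, \code{log2fc} (late - early),
#'   \code{s2}, \code{t_mod}, \code{df_total}, \code{p_value}; the fitted
#'   prior is attached as attribute \code{"prior"}.
#' @export
moderated_t_test <- function(im, groups = NULL, prior = "estimate") {
  stopifnot(inherits(im, "interval_matrix"))
  groups <- groups %||% im$groups
  x <- im$log2_values
  g_early <- groups == "early"
  g_late <- groups == "late"
  n1 <- sum(g_early); n2 <- sum(g_late)
  if (n1 < 2 || n2 < 2) stopf("each group needs at least 2 samples")
  d <- n1 + n2 - 2

  m1 <- rowMeans(x[, g_early, drop = FALSE])
  m2 <- rowMeans(x[, g_late, drop = FALSE])
  ss1 <- rowSums((x[, g_early, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, g_late, drop = FALSE] - m2)^2)
  s2 <- (ss1 + ss2) / d
  diff <- m2 - m1

  if (identical(prior, "estimate")) prior <- estimate_moderation_prior(s2, d)
  d0 <- prior$d0; s0_sq <- prior$s0_sq
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
             else (d0 * s0_sq + d * s2) / (d0 + d)
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  t_mod <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, Inf * sign(diff)))
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  p[se == 0 & diff == 0] <- 1

  out <- data.frame(im$intervals, mean_early = m1, mean_late = m2,
                    log2fc = diff, s2 = s2, t_mod = t_mod,
                    df_total = df_total, p_value = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "prior") <- list(d0 = d0, s0_sq = s0_sq)
  out
}

#' Call contiguous LOH segments from per-interval statistics
#'
#' Reports maximal runs of at least \code{min_run} consecutive intervals
#' that each drop below the fold-change threshold and pass the p-value
#' filter (default \eqn{P < 0.01}).
#'
#' @param stats per-interval statistics from \code{\link{moderated_t_test}}.
#' @param log2fc_threshold maximum log2 fold change (default -1, a halving).
#' @param p_threshold per-interval significance filter (default 0.01).
#' @param min_run minimum number of consecutive intervals (default 3).
#' @return data frame of segments (possibly empty): \code{start_index},
#'   \code{end_index} (0-based half-open interval indices), \code{chrom},
#'   \code{start}, \code{end} (bp), \code{mean_log2fc},
#'   \code{n_significant}.
#' @export
detect_loh_segment <- function(stats, log2fc_threshold = -1,
                               p_threshold = 0.01, min_run = 3) {
  hit <- stats$log2fc <= log2fc_threshold & stats$p_value < p_threshold
  r <- rle(hit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= min_run
  out <- lapply(which(keep), function(i) {
    idx <- starts[i]:ends[i]
    data.frame(start_index = as.integer(starts[i] - 1L),
               end_index = as.integer(ends[i]),
               chrom = stats$chrom[starts[i]],
               start = stats$start[starts[i]], end = stats$end[ends[i]],
               mean_log2fc = mean(stats$log2fc[idx]),
               n_significant = length(idx), stringsAsFactors = FALSE)
  })
  if (length(out) == 0) {
    return(data.frame(start_index = integer(0), end_index = integer(0),
                      chrom = character(0), start = integer(0),
                      end = integer(0), mean_log2fc = numeric(0),
                      n_significant = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Run the full LOH depth pipeline
#'
#' Normalization to the largest data store, length-corrected log2
#' quantification, moderated t filtering and segment calling. Input counts
#' are expected to come from alignments already filtered for mapping
#' quality (MAPQ >= 20) and proper pair distance (<= 1000 bp).
#'
#' @param tracks a \code{depth_track_set}.
#' @param p_threshold,log2fc_threshold,min_run passed to
#'   \code{\link{detect_loh_segment}}.
#' @param prior passed to \code{\link{moderated_t_test}}.
#' @return list with \code{stats} (per-interval table) and \code{segments}.
#' @export
loh_pipeline <- function(tracks, p_threshold = 0.01, log2fc_threshold = -1,
                         min_run = 3, prior = "estimate") {
  im <- quantify_intervals(normalize_depth(tracks))
  stats <- moderated_t_test(im, prior = prior)
  segments <- detect_loh_segment(stats, log2fc_threshold = log2fc_threshold,
                                 p_threshold = p_threshold,
                                 min_run = min_run)
  list(stats = stats, segments = segments)
}
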