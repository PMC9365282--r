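#' Poisson-corrected template concentration from partition counts
#'
#' Template molecules distribute across digital-PCR partitions approximately
#' Poisson, so the mean copies per partition is
#' \eqn{\lambda = -\ln(1 - \hat p)} where \eqn{\hat p} is the fraction of
#' positive partitions. The 95\% confidence interval is the Wilson interval
#' on \eqn{\hat p} transformed through \eqn{-\ln(1 - \cdot)}.
#'
#' @param positive number of positive partitions in the channel.
#' @param total total partitions (typically 20,000).
#' @return object of class \code{concentration_estimate}: list with
#'   \code{lam}, \code{ci_lo}, \code{ci_hi} (copies/partition) and
#'   \code{positive_fraction}.
#' @export
estimate_concentration <- function(positive, total) {
  total <- check_count(total, "total")
  positive <- check_count(positive, "positive", min = 0)
  if (positive > total) stopf("positive (%d) exceeds total (%d)",
                              positive, total)
  if (positive == total) {
    stopf("all %d partitions positive: plate saturated, lambda undefined",
          total)
  }
  p_hat <- positive / total
  z <- stats::qnorm(0.975)
  denom <- 1 + z^2 / total
  center <- (p_hat + z^2 / (2 * total)) / denom
  half <- z * sqrt(p_hat * (1 - p_hat) / total + z^2 / (4 * total^2)) / denom
  p_lo <- max(0, center - half)
  p_hi <- min(1 - 1 / (2 * total), center + half)  # keep the log finite
  structure(list(lam = -log(1 - p_hat),
                 ci_lo = -log(1 - p_lo),
                 ci_hi = -log(1 - p_hi),
                 positive_fraction = p_hat),
            class = "concentration_estimate")
}

#' Copy number of a target locus relative to a reference locus
#'
#' \eqn{CNV = ref\_copies \cdot \lambda_{target} / \lambda_{reference}}.
#' The confidence interval combines both channels' relative CI half-widths
#' by first-order error propagation. The state call uses configurable
#' thresholds: below \code{hom} is homozygous loss, up to \code{het} is
#' heterozygous loss, up to \code{gain} is diploid, above that a gain.
#'
#' @param target,reference \code{\link{estimate_concentration}} results for
#'   the two channels.
#' @param ref_copies copies of the reference locus per genome (default 2).
#' @param thresholds named vector \code{c(hom=, het=, gain=)}; defaults
#'   \code{c(0.3, 1.5, 2.5)}.
#' @return object of class \code{copy_number_result}: list with \code{cnv},
#'   \code{ci_lo}, \code{ci_hi} and \code{state}.
#' @export
estimate_copy_number <- function(target, reference, ref_copies = 2,
                                 thresholds = c(hom = 0.3, het = 1.5,
                                                gain = 2.5)) {
  stopifnot(inherits(target, "concentration_estimate"),
            inherits(reference, "concentration_estimate"))
  if (reference$lam <= 0) stopf("reference channel failed (lambda = 0)")
  cnv <- ref_copies * target$lam / reference$lam
  hw_r <- (reference$ci_hi - reference$ci_lo) / 2
  if (target$lam > 0) {
    hw_t <- (target$ci_hi - target$ci_lo) / 2
    rel <- sqrt((hw_t / target$lam)^2 + (hw_r / reference$lam)^2)
    ci_lo <- max(0, cnv * (1 - rel))
    ci_hi <- cnv * (1 + rel)
  } else {
    ci_lo <- 0
    ci_hi <- ref_copies * target$ci_hi / reference$lam
  }
  state <- if (!is.finite(cnv)) "indeterminate"
           else if (cnv < thresholds[["hom"]]) "homozygous_loss"
           else if (cnv < thresholds[["het"]]) "het_loss"
           else if (cnv <= thresholds[["gain"]]) "diploid"
           else "gain"
  structure(list(cnv = cnv, ci_lo = ci_lo, ci_hi = ci_hi, state = state),
            class = "copy_number_result")
}

#' Copy-number estimation for a table of dPCR plates
#'
#' @param plates data frame with columns \code{sample_id},
#'   \code{n_partitions}, \code{target_positive}, \code{reference_positive}
#'   (as read by \code{\link{read_plates}}), or a single
#'   \code{partition_plate}.
#' @param ref_copies reference-locus copies (default 2).
#' @param thresholds passed to \code{\link{estimate_copy_number}}.
#' @return data frame with one row per plate: \code{sample_id},
#'   \code{lam_target}, \code{lam_ref}, \code{cnv}, \code{ci_lo},
#'   \code{ci_hi}, \code{state}.
#' @export
dpcr_pipeline <- function(plates, ref_copies = 2,
                          thresholds = c(hom = 0.3, het = 1.5, gain = 2.5)) {
  if (inherits(plates, "partition_plate")) {
    plates <- data.frame(sample_id = plates$sample_id,
                         n_partitions = plates$n_partitions,
                         target_positive = plates$target_positive,
                         reference_positive = plates$reference_positive,
                         stringsAsFactors = FALSE)
  }
  rows <- lapply(seq_len(nrow(plates)), function(i) {
    tg <- estimate_concentration(plates$target_positive[i],
                                 plates$n_partitions[i])
    rf <- estimate_concentration(plates$reference_positive[i],
                                 plates$n_partitions[i])
    cn <- estimate_copy_number(tg, rf, ref_copies = ref_copies,
                               thresholds = thresholds)
    data.frame(sample_id = plates$sample_id[i], lam_target = tg$lam,
               lam_ref = rf$lam, cnv = cn$cnv, ci_lo = cn$ci_lo,
               ci_hi = cn$ci_hi, state = cn$state, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
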