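#' Filter for expressed genes
#'
#' Keeps a gene only if it is above zero in strictly more than 50\% of
#' samples.
#'
#' @param expression genes x samples numeric matrix.
#' @return the filtered matrix (possibly zero rows, with a warning).
#' @export
filter_expressed_genes <- function(expression) {
  stopifnot(is.matrix(expression), length(expression) > 0)
  frac_pos <- rowMeans(expression > 0)
  keep <- frac_pos > 0.5
  if (!any(keep)) warnf("no gene passes the >0 in >50%% of samples filter")
  expression[keep, , drop = FALSE]
}

#' Split samples into tumor and normal by TCGA sample code
#'
#' The two-digit barcode suffix identifies the tissue: codes 01-09 are
#' tumors, 10-19 normals. Samples with other or unparseable codes are
#' excluded with a warning.
#'
#' @param sample_ids character vector of barcode-style sample identifiers,
#'   or a clinical data frame with a \code{sample_id} column.
#' @return list with \code{tumor_ids} and \code{normal_ids}.
#' @export
split_by_sample_code <- function(sample_ids) {
  if (is.data.frame(sample_ids)) sample_ids <- sample_ids$sample_id
  m <- regmatches(sample_ids, regexpr("-([0-9]{2})$", sample_ids))
  code <- rep(NA_integer_, length(sample_ids))
  ok <- lengths(regmatches(sample_ids,
                           gregexpr("-([0-9]{2})$", sample_ids))) > 0
  code[ok] <- as.integer(sub("-", "", m))
  tumor <- !is.na(code) & code >= 1 & code <= 9
  normal <- !is.na(code) & code >= 10 & code <= 19
  dropped <- !(tumor | normal)
  if (any(dropped)) {
    warnf("%d sample(s) excluded (unknown or missing sample code): %s",
          sum(dropped),
          paste(utils::head(sample_ids[dropped], 5), collapse = ", "))
  }
  list(tumor_ids = sample_ids[tumor], normal_ids = sample_ids[normal])
}

#' Per-gene tumor vs normal differential test
#'
#' Two-sided unequal-variance (Welch) t test per gene, flagged significant
#' at \eqn{P < 0.001}. A gene constant in both groups yields \eqn{p = 1}
#' when the means agree.
#'
#' @param expression genes x samples matrix.
#' @param tumor_ids,normal_ids sample columns for each side (at least 2
#'   each).
#' @param genes genes to test; default all rows.
#' @param alpha significance flag threshold (default 0.001).
#' @return data frame with \code{gene}, \code{mean_tumor},
#'   \code{mean_normal}, \code{diff}, \code{t}, \code{df}, \code{p_value},
#'   \code{significant}.
#' @export
differential_means_test <- function(expression, tumor_ids, normal_ids,
                                    genes = rownames(expression),
                                    alpha = 0.001) {
  if (length(tumor_ids) < 2 || length(normal_ids) < 2) {
    stopf("need at least 2 samples per side")
  }
  rows <- lapply(genes, function(g) {
    xt <- expression[g, tumor_ids]
    xn <- expression[g, normal_ids]
    if (stats::sd(xt) == 0 && stats::sd(xn) == 0) {
      dm <- mean(xt) - mean(xn)
      return(data.frame(gene = g, mean_tumor = mean(xt),
                        mean_normal = mean(xn), diff = dm,
                        t = if (dm == 0) 0 else Inf * sign(dm),
                        df = NA_real_,
                        p_value = if (dm == 0) 1 else .Machine$double.xmin,
                        stringsAsFactors = FALSE))
    }
    tt <- stats::t.test(xt, xn, var.equal = FALSE)
    data.frame(gene = g, mean_tumor = mean(xt), mean_normal = mean(xn),
               diff = mean(xt) - mean(xn), t = unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$p_value < alpha
  out
}

#' Biweight midcorrelation
#'
#' Robust correlation using Tukey biweights around the median: with
#' \eqn{u_i = (x_i - med(x)) / (9 \cdot MAD(x))} (unscaled MAD) and weight
#' \eqn{a_i = (1 - u_i^2)^2} for \eqn{|u_i| < 1} (0 otherwise, same for y),
#' \deqn{bicor = \frac{\sum a_i b_i (x_i - med_x)(y_i - med_y)}
#'   {\sqrt{\sum [a_i (x_i - med_x)]^2} \sqrt{\sum [b_i (y_i - med_y)]^2}}.}
#' Falls back to the Pearson correlation when either MAD is zero.
#'
#' @param x,y numeric vectors of equal length (at least 5).
#' @return correlation in [-1, 1].
#' @export
bicor <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y must have equal length")
  if (length(x) < 5) stopf("bicor needs at least 5 observations")
  mx <- stats::median(x); my <- stats::median(y)
  madx <- stats::mad(x, constant = 1)
  mady <- stats::mad(y, constant = 1)
  if (madx == 0 || mady == 0) return(stats::cor(x, y))
  u <- (x - mx) / (9 * madx)
  v <- (y - my) / (9 * mady)
  a <- (1 - u^2)^2 * (abs(u) < 1)
  b <- (1 - v^2)^2 * (abs(v) < 1)
  xa <- a * (x - mx)
  yb <- b * (y - my)
  sum(xa * yb) / sqrt(sum(xa^2) * sum(yb^2))
}

#' Biweight midcorrelation matrix with p-values
#'
#' Pairwise \code{\link{bicor}} between two gene panels over the samples of
#' one cohort; p-values from the t approximation
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n - 2} df (two-sided). In the
#' square (same panel) case the matrix is symmetric with unit diagonal and
#' the diagonal p is \code{NA}.
#'
#' @param expression genes x samples matrix (one cohort's samples).
#' @param row_genes,col_genes gene panels; must be rows of
#'   \code{expression}.
#' @return object of class \code{correlation_matrix}: list with matrices
#'   \code{r} and \code{p}, sample count \code{n}, and the gene labels.
#' @export
correlation_matrix <- function(expression, row_genes, col_genes) {
  missing <- setdiff(c(row_genes, col_genes), rownames(expression))
  if (length(missing) > 0) {
    stopf("gene(s) not in expression matrix: %s",
          paste(utils::head(missing, 5), collapse = ", "))
  }
  n <- ncol(expression)
  if (n < 5) stopf("correlation needs at least 5 samples")
  r <- matrix(NA_real_, length(row_genes), length(col_genes),
              dimnames = list(row_genes, col_genes))
  for (i in seq_along(row_genes)) {
    for (j in seq_along(col_genes)) {
      r[i, j] <- bicor(expression[row_genes[i], ],
                       expression[col_genes[j], ])
    }
  }
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p <- pmax(p, .Machine$double.xmin)
  same <- identical(row_genes, col_genes)
  if (same) diag(p) <- NA_real_
  structure(list(r = r, p = p, n = n, row_genes = row_genes,
                 col_genes = col_genes, square = same),
            class = "correlation_matrix")
}

#' Select significant correlation pairs and their gene union
#'
#' @param cm a \code{\link{correlation_matrix}}.
#' @param alpha significance threshold (default 0.001).
#' @return list with \code{pairs} (data frame \code{gene1}, \code{gene2},
#'   \code{r}, \code{p}) and \code{genes} (union of genes in at least one
#'   significant pair). Halts with an explicit error when no pair is
#'   significant (nothing to score).
#' @export
select_significant_pairs <- function(cm, alpha = 0.001) {
  stopifnot(inherits(cm, "correlation_matrix"))
  sel <- which(!is.na(cm$p) & cm$p < alpha, arr.ind = TRUE)
  if (isTRUE(cm$square) && nrow(sel) > 0) {
    sel <- sel[sel[, 1] < sel[, 2], , drop = FALSE]
  }
  if (nrow(sel) == 0) {
    stopf("no significant correlation pair at alpha = %g: no genes to score",
          alpha)
  }
  pairs <- data.frame(gene1 = cm$row_genes[sel[, 1]],
                      gene2 = cm$col_genes[sel[, 2]],
                      r = cm$r[sel], p = cm$p[sel],
                      stringsAsFactors = FALSE)
  list(pairs = pairs, genes = union(pairs$gene1, pairs$gene2))
}

#' Principal-component contribution scores per individual
#'
#' Genes are standardized (zero mean, unit variance) across the selected
#' samples; the sample covariance is eigen-decomposed; the contribution of
#' individual i to component k is \eqn{100 \cdot score_{ik}^2 /
#' \sum_j score_{jk}^2} (percent, summing to 100 across individuals).
#' Individuals are also binned into 10 quantiles (deciles) of contribution.
#'
#' @param expression genes x samples matrix restricted (by \code{genes}) to
#'   the significant clock-Wnt gene union.
#' @param sample_ids samples (tumors) to score; at least 3.
#' @param genes genes to use; default all rows. At least 2 non-constant.
#' @param component which principal component (default 1).
#' @return data frame of class \code{covariance_scores}: \code{sample_id},
#'   \code{score} (signed PC score), \code{pc_contribution} (percent),
#'   \code{decile} (1-10).
#' @export
covariance_scores <- function(expression, sample_ids,
                              genes = rownames(expression), component = 1) {
  if (length(sample_ids) < 3) stopf("need at least 3 samples to score")
  x <- expression[genes, sample_ids, drop = FALSE]
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) {
    warnf("dropping %d constant gene(s) before PCA", sum(sds == 0))
    x <- x[sds > 0, , drop = FALSE]
  }
  if (nrow(x) < 2) stopf("fewer than 2 variable genes; cannot run PCA")
  xs <- (x - rowMeans(x)) / apply(x, 1, stats::sd)
  pr <- stats::prcomp(t(xs), center = TRUE, scale. = FALSE)
  if (component > ncol(pr$x)) stopf("component %d not available", component)
  sc <- pr$x[, component]
  contrib <- 100 * sc^2 / sum(sc^2)
  decile <- ceiling(10 * rank(contrib, ties.method = "first") /
                      length(contrib))
  structure(data.frame(sample_id = sample_ids, score = unname(sc),
                       pc_contribution = unname(contrib),
                       decile = pmin(10L, pmax(1L, as.integer(decile))),
                       stringsAsFactors = FALSE),
            class = c("covariance_scores", "data.frame"))
}

#' Assign high/low covariance groups
#'
#' Individuals are ranked by the absolute value of their principal
#' component contribution; the upper half becomes \code{"high"} covariance,
#' the lower half \code{"low"}. Ties are broken by stable sample-id order;
#' with odd n the extra individual goes to \code{"low"}.
#'
#' @param scores a \code{\link{covariance_scores}} data frame.
#' @return the same data frame with a \code{group} column.
#' @export
assign_groups <- function(scores) {
  n <- nrow(scores)
  ord <- order(-abs(scores$pc_contribution), seq_len(n))
  group <- rep("low", n)
  group[ord[seq_len(floor(n / 2))]] <- "high"
  scores$group <- group
  scores
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimator \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)}
#' over distinct event times, per group.
#'
#' @param clinical data frame with \code{time_days} and \code{event}
#'   (1 = death observed, 0 = censored), one row per scored sample, in the
#'   same order as \code{groups}.
#' @param groups group label per row of \code{clinical}.
#' @return data frame of class \code{survival_curves}: \code{group},
#'   \code{time}, \code{n_risk}, \code{n_event}, \code{n_censor},
#'   \code{surv}.
#' @export
kaplan_meier <- function(clinical, groups) {
  if (any(clinical$time_days < 0)) stopf("negative survival times")
  if (sum(clinical$event) < 1) {
    # no events: survival is identically 1 in every group
    return(structure(
      data.frame(group = sort(unique(groups)), time = 0, n_risk = NA_real_,
                 n_event = 0, n_censor = 0, surv = 1,
                 stringsAsFactors = FALSE),
      class = c("survival_curves", "data.frame")))
  }
  fit <- survival::survfit(
    survival::Surv(clinical$time_days, clinical$event) ~ groups)
  strata <- if (is.null(fit$strata)) {
    rep(sort(unique(groups))[1], length(fit$time))
  } else {
    rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  }
  structure(data.frame(group = strata, time = fit$time,
                       n_risk = fit$n.risk, n_event = fit$n.event,
                       n_censor = fit$n.censor, surv = fit$surv,
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("survival_curves", "data.frame"))
}

#' Two-group log-rank test
#'
#' Standard log-rank comparison: at each distinct event time the observed
#' events in group 1 are compared with the hypergeometric expectation given
#' the risk sets; the chi-square statistic has 1 df.
#'
#' @param clinical data frame with \code{time_days} and \code{event}.
#' @param groups two-level label per row.
#' @return list of class \code{chrono_test} with \code{statistic}
#'   (chi-square), \code{p_value} and \code{df}.
#' @export
logrank_test <- function(clinical, groups) {
  lev <- unique(groups)
  if (length(lev) != 2) stopf("log-rank needs exactly 2 non-empty groups")
  if (sum(clinical$event) < 1) stopf("no events observed")
  sd_fit <- survival::survdiff(
    survival::Surv(clinical$time_days, clinical$event) ~ groups)
  structure(list(statistic = unname(sd_fit$chisq),
                 p_value = stats::pchisq(sd_fit$chisq, df = 1,
                                         lower.tail = FALSE),
                 df = 1L),
            class = "chrono_test")
}

#' Clock-Wnt covariance survival pipeline
#'
#' End-to-end cohort analysis: expressed-gene filter, tumor/normal split by
#' sample code, per-gene tumor-vs-normal Welch tests on the clock panel,
#' clock x Wnt biweight midcorrelation with significance at
#' \eqn{P < alpha}, PCA-contribution covariance scores over the significant
#' gene union on tumor samples, median split into high/low covariance, and
#' Kaplan-Meier / log-rank comparison of overall survival. Samples without
#' survival records are excluded before scoring.
#'
#' @param bundle a \code{cohort_bundle} (see \code{\link{generate_cohort}});
#'   any list with \code{expression}, \code{clinical} and \code{gene_sets}
#'   works.
#' @param alpha correlation significance threshold (default 0.001).
#' @param component principal component used for scoring (default 1).
#' @param correlate_on cohort used to select significant clock-Wnt pairs:
#'   \code{"tumor"} (default; the samples later scored) or \code{"normal"}.
#' @param diff_alpha significance flag for the differential test.
#' @return list with \code{differential}, \code{correlation},
#'   \code{pairs}, \code{scores} (with groups), \code{curves},
#'   \code{logrank} and \code{n_excluded} (samples lacking survival).
#' @export
covsurv_pipeline <- function(bundle, alpha = 0.001, component = 1,
                             correlate_on = c("tumor", "normal"),
                             diff_alpha = 0.001) {
  correlate_on <- match.arg(correlate_on)
  expr <- filter_expressed_genes(bundle$expression)
  ids <- split_by_sample_code(colnames(expr))
  clock <- intersect(bundle$gene_sets$clock, rownames(expr))
  wnt <- intersect(bundle$gene_sets$wnt, rownames(expr))

  differential <- differential_means_test(expr, ids$tumor_ids,
                                          ids$normal_ids, genes = clock,
                                          alpha = diff_alpha)
  cor_ids <- if (correlate_on == "tumor") ids$tumor_ids else ids$normal_ids
  cm <- correlation_matrix(expr[, cor_ids, drop = FALSE], clock, wnt)
  sig <- select_significant_pairs(cm, alpha = alpha)

  clin <- bundle$clinical
  tumor_clin <- clin[clin$sample_id %in% ids$tumor_ids &
                       !is.na(clin$time_days) & !is.na(clin$event), ]
  n_excluded <- length(ids$tumor_ids) - nrow(tumor_clin)
  if (n_excluded > 0) {
    warnf("%d tumor sample(s) without survival records excluded",
          n_excluded)
  }
  scores <- covariance_scores(expr, tumor_clin$sample_id,
                              genes = sig$genes, component = component)
  scores <- assign_groups(scores)
  clin_ord <- tumor_clin[match(scores$sample_id, tumor_clin$sample_id), ]
  curves <- kaplan_meier(clin_ord, scores$group)
  lr <- logrank_test(clin_ord, scores$group)
  list(differential = differential, correlation = cm, pairs = sig$pairs,
       scores = scores, curves = curves, logrank = lr,
       n_excluded = n_excluded)
}
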