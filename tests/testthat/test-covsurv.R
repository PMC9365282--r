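test_that("expressed-gene filter applies the strict >50% rule", {
  m <- rbind(half = c(rep(1, 5), rep(0, 5)),     # exactly 50%: removed
             six = c(rep(1, 6), rep(0, 4)),      # 60%: kept
             none = rep(0, 10))
  colnames(m) <- sprintf("S%02d", 1:10)
  out <- filter_expressed_genes(m)
  expect_identical(rownames(out), "six")
  expect_warning(filter_expressed_genes(m["none", , drop = FALSE]),
                 "no gene")
})

test_that("sample-code split follows the barcode convention", {
  ids <- c("TCGA-AA-0001-01", "TCGA-AA-0001-11", "TCGA-AB-0002-06",
           "TCGA-AB-0002-19", "TCGA-AC-0003-20", "weird")
  expect_warning(sp <- split_by_sample_code(ids), "excluded")
  expect_identical(sp$tumor_ids, ids[c(1, 3)])
  expect_identical(sp$normal_ids, ids[c(2, 4)])
  # conservation on a clean synthetic cohort
  b <- generate_cohort(cohort_config(n_patients = 15, n_normal = 5,
                                     n_background_genes = 5, seed = 1))
  sp2 <- split_by_sample_code(colnames(b$expression))
  expect_identical(length(sp2$tumor_ids) + length(sp2$normal_ids), 20L)
})

test_that("differential test flags real shifts and calibrates under the null", {
  withr::with_seed(31, {
    n <- 50
    m <- rbind(shifted = c(rnorm(n, 5), rnorm(n, 0)),
               flat = c(rnorm(n), rnorm(n)),
               constant = rep(3, 2 * n))
    colnames(m) <- c(sprintf("T-%02d-01", 1:n), sprintf("N-%02d-11", 1:n))
    res <- differential_means_test(m, colnames(m)[1:n],
                                   colnames(m)[(n + 1):(2 * n)])
    expect_true(res$significant[res$gene == "shifted"])
    expect_false(res$significant[res$gene == "flat"])
    expect_identical(res$p_value[res$gene == "constant"], 1)

    # type-I at the 0.001 flag over 10000 null genes
    mm <- matrix(rnorm(10000 * 40), 10000,
                 dimnames = list(sprintf("g%05d", 1:10000), NULL))
    colnames(mm) <- c(sprintf("T%02d-01", 1:20), sprintf("N%02d-11", 1:20))
    resn <- differential_means_test(mm, colnames(mm)[1:20],
                                    colnames(mm)[21:40])
    rate <- mean(resn$significant)
    expect_lt(abs(rate - 0.001), 3 * sqrt(0.001 * 0.999 / 10000) + 1e-9)
  })
  expect_error(differential_means_test(matrix(1:4, 1), "a", "b"), "2 samples")
})

test_that("bicor matches the direct-formula oracle and is robust", {
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 5, 4, 10)
  # frozen value from an independent step-by-step evaluation of the
  # biweight formula (medians, unscaled MADs, (1-u^2)^2 weights)
  expect_equal(bicor(x, y), 0.8233820638340238, tolerance = 1e-12)
  expect_equal(bicor(x, x), 1, tolerance = 1e-12)
  expect_equal(bicor(x, -x), -1, tolerance = 1e-12)
  # invariant under positive affine transforms
  expect_equal(bicor(3 * x + 7, 0.5 * y - 2), bicor(x, y),
               tolerance = 1e-12)
  # close to Pearson on clean Gaussian data
  withr::with_seed(12, {
    a <- rnorm(200); b <- 0.6 * a + 0.8 * rnorm(200)
    expect_lt(abs(bicor(a, b) - cor(a, b)), 0.02)
  })
  # one gross outlier barely moves bicor but wrecks Pearson
  withr::with_seed(4, {
    a <- rnorm(30); b <- 0.8 * a + 0.6 * rnorm(30)
    a2 <- c(a, 12); b2 <- c(b, -12)
    expect_lt(abs(bicor(a2, b2) - bicor(a, b)), 0.1)
    expect_gt(abs(cor(a2, b2) - cor(a, b)), 0.3)
  })
  # MAD = 0 falls back to Pearson
  z <- c(0, 0, 0, 0, 1)
  expect_equal(bicor(z, x), cor(z, x), tolerance = 1e-12)
  expect_error(bicor(1:5, 1:4), "equal length")
})

test_that("correlation matrices are symmetric with t-based p-values", {
  b <- generate_cohort(cohort_config(n_patients = 100, n_normal = 0,
                                     n_background_genes = 5,
                                     covariance_strength = 0.9, seed = 6))
  cm <- correlation_matrix(b$expression, b$gene_sets$clock,
                           b$gene_sets$clock)
  expect_equal(unname(diag(cm$r)), rep(1, 12))
  expect_equal(cm$r, t(cm$r), tolerance = 1e-12)
  expect_true(all(is.na(diag(cm$p))))

  # a pair with bicor exactly 0 gets p = 1
  e2 <- rbind(g1 = c(-2, -1, 0, 1, 2, -2, -1, 0, 1, 2),
              g2 = c(4, 1, 0, 1, 4, 4, 1, 0, 1, 4))
  colnames(e2) <- sprintf("s%d", 1:10)
  cm2 <- correlation_matrix(e2, "g1", "g2")
  expect_equal(cm2$r[1, 1], 0, tolerance = 1e-12)
  expect_equal(cm2$p[1, 1], 1, tolerance = 1e-12)
})

test_that("significant clock-Wnt pairs are recovered from planted covariance", {
  b <- generate_cohort(cohort_config(n_patients = 400, n_normal = 400,
                                     n_background_genes = 5,
                                     covariance_strength = 0.9, seed = 13))
  nrm <- grep("-11$", colnames(b$expression), value = TRUE)
  cm <- correlation_matrix(b$expression[, nrm], b$gene_sets$clock,
                           b$gene_sets$wnt)
  sig <- select_significant_pairs(cm, alpha = 0.001)
  expect_gt(nrow(sig$pairs), 0.9 * 12 * 30)

  # strength 0: flag rate near the nominal alpha, and the empty-selection
  # halt fires
  b0 <- generate_cohort(cohort_config(n_patients = 400, n_normal = 400,
                                      n_background_genes = 5,
                                      covariance_strength = 0, seed = 13))
  nrm0 <- grep("-11$", colnames(b0$expression), value = TRUE)
  cm0 <- correlation_matrix(b0$expression[, nrm0], b0$gene_sets$clock,
                            b0$gene_sets$wnt)
  expect_lt(mean(cm0$p < 0.001), 0.005)
  p1 <- cm0
  p1$p[] <- 1
  expect_error(select_significant_pairs(p1), "no genes to score")

  # set logic: a single significant pair yields its two-gene union
  one <- cm0
  one$p[] <- 1; one$p["CLOCKG01", "WNTG05"] <- 1e-6
  sel <- select_significant_pairs(one)
  expect_identical(sel$genes, c("CLOCKG01", "WNTG05"))
})

test_that("planted correlated pairs are individually recoverable", {
  found <- vapply(1:20, function(s) {
    m <- make_planted_pairs_matrix(400, 6, 20, seed = s)
    cm <- correlation_matrix(m, grep("^A", rownames(m), value = TRUE),
                             grep("^B", rownames(m), value = TRUE))
    sig <- select_significant_pairs(cm, alpha = 0.001)
    planted <- paste0("A", sprintf("%02d", 1:6), "-",
                      "B", sprintf("%02d", 1:6))
    sum(paste0(sig$pairs$gene1, "-", sig$pairs$gene2) %in% planted)
  }, numeric(1))
  expect_gte(mean(found >= 5), 0.9)
})

test_that("PC contributions match an independent eigen-decomposition", {
  # 3 individuals x 2 genes, hand-checkable
  x <- rbind(g1 = c(1, 2, 6), g2 = c(2, 1, 7))
  colnames(x) <- c("s1", "s2", "s3")
  sc <- covariance_scores(x, colnames(x))
  expect_equal(sum(sc$pc_contribution), 100, tolerance = 1e-9)
  expect_equal(sc$pc_contribution, as.vector(pca_contrib_oracle(x)),
               tolerance = 1e-8)

  # larger random case against the same oracle
  withr::with_seed(77, {
    m <- matrix(rnorm(10 * 40), 10,
                dimnames = list(sprintf("g%02d", 1:10),
                                sprintf("s%02d", 1:40)))
    sc2 <- covariance_scores(m, colnames(m), component = 2)
    expect_equal(sc2$pc_contribution,
                 as.vector(pca_contrib_oracle(m, component = 2)),
                 tolerance = 1e-8)
  })

  # duplicated individuals receive equal contributions
  xd <- cbind(x, s4 = x[, "s3"])
  scd <- covariance_scores(xd, colnames(xd))
  expect_equal(scd$pc_contribution[3], scd$pc_contribution[4],
               tolerance = 1e-9)
  expect_identical(sort(unique(sc$decile)) %in% 1:10, rep(TRUE, 3))
})

test_that("high/low covariance split is a stable median split", {
  sc <- data.frame(sample_id = c("a", "b", "c", "d"),
                   pc_contribution = c(40, 30, 20, 10))
  g <- assign_groups(sc)
  expect_identical(g$group, c("high", "high", "low", "low"))

  # ties: stable id order, sizes differ by <= 1; odd n favors low
  sc2 <- data.frame(sample_id = letters[1:5],
                    pc_contribution = rep(20, 5))
  g2 <- assign_groups(sc2)
  expect_identical(g2$group, c("high", "high", "low", "low", "low"))
  expect_identical(sum(g2$group == "high") + sum(g2$group == "low"), 5L)
})

test_that("group assignment tracks the planted covariance level", {
  agree <- vapply(1:10, function(s) {
    b <- generate_cohort(cohort_config(covariance_strength = 1, seed = s))
    res <- suppressWarnings(covsurv_pipeline(b))
    truth <- b$truth$covariance_level[
      match(sub("SYN-(PT[0-9]+)-01", "\\1", res$scores$sample_id),
            b$truth$patient_id)]
    mean(res$scores$group == truth)
  }, numeric(1))
  expect_gte(mean(agree), 0.8)
})

test_that("Kaplan-Meier estimates match the hand product-limit oracle", {
  clin <- data.frame(time_days = c(1, 2, 3), event = c(1, 0, 1))
  km <- kaplan_meier(clin, rep("all", 3))
  expect_equal(km$surv[km$time == 1], 2 / 3, tolerance = 1e-12)
  expect_equal(km$surv[km$time == 3], 0, tolerance = 1e-12)
  expect_equal(km$surv[km$time == 1], km_oracle(clin$time_days,
                                                clin$event, 1))

  # no events: S = 1 everywhere
  clin0 <- data.frame(time_days = c(5, 6), event = c(0, 0))
  expect_true(all(kaplan_meier(clin0, rep("g", 2))$surv == 1))

  # all events, distinct times: S(t_(k)) = (n-k)/n
  clin2 <- data.frame(time_days = c(2, 4, 6, 8), event = rep(1, 4))
  km2 <- kaplan_meier(clin2, rep("g", 4))
  expect_equal(km2$surv, (3:0) / 4, tolerance = 1e-12)
  expect_true(all(diff(km2$surv) <= 0))

  expect_error(kaplan_meier(data.frame(time_days = -1, event = 1), "g"),
               "negative")
})

test_that("log-rank matches the hand hypergeometric-moment oracle", {
  # identical data in both groups: statistic 0, p 1
  clin_same <- data.frame(time_days = rep(c(1, 2, 3), 2),
                          event = rep(c(1, 0, 1), 2))
  lr0 <- logrank_test(clin_same, rep(c("a", "b"), each = 3))
  expect_lt(lr0$statistic, 1e-12)
  expect_equal(lr0$p_value, 1, tolerance = 1e-9)

  # 2 vs 2, all events at distinct times (A: 1, 3; B: 2, 4).
  # Hand evaluation: O_A = 2, E_A = 1/2 + 1/3 + 1/2 = 4/3,
  # V = 1/4 + 2/9 + 1/4 = 13/18, chi2 = (2/3)^2 / (13/18) = 8/13.
  clin <- data.frame(time_days = 1:4, event = rep(1, 4))
  lr <- logrank_test(clin, c("A", "B", "A", "B"))
  expect_equal(lr$statistic, 8 / 13, tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(8 / 13, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  expect_error(logrank_test(clin, rep("A", 4)), "2 non-empty groups")
})

test_that("log-rank power and size behave on simulated exponential cohorts", {
  sim_p <- function(hr, seed) {
    withr::with_seed(seed, {
      t1 <- rexp(200, rate = 0.001)
      t2 <- rexp(200, rate = 0.001 * hr)
      clin <- data.frame(time_days = c(t1, t2),
                         event = rep(1L, 400))
      logrank_test(clin, rep(c("a", "b"), each = 200))$p_value
    })
  }
  power <- mean(vapply(1:100, function(s) sim_p(3, s) < 0.05, logical(1)))
  expect_gte(power, 0.95)
  size <- mean(vapply(1:100, function(s) sim_p(1, 500 + s) < 0.05,
                      logical(1)))
  expect_lt(abs(size - 0.05), 3 * sqrt(0.05 * 0.95 / 100) + 1e-9)
})

test_that("log-rank p-values are uniform when covariance carries no hazard", {
  ps <- vapply(1:200, function(s) {
    b <- generate_cohort(cohort_config(n_patients = 150, n_normal = 30,
                                       n_background_genes = 30,
                                       covariance_strength = 1,
                                       hazard_ratio = 1, seed = s))
    tryCatch(suppressWarnings(covsurv_pipeline(b))$logrank$p_value,
             error = function(e) NA_real_)
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  expect_gt(length(ps), 180)
  ks <- max(abs(sort(ps) - seq_along(ps) / length(ps)))
  expect_lt(ks, 0.15)
})
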