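# configuration, dispatch and run reports tying the simulators and the
# four analysis stages into one reproducible tool

default_run_config <- function(subcommand) {
  common <- list(seed = 1L, log_level = "info", out = ".")
  params <- switch(subcommand,
    "simulate-traces" = list(n_samples = 7, duration_h = 72, dt_h = 1,
                             period_h = 24, amplitude = 3,
                             damping_per_h = 0.01, phase_h = 0,
                             baseline = 100, trend_per_h = -0.2,
                             noise_sd = 0.3, condition = "normal"),
    "simulate-dpcr" = list(n_plates = 1, n_partitions = 20000,
                           ref_lambda = 0.5, true_cnv = 2, ref_copies = 2),
    "simulate-cohort" = list(n_patients = 300, n_normal = 50,
                             n_clock_genes = 12, n_wnt_genes = 30,
                             n_background_genes = 200,
                             covariance_strength = 0.8, hazard_ratio = 2.5,
                             censor_rate = 0.3, baseline_hazard = 0.001,
                             noise_sd = 1),
    "simulate-depth" = list(n_intervals = 200, interval_len_bp = 200,
                            mean_depth = 100, dispersion = 20, n_early = 4,
                            n_late = 4, loh_start = 40, loh_end = 80,
                            loh_fold = 0),
    "rhythm" = list(traces = NULL, pairs = NULL, p_threshold = 0.001,
                    period_lo = 22, period_hi = 30, period_preset_h = 24,
                    detrend_method = "linear"),
    "dpcr" = list(plates = NULL, ref_copies = 2),
    "loh" = list(depth = NULL, groups = NULL, p = 0.01,
                 log2fc_threshold = -1, min_run = 3),
    "covsurv" = list(expr = NULL, clinical = NULL, clock = NULL,
                     wnt = NULL, alpha = 0.001, component = 1,
                     correlate_on = "tumor"),
    stopf("unknown subcommand '%s'", subcommand))
  c(common, params)
}

#' Parse a run configuration
#'
#' Builds the effective configuration for one pipeline run: the
#' subcommand's defaults (every analysis threshold defaults to its
#' published value: rhythm p 0.001, period gate 22--30 h, correlation alpha
#' 0.001, depth filter 0.01, 10 quantile bins), overlaid with a YAML/JSON
#' config file, overlaid with explicit flags. Unknown keys are rejected.
#'
#' @param subcommand one of \code{simulate-traces}, \code{simulate-dpcr},
#'   \code{simulate-cohort}, \code{simulate-depth}, \code{rhythm},
#'   \code{dpcr}, \code{loh}, \code{covsurv}.
#' @param config_file optional path to a YAML (or JSON) configuration file.
#' @param flags named list of command-line overrides (highest precedence).
#' @return list of class \code{run_config}.
#' @export
parse_run_config <- function(subcommand, config_file = NULL,
                             flags = list()) {
  cfg <- default_run_config(subcommand)
  overlay <- function(base, extra, origin) {
    unknown <- setdiff(names(extra), names(base))
    if (length(unknown) > 0) {
      stopf("unknown configuration key(s) in %s: %s", origin,
            paste(unknown, collapse = ", "))
    }
    base[names(extra)] <- extra
    base
  }
  if (!is.null(config_file)) {
    if (!file.exists(config_file)) stopf("config file '%s' not found",
                                         config_file)
    file_cfg <- yaml::read_yaml(config_file)
    cfg <- overlay(cfg, file_cfg, config_file)
  }
  cfg <- overlay(cfg, flags, "flags")
  cfg$subcommand <- subcommand
  structure(cfg, class = "run_config")
}

#' Execute one pipeline run
#'
#' Dispatches a \code{\link{parse_run_config}} configuration to the
#' corresponding module, writes all outputs under \code{config$out}, and
#' returns (and writes) a machine-readable run report with resolved
#' parameters, output checksums and warnings. Identical config + seed give
#' byte-identical outputs.
#'
#' @param config a \code{run_config}.
#' @return list of class \code{run_report}: \code{subcommand},
#'   \code{parameters}, \code{outputs} (file manifest with MD5 checksums),
#'   \code{warnings}, \code{status}, \code{failed_stage} (on error).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(name) file.path(config$out, name)
  warnings_seen <- character(0)
  report <- list(subcommand = config$subcommand,
                 parameters = unclass(config), outputs = character(0),
                 warnings = character(0), status = "ok",
                 failed_stage = NULL)
  files <- character(0)

  result <- withCallingHandlers(
    tryCatch({
      switch(config$subcommand,
        "simulate-traces" = {
          cc <- trace_config(n_samples = config$n_samples,
                             duration_h = config$duration_h,
                             dt_h = config$dt_h, period_h = config$period_h,
                             amplitude = config$amplitude,
                             damping_per_h = config$damping_per_h,
                             phase_h = config$phase_h,
                             baseline = config$baseline,
                             trend_per_h = config$trend_per_h,
                             noise_sd = config$noise_sd,
                             condition = config$condition,
                             seed = config$seed)
          files <- write_traces(generate_traces(cc), outfile("traces.csv"))
        },
        "simulate-dpcr" = {
          plates <- lapply(seq_len(config$n_plates), function(i) {
            cc <- dpcr_config(n_partitions = config$n_partitions,
                              ref_lambda = config$ref_lambda,
                              true_cnv = config$true_cnv,
                              ref_copies = config$ref_copies,
                              seed = config$seed + i - 1)
            generate_dpcr_plate(cc, sample_id = sprintf("plate_%03d", i))
          })
          files <- write_plates(plates, outfile("plates.csv"))
        },
        "simulate-cohort" = {
          cc <- cohort_config(n_patients = config$n_patients,
                              n_normal = config$n_normal,
                              n_clock_genes = config$n_clock_genes,
                              n_wnt_genes = config$n_wnt_genes,
                              n_background_genes = config$n_background_genes,
                              covariance_strength = config$covariance_strength,
                              hazard_ratio = config$hazard_ratio,
                              censor_rate = config$censor_rate,
                              baseline_hazard = config$baseline_hazard,
                              noise_sd = config$noise_sd,
                              seed = config$seed)
          bundle <- generate_cohort(cc)
          files <- c(
            write_expression(bundle$expression, outfile("expression.tsv")),
            write_clinical(bundle$clinical, outfile("clinical.tsv")))
          writeLines(bundle$gene_sets$clock, outfile("clock_genes.txt"))
          writeLines(bundle$gene_sets$wnt, outfile("wnt_genes.txt"))
          files <- c(files, outfile("clock_genes.txt"),
                     outfile("wnt_genes.txt"))
        },
        "simulate-depth" = {
          cc <- depth_config(n_intervals = config$n_intervals,
                             interval_len_bp = config$interval_len_bp,
                             mean_depth = config$mean_depth,
                             dispersion = config$dispersion,
                             n_early = config$n_early,
                             n_late = config$n_late,
                             loh_start = config$loh_start,
                             loh_end = config$loh_end,
                             loh_fold = config$loh_fold,
                             seed = config$seed)
          tracks <- generate_depth_tracks(cc)
          files <- c(write_depth(tracks, outfile("depth.tsv")))
          gm <- data.frame(sample = names(tracks$groups),
                           group = unname(tracks$groups))
          files <- c(files, write_tsv(gm, outfile("groups.tsv")))
        },
        "rhythm" = {
          traces <- read_traces(config$traces)
          res <- rhythm_pipeline(traces,
                                 detrend_method = config$detrend_method,
                                 p_threshold = config$p_threshold,
                                 period_lo = config$period_lo,
                                 period_hi = config$period_hi,
                                 period_preset_h = config$period_preset_h)
          rep_tbl <- res$report
          rep_tbl$period_h <- ifelse(rep_tbl$verdict == "NR", "NR",
                                     format(rep_tbl$period_h))
          rep_tbl$amplitude <- ifelse(rep_tbl$verdict == "NR", "NR",
                                      format(rep_tbl$amplitude))
          files <- c(write_tsv(rep_tbl, outfile("rhythm_report.tsv")))
          hm <- rhythm_heatmap_matrix(res$detrended)
          files <- c(files, write_tsv(
            data.frame(sample_id = rownames(hm), hm, check.names = FALSE),
            outfile("heatmap_matrix.tsv")))
          if (!is.null(config$pairs)) {
            pairing <- utils::read.delim(config$pairs,
                                         stringsAsFactors = FALSE)
            ratios <- amplitude_ratio(res$fits, res$calls, pairing)
            files <- c(files, write_tsv(ratios, outfile("paired_ratios.tsv")))
            wt <- wilcoxon_signed_rank(ratios$ratio)
            jsonlite::write_json(
              list(statistic = wt$statistic, p_value = wt$p_value,
                   n = wt$n),
              outfile("wilcoxon.json"), auto_unbox = TRUE, digits = NA)
            files <- c(files, outfile("wilcoxon.json"))
          }
        },
        "dpcr" = {
          plates <- read_plates(config$plates)
          res <- dpcr_pipeline(plates, ref_copies = config$ref_copies)
          files <- write_tsv(res, outfile("cnv.tsv"))
        },
        "loh" = {
          tracks <- read_depth(config$depth, group_map = config$groups)
          res <- loh_pipeline(tracks, p_threshold = config$p,
                              log2fc_threshold = config$log2fc_threshold,
                              min_run = config$min_run)
          files <- c(write_tsv(res$stats, outfile("interval_stats.tsv")),
                     write_segments_bed(res$segments,
                                        outfile("segments.bed")))
        },
        "covsurv" = {
          bundle <- list(
            expression = read_expression(config$expr),
            clinical = read_clinical(config$clinical),
            gene_sets = list(clock = read_gene_set(config$clock),
                             wnt = read_gene_set(config$wnt)))
          res <- covsurv_pipeline(bundle, alpha = config$alpha,
                                  component = config$component,
                                  correlate_on = config$correlate_on)
          files <- c(
            write_tsv(res$differential, outfile("differential.tsv")),
            write_tsv(data.frame(gene = rownames(res$correlation$r),
                                 res$correlation$r, check.names = FALSE),
                      outfile("correlation_r.tsv")),
            write_tsv(data.frame(gene = rownames(res$correlation$p),
                                 res$correlation$p, check.names = FALSE),
                      outfile("correlation_p.tsv")),
            write_tsv(res$pairs, outfile("significant_pairs.tsv")),
            write_tsv(res$scores, outfile("covariance_scores.tsv")),
            write_tsv(res$curves, outfile("km_curves.tsv")))
          jsonlite::write_json(
            list(statistic = res$logrank$statistic,
                 p_value = res$logrank$p_value, df = res$logrank$df,
                 n_high = sum(res$scores$group == "high"),
                 n_low = sum(res$scores$group == "low")),
            outfile("logrank.json"), auto_unbox = TRUE, digits = NA)
          files <- c(files, outfile("logrank.json"))
        })
      files
    }, error = function(e) {
      report$status <<- "failed"
      report$failed_stage <<- config$subcommand
      report$warnings <<- c(warnings_seen, conditionMessage(e))
      NULL
    }),
    warning = function(w) {
      warnings_seen <<- c(warnings_seen, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  report$warnings <- unique(c(report$warnings, warnings_seen))
  if (report$status == "ok") {
    report$outputs <- stats::setNames(as.character(tools::md5sum(result)),
                                      basename(result))
  }
  structure(report, class = "run_report")
}

#' Write a run report manifest
#'
#' @param report a \code{run_report} from \code{\link{run_pipeline}}.
#' @param dir output directory.
#' @return path to the written \code{run_report.json}.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- file.path(dir, "run_report.json")
  payload <- list(
    subcommand = report$subcommand,
    parameters = Filter(Negate(is.null), report$parameters),
    outputs = as.list(report$outputs),
    warnings = report$warnings,
    status = report$status,
    failed_stage = report$failed_stage)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
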