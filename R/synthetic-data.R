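#' Configuration for synthetic bioluminescence traces
#'
#' Describes a batch of organoid reporter recordings following a damped
#' cosine with linear trend and Gaussian noise:
#' \deqn{y(t) = baseline + trend \cdot t + A e^{-d t}
#'   \cos(2\pi (t - \phi)/T) + \epsilon}
#'
#' @param n_samples number of traces to generate.
#' @param duration_h recording length in hours; must be at least two periods
#'   for rhythmic conditions.
#' @param dt_h sampling interval in hours.
#' @param period_h oscillation period T in hours.
#' @param amplitude initial amplitude A in signal units.
#' @param damping_per_h exponential damping rate d (1/hours).
#' @param phase_h phase offset in hours.
#' @param baseline constant signal offset.
#' @param trend_per_h linear drift in signal units per hour.
#' @param noise_sd standard deviation of additive Gaussian noise.
#' @param condition one of \code{"normal"}, \code{"tumor"},
#'   \code{"arrhythmic"} (forces A = 0) or \code{"abnormal_period"} (period
#'   drawn outside the 22--30 h circadian band).
#' @param seed integer seed; identical seeds reproduce identical traces.
#' @return an object of class \code{trace_config}.
#' @export
trace_config <- function(n_samples = 7, duration_h = 72, dt_h = 1,
                         period_h = 24, amplitude = 3, damping_per_h = 0.01,
                         phase_h = 0, baseline = 100, trend_per_h = -0.2,
                         noise_sd = 0.3,
                         condition = c("normal", "tumor", "arrhythmic",
                                       "abnormal_period"),
                         seed = 1L) {
  condition <- match.arg(condition)
  cfg <- list(
    n_samples = check_count(n_samples, "n_samples"),
    duration_h = check_number(duration_h, "duration_h", min = 0,
                              strict_min = TRUE),
    dt_h = check_number(dt_h, "dt_h", min = 0, strict_min = TRUE),
    period_h = check_number(period_h, "period_h", min = 0, strict_min = TRUE),
    amplitude = check_number(amplitude, "amplitude", min = 0),
    damping_per_h = check_number(damping_per_h, "damping_per_h"),
    phase_h = check_number(phase_h, "phase_h"),
    baseline = check_number(baseline, "baseline"),
    trend_per_h = check_number(trend_per_h, "trend_per_h"),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    condition = condition,
    seed = check_count(seed, "seed", min = 0)
  )
  if (condition %in% c("normal", "tumor") &&
      cfg$duration_h < 2 * cfg$period_h) {
    stopf("duration_h must be >= 2 periods for rhythmic conditions")
  }
  structure(cfg, class = "trace_config")
}

#' Generate synthetic luminescence traces
#'
#' Each trace follows the damped-cosine model of \code{\link{trace_config}}.
#' Condition \code{"arrhythmic"} sets the amplitude to zero; condition
#' \code{"abnormal_period"} draws, per trace, a period uniformly from
#' \eqn{[14, 20] \cup [32, 40]} h, outside the 22--30 h gate.
#'
#' @param config a \code{\link{trace_config}}.
#' @return long-format data frame of class \code{trace_set} with columns
#'   \code{sample_id}, \code{patient_id}, \code{condition}, \code{time_h},
#'   \code{signal}.
#' @export
generate_traces <- function(config) {
  stopifnot(inherits(config, "trace_config"))
  times <- seq(0, config$duration_h, by = config$dt_h)
  with_seed(config$seed, {
    out <- lapply(seq_len(config$n_samples), function(i) {
      A <- config$amplitude
      T_h <- config$period_h
      if (config$condition == "arrhythmic") A <- 0
      if (config$condition == "abnormal_period") {
        T_h <- if (stats::runif(1) < 0.5) stats::runif(1, 14, 20)
               else stats::runif(1, 32, 40)
      }
      y <- config$baseline + config$trend_per_h * times +
        A * exp(-config$damping_per_h * times) *
          cos(2 * pi * (times - config$phase_h) / T_h) +
        stats::rnorm(length(times), 0, config$noise_sd)
      data.frame(
        sample_id = sprintf("%s_%02d", config$condition, i),
        patient_id = sprintf("PT%03d", i),
        condition = config$condition,
        time_h = times,
        signal = y,
        stringsAsFactors = FALSE
      )
    })
    structure(do.call(rbind, out), class = c("trace_set", "data.frame"))
  })
}

#' Split a long trace table into individual traces
#'
#' @param trace_set long data frame as produced by
#'   \code{\link{generate_traces}} or \code{\link{read_traces}}.
#' @return named list of \code{chrono_trace} objects (one per sample), each
#'   holding \code{times}, \code{values} and identifying labels.
#' @export
split_traces <- function(trace_set) {
  pieces <- split(trace_set, trace_set$sample_id)
  out <- lapply(pieces, function(df) {
    df <- df[order(df$time_h), ]
    new_trace(df$time_h, df$signal, sample_id = df$sample_id[1],
              patient_id = df$patient_id[1], condition = df$condition[1])
  })
  out[unique(trace_set$sample_id)]
}

#' Construct a single luminescence trace
#'
#' @param times sampling times in hours, strictly increasing.
#' @param values signal values, same length as \code{times}.
#' @param sample_id,patient_id,condition identifying labels.
#' @return object of class \code{chrono_trace}.
#' @export
new_trace <- function(times, values, sample_id = "trace",
                      patient_id = NA_character_,
                      condition = NA_character_) {
  if (length(times) != length(values)) {
    stopf("times and values must have equal length")
  }
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 sample_id = sample_id, patient_id = patient_id,
                 condition = condition),
            class = "chrono_trace")
}

#' Configuration for a synthetic digital-PCR plate
#'
#' Partition occupancy is Poisson: a partition is positive in a channel with
#' probability \eqn{1 - e^{-\lambda}}. The target concentration is
#' \code{ref_lambda * true_cnv / ref_copies}.
#'
#' @param n_partitions partitions on the plate (instrument default 20,000).
#' @param ref_lambda reference-channel concentration in copies/partition.
#' @param true_cnv true copy number of the target locus (0, 1, 2, ...).
#' @param ref_copies copy number of the reference locus (autosomal control,
#'   default 2).
#' @param seed integer seed.
#' @return object of class \code{dpcr_config}.
#' @export
dpcr_config <- function(n_partitions = 20000, ref_lambda = 0.5,
                        true_cnv = 2, ref_copies = 2, seed = 1L) {
  structure(list(
    n_partitions = check_count(n_partitions, "n_partitions"),
    ref_lambda = check_number(ref_lambda, "ref_lambda", min = 0,
                              max = 5, strict_min = TRUE),
    true_cnv = check_number(true_cnv, "true_cnv", min = 0),
    ref_copies = check_number(ref_copies, "ref_copies", min = 0,
                              strict_min = TRUE),
    seed = check_count(seed, "seed", min = 0)
  ), class = "dpcr_config")
}

#' Simulate a digital-PCR plate
#'
#' @param config a \code{\link{dpcr_config}}.
#' @param sample_id label carried into the plate record.
#' @return object of class \code{partition_plate}: a list with
#'   \code{n_partitions}, \code{target_positive}, \code{reference_positive},
#'   \code{sample_id} and the simulation ground truth \code{true_cnv}.
#' @export
generate_dpcr_plate <- function(config, sample_id = "plate") {
  stopifnot(inherits(config, "dpcr_config"))
  lam_t <- config$ref_lambda * config$true_cnv / config$ref_copies
  lam_r <- config$ref_lambda
  with_seed(config$seed, {
    target_pos <- stats::rbinom(1, config$n_partitions, 1 - exp(-lam_t))
    ref_pos <- stats::rbinom(1, config$n_partitions, 1 - exp(-lam_r))
    structure(list(n_partitions = config$n_partitions,
                   target_positive = target_pos,
                   reference_positive = ref_pos,
                   sample_id = sample_id,
                   true_cnv = config$true_cnv),
              class = "partition_plate")
  })
}

#' Configuration for a synthetic tumor/normal expression cohort
#'
#' Emulates a colon-cancer cohort on a log2-like expression scale. Core
#' clock and Wnt pathway genes load on a shared latent Gaussian factor in
#' normal tissue (loading \code{covariance_strength}); each tumor patient
#' draws a latent binary covariance level (high retains the shared factor,
#' low loses it), and overall survival is exponential with hazard
#' \code{baseline_hazard * hazard_ratio^[low level]}.
#'
#' @param n_patients tumor patients.
#' @param n_normal matched normal-tissue samples (first \code{n_normal}
#'   patients; must not exceed \code{n_patients}).
#' @param n_clock_genes,n_wnt_genes,n_background_genes gene-panel sizes.
#' @param covariance_strength loading of clock/Wnt genes on the shared
#'   latent factor, in [0, 1].
#' @param hazard_ratio hazard multiplier for low- vs high-covariance
#'   patients (> 1 means low covariance has worse survival).
#' @param censor_rate fraction of patients censored.
#' @param baseline_hazard event hazard per day for high-covariance patients.
#' @param noise_sd residual SD of log2 expression.
#' @param seed integer seed.
#' @return object of class \code{cohort_config}.
#' @export
cohort_config <- function(n_patients = 300, n_normal = 50,
                          n_clock_genes = 12, n_wnt_genes = 30,
                          n_background_genes = 200,
                          covariance_strength = 0.8, hazard_ratio = 2.5,
                          censor_rate = 0.3, baseline_hazard = 1 / 1000,
                          noise_sd = 1, seed = 1L) {
  cfg <- list(
    n_patients = check_count(n_patients, "n_patients"),
    n_normal = check_count(n_normal, "n_normal", min = 0),
    n_clock_genes = check_count(n_clock_genes, "n_clock_genes"),
    n_wnt_genes = check_count(n_wnt_genes, "n_wnt_genes"),
    n_background_genes = check_count(n_background_genes,
                                     "n_background_genes"),
    covariance_strength = check_number(covariance_strength,
                                       "covariance_strength", 0, 1),
    hazard_ratio = check_number(hazard_ratio, "hazard_ratio", min = 0,
                                strict_min = TRUE),
    censor_rate = check_number(censor_rate, "censor_rate", min = 0, max = 1),
    baseline_hazard = check_number(baseline_hazard, "baseline_hazard",
                                   min = 0, strict_min = TRUE),
    noise_sd = check_number(noise_sd, "noise_sd", min = 0),
    seed = check_count(seed, "seed", min = 0)
  )
  if (cfg$censor_rate >= 1) stopf("censor_rate must be < 1")
  if (cfg$n_normal > cfg$n_patients) {
    stopf("n_normal (%d) exceeds n_patients (%d)", cfg$n_normal,
          cfg$n_patients)
  }
  structure(cfg, class = "cohort_config")
}

#' Simulate a tumor/normal expression cohort with survival
#'
#' Sample identifiers follow the TCGA barcode convention: tumor samples end
#' in \code{"-01"}, matched normals in \code{"-11"}. The returned bundle
#' records the planted per-patient covariance level under \code{truth}
#' (simulation-only ground truth, not used by any analysis function).
#'
#' @param config a \code{\link{cohort_config}}.
#' @return object of class \code{cohort_bundle}: list with
#'   \code{expression} (genes x samples matrix), \code{clinical} (data frame
#'   with \code{sample_id}, \code{patient_id}, \code{type},
#'   \code{time_days}, \code{event}), \code{gene_sets} (named lists
#'   \code{clock}, \code{wnt}) and \code{truth}.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  clock_genes <- sprintf("CLOCKG%02d", seq_len(config$n_clock_genes))
  wnt_genes <- sprintf("WNTG%02d", seq_len(config$n_wnt_genes))
  bg_genes <- sprintf("BG%04d", seq_len(config$n_background_genes))
  genes <- c(clock_genes, wnt_genes, bg_genes)
  n_factor_genes <- config$n_clock_genes + config$n_wnt_genes

  patients <- sprintf("PT%04d", seq_len(config$n_patients))
  tumor_ids <- paste0("SYN-", patients, "-01")
  normal_ids <- paste0("SYN-", patients[seq_len(config$n_normal)], "-11")

  with_seed(config$seed, {
    mu <- stats::rnorm(length(genes), mean = 8, sd = 1.5)
    names(mu) <- genes

    sim_samples <- function(ids, loadings) {
      f <- stats::rnorm(length(ids))
      expr <- matrix(stats::rnorm(length(genes) * length(ids), 0,
                                  config$noise_sd),
                     nrow = length(genes), ncol = length(ids),
                     dimnames = list(genes, ids))
      expr <- expr + mu + outer(c(rep(1, n_factor_genes),
                                  rep(0, length(bg_genes))), f) *
        rep(loadings, each = length(genes))
      expr
    }

    # normal tissue: shared clock-Wnt factor in every sample
    expr_normal <- if (config$n_normal > 0) {
      sim_samples(normal_ids, rep(config$covariance_strength,
                                  config$n_normal))
    } else {
      NULL
    }

    # tumors: per-patient latent covariance level
    level_high <- stats::runif(config$n_patients) < 0.5
    expr_tumor <- sim_samples(tumor_ids,
                              ifelse(level_high, config$covariance_strength,
                                     0))

    hazard <- config$baseline_hazard *
      config$hazard_ratio^(!level_high)
    event_time <- stats::rexp(config$n_patients, rate = hazard)
    censored <- stats::runif(config$n_patients) < config$censor_rate
    obs_time <- ifelse(censored,
                       stats::runif(config$n_patients) * event_time,
                       event_time)

    clinical_tumor <- data.frame(
      sample_id = tumor_ids, patient_id = patients, type = "tumor",
      time_days = obs_time, event = as.integer(!censored),
      stringsAsFactors = FALSE)
    clinical_normal <- if (config$n_normal > 0) {
      idx <- seq_len(config$n_normal)
      data.frame(sample_id = normal_ids, patient_id = patients[idx],
                 type = "normal", time_days = obs_time[idx],
                 event = as.integer(!censored)[idx],
                 stringsAsFactors = FALSE)
    } else {
      NULL
    }

    structure(list(
      expression = cbind(expr_tumor, expr_normal),
      clinical = rbind(clinical_tumor, clinical_normal),
      gene_sets = list(clock = clock_genes, wnt = wnt_genes),
      truth = data.frame(patient_id = patients,
                         covariance_level = ifelse(level_high, "high", "low"),
                         stringsAsFactors = FALSE)
    ), class = "cohort_bundle")
  })
}

#' Configuration for synthetic read-depth tracks
#'
#' Negative-binomial counts per genomic interval per replicate, with an
#' optional planted deletion: intervals inside \code{loh_interval} in the
#' late group have mean \code{mean_depth * loh_fold}.
#'
#' @param n_intervals number of tiles.
#' @param interval_len_bp tile width in base pairs (default 200).
#' @param mean_depth mean reads per interval.
#' @param dispersion negative-binomial dispersion (variance =
#'   \eqn{\mu + \mu^2 / dispersion}); \code{Inf} gives Poisson counts.
#' @param n_early,n_late replicate counts per group (default 4 each).
#' @param loh_start,loh_end planted deleted segment as a 0-based half-open
#'   interval index range; \code{NULL} for no planted event.
#' @param loh_fold depth multiplier inside the segment in the late group
#'   (0 = complete loss).
#' @param seed integer seed.
#' @return object of class \code{depth_config}.
#' @export
depth_config <- function(n_intervals = 200, interval_len_bp = 200,
                         mean_depth = 100, dispersion = 20,
                         n_early = 4, n_late = 4,
                         loh_start = NULL, loh_end = NULL, loh_fold = 0,
                         seed = 1L) {
  cfg <- list(
    n_intervals = check_count(n_intervals, "n_intervals"),
    interval_len_bp = check_count(interval_len_bp, "interval_len_bp"),
    mean_depth = check_number(mean_depth, "mean_depth", min = 0,
                              strict_min = TRUE),
    dispersion = check_number(dispersion, "dispersion", min = 0,
                              strict_min = TRUE),
    n_early = check_count(n_early, "n_early", min = 2),
    n_late = check_count(n_late, "n_late", min = 2),
    loh_start = if (is.null(loh_start)) NULL
                else check_count(loh_start, "loh_start", min = 0),
    loh_end = if (is.null(loh_end)) NULL
              else check_count(loh_end, "loh_end", min = 0),
    loh_fold = check_number(loh_fold, "loh_fold", min = 0),
    seed = check_count(seed, "seed", min = 0)
  )
  if (xor(is.null(cfg$loh_start), is.null(cfg$loh_end))) {
    stopf("loh_start and loh_end must be given together")
  }
  if (!is.null(cfg$loh_start) &&
      (cfg$loh_end <= cfg$loh_start || cfg$loh_end > cfg$n_intervals)) {
    stopf("planted interval [%d, %d) outside [0, %d)", cfg$loh_start,
          cfg$loh_end, cfg$n_intervals)
  }
  structure(cfg, class = "depth_config")
}

#' Simulate interval read-depth tracks with an optional planted deletion
#'
#' @param config a \code{\link{depth_config}}.
#' @param chrom chromosome label for the emitted BED-style intervals.
#' @return object of class \code{depth_track_set}: list with
#'   \code{intervals} (data frame \code{chrom}, \code{start}, \code{end};
#'   0-based half-open), \code{counts} (intervals x samples integer matrix),
#'   \code{groups} (per-sample \code{"early"}/\code{"late"} labels) and
#'   \code{planted_loh} (\code{c(start, end)} index range or \code{NULL}).
#' @export
generate_depth_tracks <- function(config, chrom = "chr18") {
  stopifnot(inherits(config, "depth_config"))
  samples <- c(sprintf("early_%d", seq_len(config$n_early)),
               sprintf("late_%d", seq_len(config$n_late)))
  groups <- rep(c("early", "late"), c(config$n_early, config$n_late))
  mu <- matrix(config$mean_depth, nrow = config$n_intervals,
               ncol = length(samples))
  if (!is.null(config$loh_start)) {
    idx <- (config$loh_start + 1):config$loh_end
    mu[idx, groups == "late"] <- config$mean_depth * config$loh_fold
  }
  with_seed(config$seed, {
    counts <- if (is.infinite(config$dispersion)) {
      matrix(stats::rpois(length(mu), mu), nrow = nrow(mu))
    } else {
      matrix(stats::rnbinom(length(mu), size = config$dispersion, mu = mu),
             nrow = nrow(mu))
    }
    counts[mu == 0] <- 0L   # degenerate zero-mean intervals are exact zeros
    dimnames(counts) <- list(NULL, samples)
    starts <- (seq_len(config$n_intervals) - 1L) * config$interval_len_bp
    structure(list(
      intervals = data.frame(chrom = chrom, start = starts,
                             end = starts + config$interval_len_bp,
                             stringsAsFactors = FALSE),
      counts = counts,
      groups = stats::setNames(groups, samples),
      planted_loh = if (is.null(config$loh_start)) NULL
                    else c(config$loh_start, config$loh_end)
    ), class = "depth_track_set")
  })
}
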