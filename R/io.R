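# readers and writers for the formats the pipeline touches:
# CSV (traces, plates), TSV (expression, clinical, depth, reports),
# BED 0-based half-open (segments), plain lists / GMT (gene sets)

#' @rdname chronoloh-io
#' @param trace_set,path,plates,expression,clinical,tracks,group_map,x,dir
#'   see details.
#' @name chronoloh-io
#' @title Read and write pipeline files
#' @description Long trace CSVs, dPCR plate CSVs, expression and clinical
#'   TSVs, depth TSVs keyed on BED-style 0-based half-open coordinates,
#'   segment BED files, and gene sets as plain lists or GMT. Missing values
#'   are written as \code{"NA"}.
NULL

#' @rdname chronoloh-io
#' @export
write_traces <- function(trace_set, path) {
  utils::write.csv(trace_set, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname chronoloh-io
#' @export
read_traces <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "condition", "time_h", "signal")
  if (!all(need %in% names(df))) {
    stopf("trace CSV must have columns: %s", paste(need, collapse = ", "))
  }
  structure(df, class = c("trace_set", "data.frame"))
}

#' @rdname chronoloh-io
#' @export
write_plates <- function(plates, path) {
  if (inherits(plates, "partition_plate")) plates <- list(plates)
  if (is.list(plates) && !is.data.frame(plates)) {
    plates <- do.call(rbind, lapply(plates, function(p) {
      data.frame(sample_id = p$sample_id, n_partitions = p$n_partitions,
                 target_positive = p$target_positive,
                 reference_positive = p$reference_positive,
                 stringsAsFactors = FALSE)
    }))
  }
  utils::write.csv(plates, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname chronoloh-io
#' @export
read_plates <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "n_partitions", "target_positive",
            "reference_positive")
  if (!all(need %in% names(df))) {
    stopf("plate CSV must have columns: %s", paste(need, collapse = ", "))
  }
  df
}

#' @rdname chronoloh-io
#' @export
write_expression <- function(expression, path) {
  df <- data.frame(gene_id = rownames(expression), expression,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname chronoloh-io
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' @rdname chronoloh-io
#' @export
write_clinical <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname chronoloh-io
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "type", "time_days", "event")
  if (!all(need %in% names(df))) {
    stopf("clinical TSV must have columns: %s", paste(need, collapse = ", "))
  }
  df
}

#' @rdname chronoloh-io
#' @export
write_depth <- function(tracks, path) {
  df <- data.frame(tracks$intervals, tracks$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname chronoloh-io
#' @param groups named character vector (sample -> early/late) when reading
#'   depth without a group-map file.
#' @export
read_depth <- function(path, groups = NULL, group_map = NULL) {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df))) {
    stopf("depth TSV must start with columns chrom, start, end")
  }
  counts <- as.matrix(df[, setdiff(names(df), need), drop = FALSE])
  if (!is.null(group_map)) {
    gm <- utils::read.delim(group_map, stringsAsFactors = FALSE)
    groups <- stats::setNames(gm[[2]], gm[[1]])
  }
  if (is.null(groups)) stopf("sample groups required (early/late)")
  groups <- groups[colnames(counts)]
  structure(list(intervals = df[, need], counts = counts, groups = groups,
                 planted_loh = NULL),
            class = "depth_track_set")
}

#' @rdname chronoloh-io
#' @export
write_segments_bed <- function(segments, path) {
  if (nrow(segments) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.frame(segments$chrom, segments$start, segments$end,
                    sprintf("loh_segment_%d", seq_len(nrow(segments))),
                    round(segments$mean_log2fc, 4))
  utils::write.table(bed, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a gene set from a plain list or GMT file
#'
#' Plain lists carry one gene symbol per line. GMT lines are
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}; all sets in the file
#' are pooled unless \code{set_name} selects one.
#'
#' @param path file path.
#' @param set_name optional GMT set name to select.
#' @return character vector of gene symbols.
#' @export
read_gene_set <- function(path, set_name = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(character(0))
  if (any(grepl("\t", lines))) {   # GMT
    parts <- strsplit(lines, "\t")
    if (!is.null(set_name)) {
      parts <- Filter(function(p) p[1] == set_name, parts)
      if (length(parts) == 0) stopf("GMT set '%s' not found", set_name)
    }
    unique(unlist(lapply(parts, function(p) p[-(1:2)])))
  } else {
    unique(trimws(lines))
  }
}

#' @rdname chronoloh-io
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "NA")
  invisible(path)
}
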