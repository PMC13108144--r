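#' Read and write trace files
#'
#' Traces are stored as delimited text with two columns (`time_s`,
#' `intensity_au`), preceded by `#`-prefixed header lines whose first line
#' carries the trace metadata as JSON (cell id, condition, switch time, seed,
#' ground truth when synthetic). The delimiter is auto-detected among comma
#' and tab. Numeric values round-trip losslessly (17 significant digits).
#'
#' @param trace A [raw_trace()].
#' @param path File path.
#' @return `read_trace()` returns a [raw_trace()]; `write_trace()` returns
#'   `path` invisibly.
#' @examples
#' tr <- simulate_raw_trace(ground_truth("one_exp", c(P = 1, Q = 0.001)),
#'                          acquisition_config(duration = 100, sample_interval = 5))
#' p <- tempfile(fileext = ".csv")
#' write_trace(tr, p)
#' tr2 <- read_trace(p)
#' @export
write_trace <- function(trace, path) {
  if (!is.data.frame(trace) || !all(c("time_s", "intensity_au") %in% names(trace))) {
    stop_sck("`trace` must have columns `time_s` and `intensity_au`.")
  }
  meta <- trace_meta(trace)
  header <- paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA,
                                          null = "null"))
  body <- sprintf("%.17g,%.17g", trace$time_s, trace$intensity_au)
  writeLines(c(header, "time_s,intensity_au", body), path)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  if (!file.exists(path)) stop_sck(sprintf("File not found: %s", path))
  lines <- readLines(path)
  if (!length(lines)) stop_sck(sprintf("Empty trace file: %s", path))
  is_comment <- startsWith(lines, "#")
  meta <- list()
  if (any(is_comment)) {
    js <- sub("^#\\s*", "", lines[which(is_comment)[1]])
    meta <- tryCatch(jsonlite::fromJSON(js, simplifyVector = TRUE),
                     error = function(e) {
                       stop_sck(sprintf("Line %d: malformed JSON metadata header.",
                                        which(is_comment)[1]))
                     })
  }
  body_idx <- which(!is_comment)
  if (!length(body_idx)) stop_sck("Trace file has no data rows.")
  header_line <- lines[body_idx[1]]
  delim <- if (grepl("\t", header_line)) "\t" else ","
  cols <- strsplit(header_line, delim, fixed = TRUE)[[1]]
  if (!all(c("time_s", "intensity_au") %in% trimws(cols))) {
    stop_sck(sprintf("Line %d: expected columns `time_s` and `intensity_au`, got: %s",
                     body_idx[1], header_line))
  }
  data_idx <- body_idx[-1]
  if (!length(data_idx)) stop_sck("Trace file has a header but no samples.")
  parts <- strsplit(lines[data_idx], delim, fixed = TRUE)
  bad_len <- which(lengths(parts) < length(cols))
  if (length(bad_len)) {
    stop_sck(sprintf("Line %d: expected %d fields.", data_idx[bad_len[1]], length(cols)))
  }
  mat <- do.call(rbind, parts)
  colnames(mat) <- trimws(cols)
  t <- suppressWarnings(as.numeric(mat[, "time_s"]))
  x <- suppressWarnings(as.numeric(mat[, "intensity_au"]))
  if (anyNA(t) || anyNA(x)) {
    bad <- which(is.na(t) | is.na(x))[1]
    stop_sck(sprintf("Line %d: non-numeric value.", data_idx[bad]))
  }
  if (any(diff(t) <= 0)) {
    bad <- which(diff(t) <= 0)[1] + 1L
    stop_sck(sprintf("Line %d: times must be strictly increasing.", data_idx[bad]))
  }
  new_raw_trace(tibble::tibble(time_s = t, intensity_au = x),
                metadata = restore_meta(meta))
}

# fromJSON gives plain lists/vectors; re-class nested ground truths
restore_meta <- function(meta) {
  fix_gt <- function(g) {
    if (is.list(g) && !is.null(g$model) && !is.null(g$params)) {
      ground_truth(g$model, unlist(g$params))
    } else g
  }
  for (nm in intersect(names(meta),
                       c("ground_truth", "ground_truth_phase1", "ground_truth_phase2"))) {
    meta[[nm]] <- fix_gt(meta[[nm]])
  }
  meta
}

cohort_columns <- c("cell_id", "cell_type", "condition", "phase", "model",
                    "P", "Q", "A", "B", "C", "D", "R", "plateau",
                    "half_time_s", "flags")
cohort_numeric <- c("P", "Q", "A", "B", "C", "D", "R", "plateau", "half_time_s")

#' Read and write per-cell cohort tables
#'
#' A cohort table mirrors the published per-cell fit summaries: one row per
#' (cell, condition, phase) with the fitted parameters of whichever model was
#' used, the correlation coefficient, the plateau and half-time, and any
#' flags. The CSV schema is fixed:
#' `cell_id,cell_type,condition,phase,model,P,Q,A,B,C,D,R,plateau,half_time_s,flags`
#' with empty cells for unused parameters. Keys `(cell_id, condition, phase)`
#' must be unique; numeric columns round-trip losslessly.
#'
#' @param table A data frame with (a subset of) the schema columns.
#' @param path File path.
#' @return `read_cohort()` returns a tibble with the full schema;
#'   `write_cohort()` returns `path` invisibly.
#' @export
write_cohort <- function(table, path) {
  if (!is.data.frame(table) || !nrow(table)) stop_sck("`table` must be a non-empty data frame.")
  for (col in setdiff(cohort_columns, names(table))) {
    table[[col]] <- if (col %in% cohort_numeric) NA_real_ else NA_character_
  }
  table <- table[cohort_columns]
  check_cohort_keys(table)
  fmt <- vapply(seq_len(nrow(table)), function(i) {
    cells <- vapply(cohort_columns, function(col) {
      v <- table[[col]][i]
      if (is.na(v)) "" else if (col %in% cohort_numeric) sprintf("%.17g", as.numeric(v)) else as.character(v)
    }, character(1))
    paste(cells, collapse = ",")
  }, character(1))
  writeLines(c(paste(cohort_columns, collapse = ","), fmt), path)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_sck(sprintf("File not found: %s", path))
  lines <- readLines(path)
  if (!length(lines)) stop_sck(sprintf("Empty cohort file: %s", path))
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  if (!identical(trimws(header), cohort_columns)) {
    stop_sck(sprintf("Line 1: cohort header must be `%s`.",
                     paste(cohort_columns, collapse = ",")))
  }
  if (length(lines) < 2) stop_sck("Cohort file has a header but no rows.")
  parts <- strsplit(lines[-1], ",", fixed = TRUE)
  rows <- purrr::map_dfr(seq_along(parts), function(i) {
    p <- parts[[i]]
    length(p) <- length(cohort_columns) # pad trailing empties
    p[is.na(p)] <- ""
    rec <- setNames(as.list(p), cohort_columns)
    for (col in cohort_numeric) {
      v <- rec[[col]]
      if (identical(v, "")) {
        rec[[col]] <- NA_real_
      } else {
        num <- suppressWarnings(as.numeric(v))
        if (is.na(num)) {
          stop_sck(sprintf("Line %d: column `%s` is not numeric (`%s`).", i + 1L, col, v))
        }
        rec[[col]] <- num
      }
    }
    for (col in setdiff(cohort_columns, cohort_numeric)) {
      if (identical(rec[[col]], "")) rec[[col]] <- NA_character_
    }
    tibble::as_tibble(rec)
  })
  check_cohort_keys(rows, offset = 1L)
  rows
}

check_cohort_keys <- function(table, offset = 0L) {
  key <- paste(table$cell_id, table$condition, table$phase, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup)) {
    stop_sck(sprintf("Line %d: duplicate (cell_id, condition, phase) key `%s`.",
                     dup[1] + offset, table$cell_id[dup[1]]))
  }
  invisible(table)
}

#' Build a cohort-table row from a kinetic fit
#'
#' @param fit A `kinetic_fit`.
#' @param cell_id,cell_type,condition,phase Identifying labels.
#' @return A one-row tibble in the cohort schema.
#' @export
cohort_record <- function(fit, cell_id, cell_type = NA_character_,
                          condition = NA_character_, phase = NA_character_) {
  if (!inherits(fit, "kinetic_fit")) stop_sck("`fit` must be a kinetic_fit.")
  dm <- derived_metrics(fit)
  p <- as.list(fit$params)
  tibble::tibble(
    cell_id = cell_id, cell_type = cell_type, condition = condition,
    phase = phase, model = fit$model,
    P = p$P %||% NA_real_, Q = p$Q %||% NA_real_,
    A = p$A %||% NA_real_, B = p$B %||% NA_real_,
    C = p$C %||% NA_real_, D = p$D %||% NA_real_,
    R = fit$R, plateau = dm$plateau, half_time_s = dm$half_time_s,
    flags = if (length(fit$flags)) paste(fit$flags, collapse = ";") else NA_character_
  )
}
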