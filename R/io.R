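# Trial files are plain UTF-8 TSV: optional '#key=value' metadata lines,
# then one header line, then one row per sample. Columns carry their units
# in the name (time_s, platform_ap_cm, ...); mm and m displacement columns
# are converted to cm on read.

.DISP_UNITS <- c(cm = 1, mm = 0.1, m = 100)

#' Read a trial recording from a delimited text file
#'
#' Reads a tab-delimited trial table written by [write_trial()] (or exported
#' from any capture system in the same layout): optional `#key=value`
#' metadata lines, then a header naming a time column and the platform, head
#' and pelvis AP displacement columns. Displacement columns named with a
#' `_mm` or `_m` unit suffix are converted to cm.
#'
#' @param path Path to the file.
#' @param metadata Named list overriding metadata read from the file
#'   (`sampling_rate`, `subject_id`, `visual_condition`, `frequency`,
#'   `trial_index`).
#' @return A validated [trial_recording()].
#' @export
read_trial <- function(path, metadata = list()) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    stop("empty file: ", path, call. = FALSE)
  }
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  meta <- modifyList(meta, metadata)

  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2L) {
    stop("file has a header but no data rows: ", path, call. = FALSE)
  }
  tab <- read.delim(text = body, sep = "\t", header = TRUE,
                    check.names = FALSE)

  pick <- function(role) {
    hit <- grep(paste0("^", role), names(tab))
    if (length(hit) != 1L) {
      stop("expected exactly one column named '", role,
           "*' in ", path, call. = FALSE)
    }
    names(tab)[hit]
  }
  time_col <- pick("time")
  cols <- c(platform = pick("platform"), head = pick("head"),
            pelvis = pick("pelvis"))

  to_cm <- function(col) {
    unit <- sub(".*_([a-z]+)$", "\\1", col)
    scale <- .DISP_UNITS[unit]
    if (is.na(scale)) scale <- 1  # unitless header: assume cm
    as.numeric(tab[[col]]) * unname(scale)
  }

  time <- as.numeric(tab[[time_col]])
  rate <- if (!is.null(meta$sampling_rate)) {
    as.numeric(meta$sampling_rate)
  } else if (length(time) > 1L) {
    1 / median(diff(time))
  } else {
    stop("sampling_rate not declared and cannot be inferred", call. = FALSE)
  }

  trial_recording(
    time = time,
    platform_ap = to_cm(cols[["platform"]]),
    head_ap = to_cm(cols[["head"]]),
    pelvis_ap = to_cm(cols[["pelvis"]]),
    sampling_rate = rate,
    subject_id = meta$subject_id %||% "S01",
    visual_condition = meta$visual_condition %||% "EO",
    frequency = as.numeric(meta$frequency %||% 0.18),
    trial_index = as.integer(meta$trial_index %||% 1L)
  )
}

#' Write a trial recording to a delimited text file
#'
#' Writes the tab-delimited dialect that [read_trial()] inverts: metadata as
#' `#key=value` comment lines, a header
#' `time_s  platform_ap_cm  head_ap_cm  pelvis_ap_cm`, and values printed
#' with 12 decimal places so the write-read round trip preserves traces to
#' 1e-12 cm.
#'
#' @param rec A [trial_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trial <- function(rec, path) {
  validate_trial_recording(rec)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("#sampling_rate=%.10g", rec$sampling_rate),
    sprintf("#subject_id=%s", rec$subject_id),
    sprintf("#visual_condition=%s", rec$visual_condition),
    sprintf("#frequency=%.10g", rec$frequency),
    sprintf("#trial_index=%d", rec$trial_index),
    "time_s\tplatform_ap_cm\thead_ap_cm\tpelvis_ap_cm"
  ), con)
  writeLines(sprintf("%.12f\t%.12f\t%.12f\t%.12f",
                     rec$time, rec$platform_ap, rec$head_ap, rec$pelvis_ap),
             con)
  invisible(path)
}

#' Write a tidy results table
#'
#' Writes one TSV with one row per (subject, condition, frequency, segment)
#' key. Column order is preserved as given; keys must be unique.
#'
#' @param results A data frame with at least the key columns `subject`,
#'   `condition`, `frequency`, `segment`, typically the `fits` table of
#'   [run_pipeline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  key_cols <- c("subject", "condition", "frequency", "segment")
  if (nrow(results) == 0L) {
    stop("results table is empty", call. = FALSE)
  }
  missing <- setdiff(key_cols, names(results))
  if (length(missing)) {
    stop("results table lacks key column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  key <- do.call(paste, c(results[key_cols], sep = "\r"))
  if (anyDuplicated(key)) {
    stop("duplicate (subject, condition, frequency, segment) keys",
         call. = FALSE)
  }
  write.table(results, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
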