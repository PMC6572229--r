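# Episode-table readers and writers. Flat CSV is the canonical dialect
# (UTF-8, comma-separated, semicolon-joined code lists); JSON lines is
# the lossless alternative.

EPISODE_MANDATORY <- c("episode_id", "codes")
EPISODE_KNOWN <- c("episode_id", "age", "sex", "hospital_level", "codes",
                   paste0("rater", 1:3, "_pp"),
                   paste0("rater", 1:3, "_categories"))

#' Read an episode table
#'
#' Adult-inclusion filtering is applied on read: episodes aged under 18
#' are excluded and counted in the `"n_underage"` attribute. Rows whose
#' mandatory fields are missing are collected (with line numbers) into
#' the `"warnings"` attribute rather than read partially.
#'
#' @param path CSV or JSON-lines file with a header/keys including
#'   `episode_id` and `codes` (semicolon-joined) and optionally `age`,
#'   `sex`, `hospital_level`, `rater1_pp` ... `rater3_categories`.
#' @param format `"csv"` (default) or `"jsonl"`, or `NULL` to infer from
#'   the file extension.
#' @return data.frame of episodes with attributes `"warnings"` (character
#'   vector) and `"n_underage"` (integer).
#' @export
read_episode_table <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(format))
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl"
              else "csv"
  format <- match.arg(format, c("csv", "jsonl"))
  df <- if (format == "csv") {
    utils::read.csv(path, stringsAsFactors = FALSE,
                    colClasses = "character")
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    rows <- lapply(lines, function(l)
      jsonlite::fromJSON(l, simplifyVector = TRUE))
    all_names <- unique(unlist(lapply(rows, names)))
    as.data.frame(
      stats::setNames(lapply(all_names, function(nm)
        vapply(rows, function(r) {
          v <- r[[nm]]
          if (is.null(v) || length(v) == 0L) NA_character_
          else if (nm == "codes" && length(v) > 1L)
            paste(as.character(v), collapse = ";")
          else as.character(v[1])
        }, character(1))), all_names),
      stringsAsFactors = FALSE)
  }
  missing_cols <- setdiff(EPISODE_MANDATORY, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  warnings <- character()
  bad_id <- is.na(df$episode_id) | !nzchar(trimws(df$episode_id))
  if (any(bad_id)) {
    warnings <- c(warnings, sprintf("line %d: missing episode_id",
                                    which(bad_id) + 1L))
    df <- df[!bad_id, , drop = FALSE]
  }
  if (anyDuplicated(df$episode_id))
    stop("duplicate episode_id values", call. = FALSE)

  if ("age" %in% names(df)) {
    df$age <- suppressWarnings(as.numeric(df$age))
    underage <- !is.na(df$age) & df$age < 18
    n_underage <- sum(underage)
    if (n_underage > 0) {
      warnings <- c(warnings, sprintf(
        "excluded %d episode(s) aged under 18 (adult-only inclusion)",
        n_underage))
      df <- df[!underage, , drop = FALSE]
    }
  } else n_underage <- 0L

  if ("hospital_level" %in% names(df))
    df$hospital_level <- suppressWarnings(as.integer(df$hospital_level))
  for (cl in intersect(paste0("rater", 1:3, "_pp"), names(df)))
    df[[cl]] <- suppressWarnings(as.integer(df[[cl]]))
  df$codes[is.na(df$codes)] <- ""

  rownames(df) <- NULL
  attr(df, "warnings") <- warnings
  attr(df, "n_underage") <- n_underage
  df
}

#' Write an episode table
#'
#' Inverse of [read_episode_table()]: writing then reading is the
#' identity on parsed fields.
#'
#' @param episodes data.frame of episodes.
#' @param path output path.
#' @param format `"csv"` or `"jsonl"`, or `NULL` to infer from extension.
#' @return `path`, invisibly.
#' @export
write_episode_table <- function(episodes, path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.jsonl?$", path, ignore.case = TRUE)) "jsonl"
              else "csv"
  format <- match.arg(format, c("csv", "jsonl"))
  if (format == "csv") {
    utils::write.csv(episodes, path, row.names = FALSE, quote = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(episodes))) {
      row <- as.list(episodes[i, , drop = FALSE])
      row$codes <- strsplit(as.character(row$codes), ";", fixed = TRUE)[[1]]
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, na = "null"),
                 con)
    }
  }
  invisible(path)
}

#' Write a cohort's truth sidecar
#'
#' JSON-lines file carrying the latent truth of a synthetic cohort, one
#' object per episode, for parameter-recovery runs.
#'
#' @param cohort a `pp_cohort`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_truth_sidecar <- function(cohort, path) {
  stopifnot(inherits(cohort, "pp_cohort"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(cohort$truth))) {
    row <- cohort$truth[i, ]
    obj <- list(
      episode_id = row$episode_id,
      true_categories = strsplit(row$true_categories, ";",
                                 fixed = TRUE)[[1]],
      true_pp = row$true_pp
    )
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE), con)
  }
  invisible(path)
}
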