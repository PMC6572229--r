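# Consensus reference standard: up to three independent clinician
# assessments per episode collapsed into a single label. The PP flag is
# granted by two or three concordant raters; per-category consensus uses
# the same strict-majority rule among the raters that reported categories.

#' Consensus label from independent rater assessments
#'
#' @param assessments data.frame with one row per rater and columns
#'   `rater_id` (distinct), `pp_flag` (logical), and optionally
#'   `categories` (semicolon-joined letters A-H, or a list-column of
#'   character vectors; `NA` means the rater reported no per-category
#'   breakdown).
#' @return an object of class `pp_consensus_label`: list with `pp_flag`,
#'   `categories` (letters flagged by a strict majority of the raters who
#'   reported categories), `n_categories`, and `unresolved` (`TRUE` only
#'   for a discordant two-rater pair, in which case `pp_flag` is `NA`).
#'   Three raters resolve by 2-of-3 majority; two raters must agree.
#' @examples
#' a <- data.frame(rater_id = 1:3, pp_flag = c(TRUE, TRUE, FALSE))
#' pp_consensus(a)$pp_flag  # TRUE
#' @export
pp_consensus <- function(assessments) {
  stopifnot(is.data.frame(assessments),
            all(c("rater_id", "pp_flag") %in% names(assessments)))
  n <- nrow(assessments)
  if (n < 2L)
    stop("consensus requires 2 or 3 rater assessments, got ", n,
         call. = FALSE)
  if (n > 3L)
    stop("at most 3 rater assessments supported, got ", n, call. = FALSE)
  if (anyDuplicated(assessments$rater_id))
    stop("duplicate rater_id in assessments", call. = FALSE)
  flags <- as.logical(assessments$pp_flag)
  if (anyNA(flags))
    stop("pp_flag must be non-missing for every rater", call. = FALSE)

  unresolved <- FALSE
  if (n == 3L) {
    pp <- sum(flags) >= 2L
  } else {
    if (flags[1] == flags[2]) {
      pp <- flags[1]
    } else {
      pp <- NA
      unresolved <- TRUE
    }
  }

  cats <- character()
  if ("categories" %in% names(assessments)) {
    cat_sets <- parse_category_sets(assessments$categories)
    reported <- !vapply(cat_sets, function(x) length(x) == 1L && is.na(x),
                        logical(1))
    if (any(reported)) {
      sets <- cat_sets[reported]
      counts <- table(factor(unlist(sets), levels = CATEGORY_LETTERS))
      cats <- names(counts)[counts > length(sets) / 2]
    }
  }

  structure(
    list(pp_flag = pp, categories = cats, n_categories = length(cats),
         unresolved = unresolved),
    class = "pp_consensus_label"
  )
}

parse_category_sets <- function(x) {
  if (is.list(x) && !is.character(x)) {
    lapply(x, function(s) {
      if (length(s) == 0L || (length(s) == 1L && is.na(s))) return(NA)
      s <- toupper(trimws(as.character(s)))
      bad <- setdiff(s, CATEGORY_LETTERS)
      if (length(bad))
        stop("unknown category letter(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      unique(s)
    })
  } else {
    lapply(as.character(x), function(s) {
      if (is.na(s)) return(NA)
      parts <- toupper(trimws(strsplit(s, ";", fixed = TRUE)[[1]]))
      parts <- parts[nzchar(parts)]
      if (!length(parts)) return(character())
      bad <- setdiff(parts, CATEGORY_LETTERS)
      if (length(bad))
        stop("unknown category letter(s): ", paste(bad, collapse = ", "),
             call. = FALSE)
      unique(parts)
    })
  }
}

#' @export
print.pp_consensus_label <- function(x, ...) {
  cat("<pp_consensus_label: PP = ", x$pp_flag,
      if (x$unresolved) " (unresolved two-rater discordance)",
      if (length(x$categories))
        paste0("; categories {", paste(x$categories, collapse = ","), "}"),
      ">\n", sep = "")
  invisible(x)
}

#' Consensus labels for a whole episode table
#'
#' Reads the wide rater columns (`rater1_pp` ... `rater3_pp`, optional
#' `rater1_categories` ...) and applies [pp_consensus()] per episode.
#' Episodes with fewer than two rater flags get `NA` consensus; discordant
#' two-rater pairs are flagged unresolved. Both situations are counted in
#' the `"n_unresolved"`/`"n_insufficient"` attributes so downstream
#' concordance computations can exclude and report them.
#'
#' @param episodes data.frame with rater columns as above.
#' @return data.frame with columns `episode_id`, `consensus_pp`,
#'   `consensus_categories`, `consensus_n_categories`, `unresolved`.
#' @export
consensus_labels <- function(episodes) {
  stopifnot(is.data.frame(episodes), "episode_id" %in% names(episodes))
  pp_cols <- intersect(paste0("rater", 1:3, "_pp"), names(episodes))
  cat_cols <- intersect(paste0("rater", 1:3, "_categories"),
                        names(episodes))
  if (length(pp_cols) < 2L)
    stop("need at least two rater pp columns (rater1_pp, rater2_pp, ...)",
         call. = FALSE)
  n <- nrow(episodes)
  pp <- rep(NA, n)
  cats <- character(n)
  ncat <- rep(NA_integer_, n)
  unresolved <- rep(FALSE, n)
  n_insufficient <- 0L

  for (i in seq_len(n)) {
    flags <- vapply(pp_cols, function(cl) as.numeric(episodes[[cl]][i]),
                    numeric(1))
    have <- !is.na(flags)
    if (sum(have) < 2L) {
      n_insufficient <- n_insufficient + 1L
      next
    }
    a <- data.frame(rater_id = which(have),
                    pp_flag = as.logical(flags[have]))
    if (length(cat_cols)) {
      cat_vals <- vapply(paste0("rater", which(have), "_categories"),
                         function(cl)
                           if (cl %in% names(episodes))
                             as.character(episodes[[cl]][i])
                           else NA_character_,
                         character(1))
      a$categories <- cat_vals
    }
    lab <- pp_consensus(a)
    pp[i] <- lab$pp_flag
    cats[i] <- paste(lab$categories, collapse = ";")
    ncat[i] <- lab$n_categories
    unresolved[i] <- lab$unresolved
  }

  out <- data.frame(
    episode_id = as.character(episodes$episode_id),
    consensus_pp = pp,
    consensus_categories = cats,
    consensus_n_categories = ncat,
    unresolved = unresolved,
    stringsAsFactors = FALSE
  )
  attr(out, "n_unresolved") <- sum(unresolved)
  attr(out, "n_insufficient") <- n_insufficient
  out
}
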