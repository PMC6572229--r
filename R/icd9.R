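# ICD-9-CM code normalization and pattern matching.
#
# Codes are handled as canonical strings: a 3-character root (NNN, VNN or
# ENNN) plus an optional 0-2 digit decimal extension, rendered
# root["." extension]. Dotless 4-5 digit inputs are split after the third
# character (after the fourth for E-codes), the dialect used by flat MBDS
# exports.

#' Parse ICD-9-CM code strings
#'
#' Tolerant parser for raw diagnosis-code strings as found in discharge
#' extracts: surrounding whitespace, lowercase `v`/`e` prefixes and missing
#' decimal points (`"4280"` is read as `428.0`) are all accepted.
#' Malformed codes are reported, not silently dropped.
#'
#' @param x character vector of raw code strings.
#' @return A data.frame with one row per input and columns `raw`, `root`,
#'   `extension`, `is_v_code`, `is_e_code`, `canonical`, `valid`, `reason`.
#'   For invalid inputs `canonical` is `NA` and `reason` says why.
#' @examples
#' icd9_parse(c("402.91", "  v58 ", "4280", "59x"))
#' @export
icd9_parse <- function(x) {
  raw <- as.character(x)
  s <- toupper(trimws(raw))
  n <- length(s)
  reason <- rep(NA_character_, n)
  r <- rep(NA_character_, n)
  e <- rep(NA_character_, n)

  empty <- is.na(s) | !nzchar(s)
  reason[empty] <- "empty code"

  has_dot <- !empty & grepl(".", s, fixed = TRUE)
  dotted_ok <- has_dot & grepl("^[^.]+\\.[^.]*$", s)
  reason[has_dot & !dotted_ok] <- "malformed decimal point"
  r[dotted_ok] <- sub("\\..*$", "", s[dotted_ok])
  e[dotted_ok] <- sub("^[^.]*\\.", "", s[dotted_ok])

  # dotless dialect: split after the root (E-codes have 4-character roots)
  undotted <- !empty & !has_dot
  rootlen <- ifelse(!is.na(s) & startsWith(s, "E"), 4L, 3L)
  r[undotted] <- substr(s[undotted], 1L, rootlen[undotted])
  e[undotted] <- substr(s[undotted], rootlen[undotted] + 1L,
                        nchar(s[undotted]))

  cand <- !empty & is.na(reason)
  ok_root <- cand & (grepl("^[0-9]{3}$", r) | grepl("^V[0-9]{2}$", r) |
                       grepl("^E[0-9]{3}$", r))
  bad_root <- cand & !ok_root
  reason[bad_root] <- sprintf("invalid root '%s' (expected NNN, VNN or ENNN)",
                              r[bad_root])
  valid <- ok_root & grepl("^[0-9]{0,2}$", e)
  bad_ext <- ok_root & !valid
  reason[bad_ext] <- sprintf("invalid extension '%s' (0-2 digits allowed)",
                             e[bad_ext])

  root <- r; root[!valid] <- NA_character_
  ext <- e; ext[!valid] <- NA_character_
  canonical <- rep(NA_character_, n)
  canonical[valid] <- paste0(root[valid],
                             ifelse(nzchar(ext[valid]), ".", ""),
                             ext[valid])
  data.frame(
    raw = raw,
    root = root,
    extension = ext,
    is_v_code = valid & !is.na(root) & startsWith(root, "V"),
    is_e_code = valid & !is.na(root) & startsWith(root, "E"),
    canonical = canonical,
    valid = valid,
    reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Normalize ICD-9-CM codes to canonical text
#'
#' @param x character vector of raw code strings.
#' @param strict if `TRUE` (default) malformed codes raise an error; if
#'   `FALSE` they become `NA` with a warning listing the reasons.
#' @return character vector of canonical codes (`root` or `root.extension`).
#'   Normalization is idempotent.
#' @examples
#' icd9_normalize(c("4280", " 428.0 ", "v58"))  # "428.0" "428.0" "V58"
#' @export
icd9_normalize <- function(x, strict = TRUE) {
  p <- icd9_parse(x)
  if (any(!p$valid)) {
    bad <- p[!p$valid, , drop = FALSE]
    msg <- paste0("'", bad$raw, "': ", bad$reason, collapse = "; ")
    if (strict) stop("malformed ICD-9-CM code(s): ", msg, call. = FALSE)
    warning("malformed ICD-9-CM code(s) set to NA: ", msg, call. = FALSE)
  }
  p$canonical
}

#' Construct an ICD-9-CM matching pattern
#'
#' Two pattern kinds cover the catalog's vocabulary. A *prefix* pattern such
#' as `"428"` matches the bare root and every decimal child (`428`, `428.0`,
#' `428.22`, ...); a prefix with an extension such as `"402.91"` matches
#' itself and any further subdivision. A *range* pattern such as
#' `410`-`414` matches every code whose numeric root falls in the closed
#' interval, at any extension. Exceptions are prefixes carved out of the
#' matched set.
#'
#' @param prefix canonical code string to use as prefix.
#' @param exceptions character vector of code prefixes excluded from the
#'   match; each must itself fall inside the parent pattern.
#' @return an object of class `icd9_pattern`.
#' @examples
#' icd9_prefix("571", exceptions = c("571.0", "571.1"))
#' icd9_range("410", "414")
#' @export
icd9_prefix <- function(prefix, exceptions = character()) {
  prefix <- icd9_normalize(prefix)
  stopifnot(length(prefix) == 1L)
  pat <- structure(
    list(kind = "prefix", prefix = prefix,
         exceptions = if (length(exceptions)) icd9_normalize(exceptions)
                      else character()),
    class = "icd9_pattern"
  )
  check_pattern(pat)
  pat
}

#' @rdname icd9_prefix
#' @param range_start,range_end 3-character roots, inclusive endpoints.
#'   Ranges never span the numeric, V- and E- code spaces.
#' @export
icd9_range <- function(range_start, range_end, exceptions = character()) {
  range_start <- icd9_normalize(range_start)
  range_end <- icd9_normalize(range_end)
  stopifnot(length(range_start) == 1L, length(range_end) == 1L)
  pat <- structure(
    list(kind = "range", range_start = range_start, range_end = range_end,
         exceptions = if (length(exceptions)) icd9_normalize(exceptions)
                      else character()),
    class = "icd9_pattern"
  )
  check_pattern(pat)
  pat
}

root_space <- function(root) {
  if (startsWith(root, "V")) "V" else if (startsWith(root, "E")) "E" else "N"
}

root_number <- function(root) {
  as.integer(sub("^[VE]", "", root))
}

check_pattern <- function(pat) {
  if (pat$kind == "range") {
    if (grepl("\\.", pat$range_start) || grepl("\\.", pat$range_end))
      stop("range endpoints must be bare roots", call. = FALSE)
    if (root_space(pat$range_start) != root_space(pat$range_end))
      stop("range must not span numeric/V/E code spaces", call. = FALSE)
    if (root_number(pat$range_start) > root_number(pat$range_end))
      stop("range_start exceeds range_end", call. = FALSE)
  }
  # every exception must itself lie inside the parent's scope
  if (length(pat$exceptions)) {
    parent <- pat
    parent$exceptions <- character()
    inside <- icd9_matches(pat$exceptions, parent)
    if (!all(inside))
      stop("exception(s) outside parent pattern scope: ",
           paste(pat$exceptions[!inside], collapse = ", "), call. = FALSE)
  }
  invisible(pat)
}

#' @export
print.icd9_pattern <- function(x, ...) {
  body <- if (x$kind == "prefix") x$prefix
          else paste0(x$range_start, "-", x$range_end)
  exc <- if (length(x$exceptions))
    paste0(" except ", paste(x$exceptions, collapse = ", ")) else ""
  cat("<icd9_pattern ", x$kind, ": ", body, exc, ">\n", sep = "")
  invisible(x)
}

# prefix semantics on canonical strings: code equals the prefix, or shares
# the prefix's root and its extension extends the prefix's extension
matches_prefix <- function(roots, exts, prefix) {
  pp <- icd9_parse(prefix)
  same_root <- !is.na(roots) & roots == pp$root
  if (!nzchar(pp$extension)) return(same_root)
  same_root & startsWith(exts, pp$extension)
}

#' Match codes against a pattern
#'
#' @param codes character vector of codes (raw or canonical; normalized
#'   internally). `NA` or malformed codes never match.
#' @param pattern an [icd9_prefix()] or [icd9_range()] pattern.
#' @return logical vector, one element per code. Total on valid inputs;
#'   a code matching any exception prefix yields `FALSE`.
#' @examples
#' p <- icd9_prefix("571", exceptions = c("571.0", "571.1"))
#' icd9_matches(c("571.2", "571.0", "571"), p)  # TRUE FALSE TRUE
#' @export
icd9_matches <- function(codes, pattern) {
  stopifnot(inherits(pattern, "icd9_pattern"))
  p <- icd9_parse(codes)
  roots <- p$root
  exts <- p$extension
  exts[is.na(exts)] <- ""

  if (pattern$kind == "prefix") {
    hit <- matches_prefix(roots, exts, pattern$prefix)
  } else {
    space <- root_space(pattern$range_start)
    spaces <- ifelse(is.na(roots), NA_character_,
                     ifelse(substr(roots, 1, 1) == "V", "V",
                            ifelse(substr(roots, 1, 1) == "E", "E", "N")))
    num <- suppressWarnings(as.integer(sub("^[VE]", "", roots)))
    hit <- !is.na(spaces) & spaces == space & !is.na(num) &
      num >= root_number(pattern$range_start) &
      num <= root_number(pattern$range_end)
  }
  for (exc in pattern$exceptions) {
    hit <- hit & !matches_prefix(roots, exts, exc)
  }
  hit & p$valid
}
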