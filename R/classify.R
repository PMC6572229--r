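# Episode-level category assignment and the >=2-categories PP rule.

#' Assign clinical categories to one episode
#'
#' A subcategory is matched when at least one of the episode's codes
#' matches one of its patterns and no code in the episode matches one of
#' its episode-level exclusions (the V58 chemo/radiotherapy veto on G.2 is
#' the only such rule in the default catalog). The patient is flagged
#' polypathological (PP) when the matched subcategories span two or more
#' categories; a second flag repeats the rule with category H
#' (osteoarticular disease) ignored.
#'
#' Matching ignores diagnosis position (main vs secondary) and is
#' deterministic in the code multiset: order and duplication are
#' irrelevant. Malformed codes are collected, reported via the profile's
#' `invalid_codes` field, and skipped.
#'
#' @param codes character vector of raw diagnosis codes for one episode.
#' @param catalog a `pp_catalog`; defaults to the shipped rulebook.
#' @return an object of class `pp_profile`: a list with
#'   `matched_subcategories`, `matched_categories`, `triggering_codes`
#'   (named list, subcategory id -> codes that fired), `n_categories`,
#'   `pp_with_h`, `pp_without_h`, `invalid_codes`.
#' @examples
#' p <- pp_assign(c("428.0", "585.9"))
#' p$matched_categories  # "A" "B"
#' p$pp_with_h           # TRUE
#' @export
pp_assign <- function(codes, catalog = default_pp_catalog()) {
  validate_pp_catalog(catalog)
  parsed <- icd9_parse(as.character(codes))
  invalid <- unique(parsed$raw[!parsed$valid & !is.na(parsed$raw)])
  canon <- unique(parsed$canonical[parsed$valid])
  lut <- code_subcategory_lookup(canon, catalog)
  profile_from_lookup(canon, lut, invalid)
}

# match a set of unique canonical codes against every subcategory once;
# returns hit and veto logical matrices (codes x subcategories)
code_subcategory_lookup <- function(canon, catalog) {
  subs <- catalog_subcategories(catalog)
  hit <- matrix(FALSE, length(canon), length(subs),
                dimnames = list(canon, names(subs)))
  veto <- hit
  for (s in names(subs)) {
    for (pat in subs[[s]]$patterns)
      hit[, s] <- hit[, s] | icd9_matches(canon, pat)
    for (pat in subs[[s]]$episode_exclusions)
      veto[, s] <- veto[, s] | icd9_matches(canon, pat)
  }
  list(hit = hit, veto = veto,
       sub_category = vapply(subs, `[[`, character(1), "category"))
}

profile_from_lookup <- function(canon, lut, invalid) {
  idx <- match(canon, rownames(lut$hit))
  hit <- lut$hit[idx, , drop = FALSE]
  veto <- lut$veto[idx, , drop = FALSE]
  fired <- colSums(hit) > 0 & colSums(veto) == 0
  matched_subs <- colnames(hit)[fired]
  triggering <- lapply(matched_subs, function(s) canon[hit[, s]])
  names(triggering) <- matched_subs
  matched_cats <- sort(unique(unname(lut$sub_category[matched_subs])))

  structure(
    list(
      matched_subcategories = matched_subs,
      matched_categories = matched_cats,
      triggering_codes = triggering,
      n_categories = length(matched_cats),
      pp_with_h = length(matched_cats) >= 2L,
      pp_without_h = length(setdiff(matched_cats, "H")) >= 2L,
      invalid_codes = invalid
    ),
    class = "pp_profile"
  )
}

#' @export
print.pp_profile <- function(x, ...) {
  cat("<pp_profile: ", x$n_categories, " categories",
      if (x$n_categories) paste0(" {", paste(x$matched_categories,
                                             collapse = ","), "}"),
      "; PP = ", x$pp_with_h,
      if (x$pp_with_h != x$pp_without_h) " (not PP without category H)",
      ">\n", sep = "")
  if (length(x$invalid_codes))
    cat("  skipped malformed codes: ",
        paste(x$invalid_codes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Classify a table of episodes
#'
#' Applies [pp_assign()] to every episode of a table read by
#' [read_episode_table()] (or of the same shape) and returns one row per
#' episode.
#'
#' @param episodes data.frame with columns `episode_id` and `codes`
#'   (semicolon-joined code string or list-column of character vectors).
#' @param catalog a `pp_catalog`.
#' @return data.frame with columns `episode_id`, `n_categories`,
#'   `pp`, `pp_without_h`, `categories`, `subcategories` (semicolon-joined),
#'   `n_invalid_codes`; the full list of `pp_profile` objects is attached
#'   as attribute `"profiles"`.
#' @examples
#' eps <- data.frame(episode_id = c("e1", "e2"),
#'                   codes = c("428.0;585.9", "715.9"))
#' pp_classify(eps)
#' @export
pp_classify <- function(episodes, catalog = default_pp_catalog()) {
  stopifnot(is.data.frame(episodes),
            all(c("episode_id", "codes") %in% names(episodes)))
  if (anyDuplicated(episodes$episode_id))
    stop("episode_id values must be unique", call. = FALSE)
  validate_pp_catalog(catalog)
  code_lists <- episode_code_lists(episodes)
  # parse and match each distinct code once across the whole table
  all_parsed <- icd9_parse(unique(unlist(code_lists, use.names = FALSE)))
  lut <- code_subcategory_lookup(all_parsed$canonical[all_parsed$valid],
                                 catalog)
  canon_map <- stats::setNames(all_parsed$canonical, all_parsed$raw)
  valid_map <- stats::setNames(all_parsed$valid, all_parsed$raw)
  profiles <- lapply(code_lists, function(codes) {
    codes <- as.character(codes)
    invalid <- unique(codes[!valid_map[codes]])
    canon <- unique(canon_map[codes[valid_map[codes]]])
    profile_from_lookup(unname(canon), lut, unname(invalid))
  })
  out <- data.frame(
    episode_id = as.character(episodes$episode_id),
    n_categories = vapply(profiles, `[[`, integer(1), "n_categories"),
    pp = vapply(profiles, `[[`, logical(1), "pp_with_h"),
    pp_without_h = vapply(profiles, `[[`, logical(1), "pp_without_h"),
    categories = vapply(profiles, function(p)
      paste(p$matched_categories, collapse = ";"), character(1)),
    subcategories = vapply(profiles, function(p)
      paste(p$matched_subcategories, collapse = ";"), character(1)),
    n_invalid_codes = vapply(profiles, function(p)
      length(p$invalid_codes), integer(1)),
    stringsAsFactors = FALSE
  )
  attr(out, "profiles") <- profiles
  out
}

episode_code_lists <- function(episodes) {
  if (is.list(episodes$codes) && !is.character(episodes$codes)) {
    lapply(episodes$codes, as.character)
  } else {
    x <- as.character(episodes$codes)
    x[is.na(x)] <- ""
    lapply(strsplit(x, ";", fixed = TRUE),
           function(x) trimws(x[nzchar(trimws(x))]))
  }
}
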