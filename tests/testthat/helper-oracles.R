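# Independent oracles shared across test files.

# Full syntactic code space: roots 001-999 and V01-V99, extensions
# "", "0"-"9", "00"-"99".
enumerate_icd9_space <- function() {
  roots <- c(sprintf("%03d", 1:999), sprintf("V%02d", 1:99))
  exts <- c("", as.character(0:9), sprintf("%02d", 0:99))
  data.frame(
    root = rep(roots, each = length(exts)),
    ext = rep(exts, times = length(roots)),
    stringsAsFactors = FALSE
  )
}

# String-expansion membership oracle, independent of icd9_matches: works
# directly on (root, ext) pairs with plain string operations.
oracle_pattern_match <- function(space, pattern) {
  match_one_prefix <- function(prefix) {
    dot <- regexpr(".", prefix, fixed = TRUE)
    if (dot > 0) {
      proot <- substr(prefix, 1, dot - 1)
      pext <- substr(prefix, dot + 1, nchar(prefix))
    } else {
      proot <- prefix
      pext <- ""
    }
    space$root == proot &
      (pext == "" | substr(space$ext, 1, nchar(pext)) == pext)
  }
  hit <- if (pattern$kind == "prefix") {
    match_one_prefix(pattern$prefix)
  } else {
    lo <- as.integer(sub("^V", "", pattern$range_start))
    hi <- as.integer(sub("^V", "", pattern$range_end))
    v_range <- grepl("^V", pattern$range_start)
    is_v <- substr(space$root, 1, 1) == "V"
    num <- suppressWarnings(as.integer(sub("^V", "", space$root)))
    (is_v == v_range) & !is.na(num) & num >= lo & num <= hi
  }
  for (exc in pattern$exceptions) hit <- hit & !match_one_prefix(exc)
  hit
}

canonical_from_space <- function(space) {
  paste0(space$root, ifelse(nzchar(space$ext), ".", ""), space$ext)
}

# memoized full-space matcher-vs-oracle comparison over the default
# catalog; returns character vector of disagreement descriptions
.oracle_cache <- new.env(parent = emptyenv())
matcher_oracle_disagreements <- function() {
  if (!is.null(.oracle_cache$result)) return(.oracle_cache$result)
  space <- enumerate_icd9_space()
  codes <- canonical_from_space(space)
  subs <- ppdetect:::catalog_subcategories(default_pp_catalog())
  bad <- character()
  for (sub in subs) {
    pats <- c(sub$patterns, sub$episode_exclusions)
    for (k in seq_along(pats)) {
      got <- icd9_matches(codes, pats[[k]])
      want <- oracle_pattern_match(space, pats[[k]])
      if (!identical(got, want)) {
        n_bad <- sum(got != want)
        bad <- c(bad, sprintf("%s pattern %d: %d disagreement(s), e.g. %s",
                              sub$id, k, n_bad,
                              paste(utils::head(codes[got != want], 3),
                                    collapse = ", ")))
      }
    }
  }
  .oracle_cache$result <- bad
  bad
}

# kappa computed straight from two logical vectors, no package code
naive_kappa <- function(test, ref) {
  po <- mean(test == ref)
  pe <- mean(test) * mean(ref) + mean(!test) * mean(!ref)
  (po - pe) / (1 - pe)
}

# small episode table fixture: three episodes with rater flags
fixture_episodes <- function() {
  data.frame(
    episode_id = c("E1", "E2", "E3"),
    age = c(73, 45, 81),
    sex = c("M", "F", "M"),
    hospital_level = c(3, 2, 1),
    codes = c("428.0;585.9", "715.9", "162.9;V58.1;401.9"),
    rater1_pp = c(1, 0, 0),
    rater2_pp = c(1, 0, 1),
    rater3_pp = c(0, 0, 0),
    stringsAsFactors = FALSE
  )
}
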