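# The category rulebook: eight clinical categories (A-H), each a set of
# subcategories defined by ICD-9-CM patterns. The shipped JSON document is
# the single source of truth; nothing in the code hard-codes a clinical
# code list.

CATEGORY_LETTERS <- LETTERS[1:8]

new_subcategory <- function(id, label, patterns,
                            episode_exclusions = list(), notes = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            length(patterns) >= 1L)
  lapply(patterns, function(p) stopifnot(inherits(p, "icd9_pattern")))
  lapply(episode_exclusions,
         function(p) stopifnot(inherits(p, "icd9_pattern")))
  structure(
    list(id = id, label = label, patterns = patterns,
         episode_exclusions = episode_exclusions, notes = notes),
    class = "pp_subcategory"
  )
}

#' Load a category catalog from JSON or YAML
#'
#' The document schema is
#' `{version, notes?, categories: [{id, label, subcategories: [{id, label,
#' notes?, patterns: [{kind, prefix | range_start + range_end,
#' exceptions?}], episode_exclusions?}]}]}`.
#' Unknown fields are rejected with a locating message, as are duplicate
#' ids, malformed patterns and exceptions lying outside their parent
#' pattern's scope.
#'
#' @param path path to a `.json`, `.yaml` or `.yml` document.
#' @return a validated object of class `pp_catalog`.
#' @seealso [default_pp_catalog()], [write_pp_catalog()]
#' @export
read_pp_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path, call. = FALSE)
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  catalog_from_list(doc)
}

check_fields <- function(x, allowed, required, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(where, ": unknown field(s) ", paste(extra, collapse = ", "),
         call. = FALSE)
  missing <- setdiff(required, names(x))
  if (length(missing))
    stop(where, ": missing field(s) ", paste(missing, collapse = ", "),
         call. = FALSE)
}

pattern_from_list <- function(p, where) {
  check_fields(p, c("kind", "prefix", "range_start", "range_end",
                    "exceptions"), "kind", where)
  exc <- as.character(unlist(p$exceptions %||% character()))
  if (identical(p$kind, "prefix")) {
    check_fields(p, c("kind", "prefix", "exceptions"), c("kind", "prefix"),
                 where)
    icd9_prefix(p$prefix, exceptions = exc)
  } else if (identical(p$kind, "range")) {
    check_fields(p, c("kind", "range_start", "range_end", "exceptions"),
                 c("kind", "range_start", "range_end"), where)
    icd9_range(as.character(p$range_start), as.character(p$range_end),
               exceptions = exc)
  } else {
    stop(where, ": pattern kind must be 'prefix' or 'range', got '",
         p$kind, "'", call. = FALSE)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

catalog_from_list <- function(doc) {
  check_fields(doc, c("version", "notes", "categories"),
               c("version", "categories"), "catalog")
  cats <- lapply(seq_along(doc$categories), function(i) {
    cat_i <- doc$categories[[i]]
    where <- sprintf("category[%d]", i)
    check_fields(cat_i, c("id", "label", "subcategories"),
                 c("id", "label", "subcategories"), where)
    subs <- lapply(seq_along(cat_i$subcategories), function(j) {
      sub_j <- cat_i$subcategories[[j]]
      where_j <- sprintf("%s (%s) subcategory[%d]", where, cat_i$id, j)
      check_fields(sub_j, c("id", "label", "notes", "patterns",
                            "episode_exclusions"),
                   c("id", "label", "patterns"), where_j)
      if (!length(sub_j$patterns))
        stop(where_j, ": patterns must be non-empty", call. = FALSE)
      pats <- lapply(seq_along(sub_j$patterns), function(k)
        tryCatch(pattern_from_list(sub_j$patterns[[k]],
                                   sprintf("%s pattern[%d]", where_j, k)),
                 error = function(e) stop(conditionMessage(e), call. = FALSE)))
      excl <- lapply(seq_along(sub_j$episode_exclusions %||% list()),
                     function(k)
        pattern_from_list(sub_j$episode_exclusions[[k]],
                          sprintf("%s episode_exclusion[%d]", where_j, k)))
      new_subcategory(sub_j$id, sub_j$label, pats, excl,
                      notes = sub_j$notes %||% NULL)
    })
    structure(list(id = cat_i$id, label = cat_i$label, subcategories = subs),
              class = "pp_category")
  })
  cat <- structure(
    list(version = doc$version, notes = doc$notes %||% NULL,
         categories = cats),
    class = "pp_catalog"
  )
  validate_pp_catalog(cat)
  cat
}

#' Validate a category catalog
#'
#' Checks the structural invariants: category ids are exactly A-H, each
#' subcategory id is unique, each subcategory has at least one pattern, and
#' every pattern (already checked at construction) keeps its exceptions
#' inside its own scope.
#'
#' @param catalog a `pp_catalog`.
#' @return the catalog, invisibly; errors describe the first violation.
#' @export
validate_pp_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "pp_catalog"))
  ids <- vapply(catalog$categories, `[[`, character(1), "id")
  if (!identical(sort(ids), CATEGORY_LETTERS))
    stop("catalog categories must be exactly {A..H}, got {",
         paste(ids, collapse = ","), "}", call. = FALSE)
  sub_ids <- unlist(lapply(catalog$categories, function(cc)
    vapply(cc$subcategories, `[[`, character(1), "id")))
  if (anyDuplicated(sub_ids))
    stop("duplicate subcategory id(s): ",
         paste(unique(sub_ids[duplicated(sub_ids)]), collapse = ", "),
         call. = FALSE)
  for (cc in catalog$categories) {
    for (sub in cc$subcategories) {
      if (!startsWith(sub$id, cc$id))
        stop("subcategory id '", sub$id, "' does not belong to category '",
             cc$id, "'", call. = FALSE)
      if (!length(sub$patterns))
        stop("subcategory '", sub$id, "' has no patterns", call. = FALSE)
    }
  }
  invisible(catalog)
}

#' The shipped polypathology catalog
#'
#' The default rulebook: eight clinical categories (A cardiac, B
#' autoimmune/renal, C respiratory, D digestive, E neurological, F
#' vascular/diabetic, G anaemia/neoplasia, H osteoarticular), each defined
#' by ICD-9-CM prefixes and root ranges, with the `571.0`/`571.1` and
#' `443.81` carve-outs and the episode-level V58 (chemo/radiotherapy
#' admission) veto on subcategory G.2. Shipped as an editable JSON file in
#' `system.file("extdata", "pp_catalog_default.json", package = "ppdetect")`.
#'
#' @return a `pp_catalog` with exactly 8 categories and 15 subcategories.
#' @examples
#' cat <- default_pp_catalog()
#' print(cat)
#' @export
default_pp_catalog <- function() {
  if (is.null(.ppdetect_cache$default_catalog)) {
    path <- system.file("extdata", "pp_catalog_default.json",
                        package = "ppdetect")
    .ppdetect_cache$default_catalog <- read_pp_catalog(path)
  }
  .ppdetect_cache$default_catalog
}

.ppdetect_cache <- new.env(parent = emptyenv())

pattern_to_list <- function(p) {
  out <- if (p$kind == "prefix") {
    list(kind = "prefix", prefix = p$prefix)
  } else {
    list(kind = "range", range_start = p$range_start,
         range_end = p$range_end)
  }
  if (length(p$exceptions)) out$exceptions <- as.list(p$exceptions)
  out
}

catalog_to_list <- function(catalog) {
  out <- list(version = catalog$version)
  if (!is.null(catalog$notes)) out$notes <- catalog$notes
  out$categories <- lapply(catalog$categories, function(cc) {
    list(id = cc$id, label = cc$label,
         subcategories = lapply(cc$subcategories, function(sub) {
           s <- list(id = sub$id, label = sub$label)
           if (!is.null(sub$notes)) s$notes <- sub$notes
           s$patterns <- lapply(sub$patterns, pattern_to_list)
           if (length(sub$episode_exclusions))
             s$episode_exclusions <- lapply(sub$episode_exclusions,
                                            pattern_to_list)
           s
         }))
  })
  out
}

#' Serialize a catalog back to JSON or YAML
#'
#' Round-trips with [read_pp_catalog()]: writing then reading yields a
#' catalog identical to the original.
#'
#' @param catalog a `pp_catalog`.
#' @param path output path; `.yaml`/`.yml` selects YAML, anything else JSON.
#' @return `path`, invisibly.
#' @export
write_pp_catalog <- function(catalog, path) {
  validate_pp_catalog(catalog)
  doc <- catalog_to_list(catalog)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(doc, path)
  } else {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(path)
}

#' @export
print.pp_catalog <- function(x, ...) {
  n_sub <- sum(vapply(x$categories, function(cc) length(cc$subcategories),
                      integer(1)))
  cat("<pp_catalog ", x$version, ": ", length(x$categories),
      " categories, ", n_sub, " subcategories>\n", sep = "")
  for (cc in x$categories) {
    cat(" ", cc$id, " ", cc$label, "\n", sep = "")
    for (sub in cc$subcategories) {
      pats <- vapply(sub$patterns, function(p) {
        b <- if (p$kind == "prefix") p$prefix
             else paste0(p$range_start, "-", p$range_end)
        if (length(p$exceptions))
          b <- paste0(b, " (except ", paste(p$exceptions, collapse = ", "),
                      ")")
        b
      }, character(1))
      veto <- if (length(sub$episode_exclusions)) {
        v <- vapply(sub$episode_exclusions, function(p)
          if (p$kind == "prefix") p$prefix
          else paste0(p$range_start, "-", p$range_end), character(1))
        paste0(" [episode veto: ", paste(v, collapse = ", "), "]")
      } else ""
      cat("    ", format(sub$id, width = 4), paste(pats, collapse = ", "),
          veto, "\n", sep = "")
    }
  }
  invisible(x)
}

# flat view used by the classifier and the simulator
catalog_subcategories <- function(catalog) {
  out <- list()
  for (cc in catalog$categories) {
    for (sub in cc$subcategories) {
      sub$category <- cc$id
      out[[sub$id]] <- sub
    }
  }
  out
}
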