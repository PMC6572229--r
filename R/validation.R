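# Central analysis: run the automated detector over an episode table,
# adjudicate the clinician assessments, and compute every concordance and
# validity statistic in one classed result.

#' Validate the automated PP detector against clinical consensus
#'
#' The one-stop analysis. Classifies every episode with the catalog rule
#' engine, collapses the rater columns into the 2-of-3 consensus
#' reference standard, and computes: Cohen's kappa (global), the observed
#' agreement proportion with Wilson interval, sensitivity / specificity /
#' PPV / NPV / accuracy — each both with and without category H — the
#' one-way ICC between the two methods' category counts, and the
#' per-category/subcategory concordance table. Episodes with unresolved
#' or missing consensus are excluded from the statistics and counted.
#'
#' @param episodes data.frame as returned by [read_episode_table()],
#'   including rater columns.
#' @param catalog a `pp_catalog`; default the shipped rulebook.
#' @param conf_level two-sided confidence level for every interval.
#' @return object of class `pp_validation` with components `calls`
#'   (classification table), `consensus`, `table`, `table_without_h`
#'   (`pp_confusion`), `kappa`, `agreement`, `metrics`,
#'   `metrics_without_h`, `icc`, `by_category`, `n_excluded`,
#'   `conf_level`, `catalog_version`.
#' @examples
#' coh <- pp_generate_cohort(pp_sim_config(n_episodes = 120, seed = 3))
#' v <- pp_validation(coh$episodes)
#' v$kappa$kappa
#' summary(v)
#' @export
pp_validation <- function(episodes, catalog = default_pp_catalog(),
                          conf_level = 0.95) {
  calls <- pp_classify(episodes, catalog)
  cons <- consensus_labels(episodes)
  usable <- !is.na(cons$consensus_pp)
  n_excluded <- sum(!usable)

  test <- calls$pp[usable]
  test_wo_h <- calls$pp_without_h[usable]
  ref <- as.logical(cons$consensus_pp[usable])

  tab <- confusion_table(test, ref)
  tab_wo_h <- confusion_table(test_wo_h, ref)

  profiles <- attr(calls, "profiles")[usable]
  icc <- tryCatch(
    icc_category_counts(cons$consensus_n_categories[usable],
                        calls$n_categories[usable], conf_level),
    error = function(e) NULL)
  by_cat <- per_category_concordance(
    cons$consensus_categories[usable], profiles, catalog, conf_level)

  structure(
    list(calls = calls, consensus = cons,
         table = tab, table_without_h = tab_wo_h,
         kappa = cohen_kappa(tab, conf_level),
         agreement = agreement_proportion(tab, conf_level),
         metrics = diagnostic_metrics(tab, conf_level),
         metrics_without_h = diagnostic_metrics(tab_wo_h, conf_level),
         icc = icc,
         by_category = by_cat,
         n_excluded = n_excluded,
         conf_level = conf_level,
         catalog_version = catalog$version),
    class = "pp_validation"
  )
}

#' @export
print.pp_validation <- function(x, ...) {
  cat("Polypathology detector validation (catalog ", x$catalog_version,
      ")\n", sep = "")
  cat("  episodes analysed: ", x$table$n,
      if (x$n_excluded) paste0(" (", x$n_excluded,
                               " excluded: unresolved/missing consensus)"),
      "\n", sep = "")
  cat("  automated PP: ", x$table$tp + x$table$fp,
      "; consensus PP: ", x$table$tp + x$table$fn, "\n", sep = "")
  print(x$kappa)
  cat(sprintf("  agreement = %.3f (%.3f-%.3f)\n", x$agreement$estimate,
              x$agreement$ci_low, x$agreement$ci_high))
  if (!is.null(x$icc))
    cat(sprintf("  ICC(category counts) = %.3f (%.3f-%.3f)\n",
                x$icc$icc, x$icc$ci_low, x$icc$ci_high))
  invisible(x)
}

#' @export
summary.pp_validation <- function(object, ...) {
  print(object)
  cat("\nDiagnostic validity (consensus as truth criterion):\n")
  cat("with category H:\n")
  print(object$metrics)
  cat("without category H:\n")
  print(object$metrics_without_h)
  cat("\nPer-category concordance:\n")
  df <- object$by_category
  df[-(1:2)] <- lapply(df[-(1:2)], round, digits = 3)
  print(df, row.names = FALSE)
  invisible(object)
}

#' Tabular report of a validation
#'
#' Flattens a `pp_validation` into the two standard report tables: the
#' per-category concordance table and the diagnostic-metrics table (with
#' and without category H).
#'
#' @param x a `pp_validation`.
#' @return list of two data.frames, `by_category` and `diagnostics` (the
#'   latter with columns `metric`, `estimate`, `ci_low`, `ci_high`,
#'   `variant`).
#' @export
pp_report <- function(x) {
  stopifnot(inherits(x, "pp_validation"))
  flat <- function(m, variant) {
    do.call(rbind, lapply(
      c("sensitivity", "specificity", "ppv", "npv", "accuracy"),
      function(nm) data.frame(metric = nm,
                              estimate = m[[nm]]$estimate,
                              ci_low = m[[nm]]$ci_low,
                              ci_high = m[[nm]]$ci_high,
                              variant = variant,
                              stringsAsFactors = FALSE)))
  }
  list(by_category = x$by_category,
       diagnostics = rbind(flat(x$metrics, "with_H"),
                           flat(x$metrics_without_h, "without_H")))
}

#' Write validation reports to CSV and JSON
#'
#' @param x a `pp_validation`.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_pp_report <- function(x, dir) {
  rep <- pp_report(x)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c(
    by_category_csv = file.path(dir, "concordance_by_category.csv"),
    diagnostics_csv = file.path(dir, "diagnostic_metrics.csv"),
    json = file.path(dir, "validation.json")
  )
  utils::write.csv(rep$by_category, files[["by_category_csv"]],
                   row.names = FALSE)
  utils::write.csv(rep$diagnostics, files[["diagnostics_csv"]],
                   row.names = FALSE)
  payload <- list(
    schema_version = "1.0",
    catalog_version = x$catalog_version,
    n = x$table$n,
    n_excluded = x$n_excluded,
    confusion = unclass(x$table),
    kappa = x$kappa[c("kappa", "po", "pe", "se_kappa", "ci_low",
                      "ci_high", "p_value")],
    agreement = x$agreement[c("estimate", "ci_low", "ci_high")],
    icc = if (!is.null(x$icc)) x$icc[c("icc", "ci_low", "ci_high",
                                       "model_tag")],
    diagnostics = rep$diagnostics,
    by_category = rep$by_category
  )
  jsonlite::write_json(payload, files[["json"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, dataframe = "rows")
  invisible(files)
}
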