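# Agreement and diagnostic-validity statistics for the automated PP call
# against the clinical consensus reference: Cohen's kappa (asymptotic and
# Fleiss-Cohen-Everitt variances), observed agreement with Wilson score
# intervals, Se/Sp/PPV/NPV/accuracy, one-way ICC of category counts,
# precision-based kappa sample size, and reconstruction of an integer
# 2x2 table from rounded published metrics.

#' Cross-classify two binary vectors into a 2x2 confusion table
#'
#' Convention: `test` is the automated ICD-9-CM call, `ref` the clinical
#' consensus treated as the truth criterion.
#'
#' @param test,ref logical (or 0/1) vectors of equal length, no missing
#'   values.
#' @return object of class `pp_confusion`: list with integer cells `tp`,
#'   `fp`, `fn`, `tn` and total `n`.
#' @examples
#' confusion_table(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusion_table <- function(test, ref) {
  test <- as.logical(test); ref <- as.logical(ref)
  if (length(test) != length(ref))
    stop("test and ref must have equal length", call. = FALSE)
  if (length(test) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(test) || anyNA(ref))
    stop("missing values not allowed; drop or resolve them first",
         call. = FALSE)
  new_confusion(sum(test & ref), sum(test & !ref), sum(!test & ref),
                sum(!test & !ref))
}

new_confusion <- function(tp, fp, fn, tn) {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  stopifnot(all(cells >= 0), all(cells == round(cells)))
  structure(as.list(c(cells, n = sum(cells))), class = "pp_confusion")
}

#' @export
print.pp_confusion <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(test = c("+", "-"), reference = c("+", "-")))
  cat("<pp_confusion n = ", x$n, ">\n", sep = "")
  print(m)
  invisible(x)
}

z_quantile <- function(conf_level) stats::qnorm(1 - (1 - conf_level) / 2)

# Wilson score interval via prop.test without continuity correction
wilson_ci <- function(x, n, conf_level = 0.95) {
  # only the score interval is used; the chi-square test (and its small-n
  # approximation warning) is discarded
  ci <- suppressWarnings(stats::prop.test(x, n, conf.level = conf_level,
                                          correct = FALSE))$conf.int
  c(ci[1], ci[2])
}

kappa_parts <- function(table) {
  with(table, {
    po <- (tp + tn) / n
    p_test <- (tp + fp) / n
    p_ref <- (tp + fn) / n
    pe <- p_test * p_ref + (1 - p_test) * (1 - p_ref)
    list(po = po, pe = pe, p_test = p_test, p_ref = p_ref)
  })
}

# Fleiss-Cohen-Everitt large-sample variance of the kappa estimator for a
# 2x2 probability table; returns n * Var(kappa_hat)
fce_unit_variance <- function(p11, p12, p21, p22) {
  pr <- c(p11 + p12, p21 + p22)   # test marginals
  pc <- c(p11 + p21, p12 + p22)   # reference marginals
  pe <- sum(pr * pc)
  po <- p11 + p22
  if (pe >= 1) return(0)
  k <- (po - pe) / (1 - pe)
  A <- p11 * (1 - (pr[1] + pc[1]) * (1 - k))^2 +
       p22 * (1 - (pr[2] + pc[2]) * (1 - k))^2
  B <- (1 - k)^2 * (p12 * (pc[1] + pr[2])^2 + p21 * (pc[2] + pr[1])^2)
  C <- (k - pe * (1 - k))^2
  (A + B - C) / (1 - pe)^2
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement `(po - pe) / (1 - pe)` with a confidence
#' interval and a test of kappa = 0. The default standard error is the
#' simple asymptotic form `sqrt(po (1 - po) / (n (1 - pe)^2))`; the full
#' Fleiss-Cohen-Everitt variance is available via `se_method = "fce"`.
#' The p-value uses the null-hypothesis variance of the estimator.
#'
#' @param table a `pp_confusion` from [confusion_table()].
#' @param conf_level two-sided confidence level, default 0.95.
#' @param se_method `"asymptotic"` (default) or `"fce"`.
#' @return object of class `pp_agreement`: list with `kappa`, `po`, `pe`,
#'   `se_kappa`, `ci_low`, `ci_high` (truncated to \[-1, 1\]),
#'   `conf_level`, `p_value`, `se_method`.
#' @examples
#' tab <- confusion_table(rep(c(TRUE, FALSE), c(30, 70)),
#'                        rep(c(TRUE, FALSE), c(30, 70)))
#' cohen_kappa(tab)$kappa  # 1
#' @export
cohen_kappa <- function(table, conf_level = 0.95,
                        se_method = c("asymptotic", "fce")) {
  stopifnot(inherits(table, "pp_confusion"), table$n >= 1)
  se_method <- match.arg(se_method)
  parts <- kappa_parts(table)
  po <- parts$po; pe <- parts$pe
  if (pe >= 1 - .Machine$double.eps^0.5)
    stop("degenerate marginals: chance agreement is 1, kappa undefined",
         call. = FALSE)
  kappa <- (po - pe) / (1 - pe)
  n <- table$n
  se <- if (se_method == "asymptotic") {
    sqrt(po * (1 - po) / (n * (1 - pe)^2))
  } else {
    sqrt(fce_unit_variance(table$tp / n, table$fp / n, table$fn / n,
                           table$tn / n) / n)
  }
  z <- z_quantile(conf_level)
  ci <- pmin(1, pmax(-1, kappa + c(-1, 1) * z * se))

  # null-variance statistic for H0: kappa = 0
  pr <- c(parts$p_test, 1 - parts$p_test)
  pc <- c(parts$p_ref, 1 - parts$p_ref)
  var0 <- (pe + pe^2 - sum(pr * pc * (pr + pc))) / (n * (1 - pe)^2)
  p_value <- if (var0 > 0) {
    2 * stats::pnorm(-abs(kappa) / sqrt(var0))
  } else NA_real_

  structure(
    list(kappa = kappa, po = po, pe = pe, se_kappa = se,
         ci_low = ci[1], ci_high = ci[2], conf_level = conf_level,
         p_value = p_value, se_method = se_method),
    class = "pp_agreement"
  )
}

#' @export
print.pp_agreement <- function(x, digits = 3, ...) {
  cat(sprintf("kappa = %.*f (%d%% CI %.*f-%.*f), po = %.*f, p = %s\n",
              digits, x$kappa, round(100 * x$conf_level), digits, x$ci_low,
              digits, x$ci_high, digits, x$po,
              format.pval(x$p_value, digits = 2)))
  invisible(x)
}

#' Observed agreement proportion with Wilson interval
#'
#' @inheritParams cohen_kappa
#' @return list with `estimate` (= (tp+tn)/n), `ci_low`, `ci_high`,
#'   `conf_level`, `method`.
#' @param method `"wilson"` (default, score interval) or `"wald"`.
#' @export
agreement_proportion <- function(table, conf_level = 0.95,
                                 method = c("wilson", "wald")) {
  stopifnot(inherits(table, "pp_confusion"), table$n >= 1)
  method <- match.arg(method)
  x <- table$tp + table$tn
  n <- table$n
  p <- x / n
  ci <- if (method == "wilson") {
    wilson_ci(x, n, conf_level)
  } else {
    se <- sqrt(p * (1 - p) / n)
    pmin(1, pmax(0, p + c(-1, 1) * z_quantile(conf_level) * se))
  }
  list(estimate = p, ci_low = ci[1], ci_high = ci[2],
       conf_level = conf_level, method = method)
}

one_metric <- function(x, nn, conf_level, method) {
  if (nn == 0L)
    return(list(estimate = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                undefined = TRUE))
  ci <- if (method == "wilson") wilson_ci(x, nn, conf_level)
        else {
          p <- x / nn
          pmin(1, pmax(0, p + c(-1, 1) * z_quantile(conf_level) *
                         sqrt(p * (1 - p) / nn)))
        }
  list(estimate = x / nn, ci_low = ci[1], ci_high = ci[2],
       undefined = FALSE)
}

#' Diagnostic validity of the automated call against the clinical reference
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, predictive values
#' `tp/(tp+fp)` and `tn/(tn+fn)`, and accuracy `(tp+tn)/n`, each with a
#' Wilson score interval. A metric whose denominator is zero is reported
#' as undefined (`NA`), never as 0.
#'
#' @inheritParams agreement_proportion
#' @return object of class `pp_diagnostics`: named list of the five
#'   metrics, each a list `estimate`/`ci_low`/`ci_high`/`undefined`.
#' @export
diagnostic_metrics <- function(table, conf_level = 0.95,
                               method = c("wilson", "wald")) {
  stopifnot(inherits(table, "pp_confusion"))
  method <- match.arg(method)
  with(table, structure(
    list(
      sensitivity = one_metric(tp, tp + fn, conf_level, method),
      specificity = one_metric(tn, tn + fp, conf_level, method),
      ppv = one_metric(tp, tp + fp, conf_level, method),
      npv = one_metric(tn, tn + fn, conf_level, method),
      accuracy = one_metric(tp + tn, n, conf_level, method),
      conf_level = conf_level, method = method
    ),
    class = "pp_diagnostics"
  ))
}

#' @export
print.pp_diagnostics <- function(x, digits = 1, ...) {
  for (m in c("sensitivity", "specificity", "ppv", "npv", "accuracy")) {
    v <- x[[m]]
    if (v$undefined) {
      cat(sprintf("%-12s undefined (zero denominator)\n", m))
    } else {
      cat(sprintf("%-12s %.*f%% (%.*f%%-%.*f%%)\n", m,
                  digits, 100 * v$estimate, digits, 100 * v$ci_low,
                  digits, 100 * v$ci_high))
    }
  }
  invisible(x)
}

#' Intraclass correlation of category counts between the two methods
#'
#' One-way random-effects, absolute-agreement, single-measures ICC on the
#' two-column layout (clinical count, automated count), with the F-based
#' confidence interval. A two-way random-effects variant is available for
#' sensitivity analysis.
#'
#' @param clinical,automated numeric vectors of per-episode category
#'   counts, equal length >= 2.
#' @param conf_level two-sided confidence level.
#' @param model `"oneway"` (default) or `"twoway"`.
#' @return object of class `pp_icc`: list with `icc`, `ci_low`, `ci_high`,
#'   `conf_level`, `model_tag`, `n`.
#' @export
icc_category_counts <- function(clinical, automated, conf_level = 0.95,
                                model = c("oneway", "twoway")) {
  model <- match.arg(model)
  stopifnot(length(clinical) == length(automated), length(clinical) >= 2)
  if (anyNA(clinical) || anyNA(automated))
    stop("missing counts not allowed", call. = FALSE)
  m <- cbind(clinical, automated)
  n <- nrow(m); k <- ncol(m)
  if (stats::var(as.vector(m)) == 0)
    stop("zero total variance: ICC undefined", call. = FALSE)

  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  grand <- mean(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  msr <- ss_rows / (n - 1)
  alpha <- 1 - conf_level

  if (model == "oneway") {
    msw <- (ss_tot - ss_rows) / (n * (k - 1))
    icc <- (msr - msw) / (msr + (k - 1) * msw)
    fobs <- msr / msw
    fl <- fobs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- fobs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
    tag <- "oneway-random,absolute-agreement,single-measures"
  } else {
    mse <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
    msc <- ss_cols / (k - 1)
    icc <- (msr - mse) /
      (msr + (k - 1) * mse + k * (msc - mse) / n)
    # McGraw-Wong interval for ICC(A,1)
    fj <- msc / mse
    vn <- (k - 1) * (n - 1) *
      (k * icc * fj + n * (1 + (k - 1) * icc) - k * icc)^2
    vd <- (n - 1) * k^2 * icc^2 * fj^2 +
      (n * (1 + (k - 1) * icc) - k * icc)^2
    v <- vn / vd
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    ci <- c(
      n * (msr - f1 * mse) /
        (f1 * (k * msc + (k * n - k - n) * mse) + n * msr),
      n * (f2 * msr - mse) /
        (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    )
    tag <- "twoway-random,absolute-agreement,single-measures"
  }
  structure(
    list(icc = icc, ci_low = min(ci[1], icc), ci_high = min(ci[2], 1),
         conf_level = conf_level, model_tag = tag, n = n),
    class = "pp_icc"
  )
}

#' @export
print.pp_icc <- function(x, digits = 3, ...) {
  cat(sprintf("ICC = %.*f (%d%% CI %.*f-%.*f) [%s, n = %d]\n",
              digits, x$icc, round(100 * x$conf_level), digits, x$ci_low,
              digits, x$ci_high, x$model_tag, x$n))
  invisible(x)
}

#' Reconstruct an integer 2x2 table from rounded published metrics
#'
#' Exhaustive search over the reference-positive count `P` in
#' `[1, n - 1]`: for each `P` the candidate table is `tp = round(Se * P)`,
#' `fn = P - tp`, `tn = round(Sp * (n - P))`, `fp = (n - P) - tn`, and the
#' table whose implied four metrics have the smallest summed squared
#' deviation from the printed values wins (ties broken by smaller `P`).
#'
#' @param sensitivity,specificity,ppv,npv printed metrics as proportions
#'   in (0, 1) (or exactly 1 for a perfect table).
#' @param n total sample size, >= 2.
#' @param tolerance maximum absolute deviation allowed per metric for the
#'   winning table; beyond it the reconstruction fails. Default 0.005,
#'   half a percentage point, i.e. the rounding slack of metrics printed
#'   to one decimal in percent.
#' @return a `pp_confusion` with attributes `"P"` (reference positives)
#'   and `"deviation"` (summed squared deviation).
#' @examples
#' tab <- reconstruct_confusion(0.784, 0.878, 0.781, 0.880, n = 1518)
#' unclass(tab)[c("tp", "fp", "fn", "tn")]
#' @export
reconstruct_confusion <- function(sensitivity, specificity, ppv, npv, n,
                                  tolerance = 0.005) {
  stopifnot(n >= 2)
  target <- c(sensitivity, specificity, ppv, npv)
  stopifnot(all(target > 0), all(target <= 1))
  P <- seq_len(n - 1)
  tp <- round(sensitivity * P)
  fn <- P - tp
  tn <- round(specificity * (n - P))
  fp <- (n - P) - tn
  se_i <- tp / P
  sp_i <- tn / (n - P)
  ppv_i <- ifelse(tp + fp > 0, tp / (tp + fp), NA_real_)
  npv_i <- ifelse(tn + fn > 0, tn / (tn + fn), NA_real_)
  dev <- (se_i - target[1])^2 + (sp_i - target[2])^2 +
    (ppv_i - target[3])^2 + (npv_i - target[4])^2
  dev[is.na(dev)] <- Inf
  best <- which.min(dev)  # ties: which.min takes the first, i.e. smaller P
  max_abs <- max(abs(c(se_i[best] - target[1], sp_i[best] - target[2],
                       ppv_i[best] - target[3], npv_i[best] - target[4])))
  if (!is.finite(dev[best]) || max_abs > tolerance)
    stop("reconstruction failed: no integer table reproduces the printed ",
         "metrics within tolerance ", tolerance, call. = FALSE)
  out <- new_confusion(tp[best], fp[best], fn[best], tn[best])
  attr(out, "P") <- best
  attr(out, "deviation") <- dev[best]
  out
}

#' Sample size for estimating kappa with a given precision
#'
#' Builds the unique 2x2 probability table with the stated positive
#' marginals and kappa, computes the Fleiss-Cohen-Everitt large-sample
#' variance of the kappa estimator, and returns
#' `ceiling(z^2 * unit_variance / precision^2)` — the number of subjects
#' for which the two-sided confidence interval at `conf_level` has the
#' requested half-width.
#'
#' @param kappa0 anticipated kappa.
#' @param p1,p2 anticipated positive proportions of the two raters
#'   (clinician and automated method), each in (0, 1).
#' @param conf_level two-sided confidence level (e.g. 0.99).
#' @param precision confidence-interval half-width, > 0.
#' @return integer sample size.
#' @examples
#' kappa_sample_size(0.7, 0.40, 0.50, conf_level = 0.99, precision = 0.05)
#' # 1300
#' @export
kappa_sample_size <- function(kappa0, p1, p2, conf_level = 0.95,
                              precision = 0.05) {
  stopifnot(p1 > 0, p1 < 1, p2 > 0, p2 < 1, precision > 0,
            kappa0 >= -1, kappa0 <= 1, conf_level > 0, conf_level < 1)
  pe <- p1 * p2 + (1 - p1) * (1 - p2)
  po <- pe + kappa0 * (1 - pe)
  # po = p11 + p22, p11 - p22 = p1 + p2 - 1 fixes both diagonal cells
  p11 <- (po + p1 + p2 - 1) / 2
  p22 <- po - p11
  p12 <- p1 - p11
  p21 <- p2 - p11
  cells <- c(p11, p12, p21, p22)
  if (any(cells < -1e-12) || any(cells > 1 + 1e-12))
    stop("infeasible parameters: implied cell probability outside [0, 1]",
         call. = FALSE)
  unit_var <- fce_unit_variance(p11, p12, p21, p22)
  z <- z_quantile(conf_level)
  n <- ceiling(z^2 * unit_var / precision^2)
  max(1L, as.integer(n))
}

#' Per-category concordance between clinical consensus and automated call
#'
#' One row per category (A-H) and per subcategory, each cross-classifying
#' presence/absence by the two methods and reporting Cohen's kappa with
#' its CI and p-value plus the observed agreement with a Wilson interval —
#' the layout of a per-category concordance table. A category absent in
#' both sources everywhere yields an `NA` kappa row (reported, not
#' dropped).
#'
#' @param consensus_categories character vector (one per episode) of
#'   semicolon-joined consensus category letters, or list of character
#'   vectors.
#' @param profiles list of `pp_profile` objects (e.g.
#'   `attr(pp_classify(...), "profiles")`), same episode order.
#' @param catalog the `pp_catalog` defining ids; default shipped catalog.
#' @param conf_level two-sided confidence level.
#' @return data.frame with columns `id`, `level` (category/subcategory),
#'   `kappa`, `kappa_ci_low`, `kappa_ci_high`, `p_value`, `agreement`,
#'   `agreement_ci_low`, `agreement_ci_high`.
#' @export
per_category_concordance <- function(consensus_categories, profiles,
                                     catalog = default_pp_catalog(),
                                     conf_level = 0.95) {
  cons <- parse_category_sets(consensus_categories)
  stopifnot(length(cons) == length(profiles))
  subs <- catalog_subcategories(catalog)

  rows <- list()
  add_row <- function(id, level, ref, test) {
    tab <- confusion_table(test, ref)
    agr <- agreement_proportion(tab, conf_level)
    kap <- tryCatch(cohen_kappa(tab, conf_level), error = function(e) NULL)
    rows[[length(rows) + 1L]] <<- data.frame(
      id = id, level = level,
      kappa = if (is.null(kap)) NA_real_ else kap$kappa,
      kappa_ci_low = if (is.null(kap)) NA_real_ else kap$ci_low,
      kappa_ci_high = if (is.null(kap)) NA_real_ else kap$ci_high,
      p_value = if (is.null(kap)) NA_real_ else kap$p_value,
      agreement = agr$estimate,
      agreement_ci_low = agr$ci_low,
      agreement_ci_high = agr$ci_high,
      stringsAsFactors = FALSE
    )
  }

  for (cc in catalog$categories) {
    multi <- length(cc$subcategories) > 1L
    if (multi) {
      for (sub in cc$subcategories) {
        test <- vapply(profiles, function(p)
          sub$id %in% p$matched_subcategories, logical(1))
        # consensus raters label categories, not subcategories: a
        # subcategory row uses the parent category's consensus flag
        ref <- vapply(cons, function(s)
          !all(is.na(s)) && cc$id %in% s, logical(1))
        add_row(sub$id, "subcategory", ref, test)
      }
    }
    test <- vapply(profiles, function(p)
      cc$id %in% p$matched_categories, logical(1))
    ref <- vapply(cons, function(s) !all(is.na(s)) && cc$id %in% s,
                  logical(1))
    add_row(cc$id, "category", ref, test)
  }
  do.call(rbind, rows)
}
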