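test_that("confusion table cross-tabulates test against reference", {
  tab <- confusion_table(c(1, 1, 0), c(1, 0, 0))
  expect_equal(unclass(tab)[c("tp", "fp", "fn", "tn")],
               list(tp = 1L, fp = 1L, fn = 0L, tn = 1L))

  same <- confusion_table(c(TRUE, FALSE, TRUE), c(TRUE, FALSE, TRUE))
  expect_equal(same$fp + same$fn, 0L)

  opp <- confusion_table(c(TRUE, FALSE), c(FALSE, TRUE))
  expect_equal(opp$tp + opp$tn, 0L)

  expect_error(confusion_table(c(TRUE, TRUE), TRUE), "equal length")
  expect_error(confusion_table(logical(0), logical(0)), "empty")
  expect_error(confusion_table(c(TRUE, NA), c(TRUE, TRUE)), "missing")
})

test_that("kappa hits its anchor points and basic identities", {
  perfect <- ppdetect:::new_confusion(30, 0, 0, 70)
  expect_equal(cohen_kappa(perfect)$kappa, 1)

  # cells proportional to marginal products: chance-level agreement
  indep <- ppdetect:::new_confusion(20, 20, 30, 30)
  expect_equal(cohen_kappa(indep)$kappa, 0)

  # kappa <= po, and label swap leaves kappa unchanged
  set.seed(7)
  for (i in 1:20) {
    cells <- as.vector(stats::rmultinom(1, 150, runif(4, 0.05, 1)))
    tab <- ppdetect:::new_confusion(cells[1], cells[2], cells[3], cells[4])
    swap <- ppdetect:::new_confusion(cells[4], cells[3], cells[2], cells[1])
    k <- cohen_kappa(tab)
    expect_lte(k$kappa, k$po + 1e-12)
    expect_equal(cohen_kappa(swap)$kappa, k$kappa)
    expect_true(k$ci_low <= k$kappa && k$kappa <= k$ci_high)
    expect_equal(k$kappa == 1, tab$fp + tab$fn == 0)
  }

  degenerate <- ppdetect:::new_confusion(10, 0, 0, 0)
  expect_error(cohen_kappa(degenerate), "undefined")
})

test_that("kappa p-value and interval agree with a permutation oracle", {
  set.seed(11)
  cases <- list(
    list(n = 120, p_test = 0.4, p_ref = 0.45, assoc = 0.30),
    list(n = 200, p_test = 0.5, p_ref = 0.5, assoc = 0.15),
    list(n = 150, p_test = 0.3, p_ref = 0.6, assoc = 0.00)
  )
  for (cs in cases) {
    ref <- runif(cs$n) < cs$p_ref
    flip <- runif(cs$n) < cs$assoc
    test <- ifelse(flip, ref, runif(cs$n) < cs$p_test)
    tab <- confusion_table(test, ref)
    k <- cohen_kappa(tab)

    perm_k <- replicate(4000, naive_kappa(test, sample(ref)))
    p_perm <- mean(abs(perm_k) >= abs(k$kappa) - 1e-12)
    # asymptotic two-sided p within Monte-Carlo error of the permutation p
    expect_lt(abs(k$p_value - p_perm),
              0.03 + 3 * sqrt(p_perm * (1 - p_perm) / 4000))

    # permutation spread matches the null SE used for the p-value
    pe <- mean(test) * mean(ref) + mean(!test) * mean(!ref)
    pr <- c(mean(test), 1 - mean(test))
    pc <- c(mean(ref), 1 - mean(ref))
    se0 <- sqrt((pe + pe^2 - sum(pr * pc * (pr + pc))) /
                  (cs$n * (1 - pe)^2))
    expect_lt(abs(sd(perm_k) - se0) / se0, 0.10)
  }
})

test_that("asymptotic and Fleiss-Cohen-Everitt kappa intervals both cover the estimate", {
  tab <- ppdetect:::new_confusion(425, 119, 117, 857)
  k1 <- cohen_kappa(tab, se_method = "asymptotic")
  k2 <- cohen_kappa(tab, se_method = "fce")
  expect_equal(k1$kappa, k2$kappa)
  for (k in list(k1, k2)) {
    expect_true(k$ci_low <= k$kappa && k$kappa <= k$ci_high)
    expect_true(k$ci_low >= -1 && k$ci_high <= 1)
  }
  expect_false(identical(k1$se_kappa, k2$se_kappa))
})

test_that("agreement proportion uses a Wilson interval inside [0, 1]", {
  perfect <- ppdetect:::new_confusion(4, 0, 0, 6)
  expect_equal(agreement_proportion(perfect)$estimate, 1)
  none <- ppdetect:::new_confusion(0, 5, 5, 0)
  expect_equal(agreement_proportion(none)$estimate, 0)

  for (cells in list(c(1, 0, 0, 1), c(50, 3, 2, 45), c(0, 9, 1, 0),
                     c(2, 2, 2, 2))) {
    tab <- ppdetect:::new_confusion(cells[1], cells[2], cells[3], cells[4])
    a <- agreement_proportion(tab)
    expect_true(a$ci_low >= 0 && a$ci_high <= 1)
    expect_true(a$ci_low <= a$estimate && a$estimate <= a$ci_high)
    w <- agreement_proportion(tab, method = "wald")
    expect_true(w$ci_low <= a$estimate && w$ci_high >= a$estimate)
  }
})

test_that("diagnostic metrics honour their definitions and undefined cells", {
  perfect <- ppdetect:::new_confusion(12, 0, 0, 28)
  m <- diagnostic_metrics(perfect)
  for (nm in c("sensitivity", "specificity", "ppv", "npv", "accuracy"))
    expect_equal(m[[nm]]$estimate, 1)

  blind <- ppdetect:::new_confusion(0, 0, 10, 30)
  m <- diagnostic_metrics(blind)
  expect_equal(m$sensitivity$estimate, 0)
  expect_true(m$ppv$undefined)         # tp + fp = 0: undefined, not zero
  expect_true(is.na(m$ppv$estimate))

  tab <- ppdetect:::new_confusion(425, 119, 117, 857)
  m <- diagnostic_metrics(tab)
  expect_equal(m$sensitivity$estimate, 425 / 542)
  expect_equal(m$specificity$estimate, 857 / 976)
  expect_equal(m$accuracy$estimate, (425 + 857) / 1518)
})

test_that("one-way ICC matches the ANOVA oracle and its anchor cases", {
  # identical columns with variance: perfect agreement
  icc <- icc_category_counts(c(0, 1, 2, 3, 4), c(0, 1, 2, 3, 4))
  expect_equal(icc$icc, 1)

  # alternating opposite pairs: MSB = 0, MSW = 8, ICC = -1 (closed form)
  icc <- icc_category_counts(c(0, 4, 0, 4), c(4, 0, 4, 0))
  expect_equal(icc$icc, -1)

  # constant shift is penalized by absolute agreement
  icc <- icc_category_counts(c(0, 1, 2, 3, 4, 5), c(2, 3, 4, 5, 6, 7))
  expect_lt(icc$icc, 1)

  # oracle: one-way random ICC recomputed from stats::aov mean squares
  set.seed(31)
  for (i in 1:5) {
    a <- rpois(40, 3)
    b <- pmax(0, a + sample(c(-1, 0, 0, 1), 40, replace = TRUE))
    long <- data.frame(y = c(a, b), subj = factor(rep(1:40, 2)))
    ms <- anova(stats::aov(y ~ subj, data = long))
    msb <- ms["subj", "Mean Sq"]
    msw <- ms["Residuals", "Mean Sq"]
    want <- (msb - msw) / (msb + msw)
    expect_equal(icc_category_counts(a, b)$icc, want)
  }

  expect_error(icc_category_counts(c(2, 2), c(2, 2)), "zero total variance")
  tw <- icc_category_counts(c(0, 1, 2, 3, 4, 5), c(2, 3, 4, 5, 6, 7),
                            model = "twoway")
  expect_lte(tw$icc, 1)
  expect_match(tw$model_tag, "twoway")
})

test_that("confusion reconstruction recovers tables from printed metrics", {
  tab <- reconstruct_confusion(0.784, 0.878, 0.781, 0.880, n = 1518)
  expect_true(attr(tab, "P") %in% c(541, 542))
  acc <- (tab$tp + tab$tn) / tab$n
  expect_equal(round(100 * acc, 1), 84.5)

  perfect <- reconstruct_confusion(1, 1, 1, 1, n = 10)
  expect_equal(perfect$fp + perfect$fn, 0L)
  expect_equal(attr(perfect, "P"), 1L)   # tie broken at the smallest P

  expect_error(reconstruct_confusion(0.99, 0.99, 0.01, 0.99, n = 100),
               "reconstruction failed")
})

test_that("kappa precision sample size reproduces its anchor and scaling", {
  expect_identical(
    kappa_sample_size(0.7, 0.40, 0.50, conf_level = 0.99,
                      precision = 0.05),
    1300L)

  n1 <- kappa_sample_size(0.6, 0.35, 0.45, conf_level = 0.95,
                          precision = 0.05)
  n2 <- kappa_sample_size(0.6, 0.35, 0.45, conf_level = 0.95,
                          precision = 0.025)
  expect_gt(n2 / n1, 3.9)
  expect_lt(n2 / n1, 4.1)

  # perfect-agreement edge: zero variance, minimal n
  expect_identical(kappa_sample_size(1, 0.5, 0.5, 0.99, 0.05), 1L)

  expect_error(kappa_sample_size(-0.9, 0.9, 0.9, 0.95, 0.05), "infeasible")
})

test_that("kappa unit variance matches the empirical variance of simulated tables", {
  probs <- c(0.375, 0.125, 0.025, 0.475)  # column-major: tp, fn, fp, tn
  unit <- ppdetect:::fce_unit_variance(0.375, 0.025, 0.125, 0.475)
  set.seed(97)
  n <- 2000
  draws <- stats::rmultinom(10000, n, probs)
  tp <- draws[1, ]; fn <- draws[2, ]; fp <- draws[3, ]; tn <- draws[4, ]
  po <- (tp + tn) / n
  pt <- (tp + fp) / n
  pr <- (tp + fn) / n
  pe <- pt * pr + (1 - pt) * (1 - pr)
  kap <- (po - pe) / (1 - pe)
  expect_lt(abs(n * var(kap) - unit) / unit, 0.05)
})

test_that("per-category concordance reports every catalog row", {
  cohort <- pp_generate_cohort(pp_sim_config(n_episodes = 400, seed = 5))
  v <- pp_validation(cohort$episodes)
  bc <- v$by_category
  expect_equal(nrow(bc), 21L)
  expect_equal(sum(bc$level == "category"), 8L)
  expect_equal(sum(bc$level == "subcategory"), 13L)
  ok <- !is.na(bc$kappa)
  expect_true(all(bc$kappa[ok] <= 1 & bc$kappa[ok] >= -1))
  expect_true(all(bc$agreement_ci_low >= 0 & bc$agreement_ci_high <= 1))

  # identical sources: kappa 1 on every category present
  profiles <- attr(v$calls, "profiles")
  self_cats <- vapply(profiles, function(p)
    paste(p$matched_categories, collapse = ";"), character(1))
  self <- per_category_concordance(self_cats, profiles)
  present <- self$level == "category" & !is.na(self$kappa)
  expect_true(all(abs(self$kappa[present] - 1) < 1e-12))

  # flags independent of consensus: kappa near zero
  set.seed(17)
  n <- 5000
  fake_profiles <- lapply(runif(n) < 0.3, function(hit) {
    structure(list(matched_subcategories = if (hit) "A.1" else character(),
                   matched_categories = if (hit) "A" else character(),
                   triggering_codes = list(), n_categories = as.integer(hit),
                   pp_with_h = FALSE, pp_without_h = FALSE,
                   invalid_codes = character()), class = "pp_profile")
  })
  cons <- ifelse(runif(n) < 0.4, "A", "")
  indep <- per_category_concordance(cons, fake_profiles)
  expect_lt(abs(indep$kappa[indep$id == "A"]), 0.05)

  # a category absent everywhere in both sources is reported, not dropped
  empty_profiles <- fake_profiles[1:10]
  row_d <- per_category_concordance(rep("", 10), empty_profiles)
  expect_true("D" %in% row_d$id)
  expect_true(is.na(row_d$kappa[row_d$id == "D"]))
})
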