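noiseless_config <- function(n, seed) {
  pp_sim_config(
    n_episodes = n, seed = seed,
    coding_sensitivity = stats::setNames(rep(1, 8), LETTERS[1:8]),
    coding_false_rate = stats::setNames(rep(0, 8), LETTERS[1:8]),
    rater_sensitivity = rep(1, 3), rater_specificity = rep(1, 3))
}

test_that("cohorts are a pure function of their configuration", {
  a <- pp_generate_cohort(pp_sim_config(n_episodes = 80, seed = 123))
  b <- pp_generate_cohort(pp_sim_config(n_episodes = 80, seed = 123))
  expect_identical(a$episodes, b$episodes)
  expect_identical(a$truth, b$truth)
  c <- pp_generate_cohort(pp_sim_config(n_episodes = 80, seed = 124))
  expect_false(identical(a$episodes$codes, c$episodes$codes))
})

test_that("the noiseless limit gives perfect concordance and validity", {
  coh <- pp_generate_cohort(noiseless_config(400, 2))
  v <- pp_validation(coh$episodes)
  expect_equal(v$kappa$kappa, 1)
  expect_equal(v$agreement$estimate, 1)

  rec <- recover_operating_characteristics(coh)
  expect_equal(rec$metrics$sensitivity$estimate, 1)
  expect_equal(rec$metrics$specificity$estimate, 1)
})

test_that("default cohort reproduces the target study conditions", {
  coh <- pp_generate_cohort(pp_sim_config(n_episodes = 1518, seed = 20260930))
  dx <- lengths(strsplit(coh$episodes$codes, ";", fixed = TRUE))
  expect_equal(unname(stats::median(dx)), 9)
  q <- unname(stats::quantile(dx, c(0.25, 0.75)))
  expect_lte(abs(q[1] - 6), 1)
  expect_lte(abs(q[2] - 12), 1)

  cons <- consensus_labels(coh$episodes)
  clinical_pp <- mean(cons$consensus_pp, na.rm = TRUE)
  expect_lt(abs(clinical_pp - 0.35), 0.03)

  expect_lt(abs(stats::median(coh$episodes$age) - 71), 4)
  expect_lt(abs(mean(coh$episodes$sex == "male") - 0.561), 0.05)
})

test_that("every generated catalog code matches its intended category", {
  pools <- ppdetect:::subcategory_code_pools(default_pp_catalog())
  subs <- ppdetect:::catalog_subcategories(default_pp_catalog())
  for (id in names(pools)) {
    hit <- rep(FALSE, length(pools[[id]]))
    for (pat in subs[[id]]$patterns)
      hit <- hit | icd9_matches(pools[[id]], pat)
    expect_true(all(hit))
    # and classification routes each pool code back to its category
    for (code in pools[[id]][seq(1, length(pools[[id]]), by = 25)])
      expect_true(subs[[id]]$category %in%
                    pp_assign(code)$matched_categories)
  }
})

test_that("noise padding never touches catalog categories", {
  noise <- ppdetect:::noise_code_pool(default_pp_catalog(), 200L)
  for (code in noise)
    expect_equal(pp_assign(code)$n_categories, 0L)
})

test_that("episode-level sensitivity follows the binomial composition of coding errors", {
  cfg <- pp_sim_config(
    n_episodes = 20000, seed = 8,
    coding_sensitivity = stats::setNames(rep(0.9, 8), LETTERS[1:8]),
    coding_false_rate = stats::setNames(rep(0, 8), LETTERS[1:8]))
  coh <- pp_generate_cohort(cfg)
  rec <- recover_operating_characteristics(coh)

  # closed form: given k true categories, detection is Binomial(k, 0.9) >= 2;
  # average over the truth-count distribution conditional on k >= 2
  prev <- cfg$category_prevalence
  pmf <- 1
  for (p in prev) pmf <- convolve(pmf, rev(c(1 - p, p)), type = "open")
  k <- 0:8
  p_detect <- 1 - stats::pbinom(1, k, 0.9)
  se_expected <- sum(pmf[k >= 2] * p_detect[k >= 2]) / sum(pmf[k >= 2])

  n_pos <- rec$table$tp + rec$table$fn
  mc <- 3 * sqrt(se_expected * (1 - se_expected) / n_pos)
  expect_lt(abs(rec$metrics$sensitivity$estimate - se_expected), mc + 0.005)
  # false-coding rate zero: specificity only dented by double coding noise
  expect_equal(rec$metrics$specificity$estimate, 1)
})

test_that("degrading the coding sensitivity degrades detector sensitivity", {
  se_at <- function(cs) {
    cfg <- pp_sim_config(
      n_episodes = 4000, seed = 77,
      coding_sensitivity = stats::setNames(rep(cs, 8), LETTERS[1:8]),
      coding_false_rate = stats::setNames(rep(0, 8), LETTERS[1:8]))
    rec <- recover_operating_characteristics(pp_generate_cohort(cfg))
    rec$metrics$sensitivity$estimate
  }
  expect_gt(se_at(0.9), se_at(0.6) + 0.05)
})

test_that("shuffled code assignments drop the detector to chance", {
  coh <- pp_generate_cohort(pp_sim_config(n_episodes = 5000, seed = 13))
  eps <- coh$episodes
  set.seed(14)
  eps$codes <- sample(eps$codes)
  calls <- pp_classify(eps)
  k <- naive_kappa(calls$pp, coh$truth$true_pp)
  expect_lt(abs(k), 0.05)
})

test_that("kappa against consensus is continuous in rater error", {
  # independent raters: consensus carries no signal, kappa near zero
  coh <- pp_generate_cohort(pp_sim_config(n_episodes = 5000, seed = 19))
  eps <- coh$episodes
  set.seed(21)
  for (r in 1:3) eps[[paste0("rater", r, "_pp")]] <-
    as.integer(runif(nrow(eps)) < 0.4)
  v <- pp_validation(eps)
  expect_lt(abs(v$kappa$kappa), 0.05)
})
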