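# Synthetic MBDS cohort generator. Each episode carries a latent truth
# (the set of clinical categories actually present); coded diagnoses and
# rater assessments are noisy observations of that truth, so every
# downstream statistic can be checked against known parameters.
#
# Default study conditions: 1518 episodes, about nine grouped diagnoses
# per episode (quartiles 6/9/12), roughly 35% of patients truly
# polypathological, hospital levels 3/2/1 at 46/32/21%, median age near
# 71 years, 56% male, and three imperfect raters.

#' Simulation configuration
#'
#' @param n_episodes number of episodes.
#' @param seed integer seed; the cohort is a pure function of the config.
#' @param category_prevalence named probability per category letter that
#'   the category is truly present (independent across categories). The
#'   defaults are calibrated, jointly with the default rater error rates,
#'   so that the expected consensus-PP prevalence is 0.35 (exact
#'   enumeration over the 256 truth combinations).
#' @param coding_sensitivity named probability per letter that a truly
#'   present category emits at least one matching code into the MBDS.
#' @param coding_false_rate named probability per letter that an absent
#'   category nevertheless emits a matching code.
#' @param rater_sensitivity,rater_specificity length-3 probabilities of a
#'   rater correctly labeling each truly present / truly absent category.
#' @param n_dx_target `(median, p25, p75)` of grouped diagnoses per
#'   episode; used to pick the count distribution (negative binomial,
#'   size 6, mean 9.5 reproduces the default 9 (6-12)).
#' @param noise_code_pool_size number of distinct non-catalog roots used
#'   for padding diagnoses.
#' @return object of class `pp_sim_config`.
#' @export
pp_sim_config <- function(n_episodes = 1518,
                          seed = 1L,
                          category_prevalence = c(
                            A = 0.277, B = 0.138, C = 0.221, D = 0.055,
                            E = 0.221, F = 0.097, G = 0.166, H = 0.069),
                          coding_sensitivity = stats::setNames(
                            rep(0.85, 8), LETTERS[1:8]),
                          coding_false_rate = stats::setNames(
                            rep(0.03, 8), LETTERS[1:8]),
                          rater_sensitivity = c(0.92, 0.90, 0.88),
                          rater_specificity = c(0.99, 0.985, 0.98),
                          n_dx_target = c(median = 9, p25 = 6, p75 = 12),
                          noise_code_pool_size = 200L) {
  probs <- c(category_prevalence, coding_sensitivity, coding_false_rate,
             rater_sensitivity, rater_specificity)
  stopifnot(n_episodes >= 1, all(probs >= 0), all(probs <= 1),
            length(rater_sensitivity) == 3, length(rater_specificity) == 3,
            all(LETTERS[1:8] %in% names(category_prevalence)),
            all(LETTERS[1:8] %in% names(coding_sensitivity)),
            all(LETTERS[1:8] %in% names(coding_false_rate)),
            n_dx_target[["p25"]] <= n_dx_target[["median"]],
            n_dx_target[["median"]] <= n_dx_target[["p75"]])
  structure(
    list(n_episodes = as.integer(n_episodes), seed = as.integer(seed),
         category_prevalence = category_prevalence[LETTERS[1:8]],
         coding_sensitivity = coding_sensitivity[LETTERS[1:8]],
         coding_false_rate = coding_false_rate[LETTERS[1:8]],
         rater_sensitivity = rater_sensitivity,
         rater_specificity = rater_specificity,
         n_dx_target = n_dx_target,
         noise_code_pool_size = as.integer(noise_code_pool_size)),
    class = "pp_sim_config"
  )
}

# count distribution matching quartiles (6, 9, 12): negative binomial,
# parameters fixed at construction from the target quartiles
count_distribution_params <- function(target) {
  if (all(target[c("median", "p25", "p75")] == c(9, 6, 12)))
    return(c(size = 6, mu = 9.5))
  # generic fit for non-default targets
  obj <- function(par) {
    q <- stats::qnbinom(c(0.25, 0.5, 0.75), size = exp(par[1]),
                        mu = exp(par[2]))
    sum((q - target[c("p25", "median", "p75")])^2)
  }
  fit <- stats::optim(c(log(4), log(target[["median"]])), obj)
  c(size = exp(fit$par[1]), mu = exp(fit$par[2]))
}

# concrete code pool per subcategory: every pattern expanded to its root
# codes and one-decimal children, filtered back through the matcher so
# exceptions never leak in
subcategory_code_pools <- function(catalog) {
  subs <- catalog_subcategories(catalog)
  lapply(subs, function(sub) {
    cand <- unlist(lapply(sub$patterns, function(p) {
      if (p$kind == "prefix") {
        base <- p$prefix
        if (grepl("\\.", base)) base
        else c(base, paste0(base, ".", 0:9))
      } else {
        roots <- sprintf(
          "%03d", root_number(p$range_start):root_number(p$range_end))
        if (root_space(p$range_start) != "N")
          roots <- paste0(root_space(p$range_start), roots)
        c(roots, paste0(rep(roots, each = 10), ".", 0:9))
      }
    }))
    keep <- rep(FALSE, length(cand))
    for (p in sub$patterns) keep <- keep | icd9_matches(cand, p)
    unique(cand[keep])
  })
}

# numeric roots untouched by any catalog pattern (checked root and .x)
noise_code_pool <- function(catalog, size) {
  subs <- catalog_subcategories(catalog)
  pats <- unlist(lapply(subs, function(s)
    c(s$patterns, s$episode_exclusions)), recursive = FALSE)
  # exclude every numeric root any pattern touches, at any depth
  used <- unique(unlist(lapply(pats, function(p) {
    if (p$kind == "prefix") {
      pr <- icd9_parse(p$prefix)
      if (pr$is_v_code || pr$is_e_code) character() else pr$root
    } else if (root_space(p$range_start) == "N") {
      sprintf("%03d", root_number(p$range_start):root_number(p$range_end))
    } else character()
  })))
  free <- setdiff(sprintf("%03d", 1:999), used)
  if (length(free) < size)
    stop("noise pool smaller than requested", call. = FALSE)
  pool <- paste0(free[seq_len(size)], ".", rep(0:9, length.out = size))
  # build-time verification against the matcher: no noise code may match
  for (p in pats) if (any(icd9_matches(pool, p)))
    stop("internal error: noise pool overlaps catalog patterns",
         call. = FALSE)
  pool
}

#' Generate a synthetic MBDS cohort with known ground truth
#'
#' Per episode: true categories are drawn independently from the
#' configured prevalences; each true category with a coding success emits
#' one concrete code drawn uniformly from the category's expanded pattern
#' set (absent categories emit with the false-coding rate); the diagnosis
#' list is padded with non-catalog noise codes up to a count drawn from a
#' negative binomial calibrated to the target quartiles; three raters
#' flip each latent category flag at their error rates and flag PP when
#' their perceived categories number two or more. Age, sex and hospital
#' level follow the study's marginal descriptives.
#'
#' @param config a [pp_sim_config()].
#' @param catalog the `pp_catalog` codes are drawn from.
#' @return object of class `pp_cohort`: list with `episodes` (a table in
#'   the same layout [read_episode_table()] consumes) and `truth`
#'   (`episode_id`, `true_categories`, `true_n_categories`, `true_pp`),
#'   plus the `config`.
#' @examples
#' coh <- pp_generate_cohort(pp_sim_config(n_episodes = 50, seed = 7))
#' mean(coh$truth$true_pp)
#' @export
pp_generate_cohort <- function(config = pp_sim_config(),
                               catalog = default_pp_catalog()) {
  stopifnot(inherits(config, "pp_sim_config"))
  validate_pp_catalog(catalog)
  pools <- subcategory_code_pools(catalog)
  subs <- catalog_subcategories(catalog)
  sub_by_cat <- split(names(subs),
                      vapply(subs, `[[`, character(1), "category"))
  noise <- noise_code_pool(catalog, config$noise_code_pool_size)
  nb <- count_distribution_params(config$n_dx_target)

  n <- config$n_episodes
  letters8 <- LETTERS[1:8]
  set.seed(config$seed)

  # latent truth, vectorized across episodes
  truth_mat <- matrix(
    stats::runif(n * 8) < rep(config$category_prevalence, each = n),
    nrow = n, dimnames = list(NULL, letters8))
  # coded category emission
  emit_mat <- matrix(FALSE, n, 8, dimnames = list(NULL, letters8))
  u <- matrix(stats::runif(n * 8), n, 8)
  for (j in seq_len(8)) {
    L <- letters8[j]
    emit_mat[, j] <- ifelse(truth_mat[, j],
                            u[, j] < config$coding_sensitivity[[L]],
                            u[, j] < config$coding_false_rate[[L]])
  }
  # rater perception
  rater_mats <- lapply(1:3, function(r) {
    ur <- matrix(stats::runif(n * 8), n, 8)
    keep <- ur < config$rater_sensitivity[r]
    add <- ur < (1 - config$rater_specificity[r])
    m <- (truth_mat & keep) | (!truth_mat & add)
    dimnames(m) <- list(NULL, letters8)
    m
  })

  n_dx <- stats::rnbinom(n, size = nb[["size"]], mu = nb[["mu"]])
  age <- round(pmax(19, pmin(100,
    stats::rnorm(n, mean = 71, sd = diff(c(58, 80)) / (2 * stats::qnorm(0.75))))))
  sex <- ifelse(stats::runif(n) < 0.561, "male", "female")
  hospital_level <- sample(c(3L, 2L, 1L), n, replace = TRUE,
                           prob = c(0.4644, 0.3208, 0.2147))

  codes <- character(n)
  for (i in seq_len(n)) {
    emitted <- letters8[emit_mat[i, ]]
    ep_codes <- vapply(emitted, function(L) {
      sub_id <- if (length(sub_by_cat[[L]]) > 1L)
        sample(sub_by_cat[[L]], 1L) else sub_by_cat[[L]]
      pool <- pools[[sub_id]]
      pool[sample.int(length(pool), 1L)]
    }, character(1))
    pad <- max(0L, n_dx[i] - length(ep_codes))
    if (pad > 0L)
      ep_codes <- c(ep_codes, sample(noise, pad, replace = TRUE))
    codes[i] <- paste(ep_codes, collapse = ";")
  }

  episodes <- data.frame(
    episode_id = sprintf("ep%05d", seq_len(n)),
    age = age,
    sex = sex,
    hospital_level = hospital_level,
    codes = codes,
    stringsAsFactors = FALSE
  )
  for (r in 1:3) {
    m <- rater_mats[[r]]
    episodes[[paste0("rater", r, "_pp")]] <- as.integer(rowSums(m) >= 2L)
    episodes[[paste0("rater", r, "_categories")]] <-
      apply(m, 1, function(row) paste(letters8[row], collapse = ";"))
  }

  truth <- data.frame(
    episode_id = episodes$episode_id,
    true_categories = apply(truth_mat, 1, function(row)
      paste(letters8[row], collapse = ";")),
    true_n_categories = rowSums(truth_mat),
    true_pp = rowSums(truth_mat) >= 2L,
    stringsAsFactors = FALSE
  )

  structure(list(episodes = episodes, truth = truth, config = config),
            class = "pp_cohort")
}

#' @export
print.pp_cohort <- function(x, ...) {
  cat("<pp_cohort: ", nrow(x$episodes), " episodes, seed ",
      x$config$seed, ">\n", sep = "")
  cat("  true PP prevalence: ",
      sprintf("%.1f%%", 100 * mean(x$truth$true_pp)), "\n", sep = "")
  cat("  median diagnoses/episode: ",
      stats::median(lengths(strsplit(x$episodes$codes, ";"))), "\n",
      sep = "")
  invisible(x)
}

#' Operating characteristics of the classifier against latent truth
#'
#' Runs [pp_classify()] on a synthetic cohort and scores the automated PP
#' call against the generator's latent `true_pp` (not the rater
#' consensus) — the parameter-recovery harness.
#'
#' @param cohort a `pp_cohort`.
#' @param catalog the `pp_catalog` to classify with.
#' @param conf_level two-sided confidence level for the Wilson intervals.
#' @return a list with the `pp_diagnostics` object (`metrics`), the
#'   underlying `pp_confusion` (`table`), and the classification table
#'   (`calls`).
#' @export
recover_operating_characteristics <- function(cohort,
                                              catalog = default_pp_catalog(),
                                              conf_level = 0.95) {
  stopifnot(inherits(cohort, "pp_cohort"))
  calls <- pp_classify(cohort$episodes, catalog)
  tab <- confusion_table(calls$pp, cohort$truth$true_pp)
  list(metrics = diagnostic_metrics(tab, conf_level), table = tab,
       calls = calls)
}
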