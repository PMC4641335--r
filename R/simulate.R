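# Synthetic respondent cohorts: correlated latent traits, graded-threshold
# (ordinal probit) item responses, a criterion channel sharing the realised
# item latents, a PAM-13 channel driven by true barrier status, and
# item-level missingness. The truth channel is for tests only.

COHORT_TRAITS <- c("self_efficacy", "coping_P", "coping_E", "coping_D",
                   "depression", "anxiety", "locus", "social_support",
                   "burden")

# which latent trait drives each scored construct, and with what sign
construct_trait <- function(cid) {
  switch(cid,
         locus_internal = c(trait = "locus", sign = "1"),
         locus_external = c(trait = "locus", sign = "-1"),
         computer_skills = ,
         group_functioning = ,
         self_monitoring_willingness = c(trait = NA, sign = "1"),
         c(trait = cid, sign = "1"))
}

#' Default correlation structure of the latent traits
#'
#' Modest, plausible correlations: depression and anxiety strongly related;
#' self-efficacy negatively related to distress and positively to an
#' internal locus, problem-solving coping and support; burden loading with
#' distress. Verified positive definite.
#'
#' @return 9x9 correlation matrix over the scored trait dimensions.
#' @export
default_trait_corr <- function() {
  k <- length(COHORT_TRAITS)
  m <- diag(k)
  dimnames(m) <- list(COHORT_TRAITS, COHORT_TRAITS)
  set_r <- function(a, b, r) {
    m[a, b] <<- r
    m[b, a] <<- r
  }
  set_r("depression", "anxiety", 0.60)
  set_r("self_efficacy", "depression", -0.35)
  set_r("self_efficacy", "anxiety", -0.30)
  set_r("self_efficacy", "locus", 0.30)
  set_r("self_efficacy", "social_support", 0.20)
  set_r("self_efficacy", "coping_P", 0.30)
  set_r("self_efficacy", "burden", -0.25)
  set_r("burden", "depression", 0.35)
  set_r("burden", "anxiety", 0.30)
  set_r("coping_P", "coping_E", 0.20)
  set_r("coping_P", "coping_D", 0.20)
  set_r("coping_E", "coping_D", 0.30)
  set_r("social_support", "depression", -0.20)
  m
}

#' Build a cohort configuration
#'
#' Collects and validates every knob of the synthetic-cohort generator. The
#' defaults define the package's reference scenario: 204 respondents (the
#' validation-study cohort size), per-construct item discriminations giving
#' internal consistencies in the range the instrument reports, a criterion
#' channel with extra latent noise, PAM-13 generated from the published
#' regression coefficients (intercept 34.50; self-efficacy 16.43, social
#' support 6.64, locus 2.99, burden 3.51, anxiety 0.84, depression 0.04 PAM
#' points for barrier-free status), and low item-level missingness with a
#' higher rate on coping (the construct with most missing data in the
#' validation study).
#'
#' @param n cohort size.
#' @param seed integer seed; all channels derive substreams from it.
#' @param instrument a `semas_instrument` (default: the packaged one).
#' @param trait_corr trait correlation matrix (unit diagonal, positive
#'   semi-definite).
#' @param loadings named per-construct item discriminations (> 0).
#' @param offsets named per-construct threshold offsets (0 = equal marginal
#'   category probabilities); usually set by [calibrate_prevalence()].
#' @param criterion_noise_sd sd of the extra latent noise on the criterion
#'   channel (0 = criterion identical to the screener).
#' @param pam_coefficients named vector: `intercept` plus PAM points per
#'   barrier-free characteristic.
#' @param pam_noise_sd residual sd of the PAM channel.
#' @param missing_rate scalar or named per-construct item missingness
#'   probability in `[0, 1)`.
#' @param vas_scale latent-to-VAS slope for the burden item.
#' @param prevalence_targets optional named per-construct barrier
#'   prevalences for [calibrate_prevalence()].
#' @return a validated `semas_cohort_config` list.
#' @export
cohort_config <- function(n = 204, seed = 1L,
                          instrument = semas_instrument(),
                          trait_corr = default_trait_corr(),
                          loadings = NULL, offsets = NULL,
                          criterion_noise_sd = 0.6,
                          pam_coefficients = c(intercept = 34.50,
                                               self_efficacy = 16.43,
                                               social_support = 6.64,
                                               locus = 2.99,
                                               anxiety = 0.84,
                                               depression = 0.04,
                                               burden = 3.51),
                          pam_noise_sd = 12,
                          missing_rate = c(default = 0.01,
                                           coping_P = 0.06, coping_E = 0.06,
                                           coping_D = 0.06),
                          vas_scale = 1.5,
                          prevalence_targets = c(self_efficacy = 0.25,
                                                 depression = 0.12,
                                                 anxiety = 0.05,
                                                 social_support = 0.10)) {
  default_loadings <- c(self_efficacy = 1.6, coping_P = 1.3, coping_E = 1.3,
                        coping_D = 1.3, depression = 1.6, anxiety = 0.9,
                        locus_internal = 1.0, locus_external = 1.0,
                        social_support = 1.2, burden = 1.2,
                        computer_skills = 1.0, group_functioning = 1.0,
                        self_monitoring_willingness = 1.0)
  ld <- default_loadings
  if (!is.null(loadings)) ld[names(loadings)] <- loadings
  off <- stats::setNames(rep(0, length(instrument$constructs)),
                         names(instrument$constructs))
  if (!is.null(offsets)) off[names(offsets)] <- offsets

  if (!isTRUE(all.equal(trait_corr, t(trait_corr))) ||
      any(abs(diag(trait_corr) - 1) > 1e-12)) {
    stop("trait_corr must be symmetric with unit diagonal", call. = FALSE)
  }
  ev <- eigen(trait_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("trait_corr is not positive semi-definite (min eigenvalue ",
         signif(min(ev), 3), ")", call. = FALSE)
  }
  if (any(ld <= 0)) stop("loadings must be > 0", call. = FALSE)
  if (any(missing_rate < 0 | missing_rate >= 1)) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  stopifnot(criterion_noise_sd >= 0, pam_noise_sd >= 0, n >= 1)

  structure(list(n = as.integer(n), seed = as.integer(seed),
                 instrument = instrument, trait_corr = trait_corr,
                 loadings = ld, offsets = off,
                 criterion_noise_sd = criterion_noise_sd,
                 pam_coefficients = pam_coefficients,
                 pam_noise_sd = pam_noise_sd,
                 missing_rate = missing_rate, vas_scale = vas_scale,
                 prevalence_targets = prevalence_targets),
            class = "semas_cohort_config")
}

item_missing_rate <- function(config, construct) {
  mr <- config$missing_rate
  if (length(mr) == 1 && is.null(names(mr))) return(unname(mr))
  if (construct %in% names(mr)) unname(mr[construct])
  else if ("default" %in% names(mr)) unname(mr["default"])
  else 0
}

# ordered cutpoints for a k-level item: equal marginal probabilities at
# offset 0, scaled to the sd of the item latent
item_thresholds <- function(n_levels, loading, offset) {
  stats::qnorm(seq_len(n_levels - 1) / n_levels) * sqrt(loading^2 + 1) + offset
}

# draw the continuous latents and graded responses for one item
grade_item <- function(latent, scale_levels, thresholds) {
  scale_levels$code[findInterval(latent, thresholds) + 1L]
}

#' Simulate a synthetic respondent cohort
#'
#' Draws latent traits from a multivariate normal with the configured
#' correlation matrix, generates each screener item as the ordinal category
#' of `loading * trait + standard normal noise` against equal-probability
#' thresholds shifted by the construct offset (graded-threshold model; the
#' burden VAS maps its latent linearly to 0-10), generates criterion items
#' from the same realised item latents plus independent noise of
#' `criterion_noise_sd`, scores the complete responses to obtain the truth
#' barrier flags, generates PAM-13 as
#' `intercept + sum(coef * barrier-free) + noise` clamped to 0-100, and
#' finally applies independent item-level missingness to both response
#' channels. Fully reproducible: the single seed drives one substream per
#' channel, so e.g. changing the missingness rate does not change the traits.
#'
#' @param config a `semas_cohort_config` from [cohort_config()].
#' @return object of class `semas_cohort` with `semas_responses`,
#'   `criterion_responses`, `pam_scores` (respondent_id, pam), `truth`
#'   (traits, categories, barrier flags; never consumed by scoring), and the
#'   `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "semas_cohort_config"))
  instr <- config$instrument
  n <- config$n
  set.seed(config$seed)
  substream <- sample.int(.Machine$integer.max - 1L, 5)

  set.seed(substream[1])
  traits <- MASS::mvrnorm(n, mu = rep(0, ncol(config$trait_corr)),
                          Sigma = config$trait_corr)
  if (n == 1) traits <- matrix(traits, nrow = 1)
  colnames(traits) <- colnames(config$trait_corr)
  rid <- sprintf("R%04d", seq_len(n))

  items <- instr$items
  semas <- data.frame(respondent_id = rid, stringsAsFactors = FALSE)
  latents <- list()
  set.seed(substream[2])
  for (i in seq_len(nrow(items))) {
    cid <- items$construct[i]
    ct <- construct_trait(cid)
    theta <- if (is.na(ct[["trait"]])) rep(0, n) else traits[, ct[["trait"]]]
    lam <- config$loadings[[cid]] * as.numeric(ct[["sign"]])
    latent <- lam * theta + stats::rnorm(n)
    latents[[items$item_id[i]]] <- latent
    if (items$is_vas[i]) {
      semas[[items$item_id[i]]] <-
        pmin(10, pmax(0, round(5 + config$vas_scale * latent, 1)))
    } else {
      lv <- instr$scales[[items$scale[i]]]$levels
      th <- item_thresholds(nrow(lv), abs(lam), config$offsets[[cid]])
      semas[[items$item_id[i]]] <- grade_item(latent, lv, th)
    }
  }

  crit <- data.frame(respondent_id = rid, stringsAsFactors = FALSE)
  set.seed(substream[3])
  for (i in seq_len(nrow(items))) {
    cid <- items$construct[i]
    lam <- config$loadings[[cid]]
    crit_latent <- latents[[items$item_id[i]]] +
      stats::rnorm(n, sd = config$criterion_noise_sd)
    if (items$is_vas[i]) {
      crit[[items$item_id[i]]] <-
        pmin(10, pmax(0, round(5 + config$vas_scale * crit_latent, 1)))
    } else {
      lv <- instr$scales[[items$scale[i]]]$levels
      th <- item_thresholds(nrow(lv), abs(lam), config$offsets[[cid]])
      crit[[items$item_id[i]]] <- grade_item(crit_latent, lv, th)
    }
  }

  # truth: score the complete (pre-missingness) screener responses
  truth_profiles <- score_cohort(semas, instr)
  entities <- barrier_construct_entities(instr)
  truth_cat <- as.data.frame(
    lapply(stats::setNames(entities, entities), function(e) {
      truth_profiles[[paste0(e, "_cat")]]
    }), stringsAsFactors = FALSE)
  truth_barrier <- as.data.frame(lapply(truth_cat, function(cat_) {
    cat_ %in% c("minor", "major")
  }))

  set.seed(substream[4])
  coefs <- config$pam_coefficients
  pam <- rep(coefs[["intercept"]], n)
  for (e in setdiff(names(coefs), "intercept")) {
    if (!e %in% names(truth_barrier)) {
      stop("pam_coefficients name unknown characteristic '", e, "'",
           call. = FALSE)
    }
    pam <- pam + coefs[[e]] * as.numeric(!truth_barrier[[e]])
  }
  pam <- pmin(100, pmax(0, pam + stats::rnorm(n, sd = config$pam_noise_sd)))

  set.seed(substream[5])
  for (i in seq_len(nrow(items))) {
    rate <- item_missing_rate(config, items$construct[i])
    if (rate > 0) {
      semas[[items$item_id[i]]][stats::runif(n) < rate] <- NA
      crit[[items$item_id[i]]][stats::runif(n) < rate] <- NA
    }
  }

  structure(list(
    semas_responses = semas,
    criterion_responses = crit,
    pam_scores = data.frame(respondent_id = rid, pam = pam,
                            stringsAsFactors = FALSE),
    truth = list(traits = data.frame(respondent_id = rid, traits,
                                     stringsAsFactors = FALSE),
                 categories = cbind(data.frame(respondent_id = rid,
                                               stringsAsFactors = FALSE),
                                    truth_cat),
                 barrier = cbind(data.frame(respondent_id = rid,
                                            stringsAsFactors = FALSE),
                                 truth_barrier)),
    config = config), class = "semas_cohort")
}

#' @export
print.semas_cohort <- function(x, ...) {
  cat("<semas_cohort> n =", x$config$n, " seed =", x$config$seed, "\n")
  prev <- colMeans(x$truth$barrier[, -1, drop = FALSE])
  for (e in names(prev)) {
    cat(sprintf("  %-16s true barrier prevalence %.3f\n", e, prev[e]))
  }
  invisible(x)
}

# simulate the sum scores of one banded construct at a given threshold
# offset; used by the prevalence calibration (common random numbers: the
# same derived seed is reused for every offset evaluated)
simulate_construct_prevalence <- function(config, construct, offset,
                                          n = 10000) {
  instr <- config$instrument
  cons <- instr$constructs[[construct]]
  set.seed((config$seed %% 100000L) * 7L + 13L)
  theta <- stats::rnorm(n)
  sums <- rep(0, n)
  for (id in cons$items) {
    it <- instr$items[instr$items$item_id == id, ]
    lam <- config$loadings[[construct]]
    latent <- lam * theta + stats::rnorm(n)
    lv <- instr$scales[[it$scale]]$levels
    th <- item_thresholds(nrow(lv), lam, offset)
    codes <- grade_item(latent, lv, th)
    sums <- sums + lv$score[match(codes, lv$code)]
  }
  cats <- vapply(sums, function(s) categorize(cons, s, instr), character(1))
  mean(cats %in% c("minor", "major"))
}

#' Calibrate construct threshold offsets to target barrier prevalences
#'
#' Shifts each construct's shared threshold offset by bisection until the
#' simulated barrier prevalence (at `n` respondents, common random numbers)
#' matches the target within `tol`. Only constructs whose category follows
#' from a banded sum score can be calibrated: for those, prevalence is
#' monotone in the offset, which bisection requires. Style-dominance
#' (coping), dichotomy (locus) and u-shaped (burden) rules are rejected.
#'
#' @param config a `semas_cohort_config`.
#' @param targets named barrier prevalences in (0, 1); defaults to
#'   `config$prevalence_targets`.
#' @param n simulation size per evaluation.
#' @param tol acceptable absolute prevalence error.
#' @param max_iter bisection iteration cap per construct.
#' @return the config with adjusted `offsets`.
#' @export
calibrate_prevalence <- function(config, targets = config$prevalence_targets,
                                 n = 10000, tol = 0.02, max_iter = 40) {
  stopifnot(inherits(config, "semas_cohort_config"))
  if (is.null(targets) || !length(targets)) return(config)
  stopifnot(all(targets > 0 & targets < 1))
  for (construct in names(targets)) {
    cons <- config$instrument$constructs[[construct]]
    if (is.null(cons)) stop("unknown construct '", construct, "'", call. = FALSE)
    if (!cons$rule$kind %in% c("banded", "external_table")) {
      stop("construct '", construct, "' has rule kind '", cons$rule$kind,
           "'; only banded sum-score constructs can be calibrated",
           call. = FALSE)
    }
    target <- targets[[construct]]
    lo <- -6; hi <- 6
    f_lo <- simulate_construct_prevalence(config, construct, lo, n)
    f_hi <- simulate_construct_prevalence(config, construct, hi, n)
    increasing <- f_hi >= f_lo
    rng <- range(f_lo, f_hi)
    if (target < rng[1] - tol || target > rng[2] + tol) {
      stop("target prevalence ", target, " for '", construct,
           "' is unattainable (reachable range ", signif(rng[1], 3), "-",
           signif(rng[2], 3), ")", call. = FALSE)
    }
    mid <- 0
    for (iter in seq_len(max_iter)) {
      mid <- (lo + hi) / 2
      f_mid <- simulate_construct_prevalence(config, construct, mid, n)
      if (abs(f_mid - target) <= tol / 2 || (hi - lo) < 1e-4) break
      if ((f_mid < target) == increasing) lo <- mid else hi <- mid
    }
    config$offsets[[construct]] <- mid
  }
  config
}

#' The package's reference synthetic scenario
#'
#' A 204-respondent cohort with threshold offsets calibrated so the barrier
#' prevalences echo the validation study's pattern in spirit: anxiety
#' barriers rare (~5%), depression and social-support barriers uncommon,
#' self-efficacy barriers moderate; coping barriers are common by
#' construction of the style-dominance rule. Illustrative, not a
#' reproduction of the study cohort.
#'
#' @param seed integer seed.
#' @param n cohort size (default 204).
#' @param calibrate run [calibrate_prevalence()] on the default targets.
#' @return a `semas_cohort_config`.
#' @export
default_scenario_config <- function(seed = 1L, n = 204, calibrate = TRUE) {
  config <- cohort_config(n = n, seed = seed)
  if (calibrate) config <- calibrate_prevalence(config)
  config
}
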