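# Criterion rule sets and the end-to-end validation report.

#' Load a criterion rule set
#'
#' A criterion rule set maps each evaluated characteristic to a rule that
#' turns scored criterion-instrument responses into a barrier present/absent
#' flag. The published cut-offs of the original full-length instruments are
#' not redistributed with this package, so validation runs must supply rules
#' explicitly; the shipped example (`criterion_rules.yaml`) mirrors
#' SeMaS-style banding on the criterion channel and is illustrative, not a
#' published norm. Rule types:
#'
#' * `category`: barrier when the scored criterion category is minor/major;
#' * `sum_threshold`: barrier when the criterion sum satisfies `op`
#'   (`"le"`/`"ge"`) against `cutoff`;
#' * `dominance`: barrier unless a single dominant coping style is in
#'   `non_barrier_styles`;
#' * `orientation`: barrier when the locus orientation equals
#'   `barrier_orientation`.
#'
#' @param source path to a YAML file or a pre-parsed list with a `rules`
#'   entry.
#' @return named list of rules, class `criterion_rules`.
#' @export
load_criterion_rules <- function(source) {
  cfg <- if (is.character(source)) yaml::read_yaml(source) else source
  rules <- cfg$rules %||% cfg
  kinds <- c("category", "sum_threshold", "dominance", "orientation")
  for (ch in names(rules)) {
    ty <- rules[[ch]]$type
    if (is.null(ty) || !ty %in% kinds) {
      stop("criterion rule for '", ch, "' has unknown type '", ty, "'",
           call. = FALSE)
    }
    if (ty == "sum_threshold" &&
        (is.null(rules[[ch]]$op) || !rules[[ch]]$op %in% c("le", "ge") ||
         is.null(rules[[ch]]$cutoff))) {
      stop("sum_threshold rule for '", ch, "' needs op ('le'/'ge') and cutoff",
           call. = FALSE)
    }
  }
  structure(rules, class = "criterion_rules")
}

#' Example criterion rule set shipped with the package
#'
#' Illustrative rules for exercising the validation pipeline on synthetic
#' cohorts; see [load_criterion_rules()] for why real validation runs must
#' supply their own.
#'
#' @return a `criterion_rules` object.
#' @export
example_criterion_rules <- function() {
  load_criterion_rules(system.file("extdata", "criterion_rules.yaml",
                                   package = "semas", mustWork = TRUE))
}

#' Apply a criterion rule to scored criterion profiles
#'
#' @param rule one rule from a `criterion_rules` set.
#' @param characteristic the characteristic it applies to.
#' @param criterion_profiles a `semas_profiles` table scored from the
#'   criterion responses.
#' @return logical vector: `TRUE` = barrier, `NA` = not scorable.
#' @export
apply_criterion_rule <- function(rule, characteristic, criterion_profiles) {
  switch(rule$type,
    category = {
      cat_ <- criterion_profiles[[paste0(characteristic, "_cat")]]
      ifelse(cat_ == "not_scorable", NA, cat_ %in% c("minor", "major"))
    },
    sum_threshold = {
      s <- criterion_profiles[[paste0(characteristic, "_sum")]]
      if (rule$op == "le") s <= rule$cutoff else s >= rule$cutoff
    },
    dominance = {
      styles <- criterion_profiles$coping_styles
      vapply(styles, function(st) {
        if (is.na(st)) return(NA)
        parts <- strsplit(st, "+", fixed = TRUE)[[1]]
        !(length(parts) == 1 && parts %in% unlist(rule$non_barrier_styles))
      }, logical(1), USE.NAMES = FALSE)
    },
    orientation = {
      ori <- criterion_profiles$locus_orientation
      ifelse(is.na(ori), NA, ori == (rule$barrier_orientation %||% "external"))
    },
    stop("unknown rule type '", rule$type, "'", call. = FALSE))
}

#' Recoded item-score matrix for one construct over a cohort
#'
#' @param responses wide raw-response table (one row per respondent).
#' @param construct a construct id.
#' @param instrument a `semas_instrument`.
#' @return numeric matrix, one column per item.
#' @export
item_score_matrix <- function(responses, construct, instrument) {
  cons <- resolve_construct(construct, instrument)
  out <- vapply(cons$items, function(id) {
    vapply(seq_len(nrow(responses)), function(i) {
      raw <- if (id %in% names(responses)) responses[[id]][i] else NA
      as.numeric(recode_item(id, raw, instrument))
    }, numeric(1))
  }, numeric(nrow(responses)))
  colnames(out) <- cons$items
  out
}

# sum-score pair used for the criterion correlation of one characteristic;
# the locus dichotomy correlates the internal-minus-external difference
correlation_sums <- function(characteristic, profiles) {
  if (characteristic == "locus") {
    profiles$locus_internal_sum - profiles$locus_external_sum
  } else {
    profiles[[paste0(characteristic, "_sum")]]
  }
}

#' Full psychometric validation report for a cohort
#'
#' Runs the whole validation pipeline: scores the screener and criterion
#' response sets, computes per characteristic the analysed n, PPV/NPV
#' against the criterion rules (not applicable where no rule exists, e.g.
#' social support and burden), Cronbach's alpha (constructs with at least 2
#' items), and the normality-guarded correlation of sum scores; then the
#' ANOVA screen and the forced-entry regression of PAM-13 on the retained
#' characteristics. Per-characteristic failures are collected, not fatal.
#'
#' @param responses wide raw SeMaS response table (respondent_id + items).
#' @param criterion_responses wide criterion response table, aligned by
#'   respondent_id.
#' @param pam_scores data frame with `respondent_id` and `pam` (0-100), or a
#'   numeric vector aligned with `responses`.
#' @param instrument the screener `semas_instrument`.
#' @param rules a `criterion_rules` set.
#' @param criterion_instrument instrument for the criterion responses
#'   (defaults to the screener instrument: the synthetic criterion channel
#'   mirrors its structure).
#' @param screen_threshold ANOVA screen p-value threshold.
#' @return object of class `semas_validation_report`: `rows` (one per
#'   characteristic), `coping_styles` (alpha/correlation per style),
#'   `contingency` (per characteristic), `screen`, `regression`, `issues`.
#' @export
validation_report <- function(responses, criterion_responses, pam_scores,
                              instrument, rules,
                              criterion_instrument = instrument,
                              screen_threshold = 0.05) {
  profiles <- score_cohort(responses, instrument)
  crit_profiles <- score_cohort(criterion_responses, criterion_instrument)
  stopifnot(identical(profiles$respondent_id, crit_profiles$respondent_id))
  if (is.data.frame(pam_scores)) {
    pam <- pam_scores$pam[match(profiles$respondent_id,
                                pam_scores$respondent_id)]
  } else {
    pam <- pam_scores
  }

  characteristics <- barrier_construct_entities(instrument)
  issues <- character()
  contingency <- list()
  rows <- list()

  alpha_construct <- function(ids) {
    mats <- lapply(ids, function(cid) item_score_matrix(responses, cid,
                                                        instrument))
    cronbach_alpha(do.call(cbind, mats))
  }

  for (ch in characteristics) {
    n_row <- NA_integer_
    ppv <- npv <- NA_real_
    if (!is.null(rules[[ch]])) {
      sflag <- barrier_free(profiles, ch) == 0L
      cflag <- apply_criterion_rule(rules[[ch]], ch, crit_profiles)
      pn <- ppv_npv(sflag, cflag)
      contingency[[ch]] <- pn$table
      ppv <- pn$ppv; npv <- pn$npv
      n_row <- pn$n
      if (!is.na(pn$ppv_reason)) issues <- c(issues, paste0(ch, " PPV: ", pn$ppv_reason))
      if (!is.na(pn$npv_reason)) issues <- c(issues, paste0(ch, " NPV: ", pn$npv_reason))
    }
    # alpha over the characteristic's SeMaS items (k >= 2)
    alpha <- NA_real_
    item_sets <- switch(ch,
                        coping = NULL,  # reported per style below
                        locus = c("locus_internal", "locus_external"),
                        burden = NULL,
                        ch)
    if (!is.null(item_sets)) {
      a <- alpha_construct(item_sets)
      alpha <- a$alpha
      if (!is.na(a$reason)) issues <- c(issues, paste0(ch, " alpha: ", a$reason))
    }
    # correlation of sums with the criterion channel
    corr <- list(coefficient = NA_real_, method = NA_character_,
                 p_value = NA_real_, n = NA_integer_)
    if (ch != "coping") {
      x <- correlation_sums(ch, profiles)
      y <- correlation_sums(ch, crit_profiles)
      corr <- semas_correlation(x, y)
      if (!is.na(corr$reason %||% NA)) {
        issues <- c(issues, paste0(ch, " correlation: ", corr$reason))
      }
      if (is.na(n_row)) n_row <- corr$n
    }
    rows[[ch]] <- data.frame(
      characteristic = ch, n = n_row, ppv = ppv, npv = npv, alpha = alpha,
      corr = corr$coefficient, corr_method = corr$method %||% NA_character_,
      corr_p = corr$p_value, stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  rownames(rows) <- NULL

  style_rows <- do.call(rbind, lapply(c("P", "E", "D"), function(st) {
    cid <- paste0("coping_", st)
    a <- alpha_construct(cid)
    corr <- semas_correlation(profiles[[paste0(cid, "_sum")]],
                              crit_profiles[[paste0(cid, "_sum")]])
    data.frame(style = st, alpha = a$alpha, corr = corr$coefficient,
               corr_method = corr$method %||% NA_character_,
               corr_p = corr$p_value, n = corr$n, stringsAsFactors = FALSE)
  }))

  screen <- anova_screen(profiles, pam, characteristics,
                         threshold = screen_threshold)
  issues <- c(issues, attr(screen, "skipped"))
  regression <- NULL
  retained <- screen$characteristic[screen$retained]
  if (length(retained) >= 1) {
    regression <- tryCatch(
      convergent_regression(profiles, pam, retained),
      error = function(e) {
        issues <<- c(issues, paste0("regression: ", conditionMessage(e)))
        NULL
      })
  } else {
    issues <- c(issues, "regression: no characteristic passed the screen")
  }

  structure(list(rows = rows, coping_styles = style_rows,
                 contingency = contingency, screen = screen,
                 regression = regression, issues = issues,
                 n_cohort = nrow(profiles)),
            class = "semas_validation_report")
}

#' @export
print.semas_validation_report <- function(x, ...) {
  cat("<semas_validation_report> cohort n =", x$n_cohort, "\n")
  print(format_report_rows(x$rows), row.names = FALSE)
  cat("coping styles:\n")
  print(x$coping_styles, row.names = FALSE, digits = 3)
  if (!is.null(x$regression)) {
    cat(sprintf("regression: r-squared %.3f on n = %d\n",
                x$regression$r_squared, x$regression$n))
  }
  if (length(x$issues)) cat("issues:", length(x$issues), "\n")
  invisible(x)
}

format_report_rows <- function(rows) {
  fm <- rows
  for (col in c("ppv", "npv", "alpha", "corr", "corr_p")) {
    fm[[col]] <- ifelse(is.na(rows[[col]]), "N.A.",
                        sprintf("%.3f", rows[[col]]))
  }
  fm
}
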