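# Psychometric validation: internal consistency, criterion validity
# (PPV/NPV, correlations), ANOVA screen and forced-entry regression on the
# PAM-13 patient-activation score.

#' Cronbach's alpha for a construct's item scores
#'
#' Internal-consistency coefficient
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance(item sums))`,
#' computed on complete cases with n-1 sample variances. Values of 0.6-0.7
#' are conventionally acceptable, 0.7+ good. Undefined (with a reason) when
#' fewer than 2 items or 2 complete cases remain, or when the total-score
#' variance is zero.
#'
#' @param item_scores numeric matrix or data frame, respondents in rows,
#'   items in columns.
#' @return list with `alpha`, `n` (complete cases), `k` (items), and
#'   `reason` (`NA` unless alpha is undefined).
#' @export
cronbach_alpha <- function(item_scores) {
  x <- as.matrix(item_scores)
  storage.mode(x) <- "double"
  if (ncol(x) < 2) {
    return(alpha_undefined(ncol(x), nrow(x), "fewer than 2 items"))
  }
  x <- x[stats::complete.cases(x), , drop = FALSE]
  k <- ncol(x)
  n <- nrow(x)
  if (n < 2) return(alpha_undefined(k, n, "fewer than 2 complete cases"))
  total_var <- stats::var(rowSums(x))
  if (total_var <= 0) return(alpha_undefined(k, n, "zero total-score variance"))
  item_var <- sum(apply(x, 2, stats::var))
  list(alpha = (k / (k - 1)) * (1 - item_var / total_var),
       n = n, k = k, reason = NA_character_)
}

alpha_undefined <- function(k, n, reason) {
  list(alpha = NA_real_, n = n, k = k, reason = reason)
}

#' PPV and NPV of barrier detection against a criterion
#'
#' Compares per-respondent barrier flags from the screening instrument with
#' flags from the criterion (full-length) instrument. The positive predictive
#' value is the proportion of respondents flagged by the screener that the
#' criterion confirms, `tp / (tp + fp)`; the negative predictive value is the
#' proportion of respondents cleared by the screener that the criterion
#' confirms barrier-free, `tn / (tn + fn)`. Respondents not scorable on
#' either side (`NA`) are excluded and counted in `n_excluded`. A zero
#' denominator yields an undefined value with a reason, never 0.
#'
#' @param semas_binary logical vector, `TRUE` = barrier flagged by the
#'   screener (category minor or major), `NA` = not scorable.
#' @param criterion_binary logical vector aligned by respondent.
#' @return list with `table` (tp, fp, fn, tn, n_excluded), `ppv`, `npv`,
#'   `ppv_reason`, `npv_reason`, `n` (analysed).
#' @export
ppv_npv <- function(semas_binary, criterion_binary) {
  stopifnot(length(semas_binary) == length(criterion_binary))
  s <- as.logical(semas_binary)
  c_ <- as.logical(criterion_binary)
  keep <- !is.na(s) & !is.na(c_)
  tab <- list(tp = sum(s[keep] & c_[keep]),
              fp = sum(s[keep] & !c_[keep]),
              fn = sum(!s[keep] & c_[keep]),
              tn = sum(!s[keep] & !c_[keep]),
              n_excluded = sum(!keep))
  ppv <- npv <- NA_real_
  ppv_reason <- npv_reason <- NA_character_
  if (tab$tp + tab$fp > 0) ppv <- tab$tp / (tab$tp + tab$fp)
  else ppv_reason <- "no respondents flagged by the screener"
  if (tab$tn + tab$fn > 0) npv <- tab$tn / (tab$tn + tab$fn)
  else npv_reason <- "no respondents cleared by the screener"
  list(table = tab, ppv = ppv, npv = npv,
       ppv_reason = ppv_reason, npv_reason = npv_reason,
       n = sum(keep))
}

#' Correlation of screener and criterion sum scores
#'
#' Pairwise-complete correlation with the method chosen by a normality
#' check: when both vectors pass Shapiro-Wilk (at `normality_alpha`, default
#' 0.05) Pearson's r is used, otherwise Spearman's rho (rank correlation
#' with average ranks for ties). Returns a two-sided p-value. For samples
#' beyond the Shapiro-Wilk limit of 5000 the test uses an evenly spaced
#' subsample.
#'
#' @param x,y paired numeric vectors.
#' @param normality_alpha significance level of the per-vector normality
#'   check.
#' @return list with `coefficient`, `method` (`"pearson"` or `"spearman"`),
#'   `p_value`, `n`, and `reason` when undefined (constant input, n < 3).
#' @export
semas_correlation <- function(x, y, normality_alpha = 0.05) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  undef <- function(reason) list(coefficient = NA_real_, method = NA_character_,
                                 p_value = NA_real_, n = n, reason = reason)
  if (n < 3) return(undef("fewer than 3 complete pairs"))
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    return(undef("constant vector"))
  }
  normal <- vapply(list(x, y), function(v) {
    if (length(v) > 5000) v <- v[round(seq(1, length(v), length.out = 5000))]
    if (length(unique(v)) < 3) return(FALSE)
    stats::shapiro.test(v)$p.value >= normality_alpha
  }, logical(1))
  method <- if (all(normal)) "pearson" else "spearman"
  ct <- stats::cor.test(x, y, method = method, exact = FALSE)
  list(coefficient = unname(ct$estimate), method = method,
       p_value = ct$p.value, n = n, reason = NA_character_)
}

#' Barrier-free indicator for one profile characteristic
#'
#' Dichotomises a scored characteristic into 1 = no barrier, 0 = minor or
#' major barrier, `NA` = not scorable. This is the coding used by the ANOVA
#' screen and the regression (so a positive regression coefficient means
#' barrier-free respondents score higher on the dependent scale).
#'
#' @param profiles a `semas_profiles` table.
#' @param characteristic a barrier characteristic name (e.g.
#'   `"self_efficacy"`, `"coping"`, `"locus"`).
#' @return integer vector of 0/1/NA.
#' @export
barrier_free <- function(profiles, characteristic) {
  col <- paste0(characteristic, "_cat")
  if (!col %in% names(profiles)) {
    stop("profiles carry no category column for '", characteristic, "'",
         call. = FALSE)
  }
  cat_ <- profiles[[col]]
  ifelse(cat_ == "not_scorable", NA_integer_,
         ifelse(cat_ == "none", 1L, 0L))
}

#' Univariate ANOVA screen of characteristics against PAM-13
#'
#' For every barrier characteristic, tests with one-way ANOVA whether the
#' PAM-13 scores differ between the no-barrier and barrier (minor or major)
#' groups; characteristics with p below the screen threshold are retained
#' for the multivariate regression. A characteristic with fewer than 2
#' respondents in either group is skipped with a log entry.
#'
#' @param profiles a `semas_profiles` table.
#' @param pam_scores numeric PAM-13 scores (0-100) aligned with `profiles`.
#' @param characteristics which characteristics to screen; defaults to every
#'   barrier characteristic with a category column.
#' @param threshold retention p-value threshold (default 0.05).
#' @return data frame with `characteristic`, `n_none`, `n_barrier`,
#'   `f_value`, `p_value`, `retained`; skipped characteristics are listed in
#'   the `skipped` attribute.
#' @export
anova_screen <- function(profiles, pam_scores, characteristics = NULL,
                         threshold = 0.05) {
  stopifnot(nrow(profiles) == length(pam_scores))
  if (is.null(characteristics)) {
    characteristics <- sub("_cat$", "",
                           grep("_cat$", names(profiles), value = TRUE))
  }
  skipped <- character()
  rows <- list()
  for (ch in characteristics) {
    free <- barrier_free(profiles, ch)
    keep <- !is.na(free) & !is.na(pam_scores)
    g <- factor(free[keep], levels = c(0L, 1L))
    pam <- pam_scores[keep]
    if (min(table(g)) < 2) {
      skipped <- c(skipped, paste0(ch, ": a group has fewer than 2 members"))
      next
    }
    if (stats::var(pam) == 0) {
      # constant outcome: no between-group difference by definition
      f_val <- 0; p_val <- 1
    } else {
      an <- summary(stats::aov(pam ~ g))[[1]]
      f_val <- an[["F value"]][1]
      p_val <- an[["Pr(>F)"]][1]
    }
    rows[[ch]] <- data.frame(
      characteristic = ch,
      n_none = sum(g == "1"), n_barrier = sum(g == "0"),
      f_value = f_val, p_value = p_val,
      retained = p_val < threshold,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(characteristic = character(), n_none = integer(),
                      n_barrier = integer(), f_value = numeric(),
                      p_value = numeric(), retained = logical())
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Forced-entry regression of PAM-13 on dichotomised characteristics
#'
#' Ordinary least squares with PAM-13 as the dependent variable and the
#' retained characteristics as simultaneous (forced-entry) predictors, each
#' coded 1 = no barrier, 0 = barrier. A positive coefficient is the PAM-13
#' point advantage of barrier-free respondents, holding the other
#' characteristics fixed. Complete cases only (listwise). Reports the
#' unstandardised coefficient, its standard error, the standardised
#' coefficient (`beta * sd(x) / sd(y)`), a two-sided p-value, and the model
#' r-squared.
#'
#' @param profiles a `semas_profiles` table.
#' @param pam_scores numeric PAM-13 scores aligned with `profiles`.
#' @param characteristics predictors to enter (typically the screen's
#'   retained set).
#' @return list with `intercept`, `coefficients` (data frame: term, beta,
#'   se_beta, std_beta, p_value), `r_squared`, `n`.
#' @export
convergent_regression <- function(profiles, pam_scores, characteristics) {
  stopifnot(length(characteristics) >= 1)
  X <- vapply(characteristics, function(ch) barrier_free(profiles, ch),
              integer(nrow(profiles)))
  X <- as.matrix(X)
  keep <- stats::complete.cases(X) & !is.na(pam_scores)
  X <- X[keep, , drop = FALSE]
  y <- pam_scores[keep]
  qr_x <- qr(cbind(1, X))
  if (qr_x$rank < ncol(X) + 1) {
    dropped <- characteristics[qr_x$pivot[-seq_len(qr_x$rank)] - 1]
    stop("rank-deficient design; collinear predictor(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  dat <- data.frame(pam = y, X)
  fit <- stats::lm(pam ~ ., data = dat)
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- rownames(co)[-1]
  std_beta <- co[-1, "Estimate"] * apply(X, 2, stats::sd) / stats::sd(y)
  list(
    intercept = unname(co["(Intercept)", "Estimate"]),
    intercept_p = unname(co["(Intercept)", "Pr(>|t|)"]),
    coefficients = data.frame(
      term = characteristics,
      beta = unname(co[terms, "Estimate"]),
      se_beta = unname(co[terms, "Std. Error"]),
      std_beta = unname(std_beta),
      p_value = unname(co[terms, "Pr(>|t|)"]),
      stringsAsFactors = FALSE),
    r_squared = sm$r.squared,
    n = length(y)
  )
}
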