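# Scoring engine: raw item responses -> recoded scores -> construct sums ->
# barrier categories -> per-respondent profile.

round_half_up <- function(x) floor(x + 0.5)

#' Recode a raw item response to its item score
#'
#' Maps a raw response code onto the item's scale score. Missing propagates.
#' Reverse-keyed items map score to `max_score - score`. VAS items (burden)
#' pass the numeric value through after a range check; categorisation rounds
#' half-up later. On a collapsed scale two codes share one score — on the
#' coping scale "often" scores the same as "very often/continuously".
#'
#' In lenient mode (default) an out-of-range code yields `NA` plus an issue
#' message (attribute `issue`); in strict mode it is an error.
#'
#' @param item an item id present in the instrument.
#' @param raw the raw response: an integer code, a numeric VAS value in
#'   `[0, 10]`, or `NA`.
#' @param instrument a `semas_instrument`.
#' @param strict abort on illegal codes instead of treating them as missing.
#' @return the item score (integer, or numeric for VAS), or `NA`.
#' @export
recode_item <- function(item, raw, instrument, strict = FALSE) {
  it <- instrument$items[instrument$items$item_id == item, , drop = FALSE]
  if (nrow(it) != 1) stop("unknown item '", item, "'", call. = FALSE)
  if (is.null(raw) || length(raw) != 1 || is.na(raw)) return(NA_integer_)
  if (it$is_vas) {
    v <- as.numeric(raw)
    if (is.na(v) || v < 0 || v > 10) {
      return(recode_issue(item, paste0("VAS value ", raw, " outside [0, 10]"),
                          strict))
    }
    return(v)
  }
  sc <- instrument$scales[[it$scale]]
  idx <- match(as.integer(raw), sc$levels$code)
  if (is.na(idx)) {
    return(recode_issue(item, paste0("code ", raw, " not on scale '",
                                     it$scale, "'"), strict))
  }
  score <- sc$levels$score[idx]
  if (it$reverse) score <- max(sc$levels$score) - score
  score
}

recode_issue <- function(item, msg, strict) {
  if (strict) stop("item '", item, "': ", msg, call. = FALSE)
  structure(NA_integer_, issue = paste0(item, ": ", msg))
}

#' Score one construct for one respondent
#'
#' Sums the recoded item scores under the construct's missing-data policy.
#' Under `exclude_case` any missing item makes the construct not scorable
#' (sum absent). Under `treat_missing_as_zero` (social support) missing
#' subitems score 0 — a missing support source is read as "not applicable" —
#' unless every subitem is missing, which makes the construct not scorable.
#'
#' @param construct a construct id or construct spec.
#' @param record named list or vector of raw responses (names are item ids;
#'   absent or `NA` entries are missing).
#' @param instrument a `semas_instrument`.
#' @param strict abort on illegal codes.
#' @return a `construct_score` list: `construct_id`, `sum_score` (or `NA`),
#'   `category`, `n_missing`, `issues`.
#' @export
score_construct <- function(construct, record, instrument, strict = FALSE) {
  cons <- resolve_construct(construct, instrument)
  issues <- character()
  scores <- vapply(cons$items, function(id) {
    raw <- if (id %in% names(record)) record[[id]] else NA
    s <- recode_item(id, raw, instrument, strict = strict)
    if (!is.null(attr(s, "issue"))) issues <<- c(issues, attr(s, "issue"))
    as.numeric(s)
  }, numeric(1))
  n_missing <- sum(is.na(scores))
  if (cons$missing_policy == "treat_missing_as_zero") {
    sum_score <- if (n_missing == length(scores)) NA_real_ else
      sum(ifelse(is.na(scores), 0, scores))
  } else {
    sum_score <- if (n_missing > 0) NA_real_ else sum(scores)
  }
  category <- if (cons$rule$kind %in% c("banded", "u_shaped", "external_table")) {
    categorize(cons, sum_score, instrument)
  } else {
    NA_character_  # resolved at profile level (style dominance, dichotomy)
  }
  structure(list(construct_id = cons$construct_id, sum_score = sum_score,
                 category = category, n_missing = n_missing, issues = issues),
            class = "construct_score")
}

#' Map a construct sum score to its barrier category
#'
#' Looks the sum score up in the construct's category bands (closed integer
#' intervals). VAS scores are rounded half-up to an integer first. A missing
#' sum yields `not_scorable`. Default-instrument rules: self-efficacy 4-6
#' none / 2-3 minor / 0-1 major; social support 3-12 none / 2 minor / 0-1
#' major; burden 0-2 minor / 3-7 none / 8-10 minor (low burden can sap
#' motivation, high burden can impair capacity — never major).
#'
#' @param construct construct id or spec (must carry a banded rule).
#' @param sum_score the construct sum score (or `NA`).
#' @param instrument a `semas_instrument`.
#' @return one of `"none"`, `"minor"`, `"major"`, `"not_scorable"`.
#' @export
categorize <- function(construct, sum_score, instrument) {
  cons <- resolve_construct(construct, instrument)
  if (is.na(sum_score)) return("not_scorable")
  bands <- cons$rule$bands
  if (is.null(bands)) {
    stop("construct '", cons$construct_id, "' has no category bands",
         call. = FALSE)
  }
  s <- round_half_up(sum_score)
  hit <- bands$lo <= s & s <= bands$hi
  if (!any(hit)) {
    stop("internal error: sum ", s, " outside bands of '", cons$construct_id,
         "'", call. = FALSE)
  }
  bands$category[which(hit)[1]]
}

#' Resolve the dominant coping style(s) and their barrier category
#'
#' The coping construct is categorised by style dominance, not by bands: the
#' dominant style is the one with the highest sum among problem solving (P),
#' expressing emotions (E) and looking for distraction (D). A tie gives
#' multiple styles, which maps to a minor barrier; a single dominant style
#' maps through the instrument's `coping_style_category` setting (default
#' P = none, E = minor, D = minor). If any style is not scorable the whole
#' construct is not scorable (conservative: dominance cannot be established).
#'
#' @param sums named numeric vector or list with entries `P`, `E`, `D`
#'   (`NA` = style not scorable).
#' @param instrument a `semas_instrument` (supplies the style mapping).
#' @return list with `styles` (character subset of P/E/D, or `NULL`) and
#'   `category`.
#' @export
resolve_coping <- function(sums, instrument) {
  sums <- unlist(sums)[c("P", "E", "D")]
  if (anyNA(sums)) {
    return(list(styles = NULL, category = "not_scorable"))
  }
  styles <- names(sums)[sums == max(sums)]
  map <- instrument$settings$coping_style_category
  category <- if (length(styles) > 1) map$multiple else map[[styles]]
  list(styles = styles, category = category)
}

#' Resolve locus-of-control orientation and barrier category
#'
#' The two locus items are dichotomised into an internal versus external
#' orientation: internal when the internal-item score is at least the
#' external-item score (tie breaks internal by default, configurable via the
#' `locus_tie` setting). The orientation maps to a category through the
#' `locus_category` setting (default internal = none, external = minor).
#' Either score missing makes the construct not scorable.
#'
#' @param internal_score,external_score item scores (or `NA`).
#' @param instrument a `semas_instrument`.
#' @return list with `orientation` (`"internal"`, `"external"` or `NULL`) and
#'   `category`.
#' @export
resolve_locus <- function(internal_score, external_score, instrument) {
  if (is.na(internal_score) || is.na(external_score)) {
    return(list(orientation = NULL, category = "not_scorable"))
  }
  tie <- instrument$settings$locus_tie
  orientation <- if (internal_score > external_score) "internal"
    else if (internal_score < external_score) "external"
    else tie
  list(orientation = orientation,
       category = instrument$settings$locus_category[[orientation]])
}

#' Build the full SeMaS profile for one respondent
#'
#' Scores every construct, resolves the coping style and locus orientation,
#' records the guidance items verbatim (they steer the type of support and
#' are never categorised), and counts barriers: the number of barrier
#' constructs — burden, self-efficacy, locus, anxiety, depression, coping,
#' social support — whose category is minor or major. Not-scorable constructs
#' are excluded from the count and reported separately.
#'
#' @param record named list/vector of raw responses, or a one-row data frame;
#'   must carry a `respondent_id` entry or attribute.
#' @param instrument a `semas_instrument`.
#' @param strict abort on illegal codes.
#' @return a `semas_profile` list.
#' @export
build_profile <- function(record, instrument, strict = FALSE) {
  if (is.data.frame(record)) {
    stopifnot(nrow(record) == 1)
    record <- as.list(record)
  }
  rid <- record$respondent_id %||% attr(record, "respondent_id") %||% NA_character_

  scores <- list()
  issues <- character()
  for (cid in names(instrument$constructs)) {
    cs <- score_construct(cid, record, instrument, strict = strict)
    scores[[cid]] <- cs
    issues <- c(issues, cs$issues)
  }

  # coping: dominance over the three style sums
  coping <- NULL
  if (all(c("coping_P", "coping_E", "coping_D") %in% names(scores))) {
    coping <- resolve_coping(
      c(P = scores$coping_P$sum_score, E = scores$coping_E$sum_score,
        D = scores$coping_D$sum_score), instrument)
  }
  locus <- NULL
  if (all(c("locus_internal", "locus_external") %in% names(scores))) {
    locus <- resolve_locus(scores$locus_internal$sum_score,
                           scores$locus_external$sum_score, instrument)
  }

  entities <- barrier_construct_entities(instrument)
  categories <- vapply(entities, function(e) {
    if (e == "coping") coping$category
    else if (e == "locus") locus$category
    else scores[[e]]$category
  }, character(1))

  guidance <- lapply(guidance_constructs(instrument), function(g) {
    scores[[g]]$sum_score
  })
  names(guidance) <- guidance_constructs(instrument)

  structure(list(
    respondent_id = as.character(rid),
    scores = scores,
    entity_categories = categories,
    coping_styles = coping$styles,
    locus_orientation = locus$orientation,
    guidance_flags = guidance,
    barrier_count = sum(categories %in% c("minor", "major")),
    n_not_scorable = sum(categories == "not_scorable"),
    issues = issues
  ), class = "semas_profile")
}

#' @export
print.semas_profile <- function(x, ...) {
  cat("<semas_profile> respondent", x$respondent_id, "\n")
  for (e in names(x$entity_categories)) {
    cat(sprintf("  %-16s %s\n", e, x$entity_categories[e]))
  }
  cat("  barriers:", x$barrier_count,
      if (x$n_not_scorable) paste0("(", x$n_not_scorable, " not scorable)") else "",
      "\n")
  invisible(x)
}

#' Score a cohort of respondents into a profile table
#'
#' Applies [build_profile()] to every row of a wide response table and
#' returns one row per respondent with construct sums, barrier categories,
#' coping styles, locus orientation, guidance levels and the barrier count.
#'
#' @param responses data frame with a `respondent_id` column and one column
#'   per item id (blank/NA = missing).
#' @param instrument a `semas_instrument`.
#' @param strict abort on illegal codes.
#' @return a data frame of class `semas_profiles`, one row per respondent,
#'   with an `issues` attribute (per-respondent issue log).
#' @export
score_cohort <- function(responses, instrument, strict = FALSE) {
  stopifnot(is.data.frame(responses))
  if (!"respondent_id" %in% names(responses)) {
    stop("responses must have a respondent_id column", call. = FALSE)
  }
  entities <- barrier_construct_entities(instrument)
  rows <- vector("list", nrow(responses))
  issue_log <- list()
  for (i in seq_len(nrow(responses))) {
    p <- build_profile(responses[i, , drop = FALSE], instrument,
                       strict = strict)
    row <- list(respondent_id = p$respondent_id)
    for (cid in names(p$scores)) {
      if (instrument$constructs[[cid]]$role == "guidance_item") next
      row[[paste0(cid, "_sum")]] <- p$scores[[cid]]$sum_score
    }
    for (e in entities) {
      row[[paste0(e, "_cat")]] <- unname(p$entity_categories[e])
    }
    row$coping_styles <- if (is.null(p$coping_styles)) NA_character_ else
      paste(p$coping_styles, collapse = "+")
    row$locus_orientation <- p$locus_orientation %||% NA_character_
    for (g in names(p$guidance_flags)) row[[g]] <- p$guidance_flags[[g]]
    row$barrier_count <- p$barrier_count
    row$n_not_scorable <- p$n_not_scorable
    rows[[i]] <- as.data.frame(row, stringsAsFactors = FALSE)
    if (length(p$issues)) issue_log[[p$respondent_id]] <- p$issues
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "issues") <- issue_log
  class(out) <- c("semas_profiles", class(out))
  out
}

#' Tally respondents by number of barriers
#'
#' Frequency table of the per-respondent barrier count over a scored cohort
#' (the shape of the instrument's headline summary: how many respondents have
#' 0, 1, 2, ... minor-or-major barriers). Percentages are of the cohort size
#' and sum to 100.
#'
#' @param profiles a `semas_profiles` table from [score_cohort()].
#' @return data frame with `n_barriers`, `n_respondents`, `percentage`.
#' @export
barrier_count_table <- function(profiles) {
  counts <- table(factor(profiles$barrier_count,
                         levels = 0:max(profiles$barrier_count)))
  data.frame(
    n_barriers = as.integer(names(counts)),
    n_respondents = as.integer(counts),
    percentage = round_half_up(1000 * as.integer(counts) / nrow(profiles)) / 10
  )
}
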