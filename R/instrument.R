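#' @keywords internal
"_PACKAGE"

BARRIER_CATEGORIES <- c("none", "minor", "major", "not_scorable")

#' Load an instrument definition from a YAML config
#'
#' Parses and validates a declarative instrument definition: response scales
#' (code/label/score levels), constructs with their item lists, missing-data
#' policies and category rules, plus scoring settings (coping style and locus
#' mappings). All downstream scoring is driven by the returned object, never
#' by hard-coded rules.
#'
#' Validation enforces: unique ordered level codes; level scores strictly
#' increasing in code unless the scale declares `collapse: true` (then weakly
#' increasing, as in the coping scale where "often" scores the same as "very
#' often/continuously"); unique item ids; resolvable item-to-scale references;
#' and category bands that partition the attainable score range with no gap or
#' overlap. A `u_shaped` rule must have two non-adjacent `minor` bands. An
#' `external_table` rule must carry explicit bands in the config; the packaged
#' default ships placeholder anxiety/depression bands marked
#' `authoritative: false` because the source subscales' published cut-offs are
#' not redistributed here.
#'
#' A lint warning (not an error) is raised when the social-support construct
#' does not use the `treat_missing_as_zero` policy, or when any other
#' construct does: in this instrument a missing social-support subitem means
#' "not applicable" (scored 0) while missing items elsewhere invalidate the
#' construct score.
#'
#' @param config_source path to a YAML file, or a pre-parsed list.
#' @return an object of class `semas_instrument`.
#' @seealso [semas_instrument()] for the packaged default,
#'   [attainable_score_range()], [serialise_instrument()]
#' @export
#' @examples
#' instr <- semas_instrument()
#' nrow(instr$items)  # 27 items in total
load_instrument <- function(config_source) {
  cfg <- if (is.character(config_source)) {
    if (!file.exists(config_source)) {
      stop("instrument config not found: ", config_source, call. = FALSE)
    }
    yaml::read_yaml(config_source)
  } else if (is.list(config_source)) {
    config_source
  } else {
    stop("config_source must be a file path or a list", call. = FALSE)
  }

  for (field in c("scales", "constructs")) {
    if (is.null(cfg[[field]])) {
      stop("instrument config lacks required section '", field, "'", call. = FALSE)
    }
  }

  scales <- lapply(names(cfg$scales), function(nm) parse_scale(nm, cfg$scales[[nm]]))
  names(scales) <- names(cfg$scales)

  parsed <- parse_constructs(cfg$constructs, scales)

  settings <- cfg$settings %||% list()
  settings$coping_style_category <- utils::modifyList(
    list(P = "none", E = "minor", D = "minor", multiple = "minor"),
    settings$coping_style_category %||% list()
  )
  settings$locus_tie <- settings$locus_tie %||% "internal"
  settings$locus_category <- utils::modifyList(
    list(internal = "none", external = "minor"),
    settings$locus_category %||% list()
  )

  instr <- structure(
    list(
      name = cfg$name %||% "instrument",
      schema_version = cfg$schema_version %||% 1L,
      scales = scales,
      items = parsed$items,
      constructs = parsed$constructs,
      settings = settings
    ),
    class = "semas_instrument"
  )
  validate_instrument(instr)
  instr
}

#' The packaged default SeMaS instrument definition
#'
#' Loads the instrument definition shipped with the package: 27 items across
#' self-efficacy (2 items scored 0-3), coping (2 items per style P/E/D),
#' depression (3), anxiety (4), locus of control (internal + external item),
#' social support (6 subitems scored 0/1/2), perceived burden of disease
#' (VAS 0-10), and three guidance items (computer skills, group functioning,
#' willingness to self-monitor). The main instrument description counts social
#' support as 5 items; the tested criterion form adds a neighbour-support
#' subitem, and this definition follows the 6-subitem reading.
#'
#' @return a `semas_instrument` object.
#' @export
semas_instrument <- function() {
  load_instrument(system.file("extdata", "semas_instrument.yaml",
                              package = "semas", mustWork = TRUE))
}

parse_scale <- function(name, spec) {
  if (is.null(spec$levels) || length(spec$levels) < 2) {
    stop("scale '", name, "' must declare at least 2 levels", call. = FALSE)
  }
  lv <- do.call(rbind, lapply(spec$levels, function(l) {
    data.frame(code = as.integer(l$code),
               label = as.character(l$label %||% ""),
               score = as.integer(l$score),
               stringsAsFactors = FALSE)
  }))
  if (anyDuplicated(lv$code)) {
    stop("scale '", name, "' has duplicated codes", call. = FALSE)
  }
  if (is.unsorted(lv$code, strictly = TRUE)) {
    stop("scale '", name, "' codes must be ordered", call. = FALSE)
  }
  if (any(lv$score < 0)) {
    stop("scale '", name, "' scores must be >= 0", call. = FALSE)
  }
  collapse <- isTRUE(spec$collapse)
  d <- diff(lv$score)
  if (collapse) {
    if (any(d < 0)) {
      stop("scale '", name, "' scores must be weakly increasing", call. = FALSE)
    }
  } else if (any(d <= 0)) {
    stop("scale '", name, "' scores must be strictly increasing ",
         "(declare collapse: true to map two codes to one score)", call. = FALSE)
  }
  list(name = name, levels = lv, collapse = collapse)
}

parse_constructs <- function(cons_cfg, scales) {
  items <- list()
  constructs <- list()
  for (cid in names(cons_cfg)) {
    cc <- cons_cfg[[cid]]
    if (is.null(cc$items) || length(cc$items) == 0) {
      stop("construct '", cid, "' declares no items", call. = FALSE)
    }
    it <- do.call(rbind, lapply(cc$items, function(x) {
      data.frame(item_id = as.character(x$item_id),
                 construct = cid,
                 scale = as.character(x$scale %||% NA_character_),
                 reverse = isTRUE(x$reverse),
                 is_vas = isTRUE(x$vas),
                 label = as.character(x$label %||% ""),
                 stringsAsFactors = FALSE)
    }))
    bad_scale <- !it$is_vas & !(it$scale %in% names(scales))
    if (any(bad_scale)) {
      stop("item '", it$item_id[bad_scale][1], "' references unknown scale '",
           it$scale[bad_scale][1], "'", call. = FALSE)
    }
    if (any(it$is_vas & !is.na(it$scale))) {
      stop("VAS item '", it$item_id[it$is_vas & !is.na(it$scale)][1],
           "' must not reference a response scale", call. = FALSE)
    }
    rule_cfg <- cc$category_rule %||% list(kind = "none")
    rule <- list(
      kind = rule_cfg$kind %||% "none",
      authoritative = !isFALSE(rule_cfg$authoritative),
      bands = parse_bands(rule_cfg$bands)
    )
    constructs[[cid]] <- list(
      construct_id = cid,
      items = it$item_id,
      missing_policy = cc$missing_policy %||% "exclude_case",
      role = cc$role %||% "barrier_construct",
      group = cc$group %||% NA_character_,
      rule = rule
    )
    items[[cid]] <- it
  }
  items <- do.call(rbind, items)
  rownames(items) <- NULL
  if (anyDuplicated(items$item_id)) {
    stop("duplicated item_id: ",
         paste(unique(items$item_id[duplicated(items$item_id)]), collapse = ", "),
         call. = FALSE)
  }
  list(items = items, constructs = constructs)
}

parse_bands <- function(bands_cfg) {
  if (is.null(bands_cfg)) return(NULL)
  b <- do.call(rbind, lapply(bands_cfg, function(x) {
    data.frame(lo = as.integer(x$lo), hi = as.integer(x$hi),
               category = as.character(x$category), stringsAsFactors = FALSE)
  }))
  b[order(b$lo), , drop = FALSE]
}

validate_instrument <- function(instr) {
  policies <- vapply(instr$constructs, `[[`, "", "missing_policy")
  ok <- policies %in% c("exclude_case", "treat_missing_as_zero")
  if (!all(ok)) {
    stop("unknown missing_policy '", policies[!ok][1], "' on construct '",
         names(policies)[!ok][1], "'", call. = FALSE)
  }
  # policy lint: treat_missing_as_zero is the social-support convention only
  for (cid in names(instr$constructs)) {
    pol <- instr$constructs[[cid]]$missing_policy
    if (cid == "social_support" && pol != "treat_missing_as_zero") {
      warning("construct 'social_support' uses missing_policy '", pol,
              "'; missing social-support subitems conventionally score 0 ",
              "(treat_missing_as_zero)", call. = FALSE)
    }
    if (cid != "social_support" && pol == "treat_missing_as_zero") {
      warning("construct '", cid, "' uses treat_missing_as_zero; this policy ",
              "is conventional for social_support only", call. = FALSE)
    }
  }
  for (cid in names(instr$constructs)) {
    cons <- instr$constructs[[cid]]
    kind <- cons$rule$kind
    if (kind %in% c("banded", "u_shaped", "external_table")) {
      if (is.null(cons$rule$bands)) {
        stop("construct '", cid, "' rule kind '", kind,
             "' requires explicit bands", call. = FALSE)
      }
      check_band_partition(cid, cons$rule$bands,
                           attainable_score_range(cid, instr))
      if (kind == "u_shaped") {
        minors <- which(cons$rule$bands$category == "minor")
        if (length(minors) != 2 || diff(minors) < 2) {
          stop("construct '", cid,
               "' u_shaped rule needs two non-adjacent minor bands",
               call. = FALSE)
        }
      }
    }
    bad_cat <- setdiff(cons$rule$bands$category, BARRIER_CATEGORIES)
    if (length(bad_cat)) {
      stop("construct '", cid, "' has unknown category '", bad_cat[1], "'",
           call. = FALSE)
    }
  }
  # dominance / dichotomy groups must be complete
  groups <- vapply(instr$constructs, `[[`, "", "group")
  if ("coping" %in% groups &&
      !setequal(names(groups)[groups %in% "coping"],
                c("coping_P", "coping_E", "coping_D"))) {
    stop("coping group must contain exactly coping_P, coping_E, coping_D",
         call. = FALSE)
  }
  if ("locus" %in% groups &&
      !setequal(names(groups)[groups %in% "locus"],
                c("locus_internal", "locus_external"))) {
    stop("locus group must contain exactly locus_internal and locus_external",
         call. = FALSE)
  }
  invisible(instr)
}

check_band_partition <- function(cid, bands, range) {
  b <- bands[order(bands$lo), , drop = FALSE]
  if (any(b$hi < b$lo)) {
    stop("construct '", cid, "' has a band with hi < lo", call. = FALSE)
  }
  if (b$lo[1] != range[1] || b$hi[nrow(b)] != range[2]) {
    stop("construct '", cid, "' bands do not cover the attainable range ",
         range[1], "-", range[2], call. = FALSE)
  }
  if (nrow(b) > 1) {
    gaps <- b$lo[-1] - b$hi[-nrow(b)]
    if (any(gaps > 1)) {
      i <- which(gaps > 1)[1]
      stop("construct '", cid, "' has a gap between bands ", b$hi[i], " and ",
           b$lo[i + 1], call. = FALSE)
    }
    if (any(gaps < 1)) {
      i <- which(gaps < 1)[1]
      stop("construct '", cid, "' has overlapping bands at ", b$lo[i + 1],
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Attainable sum-score range of a construct
#'
#' The minimum (maximum) attainable sum score is the sum of per-item minimum
#' (maximum) scale scores. A VAS construct has range 0-10 by definition. For
#' the default instrument: self-efficacy 0-6, social support 0-12.
#'
#' @param construct a construct id or a construct spec from an instrument.
#' @param instrument a `semas_instrument`.
#' @return integer (or numeric for VAS) vector `c(min, max)`.
#' @export
attainable_score_range <- function(construct, instrument) {
  cons <- resolve_construct(construct, instrument)
  it <- instrument$items[instrument$items$item_id %in% cons$items, , drop = FALSE]
  if (any(it$is_vas)) return(c(0, 10))
  lo <- hi <- 0L
  for (i in seq_len(nrow(it))) {
    sc <- instrument$scales[[it$scale[i]]]$levels$score
    lo <- lo + min(sc)
    hi <- hi + max(sc)
  }
  c(lo, hi)
}

resolve_construct <- function(construct, instrument) {
  if (is.character(construct)) {
    cons <- instrument$constructs[[construct]]
    if (is.null(cons)) {
      stop("unknown construct '", construct, "'", call. = FALSE)
    }
    cons
  } else {
    construct
  }
}

#' Serialise an instrument definition to its canonical config form
#'
#' Produces the canonical nested-list representation of an instrument, such
#' that `load_instrument(serialise_instrument(x))` reproduces `x`. Useful for
#' diffing and versioning instrument definitions.
#'
#' @param instrument a `semas_instrument`.
#' @param path optional path; when given, the canonical YAML is written there.
#' @return the canonical config list, invisibly when `path` is given.
#' @export
serialise_instrument <- function(instrument, path = NULL) {
  scales <- lapply(instrument$scales, function(s) {
    out <- list(levels = lapply(seq_len(nrow(s$levels)), function(i) {
      list(code = s$levels$code[i], label = s$levels$label[i],
           score = s$levels$score[i])
    }))
    if (s$collapse) out <- c(list(collapse = TRUE), out)
    out
  })
  constructs <- lapply(instrument$constructs, function(cons) {
    it <- instrument$items[instrument$items$item_id %in% cons$items, , drop = FALSE]
    items <- lapply(seq_len(nrow(it)), function(i) {
      x <- list(item_id = it$item_id[i])
      if (!it$is_vas[i]) x$scale <- it$scale[i] else x$vas <- TRUE
      if (it$reverse[i]) x$reverse <- TRUE
      if (nzchar(it$label[i])) x$label <- it$label[i]
      x
    })
    rule <- list(kind = cons$rule$kind)
    if (!cons$rule$authoritative) rule$authoritative <- FALSE
    if (!is.null(cons$rule$bands)) {
      rule$bands <- lapply(seq_len(nrow(cons$rule$bands)), function(i) {
        list(lo = cons$rule$bands$lo[i], hi = cons$rule$bands$hi[i],
             category = cons$rule$bands$category[i])
      })
    }
    out <- list(role = cons$role)
    if (!is.na(cons$group)) out$group <- cons$group
    out$missing_policy <- cons$missing_policy
    out$items <- items
    out$category_rule <- rule
    out
  })
  cfg <- list(
    schema_version = instrument$schema_version,
    name = instrument$name,
    scales = scales,
    constructs = constructs,
    settings = instrument$settings
  )
  if (!is.null(path)) {
    yaml::write_yaml(cfg, path)
    return(invisible(cfg))
  }
  cfg
}

#' @export
print.semas_instrument <- function(x, ...) {
  cat("<semas_instrument> ", x$name, " (schema v", x$schema_version, ")\n",
      sep = "")
  cat("  items:", nrow(x$items), " constructs:", length(x$constructs), "\n")
  for (cid in names(x$constructs)) {
    cons <- x$constructs[[cid]]
    rng <- attainable_score_range(cid, x)
    cat(sprintf("  %-28s %d item(s), range %s-%s, rule %s [%s]\n", cid,
                length(cons$items), rng[1], rng[2], cons$rule$kind, cons$role))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

barrier_construct_entities <- function(instrument) {
  out <- character()
  seen_group <- character()
  for (cid in names(instrument$constructs)) {
    cons <- instrument$constructs[[cid]]
    if (cons$role != "barrier_construct") next
    if (!is.na(cons$group)) {
      if (cons$group %in% seen_group) next
      seen_group <- c(seen_group, cons$group)
      out <- c(out, cons$group)
    } else {
      out <- c(out, cid)
    }
  }
  out
}

guidance_constructs <- function(instrument) {
  names(instrument$constructs)[
    vapply(instrument$constructs, `[[`, "", "role") == "guidance_item"]
}
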