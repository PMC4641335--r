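# Graphic profile: one row per barrier construct, marker placed in its
# no/minor/major zone, so the result can be read at a glance.

PROFILE_ORDER <- c("burden", "self_efficacy", "locus", "anxiety",
                   "depression", "coping", "social_support")

#' Geometry of a profile rendering
#'
#' One row per barrier construct, in the fixed default order (burden,
#' self-efficacy, locus, anxiety, depression, coping, social support): the
#' normalized marker position `(sum - min) / (max - min)` within the
#' attainable range, the category as computed by the scoring engine (the
#' renderer never re-bands), and the sum and range. For the locus dichotomy
#' the position is the internal-minus-external score difference rescaled to
#' `[0, 1]` (0 = fully external, 1 = fully internal); for coping it is the
#' dominant style's sum over its range. Not-scorable rows have `NA` position.
#'
#' @param profile a `semas_profile`.
#' @param instrument the `semas_instrument` the profile was scored with.
#' @param order row order; defaults to the package's fixed order.
#' @return data frame: `construct`, `sum`, `min`, `max`, `position`,
#'   `category`, `detail`.
#' @export
profile_rows <- function(profile, instrument, order = PROFILE_ORDER) {
  entities <- intersect(order, names(profile$entity_categories))
  rows <- lapply(entities, function(e) {
    cat_e <- unname(profile$entity_categories[e])
    if (e == "locus") {
      i <- profile$scores$locus_internal$sum_score
      x <- profile$scores$locus_external$sum_score
      mx <- attainable_score_range("locus_internal", instrument)[2]
      pos <- if (is.na(i) || is.na(x)) NA_real_ else (i - x + mx) / (2 * mx)
      detail <- profile$locus_orientation %||% ""
      s <- if (is.na(i) || is.na(x)) NA_real_ else i - x
      rng <- c(-mx, mx)
    } else if (e == "coping") {
      sums <- c(P = profile$scores$coping_P$sum_score,
                E = profile$scores$coping_E$sum_score,
                D = profile$scores$coping_D$sum_score)
      rng <- attainable_score_range("coping_P", instrument)
      s <- if (anyNA(sums)) NA_real_ else max(sums)
      pos <- if (is.na(s)) NA_real_ else (s - rng[1]) / (rng[2] - rng[1])
      detail <- if (is.null(profile$coping_styles)) "" else
        paste(profile$coping_styles, collapse = "+")
    } else {
      s <- profile$scores[[e]]$sum_score
      rng <- attainable_score_range(e, instrument)
      pos <- if (is.na(s)) NA_real_ else (s - rng[1]) / (rng[2] - rng[1])
      detail <- ""
    }
    data.frame(construct = e, sum = as.numeric(s), min = rng[1], max = rng[2],
               position = pos, category = cat_e, detail = detail,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Render a SeMaS graphic profile
#'
#' Renders one respondent's profile as deterministic plain text (fixed-width,
#' locale-independent, suitable for golden-file comparison) or as a
#' standalone SVG document. Each row shows the construct, its sum score, the
#' barrier category from the scoring engine, and a track with the marker `X`
#' at the normalized score position; zone characters are `.` (none), `-`
#' (minor) and `=` (major) for banded constructs. Not-scorable constructs are
#' rendered as an explicit gap marker. Guidance item levels and the barrier
#' count follow the rows.
#'
#' @param profile a `semas_profile` from [build_profile()].
#' @param instrument the `semas_instrument` used for scoring.
#' @param format `"text"` or `"svg"`.
#' @param path optional output file; when given the document is written there.
#' @return the rendered document as a single string (invisibly when written
#'   to `path`).
#' @export
render_profile <- function(profile, instrument, format = c("text", "svg"),
                           path = NULL) {
  format <- match.arg(format)
  rows <- profile_rows(profile, instrument)
  doc <- switch(format,
                text = render_text(profile, rows, instrument),
                svg = render_svg(profile, rows, instrument))
  if (!is.null(path)) {
    con <- file(path, open = "wb")  # byte-stable: no CRLF translation
    on.exit(close(con))
    writeChar(doc, con, eos = NULL)
    return(invisible(doc))
  }
  doc
}

TRACK_WIDTH <- 21L

zone_track <- function(row, instrument) {
  if (is.na(row$position)) {
    return(paste0("[", paste(rep(" ", TRACK_WIDTH), collapse = ""), "]"))
  }
  cons <- instrument$constructs[[row$construct]]
  chars <- rep(".", TRACK_WIDTH)
  bands <- if (row$construct %in% names(instrument$constructs))
    cons$rule$bands else NULL
  if (!is.null(bands)) {
    for (col in seq_len(TRACK_WIDTH) - 1L) {
      score_at <- row$min + (row$max - row$min) * col / (TRACK_WIDTH - 1L)
      s <- round_half_up(score_at)
      hit <- bands$category[bands$lo <= s & s <= bands$hi]
      if (length(hit)) {
        chars[col + 1L] <- switch(hit[1], none = ".", minor = "-", major = "=")
      }
    }
  }
  marker_col <- 1L + as.integer(round_half_up(row$position * (TRACK_WIDTH - 1L)))
  chars[marker_col] <- "X"
  paste0("[", paste(chars, collapse = ""), "]")
}

render_text <- function(profile, rows, instrument) {
  lines <- c(
    paste0("SeMaS profile  respondent: ", profile$respondent_id),
    sprintf("%-16s %9s  %-12s %s", "construct", "score", "category",
            "low -------------- high")
  )
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    if (is.na(r$position)) {
      lines <- c(lines, sprintf("%-16s %9s  %-12s [%s]", r$construct, "--",
                                "not_scorable",
                                paste(rep(" ", TRACK_WIDTH), collapse = "")))
      next
    }
    score_txt <- if (r$construct == "burden") {
      sprintf("%.1f/%d", r$sum, as.integer(r$max))
    } else if (r$construct == "locus") {
      sprintf("%+d", as.integer(r$sum))
    } else {
      sprintf("%d/%d", as.integer(r$sum), as.integer(r$max))
    }
    cat_txt <- if (nzchar(r$detail)) paste0(r$category, " (", r$detail, ")")
      else r$category
    lines <- c(lines, sprintf("%-16s %9s  %-12s %s", r$construct, score_txt,
                              cat_txt, zone_track(r, instrument)))
  }
  guide <- vapply(names(profile$guidance_flags), function(g) {
    v <- profile$guidance_flags[[g]]
    paste0(g, ": ", if (is.na(v)) "--" else as.integer(v))
  }, character(1))
  lines <- c(lines,
             paste0("guidance  ", paste(guide, collapse = "  ")),
             sprintf("barriers: %d  not scorable: %d", profile$barrier_count,
                     profile$n_not_scorable))
  paste0(paste(lines, collapse = "\n"), "\n")
}

SVG_ZONE_FILL <- c(none = "#8bc34a", minor = "#ffc107", major = "#f44336")

render_svg <- function(profile, rows, instrument) {
  bar_x <- 170; bar_w <- 300; row_h <- 32; pad <- 40
  height <- pad + row_h * (nrow(rows) + 2)
  out <- c(
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"560\" ",
                   "height=\"%d\" font-family=\"monospace\" font-size=\"13\">"),
            height),
    sprintf("<text x=\"10\" y=\"22\">SeMaS profile: %s</text>",
            xml_escape(profile$respondent_id))
  )
  for (i in seq_len(nrow(rows))) {
    r <- rows[i, ]
    y <- pad + (i - 1) * row_h
    out <- c(out, sprintf("<text x=\"10\" y=\"%d\">%s</text>", y + 16,
                          xml_escape(r$construct)))
    cons <- instrument$constructs[[r$construct]]
    bands <- if (!is.null(cons)) cons$rule$bands else NULL
    if (!is.null(bands) && !is.na(r$position)) {
      n_attain <- r$max - r$min + 1
      for (b in seq_len(nrow(bands))) {
        x0 <- bar_x + bar_w * (bands$lo[b] - r$min) / n_attain
        w <- bar_w * (bands$hi[b] - bands$lo[b] + 1) / n_attain
        out <- c(out, sprintf(
          "<rect x=\"%.2f\" y=\"%d\" width=\"%.2f\" height=\"18\" fill=\"%s\" opacity=\"0.6\"/>",
          x0, y + 4, w, SVG_ZONE_FILL[[bands$category[b]]]))
      }
    } else {
      out <- c(out, sprintf(
        "<rect x=\"%d\" y=\"%d\" width=\"%d\" height=\"18\" fill=\"#e0e0e0\"/>",
        bar_x, y + 4, bar_w))
    }
    if (is.na(r$position)) {
      out <- c(out, sprintf(
        "<text x=\"%d\" y=\"%d\" fill=\"#666\">not scorable</text>",
        bar_x + bar_w + 10, y + 16))
    } else {
      cx <- bar_x + bar_w * r$position
      out <- c(out, sprintf(
        "<circle cx=\"%.2f\" cy=\"%d\" r=\"6\" fill=\"#1a237e\"/>", cx, y + 13))
      out <- c(out, sprintf(
        "<text x=\"%d\" y=\"%d\">%s</text>", bar_x + bar_w + 10, y + 16,
        xml_escape(if (nzchar(r$detail)) paste0(r$category, " (", r$detail, ")")
                   else r$category)))
    }
  }
  y <- pad + nrow(rows) * row_h
  guide <- vapply(names(profile$guidance_flags), function(g) {
    v <- profile$guidance_flags[[g]]
    paste0(g, ": ", if (is.na(v)) "--" else as.integer(v))
  }, character(1))
  out <- c(out,
           sprintf("<text x=\"10\" y=\"%d\">guidance  %s</text>", y + 16,
                   xml_escape(paste(guide, collapse = "  "))),
           sprintf("<text x=\"10\" y=\"%d\">barriers: %d  not scorable: %d</text>",
                   y + row_h + 16, profile$barrier_count, profile$n_not_scorable),
           "</svg>")
  paste0(paste(out, collapse = "\n"), "\n")
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}
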