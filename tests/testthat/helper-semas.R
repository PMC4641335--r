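# Shared fixtures: instrument caches, config builders, straight-line
# category oracles re-implemented from the banding rules.

the_instrument <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- semas_instrument()
    cached
  }
})

# minimal valid config list, editable per test
base_config <- function() {
  serialise_instrument(the_instrument())
}

# a complete, legal response record with every construct at "no barrier"
all_clear_record <- function() {
  list(respondent_id = "T1",
       se_1 = 4, se_2 = 4,                               # sum 6 -> none
       cop_p1 = 5, cop_p2 = 5,                           # P dominant
       cop_e1 = 1, cop_e2 = 1,
       cop_d1 = 1, cop_d2 = 1,
       dep_1 = 1, dep_2 = 1, dep_3 = 1,                  # sum 0 -> none
       anx_1 = 1, anx_2 = 1, anx_3 = 1, anx_4 = 1,       # sum 0 -> none
       loc_int = 4, loc_ext = 1,                         # internal
       ss_1 = 5, ss_2 = 5, ss_3 = 5, ss_4 = 5, ss_5 = 5, ss_6 = 5,  # 12
       burden = 5,                                       # none
       guide_pc = 3, guide_group = 3, guide_selfmon = 3)
}

# straight-line re-implementations of the published banding text,
# independent of the table-driven engine
oracle_self_efficacy <- function(s) {
  if (s >= 4) "none" else if (s >= 2) "minor" else "major"
}
oracle_social_support <- function(s) {
  if (s >= 3) "none" else if (s == 2) "minor" else "major"
}
oracle_burden <- function(v) {
  s <- floor(v + 0.5)
  if (s <= 2) "minor" else if (s <= 7) "none" else "minor"
}
# placeholder-table constructs: linear scan over the configured bands
oracle_banded <- function(s, bands) {
  for (i in seq_len(nrow(bands))) {
    if (s >= bands$lo[i] && s <= bands$hi[i]) return(bands$category[i])
  }
  stop("no band")
}

# all attainable sum scores of a construct via exhaustive enumeration of
# response combinations (scores looked up straight from the scale table)
enumerate_sums <- function(construct, instrument) {
  cons <- instrument$constructs[[construct]]
  per_item <- lapply(cons$items, function(id) {
    it <- instrument$items[instrument$items$item_id == id, ]
    instrument$scales[[it$scale]]$levels$score
  })
  rowSums(as.matrix(expand.grid(per_item)))
}

# a single-construct instrument with a fine-grained (many-level) scale;
# used where reliability checks need near-continuous items
fine_instrument_config <- function(n_levels = 21) {
  lev <- lapply(seq_len(n_levels), function(i) {
    list(code = i, label = "", score = i - 1)
  })
  top <- 2 * (n_levels - 1)
  list(schema_version = 1, name = "fine",
       scales = list(fine = list(levels = lev)),
       constructs = list(self_efficacy = list(
         role = "barrier_construct", missing_policy = "exclude_case",
         items = list(list(item_id = "f1", scale = "fine"),
                      list(item_id = "f2", scale = "fine")),
         category_rule = list(kind = "banded", bands = list(
           list(lo = 0, hi = n_levels - 1, category = "major"),
           list(lo = n_levels, hi = top, category = "none"))))))
}

fine_cohort_config <- function(n, seed, lambda, n_levels = 21, ...) {
  instr <- load_instrument(fine_instrument_config(n_levels))
  cohort_config(n = n, seed = seed, instrument = instr,
                trait_corr = matrix(1, dimnames = list("self_efficacy",
                                                       "self_efficacy")),
                loadings = c(self_efficacy = lambda),
                pam_coefficients = c(intercept = 50), pam_noise_sd = 1,
                missing_rate = 0, prevalence_targets = NULL, ...)
}

category_rank <- c(none = 0, minor = 1, major = 2)
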