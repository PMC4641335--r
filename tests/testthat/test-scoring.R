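test_that("recoding follows the response-scale tables", {
  instr <- the_instrument()
  # coping: "often" and "very often/continuously" share one score
  expect_equal(recode_item("cop_p1", 4, instr), recode_item("cop_p1", 5, instr))
  expect_equal(recode_item("cop_p1", 5, instr), 3)
  # social support: no / completely false / somewhat false -> 0,
  # somewhat true -> 1, completely true -> 2
  expect_equal(vapply(1:5, function(code) recode_item("ss_1", code, instr),
                      numeric(1)),
               c(0, 0, 0, 1, 2))
  # missing propagates
  expect_true(is.na(recode_item("se_1", NA, instr)))
  # VAS passes through
  expect_equal(recode_item("burden", 7.5, instr), 7.5)
})

test_that("reverse-keyed items map score to max minus score", {
  cfg <- base_config()
  cfg$constructs$self_efficacy$items[[2]]$reverse <- TRUE
  instr <- load_instrument(cfg)
  expect_equal(recode_item("se_1", 4, instr), 3)
  expect_equal(recode_item("se_2", 4, instr), 0)
  expect_equal(recode_item("se_2", 1, instr), 3)
})

test_that("illegal codes are missing-with-issue in lenient mode, errors in strict", {
  instr <- the_instrument()
  s <- recode_item("se_1", 9, instr)
  expect_true(is.na(s))
  expect_match(attr(s, "issue"), "se_1.*code 9")
  expect_error(recode_item("se_1", 9, instr, strict = TRUE), "se_1")
  v <- recode_item("burden", 12, instr)
  expect_true(is.na(v))
  expect_error(recode_item("burden", 12, instr, strict = TRUE), "outside")
})

test_that("missing-data policies behave as specified", {
  instr <- the_instrument()
  # exclude_case: one missing item voids the construct
  cs <- score_construct("self_efficacy", list(se_1 = 4), instr)
  expect_true(is.na(cs$sum_score))
  expect_equal(cs$category, "not_scorable")
  expect_equal(cs$n_missing, 1L)
  # social support: missing counts 0 ("not applicable")
  cs <- score_construct("social_support", list(ss_1 = 5, ss_2 = 5), instr)
  expect_equal(cs$sum_score, 4)
  expect_equal(cs$category, "none")
  expect_equal(cs$n_missing, 4L)
  # ... unless every subitem is missing
  cs <- score_construct("social_support", list(), instr)
  expect_true(is.na(cs$sum_score))
  expect_equal(cs$category, "not_scorable")
})

test_that("categorisation matches the published band examples", {
  instr <- the_instrument()
  expect_equal(categorize("self_efficacy", 5, instr), "none")
  expect_equal(categorize("self_efficacy", 2, instr), "minor")
  expect_equal(categorize("self_efficacy", 0, instr), "major")
  expect_equal(categorize("burden", 0, instr), "minor")
  expect_equal(categorize("burden", 5, instr), "none")
  expect_equal(categorize("burden", 9, instr), "minor")
  expect_equal(categorize("social_support", 2, instr), "minor")
  expect_equal(categorize("social_support", 1, instr), "major")
  expect_equal(categorize("social_support", 3, instr), "none")
  # VAS values round half-up before banding
  expect_equal(categorize("burden", 2.5, instr), "none")
  expect_equal(categorize("burden", 2.4, instr), "minor")
  expect_equal(categorize("burden", 7.5, instr), "minor")
  expect_equal(categorize("anxiety", NA, instr), "not_scorable")
})

test_that("categorize agrees with straight-line oracles over every response combination", {
  instr <- the_instrument()
  oracles <- list(
    self_efficacy = oracle_self_efficacy,
    social_support = oracle_social_support,
    depression = function(s) oracle_banded(s, instr$constructs$depression$rule$bands),
    anxiety = function(s) oracle_banded(s, instr$constructs$anxiety$rule$bands)
  )
  for (cid in names(oracles)) {
    sums <- enumerate_sums(cid, instr)   # every response combination
    got <- vapply(sums, function(s) categorize(cid, s, instr), character(1))
    want <- vapply(sums, oracles[[cid]], character(1))
    expect_identical(got, want, label = cid)
  }
  # burden VAS on a 0.1 grid
  v <- seq(0, 10, by = 0.1)
  got <- vapply(v, function(x) categorize("burden", x, instr), character(1))
  expect_identical(got, vapply(v, oracle_burden, character(1)))
})

test_that("coping resolves by style dominance", {
  instr <- the_instrument()
  r <- resolve_coping(c(P = 6, E = 2, D = 2), instr)
  expect_equal(r$styles, "P")
  expect_equal(r$category, "none")
  r <- resolve_coping(c(P = 4, E = 4, D = 1), instr)
  expect_setequal(r$styles, c("P", "E"))
  expect_equal(r$category, "minor")
  r <- resolve_coping(c(P = 3, E = 3, D = 3), instr)
  expect_setequal(r$styles, c("P", "E", "D"))
  expect_equal(r$category, "minor")
  r <- resolve_coping(c(P = 1, E = 5, D = 2), instr)
  expect_equal(r$styles, "E")
  expect_equal(r$category, "minor")
  r <- resolve_coping(c(P = 6, E = NA, D = 2), instr)
  expect_null(r$styles)
  expect_equal(r$category, "not_scorable")
})

test_that("locus dichotomises into internal versus external orientation", {
  instr <- the_instrument()
  r <- resolve_locus(3, 1, instr)
  expect_equal(r$orientation, "internal")
  expect_equal(r$category, "none")
  r <- resolve_locus(0, 3, instr)
  expect_equal(r$orientation, "external")
  expect_equal(r$category, "minor")
  # documented tie-break: internal
  r <- resolve_locus(2, 2, instr)
  expect_equal(r$orientation, "internal")
  expect_equal(r$category, "none")
  r <- resolve_locus(NA, 2, instr)
  expect_equal(r$category, "not_scorable")
})

test_that("profiles count barriers over barrier constructs only", {
  instr <- the_instrument()
  rec <- all_clear_record()
  p <- build_profile(rec, instr)
  expect_equal(p$barrier_count, 0L)
  expect_true(all(p$entity_categories == "none"))
  # guidance items recorded verbatim, never categorised
  expect_equal(p$guidance_flags$computer_skills, 2)  # code 3 -> score 2
  # minor self-efficacy + major depression -> 2 barriers
  rec$se_1 <- 2; rec$se_2 <- 2                   # sum 2 -> minor
  rec$dep_1 <- 4; rec$dep_2 <- 4; rec$dep_3 <- 4 # sum 9 -> major
  p <- build_profile(rec, instr)
  expect_equal(p$barrier_count, 2L)
  # not-scorable constructs are flagged, never counted
  rec$anx_1 <- NA
  p <- build_profile(rec, instr)
  expect_equal(p$barrier_count, 2L)
  expect_equal(p$n_not_scorable, 1L)
})

test_that("scoring is deterministic and sum is permutation invariant", {
  instr <- the_instrument()
  rec <- all_clear_record()
  expect_identical(build_profile(rec, instr), build_profile(rec, instr))
  # permute the social-support responses: same sum
  rec2 <- rec
  rec2[paste0("ss_", 1:6)] <- rec[paste0("ss_", c(3, 1, 6, 2, 5, 4))]
  expect_equal(score_construct("social_support", rec2, instr)$sum_score,
               score_construct("social_support", rec, instr)$sum_score)
})

test_that("raising one item never worsens a top-banded category", {
  instr <- the_instrument()
  for (rep_i in 1:50) {
    set.seed(rep_i)
    for (cid in c("self_efficacy", "social_support")) {
      cons <- instr$constructs[[cid]]
      codes <- vapply(cons$items, function(id) {
        it <- instr$items[instr$items$item_id == id, ]
        sample(instr$scales[[it$scale]]$levels$code, 1)
      }, numeric(1))
      rec <- as.list(codes)
      before <- score_construct(cid, rec, instr)
      bump <- sample(seq_along(codes), 1)
      it <- instr$items[instr$items$item_id == cons$items[bump], ]
      max_code <- max(instr$scales[[it$scale]]$levels$code)
      rec[[bump]] <- min(max_code, codes[bump] + 1)
      after <- score_construct(cid, rec, instr)
      expect_lte(category_rank[after$category], category_rank[before$category])
    }
  }
})

test_that("cohort barrier-count tally sums to the cohort size", {
  coh <- simulate_cohort(cohort_config(n = 204, seed = 42))
  profiles <- score_cohort(coh$semas_responses, the_instrument())
  tab <- barrier_count_table(profiles)
  expect_equal(sum(tab$n_respondents), 204L)
  expect_equal(nrow(profiles), 204L)
  max_entities <- length(unique(c("burden", "self_efficacy", "locus",
                                  "anxiety", "depression", "coping",
                                  "social_support")))
  expect_true(all(profiles$barrier_count <= max_entities))
  expect_true(abs(sum(tab$percentage) - 100) < 0.5)
})
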