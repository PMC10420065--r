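# a tiny visit with every field at its healthiest level
best_case_visit <- function() {
  list(patient_id = "A", endoscopic_score = 1,
       abdominal_pain = "no", abdominal_pain_night = "no",
       abdominal_finding = "without_findings", pressure_pain = "no",
       resistance = "no", anal_finding = "no", appetite = "good",
       activity_limitation = "no", ibd_clinic = "center_a",
       condition = "good", extraintestinal = "no", height_gain = "yes",
       perianal_eczema = "no", stool_blood = "no",
       stool_consistency = "formed", stool_quantity = "le3",
       weight_gain = "voluntary",
       albumin = 40, crp = 0.8, hematocrit = 0.4, hemoglobin = 13,
       mcv = 85, platelets = 300, leukocytes = 7, fc = 30, esr = 5)
}

test_that("brute-force range validation reproduces every published range", {
  expect_equal(validate_scoring_table(dai_scoring_table("pcdai")),
               c(0, 100))
  expect_equal(validate_scoring_table(dai_scoring_table("modpcdai")),
               c(0, 115))
  expect_equal(validate_scoring_table(dai_scoring_table("shpcdai")),
               c(0, 90))
  expect_equal(validate_scoring_table(dai_scoring_table("wpcdai")),
               c(0, 125))
  expect_equal(validate_scoring_table(dai_scoring_table("mini")),
               c(-3, 25))
  expect_message(validate_scoring_table(dai_scoring_table("abbrpcdai")),
                 "skipped")
})

test_that("a corrupted table fails range validation with a helpful error", {
  tab <- dai_scoring_table("pcdai")
  tab$components[[1]]$levels[[1]]$points <- 40
  expect_error(validate_scoring_table(tab), "does not match declared")
})

test_that("a toy one-component table scores and validates", {
  tab <- structure(list(
    name = "toy", declared_range = c(0, 5), cutoffs = list(),
    components = list(list(
      name = "only", inputs = list("anal_finding"),
      levels = list(
        list(points = 5, when = list(list(anal_finding = list("yes")))),
        list(points = 0, when = list(list(anal_finding = list("no")))))))),
    class = "endosel_dai_table")
  expect_equal(validate_scoring_table(tab), c(0, 5))
  v <- best_case_visit(); v$anal_finding <- "yes"
  expect_equal(compute_dai(v, tab)$score, 5)
})

test_that("best-case visits score zero and classify as remission", {
  v <- best_case_visit()
  for (idx in c("pcdai", "wpcdai", "shpcdai", "modpcdai")) {
    sc <- compute_dai(v, dai_scoring_table(idx))
    expect_false(sc$missing)
    expect_equal(sc$score, 0)
    expect_equal(sc$category, "remission")
  }
  mini <- compute_dai(v, dai_scoring_table("mini"))
  expect_equal(mini$score, -3)   # low calprotectin scores negative
  expect_equal(mini$category, "remission")
})

test_that("missing required inputs give missing-flagged scores (complete case per index)", {
  v <- best_case_visit(); v$albumin <- NA
  sc <- compute_dai(v, dai_scoring_table("wpcdai"))
  expect_true(sc$missing)
  expect_true(is.na(sc$score))
  expect_true("albumin" %in% sc$missing_inputs)
  # the abbreviated index has no lab inputs, so it is unaffected
  expect_false(compute_dai(v, dai_scoring_table("abbrpcdai"))$missing)
})

test_that("MINI substitutes CRP and ESR for each other but needs at least one", {
  tab <- dai_scoring_table("mini")
  v <- best_case_visit()
  both <- compute_dai(v, tab)
  v_noesr <- v; v_noesr$esr <- NA
  no_esr <- compute_dai(v_noesr, tab)
  expect_false(no_esr$missing)     # computable from FC, CRP, stools
  v_nocrp <- v; v_nocrp$crp <- NA
  expect_false(compute_dai(v_nocrp, tab)$missing)
  v_none <- v; v_none$crp <- NA; v_none$esr <- NA
  expect_true(compute_dai(v_none, tab)$missing)
  # with both markers present, both contribute
  v_hi <- v; v_hi$crp <- 30; v_hi$esr <- 60
  expect_equal(compute_dai(v_hi, tab)$score - both$score, 5 + 2)
})

test_that("classification boundaries behave exactly as published, per index", {
  eps <- 1e-9
  cls <- function(idx, s) classify_dai(s, dai_scoring_table(idx))
  # PCDAI: remission <= 10, mild 11-30, moderate-severe >= 31
  expect_equal(cls("pcdai", 10), "remission")
  expect_equal(cls("pcdai", 10 + eps), "mild")
  expect_equal(cls("pcdai", 30), "mild")
  expect_equal(cls("pcdai", 31), "moderate_severe")
  # modPCDAI: remission < 7.5, mild 7.5-10, mod-sev >= 12.5, severe > 17.5
  expect_equal(cls("modpcdai", 7.5 - eps), "remission")
  expect_equal(cls("modpcdai", 7.5), "mild")
  expect_equal(cls("modpcdai", 10), "mild")
  expect_equal(cls("modpcdai", 12.5), "moderate_severe")
  expect_equal(cls("modpcdai", 17.5), "moderate_severe")
  expect_equal(cls("modpcdai", 17.5 + eps), "severe")
  # shPCDAI: remission < 15, mild 15-30, mod-sev >= 30
  expect_equal(cls("shpcdai", 15 - eps), "remission")
  expect_equal(cls("shpcdai", 15), "mild")
  expect_equal(cls("shpcdai", 30 - eps), "mild")
  expect_equal(cls("shpcdai", 30), "moderate_severe")
  # wPCDAI: remission < 12.5, mild 12.5-40, mod-sev > 40, severe > 57.5
  expect_equal(cls("wpcdai", 12.5 - eps), "remission")
  expect_equal(cls("wpcdai", 12.5), "mild")
  expect_equal(cls("wpcdai", 40), "mild")
  expect_equal(cls("wpcdai", 40 + eps), "moderate_severe")
  expect_equal(cls("wpcdai", 57.5), "moderate_severe")
  expect_equal(cls("wpcdai", 57.5 + eps), "severe")
  # MINI: remission < 8, mild 8-11, mod-sev > 11
  expect_equal(cls("mini", 8 - eps), "remission")
  expect_equal(cls("mini", 8), "mild")
  expect_equal(cls("mini", 11), "mild")
  expect_equal(cls("mini", 11 + eps), "moderate_severe")
  # no cut-offs published for the abbreviated index
  expect_true(is.na(cls("abbrpcdai", 20)))
})

test_that("cohort-level scoring returns one row per visit with missing flags", {
  ch <- make_tiny_cohort()
  sc <- compute_dai_cohort(ch, "mini")
  expect_equal(nrow(sc), 3)
  # row 2 has missing CRP but present FC and stool data is absent ->
  # stool_quantity missing makes every MINI row missing here
  expect_true(all(sc$missing))
})
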