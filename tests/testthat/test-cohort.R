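test_that("read_cohort parses a CSV, turns blanks into missing and keeps counts", {
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(data.frame(
    patient_id = c("A", "A", "B"),
    endoscopic_score = c("1", "moderate", "4"),
    crp = c("1.5", "", "12"),
    fc = c("40", "500", "1800")), path)
  ch <- read_cohort(path)
  expect_s3_class(ch, "endosel_cohort")
  expect_equal(nrow(ch), 3)
  expect_equal(ch$endoscopic_score, c(1L, 3L, 4L))
  expect_equal(sum(is.na(ch$crp)), 1)
})

test_that("read_cohort rejects invalid outcomes and missing mandatory columns", {
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(data.frame(
    patient_id = c("A", "B"),
    endoscopic_score = c("2", "ulcerative"),
    crp = c(1, 2)), path)
  expect_error(read_cohort(path), "row.*2|2.*ulcerative")

  path2 <- tempfile(fileext = ".csv")
  write_cohort_csv(data.frame(patient_id = "A", crp = 1), path2)
  expect_error(read_cohort(path2), "endoscopic_score")
})

test_that("unparseable and non-positive lab cells become missing with a warning", {
  path <- tempfile(fileext = ".csv")
  write_cohort_csv(data.frame(
    patient_id = c("A", "B", "C"),
    endoscopic_score = c(1, 2, 3),
    crp = c("abc", "-1", "3"),
    anal_finding = c("yes", "maybe", "no")), path)
  expect_warning(expect_warning(expect_warning(
    ch <- read_cohort(path), "unparseable"), "non-positive"),
    "unknown level")
  expect_equal(sum(is.na(ch$crp)), 2)
  expect_equal(sum(is.na(ch$anal_finding)), 1)
})

test_that("log_transform takes natural logs, renames, and propagates missing", {
  ch <- make_tiny_cohort()
  lt <- log_transform(ch, vars = c("crp", "fc"))
  expect_true(all(c("log_crp", "log_fc") %in% names(lt)))
  expect_equal(lt$log_crp[1], 0)                   # CRP 1 mg/L
  expect_equal(lt$log_fc[2], log(500), tolerance = 1e-12)
  expect_equal(log(500), 6.2146081, tolerance = 1e-6)
  expect_true(is.na(lt$log_crp[2]))
})

test_that("log_transform refuses non-positive values, naming variable and row", {
  df <- data.frame(patient_id = c("A", "B"), endoscopic_score = c(1, 2),
                   crp = c(2, 1), fc = c(100, 100))
  ch <- validate_cohort(df)
  ch$crp[2] <- 0   # injected after validation
  expect_error(log_transform(ch, "crp"), "crp.*2")
})

test_that("screening excludes exactly the high-missingness and rare-category candidates", {
  ch <- make_screening_cohort()
  cands <- screen_candidates(ch, mv_rate_max = 0.20,
                             rare_level_min = 0.03)
  expect_setequal(cands$excluded$predictor,
                  c("appetite", "height_gain", "perianal_eczema", "esr"))
  expect_equal(
    cands$excluded$reason[cands$excluded$predictor == "appetite"],
    "missingness")
  expect_equal(
    cands$excluded$reason[cands$excluded$predictor == "perianal_eczema"],
    "rare-category")
  # rare but prespecified: kept through force_retain
  expect_true("abdominal_pain_night" %in% cands$retained)
  # fully observed 50/50 binary is retained
  expect_true("abdominal_pain" %in% cands$retained)
  expect_true(all(!cands$retained %in% cands$excluded$predictor))
})

test_that("screening honors manual exclusions and errors on empty retained set", {
  ch <- make_tiny_cohort()
  cands <- screen_candidates(ch, manual_exclusions = "fc")
  expect_true("fc" %in% cands$excluded$predictor)
  expect_error(
    screen_candidates(ch, manual_exclusions = c("abdominal_pain",
                                                "crp", "fc"),
                      force_retain = character()),
    "no candidate")
})

test_that("complete-case filtering drops the right rows and is idempotent", {
  ch <- make_tiny_cohort()
  cands <- screen_candidates(ch, mv_rate_max = 0.5,
                             force_retain = character())
  expect_message(cc <- complete_case_filter(ch, cands), "removed 1")
  expect_equal(nrow(cc), 2)
  expect_identical(as.data.frame(complete_case_filter(cc, cands)),
                   as.data.frame(cc))

  # 5-row fixture, 2 rows missing FC -> 3 rows
  df <- data.frame(patient_id = letters[1:5],
                   endoscopic_score = c(1, 2, 3, 4, 1),
                   fc = c(10, NA, 30, NA, 50))
  ch5 <- validate_cohort(df)
  c5 <- screen_candidates(ch5, mv_rate_max = 0.5,
                          force_retain = character())
  expect_equal(nrow(suppressMessages(complete_case_filter(ch5, c5))), 3)
})

test_that("standardization centers and scales every column with the n-1 sd", {
  df <- data.frame(patient_id = c("A", "B", "C"),
                   endoscopic_score = c(1, 2, 3),
                   fc = c(1, 2, 3), crp = c(2, 4, 8))
  ch <- validate_cohort(df)
  cands <- screen_candidates(ch, force_retain = character())
  std <- standardize(ch, cands)
  expect_equal(std$design$X[, "fc"], c(-1, 0, 1))
  expect_lt(max(abs(colMeans(std$design$X))), 1e-10)
  expect_lt(max(abs(apply(std$design$X, 2, sd) - 1)), 1e-10)
  expect_equal(std$params$table$sd[std$params$table$column == "fc"],
               sd(c(1, 2, 3)))
})

test_that("standardization errors on constant columns", {
  df <- data.frame(patient_id = c("A", "B", "C"),
                   endoscopic_score = c(1, 2, 3),
                   fc = c(5, 5, 5))
  ch <- validate_cohort(df)
  cands <- screen_candidates(ch, force_retain = character())
  expect_error(standardize(ch, cands), "zero-variance.*fc")
})

test_that("standardization round-trips raw values exactly", {
  rd <- make_recovery_design(seed = 3, n_patients = 30)
  x <- c(log_crp = log(7.3), log_fc = log(412.5))
  z <- standardize_apply(rd$params, x)
  back <- standardize_invert(rd$params, z)
  expect_equal(back, x, tolerance = 1e-12)
  # inverse of apply on a design column reproduces the column
  col <- rd$design$X[, "log_fc"]
  raw <- standardize_invert(rd$params,
                            setNames(as.data.frame(col), "log_fc"))
  z2 <- standardize_apply(rd$params, raw)
  expect_equal(z2$log_fc, col, tolerance = 1e-12)
})
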