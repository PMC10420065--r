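#' Default visit-level cohort schema
#'
#' Describes the columns of a visit-level cohort table: the patient
#' identifier, the four-level endoscopic score, the categorical clinical
#' findings recorded at each visit, and the laboratory values with their
#' units. The schema drives CSV parsing ([read_cohort()]), candidate
#' screening and design-matrix construction.
#'
#' Categorical levels use short machine-readable codes; e.g. stool
#' quantity is `"le3"` / `"gt3"` (at most vs. more than 3 stools per
#' 24 h) and weight gain is `"voluntary"` (weight gain or voluntary
#' stable weight/loss) vs `"involuntary"` (involuntary stable weight or
#' weight loss).
#'
#' @param path optional path to a YAML file overriding the built-in
#'   schema; the file must have the same structure as the return value.
#' @return A named list, one entry per column, each with a `type`
#'   (`"id"`, `"outcome"`, `"categorical"` or `"continuous"`) plus
#'   `levels` (categorical) or `unit` (continuous).
#' @export
cohort_schema <- function(path = NULL) {
  if (!is.null(path)) {
    .stop_if(!file.exists(path), "schema file not found: ", path)
    return(yaml::read_yaml(path))
  }
  cat2 <- function(...) list(type = "categorical", levels = c(...))
  cont <- function(unit) list(type = "continuous", unit = unit)
  list(
    patient_id          = list(type = "id"),
    endoscopic_score    = list(type = "outcome",
                               levels = c("remission", "mild",
                                          "moderate", "severe")),
    abdominal_pain       = cat2("no", "yes"),
    abdominal_pain_night = cat2("no", "yes"),
    abdominal_finding    = cat2("without_findings", "with_findings"),
    pressure_pain        = cat2("no", "yes"),
    resistance           = cat2("no", "yes"),
    anal_finding         = cat2("no", "yes"),
    appetite             = cat2("good", "reduced", "poor"),
    activity_limitation  = cat2("no", "yes"),
    ibd_clinic           = cat2("center_a", "center_b"),
    condition            = cat2("good", "reduced_poor"),
    extraintestinal      = cat2("no", "yes"),
    height_gain          = cat2("yes", "no"),
    perianal_eczema      = cat2("no", "yes"),
    stool_blood          = cat2("no", "yes"),
    stool_consistency    = cat2("formed", "semi_formed_liquid"),
    stool_quantity       = cat2("le3", "gt3"),
    weight_gain          = cat2("voluntary", "involuntary"),
    albumin     = cont("g/L"),
    crp         = cont("mg/L"),
    hematocrit  = cont("fraction"),
    hemoglobin  = cont("g/dL"),
    mcv         = cont("fL"),
    platelets   = cont("1e9/L"),
    leukocytes  = cont("1e9/L"),
    fc          = cont("mg/kg"),
    esr         = cont("mm/h")
  )
}

.schema_fields <- function(schema, type) {
  names(schema)[vapply(schema, function(s) s$type, "") %in% type]
}

.new_cohort <- function(df, schema) {
  structure(df, class = c("endosel_cohort", "data.frame"), schema = schema)
}

#' Read and validate a visit-level cohort CSV
#'
#' Reads a comma-separated, UTF-8 table (decimal point `"."`; missing
#' values encoded as empty cells or `"NA"`) and validates it against a
#' [cohort_schema()]. `patient_id` and `endoscopic_score` are mandatory
#' and must be valid in every row; any other cell that cannot be parsed
#' (non-numeric text in a lab column, an unknown category code, a
#' non-positive lab value) is converted to missing with a warning.
#'
#' The endoscopic score may be coded `1..4` or with the labels
#' `remission`/`mild`/`moderate`/`severe`; it is stored as an integer.
#'
#' @param path path to the CSV file.
#' @param schema column specification, see [cohort_schema()].
#' @return An `endosel_cohort` data frame (one row per visit).
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  .stop_if(!file.exists(path), "cohort file not found: ", path)
  raw <- read.csv(path, colClasses = "character",
                  na.strings = c("", "NA"), check.names = FALSE,
                  fileEncoding = "UTF-8")
  .stop_if(!all(c("patient_id", "endoscopic_score") %in% names(raw)),
           "mandatory columns missing: ",
           paste(setdiff(c("patient_id", "endoscopic_score"), names(raw)),
                 collapse = ", "))
  unknown <- setdiff(names(raw), names(schema))
  if (length(unknown))
    warning("ignoring columns not in schema: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  raw <- raw[intersect(names(schema), names(raw))]
  validate_cohort(raw, schema)
}

#' Validate an in-memory visit table against a schema
#'
#' The workhorse behind [read_cohort()]; useful for tables built in code
#' (e.g. simulated cohorts).
#'
#' @param df data frame with character or typed columns.
#' @inheritParams read_cohort
#' @return An `endosel_cohort` data frame.
#' @export
validate_cohort <- function(df, schema = cohort_schema()) {
  n <- nrow(df)
  .stop_if(n == 0L, "cohort table has no rows")

  pid <- as.character(df$patient_id)
  bad <- which(is.na(pid) | !nzchar(pid))
  .stop_if(length(bad) > 0,
           "patient_id missing/empty in row(s): ",
           paste(head(bad, 5), collapse = ", "))

  out <- .parse_outcome(df$endoscopic_score,
                        schema$endoscopic_score$levels)

  res <- data.frame(patient_id = pid, endoscopic_score = out,
                    stringsAsFactors = FALSE)
  for (nm in setdiff(names(schema), c("patient_id", "endoscopic_score"))) {
    if (!nm %in% names(df)) next
    spec <- schema[[nm]]
    x <- df[[nm]]
    if (spec$type == "continuous") {
      xc <- suppressWarnings(as.numeric(as.character(x)))
      bad <- !is.na(x) & is.na(xc)
      if (any(bad))
        warning(sum(bad), " unparseable value(s) in '", nm,
                "' treated as missing", call. = FALSE)
      nonpos <- !is.na(xc) & xc <= 0
      if (any(nonpos)) {
        warning(sum(nonpos), " non-positive value(s) in '", nm,
                "' treated as missing", call. = FALSE)
        xc[nonpos] <- NA_real_
      }
      res[[nm]] <- xc
    } else {
      xc <- as.character(x)
      bad <- !is.na(xc) & !(xc %in% spec$levels)
      if (any(bad)) {
        warning(sum(bad), " unknown level(s) in '", nm,
                "' treated as missing (e.g. \"", xc[which(bad)[1]],
                "\")", call. = FALSE)
        xc[bad] <- NA_character_
      }
      res[[nm]] <- xc
    }
  }
  .new_cohort(res, schema)
}

.parse_outcome <- function(x, levels) {
  xc <- as.character(x)
  out <- suppressWarnings(as.integer(xc))
  lab <- match(tolower(xc), levels)
  out[is.na(out)] <- lab[is.na(out)]
  bad <- which(is.na(out) | !(out %in% 1:4))
  .stop_if(length(bad) > 0,
           "invalid endoscopic_score in row(s) ",
           paste(head(bad, 5), collapse = ", "),
           " (e.g. \"", xc[bad[1]], "\"); expected 1..4 or ",
           paste(levels, collapse = "/"))
  as.integer(out)
}

#' Natural-log transform right-skewed laboratory variables
#'
#' CRP, platelets, leukocytes and fecal calprotectin have strongly
#' right-skewed distributions and enter the model on the natural-log
#' scale. Transformed columns are renamed with a `log_` prefix; missing
#' values stay missing.
#'
#' @param cohort an `endosel_cohort`.
#' @param vars names of continuous columns to transform.
#' @return The cohort with transformed, renamed columns.
#' @export
log_transform <- function(cohort,
                          vars = c("crp", "platelets", "leukocytes", "fc")) {
  schema <- attr(cohort, "schema")
  vars <- intersect(vars, names(cohort))
  for (v in vars) {
    .stop_if(!identical(schema[[v]]$type, "continuous"),
             "'", v, "' is not a continuous variable")
    x <- cohort[[v]]
    bad <- which(!is.na(x) & x <= 0)
    .stop_if(length(bad) > 0,
             "non-positive value in '", v, "' at row(s) ",
             paste(head(bad, 5), collapse = ", "),
             "; cannot log-transform")
    cohort[[v]] <- log(x)
    nm <- paste0("log_", v)
    names(cohort)[names(cohort) == v] <- nm
    schema[[nm]] <- schema[[v]]
    schema[[nm]]$unit <- paste0("log(", schema[[v]]$unit, ")")
    schema[[v]] <- NULL
  }
  attr(cohort, "schema") <- schema
  attr(cohort, "log_vars") <- union(attr(cohort, "log_vars"), vars)
  cohort
}

#' Screen candidate predictors by missingness and rare categories
#'
#' A candidate predictor is excluded when its missingness rate exceeds
#' `mv_rate_max`, when (for a categorical) any level's observed relative
#' frequency falls below `rare_level_min`, or when it is listed in
#' `manual_exclusions`. Variables in `force_retain` are kept regardless
#' (used for rare-but-prespecified clinical findings such as nocturnal
#' abdominal pain).
#'
#' @param cohort an `endosel_cohort`.
#' @param mv_rate_max maximal tolerated missingness rate, in (0, 1).
#' @param rare_level_min minimal tolerated level frequency, in (0, 1).
#' @param manual_exclusions predictor names to exclude by fiat.
#' @param force_retain predictor names exempt from the screening rules.
#' @return An `endosel_candidates` object: `retained` (character vector)
#'   and `excluded` (data frame with columns `predictor`, `reason`,
#'   `detail`).
#' @export
screen_candidates <- function(cohort, mv_rate_max = 0.20,
                              rare_level_min = 0.03,
                              manual_exclusions = character(),
                              force_retain = "abdominal_pain_night") {
  .stop_if(mv_rate_max <= 0 || mv_rate_max >= 1,
           "mv_rate_max must be in (0, 1)")
  .stop_if(rare_level_min <= 0 || rare_level_min >= 1,
           "rare_level_min must be in (0, 1)")
  schema <- attr(cohort, "schema")
  cand <- setdiff(names(cohort), c("patient_id", "endoscopic_score"))
  n <- nrow(cohort)
  excl <- list()
  retained <- character()
  for (v in cand) {
    if (v %in% manual_exclusions) {
      excl[[v]] <- c("manual", "listed in manual_exclusions")
      next
    }
    if (v %in% force_retain) { retained <- c(retained, v); next }
    mv <- mean(is.na(cohort[[v]]))
    if (mv > mv_rate_max) {
      excl[[v]] <- c("missingness", sprintf("missing rate %.2f", mv))
      next
    }
    if (identical(schema[[v]]$type, "categorical")) {
      x <- cohort[[v]][!is.na(cohort[[v]])]
      freq <- table(factor(x, levels = schema[[v]]$levels)) / length(x)
      if (any(freq < rare_level_min)) {
        lv <- names(freq)[which.min(freq)]
        excl[[v]] <- c("rare-category",
                       sprintf("level '%s' frequency %.3f", lv, min(freq)))
        next
      }
    }
    retained <- c(retained, v)
  }
  .stop_if(length(retained) == 0L, "no candidate predictors retained")
  excluded <- if (length(excl)) {
    data.frame(predictor = names(excl),
               reason = vapply(excl, `[`, "", 1),
               detail = vapply(excl, `[`, "", 2),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(predictor = character(), reason = character(),
               detail = character(), stringsAsFactors = FALSE)
  }
  structure(list(retained = retained, excluded = excluded),
            class = "endosel_candidates")
}

#' @export
print.endosel_candidates <- function(x, ...) {
  cat("Candidate screen:", length(x$retained), "retained,",
      nrow(x$excluded), "excluded\n")
  cat("retained:", paste(x$retained, collapse = ", "), "\n")
  if (nrow(x$excluded)) {
    cat("excluded:\n")
    for (i in seq_len(nrow(x$excluded)))
      cat(sprintf("  %-22s %-12s %s\n", x$excluded$predictor[i],
                  x$excluded$reason[i], x$excluded$detail[i]))
  }
  invisible(x)
}

#' Keep only visits with complete data on retained predictors
#'
#' A regression model needs non-missing values for the outcome and every
#' retained predictor, so visits with any missing modeled value are
#' dropped (complete-case analysis; no imputation).
#'
#' @param cohort an `endosel_cohort`.
#' @param candidates an `endosel_candidates` from [screen_candidates()].
#' @return The filtered cohort; the number of removed visits is reported
#'   via `message()`.
#' @export
complete_case_filter <- function(cohort, candidates) {
  .stop_if(!inherits(candidates, "endosel_candidates"),
           "candidates must come from screen_candidates()")
  cols <- c("endoscopic_score", intersect(candidates$retained,
                                          names(cohort)))
  keep <- complete.cases(cohort[cols])
  .stop_if(!any(keep), "no visits remain after complete-case filtering")
  removed <- sum(!keep)
  if (removed > 0)
    message("complete_case_filter: removed ", removed, " of ",
            nrow(cohort), " visits with missing values")
  out <- cohort[keep, , drop = FALSE]
  rownames(out) <- NULL
  .new_cohort(out, attr(cohort, "schema"))
}

#' Build a standardized design matrix from a complete-case cohort
#'
#' Categorical predictors are dummy-encoded with the most frequent level
#' as reference; every resulting column (continuous and dummy alike, as
#' the regularized horseshoe prior recommendation assumes) is centered to
#' mean zero and scaled to unit standard deviation using the sample
#' (n-1 denominator) standard deviation. The standardization parameters
#' are returned so new raw measurements can be scored later.
#'
#' @param cohort a complete-case `endosel_cohort` (see
#'   [complete_case_filter()]).
#' @param candidates an `endosel_candidates`.
#' @return A list with `design` (`endosel_design`: standardized matrix
#'   `X`, outcome `y`, `patient` grouping vector, `terms` mapping
#'   predictor terms to columns) and `params`
#'   (`endosel_standardization`).
#' @export
standardize <- function(cohort, candidates) {
  schema <- attr(cohort, "schema")
  vars <- intersect(candidates$retained, names(cohort))
  .stop_if(any(is.na(cohort[vars])),
           "cohort has missing values; run complete_case_filter() first")
  cols <- list()
  meta <- list()
  terms <- list()
  for (v in vars) {
    spec <- schema[[v]]
    if (identical(spec$type, "continuous")) {
      cols[[v]] <- as.numeric(cohort[[v]])
      meta[[v]] <- list(column = v, source = v, level = NA_character_)
      terms[[v]] <- v
    } else {
      tab <- table(factor(cohort[[v]], levels = spec$levels))
      ref <- names(tab)[which.max(tab)]
      others <- setdiff(spec$levels, ref)
      cn <- if (length(others) == 1L) v else paste(v, others, sep = ".")
      for (k in seq_along(others)) {
        cols[[cn[k]]] <- as.numeric(cohort[[v]] == others[k])
        meta[[cn[k]]] <- list(column = cn[k], source = v,
                              level = others[k], reference = ref)
      }
      terms[[v]] <- cn
    }
  }
  X <- do.call(cbind, cols)
  mu <- colMeans(X)
  sds <- apply(X, 2, sd)
  zero <- which(sds == 0 | !is.finite(sds))
  .stop_if(length(zero) > 0, "zero-variance column(s): ",
           paste(colnames(X)[zero], collapse = ", "))
  Xs <- sweep(sweep(X, 2, mu), 2, sds, "/")
  params <- structure(
    list(table = data.frame(column = colnames(X), mean = mu, sd = sds,
                            source = vapply(meta, function(m) m$source, ""),
                            level = vapply(meta, function(m) m$level, ""),
                            row.names = NULL, stringsAsFactors = FALSE),
         log_vars = attr(cohort, "log_vars") %||% character()),
    class = "endosel_standardization")
  design <- structure(
    list(X = Xs, y = cohort$endoscopic_score,
         patient = as.character(cohort$patient_id),
         terms = terms,
         outcome_levels = schema$endoscopic_score$levels),
    class = "endosel_design")
  list(design = design, params = params)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply or invert stored standardization parameters
#'
#' `standardize_apply()` maps raw model-scale values (already
#' log-transformed where applicable) to standardized scores;
#' `standardize_invert()` maps back. Round-tripping is exact to machine
#' precision.
#'
#' @param params an `endosel_standardization`.
#' @param values named numeric vector or data frame whose names are
#'   standardized design columns.
#' @return Numeric vector/data frame of the same shape.
#' @export
standardize_apply <- function(params, values) {
  tb <- params$table
  nm <- if (is.data.frame(values)) names(values) else names(values)
  idx <- match(nm, tb$column)
  .stop_if(anyNA(idx), "unknown column(s): ",
           paste(nm[is.na(idx)], collapse = ", "))
  if (is.data.frame(values)) {
    for (j in seq_along(nm))
      values[[j]] <- (values[[j]] - tb$mean[idx[j]]) / tb$sd[idx[j]]
    values
  } else {
    (values - tb$mean[idx]) / tb$sd[idx]
  }
}

#' @rdname standardize_apply
#' @export
standardize_invert <- function(params, values) {
  tb <- params$table
  nm <- names(values)
  idx <- match(nm, tb$column)
  .stop_if(anyNA(idx), "unknown column(s): ",
           paste(nm[is.na(idx)], collapse = ", "))
  if (is.data.frame(values)) {
    for (j in seq_along(nm))
      values[[j]] <- values[[j]] * tb$sd[idx[j]] + tb$mean[idx[j]]
    values
  } else {
    values * tb$sd[idx] + tb$mean[idx]
  }
}

#' @export
print.endosel_design <- function(x, ...) {
  cat("endosel design matrix:", nrow(x$X), "visits x", ncol(x$X),
      "columns;", length(unique(x$patient)), "patients\n")
  invisible(x)
}
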