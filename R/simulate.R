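#' Configuration for the synthetic cohort generator
#'
#' Defines the study conditions the generator emulates: roughly 109
#' patients contributing 1-4 visits each (about 167 visits in total),
#' outcome marginals heavily weighted towards moderate/severe disease,
#' right-skewed log-normal CRP and fecal calprotectin with CRP assay
#' detection floors, binary/categorical clinical findings at their
#' observed frequencies, per-variable missing-completely-at-random
#' rates, and a true outcome model in which (by default) only log CRP
#' and log FC carry signal, plus a patient-level random intercept.
#'
#' `beta_true` is expressed on the standardized-predictor scale (the
#' scale on which the model is fitted); names refer to design columns
#' (`log_crp`, `log_fc`, binary categoricals by their variable name,
#' multi-level categoricals as `var.level`).
#'
#' @param n_patients number of patients.
#' @param visit_rate extra-visit rate: visits per patient are
#'   `1 + Poisson(visit_rate)` (default 0.53, so the expected total visit
#'   count for 109 patients is about 167).
#' @param beta_true named numeric vector of true standardized
#'   coefficients; unnamed candidates have coefficient zero.
#' @param sigma_b standard deviation of the patient random intercept.
#' @param thresholds optional 3 increasing latent thresholds; when
#'   `NULL` they are calibrated to `target_marginals` at simulation time
#'   via [calibrate_thresholds()].
#' @param target_marginals length-4 probability vector of outcome
#'   marginals (default: the skewed remission/mild/moderate/severe mix
#'   of the target population, 7.8/4.8/37.1/50.3%).
#' @param labs named list of lab generators, each
#'   `list(log = TRUE/FALSE, mean, sd)` on the model (possibly log)
#'   scale.
#' @param categoricals named list of categorical generators, each
#'   `list(levels, probs)`.
#' @param missingness named per-variable MCAR missingness rates in
#'   `[0, 1)`.
#' @param crp_floors named assay detection floors (mg/L) per IBD center;
#'   a visit's CRP is left-censored at its center's floor.
#' @param lab_correlation optional correlation matrix (named rows and
#'   columns over continuous labs, model scale) inducing lab-lab
#'   correlation; `NULL` (the default) draws labs independently, which
#'   keeps recovery tests clean.
#' @return An `endosel_simconfig` list.
#' @export
simulation_config <- function(n_patients = 109,
                              visit_rate = 0.53,
                              beta_true = c(log_crp = 0.9, log_fc = 1.1),
                              sigma_b = 0.8,
                              thresholds = NULL,
                              target_marginals = c(0.078, 0.048,
                                                   0.371, 0.503),
                              labs = default_lab_generators(),
                              categoricals = default_categorical_generators(),
                              missingness = default_missingness_rates(),
                              crp_floors = c(center_a = 0.6, center_b = 1.0),
                              lab_correlation = NULL) {
  .stop_if(n_patients < 1, "n_patients must be positive")
  .stop_if(sigma_b < 0, "sigma_b must be non-negative")
  .stop_if(any(missingness < 0) || any(missingness >= 1),
           "missingness rates must be in [0, 1)")
  if (!is.null(thresholds)) {
    .stop_if(length(thresholds) != 3 || any(diff(thresholds) <= 0),
             "thresholds must be 3 strictly increasing values")
  }
  target_marginals <- target_marginals / sum(target_marginals)
  structure(list(n_patients = n_patients, visit_rate = visit_rate,
                 beta_true = beta_true, sigma_b = sigma_b,
                 thresholds = thresholds,
                 target_marginals = target_marginals,
                 labs = labs, categoricals = categoricals,
                 missingness = missingness, crp_floors = crp_floors,
                 lab_correlation = lab_correlation),
            class = "endosel_simconfig")
}

#' @rdname simulation_config
#' @export
default_lab_generators <- function() {
  list(
    log_crp        = list(log = TRUE,  mean = log(5),   sd = 1.0),
    log_fc         = list(log = TRUE,  mean = log(300), sd = 1.2),
    albumin        = list(log = FALSE, mean = 38,   sd = 5),
    hematocrit     = list(log = FALSE, mean = 0.36, sd = 0.05),
    hemoglobin     = list(log = FALSE, mean = 12.5, sd = 1.8),
    mcv            = list(log = FALSE, mean = 82,   sd = 6),
    log_platelets  = list(log = TRUE,  mean = log(350), sd = 0.30),
    log_leukocytes = list(log = TRUE,  mean = log(8),   sd = 0.35),
    log_esr        = list(log = TRUE,  mean = log(15),  sd = 0.7)
  )
}

#' @rdname simulation_config
#' @export
default_categorical_generators <- function() {
  g <- function(levels, probs) list(levels = levels, probs = probs)
  yn <- function(p_yes) g(c("no", "yes"), c(1 - p_yes, p_yes))
  list(
    abdominal_pain       = yn(88 / 164),
    abdominal_pain_night = yn(3 / 165),
    abdominal_finding    = g(c("without_findings", "with_findings"),
                             c(123, 42) / 165),
    pressure_pain        = yn(130 / 165),
    resistance           = yn(21 / 165),
    anal_finding         = yn(16 / 165),
    appetite             = g(c("good", "reduced", "poor"),
                             c(76, 19, 15) / 110),
    activity_limitation  = yn(70 / 155),
    ibd_clinic           = g(c("center_a", "center_b"), c(58, 109) / 167),
    condition            = g(c("good", "reduced_poor"), c(106, 58) / 164),
    extraintestinal      = yn(15 / 165),
    height_gain          = g(c("yes", "no"), c(159, 4) / 163),
    perianal_eczema      = yn(4 / 165),
    stool_blood          = yn(37 / 159),
    stool_consistency    = g(c("formed", "semi_formed_liquid"),
                             c(63, 95) / 158),
    stool_quantity       = g(c("le3", "gt3"), c(127, 25) / 152),
    weight_gain          = g(c("voluntary", "involuntary"), c(103, 62) / 165)
  )
}

#' @rdname simulation_config
#' @export
default_missingness_rates <- function() {
  c(abdominal_pain = 3 / 167, abdominal_pain_night = 3 / 167,
    abdominal_finding = 2 / 167, pressure_pain = 2 / 167,
    resistance = 2 / 167, anal_finding = 2 / 167,
    appetite = 57 / 167, activity_limitation = 12 / 167,
    ibd_clinic = 0, condition = 3 / 167, extraintestinal = 2 / 167,
    height_gain = 4 / 167, perianal_eczema = 2 / 167,
    stool_blood = 8 / 167, stool_consistency = 9 / 167,
    stool_quantity = 15 / 167, weight_gain = 2 / 167,
    albumin = 0.02, crp = 0.02, hematocrit = 0.02, hemoglobin = 0.02,
    mcv = 0.02, platelets = 0.02, leukocytes = 0.02,
    fc = 0.12, esr = 0.60)
}

# Draw one visit-level predictor table on the model scale (labs stay on
# the possibly-log scale) together with its population-standardized
# signal columns.
.draw_predictors <- function(config, n) {
  labs <- config$labs
  lab_draws <- matrix(rnorm(n * length(labs)), n, length(labs))
  colnames(lab_draws) <- names(labs)
  if (!is.null(config$lab_correlation)) {
    Rn <- config$lab_correlation
    idx <- match(colnames(Rn), names(labs))
    .stop_if(anyNA(idx), "lab_correlation names must be lab names")
    L <- chol(Rn)
    lab_draws[, colnames(Rn)] <- lab_draws[, colnames(Rn)] %*% L
  }
  lab_vals <- lab_draws
  for (v in names(labs))
    lab_vals[, v] <- labs[[v]]$mean + labs[[v]]$sd * lab_draws[, v]

  cats <- lapply(config$categoricals, function(g)
    sample(g$levels, n, replace = TRUE, prob = g$probs))
  list(labs = lab_vals, cats = as.data.frame(cats,
                                             stringsAsFactors = FALSE))
}

# Standardized (population moments) value of each named coefficient.
.standardized_signal <- function(config, drawn, coef_names) {
  out <- matrix(0, nrow(drawn$labs), length(coef_names),
                dimnames = list(NULL, coef_names))
  for (nm in coef_names) {
    if (nm %in% colnames(drawn$labs)) {
      g <- config$labs[[nm]]
      out[, nm] <- (drawn$labs[, nm] - g$mean) / g$sd
    } else {
      # categorical dummy: "var" for binary, "var.level" otherwise
      var <- nm; level <- NULL
      if (grepl(".", nm, fixed = TRUE)) {
        var <- sub("\\.[^.]*$", "", nm)
        level <- sub("^.*\\.", "", nm)
      }
      g <- config$categoricals[[var]]
      .stop_if(is.null(g), "unknown coefficient name: ", nm)
      if (is.null(level)) level <- g$levels[which.min(g$probs)]
      p <- g$probs[match(level, g$levels)]
      out[, nm] <- (as.numeric(drawn$cats[[var]] == level) - p) /
        sqrt(p * (1 - p))
    }
  }
  out
}

.simulate_eta <- function(config, n) {
  drawn <- .draw_predictors(config, n)
  beta <- config$beta_true
  eta <- rep(0, n)
  if (length(beta) && any(beta != 0)) {
    Z <- .standardized_signal(config, drawn, names(beta))
    eta <- drop(Z %*% beta)
  }
  if (config$sigma_b > 0)
    eta <- eta + rnorm(n, 0, config$sigma_b)
  list(eta = eta, drawn = drawn)
}

#' Calibrate latent thresholds to target outcome marginals
#'
#' Finds thresholds `tau` such that, under the configured predictor and
#' random-intercept distributions, the marginal outcome probabilities of
#' the cumulative-logit model match `target_marginals`. Each threshold
#' solves `E[plogis(tau_k - eta)] = cumulative target k` by root-finding
#' on a large Monte-Carlo sample of the latent predictor `eta`.
#'
#' @param target_marginals length-4 vector of positive probabilities
#'   (normalized internally).
#' @param config an `endosel_simconfig`.
#' @param n_mc Monte-Carlo sample size for the `eta` distribution.
#' @return Strictly increasing numeric vector of 3 thresholds.
#' @export
calibrate_thresholds <- function(target_marginals, config, n_mc = 2e5) {
  .stop_if(length(target_marginals) != 4,
           "target_marginals must have length 4")
  .stop_if(any(target_marginals <= 0),
           "target probabilities must be strictly positive")
  tg <- target_marginals / sum(target_marginals)
  cum <- cumsum(tg)[1:3]
  .stop_if(any(diff(c(0, cum, 1)) <= 0),
           "cumulative targets must be strictly increasing")
  eta <- .simulate_eta(config, n_mc)$eta
  if (all(eta == 0)) return(qlogis(cum))
  vapply(cum, function(ck)
    uniroot(function(tau) mean(plogis(tau - eta)) - ck,
            lower = min(eta) - 40, upper = max(eta) + 40,
            tol = 1e-10)$root,
    0)
}

#' Simulate a seeded synthetic cohort
#'
#' Generates a visit-level cohort with the configured structure: per
#' visit, predictors are drawn, the latent predictor
#' `eta = x_std' beta_true + b_patient` is formed against
#' population-standardized predictors, the ordinal outcome is drawn from
#' the cumulative-logit distribution with the (possibly calibrated)
#' thresholds, CRP is left-censored at its center's assay floor, and
#' missingness is applied completely at random per variable. The same
#' seed always reproduces the identical cohort.
#'
#' @param config an `endosel_simconfig`.
#' @param seed integer seed.
#' @return An `endosel_simcohort` list: `cohort` (an `endosel_cohort` on
#'   the raw scale, ready for [log_transform()]) and `truth` (true
#'   coefficients, thresholds, patient intercepts, latent predictor,
#'   pre-censoring CRP, thresholds used, seed).
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1) {
  .stop_if(!inherits(config, "endosel_simconfig"),
           "config must come from simulation_config()")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  npat <- config$n_patients
  nv <- 1L + rpois(npat, config$visit_rate)
  pid <- sprintf("P%03d", seq_len(npat))
  patient <- rep(pid, nv)
  n <- length(patient)
  b <- rnorm(npat, 0, config$sigma_b)
  names(b) <- pid

  sim <- .simulate_eta_with_b(config, n, b[patient])
  tau <- config$thresholds %||%
    calibrate_thresholds(config$target_marginals, config)

  cum <- vapply(tau, function(t) plogis(t - sim$eta), numeric(n))
  u <- runif(n)
  y <- 1L + rowSums(u > cum)

  df <- data.frame(patient_id = patient, endoscopic_score = y,
                   stringsAsFactors = FALSE)
  df <- cbind(df, sim$drawn$cats)

  # back-transform labs to the raw scale used in cohort CSVs
  raw_name <- function(v) sub("^log_", "", v)
  lab_raw <- sim$drawn$labs
  for (v in colnames(lab_raw))
    if (isTRUE(config$labs[[v]]$log)) lab_raw[, v] <- exp(lab_raw[, v])
  colnames(lab_raw) <- vapply(colnames(lab_raw), raw_name, "")
  crp_precensor <- lab_raw[, "crp"]
  floors <- config$crp_floors[df$ibd_clinic]
  lab_raw[, "crp"] <- pmax(lab_raw[, "crp"], floors)
  df <- cbind(df, as.data.frame(lab_raw))

  for (v in names(config$missingness)) {
    r <- config$missingness[[v]]
    if (r > 0 && v %in% names(df))
      df[[v]][runif(n) < r] <- NA
  }

  cohort <- suppressWarnings(validate_cohort(df))
  structure(list(cohort = cohort,
                 truth = list(beta_true = config$beta_true,
                              thresholds = tau,
                              sigma_b = config$sigma_b, b = b,
                              eta = sim$eta, y = y,
                              crp_precensor = crp_precensor,
                              crp_floor = unname(floors),
                              seed = seed)),
            class = "endosel_simcohort")
}

.simulate_eta_with_b <- function(config, n, b_visit) {
  drawn <- .draw_predictors(config, n)
  beta <- config$beta_true
  eta <- rep(0, n)
  if (length(beta) && any(beta != 0)) {
    Z <- .standardized_signal(config, drawn, names(beta))
    eta <- drop(Z %*% beta)
  }
  list(eta = eta + b_visit, drawn = drawn)
}

#' Write a simulated cohort to disk
#'
#' Writes the cohort as a CSV in the same schema [read_cohort()]
#' expects (missing values as empty cells) plus a JSON sidecar with
#' the ground truth (true coefficients, thresholds, patient
#' intercepts, pre-censoring CRP, seed).
#'
#' @param sim an `endosel_simcohort`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_simulated_cohort <- function(sim, dir) {
  .stop_if(!inherits(sim, "endosel_simcohort"),
           "sim must come from simulate_cohort()")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(sim$cohort), file.path(dir, "cohort.csv"),
            row.names = FALSE, na = "")
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.endosel_simcohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$cohort), "visits,",
      length(unique(x$cohort$patient_id)), "patients (seed ",
      x$truth$seed, ")\n", sep = " ")
  tab <- table(factor(x$cohort$endoscopic_score, 1:4))
  cat("outcome marginals:",
      paste(sprintf("%.1f%%", 100 * tab / sum(tab)), collapse = " "), "\n")
  invisible(x)
}
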