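# Shared fixtures built in code.

# Minimal raw cohort with controllable missingness, valid against the
# default schema.
make_tiny_cohort <- function() {
  df <- data.frame(
    patient_id = c("A", "A", "B"),
    endoscopic_score = c(1, 3, 4),
    abdominal_pain = c("no", "yes", "yes"),
    crp = c(1, NA, 12),
    fc = c(40, 500, 1800),
    stringsAsFactors = FALSE)
  validate_cohort(df)
}

# A cohort whose per-variable missingness and level frequencies follow
# the documented screening fixture: appetite 34% missing, perianal
# eczema 'yes' at 2%, height gain 'no' at 2%, ESR 60% missing,
# nocturnal abdominal pain 'yes' at 2%.
make_screening_cohort <- function(n = 200) {
  set.seed(99)
  lvl <- function(p_yes) sample(c("no", "yes"), n, TRUE,
                                c(1 - p_yes, p_yes))
  df <- data.frame(
    patient_id = sprintf("P%03d", seq_len(n)),
    endoscopic_score = sample(1:4, n, TRUE),
    abdominal_pain = lvl(0.5),
    abdominal_pain_night = c(rep("yes", 4), rep("no", n - 4)),
    perianal_eczema = c(rep("yes", 4), rep("no", n - 4)),
    height_gain = c(rep("no", 4), rep("yes", n - 4)),
    appetite = c(rep(NA, round(0.34 * n)),
                 sample(c("good", "reduced", "poor"),
                        n - round(0.34 * n), TRUE, c(0.6, 0.2, 0.2))),
    crp = exp(rnorm(n, log(5), 1)),
    fc = exp(rnorm(n, log(300), 1)),
    esr = c(rep(NA, round(0.6 * n)),
            exp(rnorm(n - round(0.6 * n), log(15), 0.5))),
    stringsAsFactors = FALSE)
  validate_cohort(df)
}

# Hand-built posterior draws with known values for oracle tests.
make_fixed_draws <- function(S = 4, p = 3, seed = 1) {
  set.seed(seed)
  beta <- matrix(rnorm(S * p), S, p,
                 dimnames = list(NULL, paste0("x", seq_len(p))))
  tau <- t(apply(matrix(rnorm(S * 3), S, 3), 1, sort))
  colnames(tau) <- paste0("tau", 1:3)
  structure(list(beta = beta, tau = tau, chain_id = rep(1:2, each = S / 2),
                 n_chains = 2, n_iter = S / 2,
                 predictors = colnames(beta)),
            class = "endosel_draws")
}

# Small standardized design with a known two-signal truth, fitted
# quickly; shared across model-level tests.
make_recovery_design <- function(seed = 7, n_patients = 98) {
  miss0 <- default_missingness_rates(); miss0[] <- 0
  cfg <- simulation_config(n_patients = n_patients, missingness = miss0)
  sim <- simulate_cohort(cfg, seed = seed)
  ch <- log_transform(sim$cohort)
  cands <- screen_candidates(ch)
  cc <- complete_case_filter(ch, cands)
  std <- standardize(cc, cands)
  list(design = std$design, params = std$params, sim = sim,
       candidates = cands)
}

# One cached short reference fit reused by several expensive tests.
cached_fit <- local({
  env <- new.env()
  function() {
    if (is.null(env$fit)) {
      env$rd <- make_recovery_design(seed = 7)
      env$fit <- suppressWarnings(
        fit_reference(env$rd$design, chains = 2, adapt = 400,
                      warmup = 300, iter = 3600, thin = 6, seed = 11,
                      check = FALSE))
    }
    list(fit = env$fit, rd = env$rd)
  }
})

write_cohort_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, na = "")
  path
}
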