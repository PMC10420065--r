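#' Run the full selection pipeline end to end
#'
#' Convenience driver chaining the whole workflow: obtain a cohort
#' (from a CSV or the synthetic generator), log-transform skewed labs,
#' screen candidates, filter to complete cases, standardize, fit the
#' reference model, run the forward search, suggest the submodel size,
#' finalize the SESM, score and compare the six disease activity
#' indices, and (optionally) write the artifacts to `out_dir`:
#' `curve.csv`, `ranking.json`, `sesm.json`, `dai_comparison.csv` and
#' a `run_info.json` with seeds and settings.
#'
#' @param cohort an `endosel_cohort` on the raw scale, or `NULL` to
#'   simulate one from `sim_config`.
#' @param sim_config `endosel_simconfig` used when `cohort` is `NULL`.
#' @param seed master seed (simulation and MCMC seeds derive from it).
#' @param out_dir optional output directory.
#' @param mv_rate_max,rare_level_min screening thresholds.
#' @param max_size forward-search depth.
#' @param fit_args list of MCMC arguments for [fit_reference()].
#' @param cv assemble the held-out performance curve via [cv_ranking()]
#'   and base the size suggestion on it (recommended); with
#'   `cv = FALSE` the training curve is used, which usually falls back
#'   to the largest size because the reference overfits in sample.
#' @param K number of CV folds.
#' @param cv_fit_args MCMC arguments for the per-fold refits (defaults
#'   to `fit_args`).
#' @param compare_dais index names to score and compare.
#' @param subset optional fixed predictor subset for the SESM,
#'   overriding the suggested size.
#' @return An `endosel_pipeline` list with every intermediate artifact.
#' @export
run_pipeline <- function(cohort = NULL, sim_config = simulation_config(),
                         seed = 1, out_dir = NULL,
                         mv_rate_max = 0.20, rare_level_min = 0.03,
                         max_size = 3, fit_args = list(),
                         cv = TRUE, K = 5, cv_fit_args = fit_args,
                         compare_dais = c("pcdai", "abbrpcdai",
                                          "modpcdai", "shpcdai",
                                          "wpcdai", "mini"),
                         subset = NULL) {
  simulated <- is.null(cohort)
  if (simulated) {
    sim <- simulate_cohort(sim_config, seed = seed)
    cohort <- sim$cohort
  } else sim <- NULL
  raw_cohort <- cohort

  cohort <- log_transform(cohort)
  cands <- screen_candidates(cohort, mv_rate_max = mv_rate_max,
                             rare_level_min = rare_level_min)
  cc <- complete_case_filter(cohort, cands)
  # remember which raw-scale rows survived (same rule, same order)
  keep <- complete.cases(cohort[c("endoscopic_score",
                                  intersect(cands$retained,
                                            names(cohort)))])
  # a rare binary finding can end up constant on the complete cases;
  # a constant column carries no information and cannot be standardized
  const <- vapply(cands$retained,
                  function(v) length(unique(cc[[v]])) < 2, TRUE)
  if (any(const)) {
    message("dropping constant predictor(s) after filtering: ",
            paste(cands$retained[const], collapse = ", "))
    cands$excluded <- rbind(cands$excluded,
                            data.frame(predictor = cands$retained[const],
                                       reason = "constant",
                                       detail = "constant after complete-case filter",
                                       stringsAsFactors = FALSE))
    cands$retained <- cands$retained[!const]
  }
  std <- standardize(cc, cands)

  fit_args$seed <- fit_args$seed %||% (seed + 1000L)
  draws <- do.call(fit_reference,
                   c(list(design = std$design), fit_args))
  fs <- forward_search(draws, std$design, max_size = max_size)
  cvr <- NULL
  if (cv) {
    cv_fit_args$seed <- cv_fit_args$seed %||% (seed + 3000L)
    cvr <- cv_ranking(std$design, K = K, seed = seed, draws = draws,
                      max_size = max_size, fit_args = cv_fit_args)
    size <- suggest_size(cvr)
  } else {
    size <- suggest_size(fs$curve)
  }
  subset <- subset %||% head(fs$ranking, max(size, 1))
  sesm <- finalize_sesm(draws, std$design, subset, params = std$params)

  # index comparison on the raw-scale visits that survived filtering
  # (complete_case_filter preserves row order, so match by position)
  raw_cc <- raw_cohort[keep, , drop = FALSE]
  visit_id <- paste0("v", seq_len(nrow(raw_cc)))

  cols <- unlist(std$design$terms[subset], use.names = FALSE)
  sesm_probs <- setNames(
    predictive_probs_observed(sesm,
                              X_new = std$design$X[, cols, drop = FALSE],
                              y = std$design$y),
    visit_id)
  dai_probs <- list(); dai_scores <- list()
  for (idx in compare_dais) {
    sc <- compute_dai_cohort(raw_cc, idx)
    dai_scores[[idx]] <- sc
    if (sum(!is.na(sc$score)) >= 10 &&
        length(unique(std$design$y[!is.na(sc$score)])) >= 2 &&
        sd(sc$score, na.rm = TRUE) > 0) {
      fitd <- fit_dai_auxiliary_model(sc$score, std$design$y,
                                      seed = seed + 2000L)
      dai_probs[[idx]] <- setNames(
        predictive_probs_observed(fitd, scores = sc$score,
                                  y = std$design$y), visit_id)
    }
  }
  comparison <- if (length(dai_probs))
    compare_to_sesm(sesm_probs, dai_probs) else NULL

  out <- structure(list(simulated = simulated, sim = sim,
                        cohort = raw_cohort, candidates = cands,
                        design = std$design, params = std$params,
                        draws = draws, forward = fs, cv = cvr,
                        suggested_size = size, subset = subset,
                        sesm = sesm, sesm_probs = sesm_probs,
                        dai_scores = dai_scores,
                        comparison = comparison, seed = seed),
                   class = "endosel_pipeline")
  if (!is.null(out_dir)) .write_pipeline(out, out_dir)
  out
}

.write_pipeline <- function(pl, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(out_dir, f)
  write.csv(pl$forward$curve, pth("curve.csv"), row.names = FALSE)
  if (!is.null(pl$cv))
    write.csv(pl$cv$curve, pth("cv_curve.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(ranking = pl$forward$ranking,
         suggested_size = pl$suggested_size, subset = pl$subset),
    pth("ranking.json"), auto_unbox = TRUE, digits = NA)
  write_sesm(pl$sesm, pth("sesm.json"))
  if (!is.null(pl$comparison))
    write.csv(pl$comparison$summary, pth("dai_comparison.csv"),
              row.names = FALSE)
  jsonlite::write_json(
    list(seed = pl$seed, simulated = pl$simulated,
         n_visits_modeled = nrow(pl$design$X),
         n_patients = length(unique(pl$design$patient)),
         package_version = as.character(utils::packageVersion("endosel"))),
    pth("run_info.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.endosel_pipeline <- function(x, ...) {
  cat("endosel pipeline run (seed ", x$seed, ")\n", sep = "")
  cat("  visits modeled:", nrow(x$design$X), "of", nrow(x$cohort), "\n")
  cat("  ranking:", paste(x$forward$ranking, collapse = " > "), "\n")
  cat("  suggested size:", x$suggested_size, " -> SESM {",
      paste(x$subset, collapse = ", "), "}\n")
  invisible(x)
}
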