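#' Greedy forward search over candidate predictor terms
#'
#' Starting from the intercept-only submodel, repeatedly adds the
#' candidate term whose latent projection ([project_draws()]) maximizes
#' the training mean log predictive density of the projected submodel.
#' Multi-column terms (multi-level categoricals) enter with all their
#' dummy columns at once. Ties are broken lexicographically by term
#' name (with a message).
#'
#' The performance curve records, for each submodel size `m = 0..max_size`,
#' `delta-MLPD(m)` (submodel MLPD minus reference MLPD, both computed
#' from draw-averaged predictive probabilities of the population-level
#' model part), its standard error over pointwise differences, and the
#' GMPD ratio `exp(delta-MLPD)`.
#'
#' @param draws an `endosel_draws` reference posterior.
#' @param design an `endosel_design`.
#' @param candidates optional restriction of the searched terms: an
#'   `endosel_candidates`, or a character vector of term names; default
#'   all design terms.
#' @param max_size largest submodel size to search.
#' @return An `endosel_forward` list: `ranking` (ordered term names),
#'   `curve` (data frame `size`, `delta_mlpd`, `se`, `lgmpd`),
#'   `mlpd_ref` (reference training MLPD), and the pointwise reference
#'   log densities.
#' @export
forward_search <- function(draws, design, candidates = NULL,
                           max_size = 3) {
  terms <- design$terms
  if (inherits(candidates, "endosel_candidates"))
    candidates <- candidates$retained
  if (!is.null(candidates)) terms <- terms[names(terms) %in% candidates]
  .stop_if(length(terms) == 0, "no candidate terms to search")
  max_size <- min(max_size, length(terms))

  X <- design$X; y <- design$y
  lp_ref <- log(colMeans(.prob_obs(latent_predictor(draws, X),
                                   draws$tau, y)))
  mlpd_ref <- mean(lp_ref)

  lp_for <- function(cols) {
    sub <- project_draws(draws, X, cols)
    .submodel_lpd(sub, X[, cols, drop = FALSE], y)
  }

  selected <- character()
  remaining <- sort(names(terms))
  lp_sizes <- list(`0` = lp_for(character()))
  for (m in seq_len(max_size)) {
    scores <- vapply(remaining, function(tm) {
      cols <- unlist(terms[c(selected, tm)], use.names = FALSE)
      # a candidate collinear with the current subset (e.g. a dummy
      # constant on this data split) is not selectable at this step
      tryCatch(mean(lp_for(cols)), error = function(e) -Inf)
    }, 0)
    best <- max(scores)
    if (!is.finite(best)) break
    hits <- remaining[scores >= best - 1e-12]
    if (length(hits) > 1)
      message("forward_search: tie at size ", m, " between ",
              paste(hits, collapse = ", "), "; keeping ", hits[1])
    pick <- hits[1]
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    lp_sizes[[as.character(m)]] <-
      lp_for(unlist(terms[selected], use.names = FALSE))
  }

  curve <- do.call(rbind, lapply(0:length(selected), function(m) {
    d <- delta_mlpd(lp_sizes[[as.character(m)]], lp_ref)
    data.frame(size = m, delta_mlpd = d$delta, se = d$se,
               lgmpd = d$lgmpd)
  }))
  structure(list(ranking = selected, curve = curve,
                 mlpd_ref = mlpd_ref, lp_ref = lp_ref,
                 terms = terms),
            class = "endosel_forward")
}

.prob_array_from_eta <- function(eta, tau) {
  S <- nrow(eta); n <- ncol(eta)
  out <- array(NA_real_, c(S, n, 4))
  for (s in seq_len(S)) out[s, , ] <- category_probs(eta[s, ], tau[s, ])
  out
}

#' @export
print.endosel_forward <- function(x, ...) {
  cat("Forward search ranking:",
      paste(seq_along(x$ranking), x$ranking, sep = ". ",
            collapse = "  "), "\n")
  print(transform(x$curve, delta_mlpd = round(delta_mlpd, 4),
                  se = round(se, 4), lgmpd = round(lgmpd, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Suggest the submodel size from a performance curve
#'
#' Returns the smallest size whose `delta-MLPD + SE` reaches 0, i.e. the
#' smallest submodel whose predictive performance is within one standard
#' error of the reference model. Falls back to the largest searched size
#' (with a message) when no size qualifies.
#'
#' @param curve data frame with columns `size`, `delta_mlpd`, `se`
#'   (e.g. `forward_search()$curve`), or an `endosel_forward`.
#' @return Integer size.
#' @export
suggest_size <- function(curve) {
  if (inherits(curve, "endosel_forward") ||
      inherits(curve, "endosel_cv_ranking")) curve <- curve$curve
  .stop_if(nrow(curve) == 0, "empty performance curve")
  ok <- which(curve$delta_mlpd + curve$se >= 0)
  if (length(ok) == 0) {
    message("suggest_size: no size within 1 SE of the reference; ",
            "falling back to the largest searched size")
    return(as.integer(max(curve$size)))
  }
  as.integer(min(curve$size[ok]))
}

#' Cross-validated predictor ranking
#'
#' Folds partition patients (all visits of a patient share a fold).
#' In each fold the reference model is refitted on the training
#' patients and a forward search run, giving one predictor ranking per
#' fold; the proportion matrix reports, for each position `m` and
#' predictor, the fraction of folds ranking that predictor at position
#' `m`. The full-data ranking comes from a search on all data.
#'
#' Besides the rankings, the cross-validation assembles a held-out
#' performance curve in the manner of a K-fold variable-selection run:
#' within each fold, the reference refit and its forward search produce
#' projected submodels of every size, which are then evaluated on the
#' fold's held-out visits (new patients, so the patient effect is
#' integrated out at zero); pooling the held-out pointwise log
#' predictive densities over folds gives `delta-MLPD(m)` against the
#' reference's own held-out densities, with a standard error. This is
#' the curve [suggest_size()] should be applied to: unlike the training
#' curve, it accounts for the reference model's overfitting.
#'
#' A fold whose training outcomes cover fewer than 2 categories
#' triggers refolding with a shifted seed (with a message).
#'
#' @param design an `endosel_design`.
#' @param K number of folds (>= 2).
#' @param seed fold-assignment seed.
#' @param max_size forward-search depth per fold.
#' @param draws optional full-data posterior (refitted when `NULL`).
#' @param fit_args list of arguments passed to [fit_reference()] for
#'   the per-fold (and, if needed, full-data) refits.
#' @param candidates optional candidate restriction, as in
#'   [forward_search()].
#' @return An `endosel_cv_ranking`: `full_ranking`, `fold_rankings`,
#'   `proportions` (max_size x predictors matrix, columns ordered by
#'   the full-data ranking), and the held-out `curve` (data frame
#'   `size`, `delta_mlpd`, `se`, `lgmpd`).
#' @export
cv_ranking <- function(design, K = 5, seed = 1, max_size = 3,
                       draws = NULL, fit_args = list(),
                       candidates = NULL) {
  .stop_if(K < 2, "K must be at least 2")
  patients <- unique(design$patient)
  .stop_if(K > length(patients), "more folds than patients")

  folds <- .assign_folds(design, patients, K, seed)
  n <- nrow(design$X)
  lp_sub <- matrix(NA_real_, n, max_size + 1)
  lp_ref <- rep(NA_real_, n)

  fold_rankings <- vector("list", K)
  for (k in seq_len(K)) {
    train <- design$patient %in% patients[folds != k]
    sub_design <- structure(
      list(X = design$X[train, , drop = FALSE], y = design$y[train],
           patient = design$patient[train], terms = design$terms,
           outcome_levels = design$outcome_levels),
      class = "endosel_design")
    fd <- do.call(fit_reference,
                  c(list(design = sub_design, check = FALSE),
                    fit_args))
    fs <- forward_search(fd, sub_design, candidates = candidates,
                         max_size = max_size)
    fold_rankings[[k]] <- fs$ranking

    # held-out evaluation on the fold's left-out visits: these are new
    # patients, so both the reference and every submodel integrate the
    # patient-intercept dispersion; submodels additionally integrate
    # their projection dispersion
    test <- !train
    X_te <- design$X[test, , drop = FALSE]
    y_te <- design$y[test]
    eta_ref <- latent_predictor(fd, X_te)
    lp_ref[test] <- log(colMeans(.prob_obs(eta_ref, fd$tau, y_te,
                                           sd = fd[["sigma_b"]])))
    for (m in 0:max_size) {
      cols <- unlist(sub_design$terms[head(fs$ranking,
                                           min(m, length(fs$ranking)))],
                     use.names = FALSE)
      pr <- project_draws(fd, sub_design$X, cols)
      lp_sub[test, m + 1] <- .submodel_lpd(pr,
                                           X_te[, cols, drop = FALSE],
                                           y_te,
                                           extra_sd = fd[["sigma_b"]])
    }
  }

  if (is.null(draws))
    draws <- do.call(fit_reference,
                     c(list(design = design, check = FALSE), fit_args))
  full <- forward_search(draws, design, candidates = candidates,
                         max_size = max_size)$ranking

  curve <- do.call(rbind, lapply(0:max_size, function(m) {
    d <- delta_mlpd(lp_sub[, m + 1], lp_ref)
    data.frame(size = m, delta_mlpd = d$delta, se = d$se,
               lgmpd = d$lgmpd)
  }))

  cols <- unique(c(full, unlist(fold_rankings)))
  prop <- matrix(0, max_size, length(cols),
                 dimnames = list(paste0("size", seq_len(max_size)),
                                 cols))
  for (r in fold_rankings)
    for (m in seq_len(min(max_size, length(r))))
      prop[m, r[m]] <- prop[m, r[m]] + 1 / K
  structure(list(full_ranking = full, fold_rankings = fold_rankings,
                 proportions = prop, curve = curve, K = K),
            class = "endosel_cv_ranking")
}

.assign_folds <- function(design, patients, K, seed) {
  for (try in 0:9) {
    set.seed(seed + try)
    folds <- sample(rep_len(seq_len(K), length(patients)))
    ok <- all(vapply(seq_len(K), function(k) {
      ytr <- design$y[design$patient %in% patients[folds != k]]
      length(unique(ytr)) >= 2
    }, TRUE))
    if (ok) {
      if (try > 0)
        message("cv_ranking: refolded ", try,
                " time(s) to avoid degenerate folds")
      return(folds)
    }
  }
  stop("could not build folds with at least 2 outcome categories ",
       "per training set", call. = FALSE)
}

#' @export
print.endosel_cv_ranking <- function(x, ...) {
  cat("Full-data ranking:", paste(x$full_ranking, collapse = " > "),
      "\n")
  cat("CV fold position proportions (", x$K, "folds ):\n")
  print(round(x$proportions, 2))
  cat("held-out performance curve:\n")
  print(transform(x$curve, delta_mlpd = round(delta_mlpd, 4),
                  se = round(se, 4), lgmpd = round(lgmpd, 4)),
        row.names = FALSE)
  invisible(x)
}

#' Finalize the selected endoscopic submodel (SESM)
#'
#' Projects the full reference posterior onto the chosen predictor
#' subset and bundles the result with the standardization parameters,
#' turning it into a self-contained prediction object for new raw
#' biomarker values.
#'
#' @param draws an `endosel_draws`.
#' @param design an `endosel_design`.
#' @param subset character vector of selected term names.
#' @param params an `endosel_standardization` (from [standardize()]);
#'   required for scoring raw inputs later.
#' @return An `endosel_sesm` (also an `endosel_submodel`).
#' @export
finalize_sesm <- function(draws, design, subset, params = NULL) {
  .stop_if(!all(subset %in% names(design$terms)),
           "unknown term(s): ",
           paste(setdiff(subset, names(design$terms)), collapse = ", "))
  cols <- unlist(design$terms[subset], use.names = FALSE)
  sub <- project_draws(draws, design$X, cols)
  sub$term_names <- subset
  sub$std_params <- params
  # carried so new-patient predictions can marginalize the patient
  # effect on request
  sub$sigma_b <- draws[["sigma_b"]]
  class(sub) <- c("endosel_sesm", class(sub))
  sub
}

#' Serialize / restore a selected submodel
#'
#' Writes the SESM (subset, per-draw projected coefficients, carried
#' thresholds, latent dispersion, standardization parameters) to a JSON
#' file at full double precision, and reads it back. Predictions from a
#' round-tripped SESM agree with the original to machine precision.
#'
#' @param sesm an `endosel_sesm`.
#' @param path output/input file path.
#' @return `write_sesm()`: the path, invisibly; `read_sesm()`: the
#'   restored `endosel_sesm`.
#' @export
write_sesm <- function(sesm, path) {
  obj <- list(
    subset = sesm$subset,
    term_names = sesm$term_names %||% sesm$subset,
    alpha = sesm$alpha,
    beta_proj = as.data.frame(sesm$beta_proj),
    tau = as.data.frame(sesm$tau),
    sigma_proj = sesm$sigma_proj,
    sigma_b = sesm[["sigma_b"]],
    outcome_levels = sesm$outcome_levels,
    std_params = if (!is.null(sesm$std_params))
      list(table = sesm$std_params$table,
           log_vars = sesm$std_params$log_vars))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_sesm
#' @export
read_sesm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sub <- list(
    subset = as.character(obj$subset),
    term_names = as.character(obj$term_names),
    alpha = as.numeric(obj$alpha),
    beta_proj = as.matrix(obj$beta_proj),
    tau = as.matrix(obj$tau),
    sigma_proj = as.numeric(obj$sigma_proj),
    outcome_levels = as.character(obj$outcome_levels))
  if (!is.null(obj$sigma_b)) sub$sigma_b <- as.numeric(obj$sigma_b)
  if (!is.null(obj$std_params)) {
    sub$std_params <- structure(
      list(table = as.data.frame(obj$std_params$table),
           log_vars = as.character(obj$std_params$log_vars)),
      class = "endosel_standardization")
  }
  structure(sub, class = c("endosel_sesm", "endosel_submodel"))
}
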