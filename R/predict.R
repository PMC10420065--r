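#' Predict endoscopic category probabilities from CRP and FC
#'
#' Scores a new visit through the selected endoscopic submodel: the raw
#' C-reactive protein (mg/L) and fecal calprotectin (mg/kg) values are
#' log-transformed, standardized with the training parameters stored in
#' the SESM, pushed through every posterior draw's projected
#' coefficients and carried thresholds with the patient effect set to
#' zero (new-patient prediction), and the per-draw category
#' probabilities are averaged.
#'
#' @param sesm an `endosel_sesm` whose subset is `log_crp` and
#'   `log_fc` (in either order) and which carries standardization
#'   parameters.
#' @param crp C-reactive protein in mg/L, strictly positive.
#' @param fc fecal calprotectin in mg/kg, strictly positive.
#' @param crp_floor assay detection floor (mg/L); values below it are
#'   accepted but flagged.
#' @param marginalize_patient integrate over the patient-intercept
#'   distribution `N(0, sigma_b^2)` instead of setting the effect to
#'   zero (requires an SESM finalized from a model with patient
#'   intercepts).
#' @return An `endosel_probs`: `probs` (length 4, sums to 1), `argmax`
#'   category, `n_draws`, `below_floor` flag.
#' @export
predict_from_biomarkers <- function(sesm, crp, fc, crp_floor = 1,
                                    marginalize_patient = FALSE) {
  .stop_if(!inherits(sesm, "endosel_submodel"),
           "sesm must be a projected submodel")
  .stop_if(!setequal(sesm$subset, c("log_crp", "log_fc")),
           "the SESM subset must be {log_crp, log_fc}; got {",
           paste(sesm$subset, collapse = ", "), "}")
  .stop_if(is.null(sesm$std_params),
           "sesm carries no standardization parameters")
  .stop_if(!is.numeric(crp) || length(crp) != 1 || !is.finite(crp) ||
             crp <= 0, "crp must be a single positive number (mg/L)")
  .stop_if(!is.numeric(fc) || length(fc) != 1 || !is.finite(fc) ||
             fc <= 0, "fc must be a single positive number (mg/kg)")
  x <- standardize_apply(sesm$std_params,
                         c(log_crp = log(crp), log_fc = log(fc)))
  X_new <- matrix(x[sesm$subset], nrow = 1,
                  dimnames = list(NULL, sesm$subset))
  extra <- 0
  if (marginalize_patient) {
    .stop_if(is.null(sesm[["sigma_b"]]),
             "sesm carries no patient-intercept draws")
    extra <- sesm[["sigma_b"]]
  }
  probs <- submodel_predict(sesm, X_new, extra_sd = extra)
  p <- colMeans(probs[, 1, ])
  structure(list(probs = p,
                 argmax = names(p)[which.max(p)],
                 n_draws = dim(probs)[1],
                 below_floor = crp < crp_floor,
                 crp = crp, fc = fc),
            class = "endosel_probs")
}

#' @export
print.endosel_probs <- function(x, ...) {
  cat(sprintf("CRP %.3g mg/L, FC %.3g mg/kg%s\n", x$crp, x$fc,
              if (x$below_floor) "  [CRP below detection floor]" else ""))
  pct <- round(100 * x$probs)
  for (k in seq_along(x$probs))
    cat(sprintf("  %-10s %3d%%%s\n", names(x$probs)[k], pct[k],
                if (k == which.max(x$probs)) "  <- most probable" else ""))
  invisible(x)
}

#' Predictive probability grid over CRP and FC values
#'
#' Evaluates [predict_from_biomarkers()] on the Cartesian product of
#' CRP and FC values, recording raw probabilities, the most probable
#' category per cell, and display percentages (independently rounded to
#' integers, so a row may not sum to exactly 100).
#'
#' @param sesm an `endosel_sesm`.
#' @param crp_values,fc_values positive numeric vectors.
#' @param crp_floor passed to [predict_from_biomarkers()].
#' @return An `endosel_grid` data frame: `fc`, `crp`, the four
#'   probability columns, `argmax`, and `pct_*` display columns.
#' @export
probability_grid <- function(sesm, crp_values, fc_values,
                             crp_floor = 1) {
  .stop_if(any(crp_values <= 0) || any(fc_values <= 0),
           "grid values must be positive")
  rows <- list()
  for (fcv in fc_values) for (crpv in crp_values) {
    pr <- predict_from_biomarkers(sesm, crpv, fcv, crp_floor)
    rows[[length(rows) + 1]] <-
      c(list(fc = fcv, crp = crpv), as.list(pr$probs),
        list(argmax = pr$argmax),
        setNames(as.list(as.integer(round(100 * pr$probs))),
                 paste0("pct_", names(pr$probs))))
  }
  out <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  class(out) <- c("endosel_grid", "data.frame")
  out
}
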