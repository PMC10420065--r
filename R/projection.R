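#' Project posterior draws onto a predictor subset
#'
#' The latent projection: for each posterior draw `s`, the reference
#' model's population-level latent predictor `eta^(s) = X_full beta^(s)`
#' is treated as a vector of Gaussian pseudo-observations and projected
#' onto the span of the submodel columns (plus an intercept) by ordinary
#' least squares — the Kullback-Leibler divergence minimizer between
#' Gaussians on the latent scale. The thresholds are carried over
#' unchanged from the reference draw, and the root-mean-square residual
#' becomes the draw's latent dispersion `sigma_perp^(s)`.
#'
#' With `patient_term = TRUE` the patient indicator block is appended to
#' the submodel and its coefficients are ridge-penalized per draw with
#' penalty `sigma_perp^2 / sigma_b^2(s)`, mirroring how a group-level
#' term shrinks in the reference model.
#'
#' @param draws an `endosel_draws`.
#' @param X_full numeric matrix with columns matching the reference
#'   coefficients.
#' @param subset character vector of column names (possibly empty: the
#'   intercept-only projection).
#' @param patient_term also project onto penalized patient indicators.
#' @param patient patient identifiers (needed for `patient_term`).
#' @return An `endosel_submodel`: `subset`, per-draw `alpha` (intercept),
#'   `beta_proj` (S x m), carried `tau`, `sigma_proj` (S), and optional
#'   patient coefficients.
#' @export
project_draws <- function(draws, X_full, subset,
                          patient_term = FALSE, patient = NULL) {
  X_full <- as.matrix(X_full)
  .stop_if(!all(subset %in% colnames(X_full)),
           "subset contains unknown columns: ",
           paste(setdiff(subset, colnames(X_full)), collapse = ", "))
  eta <- latent_predictor(draws, X_full)        # S x n, population-level
  n <- ncol(eta); S <- nrow(eta)
  Xs <- cbind(`(intercept)` = rep(1, n),
              X_full[, subset, drop = FALSE])

  if (!patient_term) {
    qrX <- qr(Xs)
    .stop_if(qrX$rank < ncol(Xs),
             "rank-deficient submodel design for subset {",
             paste(subset, collapse = ", "), "}")
    coefs <- qr.coef(qrX, t(eta))               # (m+1) x S
    fitted <- Xs %*% coefs
  } else {
    .stop_if(is.null(draws[["b"]]) || is.null(patient),
             "patient_term requires a model with patient intercepts ",
             "and patient identifiers")
    levels <- draws[["patient_levels"]]
    Z <- outer(as.character(patient), levels, "==") * 1
    coefs <- matrix(NA_real_, ncol(Xs) + ncol(Z), S)
    fitted <- matrix(NA_real_, n, S)
    XZ <- cbind(Xs, Z)
    m0 <- ncol(Xs)
    for (s in seq_len(S)) {
      # ridge on the patient block only; penalty from the draw's own
      # residual scale and sigma_b
      ols <- qr.coef(qr(Xs), eta[s, ])
      res <- eta[s, ] - drop(Xs %*% ols)
      pen <- mean(res^2) / max(draws[["sigma_b"]][s]^2, 1e-8)
      D <- diag(c(rep(0, m0), rep(pen, ncol(Z))))
      A <- crossprod(XZ) + D
      cf <- solve(A, crossprod(XZ, eta[s, ]))
      coefs[, s] <- cf
      fitted[, s] <- XZ %*% cf
    }
  }
  resid <- t(eta) - fitted
  sigma <- sqrt(colMeans(resid^2))
  beta_proj <- t(coefs[seq_along(subset) + 1, , drop = FALSE])
  colnames(beta_proj) <- subset
  out <- list(subset = subset,
              alpha = coefs[1, ],
              beta_proj = beta_proj,
              tau = draws$tau,
              sigma_proj = sigma,
              outcome_levels = attr(draws, "outcome_levels") %||%
                c("remission", "mild", "moderate", "severe"))
  if (patient_term) {
    bp <- t(coefs[-(seq_len(length(subset) + 1)), , drop = FALSE])
    colnames(bp) <- draws[["patient_levels"]]
    out$patient_coef <- bp
  }
  structure(out, class = "endosel_submodel")
}

#' Category probabilities from a projected submodel
#'
#' For each draw, forms `eta_new = alpha + X_new beta_perp` and applies
#' the carried thresholds through [category_probs()]. By default the
#' draw's latent projection dispersion `sigma_perp` is integrated out
#' by Gauss-Hermite quadrature: the projection discards part of the
#' reference model's latent predictor, and ignoring that lost variation
#' while keeping the reference thresholds would make the submodel's
#' response-scale predictions overconfident. `extra_sd` adds further
#' latent dispersion in quadrature (e.g. the patient-intercept standard
#' deviation when predicting for new patients).
#'
#' @param sub an `endosel_submodel`.
#' @param X_new matrix with columns equal to the subset (order
#'   enforced).
#' @param integrate_dispersion integrate over the latent dispersion
#'   (set to `FALSE` for plug-in predictions).
#' @param extra_sd additional latent standard deviation, a scalar or
#'   per-draw vector.
#' @param gh_nodes number of Gauss-Hermite nodes.
#' @return An S x n x 4 probability array.
#' @export
submodel_predict <- function(sub, X_new, integrate_dispersion = TRUE,
                             extra_sd = 0, gh_nodes = 15) {
  X_new <- as.matrix(X_new)
  .stop_if(!identical(sort(colnames(X_new)), sort(sub$subset)) &&
             length(sub$subset) > 0,
           "X_new columns must equal the submodel subset")
  if (length(sub$subset)) X_new <- X_new[, sub$subset, drop = FALSE]
  S <- length(sub$alpha); n <- nrow(X_new)
  eta <- matrix(sub$alpha, S, n) +
    if (length(sub$subset)) sub$beta_proj %*% t(X_new) else 0
  out <- array(NA_real_, c(S, n, 4),
               dimnames = list(NULL, NULL, sub$outcome_levels))
  sdv <- if (integrate_dispersion)
    sqrt(sub$sigma_proj^2 + rep_len(extra_sd, S)^2) else rep(0, S)
  gh <- .gauss_hermite(gh_nodes)
  for (s in seq_len(S)) {
    if (sdv[s] == 0) {
      out[s, , ] <- category_probs(eta[s, ], sub$tau[s, ])
    } else {
      acc <- matrix(0, n, 4)
      for (k in seq_len(gh_nodes))
        acc <- acc + gh$w[k] *
          category_probs(eta[s, ] + sdv[s] * gh$x[k], sub$tau[s, ])
      out[s, , ] <- acc
    }
  }
  out
}

# S x n matrix of predictive probabilities at the observed categories,
# vectorized over draws, optionally integrating a per-draw latent
# dispersion by Gauss-Hermite quadrature. This is the fast path used by
# the forward search and cross-validation, which only need the
# probability at each observed outcome.
.prob_obs <- function(eta, tau, y, sd = NULL, gh_nodes = 11) {
  tauext <- cbind(-Inf, tau, Inf)
  Hi <- tauext[, y + 1, drop = FALSE]
  Lo <- tauext[, y, drop = FALSE]
  if (is.null(sd) || all(sd == 0))
    return(plogis(Hi - eta) - plogis(Lo - eta))
  gh <- .gauss_hermite(gh_nodes)
  acc <- matrix(0, nrow(eta), ncol(eta))
  for (k in seq_len(gh_nodes)) {
    sh <- eta + sd * gh$x[k]   # sd recycles over draws (rows)
    acc <- acc + gh$w[k] * (plogis(Hi - sh) - plogis(Lo - sh))
  }
  acc
}

# pointwise log predictive density at the observed categories from a
# projected submodel, with total latent dispersion sqrt(sigma^2+extra^2)
.submodel_lpd <- function(sub, X_new, y, extra_sd = 0) {
  S <- length(sub$alpha)
  eta <- matrix(sub$alpha, S, nrow(as.matrix(X_new))) +
    if (length(sub$subset))
      sub$beta_proj %*% t(as.matrix(X_new)[, sub$subset, drop = FALSE])
  else 0
  sdv <- sqrt(sub$sigma_proj^2 + rep_len(extra_sd, S)^2)
  log(colMeans(.prob_obs(eta, sub$tau, y, sd = sdv)))
}

# probabilists' Gauss-Hermite nodes/weights for N(0,1) expectation
.gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  a <- sqrt(i / 2)
  CM <- diag(0, n)
  CM[cbind(i, i + 1)] <- a
  CM[cbind(i + 1, i)] <- a
  e <- eigen(CM, symmetric = TRUE)
  list(x = rev(e$values) * sqrt(2),
       w = rev(e$vectors[1, ]^2))
}

#' Mean log predictive density and geometric mean
#'
#' `MLPD` is the mean of the log predictive probabilities at the
#' observed outcome categories; its exponential, the geometric mean
#' predictive density `GMPD = exp(MLPD)`, lives in (0, 1] and is the
#' geometric mean of the predictive probabilities.
#'
#' @param prob_at_observed vector of predictive probabilities at the
#'   observed categories, each in (0, 1].
#' @return A list with `mlpd` and `gmpd`.
#' @export
mlpd <- function(prob_at_observed) {
  .stop_if(any(prob_at_observed < 0 | prob_at_observed > 1),
           "probabilities must lie in [0, 1]")
  if (any(prob_at_observed == 0))
    warning("zero predictive probability: MLPD is -Inf", call. = FALSE)
  m <- mean(log(prob_at_observed))
  list(mlpd = m, gmpd = exp(m))
}

#' Difference in mean log predictive density with standard error
#'
#' `delta-MLPD = mean(d_i)` and `SE = sd(d_i)/sqrt(n)` where
#' `d_i = lp_sub_i - lp_ref_i` are the pointwise log predictive density
#' differences between a submodel and the reference model.
#'
#' @param pointwise_sub,pointwise_ref numeric vectors of pointwise log
#'   predictive densities (equal length, n >= 2).
#' @return A list with `delta`, `se`, and `lgmpd = exp(delta)` (the
#'   submodel-to-reference GMPD ratio).
#' @export
delta_mlpd <- function(pointwise_sub, pointwise_ref) {
  .stop_if(length(pointwise_sub) != length(pointwise_ref),
           "pointwise vectors must have equal length")
  .stop_if(length(pointwise_sub) < 2,
           "need at least 2 observations for a standard error")
  d <- pointwise_sub - pointwise_ref
  list(delta = mean(d), se = sd(d) / sqrt(length(d)),
       lgmpd = exp(mean(d)))
}

# pointwise log predictive density: log of the draw-averaged
# probability at each observed category
.pointwise_lpd <- function(prob_array, y) {
  n <- dim(prob_array)[2]
  pbar <- vapply(seq_len(n),
                 function(i) mean(prob_array[, i, y[i]]), 0)
  log(pbar)
}

#' @export
print.endosel_submodel <- function(x, ...) {
  cat("Projected submodel {", paste(x$subset, collapse = ", "),
      "} over", length(x$alpha), "draws\n")
  if (length(x$subset)) {
    qs <- apply(x$beta_proj, 2, quantile, c(0.025, 0.5, 0.975))
    for (j in seq_along(x$subset))
      cat(sprintf("  %-22s median % .3f  [% .3f, % .3f]\n",
                  x$subset[j], qs[2, j], qs[1, j], qs[3, j]))
  }
  cat(sprintf("  latent dispersion sigma_perp: median %.3f\n",
              median(x$sigma_proj)))
  invisible(x)
}
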