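#' Cumulative-logit category probabilities
#'
#' For the four-level ordinal outcome, the cumulative-logit model puts
#' `P(y <= k) = plogis(tau_k - eta)` with strictly increasing thresholds
#' `tau_1 < tau_2 < tau_3`, so the category probabilities are the
#' telescoping differences (with `tau_0 = -Inf`, `tau_4 = +Inf`).
#'
#' @param eta numeric vector of latent predictor values.
#' @param thresholds strictly increasing numeric vector of length 3.
#' @return A `length(eta) x 4` matrix of probabilities, rows summing
#'   to 1, columns named after the outcome categories.
#' @export
category_probs <- function(eta, thresholds) {
  .stop_if(length(thresholds) != 3, "need exactly 3 thresholds")
  .stop_if(any(diff(thresholds) <= 0),
           "thresholds must be strictly increasing")
  cum <- vapply(thresholds, function(t) plogis(t - eta),
                numeric(length(eta)))
  if (is.null(dim(cum))) cum <- matrix(cum, nrow = 1)
  p <- cbind(cum[, 1], cum[, 2] - cum[, 1], cum[, 3] - cum[, 2],
             1 - cum[, 3])
  colnames(p) <- c("remission", "mild", "moderate", "severe")
  p
}

#' Prior configuration for the reference model
#'
#' The population-level coefficients get a regularized horseshoe (RH)
#' prior: `beta_j | lambda_j, tau_g, c ~ N(0, tau_g^2 * lt_j^2)` with
#' `lt_j^2 = c^2 lambda_j^2 / (c^2 + tau_g^2 lambda_j^2)`, local scales
#' `lambda_j ~ half-Cauchy(0, 1)`, global scale
#' `tau_g ~ half-Cauchy(0, tau_0)` and slab
#' `c^2 ~ scaled-inv-chi^2(slab_df, slab_scale^2)`. The default global
#' scale follows the prior-guess heuristic
#' `tau_0 = p0 / ((p - p0) sqrt(n)) * pseudo_sigma` with `p0` the guess
#' of the number of non-zero coefficients and `pseudo_sigma = 2` (a
#' logistic-scale convention).
#'
#' Thresholds get weakly-informative Student-t(3, 0, 2.5) priors
#' (ordered by truncation) and the patient-intercept standard deviation
#' a half-Student-t(3, 0, 2.5) prior.
#'
#' @param p0 prior guess of the number of non-zero coefficients.
#' @param global_scale RH global scale `tau_0`; computed from `p0`, `p`
#'   and `n` at fit time when `NULL`.
#' @param slab_df,slab_scale slab degrees of freedom and scale.
#' @param pseudo_sigma pseudo observation scale for the logistic
#'   likelihood.
#' @param threshold_df,threshold_scale Student-t prior on thresholds.
#' @param sd_df,sd_scale half-Student-t prior on the patient-intercept
#'   standard deviation.
#' @return An `endosel_priors` list.
#' @export
prior_config <- function(p0 = 2, global_scale = NULL,
                         slab_df = 4, slab_scale = 2,
                         pseudo_sigma = 2,
                         threshold_df = 3, threshold_scale = 2.5,
                         sd_df = 3, sd_scale = 2.5) {
  .stop_if(p0 <= 0 || slab_df <= 0 || slab_scale <= 0,
           "p0, slab_df and slab_scale must be positive")
  structure(list(p0 = p0, global_scale = global_scale,
                 slab_df = slab_df, slab_scale = slab_scale,
                 pseudo_sigma = pseudo_sigma,
                 threshold_df = threshold_df,
                 threshold_scale = threshold_scale,
                 sd_df = sd_df, sd_scale = sd_scale),
            class = "endosel_priors")
}

.rh_global_scale <- function(priors, p, n) {
  priors$global_scale %||%
    (priors$p0 / (max(p - priors$p0, 1) * sqrt(n)) * priors$pseudo_sigma)
}

# JAGS model code. The RH coefficients and patient intercepts use a
# non-centered parameterization, which is what makes Gibbs sampling mix
# acceptably in the horseshoe funnel.
.jags_model_code <- function(rh, random_intercept) {
  beta_prior <- if (rh) "
  for (j in 1:p) {
    z[j] ~ dnorm(0, 1)
    lambda[j] ~ dt(0, 1, 1) T(0,)
    lt2[j] <- c2 * lambda[j]^2 / (c2 + taug^2 * lambda[j]^2)
    beta[j] <- z[j] * taug * sqrt(lt2[j])
  }
  taug ~ dt(0, pow(tau0, -2), 1) T(0,)
  c2inv ~ dgamma(slab_df / 2, slab_df * slab_scale^2 / 2)
  c2 <- 1 / c2inv
" else "
  for (j in 1:p) {
    beta[j] ~ dt(0, pow(beta_scale, -2), beta_df)
  }
"
  ranef <- if (random_intercept) "
  for (g in 1:npat) {
    braw[g] ~ dnorm(0, 1)
    b[g] <- braw[g] * sigmab
  }
  sigmab ~ dt(0, pow(sd_scale, -2), sd_df) T(0,)
" else ""
  eta_term <- if (random_intercept) "inprod(X[i,], beta) + b[pat[i]]"
  else "inprod(X[i,], beta)"
  paste0("model {
  for (i in 1:n) {
    eta[i] <- ", eta_term, "
    q[i,1] <- ilogit(tau[1] - eta[i])
    q[i,2] <- ilogit(tau[2] - eta[i])
    q[i,3] <- ilogit(tau[3] - eta[i])
    pr[i,1] <- q[i,1]
    pr[i,2] <- q[i,2] - q[i,1]
    pr[i,3] <- q[i,3] - q[i,2]
    pr[i,4] <- 1 - q[i,3]
    y[i] ~ dcat(pr[i,1:4])
  }
", beta_prior, ranef, "
  tau[1] ~ dt(0, pow(thr_scale, -2), thr_df)
  tau[2] ~ dt(0, pow(thr_scale, -2), thr_df) T(tau[1],)
  tau[3] ~ dt(0, pow(thr_scale, -2), thr_df) T(tau[2],)
}")
}

# Shared MCMC driver for the reference model (RH prior, patient random
# intercepts) and the auxiliary single-score models (Student-t prior).
.fit_ordinal_jags <- function(X, y, patient = NULL,
                              prior = c("rh", "t"),
                              priors = prior_config(),
                              chains = 2, adapt = 500, warmup = 500,
                              iter = 1000, thin = 2, seed = 20230728) {
  prior <- match.arg(prior)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  .stop_if(length(y) != n, "length(y) must match nrow(X)")
  .stop_if(!all(y %in% 1:4), "y must take values in 1..4")
  .stop_if(chains < 1, "need at least 1 chain")

  random_intercept <- !is.null(patient)
  dat <- list(n = n, p = p, X = X, y = as.integer(y),
              thr_df = priors$threshold_df,
              thr_scale = priors$threshold_scale)
  if (random_intercept) {
    pat_levels <- sort(unique(as.character(patient)))
    dat$pat <- match(as.character(patient), pat_levels)
    dat$npat <- length(pat_levels)
    dat$sd_df <- priors$sd_df
    dat$sd_scale <- priors$sd_scale
  } else pat_levels <- NULL
  if (prior == "rh") {
    dat$tau0 <- .rh_global_scale(priors, p, n)
    dat$slab_df <- priors$slab_df
    dat$slab_scale <- priors$slab_scale
  } else {
    dat$beta_df <- priors$threshold_df
    dat$beta_scale <- priors$threshold_scale
  }

  inits <- lapply(seq_len(chains), function(ch) {
    ini <- list(.RNG.name = "base::Mersenne-Twister",
                .RNG.seed = as.integer((seed + 1000L * ch) %% .Machine$integer.max),
                tau = c(-1, 0, 1))
    if (prior == "rh") {
      # start outside the horseshoe funnel's neck: a moderate global
      # scale lets genuine signals grow within a short warmup, after
      # which the prior shrinks the rest
      ini$z <- rep(0, p)
      ini$lambda <- rep(1, p)
      ini$taug <- 1
    } else ini$beta <- rep(0, p)
    if (random_intercept) ini$sigmab <- 0.5
    ini
  })

  monitor <- c("beta", "tau")
  if (random_intercept) monitor <- c(monitor, "b", "sigmab")
  if (prior == "rh") monitor <- c(monitor, "lambda", "taug", "c2")

  code <- .jags_model_code(prior == "rh", random_intercept)
  jm <- rjags::jags.model(textConnection(code), data = dat,
                          inits = inits, n.chains = chains,
                          n.adapt = adapt, quiet = TRUE)
  if (warmup > 0) update(jm, warmup, progress.bar = "none")
  sm <- rjags::coda.samples(jm, monitor, n.iter = iter, thin = thin,
                            progress.bar = "none")

  M <- do.call(rbind, lapply(sm, as.matrix))
  iter_kept <- nrow(sm[[1]])
  pick <- function(prefix, k) {
    cols <- if (k == 1) prefix else paste0(prefix, "[", seq_len(k), "]")
    out <- M[, cols, drop = FALSE]
    out
  }
  beta <- pick("beta", p); colnames(beta) <- colnames(X)
  draws <- list(beta = beta,
                tau = pick("tau", 3),
                chain_id = rep(seq_len(chains), each = iter_kept),
                n_chains = chains, n_iter = iter_kept,
                predictors = colnames(X))
  colnames(draws$tau) <- paste0("tau", 1:3)
  if (random_intercept) {
    b <- pick("b", dat$npat); colnames(b) <- pat_levels
    draws[["b"]] <- b
    draws[["sigma_b"]] <- drop(pick("sigmab", 1))
    draws[["patient_levels"]] <- pat_levels
  }
  if (prior == "rh") {
    lam <- pick("lambda", p); colnames(lam) <- colnames(X)
    draws[["lambda"]] <- lam
    draws$tau_g <- drop(pick("taug", 1))
    draws[["c"]] <- sqrt(drop(pick("c2", 1)))
  }
  structure(draws, class = "endosel_draws")
}

#' Fit the Bayesian cumulative-logit reference model
#'
#' Fits the reference model by MCMC: cumulative-logit likelihood over
#' the four endoscopic categories, regularized horseshoe prior on the
#' standardized population-level coefficients (see [prior_config()]),
#' and patient-level random intercepts accounting for multiple visits
#' per patient. Convergence is checked with split-R-hat and
#' rank-normalized bulk/tail effective sample sizes
#' ([check_convergence()]); a failed check produces a warning and the
#' report is attached to the result.
#'
#' @param design an `endosel_design` from [standardize()].
#' @param priors an `endosel_priors` from [prior_config()].
#' @param chains number of MCMC chains (at least 2 for diagnostics).
#' @param adapt,warmup,iter,thin sampler phase lengths: adaptation,
#'   burn-in, retained iterations per chain, thinning.
#' @param seed integer seed; each chain derives its own RNG seed.
#' @param check run [check_convergence()] after sampling.
#' @return An `endosel_draws` object with matrices `beta` (S x p),
#'   `tau` (S x 3), `b` (S x patients), vectors `sigma_b`, `tau_g`,
#'   `c`, matrix `lambda`, and chain bookkeeping.
#' @export
fit_reference <- function(design, priors = prior_config(),
                          chains = 2, adapt = 500, warmup = 500,
                          iter = 1000, thin = 2, seed = 20230728,
                          check = TRUE) {
  .stop_if(!inherits(design, "endosel_design"),
           "design must come from standardize()")
  draws <- .fit_ordinal_jags(design$X, design$y, patient = design$patient,
                             prior = "rh", priors = priors,
                             chains = chains, adapt = adapt,
                             warmup = warmup, iter = iter, thin = thin,
                             seed = seed)
  attr(draws, "design_terms") <- design$terms
  attr(draws, "outcome_levels") <- design$outcome_levels
  if (check && chains >= 2) {
    rep <- check_convergence(draws)
    attr(draws, "convergence") <- rep
    if (!rep$pass)
      warning("convergence diagnostics failed (max split-Rhat ",
              sprintf("%.3f", rep$max_rhat), ", min ESS ",
              sprintf("%.0f", rep$min_ess), "); treat results with care",
              call. = FALSE)
  }
  draws
}

#' Serialize / restore posterior draws
#'
#' Writes the draws as a columnar CSV: one row per draw, a `chain`
#' column, and one column per scalar parameter (`beta.<name>`,
#' `tau1..tau3`, `b.<patient>`, `sigma_b`, `lambda.<name>`, `tau_g`,
#' `c`). `read_draws()` reconstructs the `endosel_draws` object.
#'
#' @param draws an `endosel_draws`.
#' @param path CSV file path.
#' @return `write_draws()`: the path, invisibly; `read_draws()`: an
#'   `endosel_draws`.
#' @export
write_draws <- function(draws, path) {
  df <- data.frame(chain = draws$chain_id)
  addm <- function(m, prefix) {
    for (j in seq_len(ncol(m)))
      df[[paste0(prefix, colnames(m)[j])]] <<- m[, j]
  }
  addm(draws$beta, "beta.")
  addm(draws$tau, "")
  if (!is.null(draws[["b"]])) {
    addm(draws[["b"]], "b.")
    df$sigma_b <- draws[["sigma_b"]]
  }
  if (!is.null(draws[["lambda"]])) {
    addm(draws[["lambda"]], "lambda.")
    df$tau_g <- draws[["tau_g"]]
    df$c <- draws[["c"]]
  }
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_draws
#' @export
read_draws <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  grab <- function(prefix) {
    cols <- grep(paste0("^", prefix, "\\."), names(df), value = TRUE)
    if (!length(cols)) return(NULL)
    m <- as.matrix(df[cols])
    colnames(m) <- sub(paste0("^", prefix, "\\."), "", cols)
    m
  }
  chain <- df$chain
  draws <- list(beta = grab("beta"),
                tau = as.matrix(df[paste0("tau", 1:3)]),
                chain_id = chain,
                n_chains = length(unique(chain)),
                n_iter = sum(chain == chain[1]))
  draws$predictors <- colnames(draws$beta)
  b <- grab("b")
  if (!is.null(b)) {
    draws$b <- b
    draws$sigma_b <- df$sigma_b
    draws$patient_levels <- colnames(b)
  }
  lam <- grab("lambda")
  if (!is.null(lam)) {
    draws$lambda <- lam
    draws$tau_g <- df$tau_g
    draws$c <- df$c
  }
  structure(draws, class = "endosel_draws")
}

#' @export
print.endosel_draws <- function(x, ...) {
  S <- nrow(x$beta)
  cat("Posterior draws:", S, "draws (", x$n_chains, "chains x",
      x$n_iter, ") over", ncol(x$beta), "coefficients\n")
  bm <- sort(abs(colMeans(x$beta)), decreasing = TRUE)
  cat("largest |posterior mean| coefficients:\n")
  for (nm in names(head(bm, 5)))
    cat(sprintf("  %-22s % .3f\n", nm, mean(x$beta[, nm])))
  invisible(x)
}

#' Latent predictor for each posterior draw
#'
#' Computes `eta^(s) = X beta^(s)` for every draw, optionally adding the
#' patient random intercepts `b` for visits from known patients.
#'
#' @param draws an `endosel_draws`.
#' @param X numeric matrix whose columns match the fitted coefficients.
#' @param include_patient add the patient intercept term.
#' @param patient character vector of patient identifiers (required when
#'   `include_patient = TRUE`); unknown patients are an error.
#' @return An S x n matrix.
#' @export
latent_predictor <- function(draws, X, include_patient = FALSE,
                             patient = NULL) {
  X <- as.matrix(X)
  .stop_if(ncol(X) != ncol(draws$beta),
           "X has ", ncol(X), " columns but the model has ",
           ncol(draws$beta), " coefficients")
  eta <- draws$beta %*% t(X)
  if (include_patient) {
    .stop_if(is.null(draws[["b"]]), "model has no patient intercepts")
    .stop_if(is.null(patient), "patient identifiers required")
    idx <- match(as.character(patient), draws[["patient_levels"]])
    .stop_if(anyNA(idx), "unknown patient(s): ",
             paste(unique(patient[is.na(idx)]), collapse = ", "))
    eta <- eta + draws[["b"]][, idx, drop = FALSE]
  }
  eta
}

#' Pointwise log-likelihood matrix
#'
#' Entry `(s, i)` is the log probability the model assigns, under draw
#' `s`, to visit `i`'s observed category:
#' `log category_probs(x_i' beta^(s) + b^(s)_patient(i), tau^(s))[y_i]`.
#'
#' @param draws an `endosel_draws`.
#' @param design an `endosel_design`.
#' @param include_patient include the patient intercept (default TRUE,
#'   matching the fitted model's likelihood).
#' @return An S x n matrix of log probabilities.
#' @export
log_likelihood <- function(draws, design, include_patient = TRUE) {
  eta <- latent_predictor(draws, design$X,
                          include_patient = include_patient &&
                            !is.null(draws[["b"]]),
                          patient = design$patient)
  .loglik_from_eta(eta, draws$tau, design$y)
}

.loglik_from_eta <- function(eta, tau, y) {
  S <- nrow(eta); n <- ncol(eta)
  out <- matrix(NA_real_, S, n)
  for (s in seq_len(S)) {
    p <- category_probs(eta[s, ], tau[s, ])
    out[s, ] <- log(p[cbind(seq_len(n), y)])
  }
  out
}
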