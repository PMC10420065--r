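test_that("projecting onto all columns reproduces the latent predictor exactly", {
  draws <- make_fixed_draws(S = 6, p = 3)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, paste0("x", 1:3)))
  sub <- project_draws(draws, X, paste0("x", 1:3))
  expect_lt(max(sub$sigma_proj), 1e-10)
  eta <- latent_predictor(draws, X)
  pred <- matrix(sub$alpha, 6, 10) + sub$beta_proj %*% t(X)
  expect_equal(pred, eta, tolerance = 1e-8)
})

test_that("the empty projection collapses to the mean with dispersion = sd(eta)", {
  draws <- make_fixed_draws(S = 5, p = 2)
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("x1", "x2")))
  sub <- project_draws(draws, X, character())
  eta <- latent_predictor(draws, X)
  expect_equal(sub$alpha, rowMeans(eta), tolerance = 1e-10)
  pop_var <- rowMeans((eta - rowMeans(eta))^2)
  expect_equal(sub$sigma_proj, sqrt(pop_var), tolerance = 1e-10)
})

test_that("per-draw projection equals a brute-force grid minimizer", {
  draws <- make_fixed_draws(S = 3, p = 3, seed = 4)
  X <- matrix(rnorm(18), 6, 3, dimnames = list(NULL, paste0("x", 1:3)))
  sub <- project_draws(draws, X, c("x1", "x2"))
  eta <- latent_predictor(draws, X)
  Xs <- cbind(1, X[, c("x1", "x2")])
  for (s in 1:3) {
    target <- eta[s, ]
    cf <- c(sub$alpha[s], sub$beta_proj[s, ])
    # coarse-to-fine grid search around the OLS solution
    best <- cf; bestval <- sum((target - Xs %*% cf)^2)
    grid <- as.matrix(expand.grid(a = seq(-1, 1, length.out = 21),
                                  b1 = seq(-1, 1, length.out = 21),
                                  b2 = seq(-1, 1, length.out = 21)))
    for (scale in c(0.5, 0.05, 0.005)) {
      cand <- sweep(grid * scale, 2, best, "+")
      vals <- colSums((target - Xs %*% t(cand))^2)
      if (min(vals) < bestval) {
        bestval <- min(vals); best <- cand[which.min(vals), ]
      }
    }
    expect_equal(unname(cf), unname(best), tolerance = 1e-4)
  }
})

test_that("rank-deficient submodels are rejected", {
  draws <- make_fixed_draws(S = 3, p = 2)
  X <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("x1", "x2")))
  X[, 2] <- 2 * X[, 1]
  expect_error(project_draws(draws, X, c("x1", "x2")),
               "rank-deficient")
})

test_that("submodel predictions compose category_probs with the linear map", {
  draws <- make_fixed_draws(S = 4, p = 2)
  X <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("x1", "x2")))
  sub <- project_draws(draws, X, c("x1", "x2"))
  X_new <- matrix(c(0.3, -1, 2, 0.5), 2, 2,
                  dimnames = list(NULL, c("x1", "x2")))
  probs <- submodel_predict(sub, X_new)
  for (s in 1:4) {
    eta <- sub$alpha[s] + drop(X_new %*% sub$beta_proj[s, ])
    expect_equal(probs[s, , ],
                 unname(category_probs(eta, sub$tau[s, ])),
                 tolerance = 1e-12, ignore_attr = TRUE)
    expect_equal(rowSums(probs[s, , ]), c(1, 1), tolerance = 1e-12)
  }
  # zero projected coefficients predict identically for every row
  sub0 <- sub; sub0$beta_proj[] <- 0
  p0 <- submodel_predict(sub0, X_new)
  expect_equal(p0[, 1, ], p0[, 2, ], tolerance = 1e-12)
})

test_that("MLPD and GMPD obey their defining identities", {
  expect_equal(mlpd(rep(1, 5)), list(mlpd = 0, gmpd = 1))
  r <- mlpd(c(0.5, 0.5))
  expect_equal(r$mlpd, log(0.5), tolerance = 1e-12)
  expect_equal(r$gmpd, 0.5, tolerance = 1e-12)
  set.seed(9)
  p <- runif(10, 0.05, 1)
  r2 <- mlpd(p)
  expect_equal(r2$gmpd, prod(p)^(1 / 10), tolerance = 1e-12)
  expect_equal(r2$gmpd, exp(r2$mlpd), tolerance = 1e-15)
  expect_warning(z <- mlpd(c(0.5, 0)), "zero")
  expect_identical(z$mlpd, -Inf)
})

test_that("delta-MLPD and its standard error follow the paired formula", {
  expect_equal(delta_mlpd(c(-1, -2), c(-1, -2))[c("delta", "se")],
               list(delta = 0, se = 0))
  d <- delta_mlpd(c(0.1, -0.1), c(0, 0))
  expect_equal(d$delta, 0)
  expect_equal(d$se, sd(c(0.1, -0.1)) / sqrt(2), tolerance = 1e-12)
  expect_equal(d$se, 0.1, tolerance = 1e-12)
  expect_error(delta_mlpd(1, 1), "at least 2")
})

test_that("forward search on fitted draws: training curve is monotone and ends at zero", {
  cf <- cached_fit()
  fit <- cf$fit; design <- cf$rd$design
  p <- length(design$terms)
  fs <- forward_search(fit, design, max_size = p)
  # greedy training criterion is non-decreasing while informative
  # candidates remain; once only noise predictors are left the forced
  # addition can dip by O(1e-4) on the draw-averaged density
  expect_true(all(diff(fs$curve$delta_mlpd)[1:5] > 0))
  expect_true(all(diff(fs$curve$delta_mlpd) > -5e-4))
  # exact projection at full size: delta = 0, se = 0
  expect_lt(abs(fs$curve$delta_mlpd[p + 1]), 1e-8)
  expect_lt(fs$curve$se[p + 1], 1e-8)
  expect_equal(fs$curve$lgmpd, exp(fs$curve$delta_mlpd),
               tolerance = 1e-12)
  # the two simulated signals lead the ranking
  expect_setequal(fs$ranking[1:2], c("log_crp", "log_fc"))
})

test_that("forward search handles a single candidate", {
  draws <- make_fixed_draws(S = 4, p = 1)
  X <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "x1"))
  design <- structure(list(X = X, y = rep(1:4, length.out = 30),
                           patient = paste0("p", 1:30),
                           terms = list(x1 = "x1")),
                      class = "endosel_design")
  fs <- forward_search(draws, design, max_size = 1)
  expect_equal(fs$ranking, "x1")
  expect_equal(nrow(fs$curve), 2)
})

test_that("size suggestion applies the one-standard-error rule", {
  curve <- data.frame(size = 1:4,
                      delta_mlpd = c(-0.5, -0.2, -0.01, -0.005),
                      se = rep(0.05, 4))
  expect_equal(suggest_size(curve), 3L)
  all_ok <- data.frame(size = 0:2, delta_mlpd = c(0, 0.1, 0.2),
                       se = rep(0.01, 3))
  expect_equal(suggest_size(all_ok), 0L)
  none <- data.frame(size = 0:2, delta_mlpd = c(-1, -0.9, -0.8),
                     se = rep(0.01, 3))
  expect_message(sz <- suggest_size(none), "falling back")
  expect_equal(sz, 2L)
})

test_that("the finalized SESM serializes losslessly", {
  cf <- cached_fit()
  sesm <- finalize_sesm(cf$fit, cf$rd$design, c("log_crp", "log_fc"),
                        params = cf$rd$params)
  # both projected signal coefficients are bounded away from zero
  qs <- apply(sesm$beta_proj, 2, quantile, c(0.025, 0.975))
  expect_true(all(qs[1, ] > 0))
  path <- tempfile(fileext = ".json")
  write_sesm(sesm, path)
  back <- read_sesm(path)
  X_new <- cf$rd$design$X[1:5, sesm$subset]
  expect_equal(submodel_predict(back, X_new),
               submodel_predict(sesm, X_new), tolerance = 1e-12)
  p1 <- predict_from_biomarkers(sesm, crp = 5, fc = 100)
  p2 <- predict_from_biomarkers(back, crp = 5, fc = 100)
  expect_equal(p1$probs, p2$probs, tolerance = 1e-12)
})

test_that("finalizing on the full term set reproduces the reference predictions", {
  cf <- cached_fit()
  design <- cf$rd$design
  sesm <- finalize_sesm(cf$fit, design, names(design$terms),
                        params = cf$rd$params)
  probs <- submodel_predict(sesm, design$X[, sesm$subset, drop = FALSE])
  eta_ref <- latent_predictor(cf$fit, design$X)
  for (s in c(1, 50)) {
    expect_equal(probs[s, , ],
                 unname(category_probs(eta_ref[s, ], cf$fit$tau[s, ])),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
})
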