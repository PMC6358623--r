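test_that("fitting a covariance constructed from the model recovers theta", {
  model <- build_model(road_sem_spec(c("d_forest", "d_constr")))
  theta0 <- national_true_theta()
  S <- implied_covariance(model, theta0)
  fit <- fit_ml(model, S, n = 500)
  expect_true(fit$converged)
  expect_lt(fit$F_ml, 1e-8)
  expect_equal(unname(fit$theta), unname(theta0[model$free_labels]),
               tolerance = 1e-4)
  expect_lt(fit$grad_norm, 1e-6)
})

test_that("estimates match the normal-equation oracle on a path model", {
  # saturated recursive path model: ML estimates equal OLS algebra on S
  spec <- sem_spec(c("x1", "x2", "y"),
                   regressions = list(c("y", "x1"), c("y", "x2")),
                   covariances = list(c("x1", "x2")))
  set.seed(88)
  n <- 400
  x1 <- rnorm(n); x2 <- 0.5 * x1 + rnorm(n)
  y <- 0.8 * x1 - 0.3 * x2 + rnorm(n)
  dat <- data.frame(x1 = x1, x2 = x2, y = y)
  S <- stats::cov(dat)
  fit <- fit_ml(build_model(spec), S, n)
  expect_true(fit$converged)
  expect_lt(abs(fit$F_ml), 1e-8)  # saturated: zero discrepancy
  b <- unname(solve(S[1:2, 1:2], S[1:2, 3]))
  psi <- S[3, 3] - drop(S[1:2, 3] %*% b)
  expect_equal(fit$theta[["y~x1"]], b[1], tolerance = 1e-4)
  expect_equal(fit$theta[["y~x2"]], b[2], tolerance = 1e-4)
  expect_equal(fit$theta[["y~~y"]], psi, tolerance = 1e-4)
  expect_equal(fit$theta[["x1~~x2"]], S[1, 2], tolerance = 1e-4)
})

test_that("estimates match the closed-form one-factor solution", {
  # just-identified 3-indicator factor model has an algebraic solution
  spec <- sem_spec(c("z1", "z2", "z3"),
                   latents = list(f = c("z1", "z2", "z3")))
  dat <- generate_sem_dataset(spec, c(
    "f=~z2" = 0.8, "f=~z3" = 1.3,
    "z1~~z1" = 0.4, "z2~~z2" = 0.5, "z3~~z3" = 0.3, "f~~f" = 1.2),
    n = 1500, seed = 44)
  S <- stats::cov(dat)
  fit <- fit_ml(build_model(spec), S, n = nrow(dat))
  expect_true(fit$converged)
  phi <- S[1, 2] * S[1, 3] / S[2, 3]
  lam2 <- S[2, 3] / S[1, 3]
  lam3 <- S[2, 3] / S[1, 2]
  expect_equal(fit$theta[["f~~f"]], phi, tolerance = 1e-4)
  expect_equal(fit$theta[["f=~z2"]], lam2, tolerance = 1e-4)
  expect_equal(fit$theta[["f=~z3"]], lam3, tolerance = 1e-4)
  expect_equal(fit$theta[["z1~~z1"]], S[1, 1] - phi, tolerance = 1e-4)
})

test_that("a one-free-parameter fit matches a grid-search oracle", {
  # y <- x with both variances fixed: profile F over the single path
  spec <- sem_spec(c("x", "y"), regressions = list(c("y", "x")),
                   fixed = c("x~~x" = 1, "y~~y" = 0.5))
  model <- build_model(spec)
  expect_equal(model_df(model), 2)
  set.seed(11)
  x <- rnorm(300); y <- 0.6 * x + rnorm(300, sd = sqrt(0.5))
  S <- stats::cov(data.frame(x = x, y = y))
  fit <- fit_ml(model, S, n = 300)
  grid <- seq(-2, 2, by = 1e-4)
  Fv <- vapply(grid, function(b) {
    Sig <- matrix(c(1, b, b, b^2 + 0.5), 2)
    log(det(Sig)) + sum(diag(S %*% solve(Sig))) - log(det(S)) - 2
  }, numeric(1))
  expect_equal(fit$theta[["y~x"]], grid[which.min(Fv)], tolerance = 1e-3)
  expect_equal(fit$F_ml, min(Fv), tolerance = 1e-6)
})

test_that("parameters are recovered without bias at moderate n", {
  model <- build_model(road_sem_spec(c("d_forest", "d_constr")))
  theta0 <- national_true_theta()[model$free_labels]
  dat <- generate_sem_dataset(model, theta0, n = 5000, seed = 202)
  fit <- fit_sem(dat, model)
  expect_true(fit$converged)
  z <- abs(unname(fit$theta) - unname(theta0)) / fit$se
  expect_true(all(z < 4))
})

test_that("fit indices reproduce chi-square tail probabilities and RMSEA", {
  fake <- structure(list(chi2 = 5.297, df = 3, n = 400), class = "rz_sem_fit")
  fi <- fit_indices(fake)
  expect_gt(fi$p_chi2, 0.1)
  expect_equal(fi$p_chi2, 0.1512972, tolerance = 1e-6)
  expect_equal(fi$rmsea, sqrt((5.297 - 3) / (3 * 399)), tolerance = 1e-12)
  # chi2 <= df clamps RMSEA at zero
  fi0 <- fit_indices(structure(list(chi2 = 2.5, df = 3, n = 400),
                               class = "rz_sem_fit"))
  expect_equal(fi0$rmsea, 0)
})

test_that("standardized paths equal implied correlations when simple", {
  m1 <- build_model(sem_spec(c("x", "y"),
                             regressions = list(c("y", "x"))))
  th <- c("y~x" = 0.7, "x~~x" = 2, "y~~y" = 0.5)
  Sig <- implied_covariance(m1, th)
  fit <- fit_ml(m1, Sig, n = 200)
  std <- standardize(fit)
  r_xy <- Sig["x", "y"] / sqrt(Sig["x", "x"] * Sig["y", "y"])
  expect_equal(std$paths$std[std$paths$label == "y~x"], r_xy,
               tolerance = 1e-6)
  expect_equal(std$r2[["y"]], r_xy^2, tolerance = 1e-6)
})

test_that("standardized solution is invariant to rescaling a variable", {
  model <- build_model(road_sem_spec(c("d_forest", "d_constr")))
  dat <- generate_sem_dataset(model, national_true_theta(), n = 3000,
                              seed = 77)
  f1 <- fit_sem(dat, model)
  dat2 <- dat
  dat2$d_elev <- dat2$d_elev * 10
  f2 <- fit_sem(dat2, model)
  s1 <- standardize(f1); s2 <- standardize(f2)
  expect_equal(s1$paths$std, s2$paths$std, tolerance = 1e-4)
  expect_equal(s1$r2, s2$r2, tolerance = 1e-4)
  expect_true(all(unlist(s1$r2) >= 0 & unlist(s1$r2) <= 1))
})

test_that("scaled chi-square stays near the plain one for normal data", {
  model <- build_model(road_sem_spec(c("d_forest", "d_constr")))
  dat <- generate_sem_dataset(model, national_true_theta(), n = 2000,
                              seed = 303)
  fit <- fit_sem(dat, model, robust = TRUE)
  expect_true(is.finite(fit$chi2_scaled))
  expect_gt(fit$scaling_factor, 0.7)
  expect_lt(fit$scaling_factor, 1.4)
})

test_that("stepwise selection keeps a fitting three-indicator model", {
  spec3 <- road_sem_spec()
  model3 <- build_model(spec3)
  theta3 <- c(national_true_theta(),
              "landcover=~d_water" = -0.3, "d_water~~d_water" = 0.6)
  dat <- generate_sem_dataset(model3, theta3, n = 1500, seed = 99)
  sel <- stepwise_indicator_selection(spec3, dat)
  expect_true(sel$met)
  expect_equal(sel$log$step[nrow(sel$log)], 0)
  expect_setequal(sel$spec$latents$landcover,
                  c("d_forest", "d_constr", "d_water"))
})

test_that("stepwise selection removes a misfitting indicator, never forest", {
  # d_water generated off-structure: correlated with the exogenous block
  # directly rather than through the latent factor
  model2 <- build_model(road_sem_spec(c("d_forest", "d_constr")))
  for (s in 1:5) {
    dat <- generate_sem_dataset(model2, national_true_theta(), n = 1200,
                                seed = 400 + s)
    set.seed(500 + s)
    dat$d_water <- 0.9 * dat$sqrt_dist - 0.8 * dat$d_pop +
      rnorm(nrow(dat), sd = 0.4)
    sel <- suppressWarnings(stepwise_indicator_selection(road_sem_spec(),
                                                         dat))
    removed <- sel$log$removed[sel$log$action == "remove"]
    expect_false("d_forest" %in% removed)
    expect_true(all(removed %in% c("d_constr", "d_water")))
    expect_gte(length(sel$spec$latents$landcover), 2)
  }
})

test_that("degenerate covariance inputs are rejected", {
  model <- build_model(sem_spec(c("x", "y")))
  bad <- matrix(c(1, 2, 2, 1), 2)  # not PD
  expect_error(fit_ml(model, bad, n = 50), "positive definite")
  asym <- matrix(c(1, 0.9, 0.1, 1), 2)
  expect_error(fit_ml(model, asym, n = 50), "symmetric")
  expect_error(fit_ml(model, diag(2), n = 2), "exceed")
})
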