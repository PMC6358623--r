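# RAM-form covariance algebra and normal-theory ML estimation.
#
# Sigma_all(theta) = B S B' with B = (I - A)^-1 over all variables
# (observed first); the model-implied covariance of the observed variables
# is the leading p x p block. The ML discrepancy is
#   F(theta) = log det Sigma + tr(S_samp Sigma^-1) - log det S_samp - p,
# minimized by quasi-Newton with an analytic gradient.

# Fill A and S from the parameter table and a free-parameter vector.
sem_matrices <- function(model, theta) {
  m <- length(model$vars)
  A <- matrix(0, m, m)
  S <- matrix(0, m, m)
  pt <- model$params
  val <- pt$value
  val[pt$free] <- theta
  for (k in seq_len(nrow(pt))) {
    if (pt$matrix[k] == "A") {
      A[pt$row[k], pt$col[k]] <- val[k]
    } else {
      S[pt$row[k], pt$col[k]] <- val[k]
      S[pt$col[k], pt$row[k]] <- val[k]
    }
  }
  list(A = A, S = S)
}

# Sigma over all variables (observed + latent).
implied_cov_all <- function(model, theta) {
  ms <- sem_matrices(model, theta)
  m <- length(model$vars)
  B <- solve(diag(m) - ms$A)
  B %*% ms$S %*% t(B)
}

#' Model-implied covariance matrix of the observed variables
#'
#' @param model an `rz_sem_model` from [build_model()].
#' @param theta numeric vector of free parameters, in `model$free_labels`
#'   order (a named vector is matched by label).
#' @return symmetric p x p matrix with observed-variable dimnames.
#' @export
implied_covariance <- function(model, theta) {
  stopifnot(inherits(model, "rz_sem_model"))
  theta <- match_theta(model, theta)
  p <- model$n_obs_var
  Sig <- implied_cov_all(model, theta)[seq_len(p), seq_len(p), drop = FALSE]
  dimnames(Sig) <- list(model$spec$observed, model$spec$observed)
  Sig
}

match_theta <- function(model, theta) {
  if (!is.null(names(theta)) && all(nzchar(names(theta)))) {
    if (!setequal(names(theta), model$free_labels))
      stop("named theta must cover exactly the free parameters")
    theta <- theta[model$free_labels]
  }
  if (length(theta) != length(model$free_labels))
    stop(sprintf("theta has length %d but the model has %d free parameters",
                 length(theta), length(model$free_labels)))
  unname(theta)
}

# F_ML and its analytic gradient. Returns +Inf-like penalty off the
# admissible region (non-invertible I - A or non-PD Sigma).
fml_objective <- function(model, S_samp, ldet_S, p) {
  m <- length(model$vars)
  pt <- model$params
  free_idx <- which(pt$free)
  function(theta, gradient = FALSE) {
    ms <- sem_matrices(model, theta)
    B <- tryCatch(solve(diag(m) - ms$A), error = function(e) NULL)
    if (is.null(B)) return(if (gradient) NULL else 1e10)
    C <- B %*% ms$S %*% t(B)
    Sig <- C[seq_len(p), seq_len(p), drop = FALSE]
    ch <- tryCatch(chol(Sig), error = function(e) NULL)
    if (is.null(ch)) return(if (gradient) NULL else 1e10)
    Sig_inv <- chol2inv(ch)
    ldet <- 2 * sum(log(diag(ch)))
    f <- ldet + sum(Sig_inv * S_samp) - ldet_S - p
    if (!gradient) return(f)
    # W = Sigma^-1 - Sigma^-1 S Sigma^-1, embedded over all variables
    W <- Sig_inv - Sig_inv %*% S_samp %*% Sig_inv
    M <- matrix(0, m, m)
    M[seq_len(p), seq_len(p)] <- W
    T1 <- t(B) %*% M %*% B      # for S-parameters
    T2 <- t(B) %*% M %*% C      # for A-parameters
    g <- numeric(length(free_idx))
    for (q in seq_along(free_idx)) {
      k <- free_idx[q]
      i <- pt$row[k]; j <- pt$col[k]
      g[q] <- if (pt$matrix[k] == "A") {
        2 * T2[i, j]
      } else if (i == j) {
        T1[i, i]
      } else {
        2 * T1[i, j]
      }
    }
    list(value = f, grad = g)
  }
}

sem_start_values <- function(model, S_samp) {
  pt <- model$params
  vars <- model$vars
  p <- model$n_obs_var
  obs <- model$spec$observed
  svar <- diag(S_samp)
  start <- numeric(sum(pt$free))
  q <- 0L
  for (k in which(pt$free)) {
    q <- q + 1L
    lab <- pt$label[k]
    if (pt$matrix[k] == "A") {
      if (grepl("=~", lab, fixed = TRUE)) {
        # loading: moment ratio against the reference indicator, which
        # carries the sign of the sample covariance
        L <- vars[pt$col[k]]
        ind1 <- model$spec$latents[[L]][1]
        i1 <- match(ind1, obs)
        start[q] <- S_samp[pt$row[k], i1] / svar[i1]
      } else {
        start[q] <- 0
      }
    } else if (pt$row[k] == pt$col[k]) {
      v <- pt$row[k]
      start[q] <- if (v <= p) {
        if (vars[v] %in% model$endogenous) 0.5 * svar[v] else svar[v]
      } else {
        # latent (dis)turbance: scale from its first indicator
        L <- vars[v]
        ind1 <- model$spec$latents[[L]][1]
        0.5 * svar[match(ind1, obs)]
      }
    } else {
      i <- pt$row[k]; j <- pt$col[k]
      start[q] <- if (i <= p && j <= p) 0.9 * S_samp[i, j] else 0
    }
  }
  start
}

#' Fit a structural model to a sample covariance matrix by maximum likelihood
#'
#' Minimizes the normal-theory ML discrepancy by quasi-Newton (`nlminb`
#' with an analytic gradient, BFGS polish) from documented start values
#' (free loadings 1, paths 0, variances from the sample diagonal). The
#' convergence flag requires the gradient max-norm at the reported optimum
#' to be below `grad_tol`; non-convergence is reported, never silent.
#'
#' @param model an `rz_sem_model`.
#' @param S_samp sample covariance matrix (symmetric positive definite),
#'   columns in `model$spec$observed` order (matched by dimnames when
#'   present).
#' @param n number of observation rows behind `S_samp`.
#' @param start optional start vector overriding the defaults.
#' @param grad_tol gradient max-norm defining convergence.
#' @return object of class `rz_sem_fit`: `theta` (named estimates),
#'   `F_ml`, `chi2 = (n-1) F_ml`, `df`, `p_chi2`, `rmsea`, `n`,
#'   `converged`, `grad_norm`, `se` (delta-method standard errors, NA when
#'   the information matrix is singular), plus the `model` and inputs.
#' @export
fit_ml <- function(model, S_samp, n, start = NULL, grad_tol = 1e-6) {
  stopifnot(inherits(model, "rz_sem_model"))
  p <- model$n_obs_var
  if (!is.null(dimnames(S_samp)) &&
      all(model$spec$observed %in% colnames(S_samp)))
    S_samp <- S_samp[model$spec$observed, model$spec$observed]
  if (nrow(S_samp) != p) stop("S_samp dimension does not match the model")
  if (max(abs(S_samp - t(S_samp))) > 1e-8 * max(abs(S_samp)))
    stop("sample covariance matrix is not symmetric")
  ch <- tryCatch(chol(S_samp), error = function(e) NULL)
  if (is.null(ch)) stop("sample covariance matrix is not positive definite")
  if (n <= p) stop("n must exceed the number of observed variables")
  ldet_S <- 2 * sum(log(diag(ch)))

  obj <- fml_objective(model, S_samp, ldet_S, p)
  fn <- function(th) obj(th)
  gr <- function(th) {
    r <- obj(th, gradient = TRUE)
    if (is.null(r)) rep(0, length(th)) else r$grad
  }
  if (is.null(start)) start <- sem_start_values(model, S_samp)
  pt <- model$params
  is_var <- pt$matrix[pt$free] == "S" & pt$row[pt$free] == pt$col[pt$free]
  lower <- ifelse(is_var, 1e-8, -Inf)

  run_from <- function(s0) {
    op <- stats::nlminb(s0, fn, gr, lower = lower,
                        control = list(iter.max = 1000, eval.max = 2000,
                                       rel.tol = 1e-14))
    th <- op$par
    # bounded quasi-Newton polish passes drive the gradient to tolerance
    for (round in 1:3) {
      if (max(abs(gr(th))) < grad_tol) break
      op2 <- tryCatch(
        stats::optim(th, fn, gr, method = "L-BFGS-B", lower = lower,
                     control = list(maxit = 500, factr = 10)),
        error = function(e) NULL)
      if (!is.null(op2) && op2$value <= fn(th)) th <- op2$par
    }
    th
  }
  theta <- run_from(start)
  # deterministic restarts if the first basin is poor (e.g. a loading-sign
  # saddle): flip loading starts, rescale variance starts
  if (max(abs(gr(theta))) >= grad_tol) {
    is_loading <- grepl("=~", pt$label[pt$free], fixed = TRUE)
    alt_starts <- list(
      {s <- start; s[is_loading] <- -s[is_loading]; s},
      {s <- start; s[is_loading] <- 0.1; s},
      {s <- start; s[is_var] <- 2 * s[is_var]; s}
    )
    for (s0 in alt_starts) {
      cand <- run_from(s0)
      if (fn(cand) < fn(theta)) theta <- cand
      if (max(abs(gr(theta))) < grad_tol) break
    }
  }
  g <- gr(theta)
  F_ml <- fn(theta)
  # first-order (KKT) condition: interior gradients vanish; a variance
  # held at its lower bound may keep a positive inward gradient
  at_bound <- is.finite(lower) & theta <= lower + 1e-7
  converged <- is.finite(F_ml) &&
    max(abs(g[!at_bound]), 0) < grad_tol && all(g[at_bound] > -grad_tol)
  if (any(at_bound))
    warning("variance estimate(s) at the lower bound (Heywood case): ",
            paste(model$free_labels[at_bound], collapse = ", "))
  if (!converged)
    warning("fit_ml did not reach the gradient tolerance (|g|max = ",
            format(max(abs(g)), digits = 3), ")")

  df <- model$df
  chi2 <- (n - 1) * F_ml
  se <- tryCatch({
    H <- numeric_hessian(gr, theta)
    V <- solve((n - 1) / 2 * (H + t(H)) / 2)
    sqrt(pmax(diag(V), 0))
  }, error = function(e) rep(NA_real_, length(theta)))

  structure(list(
    theta = stats::setNames(theta, model$free_labels),
    se = stats::setNames(se, model$free_labels),
    F_ml = F_ml, chi2 = chi2, df = df,
    p_chi2 = if (df > 0) stats::pchisq(chi2, df, lower.tail = FALSE) else
      NA_real_,
    rmsea = rmsea_value(chi2, df, n),
    n = n, S_samp = S_samp, model = model,
    converged = converged, grad_norm = max(abs(g))
  ), class = "rz_sem_fit")
}

numeric_hessian <- function(gr, theta, h = 1e-5) {
  k <- length(theta)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    H[, j] <- (gr(tp) - gr(tm)) / (2 * h)
  }
  H
}

rmsea_value <- function(chi2, df, n) {
  if (df == 0) return(0)
  sqrt(max(chi2 - df, 0) / (df * (n - 1)))
}

#' Fit indices of a structural model fit
#'
#' @param fit an `rz_sem_fit`.
#' @return list with `chi2`, `df`, `p_chi2` (upper-tail chi-square
#'   probability) and `rmsea` (`sqrt(max(chi2 - df, 0) / (df (n - 1)))`,
#'   defined as 0 for saturated models). The conventional good-fit screen
#'   is `p_chi2 > 0.05` together with `rmsea < 0.05`.
#' @export
fit_indices <- function(fit) {
  stopifnot(inherits(fit, "rz_sem_fit"))
  list(chi2 = fit$chi2, df = fit$df,
       p_chi2 = if (fit$df > 0)
         stats::pchisq(fit$chi2, fit$df, lower.tail = FALSE) else NA_real_,
       rmsea = rmsea_value(fit$chi2, fit$df, fit$n))
}

#' Standardized solution and explained variance
#'
#' Rescales every loading and path by the model-implied standard deviations
#' of its predictor and outcome (all-variable standardization) and reports
#' `R^2 = 1 - standardized residual variance` for every endogenous
#' variable. The standardized solution is invariant to rescaling any
#' observed variable and to the identification convention.
#'
#' @param fit an `rz_sem_fit`.
#' @return list with `paths` (data.frame: label, estimate, std) and `r2`
#'   (named numeric over endogenous variables).
#' @export
standardize <- function(fit) {
  stopifnot(inherits(fit, "rz_sem_fit"))
  model <- fit$model
  theta <- unname(fit$theta)
  Call <- implied_cov_all(model, theta)
  sdv <- sqrt(pmax(diag(Call), .Machine$double.eps))
  pt <- model$params
  val <- pt$value
  val[pt$free] <- theta
  a_rows <- pt$matrix == "A"
  std <- numeric(nrow(pt))
  std[a_rows] <- val[a_rows] * sdv[pt$col[a_rows]] / sdv[pt$row[a_rows]]
  cv <- pt$matrix == "S" & pt$row != pt$col
  std[cv] <- val[cv] / (sdv[pt$row[cv]] * sdv[pt$col[cv]])
  vr <- pt$matrix == "S" & pt$row == pt$col
  std[vr] <- val[vr] / sdv[pt$row[vr]]^2

  paths <- data.frame(label = pt$label, matrix = pt$matrix,
                      estimate = val, std = std, free = pt$free,
                      stringsAsFactors = FALSE)
  vi <- stats::setNames(seq_along(model$vars), model$vars)
  r2 <- vapply(model$endogenous, function(v) {
    i <- vi[[v]]
    resid <- val[pt$matrix == "S" & pt$row == i & pt$col == i]
    1 - resid / Call[i, i]
  }, numeric(1))
  list(paths = paths, r2 = r2)
}

#' @export
print.rz_sem_fit <- function(x, ...) {
  cat(sprintf(
    "<rz_sem_fit> chi2 = %.3f, df = %d, p = %s, RMSEA = %.4f, n = %d%s\n",
    x$chi2, x$df,
    if (is.na(x$p_chi2)) "NA" else sprintf("%.3f", x$p_chi2),
    x$rmsea, x$n,
    if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

# vech and duplication matrix (small p only; used for the scaled chi2).
vech <- function(M) M[lower.tri(M, diag = TRUE)]

duplication_matrix <- function(p) {
  ps <- p * (p + 1) / 2
  D <- matrix(0, p * p, ps)
  k <- 0L
  for (j in seq_len(p)) for (i in j:p) {
    k <- k + 1L
    D[(j - 1) * p + i, k] <- 1
    D[(i - 1) * p + j, k] <- 1
  }
  D
}

# Jacobian d vech(Sigma) / d theta, by central differences on the implied
# covariance (exact algebra is available for the gradient; the Jacobian is
# only needed for the scaling factor, where numeric accuracy suffices).
sigma_jacobian <- function(model, theta, h = 1e-6) {
  k <- length(theta)
  J <- matrix(0, model$n_obs_var * (model$n_obs_var + 1) / 2, k)
  for (j in seq_len(k)) {
    tp <- theta; tp[j] <- tp[j] + h
    tm <- theta; tm[j] <- tm[j] - h
    J[, j] <- (vech(implied_covariance(model, tp)) -
                 vech(implied_covariance(model, tm))) / (2 * h)
  }
  J
}

#' Fit a structural model to raw data, optionally with a scaled chi-square
#'
#' Computes the sample covariance of the (listwise-complete) data and calls
#' [fit_ml()]. With `robust = TRUE` a Satorra-Bentler-style mean-scaled
#' chi-square is added: the normal-theory statistic is divided by
#' `c = tr(U Gamma) / df`, where `Gamma` is the fourth-moment
#' (asymptotically distribution-free) covariance matrix of the sample
#' moments and `U` the normal-theory residual weight. Both the plain and
#' the scaled statistics are kept in the returned fit.
#'
#' @param data data.frame or matrix of observations (columns must include
#'   the model's observed variables).
#' @param spec an [sem_spec()] (or an already-built `rz_sem_model`).
#' @param robust logical; add the mean-scaled chi-square.
#' @param ... passed to [fit_ml()].
#' @return an `rz_sem_fit`; with `robust = TRUE` it gains `chi2_scaled`,
#'   `scaling_factor`, `p_chi2_scaled` and `rmsea_scaled`, and its headline
#'   `p_chi2`/`rmsea` switch to the scaled versions.
#' @export
fit_sem <- function(data, spec, robust = FALSE, ...) {
  model <- if (inherits(spec, "rz_sem_model")) spec else build_model(spec)
  data <- as.data.frame(data)[, model$spec$observed, drop = FALSE]
  data <- data[stats::complete.cases(data), , drop = FALSE]
  n <- nrow(data)
  S <- stats::cov(data)
  fit <- fit_ml(model, S, n, ...)
  fit$data_cols <- colnames(data)
  if (robust) {
    p <- model$n_obs_var
    Y <- scale(as.matrix(data), center = TRUE, scale = FALSE)
    Wv <- t(apply(Y, 1, function(r) vech(tcrossprod(r))))
    Gamma <- stats::cov(Wv) * (n - 1) / n
    Sig <- implied_covariance(model, unname(fit$theta))
    Sig_inv <- solve(Sig)
    D <- duplication_matrix(p)
    V <- 0.5 * t(D) %*% (Sig_inv %x% Sig_inv) %*% D
    Delta <- sigma_jacobian(model, unname(fit$theta))
    VD <- V %*% Delta
    U <- V - VD %*% solve(t(Delta) %*% VD, t(VD))
    cfac <- sum(diag(U %*% Gamma)) / fit$df
    fit$scaling_factor <- cfac
    fit$chi2_scaled <- fit$chi2 / cfac
    fit$p_chi2_scaled <- stats::pchisq(fit$chi2_scaled, fit$df,
                                       lower.tail = FALSE)
    fit$rmsea_scaled <- rmsea_value(fit$chi2_scaled, fit$df, n)
    fit$p_chi2 <- fit$p_chi2_scaled
    fit$rmsea <- fit$rmsea_scaled
  }
  fit
}

#' Simulate observations from a structural model at known parameters
#'
#' Draws `n` multivariate-normal rows whose population covariance equals
#' the model-implied covariance at `theta`; the generator for
#' parameter-recovery and calibration studies.
#'
#' @param spec an [sem_spec()] or `rz_sem_model`.
#' @param theta free-parameter vector (named by label or positional).
#' @param n number of rows.
#' @param seed integer seed (mandatory).
#' @return data.frame with the model's observed variables as columns.
#' @export
generate_sem_dataset <- function(spec, theta, n, seed) {
  if (missing(seed)) stop("seed is required")
  model <- if (inherits(spec, "rz_sem_model")) spec else build_model(spec)
  theta <- match_theta(model, theta)
  Sig <- implied_covariance(model, theta)
  ev <- eigen(Sig, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-12)
    stop(sprintf(
      "implied covariance at theta is not positive definite (eigenvalue %.3e)",
      min(ev)))
  set.seed(as.integer(seed))
  Z <- matrix(stats::rnorm(n * nrow(Sig)), n) %*% chol(Sig)
  colnames(Z) <- model$spec$observed
  as.data.frame(Z)
}

drop_indicator <- function(spec, var) {
  latents <- lapply(spec$latents, function(ind) setdiff(ind, var))
  sem_spec(observed = setdiff(spec$observed, var), latents = latents,
           regressions = spec$regressions,
           covariances = spec$covariances, fixed = spec$fixed)
}

#' Stepwise removal of land-use indicators until the model fits
#'
#' Starting from the three-indicator conceptual model, refits after
#' removing one non-forest land-cover indicator at a time until the fit
#' meets both criteria (`p_chi2 > 0.05` and `rmsea < 0.05`). At each step
#' the candidate whose removal yields the lowest RMSEA is taken; the forest
#' indicator is never a candidate. If only two indicators remain and the
#' criteria are still unmet, the procedure reports failure (it never
#' reduces the factor below two indicators). The full removal log, with
#' candidate RMSEAs, is returned.
#'
#' @param spec initial [sem_spec()] whose latent factor includes the
#'   protected indicator.
#' @param data observation data.frame.
#' @param keep indicator that must always stay (default `"d_forest"`).
#' @param p_min,rmsea_max fit criteria.
#' @param robust passed to [fit_sem()].
#' @param ... passed on to [fit_sem()].
#' @return list with `fit` (final `rz_sem_fit`), `spec` (final spec),
#'   `met` (logical: criteria satisfied), and `log` (data.frame of steps:
#'   step, action, removed, chi2, df, p_chi2, rmsea, candidates).
#' @export
stepwise_indicator_selection <- function(spec, data, keep = "d_forest",
                                         p_min = 0.05, rmsea_max = 0.05,
                                         robust = FALSE, ...) {
  stopifnot(inherits(spec, "rz_sem_spec"), length(spec$latents) == 1)
  L <- names(spec$latents)[1]
  if (!keep %in% spec$latents[[L]])
    stop("protected indicator '", keep, "' is not in the latent factor")
  log_rows <- list()
  step <- 0L
  repeat {
    fit <- fit_sem(data, spec, robust = robust, ...)
    fi <- fit_indices(fit)
    met <- isTRUE(fi$p_chi2 > p_min) && isTRUE(fi$rmsea < rmsea_max)
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      step = step, action = if (met) "accept" else "evaluate",
      removed = NA_character_, chi2 = fi$chi2, df = fi$df,
      p_chi2 = fi$p_chi2, rmsea = fi$rmsea, candidates = NA_character_)
    if (met)
      return(list(fit = fit, spec = spec, met = TRUE,
                  log = do.call(rbind, log_rows)))
    candidates <- setdiff(spec$latents[[L]], keep)
    if (length(spec$latents[[L]]) <= 2 || length(candidates) == 0) {
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        step = step, action = "fail", removed = NA_character_,
        chi2 = fi$chi2, df = fi$df, p_chi2 = fi$p_chi2, rmsea = fi$rmsea,
        candidates = "none: factor at minimum size")
      return(list(fit = fit, spec = spec, met = FALSE,
                  log = do.call(rbind, log_rows)))
    }
    cand_rmsea <- vapply(candidates, function(v) {
      f <- fit_sem(data, drop_indicator(spec, v), robust = robust, ...)
      fit_indices(f)$rmsea
    }, numeric(1))
    best <- candidates[which.min(cand_rmsea)]
    step <- step + 1L
    log_rows[[length(log_rows) + 1L]] <- data.frame(
      step = step, action = "remove", removed = best, chi2 = NA_real_,
      df = NA_real_, p_chi2 = NA_real_, rmsea = NA_real_,
      candidates = paste(sprintf("%s=%.4f", candidates, cand_rmsea),
                         collapse = "; "))
    spec <- drop_indicator(spec, best)
  }
}
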