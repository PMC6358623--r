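#' Declarative specification of a covariance-structure model
#'
#' Describes a linear structural equation model: observed variables, latent
#' factors with ordered indicator lists (the first indicator's loading is
#' fixed to 1 for identification), directed regression paths among latents
#' and observed variables, and free covariances among exogenous variables.
#' Any parameter can additionally be fixed to a constant by label.
#'
#' @param observed character vector of observed variable names.
#' @param latents named list: latent name -> character vector of indicator
#'   names (each an observed variable; at least 2 per latent). The first
#'   indicator carries the fixed unit loading.
#' @param regressions list of length-2 character vectors
#'   `c(outcome, predictor)`.
#' @param covariances list of length-2 character vectors of variable pairs
#'   given free covariances (conventionally the exogenous block).
#' @param fixed named numeric: parameter label -> fixed value (labels as in
#'   the built parameter table, e.g. `"y~x"`, `"L=~z"`, `"x~~x"`).
#' @return object of class `rz_sem_spec`.
#' @export
sem_spec <- function(observed, latents = list(), regressions = list(),
                     covariances = list(), fixed = numeric(0)) {
  stopifnot(is.character(observed), length(observed) > 0,
            !anyDuplicated(observed))
  all_vars <- c(observed, names(latents))
  if (anyDuplicated(all_vars))
    stop("latent names must not clash with observed names")
  for (L in names(latents)) {
    ind <- latents[[L]]
    if (length(ind) < 2)
      stop("latent '", L, "' needs at least 2 indicators")
    if (!all(ind %in% observed))
      stop("indicators of '", L, "' must be observed variables")
  }
  for (r in regressions) {
    if (length(r) != 2 || !all(r %in% all_vars))
      stop("regression path references undeclared variable: ",
           paste(r, collapse = " ~ "))
  }
  for (cv in covariances) {
    if (length(cv) != 2 || !all(cv %in% all_vars))
      stop("covariance references undeclared variable: ",
           paste(cv, collapse = " ~~ "))
  }
  structure(list(observed = observed, latents = latents,
                 regressions = regressions, covariances = covariances,
                 fixed = fixed),
            class = "rz_sem_spec")
}

#' Road-effect structural model specification
#'
#' The conceptual model for section-pair differences: a latent land-cover
#' factor measured by land-cover difference indicators (forest always first,
#' carrying the fixed loading), regressed on sqrt road distance, elevation
#' difference and population difference; sign-density difference regressed
#' on the latent factor and on the same three exogenous predictors; free
#' covariances among the exogenous block. With `c("d_forest", "d_constr")`
#' this is the final national-roads structure, with
#' `c("d_forest", "d_water")` the final provincial-roads structure, and
#' with all three indicators the initial conceptual model.
#'
#' @param indicators character vector of land-cover indicators (must
#'   include `"d_forest"`, which is placed first).
#' @return an [sem_spec()].
#' @export
road_sem_spec <- function(indicators = c("d_forest", "d_constr",
                                         "d_water")) {
  if (!"d_forest" %in% indicators)
    stop("the land-cover factor must include d_forest")
  indicators <- c("d_forest", setdiff(indicators, "d_forest"))
  exog <- c("sqrt_dist", "d_elev", "d_pop")
  sem_spec(
    observed = c(exog, indicators, "d_density"),
    latents = list(landcover = indicators),
    regressions = c(
      lapply(exog, function(v) c("landcover", v)),
      list(c("d_density", "landcover")),
      lapply(exog, function(v) c("d_density", v))
    ),
    covariances = list(c("sqrt_dist", "d_elev"), c("sqrt_dist", "d_pop"),
                       c("d_elev", "d_pop"))
  )
}

#' Build the parameter table of a structural model
#'
#' Lays out the free/fixed parameter bookkeeping: factor loadings (first per
#' latent fixed at 1), regression paths, variances (exogenous variances,
#' residual variances of endogenous variables, latent disturbances) and the
#' declared covariances. The model is stored in RAM form: an asymmetric
#' path/loading matrix `A` and a symmetric (co)variance matrix `S` over all
#' variables (observed first, then latents), with
#' `Sigma_all = (I - A)^-1 S (I - A)^-T`.
#'
#' @param spec an [sem_spec()].
#' @return object of class `rz_sem_model`: list with `spec`, `vars`,
#'   `n_obs_var` (count of observed variables), `params` (the parameter
#'   table), `free_labels`, and `df`.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "rz_sem_spec"))
  vars <- c(spec$observed, names(spec$latents))
  p <- length(spec$observed)
  m <- length(vars)
  vi <- stats::setNames(seq_len(m), vars)

  rows <- list()
  add <- function(mat, i, j, free, value, label) {
    rows[[length(rows) + 1L]] <<- data.frame(
      matrix = mat, row = i, col = j, free = free, value = value,
      label = label, stringsAsFactors = FALSE)
  }

  # measurement: loadings indicator <- latent
  for (L in names(spec$latents)) {
    ind <- spec$latents[[L]]
    add("A", vi[ind[1]], vi[L], FALSE, 1, paste0(L, "=~", ind[1]))
    for (v in ind[-1]) add("A", vi[v], vi[L], TRUE, NA, paste0(L, "=~", v))
  }
  # structural: outcome <- predictor
  for (r in spec$regressions)
    add("A", vi[r[1]], vi[r[2]], TRUE, NA, paste0(r[1], "~", r[2]))

  endo <- unique(c(unlist(spec$latents),
                   vapply(spec$regressions, `[`, character(1), 1)))
  # variances: exogenous variance or residual/disturbance variance
  for (v in vars)
    add("S", vi[v], vi[v], TRUE, NA, paste0(v, "~~", v))
  # declared covariances
  for (cv in spec$covariances) {
    i <- vi[cv[1]]; j <- vi[cv[2]]
    add("S", min(i, j), max(i, j), TRUE, NA,
        paste0(vars[min(i, j)], "~~", vars[max(i, j)]))
  }

  params <- do.call(rbind, rows)
  if (anyDuplicated(params$label))
    stop("duplicated parameter(s) in specification: ",
         paste(unique(params$label[duplicated(params$label)]),
               collapse = ", "))

  # user-fixed parameters override
  for (lab in names(spec$fixed)) {
    k <- match(lab, params$label)
    if (is.na(k)) stop("fixed parameter '", lab, "' not in the model")
    params$free[k] <- FALSE
    params$value[k] <- spec$fixed[[lab]]
  }

  n_free <- sum(params$free)
  df <- p * (p + 1) / 2 - n_free
  if (df < 0)
    stop(sprintf(paste0("model is under-identified: %d free parameters ",
                        "exceed %d unique covariance moments (p = %d)"),
                 n_free, p * (p + 1) / 2, p))
  structure(list(spec = spec, vars = vars, n_obs_var = p,
                 endogenous = endo, params = params,
                 free_labels = params$label[params$free], df = df),
            class = "rz_sem_model")
}

#' Degrees of freedom of a built model
#'
#' `p(p+1)/2` unique covariance moments minus the number of free
#' parameters.
#'
#' @param model an `rz_sem_model`.
#' @return integer degrees of freedom.
#' @export
model_df <- function(model) {
  stopifnot(inherits(model, "rz_sem_model"))
  model$df
}

#' @export
print.rz_sem_model <- function(x, ...) {
  cat(sprintf("<rz_sem_model> %d observed, %d latent; %d free parameters, df = %d\n",
              x$n_obs_var, length(x$vars) - x$n_obs_var,
              sum(x$params$free), x$df))
  invisible(x)
}
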