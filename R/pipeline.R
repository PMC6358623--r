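#' Configuration for a full analysis run
#'
#' Either `simulate` (arguments for [landscape_params()], seed excluded) or
#' `inputs` (paths to on-disk roads/signs/rasters) must be given. The seed
#' is mandatory and drives every stochastic stage.
#'
#' @param simulate named list of [landscape_params()] arguments, or NULL.
#' @param inputs named list of file paths (`roads`, `signs`, `elevation`,
#'   `forest`, `construction`, `water`, `population`), or NULL.
#' @param road_class road class to analyze.
#' @param schedule named list of [ring_schedule()] arguments.
#' @param band elevation band (m).
#' @param grid_cell_m analysis grid size (m).
#' @param min_area_km2 usability floor for clipped sections.
#' @param dedup_dist_m sign deduplication distance (m).
#' @param alpha per-ring significance level.
#' @param rule effect-zone rule (see [effect_zone()]).
#' @param exclusion_m minimum copy distance from roads (0 = anywhere in the
#'   study area).
#' @param sem logical; fit the structural model stage.
#' @param sem_min_rows smallest pair table the SEM stage will accept.
#' @param robust logical; scaled chi-square in the SEM stage.
#' @param seed integer seed (mandatory).
#' @param out_dir output directory, or NULL to skip writing files.
#' @return validated list of class `rz_config`.
#' @export
pipeline_config <- function(simulate = NULL, inputs = NULL,
                            road_class = "national",
                            schedule = list(), band = c(1600, 3800),
                            grid_cell_m = 15000, min_area_km2 = 0.25,
                            dedup_dist_m = 100, alpha = 0.05,
                            rule = "last_significant", exclusion_m = 0,
                            sem = TRUE, sem_min_rows = 30, robust = FALSE,
                            seed, out_dir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  if (is.null(simulate) && is.null(inputs))
    stop("either simulate parameters or input paths must be provided")
  structure(list(simulate = simulate, inputs = inputs,
                 road_class = road_class, schedule = schedule, band = band,
                 grid_cell_m = grid_cell_m, min_area_km2 = min_area_km2,
                 dedup_dist_m = dedup_dist_m, alpha = alpha, rule = rule,
                 exclusion_m = exclusion_m, sem = sem,
                 sem_min_rows = sem_min_rows, robust = robust,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "rz_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose top-level keys are [pipeline_config()]
#'   arguments.
#' @return an `rz_config`.
#' @export
read_config_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read YAML configurations")
  do.call(pipeline_config, yaml::read_yaml(path))
}

# Deterministic identifier for a configuration (rolling polynomial hash of
# its JSON serialization); stamped into every output file.
config_hash <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL  # identify the analysis, not where it lands on disk
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                        null = "null")
  b <- utf8ToInt(as.character(s))
  h <- 0
  for (v in b) h <- (h * 131 + v) %% 2147483647
  sprintf("%010d", as.integer(h))
}

load_bundle_from_inputs <- function(inputs) {
  roads <- read_roads_geojson(inputs$roads)
  signs <- utils::read.csv(inputs$signs)
  rasters <- lapply(inputs[c("elevation", "forest", "construction",
                             "water", "population")], read_ascii_grid)
  tmpl <- rasters$elevation
  structure(c(
    list(study_area = study_area_rect(
      tmpl$xmin, tmpl$ymin,
      tmpl$xmin + tmpl$ncol * tmpl$cellsize,
      tmpl$ymin + tmpl$nrow * tmpl$cellsize),
      roads = roads),
    rasters,
    list(dist = list(national = NULL, provincial = NULL),
         signs = signs, truth = NULL)
  ), class = "rz_landscape")
}

#' Run the full road-effect analysis pipeline
#'
#' Executes simulate (or load) -> ring-buffer geometry -> rigid-motion
#' randomization -> per-ring paired density tests and effect-zone rule ->
#' structural equation modelling, and (when `out_dir` is set) writes the
#' per-ring result table (CSV), the effect-zone report (JSON), the SEM
#' report (JSON) and a run manifest. Identical configuration and seed give
#' identical outputs; every output carries the configuration hash. A stage
#' failure aborts with a stage-named error and removes partial outputs.
#'
#' @param config an `rz_config` from [pipeline_config()].
#' @return list with `bundle`, `sections`, `pairs`, `ring_table`, `zone`,
#'   `sem` (NULL when skipped) and `manifest`, invisibly when writing.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "rz_config"))
  hash <- config_hash(config)
  out <- config$out_dir
  written <- character(0)
  if (!is.null(out) && !dir.exists(out))
    dir.create(out, recursive = TRUE)
  fail <- function(stage, e) {
    unlink(written)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  bundle <- tryCatch({
    if (!is.null(config$simulate)) {
      generate_landscape(do.call(
        landscape_params, c(config$simulate, list(seed = config$seed))))
    } else {
      load_bundle_from_inputs(config$inputs)
    }
  }, error = function(e) fail("simulate/load", e))

  secs <- tryCatch({
    sched <- do.call(ring_schedule, config$schedule)
    build_sections(bundle, config$road_class, sched, band = config$band,
                   grid_cell_m = config$grid_cell_m,
                   min_area_km2 = config$min_area_km2)
  }, error = function(e) fail("geoprep", e))

  pairs <- tryCatch(
    make_paired_copies(secs, bundle, seed = config$seed + 1L,
                       exclusion_m = config$exclusion_m),
    error = function(e) fail("randomization", e))

  ring_tab <- tryCatch(
    ring_test_table(pairs, bundle$signs, alpha = config$alpha,
                    dedup_dist_m = config$dedup_dist_m),
    error = function(e) fail("density_analysis", e))
  zone <- effect_zone(ring_tab, rule = config$rule, alpha = config$alpha)

  sem_out <- NULL
  if (isTRUE(config$sem)) {
    sem_out <- tryCatch({
      tab <- prepare_sem_table(pairs, bundle$signs,
                               dedup_dist_m = config$dedup_dist_m)
      if (nrow(tab) < config$sem_min_rows) {
        list(skipped = TRUE,
             reason = sprintf("only %d usable pairs (< %d required)",
                              nrow(tab), config$sem_min_rows))
      } else {
        sel <- stepwise_indicator_selection(road_sem_spec(), tab,
                                            robust = config$robust)
        std <- standardize(sel$fit)
        list(skipped = FALSE, met = sel$met,
             n = sel$fit$n, chi2 = sel$fit$chi2, df = sel$fit$df,
             p_chi2 = sel$fit$p_chi2, rmsea = sel$fit$rmsea,
             converged = sel$fit$converged,
             theta = as.list(sel$fit$theta),
             standardized = std$paths[std$paths$free |
                                        std$paths$matrix == "A", ],
             r2 = as.list(std$r2), removal_log = sel$log,
             indicators = sel$spec$latents[[1]])
      }
    }, error = function(e) fail("sem_engine", e))
  }

  manifest <- list(config = unclass(config), config_hash = hash,
                   package_version = as.character(
                     utils::packageVersion("roadzone")),
                   seed = config$seed,
                   n_sections = length(secs$sections),
                   n_usable_pairs = sum(vapply(pairs$pairs, function(p)
                     isTRUE(p$usable), logical(1))),
                   n_signs = nrow(bundle$signs))

  if (!is.null(out)) {
    f1 <- file.path(out, "ring_tests.csv")
    tab_out <- cbind(ring_tab, config_hash = hash)
    utils::write.csv(tab_out, f1, row.names = FALSE)
    written <- c(written, f1)
    f2 <- file.path(out, "effect_zone.json")
    jsonlite::write_json(c(zone, list(config_hash = hash)), f2,
                         auto_unbox = TRUE, digits = NA)
    written <- c(written, f2)
    if (!is.null(sem_out)) {
      f3 <- file.path(out, "sem_fit.json")
      jsonlite::write_json(c(sem_out, list(config_hash = hash)), f3,
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "rows", force = TRUE)
      written <- c(written, f3)
    }
    f4 <- file.path(out, "manifest.json")
    jsonlite::write_json(manifest, f4, auto_unbox = TRUE, digits = NA,
                         null = "null", force = TRUE)
    written <- c(written, f4)
  }
  res <- list(bundle = bundle, sections = secs, pairs = pairs,
              ring_table = ring_tab, zone = zone, sem = sem_out,
              manifest = manifest)
  if (is.null(out)) res else invisible(res)
}
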