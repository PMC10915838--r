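# End-to-end pipeline: synthetic benchmark (or user inputs) -> chemical-space
# map -> panel selection -> surrogate training -> volcano construction ->
# genetic optimization -> report. Every stage writes its outputs and records
# its seed; a manifest with file hashes makes re-runs verifiable.

#' Default pipeline configuration
#'
#' A flat list of stage settings with explicit per-stage seeds and no hidden
#' global RNG state. Any element can be overridden via `...` (nested lists are
#' merged).
#'
#' @param output_dir where stage outputs are written.
#' @param ... overrides merged into the defaults, e.g.
#'   `benchmark = list(n_reactions = 300)`.
#' @return nested configuration list.
#' @export
pipeline_config <- function(output_dir = "gencat_run", ...) {
  cfg <- list(
    output_dir = output_dir,
    temperature = 298.15,
    inputs = list(reactions = NULL, profiles = NULL, templates = NULL,
                  fragments = NULL, panel = NULL),
    benchmark = list(enabled = TRUE, seed = 11L, n_reactions = 400L,
                     n_profiles = 44L, noise_ddg = 0.3, noise_descriptor = 1.0,
                     noise_state = 0.5),
    fingerprint = list(n_bits = 1024L, radius = 2L),
    map = list(seed = 21L, pca_dims = 100L, perplexity = 30),
    panel = list(k = 15L, seed = 31L, perplexity = 10),
    train = list(n_splits = 25L, train_fraction = 0.9, seed = 41L,
                 booster = "gbtree", nrounds = 100L),
    volcano = list(grid_min = -25, grid_max = 25, grid_step = 0.1),
    ga = list(population_size = 10L, generations = 50L, mutation_rate = 0.10,
              selection_rate = 0.25, elitism = 1L, seed = 51L),
    scalarizer = list(ddg_threshold = 2.0, activity_target = -9.0,
                      activity_width = 3.0, degradation = 0.10,
                      spread_tolerance = 0.25)
  )
  utils::modifyList(cfg, list(...))
}

#' Read a pipeline configuration from a YAML or JSON file
#'
#' @param path configuration file; values override [pipeline_config()]
#'   defaults.
#' @return nested configuration list.
#' @export
read_pipeline_config <- function(path) {
  over <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("yaml package required")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(pipeline_config, c(list(output_dir = over$output_dir %||% "gencat_run"),
                             over[setdiff(names(over), "output_dir")]))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full inverse-design pipeline
#'
#' Executes benchmark generation (unless user inputs are supplied), reaction
#' mapping, panel selection, surrogate training for both targets, volcano
#' construction from the energy profiles, and the genetic optimization, then
#' writes a manifest (seeds, parameters, MD5 hashes of every output) and a
#' plain-text report with the best-candidate trajectory and the Pareto front
#' of all evaluated candidates.
#'
#' @param config a [pipeline_config()] list.
#' @return invisibly, a list with the stage objects (`landscape`, `map`,
#'   `panel`, `models`, `volcanoes`, `run`) and the `manifest`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$output_dir, ...)
  fp_cfg <- fingerprint_config(config$fingerprint$n_bits, config$fingerprint$radius)

  landscape <- NULL
  if (!is.null(config$inputs$reactions)) {
    reactions <- .stage("load", {
      if (!file.exists(config$inputs$reactions)) {
        stop("missing reactions file: ", config$inputs$reactions)
      }
      read_reaction_table(config$inputs$reactions)
    })
    library <- .stage("load", {
      if (is.null(config$inputs$templates) || is.null(config$inputs$fragments)) {
        stop("user inputs need both templates and fragments files")
      }
      load_library(config$inputs$templates, config$inputs$fragments)
    })
    profiles_path <- config$inputs$profiles
  } else {
    bench <- config$benchmark
    if (!isTRUE(bench$enabled)) stop("pipeline stage 'benchmark': disabled and no inputs given")
    landscape <- .stage("benchmark", make_landscape(
      seed = bench$seed, noise_ddg = bench$noise_ddg,
      noise_descriptor = bench$noise_descriptor, noise_state = bench$noise_state))
    .stage("benchmark", write_benchmark(landscape, out("benchmark"),
                                        n_reactions = bench$n_reactions,
                                        n_profiles = bench$n_profiles,
                                        seed = bench$seed))
    reactions <- read_reaction_table(out("benchmark", "reactions.csv"))
    library <- landscape$library
    profiles_path <- out("benchmark", "profiles.csv")
  }

  map <- .stage("map", embed_map(reactions, pca_dims = config$map$pca_dims,
                                 perplexity = min(config$map$perplexity,
                                                  floor((nrow(reactions) - 2) / 3)),
                                 seed = config$map$seed, config = fp_cfg))
  write_map(map, out("map.csv"))

  panel <- .stage("panel", {
    if (!is.null(config$inputs$panel)) read_panel(config$inputs$panel)
    else select_panel(reactions, k = config$panel$k, config = fp_cfg,
                      pca_dims = config$map$pca_dims,
                      perplexity = config$panel$perplexity,
                      seed = config$panel$seed)
  })
  write_panel(panel, out("panel.csv"))

  models <- .stage("train", {
    tr <- config$train
    list(
      selectivity = train_surrogate(reactions, "selectivity", fp_cfg,
                                    n_splits = tr$n_splits,
                                    train_fraction = tr$train_fraction,
                                    seed = tr$seed, booster = tr$booster,
                                    nrounds = tr$nrounds),
      descriptor = train_surrogate(reactions, "descriptor", fp_cfg,
                                   n_splits = tr$n_splits,
                                   train_fraction = tr$train_fraction,
                                   seed = tr$seed + 1L, booster = tr$booster,
                                   nrounds = tr$nrounds)
    )
  })
  cv <- lapply(models, function(m) m$cv)
  jsonlite::write_json(cv, out("cv_report.json"), auto_unbox = TRUE, digits = NA)

  volcanoes <- NULL
  if (!is.null(profiles_path)) {
    volcanoes <- .stage("volcano", {
      if (!file.exists(profiles_path)) stop("missing profiles file: ", profiles_path)
      profiles <- read_profiles(profiles_path)
      fit <- fit_lfesr(profiles)
      v <- build_volcano(fit, grid = seq(config$volcano$grid_min,
                                         config$volcano$grid_max,
                                         by = config$volcano$grid_step),
                         temperature = config$temperature)
      write_volcano(v, out("volcano.csv"))
      list(v)
    })
  }

  sc <- config$scalarizer
  spec <- scalarizer_spec(sc$ddg_threshold, sc$activity_target,
                          sc$activity_width, sc$degradation, sc$spread_tolerance)
  ga <- config$ga
  run <- .stage("evolve", evolve(
    library, panel, models,
    config = ga_config(ga$population_size, ga$generations, ga$mutation_rate,
                       ga$selection_rate, ga$elitism, ga$seed),
    spec = spec))
  utils::write.csv(run$trajectory, out("trajectory.csv"), row.names = FALSE)
  utils::write.csv(run$evaluated, out("evaluated.csv"), row.names = FALSE)

  # Pareto analysis: median selectivity vs median activity merit
  okc <- is.finite(run$evaluated$median_ddg) & is.finite(run$evaluated$median_f)
  pf <- pareto_front(run$evaluated[okc, c("median_ddg", "median_f")])
  pareto <- run$evaluated[which(okc)[pf], ]
  utils::write.csv(pareto, out("pareto.csv"), row.names = FALSE)

  report <- c(
    "gencat pipeline report",
    sprintf("reactions: %d rows, %d unique transformations",
            nrow(reactions), unique_transformations(reactions)),
    sprintf("panel: %d substrate pairs", nrow(panel)),
    sprintf("selectivity surrogate out-of-fold MAE = %.3f kcal/mol", cv$selectivity$mae),
    sprintf("descriptor surrogate out-of-fold MAE = %.3f kcal/mol", cv$descriptor$mae),
    if (!is.null(volcanoes)) {
      sprintf("volcano peak: descriptor = %.2f kcal/mol, log10 TOF = %.2f",
              volcanoes[[1]]$peak_x, volcanoes[[1]]$peak_log10_tof)
    },
    sprintf("GA: %d generations, %d unique candidates, %d model calls",
            nrow(run$trajectory), nrow(run$evaluated), run$model_calls),
    sprintf("best candidate: %s", run$best_overall$candidate$smiles),
    sprintf("  median ddG-dagger = %.2f kcal/mol -> %.0f%% ee",
            run$best_overall$objectives[["median_ddg"]],
            ee_from_ddg(max(0, run$best_overall$objectives[["median_ddg"]]),
                        config$temperature)),
    sprintf("  median activity merit = %.3g", run$best_overall$objectives[["median_f"]]),
    sprintf("Pareto front: %d candidates", nrow(pareto))
  )
  writeLines(report, out("report.txt"))

  outputs <- list.files(config$output_dir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, out("manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("gencat")),
    seeds = list(benchmark = config$benchmark$seed, map = config$map$seed,
                 panel = config$panel$seed, train = config$train$seed,
                 ga = config$ga$seed),
    config = config[setdiff(names(config), "output_dir")],
    files = stats::setNames(as.list(unname(tools::md5sum(outputs))),
                            substring(outputs, nchar(config$output_dir) + 2L))
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE, digits = NA)

  invisible(list(landscape = landscape, reactions = reactions, map = map,
                 panel = panel, models = models, volcanoes = volcanoes,
                 run = run, pareto = pareto, manifest = manifest))
}
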