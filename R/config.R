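#' Load a run configuration
#'
#' Reads a YAML or JSON configuration, validates every field, and assembles
#' the model parameter set (the packaged calibrated fixture by default,
#' with payer mix / setting / upcharge / discount overrides applied).
#' Validation failures name the offending field.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file, or
#'   NULL for the packaged default configuration.
#' @return List with `config` (validated run settings) and `params`
#'   ([model_params()]).
#' @export
load_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_config.yaml", package = "facetCEA")
  }
  if (!file.exists(path)) stop("load_config: file not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- utils::modifyList(default_run_config(), raw)
  validate_run_config(cfg)
  mix <- payer_mix(cfg$payer_mix$medicare, cfg$payer_mix$private)
  params <- fixture_model_params(mix = mix, setting = cfg$setting,
                                 upcharge = cfg$upcharge,
                                 discount_rate = cfg$discount_rate,
                                 half_cycle = cfg$half_cycle)
  if (!is.null(cfg$initial_distribution)) {
    params$initial <- tryCatch(state_distribution(cfg$initial_distribution),
                               error = function(e) stop("load_config: field 'initial_distribution': ",
                                                        conditionMessage(e)))
  }
  list(config = cfg, params = params)
}

default_run_config <- function() {
  list(seed = 1,
       horizons = c(3, 12, 24, 72, 120),
       perspectives = c("health_system", "societal"),
       wtp = c(50000, 100000, 150000),
       output_dir = "results",
       discount_rate = 0.03,
       payer_mix = list(medicare = 0.5, private = 0.5),
       setting = "inpatient",
       upcharge = 4000,
       half_cycle = FALSE,
       utility_dist = "beta",
       psa_iterations = 1000,
       owsa_fraction = 0.2,
       generate_trial = TRUE,
       trial = list(),
       initial_distribution = NULL)
}

validate_run_config <- function(cfg) {
  fail <- function(field, why) stop("load_config: field '", field, "': ", why)
  if (any(cfg$horizons <= 0) || is.unsorted(cfg$horizons, strictly = TRUE)) {
    fail("horizons", "must be positive and strictly ascending")
  }
  if (cfg$discount_rate < 0) fail("discount_rate", "must be >= 0")
  pm <- cfg$payer_mix
  if (is.null(pm$medicare) || is.null(pm$private) ||
      pm$medicare < 0 || pm$private < 0 ||
      abs(pm$medicare + pm$private - 1) > 1e-9) {
    fail("payer_mix", "weights must be nonnegative and sum to 1")
  }
  if (!cfg$setting %in% c("inpatient", "outpatient", "mixed")) {
    fail("setting", "must be inpatient, outpatient or mixed")
  }
  if (cfg$upcharge < 0) fail("upcharge", "must be >= 0")
  if (any(cfg$wtp < 0)) fail("wtp", "must be >= 0")
  if (cfg$psa_iterations < 1) fail("psa_iterations", "must be >= 1")
  if (cfg$owsa_fraction <= 0 || cfg$owsa_fraction >= 1) {
    fail("owsa_fraction", "must be in (0, 1)")
  }
  if (!all(cfg$perspectives %in% c("health_system", "societal"))) {
    fail("perspectives", "must be health_system and/or societal")
  }
  if (!is.null(cfg$initial_distribution)) {
    p <- cfg$initial_distribution
    if (length(p) != 5L) fail("initial_distribution", "must have 5 entries")
    if (abs(sum(p) - 1) > 1e-9) fail("initial_distribution", "must sum to 1")
    if (any(p < 0)) fail("initial_distribution", "entries must be >= 0")
  }
  invisible(cfg)
}

#' Run the full analysis pipeline
#'
#' Executes every stage against one configuration: synthetic-trial
#' generation (optional), health-state partition and transition estimation
#' from the generated records, the base-case cost-effectiveness table at all
#' horizons and perspectives, the scenario grid, one-way sensitivity
#' analysis, and the probabilistic sensitivity analysis with its CEAC. All
#' tables are written as CSV under the configured output directory together
#' with a JSON run manifest (seed, config hash, package version, stage row
#' counts); outputs are byte-identical under a fixed seed.
#'
#' @param config_path Configuration path (NULL for the packaged default).
#' @param output_dir Override for the configured output directory.
#' @param quiet Suppress stage messages.
#' @return Invisible list of the in-memory stage results.
#' @export
run_pipeline <- function(config_path = NULL, output_dir = NULL, quiet = FALSE) {
  loaded <- load_config(config_path)
  cfg <- loaded$config
  params <- loaded$params
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  out <- list()

  if (isTRUE(cfg$generate_trial)) {
    tc_args <- cfg$trial
    tc_args$seed <- cfg$seed
    tc <- do.call(trial_config, tc_args)
    say("stage trial: generating ", tc$n_patients, " patients")
    trial <- generate_trial(tc)
    write_trial_csv(trial, file.path(cfg$output_dir, "synthetic_trial.csv"))
    out$trial <- trial

    say("stage states: partition fit and transition estimation")
    base <- trial[trial$visit_month == 0, ]
    out$partition <- fit_state_partition(base$vas, base$odi)
    out$transitions <- estimate_transitions_by_interval(trial)
    write_states_json(list(partition = out$partition, transitions = out$transitions),
                      file.path(cfg$output_dir, "estimated_states.json"))
  }

  say("stage base_case: ", length(cfg$horizons), " horizons x ",
      length(cfg$perspectives), " perspectives")
  out$base_case <- cea_table(params, cfg$horizons, cfg$perspectives, cfg$wtp)
  utils::write.csv(out$base_case, file.path(cfg$output_dir, "base_case.csv"),
                   row.names = FALSE)

  say("stage scenarios: payer mix x setting grid")
  out$scenarios <- run_scenarios(params, horizons = intersect(cfg$horizons, c(12, 24)),
                                 wtp = cfg$wtp)
  utils::write.csv(out$scenarios, file.path(cfg$output_dir, "scenarios.csv"),
                   row.names = FALSE)

  registry <- default_owsa_parameters(params)
  say("stage owsa: ", length(registry), " parameters at +/-",
      cfg$owsa_fraction * 100, "%")
  out$owsa <- owsa(params, cfg$owsa_fraction, registry)
  utils::write.csv(out$owsa, file.path(cfg$output_dir, "owsa_tornado.csv"),
                   row.names = FALSE)

  say("stage psa: ", cfg$psa_iterations, " iterations")
  out$psa <- run_psa(params, cfg$psa_iterations, seed = cfg$seed,
                     registry = registry,
                     utility_dist = cfg$utility_dist)
  utils::write.csv(out$psa[, c("iteration", "delta_cost", "delta_qaly")],
                   file.path(cfg$output_dir, "psa_iterations.csv"),
                   row.names = FALSE)
  out$ceac <- ceac(out$psa)
  utils::write.csv(out$ceac, file.path(cfg$output_dir, "ceac.csv"),
                   row.names = FALSE)

  cfg_path <- if (is.null(config_path)) {
    system.file("extdata", "default_config.yaml", package = "facetCEA")
  } else config_path
  manifest <- list(seed = cfg$seed,
                   config_hash = unname(tools::md5sum(cfg_path)),
                   config = cfg[setdiff(names(cfg), "output_dir")],
                   package_version = as.character(utils::packageVersion("facetCEA")),
                   rows = lapply(out[c("base_case", "scenarios", "owsa", "psa")],
                                 function(x) if (is.data.frame(x)) nrow(x) else NA))
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete: outputs in ", cfg$output_dir)
  invisible(out)
}
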