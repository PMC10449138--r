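#' Model registry
#'
#' Run configurations refer to models by name. The registry maps those
#' names to functions; all bundled models are pre-registered, and users
#' can register their own plug-ins (any function with the documented
#' layer signature) before loading a configuration.
#'
#' @param name model name used in configuration files.
#' @param fn model function.
#' @return `register_model()` returns `fn` invisibly; `get_model()`
#'   returns the function registered under `name`.
#' @export
register_model <- function(name, fn) {
  sg_assert(is.character(name) && length(name) == 1 && is.function(fn),
            "`name` must be a string and `fn` a function")
  assign(name, fn, envir = .model_registry)
  invisible(fn)
}

.model_registry <- new.env(parent = emptyenv())

#' @rdname register_model
#' @export
get_model <- function(name) {
  if (exists(name, envir = .model_registry, inherits = FALSE)) {
    return(get(name, envir = .model_registry, inherits = FALSE))
  }
  sg_stop(sprintf("unknown model name '%s' (not in the registry)", name),
          "serogen_config_error")
}

register_builtin_models <- function() {
  builtins <- c(
    "exposure_model_simple_FOE", "exposure_model_dem_mod",
    "immunity_model_all_successful", "immunity_model_vacc_ifxn_simple",
    "immunity_model_biomarker_protection",
    "antibody_model_monophasic", "antibody_model_biphasic",
    "observation_model_continuous_noise", "observation_model_discrete_noise",
    "draw_parameters_fixed_fx", "draw_parameters_random_fx",
    "draw_parameters_random_fx_titer_dep")
  for (nm in builtins) {
    register_model(nm, get(nm, envir = asNamespace("serogen")))
  }
}

.onLoad <- function(libname, pkgname) {
  register_builtin_models()
}

config_field <- function(config, path_chr) {
  node <- config
  for (k in path_chr) {
    sg_assert(is.list(node) && k %in% names(node),
              sprintf("configuration is missing required field '%s'",
                      paste(path_chr, collapse = ".")),
              "serogen_config_error")
    node <- node[[k]]
  }
  node
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration describing a full simulation: the
#' simulation window, demography (a file or a generation spec), the
#' biomarker map, force-of-exposure grid and model parameter files, the
#' five model names and their extra arguments, and the observation
#' design and assay settings. Validation is field-level: missing
#' required fields, unknown top-level sections, unregistered model names
#' and extra model arguments not consumed by any selected model are all
#' rejected with the offending field named. Relative file paths are
#' resolved against the configuration file's directory.
#'
#' @param path path to a YAML configuration (see
#'   [make_quickstart_fixture()] for a complete example).
#' @return a validated `sero_config` object.
#' @export
load_config <- function(path) {
  sg_assert(file.exists(path), sprintf("config file '%s' not found", path),
            "serogen_config_error")
  config <- yaml::read_yaml(path)

  known <- c("simulation", "seed", "demography", "biomarker_map", "foe",
             "model_pars", "models", "model_args", "observation")
  unknown <- setdiff(names(config), known)
  sg_assert(length(unknown) == 0,
            sprintf("unknown configuration section(s): %s",
                    paste(unknown, collapse = ", ")),
            "serogen_config_error")

  config_field(config, c("simulation", "t_start"))
  config_field(config, c("simulation", "t_end"))
  dem <- config_field(config, "demography")
  sg_assert("file" %in% names(dem) || "n_individuals" %in% names(dem),
            "configuration field 'demography' needs 'file' or 'n_individuals'",
            "serogen_config_error")
  for (f in c("biomarker_map", "foe", "model_pars")) {
    config_field(config, c(f, "file"))
  }
  models <- config_field(config, "models")
  for (layer in c("exposure", "immunity", "antibody", "observation",
                  "draw_parameters")) {
    sg_assert(layer %in% names(models),
              sprintf("configuration is missing required field 'models.%s'",
                      layer),
              "serogen_config_error")
  }
  model_fns <- lapply(models, function(nm) get_model(nm))

  extra <- config$model_args %||% list()
  if (length(extra) > 0) {
    consumable <- unique(unlist(lapply(model_fns, function(f) {
      setdiff(names(formals(f)), "...")
    })))
    unconsumed <- setdiff(names(extra), consumable)
    sg_assert(length(unconsumed) == 0,
              sprintf("model_args not consumed by any selected model: %s",
                      paste(unconsumed, collapse = ", ")),
              "serogen_config_error")
  }

  obs <- config_field(config, "observation")
  ok_obs <- c("design_file", "sensitivity", "specificity", "noise_sd",
              "lower_bound", "upper_bound", "output")
  bad_obs <- setdiff(names(obs), ok_obs)
  sg_assert(length(bad_obs) == 0,
            sprintf("unknown observation field(s): %s",
                    paste(bad_obs, collapse = ", ")),
            "serogen_config_error")

  structure(config, class = "sero_config",
            dir = dirname(normalizePath(path)))
}

#' Write a configuration back to YAML
#'
#' @param config a `sero_config` object (or compatible list).
#' @param path output file path.
#' @export
dump_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

resolve_path <- function(config, p) {
  if (is.null(p)) return(NULL)
  if (file.exists(p)) return(p)
  file.path(attr(config, "dir") %||% ".", p)
}

#' Execute a loaded run configuration
#'
#' Reads the referenced input files, relabels character exposure and
#' biomarker ids to integers where needed, assembles the assay
#' specification (pulling `noise_sd` from the model-parameter table's
#' `obs_sd` row unless set in the configuration) and runs
#' [simulate_serosurvey()]. The whole run consumes a single RNG stream,
#' so it is reproducible from `seed` alone even when the demography is
#' generated rather than read from a file.
#'
#' @param config a `sero_config` from [load_config()].
#' @param seed optional seed overriding the configuration's `seed`.
#' @return a `serosurvey_sim` object.
#' @export
run_config <- function(config, seed = NULL) {
  sg_assert(inherits(config, "sero_config"),
            "`config` must come from load_config()", "serogen_config_error")
  seed <- seed %||% config$seed
  maybe_set_seed(seed)

  map_raw <- read_biomarker_map(resolve_path(config,
                                             config$biomarker_map$file))
  model_pars <- read_model_pars(resolve_path(config, config$model_pars$file))
  if (!is.numeric(map_raw$exposure_id) || !is.numeric(map_raw$biomarker_id)) {
    ref <- reformat_biomarker_map(map_raw)
    biomarker_map <- ref$map
    model_pars <- reformat_model_pars(model_pars, ref$exposure_key,
                                      ref$biomarker_key)
  } else {
    biomarker_map <- map_raw
  }

  dem_cfg <- config$demography
  if (!is.null(dem_cfg$file)) {
    demography <- read_demography(resolve_path(config, dem_cfg$file))
  } else {
    demography <- generate_pop_demography(
      dem_cfg$n_individuals,
      seq.int(config$simulation$t_start, config$simulation$t_end),
      prob_removal = dem_cfg$prob_removal %||% 0)
  }

  foe <- read_foe_grid(resolve_path(config, config$foe$file))

  obs_cfg <- config$observation
  noise_sd <- obs_cfg$noise_sd
  if (is.null(noise_sd)) {
    row <- model_pars[model_pars$name == "obs_sd", ]
    noise_sd <- if (nrow(row) >= 1) row$sd[1] else 0
  }
  assay <- assay_spec(
    noise_sd = noise_sd,
    sensitivity = obs_cfg$sensitivity %||% 1,
    specificity = obs_cfg$specificity %||% 1,
    lower_bound = obs_cfg$lower_bound %||% NA_real_,
    upper_bound = obs_cfg$upper_bound %||% NA_real_,
    output = obs_cfg$output %||% "continuous")
  design <- NULL
  if (!is.null(obs_cfg$design_file)) {
    design <- read.csv(resolve_path(config, obs_cfg$design_file))
  }

  args <- c(
    list(
      simulation_settings = list(t_start = config$simulation$t_start,
                                 t_end = config$simulation$t_end),
      demography = demography,
      biomarker_map = biomarker_map,
      foe_pars = foe,
      model_pars = model_pars,
      exposure_model = get_model(config$models$exposure),
      immunity_model = get_model(config$models$immunity),
      antibody_model = get_model(config$models$antibody),
      observation_model = get_model(config$models$observation),
      draw_parameters = get_model(config$models$draw_parameters),
      assay = assay,
      observation_design = design),
    config$model_args %||% list())
  do.call(simulate_serosurvey, args)
}

#' Write all simulation outputs as long CSV tables plus metadata
#'
#' Five tables (`exposure_probabilities`, `immune_histories`,
#' `biomarker_states`, `kinetics`, `observed_biomarkers`) and a
#' `metadata.yml` with the seed, window, sizes and package version.
#' Missing values (inactive cells) are written as empty fields.
#'
#' @param res a `serosurvey_sim` object.
#' @param out_dir output directory (created if missing).
#' @return invisibly, `out_dir`.
#' @export
write_run_outputs <- function(res, out_dir) {
  sg_assert(inherits(res, "serosurvey_sim"), "`res` must be a serosurvey_sim")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in c("exposure_probabilities", "immune_histories",
               "biomarker_states", "kinetics", "observed_biomarkers")) {
    write.csv(as.data.frame(res[[nm]]),
              file.path(out_dir, paste0(nm, ".csv")),
              row.names = FALSE, na = "")
  }
  yaml::write_yaml(res$metadata, file.path(out_dir, "metadata.yml"))
  invisible(out_dir)
}

cli_usage <- function() {
  paste(
    "usage: serogen <command> [options]",
    "",
    "commands:",
    "  quickstart --out DIR [--seed N]",
    "      write the bundled quickstart scenario (inputs + config)",
    "  simulate --config PATH --out DIR [--seed N]",
    "      run a configuration and write the five output tables",
    "  sweep --config PATH --thresholds A,B,... --replicates N --out DIR [--seed N]",
    "      seropositivity-threshold sensitivity/specificity sweep",
    sep = "\n")
}

parse_cli_flags <- function(argv) {
  flags <- list()
  k <- 1
  while (k <= length(argv)) {
    a <- argv[k]
    if (!startsWith(a, "--") || k == length(argv)) {
      sg_stop(sprintf("bad argument '%s'", a), "serogen_usage_error")
    }
    flags[[substring(a, 3)]] <- argv[k + 1]
    k <- k + 2
  }
  flags
}

#' Command-line entry point
#'
#' Backs the `inst/cli/serogen` Rscript wrapper. Subcommands:
#' `quickstart`, `simulate`, `sweep` (see [make_quickstart_fixture()],
#' [run_config()], [threshold_sweep()]). Progress and per-stage timings
#' are logged to stderr. Returns the process exit code: 0 on success, 2
#' on a usage error, 1 on any other failure.
#'
#' @param argv character vector of command-line arguments (defaults to
#'   the process arguments).
#' @return integer exit code, invisibly.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    sg_assert(length(argv) >= 1, "no command given", "serogen_usage_error")
    cmd <- argv[1]
    flags <- parse_cli_flags(argv[-1])
    seed <- if (!is.null(flags$seed)) as.integer(flags$seed) else NULL
    t_begin <- Sys.time()

    if (cmd == "quickstart") {
      sg_assert(!is.null(flags$out), "quickstart requires --out",
                "serogen_usage_error")
      path <- make_quickstart_fixture(flags$out, seed = seed %||% 1)
      message(sprintf("wrote quickstart fixture: %s", path))
    } else if (cmd == "simulate") {
      sg_assert(!is.null(flags$config) && !is.null(flags$out),
                "simulate requires --config and --out", "serogen_usage_error")
      config <- load_config(flags$config)
      message(sprintf("config: %s (hash %s), seed: %s",
                      flags$config, rlang::hash(unclass(config)),
                      seed %||% config$seed %||% "<none>"))
      res <- run_config(config, seed = seed)
      message(sprintf("simulation finished in %.2fs",
                      as.numeric(Sys.time() - t_begin, units = "secs")))
      write_run_outputs(res, flags$out)
      message(sprintf("outputs written to %s", flags$out))
    } else if (cmd == "sweep") {
      sg_assert(!is.null(flags$config) && !is.null(flags$out) &&
                  !is.null(flags$thresholds) && !is.null(flags$replicates),
                "sweep requires --config, --thresholds, --replicates, --out",
                "serogen_usage_error")
      config <- load_config(flags$config)
      thresholds <- as.numeric(strsplit(flags$thresholds, ",")[[1]])
      base_seed <- seed %||% config$seed %||% 1
      sweep <- threshold_sweep_config(config, thresholds,
                                      as.integer(flags$replicates),
                                      seed = base_seed)
      dir.create(flags$out, showWarnings = FALSE, recursive = TRUE)
      write_threshold_sweep(sweep, file.path(flags$out, "threshold_sweep.csv"))
      message(sprintf("sweep finished in %.2fs; results in %s",
                      as.numeric(Sys.time() - t_begin, units = "secs"),
                      flags$out))
    } else {
      sg_stop(sprintf("unknown command '%s'", cmd), "serogen_usage_error")
    }
    0L
  },
  serogen_usage_error = function(e) {
    message(conditionMessage(e))
    message(cli_usage())
    2L
  },
  error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

#' Threshold sweep driven by a run configuration
#'
#' Convenience wrapper: re-runs a loaded configuration `n_replicates`
#' times (replicate `r` with seed `seed + r`) and aggregates the
#' confusion matrices as in [threshold_sweep()].
#'
#' @inheritParams threshold_sweep
#' @param config a `sero_config`.
#' @export
threshold_sweep_config <- function(config, thresholds, n_replicates,
                                   infection_exposures = 1, seed = 1) {
  runs <- lapply(seq_len(n_replicates), function(r) {
    run_config(config, seed = as.integer(seed) + r)
  })
  sweep_with_runs(runs, thresholds, infection_exposures)
}
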