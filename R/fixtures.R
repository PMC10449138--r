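#' Quickstart model parameter table
#'
#' The bundled monophasic boosting-waning parameter table: infection
#' events boost IgG by 4 units on average (sd 2) and wane at 0.0033 per
#' time step (sd 0.0005); vaccination boosts by 2 (sd 1) and wanes at
#' 0.0016 (sd 0.0005); all log-normal random effects on the natural
#' scale. An `obs_sd` row carries the assay noise standard deviation
#' (0.25) in its `sd` column.
#'
#' @param labels if `TRUE`, return label ids (`ifxn`/`vacc`, `IgG`) as a
#'   user would write them; if `FALSE`, integer ids ready for
#'   [simulate_serosurvey()].
#' @return model parameter tibble.
#' @export
quickstart_model_pars <- function(labels = FALSE) {
  mp <- tibble::tibble(
    exposure_id = c("ifxn", "ifxn", "vacc", "vacc", ""),
    biomarker_id = c("IgG", "IgG", "IgG", "IgG", "IgG"),
    name = c("boost", "wane", "boost", "wane", "obs_sd"),
    mean = c(4, 0.0033, 2, 0.0016, NA),
    sd = c(2, 0.0005, 1, 0.0005, 0.25),
    distribution = c("log-normal", "log-normal", "log-normal", "log-normal", "")
  )
  if (labels) return(mp)
  mp$exposure_id <- c(1L, 1L, 2L, 2L, NA)
  mp$biomarker_id <- 1L
  mp
}

#' Assemble the quickstart simulation inputs
#'
#' The bundled example scenario: a 10-year simulation at monthly
#' resolution (t = 1..120) of one pathogen (natural infection, exposure
#' type 1, constant force of exposure 0.01/month) plus one vaccine
#' (exposure type 2, 0.1/month), both boosting the same IgG biomarker.
#' At most one successful infection and one successful vaccination per
#' individual; vaccine eligibility starts at age 9 months. Monophasic
#' kinetics with log-normal random effects ([quickstart_model_pars()]);
#' a continuous assay with noise sd 0.25, sensitivity 85% and
#' specificity 90%; every individual sampled once at t = 120.
#'
#' @param n_individuals population size.
#' @param n_times number of monthly time steps.
#' @param seed optional seed for the generated demography.
#' @return named list of arguments for [simulate_serosurvey()].
#' @export
quickstart_inputs <- function(n_individuals = 100, n_times = 120, seed = NULL) {
  times <- seq_len(n_times)
  demography <- generate_pop_demography(n_individuals, times,
                                        prob_removal = 0, seed = seed)
  foe <- make_foe_grid(1, n_times, 2)
  foe[, , 1] <- 0.01
  foe[, , 2] <- 0.1
  list(
    simulation_settings = list(t_start = 1, t_end = n_times),
    demography = demography,
    biomarker_map = tibble::tibble(exposure_id = c(1L, 2L),
                                   biomarker_id = c(1L, 1L)),
    foe_pars = foe,
    model_pars = quickstart_model_pars(),
    exposure_model = exposure_model_simple_FOE,
    immunity_model = immunity_model_vacc_ifxn_simple,
    antibody_model = antibody_model_monophasic,
    observation_model = observation_model_continuous_noise,
    draw_parameters = draw_parameters_random_fx,
    assay = assay_spec(noise_sd = 0.25, sensitivity = 0.85,
                       specificity = 0.9, lower_bound = 0, upper_bound = 10),
    observation_design = tibble::tibble(i = seq_len(n_individuals),
                                        t = n_times, b = 1L),
    max_events = c(1, 1),
    vacc_exposures = 2,
    vacc_age = c(NA, 9)
  )
}

#' Write the quickstart scenario as a file-based fixture
#'
#' Writes the demography, biomarker map (label ids), force-of-exposure
#' grid, model parameter table, observation design and a YAML run
#' configuration referencing them, so the scenario can be run through
#' [load_config()]/[run_config()] or the command line. Deterministic
#' given `seed`.
#'
#' @param out_dir output directory (created if missing).
#' @param seed seed for the generated demography.
#' @return invisibly, the path of the written config file.
#' @export
make_quickstart_fixture <- function(out_dir, seed = 1) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sg_assert(dir.exists(out_dir),
            sprintf("cannot create output directory '%s'", out_dir),
            "serogen_io_error")
  inputs <- quickstart_inputs(seed = seed)
  write_demography(inputs$demography, file.path(out_dir, "demography.csv"))
  write_biomarker_map(
    tibble::tibble(exposure_id = c("ifxn", "vacc"),
                   biomarker_id = c("IgG", "IgG")),
    file.path(out_dir, "biomarker_map.csv"))
  write_foe_grid(inputs$foe_pars, file.path(out_dir, "foe.csv"))
  write_model_pars(quickstart_model_pars(labels = TRUE),
                   file.path(out_dir, "model_pars.csv"))
  write.csv(as.data.frame(inputs$observation_design),
            file.path(out_dir, "observation_design.csv"), row.names = FALSE)
  config <- list(
    simulation = list(t_start = 1, t_end = 120),
    seed = as.integer(seed),
    demography = list(file = "demography.csv"),
    biomarker_map = list(file = "biomarker_map.csv"),
    foe = list(file = "foe.csv"),
    model_pars = list(file = "model_pars.csv"),
    models = list(
      exposure = "exposure_model_simple_FOE",
      immunity = "immunity_model_vacc_ifxn_simple",
      antibody = "antibody_model_monophasic",
      observation = "observation_model_continuous_noise",
      draw_parameters = "draw_parameters_random_fx"
    ),
    model_args = list(max_events = c(1, 1), vacc_exposures = 2,
                      vacc_age = c(NA, 9)),
    observation = list(design_file = "observation_design.csv",
                       sensitivity = 0.85, specificity = 0.9,
                       lower_bound = 0, upper_bound = 10)
  )
  path <- file.path(out_dir, "config.yml")
  yaml::write_yaml(config, path)
  invisible(path)
}
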