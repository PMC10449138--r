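#' Run a full serosurvey simulation
#'
#' Orchestrates the four model layers over every individual, time step
#' and exposure type. For each active `(i, t, x)` cell the engine
#' computes the probability of a successful exposure
#' \eqn{\phi_{i,t,x} = P(E_{i,t,x}=1)\,P(Z_{i,t,x}=1\mid E_{i,t,x}=1)}
#' (exposure model times immunity model) and draws the latent state
#' \eqn{Z_{i,t,x} \sim Bernoulli(\phi_{i,t,x})} in a single trial —
#' distributionally equivalent to drawing the encounter and its success
#' separately. On success, per-event kinetics parameters are drawn and
#' stored. After the time loop the antibody model evaluates the latent
#' biomarker quantity \eqn{A_{i,t,b}} at every active cell, and the
#' observation model generates observed quantities \eqn{Y} under the
#' sampling design.
#'
#' Iteration order is time-outer, individual-middle, exposure-inner on a
#' single sequential RNG stream, so a run is fully reproducible from
#' `seed`. Cells where the individual is not active (before birth, at or
#' after removal) are `NA` in every output. Entries supplied through
#' `fixed_history` are taken verbatim (known infection/vaccination
#' times); their \eqn{\phi} is recorded as `NA` with `fixed = TRUE`
#' since no model produced it. Within a time step, a success is visible
#' to immunity decisions at strictly later times only.
#'
#' @param simulation_settings list with `t_start` and `t_end`.
#' @param demography demography table ([generate_pop_demography()]).
#' @param biomarker_map integer-id biomarker map (see
#'   [reformat_biomarker_map()]).
#' @param foe_pars force-of-exposure array ([make_foe_grid()]) covering
#'   the whole window and all exposure types.
#' @param model_pars integer-id model parameter table.
#' @param exposure_model,immunity_model,antibody_model,observation_model,draw_parameters
#'   model functions for each layer (any function with the documented
#'   plug-in signature).
#' @param assay an [assay_spec()] passed to the observation model.
#' @param observation_design optional data frame (`i`, `t`, `b`) of
#'   samples to observe; `NULL` observes every biomarker of every
#'   individual at every time step.
#' @param fixed_history optional array `(N, T, X)` of known immune
#'   histories; `NA` entries are simulated, non-`NA` entries are fixed.
#' @param seed optional RNG seed making the run reproducible.
#' @param ... extra arguments forwarded to every model function (e.g.
#'   `max_events`, `vacc_exposures`, `vacc_age`).
#'
#' @return An object of class `serosurvey_sim`: a list with long-format
#'   tibbles `exposure_probabilities` (`i,t,x,value,fixed`),
#'   `immune_histories` (`i,t,x,value`), `biomarker_states`
#'   (`i,t,b,value`), `kinetics` (`i,t,x,b,name,value`),
#'   `observed_biomarkers` (`i,t,b,observed`) and a `metadata` list.
#' @examples
#' inputs <- quickstart_inputs(n_individuals = 20, seed = 1)
#' res <- do.call(simulate_serosurvey, c(inputs, list(seed = 1)))
#' head(res$observed_biomarkers)
#' @export
simulate_serosurvey <- function(simulation_settings, demography, biomarker_map,
                                foe_pars, model_pars,
                                exposure_model = exposure_model_simple_FOE,
                                immunity_model = immunity_model_all_successful,
                                antibody_model = antibody_model_monophasic,
                                observation_model = observation_model_continuous_noise,
                                draw_parameters = draw_parameters_random_fx,
                                assay = assay_spec(),
                                observation_design = NULL,
                                fixed_history = NULL,
                                seed = NULL, ...) {
  t_start <- simulation_settings$t_start
  t_end <- simulation_settings$t_end
  sg_assert(is.numeric(t_start) && is.numeric(t_end) && t_start <= t_end,
            "`simulation_settings` must give t_start <= t_end",
            "serogen_config_error")
  demography <- validate_demography(demography)
  biomarker_map <- validate_biomarker_map(biomarker_map)
  sg_assert(is.numeric(biomarker_map$exposure_id) &&
              is.numeric(biomarker_map$biomarker_id),
            "biomarker map ids must be integers; see reformat_biomarker_map()",
            "serogen_config_error")
  model_pars <- validate_model_pars(model_pars)
  foe_pars <- validate_foe_grid(foe_pars)

  times <- seq.int(t_start, t_end)
  n_t <- length(times)
  n_i <- nrow(demography)
  n_x <- max(biomarker_map$exposure_id)
  n_b <- max(biomarker_map$biomarker_id)

  t0 <- attr(foe_pars, "t_start")
  sg_assert(dim(foe_pars)[3] >= n_x &&
              t0 <= t_start && t0 + dim(foe_pars)[2] - 1L >= t_end,
            "`foe_pars` must cover the simulation window and all exposure types",
            "serogen_config_error")
  for (x in seq_len(n_x)) {
    for (b in biomarkers_of(biomarker_map, x)) {
      sg_assert(any(!is.na(model_pars$exposure_id) &
                      model_pars$exposure_id == x &
                      model_pars$biomarker_id == b &
                      model_pars$name != "obs_sd"),
                sprintf("`model_pars` has no kinetics rows for exposure %d, biomarker %d",
                        x, b),
                "serogen_config_error")
    }
  }

  active <- outer(demography$birth, times, "<=") &
    outer(demography$removal, times, ">")
  if (!is.null(fixed_history)) {
    sg_assert(is.array(fixed_history) &&
                identical(dim(fixed_history), as.integer(c(n_i, n_t, n_x))),
              "`fixed_history` must be an (N, T, X) array",
              "serogen_config_error")
    bad <- !is.na(fixed_history) & !array(rep(active, n_x), dim(fixed_history))
    sg_assert(!any(bad),
              "`fixed_history` sets values where individuals are not active",
              "serogen_validation_error")
  }

  maybe_set_seed(seed)
  dots <- list(...)
  needs_bq <- function(f) "biomarker_quantities" %in% names(formals(f))
  immunity_needs_bq <- needs_bq(immunity_model)
  draws_need_bq <- needs_bq(draw_parameters)

  Z <- array(NA_integer_, dim = c(n_i, n_t, n_x))
  phi <- array(NA_real_, dim = c(n_i, n_t, n_x))
  fixed_flag <- array(FALSE, dim = c(n_i, n_t, n_x))
  attr(Z, "t_start") <- as.integer(t_start)

  kin <- data.frame(i = integer(0), t = integer(0), x = integer(0),
                    b = integer(0), name = character(0), value = numeric(0))

  ## Latent quantities at time t from events strictly before t; used by
  ## biomarker-protection immunity and titer-dependent boosting.
  current_quantities <- function(i, t) {
    past <- kin[kin$i == i & kin$t < t, , drop = FALSE]
    vapply(seq_len(n_b), function(b) {
      do.call(antibody_model,
              c(list(i = i, t = t, b = b, kinetics = past,
                     biomarker_map = biomarker_map), dots))
    }, numeric(1))
  }

  group <- demography$group
  for (ti in seq_len(n_t)) {
    t <- times[ti]
    for (i in seq_len(n_i)) {
      if (!active[i, ti]) next
      bq <- NULL
      for (x in seq_len(n_x)) {
        if (!is.null(fixed_history) && !is.na(fixed_history[i, ti, x])) {
          Z[i, ti, x] <- fixed_history[i, ti, x]
          fixed_flag[i, ti, x] <- TRUE
        } else {
          p_e <- do.call(exposure_model,
                         c(list(i = i, t = t, x = x, g = group[i],
                                foe = foe_pars, demography = demography),
                           dots))
          im_args <- list(i = i, t = t, x = x, immune_history = Z,
                          demography = demography,
                          biomarker_map = biomarker_map)
          if (immunity_needs_bq) {
            if (is.null(bq)) bq <- current_quantities(i, t)
            im_args$biomarker_quantities <- bq
          }
          p_s <- do.call(immunity_model, c(im_args, dots))
          phi[i, ti, x] <- p_e * p_s
          Z[i, ti, x] <- rbinom(1L, 1L, phi[i, ti, x])
        }
        if (identical(Z[i, ti, x], 1L)) {
          dr_args <- list(model_pars = model_pars, i = i, t = t, x = x,
                          biomarker_map = biomarker_map)
          if (draws_need_bq) {
            if (is.null(bq)) bq <- current_quantities(i, t)
            dr_args$biomarker_quantities <- bq
          }
          kin <- rbind(kin, do.call(draw_parameters, c(dr_args, dots)))
        }
      }
    }
  }

  A <- array(NA_real_, dim = c(n_i, n_t, n_b))
  for (i in seq_len(n_i)) {
    ti_active <- which(active[i, ])
    if (length(ti_active) == 0) next
    for (b in seq_len(n_b)) {
      A[i, ti_active, b] <- do.call(
        antibody_model,
        c(list(i = i, t = times[ti_active], b = b, kinetics = kin,
               biomarker_map = biomarker_map), dots))
    }
  }

  long_xt <- function(arr, n3, name3) {
    grid <- expand.grid(third = seq_len(n3), t = times, i = seq_len(n_i))
    out <- tibble::tibble(i = grid$i, t = grid$t)
    out[[name3]] <- grid$third
    out$value <- arr[cbind(grid$i, grid$t - t_start + 1L, grid$third)]
    out
  }
  exposure_probabilities <- long_xt(phi, n_x, "x")
  exposure_probabilities$fixed <-
    fixed_flag[cbind(exposure_probabilities$i,
                     exposure_probabilities$t - t_start + 1L,
                     exposure_probabilities$x)]
  immune_histories <- long_xt(Z, n_x, "x")
  biomarker_states <- long_xt(A, n_b, "b")

  observed <- apply_observation_design(biomarker_states, observation_model,
                                       assay, observation_design)

  structure(list(
    exposure_probabilities = exposure_probabilities,
    immune_histories = immune_histories,
    biomarker_states = biomarker_states,
    kinetics = tibble::as_tibble(kin),
    observed_biomarkers = observed,
    metadata = list(
      seed = seed, t_start = t_start, t_end = t_end,
      n_individuals = n_i, n_exposures = n_x, n_biomarkers = n_b,
      package_version = as.character(utils::packageVersion("serogen"))
    )
  ), class = "serosurvey_sim")
}

#' @export
print.serosurvey_sim <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "<serosurvey_sim> %d individuals, t = %d..%d, %d exposure types, %d biomarker(s)\n",
    md$n_individuals, md$t_start, md$t_end, md$n_exposures, md$n_biomarkers))
  n_events <- sum(x$immune_histories$value == 1, na.rm = TRUE)
  cat(sprintf("  successful exposure events: %d; observed samples: %d\n",
              n_events, sum(!is.na(x$observed_biomarkers$observed))))
  invisible(x)
}

#' Summarize a completed simulation
#'
#' Event counts per exposure type, per-individual successful event
#' times, and (when a threshold is given) the final seroprevalence per
#' biomarker: the fraction of non-missing observed quantities at or
#' above the threshold.
#'
#' @param res a `serosurvey_sim` object.
#' @param threshold optional seropositivity threshold for the
#'   seroprevalence summary.
#' @return list with `event_counts`, `event_times` and (optionally)
#'   `seroprevalence` tibbles.
#' @export
summarize_run <- function(res, threshold = NULL) {
  sg_assert(inherits(res, "serosurvey_sim"), "`res` must be a serosurvey_sim")
  ih <- res$immune_histories
  events <- ih[!is.na(ih$value) & ih$value == 1, c("i", "t", "x")]
  counts <- tibble::tibble(x = seq_len(res$metadata$n_exposures))
  counts$n_events <- vapply(counts$x, function(xx) sum(events$x == xx),
                            integer(1))
  out <- list(event_counts = counts,
              event_times = tibble::as_tibble(events[order(events$i, events$t), ]))
  if (!is.null(threshold)) {
    obs <- res$observed_biomarkers
    obs <- obs[!is.na(obs$observed), ]
    sp <- vapply(seq_len(res$metadata$n_biomarkers), function(b) {
      yy <- obs$observed[obs$b == b]
      if (length(yy) == 0) NA_real_ else mean(yy >= threshold)
    }, numeric(1))
    out$seroprevalence <- tibble::tibble(
      b = seq_len(res$metadata$n_biomarkers),
      threshold = threshold, seroprevalence = sp)
  }
  out
}
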