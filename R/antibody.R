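#' Antibody-kinetics model parameters
#'
#' `model_pars` is the population-level parameter table for the antibody
#' (and observation) layer: one row per (exposure, biomarker, parameter
#' name) with a mean, a standard deviation and a distribution label.
#' Kinetics parameters (`boost`, `wane`, ...) are realized per successful
#' exposure event by a draw-parameters function; the assay noise standard
#' deviation may ride along as an `obs_sd` row with an empty exposure id.
#'
#' `distribution` is `"log-normal"`, `"normal"`, or empty/`NA` for a
#' fixed parameter. Log-normal rows are moment-matched on the natural
#' scale: the `mean` and `sd` columns are the expectation and standard
#' deviation of the drawn values themselves, via
#' \eqn{\sigma^2 = \ln(1 + (sd/mean)^2)},
#' \eqn{\mu = \ln(mean) - \sigma^2/2}.
#'
#' @name model_pars
NULL

validate_model_pars <- function(model_pars) {
  sg_assert(is.data.frame(model_pars) && nrow(model_pars) >= 1,
            "`model_pars` must be a nonempty data frame")
  need <- c("exposure_id", "biomarker_id", "name", "mean", "sd", "distribution")
  sg_assert(all(need %in% names(model_pars)),
            paste("`model_pars` needs columns", paste(need, collapse = ", ")))
  key <- paste(model_pars$exposure_id, model_pars$biomarker_id,
               model_pars$name, sep = "\r")
  sg_assert(!anyDuplicated(key),
            "duplicate (exposure_id, biomarker_id, name) rows in `model_pars`")
  sg_assert(all(is.na(model_pars$sd) | model_pars$sd >= 0),
            "`model_pars$sd` must be >= 0")
  tibble::as_tibble(model_pars)
}

#' Relabel model_pars ids using the keys from [reformat_biomarker_map()]
#'
#' Rows whose exposure or biomarker label is empty or absent from the key
#' (e.g. an assay-wide `obs_sd` row) keep an `NA` id.
#'
#' @param model_pars model parameter table with label ids.
#' @param exposure_key,biomarker_key lookup tibbles (`id`, `label`).
#' @return `model_pars` with integer ids.
#' @export
reformat_model_pars <- function(model_pars, exposure_key, biomarker_key) {
  model_pars <- validate_model_pars(model_pars)
  model_pars$exposure_id <-
    exposure_key$id[match(as.character(model_pars$exposure_id),
                          exposure_key$label)]
  model_pars$biomarker_id <-
    biomarker_key$id[match(as.character(model_pars$biomarker_id),
                           biomarker_key$label)]
  model_pars
}

## Vectorized sampler behind the random-effects draw-parameters models.
sample_parameter <- function(n, mean, sd, distribution) {
  if (is.na(sd) || sd == 0 || is.na(distribution) || distribution == "") {
    return(rep(mean, n))
  }
  switch(distribution,
    "log-normal" = {
      sg_assert(mean > 0, "log-normal parameter needs mean > 0")
      sigma2 <- log(1 + (sd / mean)^2)
      rlnorm(n, meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
    },
    "normal" = rnorm(n, mean, sd),
    sg_stop(sprintf("unknown distribution label '%s'", distribution),
            "serogen_config_error")
  )
}

#' Draw realizations of a single model parameter
#'
#' Vectorized access to the sampler used by
#' [draw_parameters_random_fx()]: draws `n` realizations of one
#' (exposure, biomarker, name) row of `model_pars`, e.g. to inspect the
#' realized random-effects distribution.
#'
#' @param model_pars integer-id model parameter table.
#' @param exposure_id,biomarker_id,name row selector.
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @return numeric vector of length `n`.
#' @export
draw_parameter_values <- function(model_pars, exposure_id, biomarker_id, name,
                                  n = 1, seed = NULL) {
  maybe_set_seed(seed)
  row <- model_pars[!is.na(model_pars$exposure_id) &
                      model_pars$exposure_id == exposure_id &
                      model_pars$biomarker_id == biomarker_id &
                      model_pars$name == name, ]
  sg_assert(nrow(row) == 1,
            sprintf("no model_pars row for (exposure %s, biomarker %s, '%s')",
                    exposure_id, biomarker_id, name),
            "serogen_config_error")
  sample_parameter(n, row$mean, row$sd, row$distribution)
}

## Kinetics rows for one successful event: one row per linked biomarker
## per parameter name. `draw_fn` maps a model_pars row to one value.
event_kinetics_rows <- function(model_pars, i, t, x, biomarker_map, draw_fn) {
  b_linked <- biomarkers_of(biomarker_map, x)
  rows <- model_pars[!is.na(model_pars$exposure_id) &
                       model_pars$exposure_id == x &
                       model_pars$biomarker_id %in% b_linked &
                       model_pars$name != "obs_sd", ]
  sg_assert(all(b_linked %in% rows$biomarker_id),
            sprintf("model_pars has no kinetics rows for exposure %d and every linked biomarker", x),
            "serogen_config_error")
  data.frame(
    i = i, t = t, x = x,
    b = rows$biomarker_id,
    name = rows$name,
    value = vapply(seq_len(nrow(rows)), function(k) draw_fn(rows[k, ]),
                   numeric(1))
  )
}

## Multiply boost-type draws by exp(-sigma * antigenic_distance) when the
## map carries distances (cross-reactive boosting).
apply_cross_reactivity <- function(draws, x, biomarker_map,
                                   cross_reactivity_sigma) {
  if (is.null(cross_reactivity_sigma) ||
      !"antigenic_distance" %in% names(biomarker_map)) {
    return(draws)
  }
  rows <- biomarker_map[biomarker_map$exposure_id == x, ]
  d <- rows$antigenic_distance[match(draws$b, rows$biomarker_id)]
  is_boost <- startsWith(draws$name, "boost")
  draws$value[is_boost] <- draws$value[is_boost] *
    cross_reactive_boost_weight(d[is_boost], cross_reactivity_sigma)
  draws
}

#' Draw per-event antibody kinetics parameters
#'
#' Called by the engine once per successful exposure event; returns one
#' realized value per linked biomarker per kinetics parameter (long rows
#' `i, t, x, b, name, value`). `draw_parameters_fixed_fx()` implements a
#' fixed-effects model (every event receives the `mean` column
#' verbatim); `draw_parameters_random_fx()` draws each parameter from its
#' row's distribution, so repeated events and different individuals get
#' independent realizations.
#'
#' When the biomarker map carries an `antigenic_distance` column and
#' `cross_reactivity_sigma` is supplied, boost parameters are attenuated
#' by [cross_reactive_boost_weight()].
#'
#' @param model_pars integer-id model parameter table.
#' @param i individual id.
#' @param t event time step.
#' @param x exposure type id.
#' @param biomarker_map integer-id biomarker map.
#' @param cross_reactivity_sigma optional antigenic decay rate.
#' @param ... further model arguments (ignored).
#' @return data frame of realized parameters.
#' @export
draw_parameters_fixed_fx <- function(model_pars, i, t, x, biomarker_map,
                                     cross_reactivity_sigma = NULL, ...) {
  draws <- event_kinetics_rows(model_pars, i, t, x, biomarker_map,
                               function(row) row$mean)
  apply_cross_reactivity(draws, x, biomarker_map, cross_reactivity_sigma)
}

#' @rdname draw_parameters_fixed_fx
#' @export
draw_parameters_random_fx <- function(model_pars, i, t, x, biomarker_map,
                                      cross_reactivity_sigma = NULL, ...) {
  draws <- event_kinetics_rows(model_pars, i, t, x, biomarker_map,
                               function(row) {
                                 sample_parameter(1, row$mean, row$sd,
                                                  row$distribution)
                               })
  apply_cross_reactivity(draws, x, biomarker_map, cross_reactivity_sigma)
}

#' @rdname draw_parameters_fixed_fx
#' @param biomarker_quantities the individual's current latent biomarker
#'   quantities (supplied by the engine), used to attenuate boosts via
#'   [apply_titer_ceiling()].
#' @param ceiling_gradient titer-ceiling gradient in `[0, 1]` per
#'   biomarker unit.
#' @export
draw_parameters_random_fx_titer_dep <- function(model_pars, i, t, x,
                                                biomarker_map,
                                                biomarker_quantities,
                                                ceiling_gradient,
                                                cross_reactivity_sigma = NULL,
                                                ...) {
  draws <- draw_parameters_random_fx(model_pars, i, t, x, biomarker_map,
                                     cross_reactivity_sigma)
  is_boost <- startsWith(draws$name, "boost")
  draws$value[is_boost] <- apply_titer_ceiling(
    draws$value[is_boost], biomarker_quantities[draws$b[is_boost]],
    ceiling_gradient)
  draws
}

#' Titer-ceiling (biomarker-dependent boosting) attenuation
#'
#' Boosting shrinks linearly with the pre-existing biomarker quantity:
#' `realized = raw_boost * max(0, 1 - gradient * current_quantity)`. A
#' naive individual (quantity 0) receives the full boost; the boost hits
#' zero once `gradient * current_quantity >= 1`.
#'
#' @param raw_boost drawn boost value(s).
#' @param current_quantity latent biomarker quantity at the event time.
#' @param gradient attenuation per biomarker unit (>= 0).
#' @return realized boost value(s).
#' @export
apply_titer_ceiling <- function(raw_boost, current_quantity, gradient) {
  sg_assert(all(gradient >= 0), "`gradient` must be >= 0")
  raw_boost * pmax(0, 1 - gradient * current_quantity)
}

## Pivot an individual's kinetics rows for one biomarker into one row per
## event (t, x) with the named parameters as columns.
event_table <- function(kinetics, i, b, par_names) {
  k <- kinetics[kinetics$i == i & kinetics$b == b, , drop = FALSE]
  if (nrow(k) == 0) return(NULL)
  ev_key <- paste(k$t, k$x, sep = "\r")
  events <- k[!duplicated(ev_key), c("t", "x")]
  for (nm in par_names) {
    sel <- k$name == nm
    sg_assert(sum(sel) == nrow(events),
              sprintf("kinetics draws missing parameter '%s' for some event", nm),
              "serogen_internal_error")
    events[[nm]] <- k$value[sel][match(paste(events$t, events$x, sep = "\r"),
                                       ev_key[sel])]
  }
  events
}

#' Monophasic boosting-waning antibody model
#'
#' Each successful exposure event at time \eqn{t'} contributes a boost
#' that wanes linearly and is floored at zero; contributions from
#' multiple events add:
#' \deqn{A_{i,t,b} = \sum_{events} boost \cdot \max(0,\, 1 - wane \cdot (t - t')).}
#' The trajectory is a deterministic function of the immune history and
#' the realized per-event `boost`/`wane` draws.
#'
#' @param i individual id.
#' @param t time step(s) at which to evaluate the latent quantity
#'   (vectorized).
#' @param b biomarker id.
#' @param kinetics realized-parameter rows accumulated by the engine
#'   (columns `i, t, x, b, name, value`).
#' @param biomarker_map integer-id biomarker map (unused; plug-in
#'   signature).
#' @param ... further model arguments (ignored).
#' @return numeric vector of latent quantities, same length as `t`.
#' @export
antibody_model_monophasic <- function(i, t, b, kinetics, biomarker_map = NULL,
                                      ...) {
  events <- event_table(kinetics, i, b, c("boost", "wane"))
  A <- numeric(length(t))
  if (is.null(events)) return(A)
  for (k in seq_len(nrow(events))) {
    dt <- t - events$t[k]
    A <- A + ifelse(dt >= 0,
                    events$boost[k] * pmax(0, 1 - events$wane[k] * dt), 0)
  }
  A
}

#' Biphasic boosting-waning antibody model
#'
#' Each event contributes a fast-decaying short-lived component and a
#' slow-decaying long-lived component, both linear-waning and floored at
#' zero:
#' \deqn{A = \sum_{events} [\,boost_{long} \max(0, 1 - wane_{long}\Delta t)
#'   + boost_{short} \max(0, 1 - wane_{short}\Delta t)\,].}
#' With `boost_short = 0` this reduces to the monophasic model.
#' `model_pars` must provide rows named `boost_long`, `boost_short`,
#' `wane_long`, `wane_short`.
#'
#' @inheritParams antibody_model_monophasic
#' @export
antibody_model_biphasic <- function(i, t, b, kinetics, biomarker_map = NULL,
                                    ...) {
  events <- event_table(kinetics, i, b,
                        c("boost_long", "boost_short", "wane_long", "wane_short"))
  A <- numeric(length(t))
  if (is.null(events)) return(A)
  for (k in seq_len(nrow(events))) {
    dt <- t - events$t[k]
    contrib <- events$boost_long[k] * pmax(0, 1 - events$wane_long[k] * dt) +
      events$boost_short[k] * pmax(0, 1 - events$wane_short[k] * dt)
    A <- A + ifelse(dt >= 0, contrib, 0)
  }
  A
}

#' Read / write a model parameter table as CSV
#'
#' Layout: columns `exposure_id`, `biomarker_id`, `name`, `mean`, `sd`,
#' `distribution`.
#'
#' @param model_pars model parameter table.
#' @param path file path.
#' @export
write_model_pars <- function(model_pars, path) {
  write.csv(as.data.frame(model_pars), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_model_pars
#' @export
read_model_pars <- function(path) {
  mp <- read.csv(path)
  mp$distribution[is.na(mp$distribution)] <- ""
  validate_model_pars(mp)
}
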