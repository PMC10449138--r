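#' Immunity models
#'
#' An immunity model gives the conditional probability that an exposure
#' encounter elicits a measurable immunological response,
#' \eqn{P(Z_{i,t,x}=1 \mid E_{i,t,x}=1)}, as a function of the
#' individual's immune history before `t`, age, and (optionally) current
#' biomarker quantities. Models share the plug-in signature
#' `function(i, t, x, immune_history, demography, ...)`; a model that
#' declares a `biomarker_quantities` argument additionally receives the
#' individual's latent biomarker quantities from events strictly before
#' `t` (events within the same time step never protect against each
#' other).
#'
#' @name immunity_models
NULL

## Count successful events of type x strictly before absolute time t.
prior_event_count <- function(immune_history, i, t, x) {
  t0 <- attr(immune_history, "t_start") %||% 1L
  ti <- t - t0 + 1L
  if (ti <= 1L) return(0L)
  sum(immune_history[i, seq_len(ti - 1L), x] == 1L, na.rm = TRUE)
}

#' @describeIn immunity_models every exposure succeeds (probability 1),
#'   regardless of history, age or biomarker quantity.
#' @param i individual id.
#' @param t time step.
#' @param x exposure type id.
#' @param immune_history partial immune-history array (entries at times
#'   `< t` are filled; `NA` marks inactive cells).
#' @param demography demography table.
#' @param ... further model arguments.
#' @export
immunity_model_all_successful <- function(i, t, x, immune_history = NULL,
                                          demography = NULL, ...) {
  1
}

#' @describeIn immunity_models success gated by per-type event caps and
#'   vaccine age eligibility: returns 0 once an individual has
#'   accumulated `max_events[x]` successful events of type `x`, and 0 for
#'   vaccine exposure types while age (time steps since birth) is below
#'   `vacc_age[x]`; otherwise 1.
#' @param max_events integer vector of per-exposure-type caps on
#'   successful events.
#' @param vacc_exposures exposure type ids that are vaccines.
#' @param vacc_age per-type minimum age of vaccine eligibility (`NA` for
#'   non-vaccine types or no age restriction).
#' @export
immunity_model_vacc_ifxn_simple <- function(i, t, x, immune_history,
                                            demography,
                                            max_events,
                                            vacc_exposures = integer(0),
                                            vacc_age = NULL, ...) {
  sg_assert(length(max_events) >= x && !is.na(max_events[x]),
            sprintf("no `max_events` cap supplied for exposure type %d", x),
            "serogen_config_error")
  if (prior_event_count(immune_history, i, t, x) >= max_events[x]) return(0)
  if (x %in% vacc_exposures) {
    va <- if (is.null(vacc_age) || length(vacc_age) < x) NA else vacc_age[x]
    if (!is.na(va)) {
      age <- t - demography$birth[match(i, demography$i)]
      if (age < va) return(0)
    }
  }
  1
}

#' @describeIn immunity_models biomarker-mediated protection: the success
#'   probability decreases with the individual's current quantity of the
#'   protective biomarker(s) linked to `x` (summed over linked
#'   biomarkers, weighted by `exp(-sigma * antigenic_distance)` when the
#'   map carries distances and `cross_reactivity_sigma` is given). In
#'   `"logistic"` mode the probability is
#'   \eqn{1 - 1/(1+e^{-k(a - a_{50})})} with midpoint `midpoint`
#'   (\eqn{a_{50}}) and steepness `steepness` (\eqn{k}); in
#'   `"threshold"` mode it is 1 below the midpoint and 0 at or above it
#'   (the steepness -> infinity limit of the logistic).
#' @param biomarker_quantities numeric vector of the individual's current
#'   latent quantities indexed by biomarker id (supplied by the engine).
#' @param biomarker_map integer-id biomarker map.
#' @param midpoint biomarker quantity at which logistic protection is
#'   50%, or the hard threshold.
#' @param steepness positive logistic steepness (per biomarker unit).
#' @param mode `"logistic"` or `"threshold"`.
#' @param cross_reactivity_sigma optional positive decay rate applied to
#'   the map's `antigenic_distance` column when weighting quantities.
#' @export
immunity_model_biomarker_protection <- function(i, t, x, immune_history = NULL,
                                                demography = NULL,
                                                biomarker_quantities,
                                                biomarker_map,
                                                midpoint, steepness = 1,
                                                mode = c("logistic", "threshold"),
                                                cross_reactivity_sigma = NULL,
                                                ...) {
  mode <- match.arg(mode)
  sg_assert(is.numeric(steepness) && steepness > 0, "`steepness` must be > 0")
  rows <- biomarker_map$exposure_id == x
  sg_assert(any(rows),
            sprintf("exposure type %d has no mapped biomarker", x),
            "serogen_config_error")
  b <- biomarker_map$biomarker_id[rows]
  w <- rep(1, length(b))
  if (!is.null(cross_reactivity_sigma) &&
      "antigenic_distance" %in% names(biomarker_map)) {
    w <- cross_reactive_boost_weight(biomarker_map$antigenic_distance[rows],
                                     cross_reactivity_sigma)
  }
  a <- sum(w * biomarker_quantities[b])
  if (mode == "threshold") {
    as.numeric(a < midpoint)
  } else {
    1 - 1 / (1 + exp(-steepness * (a - midpoint)))
  }
}
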