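# Shared fixtures built in code.

toy_map <- function() {
  tibble::tibble(exposure_id = c(1L, 2L), biomarker_id = c(1L, 1L))
}

# Fixed-effects (sd = 0) monophasic parameters so trajectories are exact.
toy_model_pars <- function(boost = c(4, 2), wane = c(0.0033, 0.0016)) {
  tibble::tibble(
    exposure_id = c(1L, 1L, 2L, 2L),
    biomarker_id = 1L,
    name = c("boost", "wane", "boost", "wane"),
    mean = c(boost[1], wane[1], boost[2], wane[2]),
    sd = 0,
    distribution = ""
  )
}

toy_demography <- function(n, t_max, birth = 1L, removal = Inf) {
  tibble::tibble(i = seq_len(n), birth = rep(birth, length.out = n),
                 removal = rep(removal, length.out = n), group = 1L)
}

# Small deterministic-kinetics simulation arguments, overridable by name.
toy_sim_args <- function(n = 5, t_max = 10, lambda = c(0.05, 0.1), ...) {
  foe <- make_foe_grid(1, t_max, length(lambda))
  for (x in seq_along(lambda)) foe[, , x] <- lambda[x]
  args <- list(
    simulation_settings = list(t_start = 1, t_end = t_max),
    demography = toy_demography(n, t_max),
    biomarker_map = toy_map(),
    foe_pars = foe,
    model_pars = toy_model_pars(),
    exposure_model = exposure_model_simple_FOE,
    immunity_model = immunity_model_all_successful,
    antibody_model = antibody_model_monophasic,
    observation_model = observation_model_continuous_noise,
    draw_parameters = draw_parameters_fixed_fx,
    assay = assay_spec()
  )
  utils::modifyList(args, list(...))
}

# Independent step-by-step trajectory accumulator: each event's
# contribution starts at its boost and loses boost*wane per unit step,
# floored at zero. Used as an oracle against the closed-form kinetics.
accumulate_trajectory <- function(events, times) {
  contrib <- numeric(nrow(events))
  A <- numeric(length(times))
  for (k in seq_along(times)) {
    t <- times[k]
    for (e in seq_len(nrow(events))) {
      if (t == events$t[e]) {
        contrib[e] <- events$boost[e]
      } else if (t > events$t[e]) {
        contrib[e] <- max(0, contrib[e] - events$boost[e] * events$wane[e])
      }
    }
    A[k] <- sum(contrib)
  }
  A
}

# Immune-history array helper for direct immunity-model tests.
history_array <- function(n, t_max, n_x, events = NULL, t_start = 1L) {
  Z <- array(0L, dim = c(n, t_max, n_x))
  attr(Z, "t_start") <- as.integer(t_start)
  if (!is.null(events)) {
    for (k in seq_len(nrow(events))) {
      Z[events$i[k], events$t[k] - t_start + 1L, events$x[k]] <- 1L
    }
  }
  Z
}
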