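#' Force-of-exposure grids
#'
#' The force of exposure (FOE) generalizes the force of infection to any
#' biomarker-generating event (infection or vaccination). It is stored as
#' a 3-dimensional array \eqn{\lambda_{g,t,x}} indexed by group `g`, time
#' step `t` (spanning the whole simulation window) and exposure type `x`.
#' \eqn{\lambda} is a per-time-step rate: users must pre-scale rates to
#' the chosen time resolution.
#'
#' @param n_groups,n_times,n_exposures grid dimensions.
#' @param lambda fill value(s), recycled into the array.
#' @param t_start time label of the first column (default 1).
#' @return numeric array of dimension `(n_groups, n_times, n_exposures)`
#'   with a `t_start` attribute.
#' @examples
#' foe <- make_foe_grid(1, 120, 2)
#' foe[, , 1] <- 0.01
#' foe[, , 2] <- 0.1
#' @export
make_foe_grid <- function(n_groups, n_times, n_exposures, lambda = 0,
                          t_start = 1L) {
  foe <- array(lambda, dim = c(n_groups, n_times, n_exposures))
  attr(foe, "t_start") <- as.integer(t_start)
  validate_foe_grid(foe)
}

validate_foe_grid <- function(foe) {
  sg_assert(is.array(foe) && length(dim(foe)) == 3,
            "`foe` must be a 3-dimensional array (group x time x exposure)")
  sg_assert(all(is.finite(foe)) && all(foe >= 0),
            "all force-of-exposure entries must be finite and >= 0")
  if (is.null(attr(foe, "t_start"))) attr(foe, "t_start") <- 1L
  foe
}

## Look up lambda_{g,t,x} with t an absolute time step.
foe_lambda <- function(foe, g, t, x) {
  ti <- t - (attr(foe, "t_start") %||% 1L) + 1L
  d <- dim(foe)
  sg_assert(g >= 1 && g <= d[1] && ti >= 1 && ti <= d[2] && x >= 1 && x <= d[3],
            sprintf("FOE grid index out of bounds: (g=%s, t=%s, x=%s)", g, t, x),
            "serogen_lookup_error")
  lambda <- foe[g, ti, x]
  sg_assert(lambda >= 0, "negative force of exposure")
  lambda
}

#' Exposure probability from the population-level force of exposure
#'
#' The simplest exposure model: the probability that individual `i`
#' encounters exposure type `x` at time `t` depends only on the force of
#' exposure for the individual's group,
#' \eqn{P(E_{i,t,x}=1) = 1 - e^{-\lambda_{g,t,x}}}.
#'
#' @param i individual id (unused here; part of the plug-in signature).
#' @param t time step.
#' @param x exposure type id.
#' @param g group id.
#' @param foe FOE grid from [make_foe_grid()].
#' @param demography demography table (unused here).
#' @param ... further model arguments (ignored).
#' @return probability in `[0, 1)`.
#' @export
exposure_model_simple_FOE <- function(i, t, x, g, foe, demography = NULL, ...) {
  1 - exp(-foe_lambda(foe, g, t, x))
}

#' Exposure probability modulated by demographic covariates
#'
#' A functional transformation of the population-level force of exposure
#' given an individual's demographic data: each matching row of
#' `dem_mod` contributes a multiplier on \eqn{\lambda}, and
#' \eqn{P(E=1) = 1 - \exp(-\lambda \prod_k m_k)}. Composing on the rate
#' (not the probability) keeps the output a valid probability.
#'
#' @inheritParams exposure_model_simple_FOE
#' @param demography demography table carrying the modifier attributes.
#' @param dem_mod data frame with columns `attribute`, `value`,
#'   `modifier` (>= 0): one multiplier per attribute level, e.g. reduced
#'   exposure for a well-nourished age group.
#' @return probability in `[0, 1)`.
#' @export
exposure_model_dem_mod <- function(i, t, x, g, foe, demography, dem_mod, ...) {
  sg_assert(is.data.frame(dem_mod) &&
              all(c("attribute", "value", "modifier") %in% names(dem_mod)),
            "`dem_mod` needs columns attribute, value, modifier",
            "serogen_config_error")
  sg_assert(all(dem_mod$modifier >= 0), "`dem_mod$modifier` must be >= 0")
  lambda <- foe_lambda(foe, g, t, x)
  for (attr_name in unique(dem_mod$attribute)) {
    sg_assert(attr_name %in% names(demography),
              sprintf("modifier attribute '%s' missing from demography", attr_name),
              "serogen_config_error")
    val <- demography[[attr_name]][match(i, demography$i)]
    hit <- dem_mod$attribute == attr_name & dem_mod$value == val
    sg_assert(any(hit),
              sprintf("no modifier for attribute '%s' value '%s'", attr_name, val),
              "serogen_config_error")
    lambda <- lambda * dem_mod$modifier[hit][1]
  }
  1 - exp(-lambda)
}

#' Read / write an FOE grid as long CSV
#'
#' Long format with columns `group`, `time`, `exposure`, `lambda`; `time`
#' holds absolute time steps.
#'
#' @param foe FOE array.
#' @param path file path.
#' @export
write_foe_grid <- function(foe, path) {
  foe <- validate_foe_grid(foe)
  d <- dim(foe)
  t0 <- attr(foe, "t_start")
  long <- expand.grid(group = seq_len(d[1]),
                      time = seq.int(t0, length.out = d[2]),
                      exposure = seq_len(d[3]))
  long$lambda <- as.vector(foe)
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_foe_grid
#' @export
read_foe_grid <- function(path) {
  long <- read.csv(path)
  sg_assert(all(c("group", "time", "exposure", "lambda") %in% names(long)),
            "FOE file needs columns group, time, exposure, lambda")
  groups <- sort(unique(long$group))
  times <- sort(unique(long$time))
  exposures <- sort(unique(long$exposure))
  foe <- array(NA_real_,
               dim = c(length(groups), length(times), length(exposures)))
  foe[cbind(match(long$group, groups), match(long$time, times),
            match(long$exposure, exposures))] <- long$lambda
  sg_assert(!anyNA(foe), "FOE file does not cover the full grid")
  attr(foe, "t_start") <- as.integer(min(times))
  validate_foe_grid(foe)
}
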