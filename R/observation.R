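#' Assay specification
#'
#' Bundles the observation-model parameters describing the assay: noise
#' standard deviation (`obs_sd`), sensitivity, specificity, limits of
#' detection and output scale.
#'
#' The observation contract for a single latent value `A`:
#' * `A > 0` (true positive): with probability `sensitivity` the observed
#'   value is drawn as `Y ~ Normal(A, noise_sd)` and clamped into
#'   `[lower_bound, upper_bound]` when bounds are given; otherwise the
#'   sample is a false negative reported as exactly 0 (even when a lower
#'   bound above 0 exists — the false-negative code takes precedence).
#' * `A = 0` (true negative): with probability `specificity` the value is
#'   reported as 0; otherwise it is a false positive drawn uniformly over
#'   the observable range `[lower_bound, upper_bound]` (both bounds are
#'   therefore required whenever true negatives can occur with
#'   `specificity < 1`).
#'
#' @param noise_sd assay noise standard deviation (>= 0).
#' @param sensitivity probability a truly positive sample is reported
#'   from the noise distribution rather than zeroed.
#' @param specificity probability a truly negative sample is reported as
#'   0.
#' @param lower_bound,upper_bound limits of detection (`NA` for none).
#' @param output `"continuous"` or `"discrete"` titers.
#' @return an object of class `assay_spec`.
#' @export
assay_spec <- function(noise_sd = 0, sensitivity = 1, specificity = 1,
                       lower_bound = NA_real_, upper_bound = NA_real_,
                       output = c("continuous", "discrete")) {
  output <- match.arg(output)
  sg_assert(is.numeric(noise_sd) && noise_sd >= 0, "`noise_sd` must be >= 0")
  sg_assert(sensitivity >= 0 && sensitivity <= 1,
            "`sensitivity` must be in [0, 1]")
  sg_assert(specificity >= 0 && specificity <= 1,
            "`specificity` must be in [0, 1]")
  if (!is.na(lower_bound) && !is.na(upper_bound)) {
    sg_assert(lower_bound < upper_bound,
              "`lower_bound` must be < `upper_bound`")
  }
  structure(list(noise_sd = noise_sd, sensitivity = sensitivity,
                 specificity = specificity, lower_bound = lower_bound,
                 upper_bound = upper_bound, output = output),
            class = "assay_spec")
}

has_bounds <- function(spec) !is.na(spec$lower_bound) && !is.na(spec$upper_bound)

clamp <- function(y, lo, hi) {
  if (!is.na(lo)) y <- pmax(y, lo)
  if (!is.na(hi)) y <- pmin(y, hi)
  y
}

#' Observe latent biomarker quantities with a continuous noisy assay
#'
#' Vectorized over `A`; `NA` inputs (individual not active) stay `NA`.
#' See [assay_spec()] for the sampling contract.
#'
#' @param A latent biomarker quantities (>= 0, `NA` allowed).
#' @param spec an [assay_spec()].
#' @param ... ignored (plug-in signature).
#' @return observed quantities `Y`, same length as `A`.
#' @export
observation_model_continuous_noise <- function(A, spec, ...) {
  sg_assert(inherits(spec, "assay_spec"), "`spec` must be an assay_spec")
  sg_assert(all(A >= 0, na.rm = TRUE), "latent quantities must be >= 0")
  y <- A
  pos <- which(!is.na(A) & A > 0)
  neg <- which(!is.na(A) & A == 0)
  if (length(neg) > 0 && spec$specificity < 1 && !has_bounds(spec)) {
    sg_stop(paste("specificity < 1 requires both assay bounds:",
                  "false positives are sampled from the observable range"),
            "serogen_config_error")
  }
  if (length(pos) > 0) {
    detected <- runif(length(pos)) < spec$sensitivity
    y[pos[!detected]] <- 0
    hit <- pos[detected]
    y[hit] <- clamp(rnorm(length(hit), A[hit], spec$noise_sd),
                    spec$lower_bound, spec$upper_bound)
  }
  if (length(neg) > 0) {
    fp <- runif(length(neg)) >= spec$specificity
    y[neg[!fp]] <- 0
    y[neg[fp]] <- runif(sum(fp), spec$lower_bound, spec$upper_bound)
  }
  y
}

#' Observe latent biomarker quantities with a discrete noisy assay
#'
#' Runs the continuous-noise observation process, then discretizes:
#' nonzero values are floored and clamped into the integer range
#' `[floor(lower_bound), floor(upper_bound)]`; exact zeros (false
#' negatives and true negatives) stay 0. Suited to dilution-ladder assays
#' such as haemagglutination inhibition once latent quantities are
#' expressed in log-dilution units.
#'
#' @inheritParams observation_model_continuous_noise
#' @export
observation_model_discrete_noise <- function(A, spec, ...) {
  sg_assert(inherits(spec, "assay_spec"), "`spec` must be an assay_spec")
  sg_assert(has_bounds(spec),
            "the discrete assay model requires both bounds",
            "serogen_config_error")
  y <- observation_model_continuous_noise(A, spec)
  nz <- which(!is.na(y) & y != 0)
  y[nz] <- clamp(floor(y[nz]), floor(spec$lower_bound), floor(spec$upper_bound))
  y
}

#' Apply a sampling design and observation model to latent quantities
#'
#' Restricts the latent biomarker states to the serosurvey's sampling
#' design (which individuals, times and biomarkers are measured) and
#' passes them through the observation model. With `design = NULL` every
#' (individual, time, biomarker) cell is observed. Rows for individuals
#' not active at the sampling time carry `NA`.
#'
#' @param biomarker_states long tibble of latent quantities with columns
#'   `i`, `t`, `b`, `value` (`NA` where inactive).
#' @param model observation model function, e.g.
#'   [observation_model_continuous_noise()].
#' @param spec an [assay_spec()].
#' @param design optional data frame with columns `i`, `t`, `b`.
#' @param ... passed on to `model`.
#' @return tibble with columns `i`, `t`, `b`, `observed`.
#' @export
apply_observation_design <- function(biomarker_states, model, spec,
                                     design = NULL, ...) {
  if (is.null(design)) {
    design <- biomarker_states[c("i", "t", "b")]
  } else {
    sg_assert(all(c("i", "t", "b") %in% names(design)),
              "`design` needs columns i, t, b")
  }
  key <- function(d) paste(d$i, d$t, d$b, sep = "\r")
  idx <- match(key(design), key(biomarker_states))
  sg_assert(!anyNA(idx),
            "observation design references (i, t, b) outside the simulated range")
  tibble::tibble(
    i = design$i, t = design$t, b = design$b,
    observed = model(biomarker_states$value[idx], spec, ...)
  )
}
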