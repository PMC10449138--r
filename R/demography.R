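#' Generate a population demography table
#'
#' Simulates the population table used by every other model layer: one row
#' per individual with a birth time, a removal time (death or loss to
#' follow-up; `Inf` when the individual stays for the whole run) and a
#' group id, plus any extra covariate columns (nutritional status, sex,
#' location, ...) supplied through `attribute_specs`.
#'
#' Birth times are uniform over the supplied time grid. With probability
#' `prob_removal` an individual receives a removal time drawn uniformly
#' from the integers in `(birth, max(times)]`; when that interval is empty
#' (birth at the final step) the individual is kept for the whole run.
#'
#' @param n_individuals number of individuals (positive integer).
#' @param times strictly increasing integer vector of simulation times.
#' @param prob_removal probability in `[0, 1]` that an individual is
#'   removed before the end of the simulation.
#' @param attribute_specs optional named list of sampler functions; each
#'   is called with `n_individuals` and must return a vector of that
#'   length, stored under its name as a covariate column.
#' @param group optional vector of group ids (length 1 or
#'   `n_individuals`); defaults to group 1 for everyone.
#' @param seed optional RNG seed for a reproducible table.
#'
#' @return A tibble with columns `i`, `birth`, `removal`, `group` and one
#'   column per attribute spec.
#' @examples
#' generate_pop_demography(10, times = 1:120, prob_removal = 0, seed = 1)
#' @export
generate_pop_demography <- function(n_individuals, times, prob_removal = 0,
                                    attribute_specs = NULL, group = NULL,
                                    seed = NULL) {
  sg_assert(is.numeric(n_individuals) && length(n_individuals) == 1 &&
              n_individuals >= 1, "`n_individuals` must be a positive integer")
  sg_assert(length(times) > 0, "`times` must be a nonempty integer vector")
  sg_assert(all(is.finite(times)) && all(diff(times) > 0) || length(times) == 1,
            "`times` must be strictly increasing and finite")
  sg_assert(is.numeric(prob_removal) && length(prob_removal) == 1 &&
              prob_removal >= 0 && prob_removal <= 1,
            "`prob_removal` must be a probability in [0, 1]")
  maybe_set_seed(seed)

  n <- as.integer(n_individuals)
  times <- as.integer(times)
  t_max <- max(times)

  birth <- times[sample.int(length(times), n, replace = TRUE)]
  removal <- rep(Inf, n)
  removed <- runif(n) < prob_removal
  for (k in which(removed)) {
    support <- seq.int(birth[k] + 1L, t_max)
    if (birth[k] >= t_max) next  # empty support: stays for the whole run
    removal[k] <- support[sample.int(length(support), 1L)]
  }

  out <- tibble::tibble(
    i = seq_len(n),
    birth = birth,
    removal = removal,
    group = if (is.null(group)) 1L else as.integer(rep(group, length.out = n))
  )
  for (nm in names(attribute_specs)) {
    val <- attribute_specs[[nm]](n)
    sg_assert(length(val) == n,
              sprintf("attribute sampler '%s' returned %d values, expected %d",
                      nm, length(val), n))
    out[[nm]] <- val
  }
  out
}

#' Is an individual active (exposable/observable) at time t?
#'
#' Activity uses the half-open convention `[birth, removal)`: an
#' individual is active at its birth step and no longer active at its
#' removal step. Inactive cells carry `NA` in every simulation output.
#'
#' @param demography demography table from [generate_pop_demography()].
#' @param individual individual id (may be a vector).
#' @param t time step (may be a vector; recycled against `individual`).
#' @return logical vector.
#' @export
is_active <- function(demography, individual, t) {
  sg_assert(all(individual %in% demography$i),
            "unknown individual id in `individual`", "serogen_lookup_error")
  idx <- match(individual, demography$i)
  demography$birth[idx] <= t & t < demography$removal[idx]
}

validate_demography <- function(demography) {
  sg_assert(is.data.frame(demography) && nrow(demography) >= 1,
            "`demography` must be a data frame with at least one row")
  sg_assert(all(c("i", "birth") %in% names(demography)),
            "`demography` must have columns `i` and `birth`")
  n <- nrow(demography)
  sg_assert(identical(as.integer(demography$i), seq_len(n)),
            "`demography$i` must be exactly 1..N with no gaps or duplicates")
  demography <- tibble::as_tibble(demography)
  if (!"removal" %in% names(demography)) demography$removal <- Inf
  demography$removal[is.na(demography$removal)] <- Inf
  if (!"group" %in% names(demography)) demography$group <- 1L
  demography$group[is.na(demography$group)] <- 1L
  sg_assert(all(demography$birth <= demography$removal),
            "every `birth` must be <= `removal`")
  demography
}

#' Read / write a demography table as CSV
#'
#' The `Inf` removal sentinel is written as an empty field and restored on
#' read; a missing `group` column is filled with group 1.
#'
#' @param demography demography table.
#' @param path file path.
#' @return `read_demography()` returns a validated tibble;
#'   `write_demography()` returns `path` invisibly.
#' @export
write_demography <- function(demography, path) {
  out <- as.data.frame(demography)
  out$removal[is.infinite(out$removal)] <- NA
  write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_demography
#' @export
read_demography <- function(path) {
  validate_demography(read.csv(path))
}
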