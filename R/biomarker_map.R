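#' Exposure-to-biomarker maps
#'
#' The biomarker map records the many-to-many relationship between
#' exposure events `x` (infections, vaccine doses, ...) and the
#' biomarkers `b` they boost (e.g. pathogen-specific IgG). An optional
#' `antigenic_distance` column carries per-pair distances in antigenic
#' space for cross-reactive boosting; an absent column means distance 0
#' (full homologous boost).
#'
#' @name biomarker_map
NULL

validate_biomarker_map <- function(map) {
  sg_assert(is.data.frame(map) && nrow(map) >= 1,
            "biomarker map must be a nonempty data frame")
  sg_assert(all(c("exposure_id", "biomarker_id") %in% names(map)),
            "biomarker map needs columns `exposure_id` and `biomarker_id`")
  key <- paste(map$exposure_id, map$biomarker_id, sep = "\r")
  sg_assert(!anyDuplicated(key),
            "biomarker map contains duplicate (exposure_id, biomarker_id) pairs")
  if ("antigenic_distance" %in% names(map)) {
    sg_assert(all(is.finite(map$antigenic_distance)) &&
                all(map$antigenic_distance >= 0),
              "`antigenic_distance` must be finite and >= 0")
  }
  tibble::as_tibble(map)
}

#' Relabel a biomarker map to consecutive integer ids
#'
#' Simulation code requires integer exposure and biomarker ids. Labels are
#' relabeled to consecutive integers starting at 1, assigned in order of
#' first appearance; lookup tables are returned so results can be mapped
#' back to the original labels. Applying the function to an
#' already-numeric map returns it unchanged (identity lookups).
#'
#' @param map data frame with columns `exposure_id`, `biomarker_id` and
#'   optionally `antigenic_distance`.
#' @return list with elements `map` (integer-id tibble), `exposure_key`
#'   and `biomarker_key` (tibbles with columns `id`, `label`).
#' @examples
#' m <- data.frame(exposure_id = c("ifxn", "vacc"), biomarker_id = "IgG")
#' reformat_biomarker_map(m)$map
#' @export
reformat_biomarker_map <- function(map) {
  map <- validate_biomarker_map(map)
  relabel <- function(v) {
    labels <- unique(v)
    list(id = match(v, labels),
         key = tibble::tibble(id = seq_along(labels),
                              label = as.character(labels)))
  }
  ex <- relabel(map$exposure_id)
  bi <- relabel(map$biomarker_id)
  out <- map
  out$exposure_id <- ex$id
  out$biomarker_id <- bi$id
  list(map = out, exposure_key = ex$key, biomarker_key = bi$key)
}

#' Biomarkers boosted by an exposure type
#'
#' @param map integer-id biomarker map.
#' @param exposure exposure type id.
#' @return integer vector of biomarker ids linked to `exposure`.
#' @export
biomarkers_of <- function(map, exposure) {
  sg_assert(exposure %in% map$exposure_id,
            sprintf("exposure type %s is not in the biomarker map", exposure),
            "serogen_lookup_error")
  sort(unique(map$biomarker_id[map$exposure_id == exposure]))
}

#' Antigenic-distance weighted boost attenuation
#'
#' Cross-reactive boosting: the boost an exposure delivers to a
#' non-matching biomarker decays exponentially with the Euclidean
#' distance between the strains in antigenic space,
#' \eqn{w = e^{-\sigma d}}.
#'
#' @param distance nonnegative antigenic distance(s).
#' @param sigma positive decay rate per unit distance.
#' @return weight(s) in `(0, 1]`.
#' @export
cross_reactive_boost_weight <- function(distance, sigma) {
  sg_assert(all(distance >= 0), "`distance` must be >= 0")
  sg_assert(is.numeric(sigma) && sigma > 0, "`sigma` must be > 0")
  exp(-sigma * distance)
}

#' Read / write a biomarker map as CSV
#' @param map biomarker map.
#' @param path file path.
#' @export
write_biomarker_map <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_biomarker_map
#' @export
read_biomarker_map <- function(path) {
  validate_biomarker_map(read.csv(path))
}
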