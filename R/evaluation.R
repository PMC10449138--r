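#' Classify serostatus against a seropositivity threshold
#'
#' An observed quantity is seropositive when `Y >= threshold` (ties count
#' as positive). Missing observations are returned as `NA` and should be
#' excluded from confusion-matrix counts.
#'
#' @param y observed biomarker quantities.
#' @param threshold finite seropositivity threshold.
#' @return logical vector: `TRUE` for seropositive.
#' @export
classify_serostatus <- function(y, threshold) {
  sg_assert(is.numeric(threshold) && length(threshold) == 1 &&
              is.finite(threshold), "`threshold` must be a single finite number")
  y >= threshold
}

#' Sensitivity and specificity of seropositivity thresholds
#'
#' Simulation-recovery sweep: runs the simulator `n_replicates` times,
#' labels every observed individual's true status from their simulated
#' immune history (positive iff at least one successful infection-type
#' event at or before the sampling time — vaccination alone does not
#' count as truth-positive, so vaccinated-uninfected individuals exert
#' false-positive pressure on low thresholds), classifies observed
#' quantities against each threshold, and aggregates confusion matrices.
#' Pooled (micro-averaged) rows combine counts across replicates.
#'
#' @param sim_args named list of arguments for [simulate_serosurvey()]
#'   (everything except `seed`).
#' @param thresholds numeric vector of seropositivity thresholds.
#' @param n_replicates number of independent simulation replicates.
#' @param infection_exposures exposure type ids whose successful events
#'   define a truly infected individual.
#' @param seed optional base seed; replicate `r` runs with `seed + r`.
#' @return tibble with one row per (threshold, replicate) plus pooled
#'   rows (`replicate = NA`): columns `threshold`, `replicate`, `tp`,
#'   `tn`, `fp`, `fn`, `sensitivity`, `specificity`.
#' @export
threshold_sweep <- function(sim_args, thresholds, n_replicates,
                            infection_exposures = 1, seed = NULL) {
  sg_assert(length(thresholds) >= 1 && all(is.finite(thresholds)),
            "`thresholds` must be finite")
  sg_assert(is.numeric(n_replicates) && n_replicates >= 1,
            "`n_replicates` must be >= 1")
  base_seed <- if (is.null(seed)) NULL else as.integer(seed)

  runs <- lapply(seq_len(n_replicates), function(r) {
    do.call(simulate_serosurvey,
            c(sim_args,
              list(seed = if (is.null(base_seed)) NULL else base_seed + r)))
  })
  sweep_with_runs(runs, thresholds, infection_exposures)
}

## Shared confusion-matrix aggregation over a list of completed runs.
## Truth: an individual is positive iff it has at least one successful
## infection-type event at or before its sampling time.
sweep_with_runs <- function(runs, thresholds, infection_exposures = 1) {
  rows <- list()
  any_observed <- FALSE
  for (r in seq_along(runs)) {
    res <- runs[[r]]
    obs <- res$observed_biomarkers
    obs <- obs[!is.na(obs$observed), ]
    if (nrow(obs) == 0) next
    any_observed <- TRUE
    ih <- res$immune_histories
    inf <- ih[!is.na(ih$value) & ih$value == 1 &
                ih$x %in% infection_exposures, c("i", "t")]
    truth <- vapply(seq_len(nrow(obs)), function(k) {
      any(inf$i == obs$i[k] & inf$t <= obs$t[k])
    }, logical(1))
    for (th in thresholds) {
      pos <- classify_serostatus(obs$observed, th)
      rows[[length(rows) + 1]] <- data.frame(
        threshold = th, replicate = r,
        tp = sum(pos & truth), tn = sum(!pos & !truth),
        fp = sum(pos & !truth), fn = sum(!pos & truth))
    }
  }
  if (!any_observed) {
    sg_stop("no observed individuals in any replicate", "serogen_empty_result")
  }
  per_rep <- do.call(rbind, rows)
  pooled <- do.call(rbind, lapply(sort(unique(per_rep$threshold)), function(th) {
    s <- per_rep[per_rep$threshold == th, ]
    data.frame(threshold = th, replicate = NA_integer_,
               tp = sum(s$tp), tn = sum(s$tn),
               fp = sum(s$fp), fn = sum(s$fn))
  }))
  out <- rbind(per_rep, pooled)
  rate <- function(num, den) ifelse(num + den > 0, num / (num + den), NA_real_)
  out$sensitivity <- rate(out$tp, out$fn)
  out$specificity <- rate(out$tn, out$fp)
  tibble::as_tibble(out[order(out$threshold, out$replicate, na.last = TRUE), ])
}

#' Write a threshold-sweep result as CSV
#'
#' Pooled rows are labeled `"pooled"` in the `replicate` column.
#'
#' @param sweep result of [threshold_sweep()].
#' @param path file path.
#' @export
write_threshold_sweep <- function(sweep, path) {
  out <- as.data.frame(sweep)
  out$replicate <- ifelse(is.na(out$replicate), "pooled",
                          as.character(out$replicate))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
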