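test_that("serostatus classification treats ties as positive", {
  expect_true(classify_serostatus(2, 2))
  expect_false(classify_serostatus(0, 0.5))
  expect_true(classify_serostatus(1e9, 350))
  expect_error(classify_serostatus(1, Inf), class = "serogen_invalid_input")
})

test_that("a hand-constructed run yields the expected confusion matrix", {
  # individual 1 infected at t = 1 (boost 4, no waning in 3 steps to speak
  # of), individual 2 naive; perfect assay; threshold 1
  fixed <- array(NA_integer_, dim = c(2, 3, 2))
  fixed[1, 1, 1] <- 1L
  args <- toy_sim_args(n = 2, t_max = 3, lambda = c(0, 0),
                       fixed_history = fixed,
                       observation_design = tibble::tibble(i = 1:2, t = 3,
                                                           b = 1L))
  sweep <- threshold_sweep(args, thresholds = 1, n_replicates = 1, seed = 1)
  pooled <- sweep[is.na(sweep$replicate), ]
  expect_equal(pooled$tp, 1)
  expect_equal(pooled$tn, 1)
  expect_equal(pooled$fp, 0)
  expect_equal(pooled$fn, 0)
  expect_equal(pooled$sensitivity, 1)
  expect_equal(pooled$specificity, 1)
})

test_that("separable classes give perfect sensitivity; absurd thresholds flip it", {
  # infection only, fixed boost 4 with negligible waning, perfect assay
  args <- toy_sim_args(
    n = 30, t_max = 20, lambda = c(0.2, 0),
    model_pars = toy_model_pars(boost = c(4, 2), wane = c(1e-5, 1e-5)),
    observation_design = tibble::tibble(i = 1:30, t = 20, b = 1L))
  sweep <- threshold_sweep(args, thresholds = c(0.5, 1e6), n_replicates = 2,
                           seed = 10)
  pooled <- sweep[is.na(sweep$replicate), ]
  low <- pooled[pooled$threshold == 0.5, ]
  expect_equal(low$sensitivity, 1)
  expect_equal(low$specificity, 1)
  high <- pooled[pooled$threshold == 1e6, ]
  expect_equal(high$sensitivity, 0)
  expect_equal(high$specificity, 1)
})

test_that("sensitivity falls and specificity rises with the threshold", {
  inp <- quickstart_inputs(n_individuals = 50, n_times = 60, seed = 21)
  inp$seed <- NULL
  sweep <- threshold_sweep(inp, thresholds = c(0.25, 1, 2, 4, 8),
                           n_replicates = 3, seed = 30)
  pooled <- sweep[is.na(sweep$replicate), ]
  pooled <- pooled[order(pooled$threshold), ]
  expect_true(all(diff(pooled$sensitivity) <= 0))
  expect_true(all(diff(pooled$specificity) >= 0))
  # confusion-matrix totals are conserved across thresholds
  totals <- rowSums(pooled[c("tp", "tn", "fp", "fn")])
  expect_equal(length(unique(totals)), 1)
})

test_that("pooled rates converge to the assay operating characteristics", {
  # infection as the only exposure type, no waning to zero, noiseless
  # assay: a threshold just above 0 recovers the assay sensitivity and
  # specificity themselves
  foe <- make_foe_grid(1, 60, 1)
  foe[, , 1] <- 0.02
  args <- list(
    simulation_settings = list(t_start = 1, t_end = 60),
    demography = toy_demography(100, 60),
    biomarker_map = tibble::tibble(exposure_id = 1L, biomarker_id = 1L),
    foe_pars = foe,
    model_pars = toy_model_pars()[1:2, ],
    exposure_model = exposure_model_simple_FOE,
    immunity_model = immunity_model_vacc_ifxn_simple,
    antibody_model = antibody_model_monophasic,
    observation_model = observation_model_continuous_noise,
    draw_parameters = draw_parameters_fixed_fx,
    assay = assay_spec(noise_sd = 0, sensitivity = 0.85, specificity = 0.9,
                       lower_bound = 0, upper_bound = 10),
    observation_design = tibble::tibble(i = 1:100, t = 60, b = 1L),
    max_events = 1)
  sweep <- threshold_sweep(args, thresholds = 1e-6, n_replicates = 5,
                           seed = 40)
  pooled <- sweep[is.na(sweep$replicate), ]
  n_pos <- pooled$tp + pooled$fn
  n_neg <- pooled$tn + pooled$fp
  expect_lt(abs(pooled$sensitivity - 0.85), 3 * sqrt(0.85 * 0.15 / n_pos))
  expect_lt(abs(pooled$specificity - 0.9), 3 * sqrt(0.9 * 0.1 / n_neg))
})

test_that("sweeps with no observed individuals are rejected", {
  args <- toy_sim_args(n = 2, t_max = 3, lambda = c(0, 0),
                       demography = toy_demography(2, 3, birth = 10L))
  expect_error(threshold_sweep(args, thresholds = 1, n_replicates = 1,
                               seed = 1),
               class = "serogen_empty_result")
})

test_that("sweep results serialize with a labeled pooled row", {
  fixed <- array(NA_integer_, dim = c(2, 3, 2))
  fixed[1, 1, 1] <- 1L
  args <- toy_sim_args(n = 2, t_max = 3, lambda = c(0, 0),
                       fixed_history = fixed,
                       observation_design = tibble::tibble(i = 1:2, t = 3,
                                                           b = 1L))
  sweep <- threshold_sweep(args, thresholds = 1, n_replicates = 2, seed = 1)
  path <- withr::local_tempfile(fileext = ".csv")
  write_threshold_sweep(sweep, path)
  out <- read.csv(path, colClasses = c(replicate = "character"))
  expect_equal(nrow(out), 3)
  expect_true("pooled" %in% out$replicate)
})
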