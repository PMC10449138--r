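test_that("zero force of exposure yields no events and zero titers", {
  args <- toy_sim_args(n = 5, t_max = 10, lambda = c(0, 0))
  res <- do.call(simulate_serosurvey, c(args, list(seed = 1)))
  expect_true(all(res$immune_histories$value == 0, na.rm = TRUE))
  expect_true(all(res$biomarker_states$value == 0, na.rm = TRUE))
  expect_equal(nrow(res$kinetics), 0)
  expect_true(all(res$exposure_probabilities$value == 0, na.rm = TRUE))
})

test_that("identical seeds reproduce the run exactly", {
  args <- toy_sim_args(n = 10, t_max = 30, lambda = c(0.05, 0.1),
                       draw_parameters = draw_parameters_random_fx,
                       assay = assay_spec(noise_sd = 0.25, sensitivity = 0.85,
                                          specificity = 0.9, lower_bound = 0,
                                          upper_bound = 10))
  r1 <- do.call(simulate_serosurvey, c(args, list(seed = 77)))
  r2 <- do.call(simulate_serosurvey, c(args, list(seed = 77)))
  expect_identical(r1$immune_histories, r2$immune_histories)
  expect_identical(r1$kinetics, r2$kinetics)
  expect_identical(r1$observed_biomarkers, r2$observed_biomarkers)
})

test_that("stored phi equals the product of the model probabilities", {
  inp <- quickstart_inputs(n_individuals = 30, n_times = 40, seed = 5)
  res <- do.call(simulate_serosurvey, c(inp, list(seed = 6)))
  ep <- res$exposure_probabilities
  ih <- res$immune_histories
  dem <- inp$demography
  for (k in which(!is.na(ep$value))) {
    i <- ep$i[k]; t <- ep$t[k]; x <- ep$x[k]
    p_e <- exposure_model_simple_FOE(i, t, x, dem$group[i], inp$foe_pars)
    prior <- sum(ih$value[ih$i == i & ih$t < t & ih$x == x] == 1, na.rm = TRUE)
    p_s <- if (prior >= 1) 0
           else if (x == 2 && (t - dem$birth[i]) < 9) 0
           else 1
    expect_identical(ep$value[k], p_e * p_s)
  }
})

test_that("fixed immune-history entries are honored verbatim", {
  n <- 3; t_max <- 5
  fixed <- array(NA_integer_, dim = c(n, t_max, 2))
  fixed[2, 3, 1] <- 1L
  args <- toy_sim_args(n = n, t_max = t_max, lambda = c(0, 0),
                       fixed_history = fixed)
  res <- do.call(simulate_serosurvey, c(args, list(seed = 2)))
  ih <- res$immune_histories
  expect_equal(ih$value[ih$i == 2 & ih$t == 3 & ih$x == 1], 1L)
  ep <- res$exposure_probabilities
  cell <- ep[ep$i == 2 & ep$t == 3 & ep$x == 1, ]
  expect_true(is.na(cell$value) && cell$fixed)
  # the fixed event produces kinetics draws and a titer boost
  expect_equal(nrow(res$kinetics), 2)
  bs <- res$biomarker_states
  expect_equal(bs$value[bs$i == 2 & bs$t == 3 & bs$b == 1], 4)
  # fixing a value where the individual is not active is rejected
  dem <- toy_demography(n, t_max, birth = c(1L, 4L, 1L))
  expect_error(
    do.call(simulate_serosurvey,
            c(toy_sim_args(n = n, t_max = t_max, demography = dem,
                           fixed_history = fixed), list(seed = 2))),
    class = "serogen_validation_error")
})

test_that("outputs are missing exactly where individuals are inactive", {
  dem <- tibble::tibble(i = 1:4, birth = c(1L, 5L, 1L, 8L),
                        removal = c(Inf, Inf, 7, Inf), group = 1L)
  args <- toy_sim_args(n = 4, t_max = 10, demography = dem,
                       lambda = c(0.3, 0.2))
  res <- do.call(simulate_serosurvey, c(args, list(seed = 3)))
  for (tab in list(res$immune_histories, res$exposure_probabilities)) {
    expect_equal(is.na(tab$value),
                 !is_active(dem, tab$i, tab$t))
  }
  bs <- res$biomarker_states
  expect_equal(is.na(bs$value), !is_active(dem, bs$i, bs$t))
})

test_that("event caps and vaccine age hold over whole simulations", {
  for (s in 1:5) {
    inp <- quickstart_inputs(n_individuals = 40, n_times = 120, seed = s)
    res <- do.call(simulate_serosurvey, c(inp, list(seed = 100 + s)))
    ih <- res$immune_histories
    ev <- ih[!is.na(ih$value) & ih$value == 1, ]
    counts <- table(ev$i, ev$x)
    expect_true(all(counts <= 1))
    vacc <- ev[ev$x == 2, ]
    if (nrow(vacc) > 0) {
      ages <- vacc$t - inp$demography$birth[vacc$i]
      expect_true(all(ages >= 9))
    }
    # conservation: one kinetics event group per successful mapped event
    groups <- unique(res$kinetics[c("i", "t", "x")])
    expect_equal(nrow(groups), nrow(ev))
  }
})

test_that("a perfect noiseless assay observes the latent state exactly", {
  args <- toy_sim_args(n = 8, t_max = 20, lambda = c(0.1, 0.1))
  res <- do.call(simulate_serosurvey, c(args, list(seed = 4)))
  merged <- merge(res$observed_biomarkers, res$biomarker_states,
                  by = c("i", "t", "b"))
  expect_equal(merged$observed, merged$value)
})

test_that("biomarker-protection immunity uses pre-decision quantities", {
  # infection boosts above the hard threshold, so a second success of the
  # other exposure type is impossible once the first has boosted.
  args <- toy_sim_args(
    n = 10, t_max = 30, lambda = c(0.5, 0.5),
    immunity_model = immunity_model_biomarker_protection,
    midpoint = 1, mode = "threshold")
  res <- do.call(simulate_serosurvey, c(args, list(seed = 9)))
  ih <- res$immune_histories
  ev <- ih[!is.na(ih$value) & ih$value == 1, ]
  # events can share a time step (same-step successes do not protect),
  # but never occur after an earlier boosting step
  for (ii in unique(ev$i)) {
    tt <- ev$t[ev$i == ii]
    expect_true(length(unique(tt)) <= 1)
  }
})

test_that("run summaries count events and seroprevalence", {
  n <- 2; t_max <- 3
  fixed <- array(NA_integer_, dim = c(n, t_max, 2))
  fixed[1, 1, 1] <- 1L
  fixed[1, 2, 2] <- 1L
  fixed[2, 3, 1] <- 1L
  args <- toy_sim_args(n = n, t_max = t_max, lambda = c(0, 0),
                       fixed_history = fixed,
                       observation_design = tibble::tibble(i = 1:2, t = 3,
                                                           b = 1L))
  res <- do.call(simulate_serosurvey, c(args, list(seed = 1)))
  s <- summarize_run(res, threshold = 1)
  expect_equal(s$event_counts$n_events, c(2L, 1L))
  expect_equal(s$event_times$t, c(1L, 2L, 3L))
  expect_equal(s$seroprevalence$seroprevalence, 1)

  empty <- do.call(simulate_serosurvey,
                   c(toy_sim_args(n = 2, t_max = 3, lambda = c(0, 0)),
                     list(seed = 1)))
  expect_equal(summarize_run(empty)$event_counts$n_events, c(0L, 0L))
})
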