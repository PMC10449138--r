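quick_pars <- function() quickstart_model_pars()

test_that("fixed-effects draws return the mean column verbatim", {
  d1 <- draw_parameters_fixed_fx(quick_pars(), i = 1, t = 5, x = 1,
                                 biomarker_map = toy_map())
  expect_equal(d1$value[d1$name == "boost"], 4)
  expect_equal(d1$value[d1$name == "wane"], 0.0033)
  set.seed(99)
  d2 <- draw_parameters_fixed_fx(quick_pars(), i = 1, t = 5, x = 1,
                                 biomarker_map = toy_map())
  expect_equal(d1, d2)  # independent of RNG state
})

test_that("draws fan out over all linked biomarkers", {
  map <- tibble::tibble(exposure_id = 1L, biomarker_id = c(1L, 2L))
  mp <- tibble::tibble(exposure_id = 1L, biomarker_id = c(1L, 2L),
                       name = "boost", mean = c(4, 3), sd = 0,
                       distribution = "")
  d <- draw_parameters_fixed_fx(mp, i = 1, t = 1, x = 1, biomarker_map = map)
  expect_equal(nrow(d), 2)
  expect_equal(d$value, c(4, 3))
})

test_that("random-effects draws recover natural-scale moments", {
  mp <- quick_pars()
  check_row <- function(x, name, mean, sd) {
    v <- draw_parameter_values(mp, x, 1, name, n = 50000, seed = 123)
    expect_lt(abs(mean(v) - mean), 3 * sd / sqrt(length(v)))
    # log-normal moment matching also fixes the natural-scale sd
    expect_lt(abs(sd(v) - sd), 4 * sd / sqrt(length(v)))
    expect_true(all(v > 0))
  }
  check_row(1, "boost", 4, 2)
  check_row(1, "wane", 0.0033, 0.0005)
  check_row(2, "boost", 2, 1)
})

test_that("normal rows and degenerate rows draw as specified", {
  mp <- tibble::tibble(exposure_id = 1L, biomarker_id = 1L,
                       name = c("boost", "wane"), mean = c(4, 0.01),
                       sd = c(1, 0), distribution = c("normal", "normal"))
  map <- toy_map()
  v <- replicate(2000, {
    d <- draw_parameters_random_fx(mp, 1, 1, 1, map)
    d$value[d$name == "boost"]
  })
  expect_lt(abs(mean(v) - 4), 3 / sqrt(2000))
  d <- draw_parameters_random_fx(mp, 1, 1, 1, map)
  expect_equal(d$value[d$name == "wane"], 0.01)  # sd = 0 is degenerate
})

test_that("bad distribution specifications are rejected", {
  map <- toy_map()
  bad_label <- tibble::tibble(exposure_id = 1L, biomarker_id = 1L,
                              name = "boost", mean = 4, sd = 1,
                              distribution = "gamma")
  expect_error(draw_parameters_random_fx(bad_label, 1, 1, 1, map),
               class = "serogen_config_error")
  neg_mean <- tibble::tibble(exposure_id = 1L, biomarker_id = 1L,
                             name = "boost", mean = -4, sd = 1,
                             distribution = "log-normal")
  expect_error(draw_parameters_random_fx(neg_mean, 1, 1, 1, map),
               class = "serogen_invalid_input")
  expect_error(draw_parameters_random_fx(quick_pars(), 1, 1, 99, map),
               class = "serogen_lookup_error")
})

test_that("monophasic kinetics evaluate the linear boost-wane form", {
  kin <- data.frame(i = 1L, t = 10L, x = 1L, b = 1L,
                    name = c("boost", "wane"), value = c(4, 0.0033))
  expect_equal(antibody_model_monophasic(1, 5, 1, kin), 0)   # before event
  expect_equal(antibody_model_monophasic(1, 10, 1, kin), 4)  # at event
  expect_equal(antibody_model_monophasic(1, 110, 1, kin), 4 * (1 - 0.33))
  expect_equal(antibody_model_monophasic(2, 10, 1, kin), 0)  # other individual
  expect_equal(antibody_model_monophasic(1, 10, 2, kin), 0)  # other biomarker
})

test_that("closed-form kinetics match the step-accumulator oracle", {
  set.seed(42)
  for (rep in 1:10) {
    n_events <- sample(1:3, 1)
    events <- data.frame(t = sort(sample(1:60, n_events)),
                         boost = runif(n_events, 1, 6),
                         wane = runif(n_events, 0.001, 0.2))
    kin <- do.call(rbind, lapply(seq_len(n_events), function(e) {
      data.frame(i = 1L, t = events$t[e], x = e, b = 1L,
                 name = c("boost", "wane"),
                 value = c(events$boost[e], events$wane[e]))
    }))
    times <- 1:120
    expect_equal(antibody_model_monophasic(1, times, 1, kin),
                 accumulate_trajectory(events, times), tolerance = 1e-12)
  }
})

test_that("biphasic kinetics reduce to monophasic and sum components", {
  bi <- data.frame(i = 1L, t = 5L, x = 1L, b = 1L,
                   name = c("boost_long", "boost_short", "wane_long",
                            "wane_short"),
                   value = c(3, 2, 0.01, 0.5))
  expect_equal(antibody_model_biphasic(1, 5, 1, bi), 5)  # both at event time
  # short component floors first: only the long component remains
  expect_equal(antibody_model_biphasic(1, 55, 1, bi), 3 * (1 - 0.01 * 50))
  # boost_short = 0 reduces exactly to the monophasic model
  bi0 <- bi
  bi0$value[bi0$name == "boost_short"] <- 0
  mono <- data.frame(i = 1L, t = 5L, x = 1L, b = 1L,
                     name = c("boost", "wane"), value = c(3, 0.01))
  expect_equal(antibody_model_biphasic(1, 1:80, 1, bi0),
               antibody_model_monophasic(1, 1:80, 1, mono))
})

test_that("titer ceiling attenuates boosts linearly and floors at zero", {
  expect_equal(apply_titer_ceiling(4, 0, 0.1), 4)
  expect_equal(apply_titer_ceiling(4, 5, 0.1), 2)
  expect_equal(apply_titer_ceiling(4, 20, 0.1), 0)
  expect_error(apply_titer_ceiling(4, 1, -0.1),
               class = "serogen_invalid_input")
})

test_that("cross-reactivity attenuates boosts by antigenic distance", {
  map <- tibble::tibble(exposure_id = c(1L, 1L), biomarker_id = c(1L, 2L),
                        antigenic_distance = c(0, 2))
  mp <- tibble::tibble(exposure_id = 1L, biomarker_id = c(1L, 2L),
                       name = "boost", mean = 4, sd = 0, distribution = "")
  d <- draw_parameters_fixed_fx(mp, 1, 1, 1, map, cross_reactivity_sigma = 0.5)
  expect_equal(d$value[d$b == 1], 4)            # homologous: full boost
  expect_equal(d$value[d$b == 2], 4 * exp(-1))  # distance 2, sigma 0.5
})

test_that("model parameter tables round-trip through CSV", {
  mp <- quickstart_model_pars(labels = TRUE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_model_pars(mp, path)
  mp2 <- read_model_pars(path)
  expect_equal(mp2$mean, mp$mean)
  expect_equal(mp2$sd, mp$sd)
  expect_equal(mp2$distribution, mp$distribution)
  ref <- reformat_biomarker_map(
    tibble::tibble(exposure_id = c("ifxn", "vacc"), biomarker_id = "IgG"))
  mpn <- reformat_model_pars(mp2, ref$exposure_key, ref$biomarker_key)
  expect_equal(mpn$exposure_id, c(1L, 1L, 2L, 2L, NA))
  expect_equal(mpn$biomarker_id, rep(1L, 5))
})
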