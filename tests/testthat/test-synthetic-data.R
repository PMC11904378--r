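test_that("spec invariants are enforced", {
  expect_error(synthetic_spec(n_occasions = 11), "exceed 11")
  expect_error(synthetic_spec(latent_correlation = 1.2), "\\[-1, 1\\]")
  expect_error(synthetic_spec(x_noise_sd = rep(0, 6)), "positive")
  expect_error(synthetic_spec(x_loadings = 1:3), "6 x_loadings")
})

test_that("population rho follows the closed form and its limits", {
  expect_equal(compute_population_rho(
    synthetic_spec(latent_correlation = 0)), 0)
  # zero loadings on one block -> pure noise -> 0
  expect_equal(compute_population_rho(
    synthetic_spec(x_loadings = rep(0, 6))), 0)
  # vanishing noise -> |latent correlation|
  expect_equal(compute_population_rho(
    synthetic_spec(latent_correlation = -0.7,
                   x_noise_sd = rep(1e-8, 6), y_noise_sd = rep(1e-8, 5))),
    0.7, tolerance = 1e-10)
  # unit loadings, unit noise: c_x = 6, c_y = 5
  expect_equal(compute_population_rho(
    synthetic_spec(latent_correlation = 0.9)),
    0.9 * sqrt(6 / 7) * sqrt(5 / 6))
})

test_that("closed-form rho agrees with a large-sample fit", {
  spec <- synthetic_spec(n_occasions = 1e5, latent_correlation = 0.9,
                         seed = 424)
  occ <- generate_occasion_matrices(spec)
  fit <- fit_pcca(occ$A_x, occ$A_y)
  expect_equal(fit$rho[1], compute_population_rho(spec), tolerance = 0.005)
})

test_that("target-rho specs invert the attenuation exactly", {
  base <- synthetic_spec(x_noise_sd = rep(0.8, 6), y_noise_sd = rep(0.8, 5))
  spec <- spec_with_target_rho(0.85, base)
  expect_equal(compute_population_rho(spec), 0.85, tolerance = 1e-12)
  expect_error(spec_with_target_rho(0.99, synthetic_spec()), "ceiling")
})

test_that("occasion generation is seeded-deterministic with named columns", {
  spec <- synthetic_spec(seed = 77)
  a <- generate_occasion_matrices(spec)
  b <- generate_occasion_matrices(spec)
  expect_identical(a$A_x, b$A_x)
  expect_identical(a$A_y, b$A_y)
  expect_equal(colnames(a$A_x), ax_variables())
  expect_equal(colnames(a$A_y), ay_variables())
  expect_equal(dim(a$A_x), c(27L, 6L))
  expect_length(a$timestamps, 27)
  c <- generate_occasion_matrices(synthetic_spec(seed = 78))
  expect_false(identical(a$A_x, c$A_x))
})

test_that("noiseless, perfectly coupled latents give sample rho near 1, and
           zero loadings give a null-level rho", {
  spec1 <- synthetic_spec(latent_correlation = 1,
                          x_noise_sd = rep(1e-6, 6),
                          y_noise_sd = rep(1e-6, 5), seed = 3)
  occ1 <- generate_occasion_matrices(spec1)
  expect_gt(fit_pcca(occ1$A_x, occ1$A_y)$rho[1], 0.999)
  spec0 <- synthetic_spec(latent_correlation = 0.9,
                          x_loadings = rep(0, 6), y_loadings = rep(0, 5),
                          seed = 3)
  occ0 <- generate_occasion_matrices(spec0)
  pn <- permute_null(occ0$A_x, occ0$A_y, B = 99, seed = 5)
  expect_gt(pn$p_value, 0.05)
})

test_that("natural-scale mapping preserves the canonical structure", {
  spec <- synthetic_spec(seed = 99, latent_correlation = 0.9)
  raw <- generate_occasion_matrices(spec)
  nat <- suppressMessages(generate_occasion_matrices(spec,
                                                     natural_scale = TRUE))
  # same seed, affine map: canonical correlations equal when nothing clips
  if (nat$n_clipped == 0) {
    expect_equal(fit_pcca(nat$A_x, nat$A_y)$rho,
                 fit_pcca(raw$A_x, raw$A_y)$rho, tolerance = 1e-10)
  }
  expect_true(all(nat$A_x >= 0))
  bl <- default_metric_baselines()
  expect_true(all(nat$A_y[, "state_anxiety"] >= 20 &
                    nat$A_y[, "state_anxiety"] <= 80))
})

test_that("plans render to streams that sessionize back exactly", {
  plan <- person_plan(
    day = c(1, 1), apps = list(c("a", "b", "a"), c("b")),
    start = as.POSIXct("2021-03-01 08:00:00", tz = "UTC") + c(0, 3600))
  ev <- render_event_stream(plan)
  expect_equal(nrow(ev), (3 + 2) + (1 + 2))
  ss <- sessionize(ev)
  expect_equal(nrow(ss$sessions), 2)
  expect_equal(ss$sessions$duration, c(15, 5))
  expect_equal(count_app_switches(ss), 2L)

  # 3 days x 5 sessions x 2 min with app sequence (A, B, A) per session:
  # hand count: 24 shots/session, switches 2 per session
  starts <- as.POSIXct("2021-03-01 08:00:00", tz = "UTC") +
    rep((0:2) * 86400, each = 5) + rep((0:4) * 1800, 3)
  apps <- rep(list(rep(c("A", "B", "A"), each = 8)), 15)
  plan3 <- person_plan(day = rep(1:3, each = 5), start = starts, apps = apps)
  d <- compute_daily_metrics(sessionize(render_event_stream(plan3)))
  expect_equal(d$n_sessions, rep(5L, 3))
  expect_equal(d$n_screenshots, rep(120L, 3))
  expect_equal(d$total_duration, rep(600, 3))
  expect_equal(d$n_app_switches, rep(10L, 3))
  expect_equal(d$n_unique_apps, rep(2L, 3))
})

test_that("degenerate plans are refused; empty plans render empty streams", {
  expect_error(person_plan(day = 1, start = Sys.time(), apps = list(character(0))),
               "at least one screenshot")
  t0 <- as.POSIXct("2021-03-01 08:00:00", tz = "UTC")
  overlap <- person_plan(day = c(1, 1), start = c(t0, t0 + 10),
                         apps = list(rep("a", 10), "b"))
  expect_error(render_event_stream(overlap), "overlap")
  empty <- person_plan(day = integer(), start = as.POSIXct(character()),
                       apps = list())
  expect_equal(nrow(render_event_stream(empty)), 0)
})

test_that("random plans round-trip through rendering and metrics", {
  for (s in 1:20) {
    plan <- random_person_plan(n_days = 3, seed = 1000 + s)
    expected <- plan_daily_summary(plan)
    got <- compute_daily_metrics(sessionize(render_event_stream(plan)))
    expect_equal(got$n_sessions, expected$n_sessions)
    expect_equal(got$n_screenshots, expected$n_screenshots)
    expect_equal(got$total_duration, expected$total_duration)
    expect_equal(got$n_app_switches, expected$n_app_switches)
    expect_equal(got$n_unique_apps, expected$n_unique_apps)
    expect_identical(got$apps, expected$apps)
    # independent hand count of switches from the plan itself
    for (d in unique(plan$day)) {
      expect_equal(expected$n_app_switches[expected$day == d],
                   hand_switch_count(plan$apps[plan$day == d]))
    }
  }
})

test_that("survey item generation round-trips totals through the scorers", {
  set.seed(61)
  for (i in 1:20) {
    tot <- list(cesd = sample(0:30, 1), stai = sample(20:80, 1),
                ina = sample(0:36, 1), hyp = sample(0:36, 1),
                pa = runif(1, 0, 100))
    row <- generate_survey_items(tot$cesd, tot$stai, tot$ina, tot$hyp,
                                 tot$pa, seed = i)
    expect_equal(score_cesd(as.numeric(row[cesd_cols]))$total, tot$cesd)
    expect_equal(score_stai_state(as.numeric(row[stai_cols]))$total, tot$stai)
    asrs <- score_asrs(as.numeric(row[asrs_cols]))
    expect_equal(asrs$inattention, tot$ina)
    expect_equal(asrs$hyperactivity, tot$hyp)
  }
  # identical seeds give byte-identical rows
  expect_identical(generate_survey_items(10, 40, 5, 5, 50, seed = 2),
                   generate_survey_items(10, 40, 5, 5, 50, seed = 2))
})
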