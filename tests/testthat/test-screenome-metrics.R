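t0 <- as.POSIXct("2021-05-01 10:00:00", tz = "UTC")

test_that("empty streams sessionize to nothing", {
  ss <- sessionize(tibble::tibble(timestamp = character(),
                                  event_type = character(),
                                  app = character()))
  expect_equal(nrow(ss$sessions), 0)
  expect_equal(count_app_switches(ss), 0L)
  expect_equal(nrow(compute_daily_metrics(ss)), 0)
})

test_that("an on/off interval with cadence screenshots forms one session", {
  ss <- sessionize(onoff_session(12, t0 = t0))
  expect_equal(nrow(ss$sessions), 1)
  expect_equal(ss$sessions$duration, 60)
  expect_equal(nrow(ss$shots), 12)
  expect_equal(count_app_switches(ss), 0L)
})

test_that("gap-threshold sessionization splits runs at large gaps", {
  # gaps (5, 5, 120, 5): two runs of sizes 3 and 2 under a 30 s threshold
  ev <- shot_stream(cumsum(c(0, 5, 5, 120, 5)), rep("a", 5), t0 = t0)
  ss <- sessionize(ev, gap_threshold = 30)
  expect_equal(nrow(ss$sessions), 2)
  expect_equal(tabulate(ss$shots$session), c(3, 2))
  expect_equal(ss$sessions$start[1], t0)
  expect_equal(ss$sessions$end[2], t0 + 135)
})

test_that("malformed streams are repaired with a warning count", {
  ev <- tibble::tibble(
    timestamp = t0 + c(0, 5, 10, 12, 15, 40),
    event_type = c("screenshot", "screenshot", "screen_on", "screenshot",
                   "screen_on", "screen_off"),
    app = c("a", "a", NA, "b", NA, NA))
  expect_warning(ss <- sessionize(ev), "repair")
  expect_gt(ss$repairs, 0)
  expect_equal(nrow(ss$shots), 3)
  expect_error(sessionize(ev[c(2, 1), ]), "non-decreasing")
  expect_error(
    sessionize(tibble::tibble(timestamp = t0, event_type = "screenshot",
                              app = NA_character_)),
    "app identifier")
})

test_that("app switches count differing consecutive pairs, policy-aware", {
  one <- sessionize(onoff_session(2, app = c("facebook", "zoom"), t0 = t0))
  expect_equal(count_app_switches(one), 1L)
  same <- sessionize(onoff_session(6, app = "maps", t0 = t0))
  expect_equal(count_app_switches(same), 0L)
  # two sessions (A, A, B) and (B, C): 2 within; cross-session B->B adds none
  two <- rbind(onoff_session(3, app = c("A", "A", "B"), t0 = t0),
               onoff_session(2, app = c("B", "C"), t0 = t0 + 300))
  ss <- sessionize(two)
  expect_equal(count_app_switches(ss, cross_session = FALSE), 2L)
  expect_equal(count_app_switches(ss, cross_session = TRUE), 2L)
  # differing apps across the boundary add one under the cross policy
  three <- rbind(onoff_session(2, app = c("A", "B"), t0 = t0),
                 onoff_session(2, app = c("C", "C"), t0 = t0 + 300))
  ss3 <- sessionize(three)
  expect_equal(count_app_switches(ss3, cross_session = FALSE), 1L)
  expect_equal(count_app_switches(ss3, cross_session = TRUE), 2L)
})

test_that("daily tabulation attributes sessions to their start day", {
  cmap <- tibble::tibble(app = c("tiktok", "maps"),
                         category = c("social", "tools"))
  ev <- sessionize(onoff_session(12, app = "tiktok", t0 = t0))
  d <- compute_daily_metrics(ev, cmap)
  expect_equal(d$n_screenshots, 12L)
  expect_equal(d$n_social_screenshots, 12L)
  expect_equal(d$n_sessions, 1L)
  expect_equal(d$total_duration, 60)
  expect_equal(d$n_unique_apps, 1L)
  expect_equal(d$n_app_switches, 0L)

  # session spanning midnight stays on its start day
  late <- as.POSIXct("2021-05-01 23:59:30", tz = "UTC")
  ev2 <- sessionize(onoff_session(24, app = "maps", t0 = late))
  d2 <- compute_daily_metrics(ev2, cmap)
  expect_equal(nrow(d2), 1)
  expect_equal(d2$date, as.Date("2021-05-01"))

  # hand-tabulated two-day stream: day 1 has two sessions, day 2 one
  ev3 <- rbind(
    onoff_session(3, app = c("tiktok", "maps", "maps"), t0 = t0),
    onoff_session(2, app = c("maps", "maps"), t0 = t0 + 3600),
    onoff_session(4, app = c("zoom", "tiktok", "tiktok", "zoom"),
                  t0 = t0 + 86400))
  d3 <- compute_daily_metrics(sessionize(ev3), cmap)
  expect_equal(d3$n_screenshots, c(5L, 4L))
  expect_equal(d3$n_social_screenshots, c(1L, 2L))
  expect_equal(d3$n_sessions, c(2L, 1L))
  expect_equal(d3$n_app_switches, c(1L, 2L))
  expect_equal(d3$n_unique_apps, c(2L, 2L))
  # screenshot conservation
  expect_equal(sum(d3$n_screenshots), sum(ev3$event_type == "screenshot"))
})

test_that("unmapped apps count as non-social", {
  ev <- sessionize(onoff_session(5, app = "mystery", t0 = t0))
  d <- compute_daily_metrics(ev, tibble::tibble(app = "tiktok",
                                                category = "social"))
  expect_equal(d$n_social_screenshots, 0L)
})

test_that("fortnight aggregation divides by active days and links units", {
  survey_t <- as.POSIXct("2021-05-14 20:00:00", tz = "UTC")
  # 7 active days, 2 sessions x 6 shots each, one social app of the two
  plan_days <- lapply(0:6, function(d) {
    rbind(onoff_session(6, app = "tiktok", t0 = t0 + d * 86400),
          onoff_session(6, app = "maps", t0 = t0 + d * 86400 + 3600))
  })
  ev <- sessionize(do.call(rbind, plan_days))
  daily <- compute_daily_metrics(
    ev, tibble::tibble(app = "tiktok", category = "social"))
  fn <- aggregate_fortnight(daily, survey_t)
  expect_equal(fn$active_days, 7L)
  expect_equal(fn$screen_time, 12)
  expect_equal(fn$social_screen_time, 6)
  expect_equal(fn$n_sessions, 2)
  expect_equal(fn$session_duration, 30)
  expect_equal(fn$n_unique_apps, 2 / 7)
  expect_equal(fn$n_app_switches, 0)
  expect_false(fn$missing)
  # count-to-hours link is exact
  expect_equal(fn$screen_time_hours, 12 * 5 / 3600)
  # internal consistency: sessions/day x mean duration == screen-on s/day
  expect_equal(fn$n_sessions * fn$session_duration,
               sum(daily$total_duration) / fn$active_days)
})

test_that("single-day and empty windows behave as stated", {
  cmap <- NULL
  day <- compute_daily_metrics(sessionize(onoff_session(10, t0 = t0)), cmap)
  one <- aggregate_fortnight(day, as.POSIXct("2021-05-02", tz = "UTC"))
  expect_equal(one$screen_time, 10)
  expect_equal(one$active_days, 1L)
  none <- aggregate_fortnight(day, as.POSIXct("2021-09-01", tz = "UTC"))
  expect_true(none$missing)
  expect_true(is.na(none$screen_time))
  expect_error(
    aggregate_fortnight(day, as.POSIXct(c("2021-05-02", "2021-05-01"),
                                        tz = "UTC")),
    "strictly increasing")
  expect_message(
    aggregate_fortnight(day, as.POSIXct(c("2021-05-02", "2021-05-04"),
                                        tz = "UTC")),
    "overlap")
})

test_that("adding a social session raises social time, never lowers total", {
  cmap <- tibble::tibble(app = "tiktok", category = "social")
  base <- do.call(rbind, lapply(0:2, function(d)
    onoff_session(8, app = "maps", t0 = t0 + d * 86400)))
  with_social <- rbind(base[1:30, ],
                       onoff_session(6, app = "tiktok", t0 = t0 + 3 * 86400))
  survey_t <- as.POSIXct("2021-05-10", tz = "UTC")
  f0 <- aggregate_fortnight(compute_daily_metrics(sessionize(base), cmap),
                            survey_t)
  f1 <- aggregate_fortnight(
    compute_daily_metrics(sessionize(with_social), cmap), survey_t)
  expect_gt(f1$social_screen_time, f0$social_screen_time)
  expect_gte(f1$screen_time * f1$active_days, f0$screen_time * f0$active_days)
  expect_gte(f1$screen_time, f1$social_screen_time)
})
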