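#' Specification for a synthetic screenome person
#'
#' Parameters of the single-factor-per-block model used to generate one
#' synthetic participant. Each fortnightly occasion `t` draws a latent pair
#' `(f_t, g_t)` from a standard bivariate normal with correlation
#' `latent_correlation`; the media-use block is
#' `x_tj = x_loadings[j] * f_t + e_txj` and the mental-health block
#' `y_tk = y_loadings[k] * g_t + e_tyk`, with independent Gaussian noise of
#' the given SDs. The population first canonical correlation of this model
#' is available in closed form from [compute_population_rho()], which is
#' what makes the generator a calibration oracle for the whole pipeline.
#'
#' `n_occasions` must exceed 11 so that the larger (6-variable) block
#' leaves enough occasions for a full-rank analysis; the study design this
#' emulates required at least 20 fortnightly surveys per person.
#'
#' @param n_occasions number of fortnights (default 27, about one year).
#' @param latent_correlation correlation of the latent pair, in \[-1, 1\].
#' @param x_loadings numeric vector of 6 loadings for the media-use block.
#' @param y_loadings numeric vector of 5 loadings for the mental-health block.
#' @param x_noise_sd,y_noise_sd positive noise SDs, one per column.
#' @param metric_baselines per-variable natural-scale means/SDs used by the
#'   natural-scale mapping; see [default_metric_baselines()].
#' @param seed integer seed or `NULL`.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_occasions = 27,
                           latent_correlation = 0.9,
                           x_loadings = rep(1, 6),
                           y_loadings = rep(1, 5),
                           x_noise_sd = rep(1, 6),
                           y_noise_sd = rep(1, 5),
                           metric_baselines = default_metric_baselines(),
                           seed = NULL) {
  if (!is_count(n_occasions) || n_occasions <= 11)
    abort_input("n_occasions must exceed 11: the analysis needs more ",
                "occasions than the 6 + 5 variables it couples")
  if (abs(latent_correlation) > 1)
    abort_input("latent_correlation must lie in [-1, 1]")
  if (length(x_loadings) != 6 || length(y_loadings) != 5)
    abort_input("need 6 x_loadings and 5 y_loadings")
  if (length(x_noise_sd) != 6 || length(y_noise_sd) != 5 ||
      any(c(x_noise_sd, y_noise_sd) <= 0))
    abort_input("noise SDs must be positive, 6 for x and 5 for y")
  structure(list(
    n_occasions = as.integer(n_occasions),
    latent_correlation = latent_correlation,
    x_loadings = as.numeric(x_loadings),
    y_loadings = as.numeric(y_loadings),
    x_noise_sd = as.numeric(x_noise_sd),
    y_noise_sd = as.numeric(y_noise_sd),
    metric_baselines = metric_baselines,
    seed = seed
  ), class = "synthetic_spec")
}

#' Default natural-scale baselines for the eleven variables
#'
#' Daily means and SDs on each variable's natural scale, used when mapping
#' latent-model output onto realistic magnitudes: roughly three hours of
#' screen time a day captured at one screenshot per five seconds, around 25
#' minutes of it social, some sixty short sessions, four distinct apps and
#' two hundred app switches per day, and mid-range survey scores. These sit
#' in the middle of the range of published descriptives for heavy adult
#' smartphone users.
#'
#' @return tibble with `variable`, `mean`, `sd`, `lower`, `upper`.
#' @export
default_metric_baselines <- function() {
  tibble::tibble(
    variable = c(ax_variables(), ay_variables()),
    mean = c(2160, 300, 58, 190, 4.1, 210, 12, 46, 7, 5, 55),
    sd   = c(600, 120, 8, 30, 0.5, 33, 5, 8, 3, 2, 15),
    lower = c(rep(0, 6), 0, 20, 0, 0, 0),
    upper = c(rep(Inf, 6), 30, 80, 36, 36, 100)
  )
}

#' Population first canonical correlation of a synthetic spec
#'
#' Closed form for the factor model of [synthetic_spec()]. With
#' `c = sum(loadings^2 / noise_sd^2)` per block, the population first
#' canonical correlation is
#' `|latent_correlation| * sqrt(c_x / (1 + c_x)) * sqrt(c_y / (1 + c_y))`
#' (Sherman–Morrison applied to the rank-one-plus-diagonal block
#' covariances). All remaining population canonical correlations are zero.
#' A block with all-zero loadings gives 0.
#'
#' @param spec a `synthetic_spec`.
#' @return population canonical correlation in \[0, 1\].
#' @examples
#' compute_population_rho(synthetic_spec(latent_correlation = 0.9))
#' @export
compute_population_rho <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  cx <- sum(spec$x_loadings^2 / spec$x_noise_sd^2)
  cy <- sum(spec$y_loadings^2 / spec$y_noise_sd^2)
  abs(spec$latent_correlation) * sqrt(cx / (1 + cx)) * sqrt(cy / (1 + cy))
}

#' Spec with a requested population canonical correlation
#'
#' Rescales `latent_correlation` of a base spec so that
#' [compute_population_rho()] equals `target` exactly, keeping loadings and
#' noise fixed. Errors if the target exceeds the attenuation ceiling
#' implied by the loadings and noise.
#'
#' @param target desired population first canonical correlation in \[0, 1\].
#' @param spec base `synthetic_spec` whose loadings/noise set the ceiling.
#' @return a `synthetic_spec` with adjusted `latent_correlation`.
#' @export
spec_with_target_rho <- function(target, spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"), target >= 0, target <= 1)
  ceiling_rho <- {
    s <- spec; s$latent_correlation <- 1
    compute_population_rho(s)
  }
  if (target > ceiling_rho)
    abort_input("target ", target, " exceeds the attenuation ceiling ",
                signif(ceiling_rho, 4), " of this loading/noise pattern")
  spec$latent_correlation <- if (ceiling_rho == 0) 0 else target / ceiling_rho
  spec
}

#' Generate one person's occasion matrices from a synthetic spec
#'
#' Draws the fortnightly latent series and renders the two blocks of the
#' factor model. With `natural_scale = TRUE` each column is affinely mapped
#' onto its natural-scale baseline (mean/SD from
#' `spec$metric_baselines`) and clipped to the variable's attainable range;
#' clipped cells are counted and reported because clipping perturbs the
#' planted canonical correlation (the affine map alone does not — canonical
#' correlations are invariant to it).
#'
#' @param spec a `synthetic_spec`.
#' @param natural_scale map onto natural scales and clip (default `FALSE`:
#'   raw latent-model scales, the form used by analytic oracle checks).
#' @return list of class `occasion_sim`: `A_x` (n x 6), `A_y` (n x 5) with
#'   the fixed variable names, `timestamps` (fortnightly POSIXct),
#'   `f`, `g` (latent series), `n_clipped`.
#' @export
generate_occasion_matrices <- function(spec, natural_scale = FALSE) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_occasions
  rho <- spec$latent_correlation
  out <- with_seed(spec$seed, {
    f <- stats::rnorm(n)
    g <- rho * f + sqrt(1 - rho^2) * stats::rnorm(n)
    A_x <- vapply(1:6, function(j)
      spec$x_loadings[j] * f + stats::rnorm(n, 0, spec$x_noise_sd[j]),
      numeric(n))
    A_y <- vapply(1:5, function(k)
      spec$y_loadings[k] * g + stats::rnorm(n, 0, spec$y_noise_sd[k]),
      numeric(n))
    list(f = f, g = g, A_x = A_x, A_y = A_y)
  })
  colnames(out$A_x) <- ax_variables()
  colnames(out$A_y) <- ay_variables()
  n_clipped <- 0L
  if (natural_scale) {
    bl <- spec$metric_baselines
    map_block <- function(A, loadings, noise_sd) {
      for (j in seq_len(ncol(A))) {
        b <- bl[bl$variable == colnames(A)[j], ]
        model_sd <- sqrt(loadings[j]^2 + noise_sd[j]^2)
        v <- b$mean + b$sd * A[, j] / model_sd
        clipped <- v < b$lower | v > b$upper
        n_clipped <<- n_clipped + sum(clipped)
        A[, j] <- pmin(pmax(v, b$lower), b$upper)
      }
      A
    }
    out$A_x <- map_block(out$A_x, spec$x_loadings, spec$x_noise_sd)
    out$A_y <- map_block(out$A_y, spec$y_loadings, spec$y_noise_sd)
    if (n_clipped > 0)
      message(n_clipped, " cell(s) clipped to natural-scale bounds; ",
              "the planted canonical correlation is perturbed accordingly")
  }
  structure(list(
    A_x = out$A_x, A_y = out$A_y,
    timestamps = as.POSIXct("2020-07-01 12:00:00", tz = "UTC") +
      86400 * 14 * (seq_len(n) - 1),
    f = out$f, g = out$g, n_clipped = n_clipped
  ), class = "occasion_sim")
}

# ---- event-level generation ------------------------------------------------

#' Construct a person plan
#'
#' A person plan is the event-level blueprint for a synthetic participant:
#' one row per planned session, with the calendar placement of the session
#' and the per-screenshot foreground-app labels. Rendering a plan with
#' [render_event_stream()] and running the metrics pipeline on the result
#' recovers the plan's session counts, durations, switches, and app counts
#' exactly — the round-trip that anchors the metric tests.
#'
#' @param day integer day index per session (1-based).
#' @param start POSIXct session start per session.
#' @param apps list of non-empty character vectors; element `i` gives the
#'   foreground app of each successive screenshot of session `i`, so the
#'   session's duration is `length(apps[[i]]) * cadence` seconds.
#' @return tibble of class `person_plan`.
#' @export
person_plan <- function(day, start, apps) {
  if (any(vapply(apps, length, integer(1)) < 1))
    abort_input("every planned session needs at least one screenshot")
  out <- tibble::tibble(day = as.integer(day), start = as.POSIXct(start, tz = "UTC"),
                        apps = apps)
  out <- out[order(out$day, out$start), ]
  class(out) <- c("person_plan", class(out))
  out
}

#' Random person plan for property tests
#'
#' Draws a valid, non-overlapping plan: for each of `n_days` days, between
#' `sessions_per_day[1]` and `sessions_per_day[2]` sessions of between
#' `shots_per_session[1]` and `shots_per_session[2]` screenshots, apps drawn
#' from `app_pool`, sessions separated by at least `gap` seconds.
#'
#' @param n_days number of days (day 1 starts at `origin`).
#' @param sessions_per_day,shots_per_session integer ranges.
#' @param app_pool candidate app identifiers.
#' @param cadence screenshot interval, seconds.
#' @param gap minimum seconds between a session's end and the next start.
#' @param origin POSIXct date-time of day 1, 00:00.
#' @param seed integer seed or `NULL`.
#' @return a `person_plan`.
#' @export
random_person_plan <- function(n_days = 3,
                               sessions_per_day = c(1, 5),
                               shots_per_session = c(1, 40),
                               app_pool = sprintf("app_%02d", 1:6),
                               cadence = 5, gap = 60,
                               origin = as.POSIXct("2021-03-01 00:00:00",
                                                   tz = "UTC"),
                               seed = NULL) {
  with_seed(seed, {
    day <- integer(); start <- as.POSIXct(character(), tz = "UTC")
    apps <- list()
    for (d in seq_len(n_days)) {
      ns <- sample(sessions_per_day[1]:sessions_per_day[2], 1)
      t <- origin + (d - 1) * 86400 + 6 * 3600
      for (s in seq_len(ns)) {
        k <- sample(shots_per_session[1]:shots_per_session[2], 1)
        day <- c(day, d); start <- c(start, t)
        apps <- c(apps, list(sample(app_pool, k, replace = TRUE)))
        t <- t + k * cadence + gap + sample(0:600, 1)
      }
    }
    person_plan(day, start, apps)
  })
}

#' Expected per-day metrics implied by a plan
#'
#' Tabulates, directly from the plan and independently of any event
#' rendering or parsing, what the daily media-use record must be:
#' screenshot and session counts, total screen-on seconds
#' (`screenshots x cadence`), within-session app switches, and distinct
#' apps.
#'
#' @param plan a `person_plan`.
#' @param cadence screenshot interval, seconds.
#' @return tibble with one row per planned day.
#' @export
plan_daily_summary <- function(plan, cadence = 5) {
  stopifnot(inherits(plan, "person_plan"))
  days <- sort(unique(plan$day))
  rows <- lapply(days, function(d) {
    p <- plan[plan$day == d, ]
    switches <- sum(vapply(p$apps, function(a)
      if (length(a) < 2) 0L else sum(a[-1] != a[-length(a)]), integer(1)))
    tibble::tibble(
      day = d,
      date = as.Date(p$start[1], tz = "UTC"),
      n_sessions = nrow(p),
      n_screenshots = sum(lengths(p$apps)),
      total_duration = cadence * sum(lengths(p$apps)),
      n_app_switches = switches,
      apps = list(sort(unique(unlist(p$apps)))),
      n_unique_apps = length(unique(unlist(p$apps)))
    )
  })
  do.call(rbind, rows)
}

#' Render a person plan as a raw screenshot-metadata event stream
#'
#' Emits, per planned session, a `screen_on` event at the session start,
#' one `screenshot` event per planned app label at the capture cadence
#' (the first at the session start), and a `screen_off` event at
#' `start + n_screenshots * cadence` — so a 12-screenshot session at the
#' default 5-second cadence spans exactly 60 seconds. Sessions within a day
#' must not overlap.
#'
#' @param plan a `person_plan`.
#' @param cadence screenshot interval, seconds (default 5).
#' @return tibble of events: `timestamp`, `event_type`, `app`, ordered in
#'   time.
#' @export
render_event_stream <- function(plan, cadence = 5) {
  stopifnot(inherits(plan, "person_plan"))
  if (nrow(plan) == 0) {
    return(tibble::tibble(timestamp = as.POSIXct(character(), tz = "UTC"),
                          event_type = character(), app = character()))
  }
  nshots <- lengths(plan$apps)
  ends <- plan$start + cadence * nshots
  later_start <- c(plan$start[-1], as.POSIXct(Inf, tz = "UTC"))
  if (any(ends > later_start))
    abort_input("overlapping planned sessions: a session ends after the ",
                "next one starts")
  # vectorized emission: per session, offsets 0 (on), 0..(n-1)*cadence
  # (screenshots, first coincides with the on event), n*cadence (off)
  offsets <- unlist(lapply(nshots, function(n)
    cadence * c(0, seq_len(n) - 1, n)), use.names = FALSE)
  base <- rep(plan$start, nshots + 2)
  event_type <- unlist(lapply(nshots, function(n)
    c("screen_on", rep("screenshot", n), "screen_off")), use.names = FALSE)
  app <- unlist(lapply(plan$apps, function(a)
    c(NA_character_, a, NA_character_)), use.names = FALSE)
  tibble::tibble(timestamp = base + offsets, event_type = event_type,
                 app = app)
}

# ---- survey item generation ------------------------------------------------

# distribute (total - k*lo) unit increments at random over k items in [lo, hi]
allocate_total <- function(total, k, lo, hi, scale) {
  if (is.na(total) || total < k * lo || total > k * hi ||
      total != trunc(total))
    abort_input(scale, " target total ", total, " unattainable; range is [",
                k * lo, ", ", k * hi, "]")
  eff <- rep(lo, k)
  rem <- total - k * lo
  while (rem > 0) {
    open <- which(eff < hi)
    i <- if (length(open) == 1) open else sample(open, 1)
    eff[i] <- eff[i] + 1
    rem <- rem - 1
  }
  eff
}

#' Generate item-level survey responses scoring to given totals
#'
#' Produces one fortnight's item responses that, when scored through the
#' survey-scoring module with the same keys, reproduce the target totals
#' exactly — including reverse-keyed items, which are emitted on the raw
#' (un-reversed) scale. Unattainable targets are refused with the
#' attainable range.
#'
#' @param cesd_total target CES-D-10 total (0–30 under the default key).
#' @param stai_total target STAI-state total (20–80).
#' @param inattention_total,hyperactivity_total target ASRS subscale totals
#'   (0–36 each).
#' @param positive_affect affect slider value (0–100).
#' @param cesd_key,stai_key,asrs_map scoring configuration (must match what
#'   the scorer will use).
#' @param seed integer seed or `NULL`.
#' @return one-row tibble with columns `cesd_01`..`cesd_10`,
#'   `stai_01`..`stai_20`, `asrs_01`..`asrs_18`, `positive_affect`.
#' @export
generate_survey_items <- function(cesd_total, stai_total,
                                  inattention_total, hyperactivity_total,
                                  positive_affect,
                                  cesd_key = cesd_reverse_key(),
                                  stai_key = stai_reverse_key(),
                                  asrs_map = asrs_subscale_map(),
                                  seed = NULL) {
  if (is.na(positive_affect) || positive_affect < 0 || positive_affect > 100)
    abort_input("positive affect target unattainable; range is [0, 100]")
  with_seed(seed, {
    cesd <- allocate_total(cesd_total, 10, 0, 3, "CES-D")
    cesd[cesd_key] <- 3 - cesd[cesd_key]        # undo reverse-coding
    stai <- allocate_total(stai_total, 20, 1, 4, "STAI-state")
    stai[stai_key] <- 5 - stai[stai_key]
    asrs <- integer(18)
    asrs[asrs_map$inattention] <-
      allocate_total(inattention_total, 9, 0, 4, "ASRS inattention")
    asrs[asrs_map$hyperactivity] <-
      allocate_total(hyperactivity_total, 9, 0, 4, "ASRS hyperactivity")
    out <- c(stats::setNames(cesd, sprintf("cesd_%02d", 1:10)),
             stats::setNames(stai, sprintf("stai_%02d", 1:20)),
             stats::setNames(asrs, sprintf("asrs_%02d", 1:18)),
             positive_affect = positive_affect)
    tibble::as_tibble(as.list(out))
  })
}

#' Generate a fortnightly survey series from per-occasion totals
#'
#' @param totals tibble with `timestamp` and the five score columns
#'   (`depression`, `state_anxiety`, `inattention`, `hyperactivity`,
#'   `positive_affect`), one row per occasion.
#' @inheritParams generate_survey_items
#' @return item-level tibble, one row per occasion, in the survey CSV
#'   layout expected by [score_surveys()].
#' @export
generate_survey_series <- function(totals,
                                   cesd_key = cesd_reverse_key(),
                                   stai_key = stai_reverse_key(),
                                   asrs_map = asrs_subscale_map(),
                                   seed = NULL) {
  seeds <- derive_seeds(seed %||% sample.int(.Machine$integer.max - 1L, 1),
                        nrow(totals))
  rows <- lapply(seq_len(nrow(totals)), function(i) {
    r <- totals[i, ]
    items <- generate_survey_items(
      r$depression, r$state_anxiety, r$inattention, r$hyperactivity,
      r$positive_affect,
      cesd_key = cesd_key, stai_key = stai_key, asrs_map = asrs_map,
      seed = seeds[i])
    cbind(tibble::tibble(timestamp = format_instant(parse_instant(r$timestamp))),
          items)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

# ---- full-person event simulation -----------------------------------------

# integer day plan achieving exact shot/session/switch/unique-app counts;
# social shots exact when the block structure permits, else best effort
plan_day_sessions <- function(N, S, W, U, Ns, day, day_start,
                              cadence = 5, gap = 120,
                              social_app = "social_01") {
  S <- max(1L, min(S, N))
  U <- max(1L, min(U, N))
  W <- max(0L, min(W, N - S))
  if (U > W + S) U <- W + S                 # need >= U blocks to show U apps
  B <- W + S
  pool <- if (Ns > 0) c(social_app, sprintf("app_%02d", seq_len(max(U - 1, 0))))
          else sprintf("app_%02d", seq_len(U))
  if (length(pool) == 0) pool <- social_app
  # blocks per session: spread B blocks over S sessions, each >= 1
  bps <- rep(B %/% S, S); if (B %% S) bps[seq_len(B %% S)] <- bps[seq_len(B %% S)] + 1
  block_apps <- rep(pool, length.out = B)
  # block sizes: start at 1, steer extras toward the social target
  sizes <- rep(1L, B)
  rem <- N - B
  soc <- which(block_apps == social_app)
  if (Ns > 0 && length(soc) > 0) {
    soc_extra <- min(max(Ns - length(soc), 0), rem)
    i <- 1
    while (soc_extra > 0) {
      sizes[soc[i]] <- sizes[soc[i]] + 1L
      soc_extra <- soc_extra - 1; rem <- rem - 1
      i <- i %% length(soc) + 1
    }
  }
  nonsoc <- if (length(soc)) setdiff(seq_len(B), soc) else seq_len(B)
  if (length(nonsoc) == 0) nonsoc <- seq_len(B)
  i <- 1
  while (rem > 0) {
    sizes[nonsoc[i]] <- sizes[nonsoc[i]] + 1L
    rem <- rem - 1
    i <- i %% length(nonsoc) + 1
  }
  # assemble sessions
  day_v <- integer(); start_v <- as.POSIXct(character(), tz = "UTC")
  apps_v <- list()
  b0 <- 0L; t <- day_start
  for (s in seq_len(S)) {
    idx <- b0 + seq_len(bps[s]); b0 <- b0 + bps[s]
    seqapps <- unlist(mapply(function(a, k) rep(a, k), block_apps[idx],
                             sizes[idx], SIMPLIFY = FALSE), use.names = FALSE)
    day_v <- c(day_v, day); start_v <- c(start_v, t)
    apps_v <- c(apps_v, list(seqapps))
    t <- t + length(seqapps) * cadence + gap
  }
  list(day = day_v, start = start_v, apps = apps_v)
}

#' Simulate a complete synthetic participant on disk
#'
#' End-to-end generator: draws natural-scale occasion matrices from `spec`,
#' renders a raw event stream whose fortnightly metrics match the
#' (integer-rounded) media-use block, emits item-level surveys that score
#' exactly to the (rounded) mental-health block, and writes everything in
#' the pipeline's input formats: `events.jsonl`, `surveys.csv`,
#' `category_map.csv`, plus `truth.json` holding the spec, the planted
#' population canonical correlation, and the pre-rounding matrices.
#'
#' @param spec a `synthetic_spec`.
#' @param out_dir output directory (created if needed).
#' @param seed integer seed; defaults to `spec$seed`.
#' @param cadence screenshot interval, seconds.
#' @param active_days_per_fortnight days with phone use per occasion window
#'   (default 14: every day active).
#' @return invisibly, a list with the file paths and the truth values.
#' @export
simulate_person <- function(spec, out_dir, seed = spec$seed, cadence = 5,
                            active_days_per_fortnight = 14) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec$seed <- seed
  occ <- generate_occasion_matrices(spec, natural_scale = TRUE)
  seeds <- derive_seeds(seed %||% 1L, spec$n_occasions + 1L)

  # surveys: round mental-health block to attainable integer totals
  bl <- spec$metric_baselines
  clipr <- function(v, nm) {
    b <- bl[bl$variable == nm, ]
    pmin(pmax(round(v), b$lower), min(b$upper, 1e9))
  }
  totals <- tibble::tibble(
    timestamp = occ$timestamps,
    depression = clipr(occ$A_y[, "depression"], "depression"),
    state_anxiety = clipr(occ$A_y[, "state_anxiety"], "state_anxiety"),
    inattention = clipr(occ$A_y[, "inattention"], "inattention"),
    hyperactivity = clipr(occ$A_y[, "hyperactivity"], "hyperactivity"),
    positive_affect = pmin(pmax(occ$A_y[, "positive_affect"], 0), 100)
  )
  surveys <- generate_survey_series(totals, seed = seeds[1])

  # events: one 14-day plan per occasion from the media-use block
  day_list <- list(); start_list <- list(); apps_list <- list()
  for (k in seq_len(spec$n_occasions)) {
    r <- occ$A_x[k, ]
    N <- max(1L, as.integer(round(r["screen_time"])))
    Ns <- max(0L, min(N, as.integer(round(r["social_screen_time"]))))
    S <- max(1L, as.integer(round(r["n_sessions"])))
    U <- max(1L, as.integer(round(r["n_unique_apps"])))
    W <- max(0L, as.integer(round(r["n_app_switches"])))
    occ_end <- as.Date(occ$timestamps[k], tz = "UTC")
    days <- with_seed(seeds[k + 1],
                      sort(sample(0:13, active_days_per_fortnight)))
    for (d in days) {
      date <- occ_end - 13 + d
      day_start <- as.POSIXct(paste(date, "08:00:00"), tz = "UTC")
      pd <- plan_day_sessions(N, S, W, U, Ns,
                              day = as.integer(date - as.Date("2020-01-01")),
                              day_start = day_start, cadence = cadence)
      day_list <- c(day_list, list(pd$day))
      start_list <- c(start_list, list(pd$start))
      apps_list <- c(apps_list, pd$apps)
    }
  }
  plan <- person_plan(unlist(day_list), do.call(c, start_list), apps_list)
  events <- render_event_stream(plan, cadence = cadence)

  apps_used <- sort(unique(unlist(plan$apps)))
  category_map <- tibble::tibble(
    app = apps_used,
    category = ifelse(grepl("^social_", apps_used), "social", "other"))

  paths <- list(
    events = file.path(out_dir, "events.jsonl"),
    surveys = file.path(out_dir, "surveys.csv"),
    category_map = file.path(out_dir, "category_map.csv"),
    truth = file.path(out_dir, "truth.json"))
  write_events_jsonl(events, paths$events)
  utils::write.csv(surveys, paths$surveys, row.names = FALSE)
  utils::write.csv(category_map, paths$category_map, row.names = FALSE)
  truth <- list(
    population_rho = compute_population_rho(spec),
    n_occasions = spec$n_occasions,
    latent_correlation = spec$latent_correlation,
    A_x = as.list(as.data.frame(occ$A_x)),
    A_y = as.list(as.data.frame(occ$A_y)),
    timestamps = format_instant(occ$timestamps))
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(paths = paths, truth = truth, spec = spec))
}
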