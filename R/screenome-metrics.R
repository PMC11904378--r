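#' Sessionize a screenshot-metadata event stream
#'
#' Groups a time-ordered stream of device events (`screen_on`, `screenshot`,
#' `screen_off`) into screen-on sessions. When explicit on/off events are
#' present, sessions are the on-to-off intervals that contain at least one
#' screenshot. Malformed streams are repaired rather than rejected: a
#' screenshot outside any session opens an implicit session, a nested
#' `screen_on` closes the current session and opens a new one, and a
#' dangling `screen_off` is dropped; the number of repairs is recorded and
#' reported with a warning. When the stream carries no on/off events at
#' all, sessions are maximal runs of screenshots whose inter-screenshot gap
#' does not exceed `gap_threshold` seconds, with session start/end at the
#' first/last screenshot of the run.
#'
#' @param events data frame with columns `timestamp` (POSIXct or ISO-8601
#'   string), `event_type` (one of `screen_on`, `screenshot`, `screen_off`),
#'   `app` (required for screenshots), optional `category`.
#' @param gap_threshold seconds; maximum gap between screenshots of one
#'   session when no on/off events exist (default 30, i.e. six missed
#'   5-second captures).
#' @return an object of class `screen_sessions`: list with `sessions`
#'   (tibble: `session`, `start`, `end`, `duration` seconds), `shots`
#'   (tibble: `session`, `timestamp`, `app`, `category`), and `repairs`
#'   (count of stream repairs applied).
#' @examples
#' ev <- tibble::tibble(
#'   timestamp = as.POSIXct("2021-01-01 09:00:00", tz = "UTC") + c(0, 0, 5, 10),
#'   event_type = c("screen_on", "screenshot", "screenshot", "screen_off"),
#'   app = c(NA, "maps", "maps", NA)
#' )
#' sessionize(ev)
#' @export
sessionize <- function(events, gap_threshold = 30) {
  if (nrow(events) == 0) {
    return(new_screen_sessions(empty_sessions(), empty_shots(), 0L))
  }
  events$timestamp <- parse_instant(events$timestamp)
  if (is.unsorted(events$timestamp)) {
    abort_input("event timestamps must be non-decreasing")
  }
  if (!"category" %in% names(events)) events$category <- NA_character_
  is_shot <- events$event_type == "screenshot"
  if (any(is_shot & (is.na(events$app) | events$app == ""))) {
    abort_input("screenshot events must carry an app identifier")
  }
  has_onoff <- any(events$event_type %in% c("screen_on", "screen_off"))
  if (has_onoff) sessionize_onoff(events) else {
    sessionize_gaps(events[is_shot, , drop = FALSE], gap_threshold)
  }
}

empty_sessions <- function() {
  tibble::tibble(session = integer(), start = as.POSIXct(character(), tz = "UTC"),
                 end = as.POSIXct(character(), tz = "UTC"), duration = numeric())
}
empty_shots <- function() {
  tibble::tibble(session = integer(), timestamp = as.POSIXct(character(), tz = "UTC"),
                 app = character(), category = character())
}

new_screen_sessions <- function(sessions, shots, repairs) {
  structure(list(sessions = sessions, shots = shots, repairs = repairs),
            class = "screen_sessions")
}

sessionize_onoff <- function(events) {
  ty <- events$event_type
  # fast path for well-formed streams: on/off strictly alternate, every
  # screenshot inside an on..off interval, stream closed at the end
  depth <- cumsum((ty == "screen_on") - (ty == "screen_off"))
  if (all(depth >= 0L & depth <= 1L) &&
      all(depth[ty == "screenshot"] == 1L) &&
      depth[length(depth)] == 0L) {
    sid_all <- cumsum(ty == "screen_on")
    starts <- events$timestamp[ty == "screen_on"]
    ends <- events$timestamp[ty == "screen_off"]
    shot_i <- which(ty == "screenshot")
    sid <- sid_all[shot_i]
    counts <- tabulate(sid, nbins = length(starts))
    keep <- which(counts > 0)               # sessions need >= 1 screenshot
    renum <- match(sid, keep)
    sessions <- tibble::tibble(
      session = seq_along(keep), start = starts[keep], end = ends[keep],
      duration = as.numeric(ends[keep]) - as.numeric(starts[keep]))
    shots <- tibble::tibble(
      session = renum, timestamp = events$timestamp[shot_i],
      app = events$app[shot_i], category = events$category[shot_i])
    return(new_screen_sessions(sessions, shots, 0L))
  }
  sessionize_onoff_repair(events)
}

# event-by-event walk applying stream repairs; only reached for malformed
# streams, which are small in practice
sessionize_onoff_repair <- function(events) {
  n <- nrow(events)
  repairs <- 0L
  open_at <- NULL
  cur_shots <- list()
  sess_start <- list(); sess_end <- list(); sess_shots <- list()

  close_session <- function(end_time) {
    if (length(cur_shots) > 0) {
      sess_start[[length(sess_start) + 1]] <<- open_at
      sess_end[[length(sess_end) + 1]] <<- end_time
      sess_shots[[length(sess_shots) + 1]] <<- do.call(rbind, cur_shots)
    }
    open_at <<- NULL
    cur_shots <<- list()
  }

  for (i in seq_len(n)) {
    ty <- events$event_type[i]
    tm <- events$timestamp[i]
    if (ty == "screen_on") {
      if (!is.null(open_at)) {           # nested on: close implicitly
        repairs <- repairs + 1L
        close_session(tm)
      }
      open_at <- tm
    } else if (ty == "screen_off") {
      if (is.null(open_at)) {            # off before on: drop
        repairs <- repairs + 1L
      } else {
        close_session(tm)
      }
    } else if (ty == "screenshot") {
      if (is.null(open_at)) {            # orphan shot: open implicitly
        repairs <- repairs + 1L
        open_at <- tm
      }
      cur_shots[[length(cur_shots) + 1]] <- data.frame(
        timestamp = tm, app = events$app[i], category = events$category[i],
        stringsAsFactors = FALSE)
    } else {
      abort_input("unknown event_type: ", ty)
    }
  }
  if (!is.null(open_at)) {               # dangling open at end of stream
    repairs <- repairs + 1L
    close_session(events$timestamp[n])
  }
  if (repairs > 0) warning(repairs, " stream repair(s) applied during sessionization")

  assemble_sessions(sess_start, sess_end, sess_shots, repairs)
}

sessionize_gaps <- function(shots, gap_threshold) {
  if (nrow(shots) == 0) {
    return(new_screen_sessions(empty_sessions(), empty_shots(), 0L))
  }
  gaps <- diff(as.numeric(shots$timestamp))
  grp <- cumsum(c(0, gaps > gap_threshold)) + 1L
  sess_start <- sess_end <- sess_shots <- list()
  for (g in unique(grp)) {
    s <- shots[grp == g, , drop = FALSE]
    sess_start[[g]] <- s$timestamp[1]
    sess_end[[g]] <- s$timestamp[nrow(s)]
    sess_shots[[g]] <- data.frame(timestamp = s$timestamp, app = s$app,
                                  category = s$category,
                                  stringsAsFactors = FALSE)
  }
  assemble_sessions(sess_start, sess_end, sess_shots, 0L)
}

assemble_sessions <- function(sess_start, sess_end, sess_shots, repairs) {
  k <- length(sess_start)
  if (k == 0) return(new_screen_sessions(empty_sessions(), empty_shots(), repairs))
  starts <- do.call(c, sess_start)
  ends <- do.call(c, sess_end)
  sessions <- tibble::tibble(
    session = seq_len(k), start = starts, end = ends,
    duration = as.numeric(ends) - as.numeric(starts))
  shots <- do.call(rbind, lapply(seq_len(k), function(i) {
    cbind(session = i, sess_shots[[i]])
  }))
  shots <- tibble::as_tibble(shots)
  new_screen_sessions(sessions, shots, repairs)
}

#' @export
print.screen_sessions <- function(x, ...) {
  cat(sprintf("screen sessions: %d sessions, %d screenshots, %d repair(s)\n",
              nrow(x$sessions), nrow(x$shots), x$repairs))
  invisible(x)
}

#' Count app switches across consecutive screenshots
#'
#' An app switch is a pair of consecutive screenshots whose foreground app
#' identifiers differ (e.g. a screenshot of Facebook followed by one of
#' Zoom is one switch). By default only pairs within the same session are
#' counted; with `cross_session = TRUE` the transition from the last
#' screenshot of one session to the first of the next also counts when the
#' apps differ.
#'
#' @param x a `screen_sessions` object from [sessionize()].
#' @param cross_session also count transitions across session boundaries
#'   (default `FALSE`).
#' @return integer switch count.
#' @export
count_app_switches <- function(x, cross_session = FALSE) {
  stopifnot(inherits(x, "screen_sessions"))
  shots <- x$shots
  if (nrow(shots) < 2) return(0L)
  same_pair <- shots$app[-1] != shots$app[-nrow(shots)]
  boundary <- shots$session[-1] != shots$session[-nrow(shots)]
  if (cross_session) sum(same_pair) else sum(same_pair & !boundary)
}

resolve_category <- function(shots, category_map) {
  if (!is.null(category_map)) {
    if (!all(c("app", "category") %in% names(category_map)))
      abort_input("category map needs columns app, category")
    idx <- match(shots$app, category_map$app)
    mapped <- category_map$category[idx]
    # map wins; fall back to the event's own label; unmapped -> non-social
    shots$category <- ifelse(!is.na(mapped), mapped, shots$category)
  }
  shots$category[is.na(shots$category)] <- "other"
  shots
}

#' Per-day media-use tabulation
#'
#' Collapses sessionized events to one record per local calendar day. A
#' session — and every screenshot in it — belongs to the day containing its
#' start, so sessions spanning midnight are attributed wholly to the start
#' day. A day is active iff it has at least one screenshot. Apps not
#' resolved to a category by `category_map` (columns `app`, `category`) are
#' treated as non-social.
#'
#' @param x a `screen_sessions` object.
#' @param category_map data frame mapping `app` to `category`; category
#'   `"social"` feeds the social-screen-time metric. `NULL` keeps any
#'   category labels already on the events.
#' @param tz timezone defining day boundaries (default `"UTC"`).
#' @param cross_session_switches count switches across session boundaries
#'   within a day (default `FALSE`).
#' @return tibble with one row per active day: `date`, `n_screenshots`,
#'   `n_social_screenshots`, `n_sessions`, `total_duration` (seconds),
#'   `apps` (list column of distinct app ids), `n_unique_apps`,
#'   `n_app_switches`.
#' @export
compute_daily_metrics <- function(x, category_map = NULL, tz = "UTC",
                                  cross_session_switches = FALSE) {
  stopifnot(inherits(x, "screen_sessions"))
  if (nrow(x$sessions) == 0) {
    return(tibble::tibble(date = as.Date(character()),
                          n_screenshots = integer(),
                          n_social_screenshots = integer(),
                          n_sessions = integer(), total_duration = numeric(),
                          apps = list(), n_unique_apps = integer(),
                          n_app_switches = integer()))
  }
  shots <- resolve_category(x$shots, category_map)
  sess <- x$sessions
  sess$date <- as.Date(sess$start, tz = tz)
  shots$date <- sess$date[match(shots$session, sess$session)]

  days <- sort(unique(sess$date))
  fday <- factor(shots$date, levels = as.character(days))
  sday <- factor(sess$date, levels = as.character(days))

  # consecutive-shot pairs; a pair belongs to the day of its session
  m <- nrow(shots)
  if (m >= 2) {
    differs <- shots$app[-1] != shots$app[-m]
    boundary <- shots$session[-1] != shots$session[-m]
    same_day <- shots$date[-1] == shots$date[-m]
    counts_pair <- if (cross_session_switches) differs & same_day
                   else differs & !boundary
    pair_day <- factor(shots$date[-1], levels = as.character(days))
    switches <- as.integer(tapply(counts_pair, pair_day, sum, default = 0L))
  } else {
    switches <- integer(length(days))
  }

  apps_by_day <- lapply(split(shots$app, fday), function(a) sort(unique(a)))
  tibble::tibble(
    date = days,
    n_screenshots = as.integer(tabulate(fday, nbins = length(days))),
    n_social_screenshots = as.integer(
      tapply(shots$category == "social", fday, sum, default = 0L)),
    n_sessions = as.integer(tabulate(sday, nbins = length(days))),
    total_duration = as.numeric(
      tapply(sess$duration, sday, sum, default = 0)),
    apps = unname(apps_by_day),
    n_unique_apps = lengths(apps_by_day, use.names = FALSE),
    n_app_switches = switches
  )
}

#' Media-use block variable names, in fixed order
#' @export
ax_variables <- function() {
  c("screen_time", "social_screen_time", "n_sessions", "session_duration",
    "n_unique_apps", "n_app_switches")
}

#' Aggregate daily media use into fortnightly occasions
#'
#' For each survey time `t`, aggregates the active days falling in the
#' half-open fortnight window `(t - window_days, t]` (by local calendar
#' date) into one occasion row of the media-use block:
#' \describe{
#'   \item{screen_time}{mean screenshots per active day (also exposed in
#'     hours/day as `screen_time_hours` = count x cadence / 3600);}
#'   \item{social_screen_time}{same for social-app screenshots;}
#'   \item{n_sessions}{mean sessions per active day;}
#'   \item{session_duration}{mean seconds per session over all sessions in
#'     the window;}
#'   \item{n_unique_apps}{distinct apps over the whole fortnight divided by
#'     active days;}
#'   \item{n_app_switches}{switch count divided by active days.}
#' }
#' An occasion with no active days is returned with all metrics `NA` and
#' its `missing` flag set; downstream analysis drops such rows listwise.
#' Surveys closer together than `window_days` produce overlapping windows;
#' this is allowed and logged.
#'
#' @param daily per-day records from [compute_daily_metrics()].
#' @param survey_times strictly increasing POSIXct (or ISO-8601 strings).
#' @param window_days length of the aggregation window (default 14).
#' @param cadence capture interval in seconds (default 5), used for the
#'   count-to-hours conversion.
#' @param tz timezone used to place survey times on calendar dates.
#' @return tibble with `timestamp`, the six metric columns in fixed order,
#'   `screen_time_hours`, `social_screen_time_hours`, `active_days`,
#'   `missing`.
#' @export
aggregate_fortnight <- function(daily, survey_times, window_days = 14,
                                cadence = 5, tz = "UTC") {
  survey_times <- parse_instant(survey_times)
  if (length(survey_times) > 1 && any(diff(as.numeric(survey_times)) <= 0))
    abort_input("survey times must be strictly increasing")
  if (length(survey_times) > 1 &&
      any(diff(as.numeric(survey_times)) < window_days * 86400))
    message("some survey intervals are shorter than ", window_days,
            " days; fortnight windows overlap")

  rows <- lapply(survey_times, function(t) {
    d_end <- as.Date(t, tz = tz)
    win <- daily[daily$date > d_end - window_days & daily$date <= d_end, ,
                 drop = FALSE]
    active <- nrow(win)
    if (active == 0) {
      return(tibble::tibble(
        timestamp = t, screen_time = NA_real_, social_screen_time = NA_real_,
        n_sessions = NA_real_, session_duration = NA_real_,
        n_unique_apps = NA_real_, n_app_switches = NA_real_,
        screen_time_hours = NA_real_, social_screen_time_hours = NA_real_,
        active_days = 0L, missing = TRUE))
    }
    shots_day <- sum(win$n_screenshots) / active
    social_day <- sum(win$n_social_screenshots) / active
    total_sessions <- sum(win$n_sessions)
    tibble::tibble(
      timestamp = t,
      screen_time = shots_day,
      social_screen_time = social_day,
      n_sessions = total_sessions / active,
      session_duration = if (total_sessions > 0)
        sum(win$total_duration) / total_sessions else 0,
      n_unique_apps = length(unique(unlist(win$apps))) / active,
      n_app_switches = sum(win$n_app_switches) / active,
      screen_time_hours = shots_day * cadence / 3600,
      social_screen_time_hours = social_day * cadence / 3600,
      active_days = active,
      missing = FALSE)
  })
  do.call(rbind, rows)
}

#' Extract the numeric media-use block from fortnightly metrics
#'
#' @param fortnights output of [aggregate_fortnight()].
#' @return occasions x 6 numeric matrix with the fixed column order.
#' @export
ax_block <- function(fortnights) {
  as.matrix(fortnights[ax_variables()])
}
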