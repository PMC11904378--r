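# Independent oracles used across the suite. These deliberately avoid the
# package's SVD code path: the CCA oracle maximizes the correlation of the
# two linear composites directly by multi-start numerical optimization.

oracle_rho1 <- function(A_x, A_y, n_starts = 12, seed = 1) {
  Zx <- scale(A_x)
  Zy <- scale(A_y)
  p <- ncol(Zx)
  q <- ncol(Zy)
  obj <- function(par) {
    zx <- Zx %*% par[1:p]
    zy <- Zy %*% par[p + 1:q]
    if (stats::sd(zx) < 1e-10 || stats::sd(zy) < 1e-10) return(0)
    -abs(stats::cor(zx, zy))
  }
  best <- 0
  set.seed(seed)
  for (s in seq_len(n_starts)) {
    o <- stats::optim(stats::rnorm(p + q), obj, method = "BFGS",
                      control = list(maxit = 1000,
                                     reltol = .Machine$double.eps^0.75))
    best <- max(best, -o$value)
  }
  best
}

# hand count of app switches in a per-screenshot app sequence
hand_switch_count <- function(apps_by_session, cross_session = FALSE) {
  within <- sum(vapply(apps_by_session, function(a)
    if (length(a) < 2) 0L else sum(a[-1] != a[-length(a)]), integer(1)))
  if (!cross_session || length(apps_by_session) < 2) return(within)
  lasts <- vapply(apps_by_session[-length(apps_by_session)],
                  function(a) a[length(a)], character(1))
  firsts <- vapply(apps_by_session[-1], function(a) a[1], character(1))
  within + sum(lasts != firsts)
}

# small event-stream builder: screenshots only, at given offsets (seconds)
shot_stream <- function(offsets, apps,
                        t0 = as.POSIXct("2021-05-01 10:00:00", tz = "UTC")) {
  tibble::tibble(timestamp = t0 + offsets, event_type = "screenshot",
                 app = apps)
}

# one well-formed on/off session: on at t0, n shots at the cadence, off
onoff_session <- function(n, app = "app_a", cadence = 5,
                          t0 = as.POSIXct("2021-05-01 10:00:00", tz = "UTC")) {
  if (length(app) == 1) app <- rep(app, n)
  tibble::tibble(
    timestamp = c(t0, t0 + cadence * (seq_len(n) - 1), t0 + cadence * n),
    event_type = c("screen_on", rep("screenshot", n), "screen_off"),
    app = c(NA, app, NA))
}

# survey item columns helpers
cesd_cols <- sprintf("cesd_%02d", 1:10)
stai_cols <- sprintf("stai_%02d", 1:20)
asrs_cols <- sprintf("asrs_%02d", 1:18)

# reduced-scale baselines for fast end-to-end tests: same shape as the
# realistic defaults, an order of magnitude fewer screenshots
small_baselines <- function() {
  bl <- default_metric_baselines()
  bl$mean <- c(400, 60, 10, 190, 4.1, 40, 12, 46, 7, 5, 55)
  bl$sd <- c(80, 20, 2, 30, 0.5, 8, 5, 8, 3, 2, 15)
  bl
}
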