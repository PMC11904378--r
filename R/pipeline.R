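#' Build a per-person run configuration
#'
#' Collects every knob of the per-person pipeline with its default. Can be
#' loaded from a YAML file via `run_config_from_yaml()`; unknown fields are
#' rejected so typos surface early.
#'
#' @param events,surveys,category_map,out_dir input/output paths.
#'   `category_map` may be `NULL`.
#' @param tz timezone for day boundaries.
#' @param cadence screenshot interval, seconds.
#' @param gap_threshold sessionization gap for on/off-less streams, seconds.
#' @param window_days fortnight window length.
#' @param B permutation count.
#' @param scheme,shuffled_block permutation scheme, see [permute_null()].
#' @param ridge ridge for [fit_pcca()].
#' @param cesd_key,stai_key,asrs_map scoring keys.
#' @param thresholds clinical-threshold overrides, see [score_surveys()].
#' @param min_occasions minimum complete occasions required (default 12,
#'   one more than the 6 + 5 variables coupled).
#' @param seed integer seed for the permutation null.
#' @return a list of class `run_config`.
#' @export
run_config <- function(events = NULL, surveys = NULL, category_map = NULL,
                       out_dir = NULL, tz = "UTC", cadence = 5,
                       gap_threshold = 30, window_days = 14,
                       B = 1000, scheme = "within_column",
                       shuffled_block = "y", ridge = 0,
                       cesd_key = cesd_reverse_key(),
                       stai_key = stai_reverse_key(),
                       asrs_map = asrs_subscale_map(),
                       thresholds = list(), min_occasions = 12,
                       seed = 1) {
  if (window_days < 1) abort_input("window_days must be >= 1")
  if (!is_count(B) || B < 1) abort_input("B must be a positive integer")
  if (cadence <= 0) abort_input("cadence must be positive")
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose top-level keys are `run_config()` arguments.
#' @export
run_config_from_yaml <- function(path) {
  if (!file.exists(path)) abort_input("no such config file: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    abort_input("unknown config field(s): ", paste(bad, collapse = ", "))
  do.call(run_config, vals)
}

#' Run the full per-person pipeline
#'
#' Executes every stage for one participant: read events, surveys, and the
#' category map; sessionize and compute fortnightly media-use metrics at
#' the survey times; score the surveys; listwise-drop occasions missing
#' either block; fit the p-technique CCA; build the permutation null; and
#' write the report artifacts into `config$out_dir` (`report.json`,
#' `variates.csv`, `null.csv`, `dropped.csv`). The pipeline is strictly
#' per-person: nothing is pooled across participants.
#'
#' @param config a `run_config`. `events` and `surveys` may be file paths
#'   or in-memory tibbles.
#' @return an object of class `person_report`: list with `descriptives`
#'   (per-variable mean/SD), `risk_periods`, `solution` (a `pcca`), `null`
#'   (a `permutation_null`), `dropped` (tibble of dropped occasions with
#'   reasons), `n_occasions`, and `paths` of the written artifacts.
#' @export
run_person <- function(config) {
  stopifnot(inherits(config, "run_config"))
  events <- if (is.character(config$events)) read_events(config$events)
            else config$events
  surveys <- if (is.character(config$surveys)) read_surveys(config$surveys)
             else config$surveys
  cmap <- if (is.character(config$category_map))
            read_category_map(config$category_map) else config$category_map

  scored <- score_surveys(surveys, cesd_key = config$cesd_key,
                          stai_key = config$stai_key,
                          asrs_map = config$asrs_map,
                          thresholds = config$thresholds)
  ss <- sessionize(events, gap_threshold = config$gap_threshold)
  daily <- compute_daily_metrics(ss, category_map = cmap, tz = config$tz)
  fortnights <- aggregate_fortnight(daily, scored$timestamp,
                                    window_days = config$window_days,
                                    cadence = config$cadence, tz = config$tz)

  drop_x <- fortnights$missing
  drop_y <- scored$missing
  dropped <- tibble::tibble(
    timestamp = scored$timestamp[drop_x | drop_y],
    reason = ifelse(drop_x[drop_x | drop_y] & drop_y[drop_x | drop_y],
                    "no media-use data and incomplete survey",
                    ifelse(drop_x[drop_x | drop_y], "no media-use data",
                           "incomplete survey")))
  keep <- !(drop_x | drop_y)
  n_complete <- sum(keep)
  if (n_complete < config$min_occasions)
    abort_input("only ", n_complete, " complete occasions; need at least ",
                config$min_occasions,
                " (more occasions than the 6 + 5 variables analysed)")

  A_x <- ax_block(fortnights[keep, ])
  A_y <- ay_block(scored[keep, ])
  solution <- fit_pcca(A_x, A_y, ridge = config$ridge)
  null <- permute_null(A_x, A_y, B = config$B, scheme = config$scheme,
                       shuffled_block = config$shuffled_block,
                       seed = config$seed, ridge = config$ridge)

  desc <- rbind(
    block_descriptives(A_x, "media_use"),
    block_descriptives(A_y, "mental_health"))
  report <- structure(list(
    descriptives = desc,
    risk_periods = count_clinical_risk_periods(scored),
    solution = solution,
    null = null,
    dropped = dropped,
    n_occasions = n_complete,
    timestamps = scored$timestamp[keep],
    paths = NULL
  ), class = "person_report")

  if (!is.null(config$out_dir)) {
    report$paths <- write_person_report(report, config$out_dir)
  }
  report
}

block_descriptives <- function(A, block) {
  tibble::tibble(
    block = block,
    variable = colnames(A),
    mean = apply(A, 2, mean),
    sd = apply(A, 2, stats::sd))
}

write_person_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    report = file.path(out_dir, "report.json"),
    variates = file.path(out_dir, "variates.csv"),
    null = file.path(out_dir, "null.csv"),
    dropped = file.path(out_dir, "dropped.csv"))
  sol <- report$solution
  json <- list(
    n_occasions = report$n_occasions,
    rho = sol$rho,
    wilks = sol$wilks,
    p_value = report$null$p_value,
    permutations = report$null$B,
    scheme = report$null$scheme,
    shuffled_block = report$null$shuffled_block,
    seed = report$null$seed,
    x_weights = as.list(as.data.frame(sol$x_weights)),
    y_weights = as.list(as.data.frame(sol$y_weights)),
    x_loadings = as.list(sol$x_loadings),
    y_loadings = as.list(sol$y_loadings),
    descriptives = as.list(report$descriptives),
    risk_periods = as.list(report$risk_periods),
    dropped = as.list(tibble::tibble(
      timestamp = format_instant(report$dropped$timestamp),
      reason = report$dropped$reason)))
  jsonlite::write_json(json, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(
    data.frame(timestamp = format_instant(report$timestamps),
               z_x = sol$z_x[, 1], z_y = sol$z_y[, 1]),
    paths$variates, row.names = FALSE)
  utils::write.csv(
    data.frame(iteration = seq_len(report$null$B),
               rho = report$null$null_rhos),
    paths$null, row.names = FALSE)
  utils::write.csv(
    data.frame(timestamp = format_instant(report$dropped$timestamp),
               reason = report$dropped$reason),
    paths$dropped, row.names = FALSE)
  paths
}

#' Render a human-readable person summary
#'
#' Formats the headline line (`r = ..., P = ..., n = ...`), Wilks' lambda,
#' and the structure-loading table of the first canonical pair, ordered by
#' absolute loading.
#'
#' @param report a `person_report` from [run_person()].
#' @return character vector of report lines (also printed).
#' @export
make_report <- function(report) {
  stopifnot(inherits(report, "person_report"))
  if (length(report$null$null_rhos) == 0)
    abort_input("report has an empty permutation null")
  sol <- report$solution
  fmt_load <- function(loadings, label) {
    ord <- order(abs(loadings), decreasing = TRUE)
    c(sprintf("%s loadings (first canonical pair):", label),
      sprintf("  %-22s %+.2f", names(loadings)[ord], loadings[ord]))
  }
  lines <- c(
    sprintf("r=%.2f, P=%s, n=%d", sol$rho[1],
            sub("^0\\.", ".", format(round(report$null$p_value, 3))),
            report$n_occasions),
    sprintf("Wilks lambda = %.4f (B = %d permutations, %s on block %s)",
            sol$wilks, report$null$B, report$null$scheme,
            report$null$shuffled_block),
    fmt_load(sol$x_loadings, "media use"),
    fmt_load(sol$y_loadings, "mental health"),
    sprintf("clinical risk periods: depression %d, anxiety %d, adhd %d",
            report$risk_periods["depression"], report$risk_periods["anxiety"],
            report$risk_periods["adhd"]),
    sprintf("dropped occasions: %d", nrow(report$dropped)))
  cat(lines, sep = "\n")
  invisible(lines)
}

#' @export
print.person_report <- function(x, ...) {
  make_report(x)
  invisible(x)
}
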