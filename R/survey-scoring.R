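#' Default reverse-key and subscale maps
#'
#' The instruments' published keys. The source dataset's exact keys are a
#' configuration choice: every scorer accepts its key as an argument, and
#' these defaults follow the published short forms — CES-D-10 positive items
#' 5 and 8, STAI-state anxiety-absent items 1, 2, 5, 8, 10, 11, 15, 16, 19,
#' 20, and the 18-item adult ADHD scale split into 9 inattention items
#' (1–4, 7–11) and 9 hyperactivity items (5, 6, 12–18), so that the first
#' six screener items comprise four inattention and two hyperactivity items.
#'
#' @return integer vectors of item indices (`cesd_reverse_key`,
#'   `stai_reverse_key`) or a named list of two index vectors
#'   (`asrs_subscale_map`).
#' @export
cesd_reverse_key <- function() c(5L, 8L)

#' @rdname cesd_reverse_key
#' @export
stai_reverse_key <- function() c(1L, 2L, 5L, 8L, 10L, 11L, 15L, 16L, 19L, 20L)

#' @rdname cesd_reverse_key
#' @export
asrs_subscale_map <- function() {
  list(inattention = c(1:4, 7:11), hyperactivity = c(5L, 6L, 12:18))
}

check_items <- function(items, n, lo, hi, scale) {
  if (length(items) != n)
    abort_input(scale, " needs ", n, " items, got ", length(items))
  ok <- is.na(items) | (items >= lo & items <= hi & items == trunc(items))
  if (!all(ok))
    abort_input(scale, " item level(s) out of range [", lo, ", ", hi, "]: ",
                paste(items[!ok], collapse = ", "))
  items
}

#' Score the 10-item CES-D depression scale
#'
#' Items are 0–3 Likert levels. Positively worded items listed in
#' `reverse_key` are reverse-coded (`level -> 3 - level`) and all ten items
#' summed, giving a total in 0–30. Totals strictly above the clinical
#' threshold (default 16) flag a depression risk fortnight. Any missing item
#' invalidates the scale for the occasion — no prorating or imputation.
#'
#' @param items numeric vector of 10 levels in 0–3 (NA allowed).
#' @param reverse_key indices of reverse-coded items.
#' @param threshold risk if total is strictly greater (default 16).
#' @return list with `total` and logical `risk` (both NA if any item missing).
#' @examples
#' score_cesd(c(3, 3, 3, 3, 3, 3, 3, 3, 0, 0), reverse_key = c(9, 10))
#' @export
score_cesd <- function(items, reverse_key = cesd_reverse_key(),
                       threshold = 16) {
  items <- check_items(items, 10L, 0, 3, "CES-D")
  if (anyNA(items)) return(list(total = NA_real_, risk = NA))
  items[reverse_key] <- 3 - items[reverse_key]
  total <- sum(items)
  list(total = total, risk = total > threshold)
}

#' Score the 20-item STAI state-anxiety scale
#'
#' Items are 1–4 Likert levels; anxiety-absent items in `reverse_key` are
#' reverse-coded (`level -> 5 - level`). Totals range 20–80; totals strictly
#' above the threshold (default 40) indicate moderate-to-high state anxiety.
#'
#' @param items numeric vector of 20 levels in 1–4 (NA allowed).
#' @inheritParams score_cesd
#' @return list with `total` and logical `risk`.
#' @export
score_stai_state <- function(items, reverse_key = stai_reverse_key(),
                             threshold = 40) {
  items <- check_items(items, 20L, 1, 4, "STAI-state")
  if (anyNA(items)) return(list(total = NA_real_, risk = NA))
  items[reverse_key] <- 5 - items[reverse_key]
  total <- sum(items)
  list(total = total, risk = total > threshold)
}

#' Score the 18-item adult ADHD self-report scale
#'
#' Items are 0–4 frequency levels. Subscale totals (9 items each, range
#' 0–36) are plain sums under `subscale_map`. The screener rule flags
#' clinical risk when the sum of the first six items (`screener_items`) is
#' greater than or equal to `threshold` (default 9).
#'
#' @param items numeric vector of 18 levels in 0–4 (NA allowed).
#' @param subscale_map list with `inattention` and `hyperactivity` index
#'   vectors (9 each).
#' @param screener_items indices forming the screener sum (default 1:6).
#' @param threshold risk if screener sum `>=` this value (default 9).
#' @return list with `inattention`, `hyperactivity`, and logical `risk`.
#' @examples
#' score_asrs(c(4, 4, 1, 0, 0, 0, rep(0, 12))) # screener sum 9 -> risk
#' @export
score_asrs <- function(items, subscale_map = asrs_subscale_map(),
                       screener_items = 1:6, threshold = 9) {
  items <- check_items(items, 18L, 0, 4, "ASRS")
  if (!setequal(c(subscale_map$inattention, subscale_map$hyperactivity),
                1:18))
    abort_input("subscale map must partition items 1-18")
  if (anyNA(items))
    return(list(inattention = NA_real_, hyperactivity = NA_real_, risk = NA))
  list(
    inattention = sum(items[subscale_map$inattention]),
    hyperactivity = sum(items[subscale_map$hyperactivity]),
    risk = sum(items[screener_items]) >= threshold
  )
}

#' Score a fortnightly survey table into the mental-health block
#'
#' Takes item-level responses, one row per fortnightly occasion, with
#' columns `timestamp`, `cesd_01`..`cesd_10`, `stai_01`..`stai_20`,
#' `asrs_01`..`asrs_18`, `positive_affect`, and returns one scored row per
#' occasion: the five mental-health variables (depression, state anxiety,
#' inattention, hyperactivity, positive affect) plus per-scale risk flags
#' and a `missing` flag set when any scale could not be scored.
#'
#' @param surveys data frame of item-level responses (see
#'   [generate_survey_series()] for the column layout).
#' @param cesd_key,stai_key,asrs_map,asrs_screener scoring configuration,
#'   see the individual scorers.
#' @param thresholds named list overriding clinical thresholds
#'   (`depression`, `anxiety`, `adhd`).
#' @return a tibble with `timestamp`, the five score columns, `risk_*`
#'   flags, and `missing`.
#' @export
score_surveys <- function(surveys,
                          cesd_key = cesd_reverse_key(),
                          stai_key = stai_reverse_key(),
                          asrs_map = asrs_subscale_map(),
                          asrs_screener = 1:6,
                          thresholds = list()) {
  thr <- utils::modifyList(list(depression = 16, anxiety = 40, adhd = 9),
                           thresholds)
  need <- c("timestamp", sprintf("cesd_%02d", 1:10),
            sprintf("stai_%02d", 1:20), sprintf("asrs_%02d", 1:18),
            "positive_affect")
  miss <- setdiff(need, names(surveys))
  if (length(miss))
    abort_input("survey table lacks column(s): ", paste(miss, collapse = ", "))

  if (nrow(surveys) == 0) {
    return(tibble::tibble(
      timestamp = as.POSIXct(character(), tz = "UTC"),
      depression = numeric(), state_anxiety = numeric(),
      inattention = numeric(), hyperactivity = numeric(),
      positive_affect = numeric(), risk_depression = logical(),
      risk_anxiety = logical(), risk_adhd = logical(), missing = logical()))
  }
  rows <- lapply(seq_len(nrow(surveys)), function(i) {
    r <- surveys[i, ]
    cesd <- score_cesd(as.numeric(r[sprintf("cesd_%02d", 1:10)]),
                       cesd_key, thr$depression)
    stai <- score_stai_state(as.numeric(r[sprintf("stai_%02d", 1:20)]),
                             stai_key, thr$anxiety)
    asrs <- score_asrs(as.numeric(r[sprintf("asrs_%02d", 1:18)]),
                       asrs_map, asrs_screener, thr$adhd)
    pa <- as.numeric(r[["positive_affect"]])
    if (!is.na(pa) && (pa < 0 || pa > 100))
      abort_input("positive_affect outside [0, 100]: ", pa)
    tibble::tibble(
      timestamp = parse_instant(r[["timestamp"]]),
      depression = cesd$total, state_anxiety = stai$total,
      inattention = asrs$inattention, hyperactivity = asrs$hyperactivity,
      positive_affect = pa,
      risk_depression = cesd$risk, risk_anxiety = stai$risk,
      risk_adhd = asrs$risk
    )
  })
  out <- do.call(rbind, rows)
  out$missing <- is.na(out$depression) | is.na(out$state_anxiety) |
    is.na(out$inattention) | is.na(out$hyperactivity) |
    is.na(out$positive_affect)
  out
}

#' Mental-health block variable names, in fixed order
#' @export
ay_variables <- function() {
  c("depression", "state_anxiety", "inattention", "hyperactivity",
    "positive_affect")
}

#' Extract the numeric mental-health block from scored occasions
#'
#' @param scored output of [score_surveys()].
#' @return occasions x 5 numeric matrix with the fixed column order.
#' @export
ay_block <- function(scored) {
  as.matrix(scored[ay_variables()])
}

#' Count clinical-risk fortnights per scale
#'
#' A clinical-risk period is a fortnightly occasion whose scored value
#' exceeds the scale's clinical threshold (depression total > 16, state
#' anxiety > 40, ADHD screener sum of the first six items >= 9). Occasions
#' with an unscoreable (missing) scale do not count.
#'
#' @param scored output of [score_surveys()].
#' @return named integer vector: `depression`, `anxiety`, `adhd`.
#' @export
count_clinical_risk_periods <- function(scored) {
  cnt <- function(x) sum(x, na.rm = TRUE)
  c(depression = cnt(scored$risk_depression),
    anxiety = cnt(scored$risk_anxiety),
    adhd = cnt(scored$risk_adhd))
}
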