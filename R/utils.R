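#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# stop() with call. = FALSE everywhere; these keep messages uniform
abort_input <- function(...) stop(..., call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) &&
  x == trunc(x)

# POSIXct in UTC from ISO-8601 strings (with or without 'T'/'Z')
parse_instant <- function(x) {
  if (inherits(x, "POSIXct")) return(as.POSIXct(x, tz = "UTC"))
  x <- gsub("T", " ", x, fixed = TRUE)
  x <- sub("Z$", "", x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  if (anyNA(out)) abort_input("unparseable timestamp(s): ",
                              paste(utils::head(x[is.na(out)], 3), collapse = ", "))
  out
}

format_instant <- function(x) format(x, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

# run code with a temporary RNG state when seed is given; leaves the
# caller's RNG untouched either way
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# deterministic per-iteration substreams below 2^31
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n, replace = FALSE))
}
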