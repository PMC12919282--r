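#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
# All generator randomness flows through this; no function leaves global
# RNG state modified.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a sub-seed for a named generator stage from the master seed, kept
# within 32-bit integer range so set.seed() accepts it.
derive_seed <- function(seed, stage) {
  offset <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 1009 + offset) %% 2147483629L)
}

stop_invalid <- function(...) {
  stop(structure(
    class = c("budwatch_invalid_config", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
  all(abs(x - round(x)) < 1e-8)

# month_index 1..T -> month-of-year 1..12, anchored to the epoch month
month_of_year <- function(month_index, epoch_month = 4L) {
  ((epoch_month - 1L + month_index - 1L) %% 12L) + 1L
}

# First calendar day of month_index given an epoch "YYYY-MM-01"
month_start <- function(month_index, epoch = as.Date("2013-04-01")) {
  seq(epoch, by = "month", length.out = max(month_index))[month_index]
}

days_in_month <- function(month_index, epoch = as.Date("2013-04-01")) {
  s <- month_start(month_index, epoch)
  e <- seq(epoch, by = "month", length.out = max(month_index) + 1L)[month_index + 1L]
  as.integer(e - s)
}
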