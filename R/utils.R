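#' @keywords internal
"_PACKAGE"

# Days per month used for every duration conversion in the package.
DAYS_PER_MONTH <- 30.4375

days_to_months <- function(days) days / DAYS_PER_MONTH

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

is_count <- function(x, min = 0L) {
  length(x) == 1L && is.numeric(x) && !is.na(x) && x >= min && x == floor(x)
}

is_prob <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x <= 1)
}

# Deterministic child seed derived from a parent seed and a stream label,
# kept below 2^31 so it is always a valid R integer seed.
child_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
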