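## Small shared helpers.

# Stable 31-bit hash of a seed plus arbitrary string tokens (FNV-1a).
# Used to fan a single user seed out into independent per-stage /
# per-well / per-field streams without the digest package.
seed_stream <- function(seed, ...) {
  s <- paste(c(format(seed), ...), collapse = "/")
  h <- 2166136261 %% 2147483648  # keep within 31 bits for bitwXor
  for (b in utf8ToInt(s)) {
    h <- bitwXor(h, b)
    h <- (h * 16777619) %% 2147483648
  }
  as.integer(h)
}

# Truncated normal draws by rejection; bounds are hard limits that keep
# multiplicative parameters positive.
rtruncnorm <- function(n, mean, sd, lower, upper) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- rnorm(length(need), mean, sd)
    ok <- x >= lower & x <= upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number", call. = FALSE)
  if (x < lower || (strict_lower && x == lower) || x > upper)
    stop("'", name, "' must be in ", if (strict_lower) "(" else "[",
         lower, ", ", upper, "]", call. = FALSE)
  invisible(x)
}

# Valid 96-well labels A1..H12
well_labels_96 <- function() {
  as.vector(outer(LETTERS[1:8], 1:12, paste0))
}

moving_average <- function(y, window) {
  if (window <= 1L) return(y)
  if (window %% 2L == 0L) window <- window + 1L
  k <- (window - 1L) %/% 2L
  n <- length(y)
  cs <- cumsum(c(0, y))
  lo <- pmax(seq_len(n) - k, 1L)
  hi <- pmin(seq_len(n) + k, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}
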