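# internal helpers shared across modules

# numerically stable log(1 + exp(x))
softplus <- function(x) {
  out <- numeric(length(x))
  hi <- x > 30
  out[hi] <- x[hi] + log1p(exp(-x[hi]))
  out[!hi] <- log1p(exp(x[!hi]))
  out
}

stop_domain <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Duration of a moving-variance segment
#'
#' Length in hours of an `n`-sample acquisition segment at sampling interval
#' `dt_s` seconds. With the defaults (512 samples at 160 s) this is 22.7555...,
#' conventionally reported truncated to two decimals as 22.75 h.
#'
#' @param n number of samples.
#' @param dt_s sampling interval in seconds.
#' @return duration in hours.
#' @export
segment_duration_h <- function(n = 512L, dt_s = 160) n * dt_s / 3600

# FNV-1a 32-bit hash over a character scalar; returned as 8-char hex.
# Used for config hashing in run manifests (stable, dependency-free).
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(x))
  # track the 32-bit state as two 16-bit halves so all arithmetic stays exact
  hi <- 0x811c; lo <- 0x9dc5
  for (b in bytes) {
    lo <- bitwXor(lo, b)
    # (hi*2^16 + lo) * 16777619 mod 2^32, 16777619 = 256*2^16 + 403
    t <- lo * 403 + ((lo * 256 + hi * 403) %% 65536) * 65536
    t <- t %% 4294967296
    hi <- t %/% 65536; lo <- t %% 65536
  }
  sprintf("%04x%04x", hi, lo)
}

# canonical JSON of a nested list with recursively sorted keys
canonical_json <- function(x) {
  sort_rec <- function(v) {
    if (is.list(v) && !is.null(names(v)) && length(v)) {
      v <- v[order(names(v))]
      lapply(v, sort_rec)
    } else if (is.list(v)) lapply(v, sort_rec) else v
  }
  as.character(jsonlite::toJSON(sort_rec(x), auto_unbox = TRUE, digits = NA,
                                null = "null"))
}
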