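# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# FNV-1a 32-bit hash of a character scalar; used for report provenance only
fnv1a32 <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b %% 256))
    # h * 16777619 mod 2^32, split as h*(2^24 + 403) to stay exact in doubles
    h <- ((h %% 256) * 16777216 + h * 403) %% 4294967296
  }
  hi <- floor(h / 65536)
  sprintf("%04x%04x", as.integer(hi), as.integer(h - hi * 65536))
}

# linear interpolation of the two half-maximum crossings around the peak of a
# sampled curve; returns c(left, right) in x units, NA where no crossing
half_crossings <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  ipk <- which.max(y)
  half <- y[ipk] / 2
  left <- NA_real_
  if (ipk > 1) {
    below <- which(y[seq_len(ipk - 1)] < half)
    if (length(below)) {
      i <- max(below)
      left <- x[i] + (half - y[i]) * (x[i + 1] - x[i]) / (y[i + 1] - y[i])
    }
  }
  right <- NA_real_
  if (ipk < length(y)) {
    above <- which(y[seq(ipk + 1, length(y))] < half)
    if (length(above)) {
      j <- ipk + min(above)
      right <- x[j - 1] + (half - y[j - 1]) * (x[j] - x[j - 1]) /
        (y[j] - y[j - 1])
    }
  }
  c(left = left, right = right)
}
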