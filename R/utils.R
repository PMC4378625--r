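#' @keywords internal
"_PACKAGE"

#' @importFrom stats coef cor lm median optimize qnorm quantile rlnorm rnorm
#'   sd setNames t.test var predict pt pf residuals
#' @importFrom utils read.csv write.csv head tail
NULL

## Run code with a temporary RNG state seeded from `seed`, restoring the
## caller's state afterwards. All generator randomness flows through this.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

## FNV-1a hash of a character scalar, returned as 8 hex digits. Used for
## provenance headers on output tables (no cryptographic intent).
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    ## xor touches only the low byte since b < 256
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    ## 32-bit modular multiply by the FNV prime 16777619, split to stay
    ## inside exact double-precision integer range
    hi <- h %/% 65536; lo2 <- h %% 65536
    h <- (lo2 * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  paste0(sprintf("%04x", h %/% 65536), sprintf("%04x", h %% 65536))
}

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

is_number <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
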