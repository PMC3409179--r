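# Shared constants and small helpers.

BASES <- c("A", "C", "G", "T")

# Dinucleotide labels ordered so that index = (prev - 1) * 4 + cur,
# with prev/cur the integer codes of the previous and current base.
DINUCS <- paste0(rep(BASES, each = 4), rep(BASES, 4))

# ASCII lookup: A/C/G/T -> 1..4, everything else (incl. N) -> NA
.base_code <- local({
  x <- rep(NA_integer_, 127L)
  x[utf8ToInt("A")] <- 1L
  x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L
  x[utf8ToInt("T")] <- 4L
  x
})

dna_int <- function(s) .base_code[utf8ToInt(s)]

int_dna <- function(v) {
  stopifnot(!anyNA(v))
  intToUtf8(c(65L, 67L, 71L, 84L)[v])
}

# complement of the integer base code (A<->T, C<->G)
comp_int <- function(v) 5L - v

stop_invalid <- function(...) {
  stop(errorCondition(paste0(...), class = c("spikecal_invalid_parameter", "error")))
}

stop_data <- function(...) {
  stop(errorCondition(paste0(...), class = c("spikecal_data_error", "error")))
}

# Evaluate `code` with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) stop_invalid("a seed is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# positive scalar integer check
check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < min || x != floor(x)) {
    stop_invalid(name, " must be a single integer >= ", min)
  }
  as.integer(x)
}

check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lo || x > hi) {
    stop_invalid(name, " must be a single number in [", lo, ", ", hi, "]")
  }
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
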