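#' Construct a ground-truth sequencing error model
#'
#' Describes the generative error process used by the simulators. A base
#' at machine cycle `c` with reported Phred quality `q` and sequencing-
#' orientation dinucleotide context `d`, sequenced from reference site `s`
#' on strand `t`, has true error probability
#' \deqn{p = 10^{-(q + o_{qs}(q) + o_{cyc}(c) + o_{din}(d) + o_{site}(s,t))/10}}
#' clamped to at most `p_max`. Offsets are in Phred units; a negative
#' offset means the base is worse than reported. With all offsets zero the
#' instrument is perfectly calibrated and the empirical error rate in each
#' reported-quality bin converges to `10^(-q/10)`.
#'
#' Site offsets model systematic sequencing errors (SSEs): a fraction of
#' reference site/strand combinations draws a persistent negative offset,
#' so errors accumulate preferentially at those sites on that strand.
#'
#' @param read_len read length in bp.
#' @param q_levels integer reported Phred values the instrument emits
#'   (within 2..41).
#' @param q_prob probabilities for `q_levels` (normalised; default uniform).
#' @param qs_offset named numeric, offset per reported quality (names are
#'   quality values); unnamed levels default to 0.
#' @param cycle_offset numeric of length `read_len`, offset per cycle
#'   (default all 0).
#' @param dinuc_offset named numeric over dinucleotide labels (e.g. `"GG"`);
#'   unnamed contexts default to 0.
#' @param site_fraction fraction of site/strand combinations carrying a
#'   site offset (default 0: no SSE sites).
#' @param site_offset_range length-2 range; site offsets are drawn
#'   uniformly from it.
#' @param substitution `"uniform"` (each wrong base equiprobable) or a 4x4
#'   row-stochastic-off-diagonal matrix of substitution probabilities
#'   (rows = true base A,C,G,T; diagonal ignored).
#' @param paired logical; mate handling (mate-2 cycles are negated in
#'   recalibration tables). The simulator emits single-end reads.
#' @param p_max clamp on the true error probability (default 0.75, the
#'   fully random limit).
#' @return An object of class `error_model`.
#' @seealso [illumina_rnaseq_model()] for the miscalibrated preset used as
#'   the package's study condition.
#' @export
error_model <- function(read_len = 100L, q_levels = 20:40, q_prob = NULL,
                        qs_offset = NULL, cycle_offset = NULL,
                        dinuc_offset = NULL, site_fraction = 0,
                        site_offset_range = c(0, 0),
                        substitution = "uniform", paired = FALSE,
                        p_max = 0.75) {
  read_len <- check_count(read_len, "read_len")
  q_levels <- as.integer(q_levels)
  if (any(q_levels < 2L | q_levels > 41L)) stop_invalid("q_levels must lie in 2..41")
  q_prob <- q_prob %||% rep(1, length(q_levels))
  if (length(q_prob) != length(q_levels) || any(q_prob < 0) || sum(q_prob) <= 0) {
    stop_invalid("q_prob must be non-negative with a positive sum, one per q level")
  }
  q_prob <- q_prob / sum(q_prob)

  qs_full <- stats::setNames(rep(0, 40L), as.character(2:41))
  if (!is.null(qs_offset)) {
    if (is.null(names(qs_offset))) stop_invalid("qs_offset must be named by quality value")
    qs_full[names(qs_offset)] <- qs_offset
  }
  cycle_offset <- cycle_offset %||% rep(0, read_len)
  if (length(cycle_offset) != read_len) stop_invalid("cycle_offset must have length read_len")
  din_full <- stats::setNames(rep(0, 16L), DINUCS)
  if (!is.null(dinuc_offset)) {
    if (is.null(names(dinuc_offset)) || !all(names(dinuc_offset) %in% DINUCS)) {
      stop_invalid("dinuc_offset must be named by dinucleotide labels")
    }
    din_full[names(dinuc_offset)] <- dinuc_offset
  }
  site_fraction <- check_fraction(site_fraction, "site_fraction")
  if (length(site_offset_range) != 2L || site_offset_range[1] > site_offset_range[2]) {
    stop_invalid("site_offset_range must be an increasing length-2 range")
  }
  if (is.character(substitution)) {
    substitution <- match.arg(substitution, "uniform")
  } else {
    substitution <- as.matrix(substitution)
    if (!all(dim(substitution) == c(4L, 4L)) || any(substitution < 0)) {
      stop_invalid("substitution must be 'uniform' or a 4x4 non-negative matrix")
    }
  }
  p_max <- check_fraction(p_max, "p_max", lo = 1e-12, hi = 1)
  structure(list(
    read_len = read_len, q_levels = q_levels, q_prob = q_prob,
    qs_offset = qs_full, cycle_offset = as.numeric(cycle_offset),
    dinuc_offset = din_full, site_fraction = site_fraction,
    site_offset_range = as.numeric(site_offset_range),
    substitution = substitution, paired = isTRUE(paired), p_max = p_max
  ), class = "error_model")
}

#' @export
print.error_model <- function(x, ...) {
  cat(sprintf(
    "<error_model> read_len=%d, q in [%d,%d], %d non-zero dinuc offsets, site SSE fraction=%.3g\n",
    x$read_len, min(x$q_levels), max(x$q_levels),
    sum(x$dinuc_offset != 0), x$site_fraction
  ))
  invisible(x)
}

#' Miscalibrated Illumina-like RNA-seq error model
#'
#' A preset [error_model()] emulating the qualitative miscalibration
#' patterns reported for Illumina RNA sequencing: top-of-range reported
#' qualities that over-state accuracy, mildly pessimistic low qualities,
#' quality degradation over the final fifth of the read, under-performing
#' AC/CC/GC/GG/TC dinucleotide contexts (with TA slightly better than
#' reported), and a sparse population of strand-specific SSE sites whose
#' error rate is 5-20 times the reported one. Reported qualities follow a
#' discretised normal on Q20-Q40 (mean 32, sd 5). All covariate offsets
#' are within +/-5 Phred units.
#'
#' @param read_len read length in bp (default 100).
#' @return An `error_model`.
#' @export
illumina_rnaseq_model <- function(read_len = 100L) {
  read_len <- check_count(read_len, "read_len")
  q <- 20:40
  tail_len <- max(1L, round(read_len / 5))
  cyc <- rep(0, read_len)
  cyc[(read_len - tail_len + 1L):read_len] <- seq(0, -3, length.out = tail_len)
  error_model(
    read_len = read_len,
    q_levels = q,
    q_prob = stats::dnorm(q, mean = 32, sd = 5),
    qs_offset = c("38" = -2, "39" = -2, "40" = -2, "20" = 1, "21" = 1, "22" = 1),
    cycle_offset = cyc,
    dinuc_offset = c(GG = -5, GC = -4, AC = -3, CC = -3, TC = -2, TA = 2),
    site_fraction = 0.05,
    site_offset_range = c(-13, -7)
  )
}

#' Draw the per-site SSE offset surface for a reference
#'
#' Samples which reference site/strand combinations carry a systematic
#' error offset under `model`, deterministically for a given seed. The
#' same `(ref, model, seed)` always yields the same surface, so repeated
#' simulations over one reference share their SSE sites.
#'
#' @param ref a `spike_ref`.
#' @param model an `error_model`.
#' @param seed integer seed.
#' @return numeric matrix `[total reference length, 2]` of Phred offsets
#'   (columns: plus, minus strand), with attribute `flat` (the reference
#'   layout from which row indices are computed).
#' @export
site_effects <- function(ref, model, seed) {
  fl <- ref_flat(ref)
  total <- sum(fl$lens)
  off <- matrix(0, nrow = total, ncol = 2L)
  if (model$site_fraction > 0) {
    off[] <- with_seed(seed, {
      hit <- stats::runif(2L * total) < model$site_fraction
      o <- numeric(2L * total)
      o[hit] <- stats::runif(sum(hit), model$site_offset_range[1], model$site_offset_range[2])
      o
    })
  }
  attr(off, "flat") <- fl
  off
}
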