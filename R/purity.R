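#' Posterior probability that a base's purity meets a threshold
#'
#' Beta-binomial model for per-base purity: the impurity fraction (the
#' fraction of molecules not carrying the reference base) has a
#' `Beta(alpha, beta)` prior and mismatches are binomial, so after
#' observing `k` mismatches in `n` bases the impurity posterior is
#' `Beta(alpha + k, beta + n - k)`. The returned value is the posterior
#' probability that purity is at least `theta`, i.e. the regularised
#' incomplete beta function evaluated at `1 - theta`.
#'
#' With the flat `Beta(1, 1)` prior and `k = 0` this reduces to the
#' closed form `1 - theta^(n + 1)`.
#'
#' @param n number of observed bases (>= 0).
#' @param k number of mismatching bases (0 <= k <= n). Vectorised with `n`.
#' @param theta purity threshold in (0, 1) (default 0.99).
#' @param prior length-2 `(alpha, beta)` of the impurity prior
#'   (default flat `c(1, 1)`).
#' @return posterior probability (vectorised).
#' @export
purity_posterior <- function(n, k, theta = 0.99, prior = c(1, 1)) {
  if (any(n < 0) || any(k < 0) || any(k > n)) {
    stop_invalid("need 0 <= k <= n")
  }
  if (length(theta) != 1L || theta <= 0 || theta >= 1) stop_invalid("theta must be in (0, 1)")
  if (length(prior) != 2L || any(prior <= 0)) stop_invalid("prior (alpha, beta) must be > 0")
  stats::pbeta(1 - theta, prior[1] + k, prior[2] + n - k)
}

#' Minimum error-free coverage for confident purity
#'
#' The smallest `n` such that `n` observations with zero mismatches give
#' posterior probability at least `confidence` that purity >= `theta`.
#' Exact integer, found by monotone (exponential then binary) search.
#'
#' @param theta purity threshold in (0, 1).
#' @param confidence required posterior probability in (0, 1).
#' @param prior impurity prior `(alpha, beta)`.
#' @return integer coverage.
#' @export
min_coverage_for_confidence <- function(theta = 0.99, confidence = 0.95,
                                        prior = c(1, 1)) {
  if (purity_posterior(0, 0, theta, prior) >= confidence) return(0L)
  hi <- 1L
  while (purity_posterior(hi, 0, theta, prior) < confidence) {
    hi <- hi * 2L
    if (hi > 1e9) stop_invalid("confidence unreachable at any practical coverage")
  }
  lo <- hi %/% 2L
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (purity_posterior(mid, 0, theta, prior) >= confidence) hi <- mid else lo <- mid
  }
  hi
}

# per-position (n, k) for one pileup under the six strand/tier modes
purity_modes <- function(bc) {
  cn <- bc$counts
  total <- dim(cn)[1]
  ridx <- cbind(seq_len(total), bc$refbase)
  out <- vector("list", 6L)
  m <- 1L
  for (ti in 1:2) {
    for (s in list(1:2, 1L, 2L)) {
      sl <- cn[, , s, ti, drop = FALSE]
      n <- rowSums(sl)
      refc <- apply(sl, c(1, 2), sum)[ridx]
      out[[m]] <- list(n = n, k = n - refc)
      m <- m + 1L
    }
  }
  names(out) <- c("both_all", "plus_all", "minus_all",
                  "both_hq", "plus_hq", "minus_hq")
  out
}

#' Certify high-purity reference bases across platforms
#'
#' For every reference position and every platform pileup, the purity
#' posterior is evaluated under six modes: both strands together and each
#' strand separately, crossed with all bases versus high-quality bases
#' only. A platform *supports* purity at a base when the maximum posterior
#' across its six modes reaches `confidence` - a systematic error visible
#' on one strand only, or only among low-quality bases, does not condemn
#' the base. The verdict is:
#'
#' * `high_purity` - at least one platform supports purity;
#' * `impure` - every platform has sufficient both-strand coverage
#'   (at least [min_coverage_for_confidence()]) and none supports purity;
#' * `low_coverage` - otherwise;
#' * `ENDSKIP` / `POLYA` overrides - positions within `end_skip` bases of
#'   the insert boundaries (or outside the insert), and positions inside
#'   homopolymer A/T runs of length >= `polyA_min_run`, are excluded
#'   unconditionally.
#'
#' @param pileups a named list of `base_counts`, one per platform.
#' @param ref the `spike_ref` the pileups were computed against.
#' @param theta purity threshold (default 0.99).
#' @param confidence posterior probability required (default 0.95).
#' @param prior impurity prior (default flat).
#' @param end_skip bases to skip at each insert end (default 50).
#' @param polyA_min_run minimum homopolymer A/T run length to exclude
#'   (default 6).
#' @return A `purity_calls` data frame: `id`, `pos` (0-based), `ref`,
#'   `verdict`, plus one posterior column per platform (the max over the
#'   six modes) and the both-strand/all-bases `n` and `k` per platform.
#' @export
classify_bases <- function(pileups, ref, theta = 0.99, confidence = 0.95,
                           prior = c(1, 1), end_skip = 50L, polyA_min_run = 6L) {
  if (!length(pileups)) stop_invalid("at least one platform pileup is required")
  if (is.null(names(pileups))) names(pileups) <- paste0("platform", seq_along(pileups))
  fl <- ref_flat(ref)
  total <- sum(fl$lens)
  min_cov <- min_coverage_for_confidence(theta, confidence, prior)

  support <- matrix(FALSE, total, length(pileups))
  sufficient <- matrix(FALSE, total, length(pileups))
  post_max <- matrix(NA_real_, total, length(pileups),
                     dimnames = list(NULL, names(pileups)))
  nk <- vector("list", length(pileups))
  for (i in seq_along(pileups)) {
    bc <- pileups[[i]]
    stopifnot(identical(bc$flat$ids, fl$ids), identical(bc$flat$lens, fl$lens))
    modes <- purity_modes(bc)
    pm <- rep(0, total)
    for (m in modes) pm <- pmax(pm, purity_posterior(m$n, m$k, theta, prior))
    post_max[, i] <- pm
    support[, i] <- pm >= confidence
    sufficient[, i] <- modes$both_all$n >= min_cov
    nk[[i]] <- modes$both_all
  }

  verdict <- ifelse(
    rowSums(support) > 0L, "high_purity",
    ifelse(rowSums(sufficient) == length(pileups), "impure", "low_coverage")
  )

  # positional exclusions: insert boundaries and homopolymer A/T runs
  r <- ref$records
  pos_in_rec <- unlist(lapply(fl$lens, function(L) seq.int(0L, L - 1L)), use.names = FALSE)
  rec_of_pos <- rep(seq_along(fl$lens), fl$lens)
  lo <- r$insert_start[rec_of_pos] + end_skip
  hi <- r$insert_end[rec_of_pos] - end_skip
  endskip <- pos_in_rec < lo | pos_in_rec >= hi
  polya <- homopolymer_runs(fl, polyA_min_run)
  verdict[polya] <- "POLYA"
  verdict[endskip] <- "ENDSKIP"

  out <- data.frame(
    id = rep(fl$ids, fl$lens), pos = pos_in_rec, ref = BASES[fl$codes],
    verdict = verdict, stringsAsFactors = FALSE
  )
  for (i in seq_along(pileups)) {
    out[[paste0("post_", names(pileups)[i])]] <- post_max[, i]
    out[[paste0("n_", names(pileups)[i])]] <- nk[[i]]$n
    out[[paste0("k_", names(pileups)[i])]] <- nk[[i]]$k
  }
  attr(out, "theta") <- theta
  attr(out, "confidence") <- confidence
  attr(out, "min_coverage") <- min_cov
  class(out) <- c("purity_calls", "data.frame")
  out
}

# positions inside A or T homopolymer runs of length >= min_run,
# evaluated within each record separately
homopolymer_runs <- function(fl, min_run) {
  out <- logical(sum(fl$lens))
  for (i in seq_along(fl$lens)) {
    sl <- fl$codes[fl$offset[i] + seq_len(fl$lens[i])]
    r <- rle(sl)
    flag <- rep(r$values %in% c(1L, 4L) & r$lengths >= min_run, r$lengths)
    out[fl$offset[i] + seq_len(fl$lens[i])] <- flag
  }
  out
}

#' Positions certified high-purity
#' @param calls a `purity_calls` data frame.
#' @return data frame `id`, `pos` (0-based) of high-purity bases.
#' @export
high_purity_positions <- function(calls) {
  v <- calls[calls$verdict == "high_purity", c("id", "pos")]
  rownames(v) <- NULL
  v
}
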