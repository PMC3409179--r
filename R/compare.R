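#' Aggregate a recalibration table over covariates
#'
#' Marginalises a `recal_table` onto a covariate tuple by summing counts;
#' empirical qualities are recomputed from the summed counts (never
#' averaged). Rows without a dinucleotide context (`"NA"`) are dropped
#' when aggregating by dinucleotide.
#'
#' @param table a `recal_table`.
#' @param by character vector of covariates from `c("q", "cycle",
#'   "dinuc")`, e.g. `c("q", "dinuc")`.
#' @return data frame with the `by` columns plus `observations`, `errors`
#'   and `empirical_q`.
#' @export
aggregate_table <- function(table, by = "q") {
  if (!length(by) || !all(by %in% c("q", "cycle", "dinuc"))) {
    stop_invalid("by must be a subset of c('q', 'cycle', 'dinuc')")
  }
  x <- as.data.frame(table)
  if ("dinuc" %in% by) x <- x[x$dinuc != "NA", , drop = FALSE]
  key <- do.call(paste, c(lapply(by, function(b) {
    if (b == "q") sprintf("%02d", x$q) else as.character(x[[b]])
  }), sep = "\r"))
  obs <- rowsum(x$observations, key)
  err <- rowsum(x$errors, key)
  keys <- strsplit(rownames(obs), "\r", fixed = TRUE)
  out <- as.data.frame(
    stats::setNames(
      lapply(seq_along(by), function(i) vapply(keys, `[[`, character(1), i)),
      by
    ),
    stringsAsFactors = FALSE
  )
  if ("q" %in% by) out$q <- as.integer(out$q)
  if ("cycle" %in% by) out$cycle <- as.integer(out$cycle)
  out$observations <- as.numeric(obs)
  out$errors <- as.numeric(err)
  out$empirical_q <- empirical_quality(out$errors, out$observations)
  rownames(out) <- NULL
  out
}

#' Observation-weighted mean absolute difference of empirical qualities
#'
#' Aggregates two recalibration tables onto the same covariate tuple and
#' returns the mean absolute difference of their empirical qualities over
#' shared cells, weighted by the observations of the first (reference)
#' table. Cells with fewer than `min_observations` observations in either
#' table are excluded.
#'
#' @param table_a reference `recal_table` (supplies the weights).
#' @param table_b comparison `recal_table`.
#' @param by covariate tuple as in [aggregate_table()].
#' @param min_observations minimum observations per cell in both tables
#'   (default 100).
#' @return list with `mad` (Phred units), `n_cells`, and `cells` (the
#'   per-cell differences and weights).
#' @export
weighted_mad <- function(table_a, table_b, by = "q", min_observations = 100) {
  a <- aggregate_table(table_a, by)
  b <- aggregate_table(table_b, by)
  key_a <- do.call(paste, c(a[by], sep = "\r"))
  key_b <- do.call(paste, c(b[by], sep = "\r"))
  m <- match(key_a, key_b)
  ok <- !is.na(m) & a$observations >= min_observations &
    b$observations[m] >= min_observations
  if (!any(ok)) stop_data("no shared cells meet the observation threshold")
  diff <- a$empirical_q[ok] - b$empirical_q[m][ok]
  w <- a$observations[ok]
  cells <- a[ok, by, drop = FALSE]
  cells$diff <- diff
  cells$weight <- w
  rownames(cells) <- NULL
  list(mad = sum(w * abs(diff)) / sum(w), n_cells = sum(ok), cells = cells)
}

#' Randomly split reference positions into two disjoint halves
#'
#' Emulates the split-half accuracy estimate: the high-purity bases are
#' partitioned at random into set A and set B, and each half receives a
#' mask that hides everything except that half, so that two independent
#' recalibration tables can be counted from one read set.
#'
#' @param positions data frame `id`, `pos` of (high-purity) positions to
#'   split.
#' @param fraction fraction assigned to set A, in (0, 1) (default 0.5).
#' @param seed integer seed.
#' @param all_positions data frame of every reference position (see
#'   [all_reference_positions()]); defaults to `positions`, in which case
#'   each mask is exactly the opposite half.
#' @return list with `set_a`, `set_b` (the disjoint, exhaustive halves)
#'   and `mask_a`, `mask_b` (`all_positions` minus the respective set).
#' @export
split_half_reference <- function(positions, fraction = 0.5, seed,
                                 all_positions = NULL) {
  fraction <- check_fraction(fraction, "fraction")
  n <- nrow(positions)
  n_a <- round(n * fraction)
  if (n_a == 0L || n_a == n) {
    stop_invalid("fraction ", fraction, " leaves one half empty (n = ", n, ")")
  }
  all_positions <- all_positions %||% positions[, c("id", "pos")]
  with_seed(seed, {
    idx <- sample.int(n, n_a)
    set_a <- positions[sort(idx), c("id", "pos")]
    set_b <- positions[sort(setdiff(seq_len(n), idx)), c("id", "pos")]
    rownames(set_a) <- rownames(set_b) <- NULL
    keyed <- function(d) paste(d$id, d$pos)
    mask_a <- all_positions[!keyed(all_positions) %in% keyed(set_a), , drop = FALSE]
    mask_b <- all_positions[!keyed(all_positions) %in% keyed(set_b), , drop = FALSE]
    rownames(mask_a) <- rownames(mask_b) <- NULL
    list(set_a = set_a, set_b = set_b, mask_a = mask_a, mask_b = mask_b)
  })
}

#' Downsample a read set
#'
#' Keeps each read independently with probability `keep_fraction`
#' (Bernoulli thinning, the model of random read removal); kept reads are
#' unmodified.
#'
#' @param reads an `aligned_reads` object.
#' @param keep_fraction probability of keeping each read.
#' @param seed integer seed.
#' @return the downsampled `aligned_reads`.
#' @export
downsample_reads <- function(reads, keep_fraction, seed) {
  keep_fraction <- check_fraction(keep_fraction, "keep_fraction")
  if (keep_fraction == 1) return(reads)
  with_seed(seed, {
    subset_reads(reads, stats::runif(nrow(reads$seq)) < keep_fraction)
  })
}

#' Randomly remove reference bases from the visible set
#'
#' Selects a fraction of (high-purity) reference positions uniformly at
#' random and appends them to an exclusion mask, emulating recalibration
#' from a shorter spike-in reference.
#'
#' @param positions data frame `id`, `pos` of candidate positions.
#' @param remove_fraction fraction to remove, in \[0, 1\].
#' @param seed integer seed.
#' @param mask optional existing mask to augment.
#' @return data frame `id`, `pos`: the augmented mask (duplicates
#'   removed).
#' @export
remove_reference_bases <- function(positions, remove_fraction, seed, mask = NULL) {
  remove_fraction <- check_fraction(remove_fraction, "remove_fraction")
  n_rm <- round(nrow(positions) * remove_fraction)
  extra <- if (n_rm > 0L) {
    with_seed(seed, positions[sample.int(nrow(positions), n_rm), c("id", "pos")])
  } else {
    positions[0, c("id", "pos")]
  }
  out <- rbind(if (!is.null(mask)) mask[, c("id", "pos")], extra)
  out <- out[!duplicated(paste(out$id, out$pos)), , drop = FALSE]
  out <- out[order(out$id, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Nucleotide-change error rates and Ti/Tv
#'
#' For each of the 12 ordered nucleotide changes X>Y, the proportion of
#' aligned bases observed as Y at positions whose reference base is X,
#' relative to all observations at reference-X positions (matching or
#' not). By default only the high-quality tier of the pileup is used, so
#' random errors are suppressed and biological changes stand out. The
#' transition/transversion ratio is computed from the error counts:
#' `(A<->G + C<->T) / (all other changes)`; uniformly random errors give
#' Ti/Tv = 0.5, biological mutations much more.
#'
#' @param counts a `base_counts` pileup.
#' @param tier `"highQ"` (default) or `"all"`.
#' @param exclude optional site set (data frame `id`, `pos`) to exclude,
#'   e.g. impure bases or known variants.
#' @return list with `rates` (data frame `from`, `to`, `count`, `total`,
#'   `rate`) and `titv`.
#' @export
nucleotide_change_rates <- function(counts, tier = c("highQ", "all"),
                                    exclude = NULL) {
  tier <- match.arg(tier)
  ti <- if (tier == "all") 1L else 2L
  fl <- counts$flat
  keep <- rep(TRUE, length(counts$refbase))
  if (!is.null(exclude) && nrow(exclude) > 0L) keep[mask_index(exclude, fl)] <- FALSE
  # both strands pooled within the chosen tier
  cn <- counts$counts[, , 1L, ti] + counts$counts[, , 2L, ti]
  tab <- matrix(0, 4L, 4L, dimnames = list(BASES, BASES))
  for (rb in 1:4) {
    sel <- keep & counts$refbase == rb
    if (any(sel)) tab[rb, ] <- colSums(cn[sel, , drop = FALSE])
  }
  total <- rowSums(tab)
  rates <- data.frame(
    from = rep(BASES, each = 4L), to = rep(BASES, 4L),
    count = as.vector(t(tab)), total = rep(total, each = 4L),
    stringsAsFactors = FALSE
  )
  rates <- rates[rates$from != rates$to, , drop = FALSE]
  rates$rate <- ifelse(rates$total > 0, rates$count / rates$total, NA_real_)
  rownames(rates) <- NULL
  transitions <- with(rates, (from == "A" & to == "G") | (from == "G" & to == "A") |
                        (from == "C" & to == "T") | (from == "T" & to == "C"))
  ti_n <- sum(rates$count[transitions])
  tv_n <- sum(rates$count[!transitions])
  list(rates = rates, titv = if (tv_n > 0) ti_n / tv_n else NA_real_, tier = tier)
}

#' Compare paired nucleotide-change rate tables
#'
#' Paired t-tests per nucleotide change with a variance pooled across the
#' 12 changes, Bonferroni-adjusted. The pooled standard deviation is
#' computed from the within-change variances of the paired differences
#' (degrees of freedom `12 * (n - 1)`).
#'
#' @param rates_a,rates_b lists of rate results (from
#'   [nucleotide_change_rates()]) or of their `rates` data frames, one
#'   per sample, pairwise matched.
#' @return data frame per change: `from`, `to`, `mean_diff`, `t`, `df`,
#'   `p`, `p_adj`, `degenerate` (TRUE when the pooled variance is zero).
#' @export
compare_rates <- function(rates_a, rates_b) {
  get_rates <- function(x) if (is.data.frame(x)) x else x$rates
  a <- lapply(rates_a, get_rates)
  b <- lapply(rates_b, get_rates)
  n <- length(a)
  if (n != length(b) || n < 2L) stop_invalid("need >= 2 paired samples")
  key <- paste(a[[1]]$from, a[[1]]$to, sep = ">")
  d <- vapply(seq_len(n), function(j) {
    stopifnot(identical(paste(a[[j]]$from, a[[j]]$to, sep = ">"), key))
    a[[j]]$rate - b[[j]]$rate
  }, numeric(length(key)))
  means <- rowMeans(d)
  ss <- rowSums((d - means)^2)
  df <- length(key) * (n - 1L)
  sp <- sqrt(sum(ss) / df)
  # numerically-zero pooled variance (identical or uniformly shifted pairs)
  degenerate <- sp < 1e-12 + 1e-8 * max(abs(means))
  tstat <- if (degenerate) ifelse(means == 0, 0, Inf * sign(means)) else means / (sp / sqrt(n))
  p <- ifelse(is.infinite(tstat), 0, 2 * stats::pt(-abs(tstat), df))
  p[degenerate & means == 0] <- 1
  data.frame(
    from = a[[1]]$from, to = a[[1]]$to, mean_diff = means,
    t = tstat, df = df, p = p, p_adj = pmin(1, length(key) * p),
    degenerate = degenerate, stringsAsFactors = FALSE
  )
}

#' Per-cell significance of error-proportion differences
#'
#' For every covariate cell shared by two recalibration tables, tests
#' whether the error proportions differ using a binomial likelihood-ratio
#' statistic against chi-squared with one degree of freedom, Bonferroni-
#' adjusted over the tested cells. Cells without observations in either
#' table are skipped (marked `NA`).
#'
#' @param table_a,table_b `recal_table` objects.
#' @param by covariate tuple as in [aggregate_table()].
#' @return data frame with the `by` columns, counts, `lr` statistic, `p`
#'   and `p_adj`.
#' @export
cell_significance <- function(table_a, table_b, by = c("q", "dinuc")) {
  a <- aggregate_table(table_a, by)
  b <- aggregate_table(table_b, by)
  key_a <- do.call(paste, c(a[by], sep = "\r"))
  key_b <- do.call(paste, c(b[by], sep = "\r"))
  m <- match(key_a, key_b)
  ok <- !is.na(m)
  a <- a[ok, , drop = FALSE]
  bm <- b[m[ok], , drop = FALSE]
  ll <- function(k, n, p) {
    out <- numeric(length(k))
    nz <- k > 0
    out[nz] <- k[nz] * log(p[nz])
    nz2 <- n - k > 0
    out[nz2] <- out[nz2] + (n - k)[nz2] * log1p(-p[nz2])
    out
  }
  n1 <- a$observations
  k1 <- a$errors
  n2 <- bm$observations
  k2 <- bm$errors
  testable <- n1 > 0 & n2 > 0
  p1 <- ifelse(n1 > 0, k1 / n1, NA)
  p2 <- ifelse(n2 > 0, k2 / n2, NA)
  pp <- (k1 + k2) / (n1 + n2)
  lr <- rep(NA_real_, nrow(a))
  lr[testable] <- 2 * (ll(k1, n1, p1) + ll(k2, n2, p2) -
                         ll(k1 + k2, n1 + n2, pp))[testable]
  lr <- pmax(lr, 0)
  p <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
  out <- a[, by, drop = FALSE]
  out$obs_a <- n1
  out$err_a <- k1
  out$obs_b <- n2
  out$err_b <- k2
  out$lr <- lr
  out$p <- p
  out$p_adj <- pmin(1, sum(testable) * p)
  rownames(out) <- NULL
  out
}
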