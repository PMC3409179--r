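#' Empirical Phred quality from error counts
#'
#' Converts observed error counts into a Phred-scaled empirical quality
#' with add-one/add-two (Laplace) smoothing so that empty and error-free
#' cells stay finite:
#' \deqn{Q_{emp} = -10 \log_{10}\frac{errors + 1}{observations + 2}}
#' capped at 60. The smoothing constant only matters for sparsely
#' populated cells; differences of empirical qualities at high counts are
#' insensitive to it.
#'
#' @param errors error counts (vectorised).
#' @param observations observation counts, componentwise >= `errors`.
#' @return empirical quality in Phred units.
#' @export
empirical_quality <- function(errors, observations) {
  if (any(errors < 0) || any(observations < 0)) stop_invalid("counts must be >= 0")
  if (any(errors > observations)) stop_invalid("errors cannot exceed observations")
  pmin(-10 * log10((errors + 1) / (observations + 2)), 60)
}

#' Per-base dinucleotide context of a read
#'
#' Context labels (previous sequenced base + current base) in sequencing
#' orientation: reverse-strand reads are reverse-complemented before the
#' lookup. The first sequenced base has no context (`NA`); `N` bases and
#' their successors carry no context either.
#'
#' @param sequence character string, the read sequence as stored in the
#'   alignment (reference-oriented).
#' @param strand `"+"` or `"-"`; for `"-"` the stored sequence is
#'   reverse-complemented to recover sequencing order.
#' @return character vector of context labels in sequencing order, `NA`
#'   where undefined.
#' @export
dinucleotide_context <- function(sequence, strand = "+") {
  v <- dna_int(sequence)
  if (identical(strand, "-")) v <- comp_int(rev(v))
  L <- length(v)
  if (L == 0L) return(character(0))
  prev <- c(NA_integer_, v[-L])
  idx <- (prev - 1L) * 4L + v
  out <- rep(NA_character_, L)
  ok <- !is.na(idx)
  out[ok] <- DINUCS[idx[ok]]
  out
}

# internal: covariate matrices for a read set against a reference.
# Contexts and error status are evaluated against the *reference* bases in
# sequencing orientation, so that errors are attributed to the context of
# the site being sequenced (see the methods vignette).
covariate_layout <- function(reads, ref) {
  fl <- ref_flat(ref)
  bad <- setdiff(reads$ref_ids[sort(unique(reads$rec))], fl$ids)
  if (length(bad)) stop_data("reads reference records absent from ref: ",
                             paste(bad, collapse = ", "))
  rec <- match(reads$ref_ids, fl$ids)[reads$rec]
  n <- nrow(reads$seq)
  L <- reads$read_len
  g <- fl$offset[rec] + reads$start
  IDX <- outer(g, 0:(L - 1L), "+") + 1L
  Bref <- matrix(fl$codes[IDX], n, L)
  Sref <- Bref
  if (any(reads$rev)) Sref[reads$rev, ] <- 5L - Bref[reads$rev, L:1, drop = FALSE]
  # IDX is reference-oriented; map each sequencing-order column to its
  # reference position
  IDXs <- IDX
  if (any(reads$rev)) IDXs[reads$rev, ] <- IDX[reads$rev, L:1, drop = FALSE]
  D <- cbind(NA_integer_, (Sref[, -L, drop = FALSE] - 1L) * 4L + Sref[, -1L, drop = FALSE])
  list(fl = fl, n = n, L = L, gpos = IDXs, Sref = Sref, D = D)
}

# global (1-based, concatenated) indices of masked sites
mask_index <- function(mask, fl) {
  if (is.null(mask) || nrow(mask) == 0L) return(integer())
  ri <- match(mask$id, fl$ids)
  if (anyNA(ri)) stop_data("mask references unknown ids: ",
                           paste(unique(mask$id[is.na(ri)]), collapse = ", "))
  if (any(mask$pos < 0L | mask$pos >= fl$lens[ri])) stop_data("mask positions out of range")
  fl$offset[ri] + mask$pos + 1L
}

#' Count recalibration covariates
#'
#' Builds the BQSR sufficient statistic: for every aligned non-`N` base at
#' an unmasked reference position, one observation is added to its
#' (read group, reported quality, machine cycle, dinucleotide) cell, and
#' one error iff the read base differs from the reference base. Machine
#' cycle is the 1-based position in sequencing order (negated for mate 2);
#' dinucleotide context is evaluated in sequencing orientation against the
#' reference sequence, so errors count toward the context of the site at
#' which they occurred.
#'
#' @param reads an `aligned_reads` object (or SAM path).
#' @param ref a `spike_ref`.
#' @param mask optional site set (data frame `id`, `pos` 0-based) to
#'   exclude, e.g. from [read_site_vcf()]; masked positions contribute
#'   nothing.
#' @return A `recal_table`: data frame with `read_group`, `q`, `cycle`,
#'   `dinuc` (a dinucleotide label or `"NA"` for the first cycle),
#'   `observations`, `errors`.
#' @export
count_covariates <- function(reads, ref, mask = NULL) {
  if (is.character(reads)) reads <- read_sam(reads, ref)
  cl <- covariate_layout(reads, ref)
  L <- cl$L
  cyc <- matrix(rep(seq_len(L), each = cl$n), cl$n, L)
  if (any(reads$mate == 2L)) cyc[reads$mate == 2L, ] <- -cyc[reads$mate == 2L, ]
  err <- reads$seq != cl$Sref
  keep <- !is.na(reads$seq)
  mi <- mask_index(mask, cl$fl)
  if (length(mi)) {
    mvec <- logical(length(cl$fl$codes))
    mvec[mi] <- TRUE
    keep <- keep & !matrix(mvec[cl$gpos], cl$n, L)
  }
  q <- reads$qual
  din <- cl$D
  din[is.na(din)] <- 17L
  # cell key: quality (2..41) x signed cycle x dinucleotide (+ "NA")
  cyc_idx <- ifelse(cyc > 0L, cyc + L, cyc + L + 1L)
  key <- (((q - 2L) * (2L * L) + (cyc_idx - 1L)) * 17L + din)
  nb <- 40L * 2L * L * 17L
  kv <- key[keep]
  obs <- tabulate(kv, nbins = nb)
  ev <- tabulate(key[keep & err], nbins = nb)
  nz <- which(obs > 0L)
  k0 <- nz - 1L
  din_i <- k0 %% 17L + 1L
  cyc_i <- (k0 %/% 17L) %% (2L * L) + 1L
  q_i <- k0 %/% (17L * 2L * L) + 2L
  out <- data.frame(
    read_group = reads$read_group %||% "RG1",
    q = as.integer(q_i),
    cycle = as.integer(ifelse(cyc_i > L, cyc_i - L, cyc_i - L - 1L)),
    dinuc = c(DINUCS, "NA")[din_i],
    observations = as.numeric(obs[nz]),
    errors = as.numeric(ev[nz]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$q, out$cycle, out$dinuc), ]
  rownames(out) <- NULL
  structure(out, class = c("recal_table", "data.frame"),
            n_masked = length(mi))
}

#' Merge recalibration tables cell-wise
#'
#' Recalibration tables are additive under dataset union; this sums the
#' observation and error counts of matching cells.
#'
#' @param ... `recal_table` objects.
#' @return A `recal_table`.
#' @export
merge_recal_tables <- function(...) {
  tabs <- list(...)
  x <- do.call(rbind, lapply(tabs, as.data.frame))
  key <- paste(x$read_group, x$q, x$cycle, x$dinuc, sep = "\r")
  obs <- rowsum(x$observations, key)
  err <- rowsum(x$errors, key)
  first <- x[!duplicated(key), c("read_group", "q", "cycle", "dinuc")]
  first <- first[match(rownames(obs), key[!duplicated(key)]), ]
  out <- data.frame(first, observations = as.numeric(obs),
                    errors = as.numeric(err), stringsAsFactors = FALSE)
  out <- out[order(out$q, out$cycle, out$dinuc), ]
  rownames(out) <- NULL
  structure(out, class = c("recal_table", "data.frame"))
}

#' Compute hierarchical recalibration deltas
#'
#' Decomposes the difference between empirical and reported qualities into
#' a global shift, a per-reported-quality shift, and parallel per-cycle
#' and per-dinucleotide corrections:
#' * `delta_global` = Qemp(all counts) - observation-weighted mean
#'   reported quality;
#' * `delta_qs[q]` = Qemp(q marginal) - q - `delta_global`;
#' * `delta_cycle[q, c]` = Qemp(q, c marginal) - q - `delta_global` -
#'   `delta_qs[q]`, and `delta_dinuc[q, d]` likewise.
#'
#' Cells with fewer than `min_observations` observations are marked as
#' missing (`NA`) and contribute no correction when applied.
#'
#' @param table a `recal_table` (read groups are pooled).
#' @param min_observations minimum observations per cell (default 100).
#' @return A `recal_deltas` object.
#' @export
compute_deltas <- function(table, min_observations = 100) {
  o <- table$observations
  e <- table$errors
  tot_o <- sum(o)
  if (tot_o <= 0) stop_data("recalibration table is empty")
  mean_q <- sum(o * table$q) / tot_o
  dg <- empirical_quality(sum(e), tot_o) - mean_q

  marg <- function(keys) {
    ob <- rowsum(o, keys)
    er <- rowsum(e, keys)
    data.frame(key = rownames(ob), observations = as.numeric(ob),
               errors = as.numeric(er), stringsAsFactors = FALSE)
  }

  qm <- marg(sprintf("%02d", table$q))
  qv <- as.integer(qm$key)
  dqs <- ifelse(qm$observations >= min_observations,
                empirical_quality(qm$errors, qm$observations) - qv - dg, NA_real_)
  names(dqs) <- as.character(qv)
  dqs_eff <- ifelse(is.na(dqs), 0, dqs)

  two_way <- function(second, levels2) {
    keys <- paste(sprintf("%02d", table$q), second, sep = "\r")
    m <- marg(keys)
    parts <- strsplit(m$key, "\r", fixed = TRUE)
    mq <- as.integer(vapply(parts, `[[`, character(1), 1L))
    ms <- vapply(parts, `[[`, character(1), 2L)
    d <- ifelse(m$observations >= min_observations,
                empirical_quality(m$errors, m$observations) - mq - dg -
                  dqs_eff[as.character(mq)], NA_real_)
    out <- matrix(NA_real_, length(qv), length(levels2),
                  dimnames = list(as.character(qv), levels2))
    out[cbind(match(as.character(mq), rownames(out)), match(ms, levels2))] <- d
    out
  }

  cyc_levels <- as.character(sort(unique(table$cycle)))
  dc <- two_way(as.character(table$cycle), cyc_levels)
  keep <- table$dinuc != "NA"
  dd <- matrix(NA_real_, length(qv), 16L, dimnames = list(as.character(qv), DINUCS))
  if (any(keep)) {
    sub <- table[keep, , drop = FALSE]
    keys <- paste(sprintf("%02d", sub$q), sub$dinuc, sep = "\r")
    ob <- rowsum(sub$observations, keys)
    er <- rowsum(sub$errors, keys)
    parts <- strsplit(rownames(ob), "\r", fixed = TRUE)
    mq <- as.integer(vapply(parts, `[[`, character(1), 1L))
    ms <- vapply(parts, `[[`, character(1), 2L)
    d <- ifelse(as.numeric(ob) >= min_observations,
                empirical_quality(as.numeric(er), as.numeric(ob)) - mq - dg -
                  dqs_eff[as.character(mq)], NA_real_)
    dd[cbind(match(as.character(mq), rownames(dd)), match(ms, DINUCS))] <- d
  }

  structure(list(
    global = dg, qs = dqs, cycle = dc, dinuc = dd,
    min_observations = min_observations, mean_reported = mean_q,
    empirical_all = empirical_quality(sum(e), tot_o)
  ), class = "recal_deltas")
}

#' @export
print.recal_deltas <- function(x, ...) {
  cat(sprintf(
    "<recal_deltas> global %+.3f (empirical %.2f vs mean reported %.2f); %d quality levels\n",
    x$global, x$empirical_all, x$mean_reported, length(x$qs)
  ))
  invisible(x)
}

# effective (NA -> 0) delta lookups used at application time
delta_lookup <- function(deltas, qchar, cyc = NULL, din = NULL) {
  dqs <- deltas$qs[qchar]
  dqs[is.na(dqs)] <- 0
  out <- deltas$global + dqs
  if (!is.null(cyc)) {
    dc <- deltas$cycle[cbind(match(qchar, rownames(deltas$cycle)),
                             match(as.character(cyc), colnames(deltas$cycle)))]
    dc[is.na(dc)] <- 0
    out <- out + dc
  }
  if (!is.null(din)) {
    dd <- deltas$dinuc[cbind(match(qchar, rownames(deltas$dinuc)),
                             match(din, colnames(deltas$dinuc)))]
    dd[is.na(dd)] <- 0
    out <- out + dd
  }
  unname(out)
}

#' Net recalibration shift for a covariate combination
#'
#' The total (unrounded) quality adjustment a base with the given
#' covariates would receive: global + per-quality + per-cycle +
#' per-dinucleotide deltas, with missing cells contributing zero.
#'
#' @param deltas a `recal_deltas` object.
#' @param q reported quality (vectorised).
#' @param cycle machine cycle, or `NULL` to omit the cycle term.
#' @param dinuc dinucleotide label, or `NULL` to omit the dinucleotide
#'   term.
#' @return numeric shift in Phred units.
#' @export
delta_shift <- function(deltas, q, cycle = NULL, dinuc = NULL) {
  delta_lookup(deltas, as.character(q), cycle, dinuc)
}

#' Apply recalibration deltas to reads
#'
#' Each base's new quality is `round(q + delta_global + delta_qs +
#' delta_cycle + delta_dinuc)` clamped to `[2, 60]`; bases without a
#' dinucleotide context (first cycle, `N` neighbourhood) skip the
#' dinucleotide term, and cells marked missing contribute zero. Contexts
#' are computed from the read bases (no reference is needed to apply a
#' recalibration).
#'
#' @param reads an `aligned_reads` object.
#' @param deltas a `recal_deltas` object.
#' @return the reads with recalibrated qualities.
#' @export
recalibrate_reads <- function(reads, deltas) {
  n <- nrow(reads$seq)
  L <- reads$read_len
  if (n == 0L) return(reads)
  S <- reads$seq
  D <- cbind(NA_integer_, (S[, -L, drop = FALSE] - 1L) * 4L + S[, -1L, drop = FALSE])
  din <- matrix(c(DINUCS, NA_character_)[ifelse(is.na(D), 17L, D)], n, L)
  cyc <- matrix(rep(seq_len(L), each = n), n, L)
  if (any(reads$mate == 2L)) cyc[reads$mate == 2L, ] <- -cyc[reads$mate == 2L, ]
  shift <- delta_lookup(deltas, as.character(reads$qual), cyc, din)
  newq <- pmin(pmax(round(reads$qual + shift), 2), 60)
  reads$qual <- matrix(as.integer(newq), n, L)
  reads
}

#' Write a recalibration table to TSV
#'
#' Columns `ReadGroup`, `RpQS`, `Cycle`, `Dinuc`, `Observations`,
#' `Errors`, `EmpiricalQ` (a GATK-v1-csv-like dialect, tab-separated).
#'
#' @param table a `recal_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_recal_table <- function(table, path) {
  out <- data.frame(
    ReadGroup = table$read_group, RpQS = table$q, Cycle = table$cycle,
    Dinuc = table$dinuc,
    Observations = format(table$observations, scientific = FALSE, trim = TRUE),
    Errors = format(table$errors, scientific = FALSE, trim = TRUE),
    EmpiricalQ = sprintf("%.4f", empirical_quality(table$errors, table$observations)),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a recalibration table written by [write_recal_table()]
#' @param path TSV path.
#' @return A `recal_table`.
#' @export
read_recal_table <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "",
                         colClasses = c(Dinuc = "character"))
  out <- data.frame(
    read_group = x$ReadGroup, q = as.integer(x$RpQS),
    cycle = as.integer(x$Cycle), dinuc = x$Dinuc,
    observations = as.numeric(x$Observations), errors = as.numeric(x$Errors),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("recal_table", "data.frame"))
}
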