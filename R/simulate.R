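#' Simulate aligned reads with known ground truth
#'
#' Draws substitution-only reads from a reference set: records are chosen
#' proportionally to pool weight times the number of eligible start
#' positions, start positions are uniform, strands equiprobable. Each base
#' receives an i.i.d. reported quality from the model's quality
#' distribution and is miscalled with the model's true error probability
#' for its (reported quality, cycle, sequencing-orientation dinucleotide,
#' site) combination; see [error_model()]. Reads over variant sites sample
#' the alternate allele with the variant's allele fraction - these bases
#' are biological, not errors, and are recorded separately in the truth
#' sidecar.
#'
#' Reads never span record boundaries and carry an all-match CIGAR; for
#' reverse-strand reads the sequenced bases are the reverse complement of
#' the reference slice, and dinucleotide context for error injection is
#' evaluated in sequencing orientation (previous sequenced base + current).
#'
#' @param ref a `spike_ref`.
#' @param n_reads number of reads.
#' @param model an `error_model`.
#' @param seed integer seed; fixed seeds reproduce the read set exactly.
#' @param pool optional `pool_profile` (default equimolar).
#' @param variants optional `variant_set` from [inject_variants()].
#' @param insert_only if `TRUE`, reads are confined to the insert spans.
#' @param read_group read group identifier stored with the reads.
#' @param site optional site-offset surface from [site_effects()]; by
#'   default it is derived from `(ref, model, seed)`, so repeated calls
#'   with one seed share their SSE sites.
#' @return An `aligned_reads` object. Fields: `rec` (record index),
#'   `start` (0-based leftmost reference position), `rev` (strand flag),
#'   `seq`/`qual` (integer matrices in sequencing orientation), and
#'   `truth`, a data frame with one row per injected error or sampled
#'   alternate allele (`read`, `cycle`, `ref_id`, `ref_pos`, `type`).
#' @export
simulate_reads <- function(ref, n_reads, model, seed, pool = NULL,
                           variants = NULL, insert_only = FALSE,
                           read_group = "RG1", site = NULL) {
  n_reads <- check_count(n_reads, "n_reads")
  stopifnot(inherits(ref, "spike_ref"), inherits(model, "error_model"))
  L <- model$read_len
  fl <- ref_flat(ref)
  r <- ref$records
  base_start <- if (insert_only) r$insert_start else rep(0L, nrow(r))
  span <- if (insert_only) r$insert_end - r$insert_start else r$length
  elig <- span - L + 1L
  if (any(elig < 1L)) {
    stop_invalid("read_len (", L, ") exceeds the shortest eligible span (", min(span), ")")
  }
  w <- if (is.null(pool)) rep(1, nrow(r)) else as.numeric(pool[r$id])
  if (anyNA(w)) stop_data("pool profile is missing some reference ids")
  w <- w * elig
  if (is.null(site)) site <- site_effects(ref, model, seed)

  with_seed(seed, {
    rec <- sample.int(nrow(r), n_reads, replace = TRUE, prob = w)
    start <- base_start[rec] + as.integer(floor(stats::runif(n_reads) * elig[rec]))
    rev <- stats::runif(n_reads) < 0.5
    g <- fl$offset[rec] + start # 0-based global leftmost

    IDX <- outer(g, 0:(L - 1L), "+") + 1L # 1-based into fl$codes
    B <- matrix(fl$codes[IDX], n_reads, L) # reference-oriented true bases

    Vmask <- NULL
    if (!is.null(variants) && nrow(variants) > 0L) {
      vlk <- integer(length(fl$codes))
      vg <- fl$offset[match(variants$id, fl$ids)] + variants$pos + 1L
      vlk[vg] <- seq_len(nrow(variants))
      vi <- matrix(vlk[IDX], n_reads, L)
      hit <- which(vi > 0L)
      if (length(hit)) {
        take <- hit[stats::runif(length(hit)) < variants$af[vi[hit]]]
        if (length(take)) {
          B[take] <- match(variants$alt, BASES)[vi[take]]
          Vmask <- matrix(FALSE, n_reads, L)
          Vmask[take] <- TRUE
        }
      }
    }

    # sequencing orientation: reverse-complement the reverse-strand rows
    S0 <- B
    if (any(rev)) S0[rev, ] <- 5L - B[rev, L:1, drop = FALSE]
    Vs <- Vmask
    if (!is.null(Vs) && any(rev)) Vs[rev, ] <- Vmask[rev, L:1, drop = FALSE]

    Q <- matrix(
      model$q_levels[sample.int(length(model$q_levels), n_reads * L,
                                replace = TRUE, prob = model$q_prob)],
      n_reads, L
    )

    D <- cbind(NA_integer_, (S0[, -L, drop = FALSE] - 1L) * 4L + S0[, -1L, drop = FALSE])
    off <- unname(model$qs_offset)[Q - 1L] + model$cycle_offset[col(Q)]
    doff <- unname(model$dinuc_offset)[D]
    doff[is.na(doff)] <- 0
    soff <- matrix(site[cbind(as.vector(IDX), rep(1L + rev, times = L))], n_reads, L)
    p <- 10^(-(Q + off + doff + soff) / 10)
    p[p > model$p_max] <- model$p_max

    err <- matrix(stats::runif(n_reads * L) < p, n_reads, L)
    S <- S0
    ei <- which(err)
    if (length(ei)) {
      b <- S0[ei]
      if (identical(model$substitution, "uniform")) {
        u <- sample.int(3L, length(ei), replace = TRUE)
      } else {
        u <- integer(length(ei))
        for (tb in 1:4) {
          sel <- b == tb
          if (!any(sel)) next
          pr <- model$substitution[tb, -tb]
          u[sel] <- sample.int(3L, sum(sel), replace = TRUE, prob = pr)
        }
      }
      S[ei] <- u + (u >= b)
    }

    truth <- truth_frame(err, Vs, rec, g, rev, fl, L)
    structure(list(
      ref_ids = fl$ids, rec = rec, start = start, rev = rev,
      mate = rep(1L, n_reads), seq = S, qual = Q,
      read_group = read_group, read_len = L, truth = truth
    ), class = "aligned_reads")
  })
}

# build the truth sidecar from error / variant masks (sequencing orientation)
truth_frame <- function(err, vmask, rec, g, rev, fl, L) {
  rows <- function(mask, type) {
    w <- which(mask, arr.ind = TRUE)
    if (nrow(w) == 0L) return(NULL)
    rd <- w[, 1]
    cyc <- w[, 2]
    gpos <- ifelse(rev[rd], g[rd] + L - cyc, g[rd] + cyc - 1L)
    ri <- rec[rd]
    data.frame(
      read = rd, cycle = as.integer(cyc), ref_id = fl$ids[ri],
      ref_pos = as.integer(gpos - fl$offset[ri]), type = type,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(rows(err, "error"), if (!is.null(vmask)) rows(vmask, "variant"))
  if (is.null(out)) {
    out <- data.frame(
      read = integer(), cycle = integer(), ref_id = character(),
      ref_pos = integer(), type = character(), stringsAsFactors = FALSE
    )
  }
  out[order(out$read, out$cycle), , drop = FALSE]
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat(sprintf(
    "<aligned_reads> %d reads x %d bp, %d truth records (%d errors)\n",
    nrow(x$seq), x$read_len, nrow(x$truth), sum(x$truth$type == "error")
  ))
  invisible(x)
}

#' Number of reads in an aligned read set
#' @param reads an `aligned_reads` object.
#' @return integer count.
#' @export
n_reads <- function(reads) nrow(reads$seq)

#' Subset an aligned read set
#'
#' @param reads an `aligned_reads` object.
#' @param idx integer or logical index of reads to keep.
#' @return the subsetted `aligned_reads` (truth sidecar re-indexed).
#' @export
subset_reads <- function(reads, idx) {
  if (is.logical(idx)) idx <- which(idx)
  keep <- reads
  for (f in c("rec", "start", "rev", "mate")) keep[[f]] <- reads[[f]][idx]
  keep$seq <- reads$seq[idx, , drop = FALSE]
  keep$qual <- reads$qual[idx, , drop = FALSE]
  tr <- reads$truth[reads$truth$read %in% idx, , drop = FALSE]
  tr$read <- match(tr$read, idx)
  rownames(tr) <- NULL
  keep$truth <- tr
  keep
}

# reference-oriented base and quality matrices
ref_oriented <- function(reads) {
  L <- reads$read_len
  R <- reads$seq
  Q <- reads$qual
  if (any(reads$rev)) {
    rv <- reads$rev
    R[rv, ] <- 5L - reads$seq[rv, L:1, drop = FALSE]
    # N (NA) complements stay NA automatically via arithmetic on NA
    Q[rv, ] <- reads$qual[rv, L:1, drop = FALSE]
  }
  list(bases = R, qual = Q)
}
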