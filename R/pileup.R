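#' Pile aligned reads into per-position base counts
#'
#' Collapses a read set into per-reference-position nucleotide counts
#' stratified by strand and quality tier. Every aligned A/C/G/T base is
#' counted once under the `all` tier and additionally under the `highQ`
#' tier iff its reported quality is at least `highq_threshold`; `N` bases
#' are skipped entirely. The strand is taken from the alignment flag.
#'
#' @param reads an `aligned_reads` object or a path to a SAM file.
#' @param ref a `spike_ref`.
#' @param highq_threshold Phred cutoff for the high-quality tier
#'   (default 30).
#' @return A `base_counts` object: array `counts[position, base, strand,
#'   tier]` over the concatenated reference, plus the reference layout and
#'   per-position reference bases.
#' @export
pileup <- function(reads, ref, highq_threshold = 30L) {
  if (is.character(reads)) reads <- read_sam(reads, ref)
  stopifnot(inherits(reads, "aligned_reads"), inherits(ref, "spike_ref"))
  fl <- ref_flat(ref)
  bad <- setdiff(reads$ref_ids[sort(unique(reads$rec))], fl$ids)
  if (length(bad)) stop_data("reads reference records absent from ref: ",
                             paste(bad, collapse = ", "))
  rec <- match(reads$ref_ids, fl$ids)[reads$rec]
  total <- sum(fl$lens)
  n <- nrow(reads$seq)
  L <- reads$read_len
  counts <- array(0L, dim = c(total, 4L, 2L, 2L),
                  dimnames = list(NULL, BASES, c("+", "-"), c("all", "highQ")))
  if (n > 0L) {
    ro <- ref_oriented(reads)
    g <- fl$offset[rec] + reads$start
    IDX <- outer(g, 0:(L - 1L), "+") + 1L
    strand <- matrix(1L + reads$rev, n, L)
    b <- as.vector(ro$bases)
    p <- as.vector(IDX)
    s <- as.vector(strand)
    hi <- as.vector(ro$qual) >= highq_threshold
    keep <- !is.na(b)
    key <- s[keep] + 2L * (b[keep] - 1L) + 8L * (p[keep] - 1L)
    tab_all <- tabulate(key, nbins = total * 8L)
    tab_hi <- tabulate(key[hi[keep]], nbins = total * 8L)
    counts[, , , 1L] <- aperm(array(tab_all, dim = c(2L, 4L, total)), c(3L, 2L, 1L))
    counts[, , , 2L] <- aperm(array(tab_hi, dim = c(2L, 4L, total)), c(3L, 2L, 1L))
  }
  structure(list(
    counts = counts, refbase = fl$codes, flat = fl,
    highq_threshold = as.integer(highq_threshold)
  ), class = "base_counts")
}

#' @export
print.base_counts <- function(x, ...) {
  d <- rowSums(x$counts[, , , 1L, drop = FALSE])
  cat(sprintf(
    "<base_counts> %d positions over %d records, mean depth %.1f (highQ threshold %d)\n",
    length(x$refbase), length(x$flat$ids), mean(d), x$highq_threshold
  ))
  invisible(x)
}

#' Add two pileups position-wise
#'
#' Pileup is additive: the pileup of concatenated read sets equals the
#' element-wise sum of the individual pileups.
#'
#' @param e1,e2 `base_counts` over the same reference and threshold.
#' @return A `base_counts`.
#' @export
`+.base_counts` <- function(e1, e2) {
  stopifnot(
    identical(e1$flat$ids, e2$flat$ids),
    identical(e1$flat$lens, e2$flat$lens),
    e1$highq_threshold == e2$highq_threshold
  )
  e1$counts <- e1$counts + e2$counts
  e1
}

#' Per-position depth of a pileup
#'
#' @param counts a `base_counts`.
#' @param tier `"all"` or `"highQ"`.
#' @return integer vector over the concatenated reference positions.
#' @export
pileup_depth <- function(counts, tier = c("all", "highQ")) {
  tier <- match.arg(tier)
  ti <- if (tier == "all") 1L else 2L
  as.integer(rowSums(counts$counts[, , , ti, drop = FALSE]))
}

#' @export
as.data.frame.base_counts <- function(x, ...) {
  fl <- x$flat
  pos1 <- unlist(lapply(fl$lens, seq_len), use.names = FALSE)
  out <- data.frame(
    ref_id = rep(fl$ids, fl$lens),
    pos = pos1, # 1-based in the external dump
    ref = BASES[x$refbase],
    depth = pileup_depth(x, "all"),
    stringsAsFactors = FALSE
  )
  for (ti in 1:2) {
    suff <- if (ti == 1L) "" else "_hq"
    for (s in 1:2) {
      for (b in 1:4) {
        out[[paste0(BASES[b], c("p", "m")[s], suff)]] <- x$counts[, b, s, ti]
      }
    }
  }
  out
}

#' Write a pileup to TSV
#' @param counts a `base_counts`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(counts, path) {
  utils::write.table(as.data.frame(counts), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
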