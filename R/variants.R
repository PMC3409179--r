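#' Inject biological variants into a reference set
#'
#' Chooses variant sites inside the insert spans, with CpG-context sites
#' (positions that are part of a CG dinucleotide on either strand,
#' emulating the hypermutability of methylated cytosines) up-weighted by
#' `cpg_multiplier`. Alternate alleles are transition-biased: a transition
#' is drawn with probability `titv / (titv + 1)`, otherwise one of the two
#' transversions equiprobably. Variants flagged `in_database` stand for
#' sites a SNP database would know about (and a recalibration mask would
#' exclude); the remainder are the unannotated variants that conventional
#' genome-trained recalibration mistakes for systematic errors.
#'
#' @param ref a `spike_ref`.
#' @param n_known number of database-annotated variants.
#' @param n_unknown number of unannotated variants.
#' @param cpg_multiplier sampling weight of CpG-context sites relative to
#'   other sites (>= 0).
#' @param allele_fractions numeric vector of candidate allele fractions in
#'   (0, 1]; each variant draws one uniformly (default `c(0.5, 1)`,
#'   heterozygous/homozygous).
#' @param titv transition/transversion ratio of the alternate alleles
#'   (default 2, the genome-wide mutation pattern).
#' @param seed integer seed.
#' @return A `variant_set`: data frame with `id`, `pos` (0-based), `ref`,
#'   `alt`, `af`, `in_database`.
#' @export
inject_variants <- function(ref, n_known = 0L, n_unknown = 0L,
                            cpg_multiplier = 1, allele_fractions = c(0.5, 1),
                            titv = 2, seed) {
  n_known <- check_count(n_known, "n_known", min = 0L)
  n_unknown <- check_count(n_unknown, "n_unknown", min = 0L)
  if (length(cpg_multiplier) != 1L || !is.numeric(cpg_multiplier) ||
      is.na(cpg_multiplier) || cpg_multiplier < 0) {
    stop_invalid("cpg_multiplier must be a single number >= 0")
  }
  if (any(allele_fractions <= 0 | allele_fractions > 1)) {
    stop_invalid("allele fractions must lie in (0, 1]")
  }
  if (titv <= 0) stop_invalid("titv must be > 0")
  n <- n_known + n_unknown
  empty <- data.frame(
    id = character(), pos = integer(), ref = character(), alt = character(),
    af = numeric(), in_database = logical(), stringsAsFactors = FALSE
  )
  if (n == 0L) return(structure(empty, class = c("variant_set", "data.frame")))

  fl <- ref_flat(ref)
  cand <- all_reference_positions(ref, insert_only = TRUE)
  gidx <- fl$offset[match(cand$id, fl$ids)] + cand$pos + 1L
  base <- fl$codes[gidx]
  prev <- fl$codes[pmax(gidx - 1L, 1L)]
  prev[cand$pos == 0L & match(cand$id, fl$ids) == 1L] <- NA_integer_
  nxt <- fl$codes[pmin(gidx + 1L, length(fl$codes))]
  # CpG context: current base part of a CG dinucleotide on either strand
  is_cpg <- (prev == 2L & base == 3L) | (base == 2L & nxt == 3L)
  is_cpg[is.na(is_cpg)] <- FALSE
  if (n > nrow(cand)) stop_invalid("more variants requested than candidate sites")

  with_seed(seed, {
    w <- ifelse(is_cpg, cpg_multiplier, 1)
    if (all(w == 0)) w <- rep(1, length(w))
    pick <- sample.int(nrow(cand), n, prob = w)
    b <- base[pick]
    transition <- stats::runif(n) < titv / (titv + 1)
    # transition partner: A<->G (1<->3), C<->T (2<->4)
    tr <- c(3L, 4L, 1L, 2L)[b]
    tv_choice <- stats::runif(n) < 0.5
    alt <- ifelse(transition, tr, NA_integer_)
    # transversion partners: the two bases that are neither ref nor transition
    for (i in which(!transition)) {
      others <- setdiff(1:4, c(b[i], tr[i]))
      alt[i] <- others[1 + tv_choice[i]]
    }
    af <- allele_fractions[sample.int(length(allele_fractions), n, replace = TRUE)]
    out <- data.frame(
      id = cand$id[pick], pos = cand$pos[pick],
      ref = BASES[b], alt = BASES[alt], af = af,
      in_database = rep(c(TRUE, FALSE), c(n_known, n_unknown)),
      stringsAsFactors = FALSE
    )
    out <- out[order(out$id, out$pos), ]
    rownames(out) <- NULL
    structure(out, class = c("variant_set", "data.frame"))
  })
}

#' Extract the database-annotated sites of a variant set as a mask
#'
#' @param variants a `variant_set`.
#' @return data frame `id`, `pos` of `in_database` sites (a site set
#'   usable as a recalibration mask).
#' @export
known_sites <- function(variants) {
  v <- variants[variants$in_database, c("id", "pos")]
  rownames(v) <- NULL
  v
}
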