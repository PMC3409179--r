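# Pre-packaged experiment drivers mirroring the package's study designs.
# They wire the generators, simulators and comparison statistics together
# so the same experiment can be run from tests, scripts and the vignette.

#' Ti/Tv of uniformly random sequencing errors
#'
#' Simulates reads carrying only uniform random substitution errors (each
#' wrong base equiprobable) at a fixed rate, piles them up and computes
#' the transition/transversion ratio of the nucleotide-change error
#' counts. Under uniform errors every reference base has one transition
#' and two transversion partners, so the expected Ti/Tv is 0.5.
#'
#' @param seed integer seed.
#' @param n_bases minimum number of aligned bases to simulate (default
#'   6e6, giving a Ti/Tv standard error well under 0.02 at the default
#'   error rate).
#' @param error_rate per-base error rate (default 1e-3, i.e. reported
#'   Q30 with a calibrated instrument).
#' @return list with `titv`, `n_bases`, `n_errors`.
#' @export
experiment_uniform_titv <- function(seed, n_bases = 6e6, error_rate = 1e-3) {
  q <- as.integer(round(-10 * log10(error_rate)))
  read_len <- 50L
  ref <- generate_reference(8, c(500L, 700L), vector_len = 0L,
                            gc_fraction = 0.5, seed = seed)
  model <- error_model(read_len = read_len, q_levels = q)
  n_reads <- ceiling(n_bases / read_len)
  reads <- simulate_reads(ref, n_reads, model, seed = seed + 1L)
  bc <- pileup(reads, ref, highq_threshold = 0L)
  ncr <- nucleotide_change_rates(bc, tier = "all")
  list(titv = ncr$titv, n_bases = n_reads * read_len,
       n_errors = sum(ncr$rates$count))
}

# the certified-base pool used by the large-scale table experiments:
# 96 vector-free standards, 50-base end skips, and a fixed-size sample of
# usable bases emulating the certified high-purity set
certified_positions <- function(seed, n_certified = 78950L) {
  ref <- generate_reference(96, c(273L, 1800L), vector_len = 0L,
                            gc_fraction = 0.5, seed = seed)
  usable <- all_reference_positions(ref, insert_only = TRUE)
  ie <- ref$records$insert_end[match(usable$id, ref$records$id)]
  usable <- usable[usable$pos >= 50L & usable$pos < ie - 50L, ]
  if (nrow(usable) > n_certified) {
    usable <- with_seed(seed + 1L, {
      usable[sort(sample.int(nrow(usable), n_certified)), ]
    })
  }
  rownames(usable) <- NULL
  list(ref = ref, positions = usable)
}

#' Split-half accuracy of recalibration tables at scale
#'
#' The split-half accuracy experiment: a 96-standard reference with a
#' certified high-purity base set, a miscalibrated Illumina-like error
#' model, and a count-level simulation of `n_reads` reads. The certified
#' bases are partitioned into two random halves, a recalibration table is
#' counted from each half, and the observation-weighted mean absolute
#' differences of empirical qualities are computed for the (RpQS),
#' (RpQS, cycle) and (RpQS, dinucleotide) aggregations.
#'
#' @param seed integer seed.
#' @param n_reads number of reads (default 5e6).
#' @param read_len read length (default 100).
#' @param n_certified size of the certified base set (default 78950).
#' @return list with `mads` (named: `q`, `cycle`, `dinuc`), `n_reads`,
#'   `n_certified`.
#' @export
experiment_split_half_mad <- function(seed, n_reads = 5e6, read_len = 100L,
                                      n_certified = 78950L) {
  cp <- certified_positions(seed, n_certified)
  model <- illumina_rnaseq_model(read_len = read_len)
  halves <- split_half_reference(cp$positions, 0.5, seed = seed + 2L)
  tabs <- simulate_count_tables(cp$ref, model, n_reads, seed = seed + 3L,
                                position_groups = list(A = halves$set_a,
                                                       B = halves$set_b))
  mads <- c(
    q = weighted_mad(tabs$A, tabs$B, "q")$mad,
    cycle = weighted_mad(tabs$A, tabs$B, c("q", "cycle"))$mad,
    dinuc = weighted_mad(tabs$A, tabs$B, c("q", "dinuc"))$mad
  )
  list(mads = mads, n_reads = n_reads, n_certified = nrow(cp$positions))
}

#' Recovery of injected covariate offsets
#'
#' Simulates reads under a model with a single injected covariate offset
#' (a dinucleotide offset on GG, and separately a cycle-band offset),
#' fits the recalibration model, and reports the net recalibration shift
#' of the affected cells, which should recover the injected offset.
#'
#' @param seed integer seed.
#' @param offset injected offset in Phred units (default -5).
#' @param n_reads reads per simulation (default 1.2e5 100-bp reads, i.e.
#'   at least 1e5 observations per affected cell).
#' @return list with `dinuc_recovered`, `cycle_recovered`, `offset`, and
#'   the affected observation counts.
#' @export
experiment_offset_recovery <- function(seed, offset = -5, n_reads = 120000L) {
  ref <- generate_reference(6, c(900L, 1100L), vector_len = 0L,
                            gc_fraction = 0.5, seed = seed)
  # dinucleotide offset on GG
  m1 <- error_model(read_len = 100L, q_levels = 30L,
                    dinuc_offset = c(GG = offset))
  r1 <- simulate_reads(ref, n_reads, m1, seed = seed + 1L)
  f1 <- bqsr(r1, ref)
  din_obs <- sum(f1$table$observations[f1$table$dinuc == "GG"])
  # cycle offset on a 20-cycle band
  co <- rep(0, 100)
  band <- 41:60
  co[band] <- offset
  m2 <- error_model(read_len = 100L, q_levels = 30L, cycle_offset = co)
  r2 <- simulate_reads(ref, n_reads, m2, seed = seed + 2L)
  f2 <- bqsr(r2, ref)
  cyc_tab <- f2$table[f2$table$cycle %in% band, ]
  cyc_obs <- sum(cyc_tab$observations)
  cyc_rec <- stats::weighted.mean(
    delta_shift(f2$deltas, rep(30L, length(band)), cycle = band),
    vapply(band, function(c) sum(f2$table$observations[f2$table$cycle == c]), 0)
  )
  list(
    dinuc_recovered = delta_shift(f1$deltas, 30L, dinuc = "GG"),
    cycle_recovered = cyc_rec,
    offset = offset,
    dinuc_observations = din_obs,
    cycle_observations = cyc_obs
  )
}

#' Reference-size versus coverage inflation of table differences
#'
#' The reference-shrinkage experiment: at a fixed read count, hide 90% of
#' the certified bases and compare the resulting recalibration table to
#' the full table; separately, keep all bases but only 10% of the reads
#' (the observation-matched coverage reduction). The inflation factor of
#' each aggregation is the ratio of the two mean absolute differences.
#' Dinucleotide cells partition the reference positions, so shrinking the
#' reference adds position-sampling error that coverage reduction does
#' not; cycle cells average over all positions and are insensitive to
#' which bases are visible.
#'
#' @param seed integer seed.
#' @param n_reads fixed read count (default 2e7 100-bp reads; the
#'   position-sampling term is depth-independent, so deeper data
#'   separates it more sharply from counting noise).
#' @param remove_fraction fraction of certified bases hidden
#'   (default 0.9).
#' @param n_certified certified pool size (default 78950).
#' @return list with `factor_cycle`, `factor_dinuc` and the four MADs.
#' @export
experiment_reference_size <- function(seed, n_reads = 2e7,
                                      remove_fraction = 0.9,
                                      n_certified = 78950L) {
  cp <- certified_positions(seed, n_certified)
  model <- illumina_rnaseq_model(read_len = 100L)
  pos <- cp$positions
  rm_idx <- with_seed(seed + 2L, {
    sample.int(nrow(pos), round(remove_fraction * nrow(pos)))
  })
  visible <- pos[-sort(rm_idx), ]
  hidden <- pos[sort(rm_idx), ]
  tabs <- simulate_count_tables(cp$ref, model, n_reads, seed = seed + 3L,
                                position_groups = list(v = visible, h = hidden))
  full_pos <- merge_recal_tables(tabs$v, tabs$h)
  tabs2 <- simulate_count_tables(
    cp$ref, model, n_reads, seed = seed + 4L,
    position_groups = list(all = pos),
    read_fractions = c(keep = 1 - remove_fraction, drop = remove_fraction)
  )
  full_reads <- merge_recal_tables(tabs2$all.keep, tabs2$all.drop)
  mad <- function(full, sub, by) weighted_mad(full, sub, by)$mad
  m <- list(
    ref_cycle = mad(full_pos, tabs$v, c("q", "cycle")),
    ref_dinuc = mad(full_pos, tabs$v, c("q", "dinuc")),
    reads_cycle = mad(full_reads, tabs2$all.keep, c("q", "cycle")),
    reads_dinuc = mad(full_reads, tabs2$all.keep, c("q", "dinuc"))
  )
  c(m, list(factor_cycle = m$ref_cycle / m$reads_cycle,
            factor_dinuc = m$ref_dinuc / m$reads_dinuc))
}

#' Genome-mode versus spike-in recalibration bias
#'
#' Simulates a "genome" carrying unannotated CpG-biased transition
#' variants alongside clean spike-in standards, recalibrates from each
#' (masking only the database-annotated variants in the genome), and
#' measures two directions: the mean difference of CG-dinucleotide
#' empirical qualities (genome minus spike-in, expected negative - CpG
#' variants masquerade as systematic errors) and the Ti/Tv of apparent
#' errors (expected higher in genome mode, since biological changes are
#' transition-biased).
#'
#' @param seed integer seed.
#' @param n_genome_reads,n_spike_reads 50-bp reads per compartment.
#' @param n_variants database-annotated and unannotated variant counts.
#' @param cpg_multiplier CpG-context weighting of variant sites.
#' @return list with `cg_diff` (mean CG cell difference, Phred units),
#'   `titv_genome`, `titv_spike`, `n_cg_cells`.
#' @export
experiment_genome_bias <- function(seed, n_genome_reads = 60000L,
                                   n_spike_reads = 20000L,
                                   n_variants = c(known = 150L, unknown = 150L),
                                   cpg_multiplier = 8) {
  genome <- generate_reference(20, c(2000L, 3000L), vector_len = 0L,
                               gc_fraction = 0.5, seed = seed)
  spike <- generate_reference(8, c(500L, 1000L), vector_len = 0L,
                              gc_fraction = 0.5, seed = seed + 1L)
  model <- illumina_rnaseq_model(read_len = 50L)
  vars <- inject_variants(genome, n_known = n_variants[["known"]],
                          n_unknown = n_variants[["unknown"]],
                          cpg_multiplier = cpg_multiplier, seed = seed + 2L)
  reads_g <- simulate_reads(genome, n_genome_reads, model, seed = seed + 3L,
                            variants = vars)
  reads_s <- simulate_reads(spike, n_spike_reads, model, seed = seed + 4L)
  dbsnp <- known_sites(vars)
  tg <- count_covariates(reads_g, genome, mask = dbsnp)
  ts <- count_covariates(reads_s, spike)
  ag <- aggregate_table(tg, c("q", "dinuc"))
  as <- aggregate_table(ts, c("q", "dinuc"))
  key <- function(x) paste(x$q, x$dinuc)
  m <- match(key(ag), key(as))
  ok <- !is.na(m) & ag$observations >= 100 & as$observations[m] >= 100 &
    ag$dinuc == "CG"
  cg_diff <- mean(ag$empirical_q[ok] - as$empirical_q[m][ok])
  titv_g <- nucleotide_change_rates(pileup(reads_g, genome, 30L),
                                    exclude = dbsnp)$titv
  titv_s <- nucleotide_change_rates(pileup(reads_s, spike, 30L))$titv
  list(cg_diff = cg_diff, titv_genome = titv_g, titv_spike = titv_s,
       n_cg_cells = sum(ok))
}
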