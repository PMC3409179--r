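#' Default run configuration
#'
#' @return named list of defaults (seeds per stage, thresholds, sizes)
#'   accepted by [run_workflow()].
#' @export
default_run_config <- function() {
  list(
    outdir = "spikecal_run",
    seed_reference = 1L, seed_pool = 2L, seed_reads = 3L, seed_split = 4L,
    n_inserts = 6L, insert_len_range = c(273L, 500L), vector_len = 150L,
    gc_fraction = 0.5, pool_mode = "equimolar", pool_span = 1e6,
    read_len = 50L, n_reads = 120000L,
    theta = 0.99, confidence = 0.95, end_skip = 20L, polyA_min_run = 6L,
    highq_threshold = 30L, min_observations = 100L,
    workflow = c("purity", "recal", "compare")
  )
}

#' Read and validate a YAML run configuration
#'
#' @param path YAML file; keys override [default_run_config()].
#' @return validated config list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), user)
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  if (cfg$theta <= 0 || cfg$theta >= 1) stop_invalid("theta must be in (0, 1)")
  if (cfg$confidence <= 0 || cfg$confidence >= 1) stop_invalid("confidence must be in (0, 1)")
  if (cfg$highq_threshold < 0 || cfg$highq_threshold > 60) {
    stop_invalid("highq_threshold must be in [0, 60]")
  }
  if (!all(cfg$workflow %in% c("purity", "recal", "compare"))) {
    stop_invalid("workflow stages must be among purity, recal, compare")
  }
  for (s in grep("^seed_", names(cfg), value = TRUE)) {
    if (is.null(cfg[[s]])) stop_invalid("every stochastic stage needs a seed: missing ", s)
  }
  cfg
}

#' Run the spike-in recalibration workflow end to end
#'
#' Executes the configured stages in dependency order - reference and
#' pool generation, read simulation, pileup, purity certification with
#' exclusion VCF, split-half BQSR and table comparison - writing every
#' artifact under `config$outdir` and hashing each output file into a
#' machine-readable summary (`summary.json`). Re-running with the same
#' configuration reproduces identical hashes.
#'
#' @param config a config list (see [default_run_config()]) or the path
#'   to a YAML file.
#' @return the summary list, invisibly.
#' @export
run_workflow <- function(config = default_run_config()) {
  cfg <- if (is.character(config)) read_run_config(config) else
    validate_run_config(utils::modifyList(default_run_config(), config))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(cfg$outdir, f)
  artifacts <- character()

  ref <- generate_reference(cfg$n_inserts, cfg$insert_len_range, cfg$vector_len,
                            cfg$gc_fraction, seed = cfg$seed_reference)
  pool <- assign_concentrations(ref, cfg$pool_mode, span = cfg$pool_span,
                                seed = cfg$seed_pool)
  write_fasta(ref, pth("ref.fa"), pool = pool)
  artifacts <- c(artifacts, pth("ref.fa"), pth("ref.fa.manifest.tsv"))

  model <- illumina_rnaseq_model(read_len = cfg$read_len)
  reads <- simulate_reads(ref, cfg$n_reads, model, seed = cfg$seed_reads,
                          pool = pool)
  write_sam(reads, ref, pth("reads.sam"))
  artifacts <- c(artifacts, pth("reads.sam"))
  bc <- pileup(reads, ref, highq_threshold = cfg$highq_threshold)

  summary <- list(config = cfg)
  mask <- NULL
  if ("purity" %in% cfg$workflow) {
    calls <- classify_bases(list(sim = bc), ref, theta = cfg$theta,
                            confidence = cfg$confidence,
                            end_skip = cfg$end_skip,
                            polyA_min_run = cfg$polyA_min_run)
    write_exclusion_vcf(calls, pth("excluded.vcf"))
    artifacts <- c(artifacts, pth("excluded.vcf"))
    mask <- read_site_vcf(pth("excluded.vcf"))[, c("id", "pos")]
    summary$purity <- as.list(table(calls$verdict))
  }
  fit <- NULL
  if ("recal" %in% cfg$workflow) {
    fit <- bqsr(reads, ref, mask = mask,
                min_observations = cfg$min_observations)
    write_recal_table(fit$table, pth("recal_table.tsv"))
    artifacts <- c(artifacts, pth("recal_table.tsv"))
    summary$recal <- list(
      observations = fit$n_observations, errors = fit$n_errors,
      global_delta = fit$deltas$global
    )
  }
  if ("compare" %in% cfg$workflow) {
    visible <- if (is.null(mask)) all_reference_positions(ref, insert_only = TRUE) else {
      ap <- all_reference_positions(ref)
      ap[!paste(ap$id, ap$pos) %in% paste(mask$id, mask$pos), ]
    }
    halves <- split_half_reference(visible, seed = cfg$seed_split,
                                   all_positions = all_reference_positions(ref))
    ta <- count_covariates(reads, ref, mask = halves$mask_a)
    tb <- count_covariates(reads, ref, mask = halves$mask_b)
    write_recal_table(ta, pth("recal_table_A.tsv"))
    write_recal_table(tb, pth("recal_table_B.tsv"))
    artifacts <- c(artifacts, pth("recal_table_A.tsv"), pth("recal_table_B.tsv"))
    summary$compare <- list(
      mad_q = weighted_mad(ta, tb, "q", cfg$min_observations)$mad,
      mad_cycle = weighted_mad(ta, tb, c("q", "cycle"), cfg$min_observations)$mad,
      mad_dinuc = weighted_mad(ta, tb, c("q", "dinuc"), cfg$min_observations)$mad
    )
  }

  summary$artifacts <- as.list(tools::md5sum(artifacts))
  jsonlite::write_json(summary, pth("summary.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(summary)
}

#' Small bundled demonstration dataset
#'
#' Generates, in memory and in a few seconds, a compact dataset
#' exercising the whole stack: a reference set with a miscalibrated
#' error model, injected known and unknown variants, simulated reads
#' with truth sidecar, a pileup, and the purity calls. Used throughout
#' the examples and the test suite.
#'
#' @param seed integer seed; the fixture regenerates bit-identically.
#' @return list with `ref`, `pool`, `model`, `variants`, `reads`,
#'   `pileup`, `calls`.
#' @export
demo_fixture <- function(seed = 1L) {
  # coverage ~1800x: purity certification needs depth well beyond the
  # minimal confident coverage, as in real spike-in designs
  ref <- generate_reference(4, c(250L, 400L), vector_len = 100L,
                            gc_fraction = 0.5, seed = seed)
  pool <- assign_concentrations(ref, "equimolar")
  model <- illumina_rnaseq_model(read_len = 50L)
  variants <- inject_variants(ref, n_known = 4L, n_unknown = 4L,
                              cpg_multiplier = 10, seed = seed + 1L)
  reads <- simulate_reads(ref, 60000L, model, seed = seed + 2L, pool = pool,
                          variants = variants)
  bc <- pileup(reads, ref, highq_threshold = 30L)
  calls <- classify_bases(list(sim = bc), ref, end_skip = 20L)
  list(ref = ref, pool = pool, model = model, variants = variants,
       reads = reads, pileup = bc, calls = calls)
}
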