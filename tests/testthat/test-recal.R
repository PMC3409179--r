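test_that("empirical quality implements smoothed Phred with a cap", {
  expect_equal(empirical_quality(0, 0), -10 * log10(1 / 2), tolerance = 1e-6)
  expect_equal(empirical_quality(1, 998), -10 * log10(2 / 1000), tolerance = 1e-6)
  expect_equal(empirical_quality(98, 98), -10 * log10(99 / 100), tolerance = 1e-6)
  expect_equal(empirical_quality(0, 1e8), 60) # cap
  expect_error(empirical_quality(2, 1), class = "spikecal_invalid_parameter")
  expect_error(empirical_quality(-1, 5), class = "spikecal_invalid_parameter")
})

test_that("dinucleotide context follows sequencing orientation and N policy", {
  expect_equal(dinucleotide_context("ACGG"), c(NA, "AC", "CG", "GG"))
  # stored "CCGT" on the minus strand was sequenced as ACGG
  expect_equal(dinucleotide_context("CCGT", strand = "-"),
               c(NA, "AC", "CG", "GG"))
  # N bases and their successors carry no context
  expect_equal(dinucleotide_context("ANGT"), c(NA, NA, NA, "GT"))
  expect_equal(dinucleotide_context(""), character(0))
})

test_that("covariate counting attributes observations and errors to cells", {
  ref <- tiny_ref(1, c(100, 100), seed = 81)
  seq4 <- ref_substr(ref, 1, 0, 4)
  rd <- manual_read(ref, seq4, qual = rep(40, 4))
  tab <- count_covariates(rd, ref)
  expect_s3_class(tab, "recal_table")
  expect_equal(sum(tab$observations), 4)
  expect_equal(sum(tab$errors), 0)
  expect_equal(sort(tab$cycle), 1:4)
  expect_equal(tab$dinuc[tab$cycle == 1], "NA")

  # a mismatch at cycle 3 becomes one error in that cell
  v <- spikecal:::dna_int(seq4)
  v[3] <- v[3] %% 4L + 1L
  rd2 <- manual_read(ref, spikecal:::int_dna(v), qual = rep(40, 4))
  tab2 <- count_covariates(rd2, ref)
  expect_equal(sum(tab2$errors), 1)
  expect_equal(tab2$errors[tab2$cycle == 3], 1)
  # context of the error cell comes from the reference, not the read
  expect_equal(tab2$dinuc[tab2$cycle == 3], dinucleotide_context(seq4)[3])

  # masking the position removes both observation and error
  mask <- data.frame(id = ref$records$id, pos = 2L)
  tab3 <- count_covariates(rd2, ref, mask = mask)
  expect_equal(sum(tab3$observations), 3)
  expect_equal(sum(tab3$errors), 0)
})

test_that("table error totals match the truth sidecar at unmasked positions", {
  ref <- tiny_ref(3, c(400, 500), seed = 82)
  model <- illumina_rnaseq_model(read_len = 50)
  reads <- simulate_reads(ref, 1500, model, seed = 83)
  tab <- count_covariates(reads, ref)
  expect_equal(sum(tab$errors), sum(reads$truth$type == "error"))
  expect_equal(sum(tab$observations), 1500 * 50)

  # masking monotonicity: adding mask sites never increases any cell
  mask <- all_reference_positions(ref)[seq(1, 600, by = 3), ]
  tm <- count_covariates(reads, ref, mask = mask)
  key <- function(t) paste(t$q, t$cycle, t$dinuc)
  m <- match(key(tm), key(tab))
  expect_true(all(!is.na(m)))
  expect_true(all(tm$observations <= tab$observations[m]))
  expect_true(all(tm$errors <= tab$errors[m]))
})

test_that("recal tables are additive under dataset union", {
  ref <- tiny_ref()
  model <- illumina_rnaseq_model(read_len = 50)
  a <- simulate_reads(ref, 400, model, seed = 84)
  b <- simulate_reads(ref, 300, model, seed = 85)
  ta <- count_covariates(a, ref)
  tb <- count_covariates(b, ref)
  merged <- merge_recal_tables(ta, tb)
  # pileup-level union: concatenate reads
  ab <- subset_reads(a, seq_len(400))
  comb <- list(
    ref_ids = a$ref_ids, rec = c(a$rec, b$rec), start = c(a$start, b$start),
    rev = c(a$rev, b$rev), mate = c(a$mate, b$mate),
    seq = rbind(a$seq, b$seq), qual = rbind(a$qual, b$qual),
    read_group = "RG1", read_len = 50L, truth = a$truth
  )
  class(comb) <- "aligned_reads"
  tu <- count_covariates(comb, ref)
  key <- function(t) paste(t$q, t$cycle, t$dinuc)
  m <- match(key(tu), key(merged))
  expect_true(all(!is.na(m)))
  expect_equal(tu$observations, merged$observations[m])
  expect_equal(tu$errors, merged$errors[m])
})

test_that("delta decomposition reproduces a single dominant cell", {
  tab <- structure(data.frame(
    read_group = "RG1", q = 30L, cycle = 5L, dinuc = "AC",
    observations = 1e6, errors = 1e3, stringsAsFactors = FALSE
  ), class = c("recal_table", "data.frame"))
  d <- compute_deltas(tab)
  expect_equal(d$empirical_all, 30, tolerance = 1e-2)
  expect_equal(d$global, 0, tolerance = 1e-2)
  expect_equal(unname(d$qs["30"]), 0, tolerance = 1e-2)
  expect_equal(d$cycle["30", "5"], 0, tolerance = 1e-2)
  expect_equal(d$dinuc["30", "AC"], 0, tolerance = 1e-2)
})

test_that("calibrated data yields near-zero deltas and a stable round-trip", {
  # single reported quality, error rate high enough that every cell is
  # densely populated: all delta components should vanish
  ref <- tiny_ref(4, c(500, 600), seed = 86)
  model <- error_model(read_len = 50, q_levels = 13)
  reads <- simulate_reads(ref, 30000, model, seed = 87)
  fit <- bqsr(reads, ref)
  d <- fit$deltas
  expect_lt(abs(d$global), 0.2)
  expect_true(all(abs(d$qs) < 0.2, na.rm = TRUE))
  wrms <- function(delta, margin) {
    ag <- aggregate_table(fit$table, c("q", margin))
    key <- paste(ag$q, ag[[margin]])
    dk <- delta[cbind(match(as.character(ag$q), rownames(delta)),
                      match(as.character(ag[[margin]]), colnames(delta)))]
    sqrt(sum(ag$observations * dk^2, na.rm = TRUE) /
           sum(ag$observations[!is.na(dk)]))
  }
  expect_lt(wrms(d$cycle, "cycle"), 0.3)
  expect_lt(wrms(d$dinuc, "dinuc"), 0.3)
  # round-trip: recalibration changes the obs-weighted mean quality < 0.2
  recal <- predict(fit, reads)
  expect_lt(abs(mean(recal$qual) - mean(reads$qual)), 0.2)
})

test_that("per-quality deltas compensate the global Phred-mixture offset", {
  # with mixed reported qualities the global delta is non-zero even for a
  # calibrated instrument (the Phred of an average error rate is not the
  # average of the Phreds); the per-quality deltas must absorb it so the
  # net shift at every quality is ~0
  ref <- tiny_ref(4, c(500, 600), seed = 86)
  model <- error_model(read_len = 50, q_levels = c(13, 16, 19),
                       q_prob = c(0.3, 0.4, 0.3))
  reads <- simulate_reads(ref, 30000, model, seed = 88)
  d <- compute_deltas(count_covariates(reads, ref))
  expect_gt(abs(d$global), 0.5) # the mixture offset is real ...
  net <- delta_shift(d, c(13, 16, 19))
  expect_lt(max(abs(net)), 0.15) # ... and fully compensated per quality
})

test_that("recalibration arithmetic, clamping and NA-context handling", {
  d <- structure(list(
    global = 1, qs = c("30" = -3),
    cycle = matrix(0.5, 1, 1, dimnames = list("30", "2")),
    dinuc = matrix(-0.5, 1, 16, dimnames = list("30", spikecal:::DINUCS)),
    min_observations = 0, mean_reported = 30, empirical_all = 28
  ), class = "recal_deltas")
  ref <- tiny_ref(1, c(100, 100), seed = 88)
  rd <- manual_read(ref, ref_substr(ref, 1, 0, 2), qual = c(30, 30))
  out <- recalibrate_reads(rd, d)
  # cycle 1: no dinuc term, no cycle cell ("1" absent -> 0): 30+1-3 = 28
  expect_equal(out$qual[1, 1], 28L)
  # cycle 2: 30+1-3+0.5-0.5 = 28
  expect_equal(out$qual[1, 2], 28L)

  # all deltas zero -> unchanged
  d0 <- structure(list(
    global = 0, qs = c("30" = 0),
    cycle = matrix(0, 1, 1, dimnames = list("30", "1")),
    dinuc = matrix(0, 1, 16, dimnames = list("30", spikecal:::DINUCS)),
    min_observations = 0, mean_reported = 30, empirical_all = 30
  ), class = "recal_deltas")
  expect_equal(recalibrate_reads(rd, d0)$qual, rd$qual)

  # clamp at the floor
  dneg <- d0
  dneg$global <- -10
  rd4 <- manual_read(ref, ref_substr(ref, 1, 0, 2), qual = c(4, 4))
  expect_equal(unique(as.integer(recalibrate_reads(rd4, dneg)$qual)), 2L)
  # delta_shift exposes the same arithmetic pre-rounding
  expect_equal(delta_shift(d, 30, cycle = 2, dinuc = "AA"), -2)
})

test_that("injected covariate offsets are recovered by the delta chain", {
  ref <- tiny_ref(4, c(900, 1100), seed = 89)
  model <- error_model(read_len = 50, q_levels = 30, dinuc_offset = c(GG = -5))
  reads <- simulate_reads(ref, 60000, model, seed = 90)
  fit <- bqsr(reads, ref)
  expect_equal(delta_shift(coef(fit), 30, dinuc = "GG"), -5, tolerance = 0.3)
  others <- setdiff(spikecal:::DINUCS, "GG")
  sh <- vapply(others, function(x) delta_shift(coef(fit), 30, dinuc = x), 0)
  expect_lt(mean(abs(sh)), 0.25)
  expect_lt(max(abs(sh)), 1)
})

test_that("recal table TSV round-trips", {
  fx <- demo_fixture(seed = 6)
  tab <- count_covariates(fx$reads, fx$ref)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_recal_table(tab, f)
  back <- read_recal_table(f)
  expect_equal(back$q, tab$q)
  expect_equal(back$cycle, tab$cycle)
  expect_equal(back$dinuc, tab$dinuc)
  expect_equal(back$observations, tab$observations)
  expect_equal(back$errors, tab$errors)
})

test_that("bqsr model object supports the standard verbs", {
  fx <- demo_fixture(seed = 7)
  mask <- fx$calls[fx$calls$verdict != "high_purity", c("id", "pos")]
  fit <- bqsr(fx$reads, fx$ref, mask = mask)
  expect_s3_class(fit, "bqsr")
  expect_output(print(fit), "recalibration")
  expect_output(print(summary(fit)), "dinucleotide")
  expect_s3_class(coef(fit), "recal_deltas")
  # residuals need dense full cells: use a concentrated-quality fit
  refr <- tiny_ref(3, c(500, 600), seed = 91)
  rdr <- simulate_reads(refr, 20000, error_model(read_len = 50, q_levels = 30),
                        seed = 92)
  fitr <- bqsr(rdr, refr)
  res <- residuals(fitr)
  expect_true(is.numeric(res) && length(res) > 0)
  expect_lt(abs(stats::median(res)), 5)
  recal <- predict(fit, fx$reads)
  expect_true(all(recal$qual >= 2 & recal$qual <= 60))
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f)
  expect_no_error(plot(fitr))
  grDevices::dev.off()
})
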