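make_table <- function(df) {
  df$read_group <- df$read_group %||% "RG1"
  structure(as.data.frame(df), class = c("recal_table", "data.frame"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("aggregation sums counts and recomputes empirical quality", {
  tab <- make_table(data.frame(
    q = c(30L, 30L), cycle = c(1L, 2L), dinuc = c("AA", "AC"),
    observations = c(100, 300), errors = c(1, 3)
  ))
  one <- aggregate_table(tab, c("q", "cycle", "dinuc"))
  expect_equal(nrow(one), 2)
  agg <- aggregate_table(tab, "q")
  expect_equal(agg$observations, 400)
  expect_equal(agg$errors, 4)
  expect_equal(agg$empirical_q, empirical_quality(4, 400))

  # aggregation commutes with table addition
  tb <- make_table(data.frame(
    q = 30L, cycle = 2L, dinuc = "AC", observations = 50, errors = 2
  ))
  left <- aggregate_table(merge_recal_tables(tab, tb), "q")
  right <- merge_recal_tables(tab, tb)
  expect_equal(left$observations, sum(right$observations))
  expect_equal(left$errors, sum(right$errors))
})

test_that("weighted MAD matches hand arithmetic and its identities", {
  ta <- make_table(data.frame(
    q = c(30L, 35L), cycle = 1L, dinuc = c("AA", "AA"),
    observations = c(4000, 1000), errors = c(4, 1)
  ))
  expect_equal(weighted_mad(ta, ta, "q")$mad, 0)
  # construct diffs of 2 (w 4) and 1 (w 1): solve for errors giving exact
  # empirical quality differences is awkward; instead check the weighting
  # formula on synthetic empirical qualities via a two-cell example
  tb <- make_table(data.frame(
    q = c(30L, 35L), cycle = 1L, dinuc = c("AA", "AA"),
    observations = c(4000, 1000), errors = c(4 * 10^(2 / 10) + 3, 10^(1 / 10) * 2 - 1)
  ))
  w <- weighted_mad(ta, tb, "q", min_observations = 100)
  manual <- sum(c(4000, 1000) * abs(
    empirical_quality(ta$errors, ta$observations) -
      empirical_quality(tb$errors, tb$observations)
  )) / 5000
  expect_equal(w$mad, manual)
  expect_equal(w$n_cells, 2)

  # triangle-like bound with weights taken from A throughout
  tc <- make_table(data.frame(
    q = c(30L, 35L), cycle = 1L, dinuc = c("AA", "AA"),
    observations = c(4000, 1000), errors = c(12, 5)
  ))
  qa <- empirical_quality(ta$errors, ta$observations)
  qb <- empirical_quality(tb$errors, tb$observations)
  qc <- empirical_quality(tc$errors, tc$observations)
  wgt <- ta$observations / sum(ta$observations)
  expect_lte(sum(wgt * abs(qa - qc)),
             sum(wgt * abs(qa - qb)) + sum(wgt * abs(qb - qc)) + 1e-12)
})

test_that("split halves partition the positions and are reproducible", {
  pos <- all_reference_positions(tiny_ref(2, c(200, 300), seed = 93),
                                 insert_only = TRUE)
  h <- split_half_reference(pos, 0.5, seed = 7)
  key <- function(d) paste(d$id, d$pos)
  expect_equal(sort(c(key(h$set_a), key(h$set_b))), sort(key(pos)))
  expect_length(intersect(key(h$set_a), key(h$set_b)), 0)
  # masks hide exactly the opposite half
  expect_setequal(key(h$mask_a), key(h$set_b))
  h2 <- split_half_reference(pos, 0.5, seed = 7)
  expect_identical(h, h2)
  expect_error(split_half_reference(pos, 1, seed = 1),
               class = "spikecal_invalid_parameter")
})

test_that("read downsampling is Bernoulli thinning", {
  ref <- tiny_ref()
  model <- error_model(read_len = 50, q_levels = 30)
  reads <- simulate_reads(ref, 3000, model, seed = 94)
  expect_identical(downsample_reads(reads, 1, seed = 1), reads)
  none <- downsample_reads(reads, 0, seed = 1)
  expect_equal(n_reads(none), 0)
  third <- downsample_reads(reads, 1 / 3, seed = 95)
  ci <- binom_ci99(3000, 1 / 3)
  expect_gte(n_reads(third), ci[1])
  expect_lte(n_reads(third), ci[2])
  # kept reads unmodified
  expect_true(all(third$seq %in% 1:4))
})

test_that("reference-base removal augments masks disjointly", {
  pos <- all_reference_positions(tiny_ref(2, c(300, 400), seed = 96))
  base_mask <- pos[1:10, ]
  same <- remove_reference_bases(pos[-(1:10), ], 0, seed = 1, mask = base_mask)
  expect_equal(nrow(same), 10)
  aug <- remove_reference_bases(pos[-(1:10), ], 0.9, seed = 2, mask = base_mask)
  expect_equal(nrow(aug), 10 + round(0.9 * (nrow(pos) - 10)))
  expect_false(any(duplicated(paste(aug$id, aug$pos))))
})

test_that("nucleotide-change rates match direct arithmetic", {
  ref <- tiny_ref(1, c(100, 100), seed = 97)
  # find a reference-A position and fabricate counts there
  model <- error_model(read_len = 50, q_levels = 40, p_max = 1e-12)
  bc <- pileup(simulate_reads(ref, 10, model, seed = 98), ref)
  bc$counts[] <- 0L
  apos <- which(bc$refbase == 1L)[1]
  bc$counts[apos, 1, 1, ] <- 990L
  bc$counts[apos, 3, 1, ] <- 5L
  bc$counts[apos, 2, 1, ] <- 3L
  bc$counts[apos, 4, 1, ] <- 2L
  ncr <- nucleotide_change_rates(bc, tier = "highQ")
  r <- ncr$rates
  expect_equal(r$rate[r$from == "A" & r$to == "G"], 0.005)
  expect_equal(r$rate[r$from == "A" & r$to == "C"], 0.003)
  expect_equal(r$rate[r$from == "A" & r$to == "T"], 0.002)
  expect_equal(ncr$titv, 5 / 5)

  # excluding the position empties the table
  excl <- data.frame(id = ref$records$id, pos = apos - 1L)
  ncr2 <- nucleotide_change_rates(bc, exclude = excl)
  expect_true(all(ncr2$rates$count == 0))
})

test_that("uniform errors give Ti/Tv 0.5 and biased variants raise it", {
  ref <- tiny_ref(4, c(500, 600), seed = 99)
  model <- error_model(read_len = 50, q_levels = 30)
  reads <- simulate_reads(ref, 60000, model, seed = 100)
  bc <- pileup(reads, ref, highq_threshold = 0)
  ncr <- nucleotide_change_rates(bc, tier = "all")
  expect_equal(ncr$titv, 0.5, tolerance = 0.1)

  vars <- inject_variants(ref, n_unknown = 40, titv = 4, seed = 101)
  rv <- simulate_reads(ref, 25000, model, seed = 102, variants = vars)
  bv <- pileup(rv, ref, highq_threshold = 0)
  ncrv <- nucleotide_change_rates(bv, tier = "all")
  expect_gt(ncrv$titv, 2)
})

test_that("paired rate comparison matches the textbook pooled t", {
  set.seed(103)
  base <- expand.grid(from = c("A", "C", "G", "T"), to = c("A", "C", "G", "T"),
                      stringsAsFactors = FALSE)
  base <- base[base$from != base$to, ]
  mk <- function(rates) {
    d <- base
    d$rate <- rates
    d
  }
  n <- 4
  ra <- lapply(seq_len(n), function(i) mk(0.002 + rnorm(12, 0, 2e-4)))
  rb <- lapply(seq_len(n), function(i) mk(0.001 + rnorm(12, 0, 2e-4)))
  res <- compare_rates(ra, rb)
  # oracle for one change with the pooled SD
  d <- sapply(seq_len(n), function(j) ra[[j]]$rate - rb[[j]]$rate)
  sp <- sqrt(sum((d - rowMeans(d))^2) / (12 * (n - 1)))
  t1 <- rowMeans(d)[1] / (sp / sqrt(n))
  expect_equal(res$t[1], t1)
  expect_equal(res$df[1], 12 * (n - 1))
  expect_equal(res$p_adj, pmin(1, 12 * res$p))

  # identical tables: t = 0, adjusted p = 1, flagged degenerate
  same <- compare_rates(ra, ra)
  expect_true(all(same$t == 0))
  expect_true(all(same$p_adj == 1))
  expect_true(all(same$degenerate))

  # constant shift with zero within-pair variance: degenerate, p -> 0
  shifted <- lapply(ra, function(x) mk(x$rate + 1e-3))
  res2 <- compare_rates(shifted, ra)
  expect_true(all(res2$degenerate))
  expect_true(all(res2$p == 0))
})

test_that("cell significance separates unequal error proportions", {
  ta <- make_table(data.frame(
    q = c(30L, 30L), cycle = c(1L, 1L), dinuc = c("AA", "AC"),
    observations = c(1000, 1000), errors = c(10, 10)
  ))
  tb <- make_table(data.frame(
    q = c(30L, 30L), cycle = c(1L, 1L), dinuc = c("AA", "AC"),
    observations = c(1000, 1000), errors = c(100, 10)
  ))
  res <- cell_significance(ta, tb, by = c("q", "dinuc"))
  expect_lt(res$p_adj[res$dinuc == "AA"], 0.01)
  expect_gt(res$p_adj[res$dinuc == "AC"], 0.99)
  # chi-square oracle for the unequal cell
  ll <- function(k, n, p) k * log(p) + (n - k) * log(1 - p)
  g <- 2 * (ll(10, 1000, 0.01) + ll(100, 1000, 0.1) - ll(110, 2000, 0.055))
  expect_equal(res$lr[res$dinuc == "AA"], g, tolerance = 1e-8)

  # zero-observation cells are skipped with a marker
  tz <- make_table(data.frame(
    q = 30L, cycle = 1L, dinuc = "AA", observations = 0, errors = 0
  ))
  resz <- cell_significance(tz, tz, by = c("q", "dinuc"))
  expect_true(is.na(resz$lr))
})

test_that("split-half MAD scales with coverage like counting noise", {
  ref <- generate_reference(24, c(273, 800), vector_len = 0, seed = 104)
  model <- illumina_rnaseq_model(read_len = 50)
  pos <- all_reference_positions(ref, insert_only = TRUE)
  h <- split_half_reference(pos, 0.5, seed = 105)
  mads <- sapply(c(1e5, 4e5), function(nr) {
    tabs <- simulate_count_tables(ref, model, nr, seed = 106,
                                  position_groups = list(A = h$set_a, B = h$set_b))
    weighted_mad(tabs$A, tabs$B, "q", min_observations = 50)$mad
  })
  # 4x the reads should roughly halve the MAD
  expect_equal(mads[1] / mads[2], 2, tolerance = 1)

  # and MAD decreases monotonically in expectation: mean over 5 seeds at
  # three coverage levels
  mean_mads <- sapply(c(1e5, 3e5, 9e5), function(nr) {
    mean(sapply(1:5, function(s) {
      tabs <- simulate_count_tables(ref, model, nr, seed = 200 + s,
                                    position_groups = list(A = h$set_a, B = h$set_b))
      weighted_mad(tabs$A, tabs$B, c("q", "cycle"), min_observations = 50)$mad
    }))
  })
  expect_true(all(diff(mean_mads) < 0))
})
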