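test_that("purity posterior matches closed forms for the flat prior", {
  # prior mass below 1% impurity
  expect_equal(purity_posterior(0, 0, 0.99, c(1, 1)), 0.01)
  # k = 0 closed form: 1 - theta^(n+1)
  expect_equal(purity_posterior(300, 0), 1 - 0.99^301, tolerance = 1e-12)
  expect_gt(purity_posterior(300, 0), 0.95)
  expect_equal(purity_posterior(200, 0), 1 - 0.99^201, tolerance = 1e-12)
  expect_lt(purity_posterior(200, 0), 0.95)
  # gross impurity
  expect_lt(purity_posterior(1000, 100), 1e-6)
  expect_error(purity_posterior(10, 11), class = "spikecal_invalid_parameter")
})

test_that("posterior agrees with numerical integration of the Beta density", {
  set.seed(71)
  grid <- data.frame(
    n = sample(0:2000, 200, replace = TRUE),
    theta = runif(200, 0.8, 0.999),
    a = runif(200, 0.5, 3), b = runif(200, 0.5, 3)
  )
  grid$k <- rbinom(200, grid$n, 0.01)
  for (i in seq_len(200)) {
    with(grid[i, ], {
      oracle <- stats::integrate(
        function(x) stats::dbeta(x, a + k, b + n - k),
        0, 1 - theta, rel.tol = 1e-12, abs.tol = 1e-12
      )$value
      expect_equal(purity_posterior(n, k, theta, c(a, b)), oracle,
                   tolerance = 1e-8)
    })
  }
})

test_that("posterior is monotone in k and in n", {
  n <- 500
  post_k <- purity_posterior(rep(n, 21), 0:20)
  expect_true(all(diff(post_k) <= 0))
  post_n <- purity_posterior(0:1000, 0)
  expect_true(all(diff(post_n) >= 0))
})

test_that("minimum confident coverage is exact", {
  expect_identical(min_coverage_for_confidence(0.99, 0.95, c(1, 1)), 298L)
  expect_identical(min_coverage_for_confidence(0.99, 0.01, c(1, 1)), 0L)
  expect_identical(min_coverage_for_confidence(0.5, 0.95, c(1, 1)), 4L)
})

test_that("classification verdicts follow the mode and platform rules", {
  ref <- tiny_ref(1, c(300, 300), seed = 72)
  fl <- spikecal:::ref_flat(ref)
  # hand-build pileups: a clean platform with n=300 per strand,
  # all at one interior position set via direct array surgery
  blank <- function() {
    model <- error_model(read_len = 50, q_levels = 40, p_max = 1e-12)
    pileup(simulate_reads(ref, 10, model, seed = 73), ref) # layout donor
  }
  clean <- blank()
  clean$counts[] <- 0L
  for (p in seq_len(300)) {
    b <- fl$codes[p]
    clean$counts[p, b, 1, ] <- 150L
    clean$counts[p, b, 2, ] <- 150L
  }
  calls <- classify_bases(list(p1 = clean), ref, end_skip = 50)
  inner <- calls$verdict[calls$pos >= 50 & calls$pos < 250]
  expect_true(all(inner %in% c("high_purity", "POLYA")))
  expect_true(all(calls$verdict[calls$pos < 50] == "ENDSKIP"))

  # strand-specific SSE: + strand dirty, - strand clean with n = 400 ->
  # still high purity (max over modes)
  sse <- blank()
  sse$counts[] <- 0L
  p0 <- 150L
  b <- fl$codes[p0]
  wrong <- if (b == 1L) 2L else 1L
  sse$counts[p0, b, 1, ] <- 380L
  sse$counts[p0, wrong, 1, ] <- 20L # 5% mismatch on + strand
  sse$counts[p0, b, 2, ] <- 400L # clean - strand
  calls <- classify_bases(list(p1 = sse), ref, end_skip = 50)
  expect_equal(calls$verdict[calls$pos == p0 - 1L], "high_purity")

  # cross-platform impurity: 5% mismatch both strands on two platforms
  dirty <- blank()
  dirty$counts[] <- 0L
  dirty$counts[p0, b, 1, ] <- 475L
  dirty$counts[p0, wrong, 1, ] <- 25L
  dirty$counts[p0, b, 2, ] <- 475L
  dirty$counts[p0, wrong, 2, ] <- 25L
  calls <- classify_bases(list(p1 = dirty, p2 = dirty), ref, end_skip = 50)
  expect_equal(calls$verdict[calls$pos == p0 - 1L], "impure")
  # but low coverage elsewhere
  expect_true("low_coverage" %in% calls$verdict)
})

test_that("simulated clean data certifies nearly all interior bases", {
  ref <- tiny_ref(2, c(400, 500), seed = 74)
  model <- error_model(read_len = 50, q_levels = c(33, 36, 39),
                       q_prob = c(1, 1, 1))
  # coverage >= 2x the minimal confident coverage
  total <- sum(ref$records$length)
  n <- ceiling(2.5 * 298 * total / 50)
  reads <- simulate_reads(ref, n, model, seed = 75)
  bc <- pileup(reads, ref)
  calls <- classify_bases(list(sim = bc), ref, end_skip = 20)
  inner <- calls[calls$verdict %in% c("high_purity", "impure", "low_coverage"), ]
  expect_gte(mean(inner$verdict == "high_purity"), 0.99)

  # an injected >= 5% variant with deep cross-platform coverage is impure
  vars <- data.frame(id = ref$records$id[1], pos = 200L,
                     ref = substr(ref$sequences[[1]], 201, 201),
                     alt = setdiff(c("A", "C", "G", "T"),
                                   substr(ref$sequences[[1]], 201, 201))[1],
                     af = 0.3, in_database = FALSE)
  class(vars) <- c("variant_set", "data.frame")
  rv <- simulate_reads(ref, n, model, seed = 76, variants = vars)
  bv <- pileup(rv, ref)
  calls2 <- classify_bases(list(a = bv, b = bv), ref, end_skip = 20)
  expect_equal(calls2$verdict[calls2$id == vars$id & calls2$pos == 200L], "impure")
})

test_that("exclusion VCF round-trips and honours end-skip geometry", {
  fx <- demo_fixture(seed = 5)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_exclusion_vcf(fx$calls, f)
  back <- read_site_vcf(f)
  bad <- fx$calls[fx$calls$verdict != "high_purity", ]
  expect_equal(nrow(back), nrow(bad))
  expect_equal(back$pos, bad$pos)
  expect_true(all(back$verdict %in% c("LOWCOV", "IMPURE", "ENDSKIP", "POLYA")))

  # a 100-bp insert with end_skip 50 is excluded wholesale
  short <- generate_reference(1, c(100, 100), vector_len = 0, seed = 77)
  model <- error_model(read_len = 50, q_levels = 35)
  bc <- pileup(simulate_reads(short, 2000, model, seed = 78), short)
  calls <- classify_bases(list(x = bc), short, end_skip = 50)
  expect_true(all(calls$verdict == "ENDSKIP"))

  # empty call set -> header-only VCF
  none <- fx$calls[0, ]
  class(none) <- class(fx$calls)
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_exclusion_vcf(none, f2)
  expect_true(all(startsWith(readLines(f2), "#")))
  expect_equal(nrow(read_site_vcf(f2)), 0)
})

test_that("exclusion VCF is parseable by an independent VCF reader", {
  skip_if_not_installed("vcfR")
  fx <- demo_fixture(seed = 5)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_exclusion_vcf(fx$calls, f)
  v <- suppressWarnings(vcfR::read.vcfR(f, verbose = FALSE))
  expect_equal(nrow(v@fix), sum(fx$calls$verdict != "high_purity"))
  expect_equal(as.integer(v@fix[1, "POS"]) - 1L,
               fx$calls$pos[fx$calls$verdict != "high_purity"][1])
})
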