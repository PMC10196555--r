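# Small fixed landscape used throughout: 204-nt reference with the
# variant mid-fragment, three tagged sites.
ref <- synthetic_reference(seed = 99)
scheme3 <- make_tag_scheme(c("A", "B", "C"), n_legs = c(50, 50, 50),
                           year = 2016, seed = 100)

pool_reads <- function(p, site, depth, error_rate = 0, seed = 1,
                       allocation = "proportional", n = 100) {
  tally <- tibble::tibble(ss = round(n * (1 - p)), rr = round(n * p), rs = 0)
  simulate_pooled_reads(tally, site, scheme3, ref, depth = depth,
                        error_rate = error_rate, allocation = allocation,
                        seed = seed)
}

test_that("demultiplexing assigns by exact tag pair and conserves reads", {
  rd <- pool_reads(0.5, "A", depth = 10)
  out <- demultiplex_reads(rd$r1, rd$r2, scheme3)
  expect_equal(nrow(out$reads), 10)
  expect_equal(out$n_rejected, 0)
  expect_true(all(out$reads$site == "A"))
  expect_true(all(nchar(out$reads$sequence) == 204))

  # a pair whose tags match no site is rejected, never misassigned
  alien <- make_tag_scheme("Z", n_legs = 10, year = 2016, seed = 1234)
  rz <- simulate_pooled_reads(tibble::tibble(ss = 5, rs = 0, rr = 5), "Z",
                              alien, ref, depth = 1, error_rate = 0, seed = 2)
  out2 <- demultiplex_reads(rz$r1, rz$r2, scheme3)
  expect_equal(nrow(out2$reads), 0)
  expect_equal(out2$n_rejected, 1)
})

test_that("a three-site error-free mix is recovered exactly", {
  ra <- pool_reads(0.1, "A", 100, seed = 3)
  rb <- pool_reads(0.2, "B", 200, seed = 4)
  rc <- pool_reads(0.5, "C", 300, seed = 5)
  r1 <- c(ra$r1, rb$r1, rc$r1)
  r2 <- c(ra$r2, rb$r2, rc$r2)
  out <- demultiplex_reads(r1, r2, scheme3)
  expect_equal(out$n_rejected, 0)
  expect_equal(as.list(table(out$reads$site)), list(A = 100L, B = 200L, C = 300L))
  expect_equal(nrow(out$reads) + out$n_rejected, length(r1))

  # per-site frequencies are exact under proportional error-free allocation
  counts <- count_alleles_by_site(out$reads, scheme3,
                                  reference = ref$sequence,
                                  variant_pos = ref$variant_pos)
  freqs <- site_frequency(counts)
  expect_equal(freqs$frequency[order(freqs$site)], c(0.1, 0.2, 0.5))
})

test_that("overlap disagreement between mates rejects the pair", {
  rd <- pool_reads(0, "A", depth = 4)
  r1 <- rd$r1
  # corrupt one base inside the overlap region of the first mate
  substr(r1[[1]], 120, 120) <- if (substr(r1[[1]], 120, 120) == "A") "C" else "A"
  out <- demultiplex_reads(r1, rd$r2, scheme3)
  expect_equal(nrow(out$reads), 3)
  expect_equal(out$n_rejected, 1)
})

test_that("FASTQ round-trip preserves the read pairs", {
  rd <- pool_reads(0.3, "B", depth = 20, seed = 8)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(rd$r1, f1)
  write_fastq(rd$r2, f2)
  out <- demultiplex_reads(f1, f2, scheme3)
  expect_equal(nrow(out$reads), 20)
  expect_equal(out$n_rejected, 0)
})

test_that("the 1/(2n) filter removes rare sequences and is idempotent", {
  base <- ref$sequence
  variant_at <- function(pos, to) { s <- base; substr(s, pos, pos) <- to; s }

  # n_legs = 1: threshold 0.5, the 40% variant is removed
  seqs <- c(rep(base, 6), rep(variant_at(ref$variant_pos, "C"), 4))
  out1 <- count_alleles(seqs, n_legs = 1, reference = base,
                        variant_pos = ref$variant_pos)
  expect_equal(out1$threshold, 0.5)
  expect_equal(out1$n_distinct_surviving, 1)
  expect_equal(out1$r_count, 0)
  expect_equal(out1$s_count, 6)

  # n_legs = 100: a 3-in-10000 sequencing-error variant falls below 1/200
  err_seq <- variant_at(10, "G")
  seqs2 <- c(rep(base, 9997), rep(err_seq, 3))
  out2 <- count_alleles(seqs2, n_legs = 100, reference = base,
                        variant_pos = ref$variant_pos)
  expect_equal(out2$threshold, 0.005)
  expect_equal(out2$n_distinct_surviving, 1)
  expect_equal(out2$n_reads_surviving, 9997)

  # threshold for the yearly average pool of 996 moths
  out3 <- count_alleles(base, n_legs = 996, reference = base,
                        variant_pos = ref$variant_pos)
  expect_equal(out3$threshold, 1 / 1992, tolerance = 1e-12)

  # idempotence: refiltering the surviving reads changes nothing
  survivors <- rep(base, 9997)
  out_again <- count_alleles(survivors, n_legs = 100, reference = base,
                             variant_pos = ref$variant_pos)
  expect_equal(out_again$n_reads_surviving, out2$n_reads_surviving)
  expect_equal(out_again$r_count, out2$r_count)
  expect_equal(out_again$s_count, out2$s_count)

  # a sequence exactly at the threshold survives (strictly-less-than rule)
  seqs3 <- c(rep(base, 995), rep(variant_at(ref$variant_pos, "C"), 5))
  out4 <- count_alleles(seqs3, n_legs = 100, reference = base,
                        variant_pos = ref$variant_pos)
  expect_equal(out4$r_count, 5)

  expect_error(count_alleles(base, 10, base, variant_pos = 500), "beyond")
})

test_that("site frequency divides resistant reads by all surviving reads", {
  counts <- tibble::tibble(r_count = 100, s_count = 880, other_count = 20)
  expect_equal(site_frequency(counts)$frequency, 0.1)
  expect_equal(site_frequency(
    tibble::tibble(r_count = 0, s_count = 1000, other_count = 0))$frequency, 0)
  expect_equal(site_frequency(
    tibble::tibble(r_count = 500, s_count = 500, other_count = 0))$frequency, 0.5)
  expect_error(site_frequency(
    tibble::tibble(site = "X", r_count = 0, s_count = 0, other_count = 0)), "X")
})

test_that("annual bootstrap mean is deterministic and matches the exhaustive oracle", {
  single <- annual_mean_bootstrap(0.07, seed = 1)
  expect_equal(single$lower, 0.07)
  expect_equal(single$upper, 0.07)

  flat <- annual_mean_bootstrap(c(0.1, 0.1, 0.1), seed = 1)
  expect_equal(c(flat$mean, flat$lower, flat$upper), c(0.1, 0.1, 0.1))

  vals <- c(0.02, 0.08, 0.11, 0.19)
  b1 <- annual_mean_bootstrap(vals, reps = 1000, seed = 42)
  b2 <- annual_mean_bootstrap(vals, reps = 1000, seed = 42)
  expect_identical(b1, b2)
  eight <- c(0.02, 0.05, 0.08, 0.09, 0.11, 0.13, 0.16, 0.19)
  s1 <- annual_mean_bootstrap(eight, reps = 1000, seed = 43)
  s2 <- annual_mean_bootstrap(eight, reps = 1000, seed = 44)
  expect_false(identical(c(s1$lower, s1$upper), c(s2$lower, s2$upper)))

  # with 1000 resamples the estimated 2.5%/97.5% points sit within a
  # +/- 3 standard-error band of the exhaustive resampling distribution
  # (SE of the coverage level ~ sqrt(0.025 * 0.975 / 1000) ~ 0.005)
  oracle <- oracle_bootstrap_quantiles(vals,
                                       probs = c(0.010, 0.045, 0.955, 0.990))
  expect_gte(b1$lower, oracle$quantiles[1])
  expect_lte(b1$lower, oracle$quantiles[2])
  expect_gte(b1$upper, oracle$quantiles[3])
  expect_lte(b1$upper, oracle$quantiles[4])

  # near-zero means can bootstrap to a zero lower bound
  near_zero <- annual_mean_bootstrap(c(0, 0, 0, 0.004), reps = 1000, seed = 7)
  expect_equal(near_zero$lower, 0)

  # interval covers the centre of sites drawn around 0.10
  set.seed(21)
  eight <- pmin(1, pmax(0, rnorm(8, 0.10, 0.02)))
  cover <- annual_mean_bootstrap(eight, reps = 1000, seed = 9)
  expect_lte(cover$lower, 0.10)
  expect_gte(cover$upper, 0.10)

  # square-root-of-legs weighting is available and changes the weights only
  df <- tibble::tibble(frequency = c(0.1, 0.2), n_legs = c(100, 400))
  wtd <- annual_mean_bootstrap(df, seed = 1, weighting = "sqrt_legs")
  expect_equal(wtd$mean, (0.1 * 10 + 0.2 * 20) / 30)
})

test_that("tag scheme validation rejects malformed schemes", {
  bad_len <- tibble::tibble(site = "A", forward_tag = "ACGTA",
                            reverse_tag = "ACGTAA", n_legs = 10L, year = 2016L)
  expect_error(demultiplex_reads(character(), character(), bad_len), "6-mers")

  dup <- tibble::tibble(site = c("A", "B"),
                        forward_tag = c("ACGTAC", "ACGTAC"),
                        reverse_tag = c("TTTTTT", "TTTTTT"),
                        n_legs = c(10L, 10L), year = 2016L)
  expect_error(demultiplex_reads(character(), character(), dup), "unique")

  csv <- withr::local_tempfile(fileext = ".csv")
  write_tag_scheme(scheme3, csv)
  back <- read_tag_scheme(csv)
  expect_equal(as.data.frame(back), as.data.frame(scheme3))
})
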