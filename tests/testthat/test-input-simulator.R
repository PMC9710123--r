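# a model whose effective genome is two single-base positions with
# coverage 4 and 1 (p = 0.8 / 0.2): five length-1 unimappers
two_position_model <- function() {
  ids <- c("x1", "x2", "x3", "x4", "y1")
  lib <- new_mapping_library(
    data.table(read_id = ids, chrom = "chr1",
               start = c(0L, 0L, 0L, 0L, 10L),
               end = c(1L, 1L, 1L, 1L, 11L)),
    setNames(rep(1L, 5L), ids), c(chr1 = 20L))
  build_probability_model(compute_weighted_coverage(lib), lib)
}

test_that("position sampling follows the coverage distribution", {
  mod <- two_position_model()
  draws <- sample_position(mod, n = 100000L, seed = 42L)
  expect_setequal(unique(draws$pos), c(0L, 10L))
  f0 <- mean(draws$pos == 0L)
  # binomial 3 sigma around 0.8 at n = 1e5
  expect_gt(f0, 0.8 - 3 * sqrt(0.8 * 0.2 / 1e5))
  expect_lt(f0, 0.8 + 3 * sqrt(0.8 * 0.2 / 1e5))

  # a single effective position is always returned
  uni <- new_mapping_library(
    data.table(read_id = "u", chrom = "chr1", start = 5L, end = 6L),
    c(u = 1L), c(chr1 = 20L))
  m1 <- build_probability_model(compute_weighted_coverage(uni), uni)
  expect_true(all(sample_position(m1, 200L, seed = 1L)$pos == 5L))
})

test_that("masked positions are sampled with frequency exactly zero", {
  ids <- c("x1", "x2", "x3", "x4", "y1")
  lib <- new_mapping_library(
    data.table(read_id = ids, chrom = "chr1",
               start = c(0L, 0L, 0L, 0L, 10L),
               end = c(1L, 1L, 1L, 1L, 11L)),
    setNames(rep(1L, 5L), ids), c(chr1 = 20L))
  mod <- build_probability_model(compute_weighted_coverage(lib), lib,
                                 mask = region_mask("chr1", 0L, 1L))
  draws <- sample_position(mod, n = 5000L, seed = 7L)
  expect_true(all(draws$pos == 10L))
})

test_that("read draws at a position are weighted by 1/(cov_n N_r)", {
  # worked example: at position 17, read A (N=1) has p = 2/3 and
  # read B (N=2) has p = 1/3
  lib <- two_read_library()
  mod <- build_probability_model(compute_weighted_coverage(lib), lib)
  picks <- sample_read_at_position(mod, rep("chr1", 60000L),
                                   rep(17L, 60000L), seed = 11L)
  fA <- mean(picks == "A")
  expect_gt(fA, 2 / 3 - 3 * sqrt((2 / 3) * (1 / 3) / 60000))
  expect_lt(fA, 2 / 3 + 3 * sqrt((2 / 3) * (1 / 3) / 60000))
  # a position covered by a single unimapper returns it with certainty
  expect_true(all(sample_read_at_position(
    mod, rep("chr1", 100L), rep(105L, 100L), seed = 2L) == "B"))
})

test_that("center shifting translates all mappings and truncates at bounds", {
  sizes <- c(chr1 = 200L)
  b <- data.table(chrom = "chr1", start = c(15L, 100L), end = c(25L, 110L))
  # center of [15,25) is 19; target 17 gives delta -2
  sh <- center_shift_mappings(b, 1L, 17L, sizes)
  expect_equal(sh$start, c(13L, 98L))
  expect_equal(sh$end, c(23L, 108L))
  # shifting to the mapping's own center is the identity
  sh0 <- center_shift_mappings(b, 1L, 19L, sizes)
  expect_equal(sh0, b[, .(chrom, start, end)])
  # a mapping pushed to start -3 is truncated to its in-bounds part
  c2 <- data.table(chrom = "chr1", start = c(50L, 0L), end = c(60L, 10L))
  # delta = -3: select first mapping (center 54), target 51
  sh2 <- center_shift_mappings(c2, 1L, 51L, sizes)
  expect_equal(sh2$start, c(47L, 0L))
  expect_equal(sh2$end, c(57L, 7L))
  # a mapping pushed entirely out of bounds is dropped
  c3 <- data.table(chrom = "chr1", start = c(100L, 0L), end = c(110L, 5L))
  sh3 <- center_shift_mappings(c3, 1L, 2L, sizes)  # delta = -102
  expect_equal(nrow(sh3), 1L)
})

test_that("simulated libraries are deterministic in (seed, iteration)", {
  lib <- random_library(300L, 4000L, multi_frac = 0.4, seed = 6L)
  mod <- build_probability_model(compute_weighted_coverage(lib), lib)
  a <- simulate_library(mod, 250L, seed = 5L, iteration = 3L)
  b <- simulate_library(mod, 250L, seed = 5L, iteration = 3L)
  expect_identical(a$mappings, b$mappings)
  expect_identical(a$reads, b$reads)
  # a different iteration gives a different library
  c_ <- simulate_library(mod, 250L, seed = 5L, iteration = 4L)
  expect_false(identical(a$mappings, c_$mappings))
  # the iteration substream does not depend on execution order
  invisible(simulate_library(mod, 250L, seed = 5L, iteration = 9L))
  d <- simulate_library(mod, 250L, seed = 5L, iteration = 3L)
  expect_identical(a$mappings, d$mappings)
})

test_that("simulated libraries match the sample size and input structure", {
  lib <- random_library(200L, 3000L, multi_frac = 0, seed = 9L)
  mod <- build_probability_model(compute_weighted_coverage(lib), lib)
  sim <- simulate_library(mod, 1000L, seed = 1L, iteration = 1L)
  expect_equal(n_reads(sim), 1000L)
  # an all-unimapper input yields only unimapper simulated reads
  expect_true(all(sim$reads$n_mappings == 1L))
  # every simulated read's mapping set is a translate of a source read's
  prov <- attr(sim, "provenance")
  expect_equal(nrow(prov$source), 1000L)
  multi <- random_library(150L, 3000L, multi_frac = 1, max_n = 3L, seed = 4L)
  modm <- build_probability_model(compute_weighted_coverage(multi), multi)
  simm <- simulate_library(modm, 400L, seed = 2L, iteration = 1L)
  src <- attr(simm, "provenance")$source
  nm <- multi$reads[src$source_read_id, n_mappings, on = "read_id"]
  # N_r can only shrink through boundary truncation
  expect_true(all(simm$reads[order(as.integer(sub("s1_", "", read_id))),
                             n_mappings] <= nm))
  expect_error(simulate_library(mod, 0L), "positive")
})

test_that("unimapper simulation reproduces smoothed input coverage", {
  # symmetry property: expected per-base coverage of simulated libraries
  # tracks the input coverage up to center-shift edge smoothing; the
  # input needs density structure wider than the smoothing scale (~2 read
  # lengths), as real accessibility biases are
  spec <- fixture_spec(chrom_sizes = c(chr1 = 8000L),
                       families = data.frame(family_id = "TEz",
                                             n_copies = 2L,
                                             copy_length = 100L,
                                             divergence = 0.2),
                       read_length = 20L, input_reads = 6000L,
                       gamma_shape = 2, seed = 12L)
  fx <- generate_genome_and_annotation(spec)
  lib <- generate_mapping_library(fx, "input")
  mod <- build_probability_model(compute_weighted_coverage(lib), lib)
  acc <- numeric(8000L)
  for (i in 1:20) {
    sim <- simulate_library(mod, 3000L, seed = 3L, iteration = i)
    acc <- acc + oracle_coverage(sim)$chr1
  }
  expect_gt(cor(acc, oracle_coverage(lib)$chr1), 0.95)
})
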