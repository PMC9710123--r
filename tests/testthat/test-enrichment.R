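test_that("empirical P-values count ties toward the numerator", {
  bg <- c(4.1, 5.0, 5.3, 3.9, 4.4, 4.0, 4.2, 4.8, 3.5, 4.6)
  expect_equal(empirical_pvalue(5.0, bg), 0.2)
  # a sample above every background gets p = 0
  expect_equal(empirical_pvalue(10, bg), 0)
  # zero sample against all-zero backgrounds gets p = 1
  expect_equal(empirical_pvalue(0, rep(0, 10)), 1)
})

test_that("fold change uses the background mean with zero conventions", {
  bg <- c(4.1, 5.0, 5.3, 3.9, 4.4, 4.0, 4.2, 4.8, 3.5, 4.6)
  expect_equal(fold_change(5.0, bg), 5.0 / mean(bg))
  expect_equal(round(fold_change(5.0, bg), 4), 1.1416)
  expect_equal(fold_change(mean(bg), bg), 1)
  expect_equal(fold_change(0, rep(0, 5)), 1)
  expect_identical(fold_change(0.4, rep(0, 5)), Inf)
})

test_that("run_enrichment recovers a planted signal and nothing else", {
  spec <- fixture_spec(chrom_sizes = c(chr1 = 40000L),
                       families = data.frame(
                         family_id = paste0("TE", 1:4), n_copies = 6L,
                         copy_length = 200L, divergence = rep(c(0, 0.05), 2)),
                       read_length = 40L, input_reads = 6000L,
                       sample_reads = 3000L, enrichment = c(TE1 = 3),
                       seed = 17L)
  fx <- generate_genome_and_annotation(spec)
  inp <- generate_mapping_library(fx, "input")
  smp <- generate_mapping_library(fx, "sample")
  res <- run_enrichment(smp, inp, fx$annotation, N = 50L, seed = 4L)
  expect_true(res[family_id == "TE1", enriched])
  expect_gt(res[family_id == "TE1", fold_change], 2)
  expect_false(any(res[family_id != "TE1", enriched]))
  # p-values live on the 1/N grid
  expect_true(all(abs(res$pvalue * 50 - round(res$pvalue * 50)) < 1e-12))
  # with N = 1 the p-value is 0 or 1
  res1 <- run_enrichment(smp, inp, fx$annotation, N = 1L, seed = 4L)
  expect_true(all(res1$pvalue %in% c(0, 1)))
  expect_error(run_enrichment(smp, inp, fx$annotation, N = 0L), "N")
})

test_that("background means are proportional to input family counts", {
  spec <- fixture_spec(chrom_sizes = c(chr1 = 50000L),
                       families = data.frame(
                         family_id = paste0("TE", 1:5),
                         n_copies = c(2L, 4L, 8L, 12L, 20L),
                         copy_length = 150L, divergence = 0),
                       read_length = 30L, input_reads = 8000L,
                       enrichment = numeric(0), seed = 23L)
  fx <- generate_genome_and_annotation(spec)
  inp <- generate_mapping_library(fx, "input")
  smp <- generate_mapping_library(fx, "sample", n_reads = 4000L)
  res <- run_enrichment(smp, inp, fx$annotation, N = 30L, seed = 2L)
  input_counts <- count_family_mappings(inp, fx$annotation)
  expect_gt(cor(res$background_mean, input_counts$count), 0.95)
})

test_that("uniform shuffling matches placement-counting expectations", {
  # family of one 100 bp copy mid-genome; span-10 mappings overlap it for
  # 109 of the 991 placements
  size <- 1000L
  ann <- new_te_annotation(data.table(
    chrom = "chr1", start = 200L, end = 300L, family_id = "F"))
  ids <- sprintf("r%03d", 1:200)
  lib <- new_mapping_library(
    data.table(read_id = ids, chrom = "chr1",
               start = rep(0L, 200L), end = rep(10L, 200L)),
    setNames(rep(10L, 200L), ids), c(chr1 = size))
  ub <- uniform_background_counts(lib, c(chr1 = size), ann, N = 100L,
                                  seed = 31L)
  expected <- 200 * 109 / 991
  sd3 <- 3 * sqrt(200 * (109 / 991) * (1 - 109 / 991) / 100)
  expect_lt(abs(ub$mean_shuffled - expected), sd3)
  # a family covering the whole genome captures every mapping
  ann_all <- new_te_annotation(data.table(
    chrom = "chr1", start = 0L, end = size, family_id = "All"))
  ub2 <- uniform_background_counts(lib, c(chr1 = size), ann_all, N = 5L,
                                   seed = 1L)
  expect_equal(unname(ub2$mean_shuffled), 200)
  # a zero-extent annotation counts nothing
  ann_none <- new_te_annotation(data.table(
    chrom = character(), start = integer(), end = integer(),
    family_id = character()))
  ub3 <- uniform_background_counts(lib, c(chr1 = size), ann_none, N = 2L,
                                   seed = 1L)
  expect_equal(nrow(ub3), 0L)
  # impossible placements are an error
  tiny <- new_mapping_library(
    data.table(read_id = "x", chrom = "chr1", start = 0L, end = 10L),
    c(x = 10L), c(chr1 = 1000L))
  expect_error(uniform_background_counts(tiny, c(chr1 = 5L), ann, N = 1L),
               "longer than every chromosome")
})

test_that("result TSVs are sorted, tie-broken, and round-trip", {
  spec <- fixture_spec(chrom_sizes = c(chr1 = 20000L),
                       families = data.frame(
                         family_id = c("TEa", "TEb"), n_copies = 4L,
                         copy_length = 150L, divergence = 0),
                       read_length = 30L, input_reads = 3000L,
                       sample_reads = 1500L, enrichment = numeric(0),
                       seed = 8L)
  fx <- generate_genome_and_annotation(spec)
  inp <- generate_mapping_library(fx, "input")
  smp <- generate_mapping_library(fx, "sample")
  res <- run_enrichment(smp, inp, fx$annotation, N = 10L, seed = 3L)
  tf <- tempfile(fileext = ".tsv")
  write_results(res, tf)
  back <- data.table::fread(tf)
  expect_equal(back$family_id,
               res[order(-fold_change, family_id), family_id])
  expect_equal(back$fold_change,
               signif(res[order(-fold_change, family_id), fold_change], 6L),
               tolerance = 1e-6)
  # a zero p-value is labelled as below the empirical floor
  res0 <- data.table::copy(res)[1, pvalue := 0]
  data.table::setattr(res0, "class", class(res))
  data.table::setattr(res0, "N", attr(res, "N"))
  tf0 <- tempfile(fileext = ".tsv")
  write_results(res0, tf0)
  expect_true("<0.1" %in% data.table::fread(tf0, colClasses = "character")$pvalue_label)
  # identical runs produce byte-identical reports
  res2 <- run_enrichment(smp, inp, fx$annotation, N = 10L, seed = 3L)
  tf2 <- tempfile(fileext = ".tsv")
  write_results(res2, tf2)
  expect_identical(unname(tools::md5sum(tf)), unname(tools::md5sum(tf2)))
  # an empty result set still writes a header
  tfe <- tempfile(fileext = ".tsv")
  write_results(res[0L], tfe)
  expect_equal(nrow(data.table::fread(tfe)), 0L)
})
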