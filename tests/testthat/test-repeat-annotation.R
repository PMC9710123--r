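test_that("rmsk table parsing is lossless and 0-based half-open", {
  tf <- tempfile(fileext = ".txt")
  rows <- c(
    # 17-column dump with leading bin; satellite rows survive parsing
    paste(c(1, 463, 13, 6, 17, "chr1", 10468, 11447, "-248945975", "-",
            "TAR1", "Satellite", "telo", "-399", 1712, 483, 1), collapse = "\t"),
    paste(c(1, 2000, 10, 2, 1, "chr1", 20000, 20300, "-1", "+",
            "AluY", "SINE", "Alu", 1, 300, 0, 2), collapse = "\t")
  )
  writeLines(rows, tf)
  rec <- parse_repeatmasker(tf, dialect = "rmsk_table")
  expect_equal(nrow(rec), 2L)
  tar1 <- rec[name == "TAR1"]
  expect_equal(tar1$start, 10468L)
  expect_equal(tar1$end, 11447L)
  expect_equal(tar1$rep_class, "Satellite")
  expect_equal(rec[name == "AluY", rep_family], "Alu")

  # empty file gives an empty record set
  tf2 <- tempfile(fileext = ".txt")
  file.create(tf2)
  expect_equal(nrow(parse_repeatmasker(tf2, dialect = "rmsk_table")), 0L)
})

test_that("BED dialect decodes name:family:class and round-trips", {
  tf <- tempfile(fileext = ".bed")
  writeLines("chr2\t100\t200\tAluY:Alu:SINE", tf)
  rec <- parse_repeatmasker(tf, dialect = "bed")
  expect_equal(rec$chrom, "chr2")
  expect_equal(rec$start, 100L)
  expect_equal(rec$end, 200L)
  expect_equal(rec$name, "AluY")
  expect_equal(rec$rep_family, "Alu")
  expect_equal(rec$rep_class, "SINE")

  # fixture writer -> parser round trip
  spec <- fixture_spec(chrom_sizes = c(chr1 = 20000L),
                       families = data.frame(family_id = c("TEa", "TEb"),
                                             n_copies = 4L, copy_length = 150L,
                                             divergence = 0),
                       read_length = 30L, seed = 3L)
  fx <- generate_genome_and_annotation(spec)
  paths <- write_fixture_files(fx, tempfile())
  rec2 <- parse_repeatmasker(paths[["bed"]], dialect = "bed")
  ann2 <- merge_family_copies(rec2, level = "name")
  expect_equal(ann2$copies, fx$annotation$copies)
})

test_that("RepeatMasker .out dialect parses header and C strands", {
  tf <- tempfile(fileext = ".out")
  writeLines(c(
    "   SW  perc perc perc  query     position in query    matching repeat",
    "score  div. del. ins.  sequence  begin  end  (left)   repeat  class/family",
    "",
    "  463  1.3  0.6  1.7  chr1   10469  11447 (-2489) C  TAR1  Satellite/telo  399  1712  (483)   1",
    " 2000  1.0  0.2  0.1  chr1   20001  20300 (-1)    +  AluY  SINE/Alu          1   300    (0)   2"
  ), tf)
  rec <- parse_repeatmasker(tf, dialect = "rm_out")
  expect_equal(rec$start, c(10468L, 20000L))
  expect_equal(rec$end, c(11447L, 20300L))
  expect_equal(rec$strand, c("-", "+"))
  expect_equal(rec$rep_class, c("Satellite", "SINE"))
  expect_equal(rec$rep_family, c("telo", "Alu"))
})

test_that("non-TE repeat classes are filtered out, Unknown is kept", {
  rec <- data.table::data.table(
    chrom = "chr1", start = (0:6) * 1000L, end = (0:6) * 1000L + 100L,
    name = c("(AT)n", "TAR1", "AluY", "L1MA4", "U6", "MER4-like", "polyA"),
    rep_class = c("Simple_repeat", "Satellite", "SINE", "LINE", "snRNA",
                  "Unknown", "Low_complexity"),
    rep_family = c("Simple_repeat", "telo", "Alu", "L1", "snRNA",
                   "Unknown", "Low_complexity"),
    strand = "+"
  )
  kept <- filter_te_records(rec)
  expect_setequal(kept$name, c("AluY", "L1MA4", "MER4-like"))
  # mitochondrial records are dropped too
  rec2 <- data.table::copy(rec)[name == "AluY", chrom := "chrM"]
  expect_false("AluY" %in% filter_te_records(rec2)$name)
})

test_that("copy merging unions overlap and zero gaps within a family only", {
  mk <- function(start, end, name) {
    data.table::data.table(chrom = "chr1", start = start, end = end,
                           name = name, rep_class = "SINE",
                           rep_family = "Alu", strand = "+")
  }
  # zero-gap adjacency merges
  a <- merge_family_copies(mk(c(100L, 200L), c(200L, 300L), "AluY"))
  expect_equal(nrow(a$copies), 1L)
  expect_equal(a$copies$start, 100L)
  expect_equal(a$copies$end, 300L)
  # a 5 bp gap does not merge
  b <- merge_family_copies(mk(c(100L, 205L), c(200L, 300L), "AluY"))
  expect_equal(nrow(b$copies), 2L)
  # different families never merge even when overlapping
  c_ <- merge_family_copies(mk(c(100L, 150L), c(200L, 250L),
                               c("AluY", "AluSc")))
  expect_equal(nrow(c_$copies), 2L)
  expect_equal(sort(c_$families$family_id), c("AluSc", "AluY"))
})

test_that("merging is idempotent and preserves per-family covered bases", {
  set.seed(42)
  for (rep in 1:5) {
    n <- 60L
    rec <- data.table::data.table(
      chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
      start = sample.int(5000L, n) - 1L,
      name = sample(c("F1", "F2", "F3"), n, replace = TRUE),
      rep_class = "LTR", strand = "+"
    )
    rec[, end := start + sample(20:200, n, replace = TRUE)]
    rec[, rep_family := name]
    data.table::setcolorder(rec, c("chrom", "start", "end", "name",
                                   "rep_class", "rep_family", "strand"))
    ann <- merge_family_copies(rec, level = "name")
    # idempotence: merging the merged copies changes nothing
    rec2 <- ann$copies[, .(chrom, start, end, name = family_id,
                           rep_class = "LTR", rep_family = family_id,
                           strand = "+")]
    ann2 <- merge_family_copies(rec2, level = "name")
    expect_equal(ann2$copies, ann$copies)
    # covered bp per family equals the brute-force per-base union
    for (ff in unique(rec$name)) {
      sub <- rec[name == ff]
      expect_equal(ann$families[family_id == ff, total_bp],
                   oracle_union_bp(sub$chrom, sub$start, sub$end))
    }
    # every copy's family appears in exactly one census entry
    expect_equal(sort(unique(ann$copies$family_id)),
                 sort(ann$families$family_id))
    expect_equal(anyDuplicated(ann$families$family_id), 0L)
  }
})

test_that("family eligibility applies the copy-count threshold inclusively", {
  cp <- data.table::data.table(
    chrom = "chr1",
    start = seq(0L, by = 100L, length.out = 99L),
    end = seq(50L, by = 100L, length.out = 99L),
    family_id = c(rep("F50", 50L), rep("F49", 49L))
  )
  ann <- new_te_annotation(cp)
  expect_equal(eligible_families(ann, min_copies = 50L), "F50")
  expect_setequal(eligible_families(ann, min_copies = 1L), c("F49", "F50"))
})
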