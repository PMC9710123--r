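# Brute-force reference implementations used as independent oracles.
# They follow the defining formulas literally (per-read, per-base loops)
# and stay independent of the package's vectorised engines.

library(data.table)

# per-base ambiguity-weighted coverage: dense numeric vector per chromosome
oracle_coverage <- function(library) {
  sizes <- library$chrom_sizes
  cov <- lapply(sizes, function(s) numeric(s))
  nr <- setNames(library$reads$n_mappings, library$reads$read_id)
  mp <- library$mappings
  for (i in seq_len(nrow(mp))) {
    s <- max(mp$start[i], 0L)
    e <- min(mp$end[i], sizes[[mp$chrom[i]]])
    if (e > s) {
      idx <- (s + 1L):e
      cov[[mp$chrom[i]]][idx] <- cov[[mp$chrom[i]]][idx] +
        1 / nr[[mp$read_id[i]]]
    }
  }
  cov
}

# C_K by the triple loop over copies, reads and mappings
oracle_family_counts <- function(library, annotation) {
  fams <- sort(unique(annotation$copies$family_id))
  out <- setNames(numeric(length(fams)), fams)
  rd <- library$reads
  mp <- library$mappings
  cp <- annotation$copies
  for (k in seq_len(nrow(cp))) {
    for (i in seq_len(nrow(mp))) {
      if (mp$chrom[i] != cp$chrom[k]) next
      l <- min(mp$end[i], cp$end[k]) - max(mp$start[i], cp$start[k])
      if (l <= 0) next
      ri <- match(mp$read_id[i], rd$read_id)
      out[[cp$family_id[k]]] <- out[[cp$family_id[k]]] +
        l / (rd$n_mappings[ri] * rd$length[ri])
    }
  }
  out
}

# total bp covered by a set of intervals, by per-base union on a bitmap
oracle_union_bp <- function(chrom, start, end, max_len = 1e5) {
  bp <- 0L
  for (cc in unique(chrom)) {
    v <- logical(max_len)
    idx <- which(chrom == cc)
    for (i in idx) v[(start[i] + 1L):end[i]] <- TRUE
    bp <- bp + sum(v)
  }
  bp
}

# the two-read worked example used across the background-model tests:
# read A (unimapper, length 10) on chr1:[10,20); read B (two mappings,
# length 10) on chr1:[15,25) and chr1:[100,110)
two_read_library <- function(chrom_size = 200L) {
  new_mapping_library(
    data.table(read_id = c("A", "B", "B"), chrom = "chr1",
               start = c(10L, 15L, 100L), end = c(20L, 25L, 110L)),
    data.table(read_id = c("A", "B"), length = c(10L, 10L)),
    c(chr1 = chrom_size)
  )
}

# a small random library on one chromosome (dense enough to exercise
# overlaps), with multimappers of controlled ambiguity
random_library <- function(n_reads, chrom_size, read_len = 20L,
                           multi_frac = 0.3, max_n = 4L, seed = 1L) {
  set.seed(seed)
  ids <- sprintf("r%05d", seq_len(n_reads))
  nmap <- ifelse(runif(n_reads) < multi_frac,
                 sample(2:max_n, n_reads, replace = TRUE), 1L)
  mp <- data.table(
    read_id = rep(ids, nmap),
    chrom = "chr1",
    start = sample.int(chrom_size - read_len, sum(nmap), replace = TRUE) - 1L
  )
  mp[, end := start + read_len]
  new_mapping_library(mp, data.table(read_id = ids, length = read_len),
                      c(chr1 = as.integer(chrom_size)))
}

# random TE annotation: n_fam families, copies of length copy_len placed
# anywhere (cross-family overlaps allowed, as in real annotations)
random_annotation <- function(n_fam, copies_per_fam, chrom_size,
                              copy_len = 60L, seed = 2L) {
  set.seed(seed)
  dt <- data.table(
    chrom = "chr1",
    start = sample.int(chrom_size - copy_len,
                       n_fam * copies_per_fam, replace = TRUE) - 1L,
    family_id = rep(sprintf("F%02d", seq_len(n_fam)), each = copies_per_fam)
  )
  dt[, end := start + copy_len]
  rec <- dt[, .(chrom, start, end, name = family_id, rep_class = "SINE",
                rep_family = family_id, strand = "+")]
  merge_family_copies(rec, level = "name")
}

# subset a MappingLibrary to a set of read ids
subset_library <- function(library, keep) {
  new_mapping_library(
    library$mappings[read_id %in% keep],
    library$reads[read_id %in% keep, .(read_id, length)],
    library$chrom_sizes
  )
}
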