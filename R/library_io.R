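# Ingestion of all-mappings alignments into the grouped read/mapping data
# model, plus the standard read-level filters and down-sampling.

#' Construct a MappingLibrary
#'
#' The core container for one sequencing library: every mapping of every
#' read, grouped by read name, with per-read ambiguity `N_r` (number of
#' mappings) and read length `L_r`.
#'
#' @param mappings `data.table` with `read_id`, `chrom`, `start`, `end`
#'   (0-based half-open reference span of each mapping).
#' @param read_lengths Named vector or `data.table(read_id, length)` giving
#'   the full read length `L_r` per read.
#' @param chrom_sizes Named integer vector of chromosome lengths.
#' @return A `MappingLibrary` object.
#' @export
new_mapping_library <- function(mappings, read_lengths, chrom_sizes) {
  mp <- as.data.table(mappings)[, .(read_id = as.character(read_id),
                                    chrom = as.character(chrom),
                                    start = as.integer(start),
                                    end = as.integer(end))]
  if (nrow(mp) && any(mp$start >= mp$end)) {
    stop("mapping with non-positive span")
  }
  if (is.data.table(read_lengths) || is.data.frame(read_lengths)) {
    rl <- as.data.table(read_lengths)[, .(read_id = as.character(read_id),
                                          length = as.integer(length))]
  } else {
    rl <- data.table(read_id = names(read_lengths),
                     length = as.integer(read_lengths))
  }
  nm <- mp[, .(n_mappings = .N), by = read_id]
  reads <- merge(nm, rl, by = "read_id", all.x = TRUE)
  if (any(is.na(reads$length)) || any(reads$length <= 0L)) {
    bad <- reads$read_id[which(is.na(reads$length) | reads$length <= 0L)[1L]]
    stop("no resolvable read length for read ", bad)
  }
  setkey(mp, chrom, start, end)
  setkey(reads, read_id)
  structure(
    list(reads = reads, mappings = mp,
         chrom_sizes = setNames(as.integer(chrom_sizes), names(chrom_sizes))),
    class = "MappingLibrary"
  )
}

#' Number of reads in a library
#' @param library `MappingLibrary`.
#' @export
n_reads <- function(library) nrow(library$reads)

#' Number of mappings in a library
#' @param library `MappingLibrary`.
#' @export
n_mappings <- function(library) nrow(library$mappings)

#' @export
print.MappingLibrary <- function(x, ...) {
  nm <- n_mappings(x)
  nr <- n_reads(x)
  cat(sprintf(
    "MappingLibrary: %d reads, %d mappings (%.2f per read), %d chromosomes\n",
    nr, nm, if (nr) nm / nr else 0, length(x$chrom_sizes)))
  invisible(x)
}

# mappings joined with per-read N_r and L_r -- the table most engines use
.mapinfo <- function(library) {
  mi <- library$mappings[library$reads, on = "read_id",
                         nomatch = NULL]
  setnames(mi, c("n_mappings", "length"), c("N_r", "L_r"))
  mi
}

#' Load an all-mappings alignment file
#'
#' Reads a SAM or BAM file produced by a mapper configured to report all
#' mappings per read (primary + secondary records). Secondary alignments
#' are required and kept; supplementary and duplicate-flagged records are
#' skipped (duplicates are expected to have been removed upstream).
#' The reference span of each mapping comes from its CIGAR; the read
#' length `L_r` is the full sequence length, resolved from the primary
#' record when secondary records omit the sequence.
#'
#' @param path SAM or BAM file.
#' @param chrom_sizes Named integer vector (see [read_chrom_sizes()]).
#' @return `MappingLibrary` (unfiltered; see [apply_standard_filters()]).
#' @export
load_mappings <- function(path, chrom_sizes) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSupplementaryAlignment = FALSE,
                                  isDuplicate = FALSE),
    what = c("qname", "flag", "rname", "pos", "cigar", "seq")
  )
  res <- Rsamtools::scanBam(bam, param = param)[[1L]]
  if (length(res$qname) == 0L) {
    return(new_mapping_library(
      data.table(read_id = character(), chrom = character(),
                 start = integer(), end = integer()),
      data.table(read_id = character(), length = integer()),
      chrom_sizes))
  }
  span <- GenomicAlignments::cigarWidthAlongReferenceSpace(res$cigar)
  mp <- data.table(
    read_id = res$qname,
    chrom = as.character(res$rname),
    start = res$pos - 1L,
    end = res$pos - 1L + as.integer(span)
  )
  seqw <- Biostrings::width(res$seq)
  is_secondary <- bitwAnd(res$flag, 256L) != 0L
  rl <- data.table(read_id = res$qname, w = seqw, secondary = is_secondary)
  # prefer the primary record's sequence length; fall back to any record
  # that carries a sequence
  rl <- rl[, .(length = {
    cand <- w[!secondary & w > 0L]
    if (!length(cand)) cand <- w[w > 0L]
    if (!length(cand)) NA_integer_ else max(cand)
  }), by = read_id]
  if (any(is.na(rl$length))) {
    stop("no resolvable read length for read ",
         rl$read_id[which(is.na(rl$length))[1L]])
  }
  new_mapping_library(mp, rl, chrom_sizes)
}

#' Apply the standard read-level filters
#'
#' Removes mappings on the mitochondrial chromosome and on contigs absent
#' from the chromosome-sizes table (non-chromosomal scaffolds); reads whose
#' mapping set becomes empty are dropped, and the per-read ambiguity `N_r`
#' is recomputed on the filtered universe.
#'
#' @param library `MappingLibrary`.
#' @return Filtered `MappingLibrary`.
#' @export
apply_standard_filters <- function(library) {
  stopifnot(inherits(library, "MappingLibrary"))
  keep_chroms <- setdiff(names(library$chrom_sizes), .MITO_NAMES)
  mp <- library$mappings[chrom %in% keep_chroms]
  removed <- n_mappings(library) - nrow(mp)
  if (removed > 0L) {
    message("apply_standard_filters: removed ", removed,
            " mapping(s) on chrM/scaffolds; N_r recomputed")
  }
  rl <- library$reads[read_id %in% unique(mp$read_id),
                      .(read_id, length)]
  new_mapping_library(mp, rl,
                      library$chrom_sizes[keep_chroms])
}

#' Randomly down-sample a library to a fixed number of reads
#'
#' Chooses reads uniformly without replacement; each retained read keeps
#' all of its mappings. A library with at most `n` reads is returned
#' unchanged.
#'
#' @param library `MappingLibrary`.
#' @param n Target number of reads (default 20 million).
#' @param seed Integer seed for reproducibility.
#' @return Down-sampled `MappingLibrary`.
#' @export
downsample_reads <- function(library, n = 2e7, seed = 1L) {
  stopifnot(inherits(library, "MappingLibrary"))
  if (n >= n_reads(library)) return(library)
  keep <- with_seed(seed, sample(library$reads$read_id, size = n,
                                 replace = FALSE))
  mp <- library$mappings[read_id %in% keep]
  rl <- library$reads[read_id %in% keep, .(read_id, length)]
  new_mapping_library(mp, rl, library$chrom_sizes)
}

#' Write normalised mappings as BED (debugging aid)
#'
#' @param library `MappingLibrary`.
#' @param path Output path.
#' @export
write_mappings_bed <- function(library, path) {
  mi <- .mapinfo(library)
  setorder(mi, chrom, start, end, read_id)
  fwrite(mi[, .(chrom, start, end, read_id, N_r)], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}
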