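# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so that seeded operations do not
#' perturb the caller's random number stream. With `seed = NULL` the
#' expression is evaluated with the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1L)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed %% 2147483646L) + 1L)
  }
  code
}

# Substream seed for simulation iteration i; stays below 2^31.
.iter_seed <- function(seed, iteration) {
  as.integer((as.numeric(seed) + as.numeric(iteration)) %% 2147483647)
}

# Convert 0-based half-open intervals to a GRanges (1-based closed).
# `chrom_sizes` (named vector) fixes the seqlevels and seqlengths.
.as_granges <- function(chrom, start0, end0, chrom_sizes = NULL) {
  if (is.null(chrom_sizes)) {
    lv <- unique(as.character(chrom))
    GenomicRanges::GRanges(
      seqnames = factor(as.character(chrom), levels = lv),
      ranges = IRanges::IRanges(start = start0 + 1L, end = end0)
    )
  } else {
    GenomicRanges::GRanges(
      seqnames = factor(as.character(chrom), levels = names(chrom_sizes)),
      ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
      seqlengths = chrom_sizes
    )
  }
}

# GRanges back to a 0-based half-open data.table.
.gr_to_dt <- function(gr) {
  data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
}

#' Read a two-column chromosome sizes table
#'
#' @param path Path to a TSV with columns chromosome name and length.
#' @return Named integer vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  dt <- fread(path, header = FALSE, select = 1:2,
              col.names = c("chrom", "size"))
  if (nrow(dt) == 0L) stop("empty chromosome sizes file: ", path)
  if (any(is.na(dt$size)) || any(dt$size <= 0)) {
    stop("invalid chromosome length in ", path)
  }
  setNames(as.integer(dt$size), dt$chrom)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
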