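# Input-based background model: ambiguity-weighted coverage, the derived
# per-position sampling distribution, and coverage-percentile artifact
# masking.

#' Ambiguity-weighted coverage of a mapping library
#'
#' Every base covered by the i-th mapping of read r contributes `1/N_r`
#' to that position's coverage, where `N_r` is the read's number of
#' genomic mappings. Mappings extending past a chromosome end contribute
#' only for their in-bounds bases. With equal mapping spans and no
#' truncation the total coverage equals the summed read lengths.
#'
#' @param library Filtered `MappingLibrary` (see [apply_standard_filters()]).
#' @return A `CoverageModel`: per-chromosome run-length encoded coverage
#'   (`cov`, an `RleList`), per-chromosome totals `cov_c`, and the
#'   chromosome sizes.
#' @export
compute_weighted_coverage <- function(library) {
  stopifnot(inherits(library, "MappingLibrary"))
  if (n_reads(library) == 0L) {
    stop("cannot build background from empty input library")
  }
  mi <- .mapinfo(library)
  sizes <- library$chrom_sizes
  bad <- !(mi$chrom %in% names(sizes))
  if (any(bad)) stop("mapping on chromosome absent from sizes table: ",
                     mi$chrom[which(bad)[1L]])
  # truncate at chromosome bounds before building ranges
  mi[, end := pmin(end, sizes[chrom])]
  mi[, start := pmax(start, 0L)]
  mi <- mi[end > start]
  gr <- .as_granges(mi$chrom, mi$start, mi$end, sizes)
  cov <- GenomicRanges::coverage(gr, weight = 1 / mi$N_r)
  cov_c <- vapply(cov, sum, numeric(1L))
  structure(
    list(cov = cov, cov_c = cov_c, chrom_sizes = sizes),
    class = "CoverageModel"
  )
}

#' @export
print.CoverageModel <- function(x, ...) {
  cat(sprintf("CoverageModel: %d chromosomes, total weighted coverage %.2f\n",
              length(x$cov), sum(x$cov_c)))
  invisible(x)
}

#' Coverage value at single positions (0-based)
#'
#' @param coverage `CoverageModel`.
#' @param chrom Chromosome name(s).
#' @param pos 0-based position(s).
#' @return Numeric vector of weighted coverage values.
#' @export
coverage_at <- function(coverage, chrom, pos) {
  stopifnot(inherits(coverage, "CoverageModel"))
  mapply(function(cc, pp) {
    as.numeric(coverage$cov[[cc]][pp + 1L])
  }, as.character(chrom), as.integer(pos), USE.NAMES = FALSE)
}

#' Build a region mask from intervals
#'
#' @param chrom,start,end Parallel vectors of 0-based half-open intervals,
#'   or a `data.table`/`GRanges` passed as `chrom` alone.
#' @return A `RegionMask` holding disjoint sorted intervals.
#' @export
region_mask <- function(chrom, start = NULL, end = NULL) {
  if (inherits(chrom, "GRanges")) {
    gr <- GenomicRanges::reduce(chrom)
  } else if (is.data.frame(chrom)) {
    dt <- as.data.table(chrom)
    gr <- GenomicRanges::reduce(.as_granges(dt$chrom, dt$start, dt$end))
  } else {
    gr <- GenomicRanges::reduce(.as_granges(chrom, start, end))
  }
  structure(list(gr = sort(gr)), class = "RegionMask")
}

#' @export
print.RegionMask <- function(x, ...) {
  cat(sprintf("RegionMask: %d intervals, %d bp\n", length(x$gr),
              sum(GenomicRanges::width(x$gr))))
  invisible(x)
}

#' Write a region mask as BED
#' @param mask `RegionMask`.
#' @param path Output path.
#' @export
write_mask_bed <- function(mask, path) {
  stopifnot(inherits(mask, "RegionMask"))
  fwrite(.gr_to_dt(mask$gr), path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read a region mask from BED
#' @param path BED file (chrom, start, end).
#' @return `RegionMask`.
#' @export
read_mask_bed <- function(path) {
  dt <- fread(path, header = FALSE, select = 1:3,
              col.names = c("chrom", "start", "end"))
  region_mask(dt)
}

#' Zero out coverage inside masked regions
#'
#' Sets `cov_n = 0` inside every masked interval and recomputes the
#' per-chromosome totals. Masking never increases coverage anywhere.
#'
#' @param coverage `CoverageModel`.
#' @param mask `RegionMask`.
#' @return Masked `CoverageModel`.
#' @export
apply_region_mask <- function(coverage, mask) {
  stopifnot(inherits(coverage, "CoverageModel"),
            inherits(mask, "RegionMask"))
  if (length(mask$gr) == 0L) return(coverage)
  cov <- coverage$cov
  for (cc in unique(as.character(GenomicRanges::seqnames(mask$gr)))) {
    if (!cc %in% names(cov)) next
    sub <- mask$gr[GenomicRanges::seqnames(mask$gr) == cc]
    len <- length(cov[[cc]])
    keep <- rep(1, len)
    kr <- IRanges::coverage(IRanges::restrict(IRanges::ranges(sub),
                                              start = 1L, end = len),
                            width = len)
    cov[[cc]] <- cov[[cc]] * (kr == 0L)
  }
  cov_c <- vapply(cov, sum, numeric(1L))
  structure(list(cov = cov, cov_c = cov_c,
                 chrom_sizes = coverage$chrom_sizes),
            class = "CoverageModel")
}

#' Sampling distribution over the effective genome
#'
#' Converts weighted input-control coverage into the per-position
#' probability `p_n = cov_n / cov_c` (per chromosome), with chromosome
#' weights `w_c` proportional to `cov_c` so that genome-wide draw
#' frequencies are proportional to `cov_n`. Positions with zero coverage
#' (outside the effective genome, or masked) have probability exactly
#' zero. The model also carries the source library's mapping index so
#' that a read can be drawn at any effective position with probability
#' `1 / (cov_n * N_r)`.
#'
#' @param coverage `CoverageModel` of the input-control library.
#' @param library The same input-control `MappingLibrary` (source of the
#'   per-position read index).
#' @param mask Optional `RegionMask`; masked positions are removed from
#'   the effective set before normalisation.
#' @return A `ProbabilityModel`.
#' @export
build_probability_model <- function(coverage, library, mask = NULL) {
  stopifnot(inherits(coverage, "CoverageModel"),
            inherits(library, "MappingLibrary"))
  if (!is.null(mask)) coverage <- apply_region_mask(coverage, mask)
  runs <- lapply(names(coverage$cov), function(cc) {
    r <- coverage$cov[[cc]]
    rv <- as.numeric(S4Vectors::runValue(r))
    rl <- S4Vectors::runLength(r)
    ends <- cumsum(as.numeric(rl))
    keep <- rv > 0
    if (!any(keep)) return(NULL)
    dt <- data.table(
      run_start0 = as.integer(ends[keep] - rl[keep]),
      run_len = as.integer(rl[keep]),
      value = rv[keep]
    )
    dt[, w := value * run_len]
    dt[, cumw := cumsum(w)]
    dt
  })
  names(runs) <- names(coverage$cov)
  runs <- runs[!vapply(runs, is.null, logical(1L))]
  if (length(runs) == 0L) stop("no effective positions (all masked?)")
  cov_c <- vapply(runs, function(d) d$cumw[nrow(d)], numeric(1L))
  w_c <- cov_c / sum(cov_c)
  mi <- .mapinfo(library)
  mi[, `:=`(start = pmax(start, 0L),
            end = pmin(end, library$chrom_sizes[chrom]))]
  mi <- mi[end > start]
  # keyed closed-interval index for point-in-mapping queries
  map_idx <- mi[, .(chrom, s = start, e = end - 1L, m_start = start,
                    m_end = end, read_id, N_r, L_r)]
  setkey(map_idx, chrom, s, e)
  structure(
    c(list(cov = coverage$cov, cov_c = cov_c, w_c = w_c, runs = runs,
           mapinfo = mi, map_idx = map_idx,
           chrom_sizes = library$chrom_sizes),
      .joint_sampler_arrays(mi, mask, library$chrom_sizes)),
    class = "ProbabilityModel"
  )
}

# Flat-array representation driving the simulation hot loop. Drawing a
# genomic position from p_n and then a read with probability
# 1/(cov_n N_r) is jointly equivalent to drawing one *unmasked piece of
# one mapping* with weight piece_length/N_r and a uniform base inside
# it: p(read, pos) = (1/N_r)/sum_c cov_c either way. This removes every
# interval query from the per-iteration path.
.joint_sampler_arrays <- function(mi, mask, chrom_sizes) {
  n <- nrow(mi)
  if (is.null(mask) || length(mask$gr) == 0L) {
    piece_row <- seq_len(n)
    piece_start <- mi$start
    piece_len <- mi$end - mi$start
  } else {
    gr <- .as_granges(mi$chrom, mi$start, mi$end, chrom_sizes)
    mg <- mask$gr
    GenomeInfoDb::seqlevels(mg) <- GenomeInfoDb::seqlevels(gr)
    pieces <- GenomicRanges::subtract(gr, mg, ignore.strand = TRUE)
    piece_row <- rep(seq_len(n), lengths(pieces))
    pieces <- unlist(pieces)
    piece_start <- GenomicRanges::start(pieces) - 1L
    piece_len <- GenomicRanges::width(pieces)
  }
  keep <- piece_len > 0L
  piece_row <- piece_row[keep]
  piece_start <- piece_start[keep]
  piece_len <- piece_len[keep]
  piece_cumw <- cumsum(piece_len / mi$N_r[piece_row])
  # expansion index: mapping rows grouped by read
  rfac <- match(mi$read_id, unique(mi$read_id))
  read_rows <- order(rfac)
  read_nmap <- tabulate(rfac)
  read_base <- cumsum(c(0L, read_nmap[-length(read_nmap)]))
  list(
    piece_row = piece_row, piece_start = piece_start,
    piece_len = piece_len, piece_cumw = piece_cumw,
    chrom_names = names(chrom_sizes),
    m_chrom = match(mi$chrom, names(chrom_sizes)),
    m_start = mi$start, m_end = mi$end,
    m_size = unname(chrom_sizes[mi$chrom]),
    m_read = rfac, m_L = mi$L_r, m_N = mi$N_r,
    read_rows = read_rows, read_nmap = read_nmap, read_base = read_base,
    read_ids = unique(mi$read_id)
  )
}

#' @export
print.ProbabilityModel <- function(x, ...) {
  np <- sum(vapply(x$runs, function(d) sum(d$run_len), numeric(1L)))
  cat(sprintf(
    "ProbabilityModel: %d chromosomes, %.0f effective positions, %d mappings\n",
    length(x$runs), np, nrow(x$mapinfo)))
  invisible(x)
}

#' Per-position sampling probability p_n
#'
#' Probability that a position draw on its chromosome returns `pos`
#' (`p_n = cov_n / cov_c`; chromosome choice itself has weight `w_c`).
#'
#' @param model `ProbabilityModel`.
#' @param chrom Chromosome name(s).
#' @param pos 0-based position(s).
#' @param genome_wide Multiply by the chromosome weight `w_c`.
#' @return Numeric probabilities.
#' @export
position_probability <- function(model, chrom, pos, genome_wide = FALSE) {
  stopifnot(inherits(model, "ProbabilityModel"))
  chrom <- as.character(chrom)
  covn <- mapply(function(cc, pp) as.numeric(model$cov[[cc]][pp + 1L]),
                 chrom, as.integer(pos), USE.NAMES = FALSE)
  p <- covn / unname(model$cov_c[chrom])
  p[is.na(p)] <- 0
  if (genome_wide) p <- p * unname(model$w_c[chrom])
  p
}

#' Detect artifact windows from extreme read-mapping counts
#'
#' Counts read mappings in sliding windows (a mapping counts in every
#' window it overlaps), computes a per-chromosome and a genome-wide
#' percentile threshold over the non-zero window counts, and flags
#' windows whose count strictly exceeds both thresholds (the conservative
#' reading; set `combine = "union"` to require either). Overlapping
#' flagged windows are unioned into the returned mask.
#'
#' @param library `MappingLibrary`.
#' @param window Window size in bp (default 100).
#' @param step Step between window starts in bp (default 50).
#' @param percentile Percentile of non-zero window counts (default
#'   99.997), computed with linear interpolation between order statistics
#'   (quantile type 7).
#' @param combine `"intersection"` (exceed both thresholds) or
#'   `"union"` (exceed either).
#' @return `RegionMask` of flagged regions.
#' @export
detect_artifact_windows <- function(library, window = 100L, step = 50L,
                                    percentile = 99.997,
                                    combine = c("intersection", "union")) {
  combine <- match.arg(combine)
  stopifnot(inherits(library, "MappingLibrary"))
  if (window <= 0L || step <= 0L) stop("window and step must be positive")
  if (n_reads(library) == 0L) stop("cannot scan an empty library")
  sizes <- library$chrom_sizes
  chrs <- names(sizes)
  tiles <- GenomicRanges::slidingWindows(
    GenomicRanges::GRanges(factor(chrs, levels = chrs),
                           IRanges::IRanges(1L, sizes), seqlengths = sizes),
    width = as.integer(window), step = as.integer(step))
  wins <- unlist(tiles)
  mi <- library$mappings
  mgr <- .as_granges(mi$chrom, pmax(mi$start, 0L),
                     pmin(mi$end, sizes[mi$chrom]), sizes)
  counts <- GenomicRanges::countOverlaps(wins, mgr)
  nz <- counts > 0L
  if (!any(nz)) return(region_mask(GenomicRanges::GRanges()))
  thr_genome <- quantile(counts[nz], probs = percentile / 100,
                         type = 7, names = FALSE)
  wchr <- as.character(GenomicRanges::seqnames(wins))
  thr_chr <- tapply(counts[nz], wchr[nz], quantile,
                    probs = percentile / 100, type = 7)
  tc <- unname(thr_chr[wchr])
  tc[is.na(tc)] <- Inf
  over_chr <- counts > tc
  over_gen <- counts > thr_genome
  flagged <- if (combine == "intersection") over_chr & over_gen
             else over_chr | over_gen
  region_mask(wins[flagged])
}
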