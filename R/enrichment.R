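# Enrichment orchestration: N background simulations, empirical P-values
# and fold-changes per family, the uniform-shuffle baseline, and the
# results writer.

#' Empirical P-value against simulated background counts
#'
#' `p = |{b : b >= sample_count}| / N`; ties count toward the numerator,
#' so the P-value of a sample equal to every background is 1 and a sample
#' strictly above all backgrounds has P-value 0 (reported as `< 1/N` in
#' the text column of [write_results()]).
#'
#' @param sample_count Observed family count in the ChIP-seq sample.
#' @param background_counts Numeric vector of the family's counts across
#'   the N simulated input libraries.
#' @return Empirical P-value in `{0, 1/N, ..., 1}`.
#' @export
empirical_pvalue <- function(sample_count, background_counts) {
  stopifnot(length(background_counts) >= 1L)
  sum(background_counts >= sample_count) / length(background_counts)
}

#' Fold-change against the mean simulated background count
#'
#' `FC = sample_count / mean(background_counts)`. A family with zero
#' background mean and zero sample count gets FC 1 by convention; zero
#' background mean with a positive sample count yields `Inf` (an unstable
#' estimate, typically a family supported by very few annotated copies).
#'
#' @inheritParams empirical_pvalue
#' @return Fold-change (possibly `Inf`).
#' @export
fold_change <- function(sample_count, background_counts) {
  stopifnot(length(background_counts) >= 1L)
  m <- mean(background_counts)
  if (m > 0) return(sample_count / m)
  if (sample_count == 0) 1 else Inf
}

#' TE family enrichment with an input-based simulated background
#'
#' Builds the background probability model from the input-control
#' library (optionally masking artifact regions), simulates `N` input
#' libraries of the ChIP-seq sample's size, counts each with the
#' ambiguity-weighted counting engine, and derives an empirical P-value
#' and fold-change per family. Families with `P < alpha` are flagged
#' enriched.
#'
#' @param sample Filtered `MappingLibrary` of the ChIP-seq sample.
#' @param input Filtered `MappingLibrary` of its input control.
#' @param annotation `TEAnnotation`.
#' @param N Number of simulated input libraries (default 100).
#' @param alpha Significance level for the enrichment flag (default 0.01).
#' @param seed Base seed; iteration `i` uses substream `seed + i`.
#' @param mask Optional `RegionMask` of artifact regions. By default it is
#'   applied both to the background model and to the counted annotation
#'   (masked bases collect no counts in sample or simulations); set
#'   `mask_counts = FALSE` to restrict masking to the background model.
#' @param mask_counts Apply the mask to the counting step too.
#' @param model Optional precomputed `ProbabilityModel` (skips the
#'   coverage build; must come from `input` with the same mask).
#' @return An `EnrichmentResult` `data.table`: `family_id`, `n_copies`,
#'   `sample_count`, `background_mean`, `fold_change`, `pvalue`,
#'   `enriched`, `unstable`. The full N x families background count
#'   matrix is in the `"background_counts"` attribute; `N`, `alpha` and
#'   `seed` are attributes too.
#' @export
run_enrichment <- function(sample, input, annotation, N = 100L,
                           alpha = 0.01, seed = 1L, mask = NULL,
                           mask_counts = TRUE, model = NULL) {
  stopifnot(inherits(sample, "MappingLibrary"),
            inherits(input, "MappingLibrary"),
            inherits(annotation, "TEAnnotation"))
  if (N < 1L) stop("N must be >= 1")
  if (n_reads(input) == 0L) {
    stop("cannot build background from empty input library")
  }
  if (is.null(model)) {
    cov <- compute_weighted_coverage(input)
    model <- build_probability_model(cov, input, mask = mask)
  }
  count_anno <- annotation
  if (!is.null(mask) && mask_counts) {
    count_anno <- mask_annotation(annotation, mask)
  }
  sample_counts <- .count_families(.mapinfo(sample), count_anno)
  fams <- names(sample_counts)
  size <- n_reads(sample)
  bg <- matrix(0, nrow = N, ncol = length(fams),
               dimnames = list(NULL, fams))
  fc <- .make_fast_counter(count_anno, model$chrom_names)
  for (i in seq_len(N)) {
    sim_mi <- .simulate_mapinfo(model, size, seed = seed, iteration = i)
    bg[i, ] <- .count_families_fast(sim_mi, fc)
  }
  bg_mean <- colMeans(bg)
  pv <- vapply(seq_along(fams),
               function(j) empirical_pvalue(sample_counts[j], bg[, j]),
               numeric(1L))
  fc <- vapply(seq_along(fams),
               function(j) fold_change(sample_counts[j], bg[, j]),
               numeric(1L))
  out <- data.table(
    family_id = fams,
    n_copies = annotation$families$n_copies[match(fams, annotation$families$family_id)],
    sample_count = unname(sample_counts),
    background_mean = unname(bg_mean),
    fold_change = unname(fc),
    pvalue = unname(pv),
    enriched = unname(pv) < alpha,
    unstable = unname(bg_mean) == 0 & unname(sample_counts) > 0
  )
  setattr(out, "background_counts", bg)
  setattr(out, "N", as.integer(N))
  setattr(out, "alpha", alpha)
  setattr(out, "seed", seed)
  setattr(out, "class", c("EnrichmentResult", class(out)))
  out[]
}

#' Remove masked bases from an annotation's copies
#'
#' Subtracts mask intervals from every TE copy, so masked regions collect
#' no counts; copy counts in the census are left at their pre-masking
#' values (the census describes the annotation, not the mask).
#'
#' @param annotation `TEAnnotation`.
#' @param mask `RegionMask`.
#' @return `TEAnnotation` with trimmed copies.
#' @export
mask_annotation <- function(annotation, mask) {
  stopifnot(inherits(annotation, "TEAnnotation"),
            inherits(mask, "RegionMask"))
  if (length(mask$gr) == 0L) return(annotation)
  cp <- annotation$copies
  gr <- .as_granges(cp$chrom, cp$start, cp$end)
  S4Vectors::mcols(gr)$family_id <- cp$family_id
  mg <- mask$gr
  GenomeInfoDb::seqlevels(mg) <- union(GenomeInfoDb::seqlevels(mg),
                                       GenomeInfoDb::seqlevels(gr))
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqlevels(mg)
  kept <- GenomicRanges::subtract(gr, mg, ignore.strand = TRUE)
  fam <- rep(S4Vectors::mcols(gr)$family_id, lengths(kept))
  kept <- unlist(kept)
  newcp <- data.table(
    chrom = as.character(GenomicRanges::seqnames(kept)),
    start = GenomicRanges::start(kept) - 1L,
    end = GenomicRanges::end(kept),
    family_id = fam
  )
  out <- new_te_annotation(newcp, level = annotation$level,
                           chrom_sizes = annotation$chrom_sizes)
  # keep the original census (copy counts refer to the unmasked annotation)
  out$families <- annotation$families
  out
}

#' Uniform-shuffle baseline counts
#'
#' Relocates every mapping independently and uniformly across the genome
#' (chromosome chosen with probability proportional to the number of
#' placements keeping the mapping fully inside it), then counts, per
#' shuffle, the number of mappings overlapping each family's copies
#' (mapping-level, unweighted). This is the naive null that ignores both
#' ambiguity and input biases; comparing it with the input-based
#' background exposes its false-positive/false-negative behaviour.
#'
#' @param library Filtered `MappingLibrary`.
#' @param chrom_sizes Named chromosome lengths.
#' @param annotation `TEAnnotation`.
#' @param N Number of shuffles (default 100).
#' @param seed Seed.
#' @return A `UniformBaseline` `data.table`: `family_id`,
#'   `observed_count` (mapping-level count of the actual library),
#'   `mean_shuffled`, `log2_fc`, `pvalue` (empirical, ties upward). The
#'   N x families shuffled count matrix is in the `"shuffled_counts"`
#'   attribute.
#' @export
uniform_background_counts <- function(library, chrom_sizes, annotation,
                                      N = 100L, seed = 1L) {
  stopifnot(inherits(library, "MappingLibrary"),
            inherits(annotation, "TEAnnotation"))
  mp <- library$mappings
  if (nrow(mp) == 0L) stop("empty library")
  span <- mp$end - mp$start
  sizes <- setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  # placements per chromosome for each span; a mapping longer than every
  # chromosome cannot be placed
  placem <- outer(span, sizes, function(s, z) pmax(z - s + 1, 0))
  tot <- rowSums(placem)
  if (any(tot == 0)) stop("mapping longer than every chromosome")
  cum <- placem %*% upper.tri(diag(ncol(placem)), diag = TRUE)
  observed <- .binary_family_counts(mp, annotation)
  fams <- annotation$families$family_id
  shuf <- matrix(0, nrow = N, ncol = length(fams),
                 dimnames = list(NULL, fams))
  with_seed(seed, {
    for (i in seq_len(N)) {
      u <- runif(nrow(mp)) * tot
      ci <- max.col(u <= cum, ties.method = "first")
      cc <- names(sizes)[ci]
      s0 <- as.integer(floor(runif(nrow(mp)) *
                               pmax(sizes[cc] - span + 1, 1)))
      sdt <- data.table(read_id = mp$read_id, chrom = cc, start = s0,
                        end = s0 + span)
      shuf[i, ] <- .binary_family_counts(sdt, annotation)
    }
  })
  ms <- colMeans(shuf)
  out <- data.table(
    family_id = fams,
    observed_count = unname(observed),
    mean_shuffled = unname(ms),
    log2_fc = log2(ifelse(unname(observed) == 0 & ms == 0, 1,
                          unname(observed) / ms)),
    pvalue = vapply(seq_along(fams),
                    function(j) empirical_pvalue(observed[j], shuf[, j]),
                    numeric(1L))
  )
  setattr(out, "shuffled_counts", shuf)
  setattr(out, "class", c("UniformBaseline", class(out)))
  out[]
}

# number of mappings overlapping each family by >= 1 bp (a mapping
# overlapping several copies of one family counts once for that family)
.binary_family_counts <- function(mappings, annotation) {
  fams <- annotation$families$family_id
  out <- setNames(numeric(length(fams)), fams)
  if (nrow(mappings) == 0L || nrow(annotation$copies) == 0L) return(out)
  mgr <- .as_granges(mappings$chrom, mappings$start, mappings$end)
  hits <- GenomicRanges::findOverlaps(mgr, annotation$index,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(out)
  pairs <- unique(data.table(
    m = S4Vectors::queryHits(hits),
    family_id = annotation$copies$family_id[S4Vectors::subjectHits(hits)]
  ))
  tab <- pairs[, .N, by = family_id]
  out[tab$family_id] <- tab$N
  out
}

#' Write enrichment results as a TSV report
#'
#' Rows are sorted by fold-change descending with ties broken
#' alphabetically by family id; numeric columns are printed at 6
#' significant digits. P-values of 0 are additionally rendered as
#' `"<1/N"` in the `pvalue_label` column.
#'
#' @param results `EnrichmentResult` from [run_enrichment()].
#' @param path Output path.
#' @param min_copies Report only families with at least this many merged
#'   copies (default 1 = all).
#' @return The path, invisibly.
#' @export
write_results <- function(results, path, min_copies = 1L) {
  stopifnot(inherits(results, "EnrichmentResult"))
  N <- attr(results, "N")
  out <- as.data.table(results)[n_copies >= min_copies]
  setorder(out, -fold_change, family_id)
  fmt <- function(x) {
    ifelse(is.finite(x), vapply(signif(x, 6L), as.character, character(1L)),
           ifelse(is.infinite(x) & x > 0, "Inf", "NA"))
  }
  txt <- data.table(
    family_id = out$family_id,
    n_copies = out$n_copies,
    sample_count = fmt(out$sample_count),
    background_mean = fmt(out$background_mean),
    fold_change = fmt(out$fold_change),
    pvalue = fmt(out$pvalue),
    pvalue_label = ifelse(out$pvalue == 0, paste0("<", fmt(1 / N)),
                          fmt(out$pvalue)),
    enriched = out$enriched
  )
  fwrite(txt, path, sep = "\t", quote = FALSE)
  invisible(path)
}
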