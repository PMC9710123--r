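# Ambiguity-weighted, nucleotide-fraction counting per TE family, and the
# read-ambiguity diagnostics (uni/multimapper composition per family and
# per library).

# Fast counting core: takes a mapinfo table (read_id, chrom, start, end,
# N_r, L_r) and returns a named numeric vector of counts aligned to the
# annotation's family universe. Each (mapping, copy) overlap contributes
# overlap_bp / (N_r * L_r). Runs inside the simulation loop, so it works
# on the annotation's prebuilt keyed interval table.
.count_families <- function(mapinfo, annotation) {
  fams <- annotation$families$family_id
  out <- setNames(numeric(length(fams)), fams)
  if (nrow(mapinfo) == 0L || nrow(annotation$copies) == 0L) return(out)
  x <- mapinfo[, .(chrom, s = start, e = end - 1L, m_start = start,
                   m_end = end, N_r, L_r)]
  ov <- foverlaps(x, annotation$idx_dt, by.x = c("chrom", "s", "e"),
                  type = "any", nomatch = NULL)
  if (nrow(ov) == 0L) return(out)
  l <- pmin(ov$m_end, ov$c_end) - pmax(ov$m_start, ov$c_start)
  agg <- rowsum(l / (ov$N_r * ov$L_r), ov$family_id)
  out[rownames(agg)] <- agg[, 1L]
  out
}

# Loop-over-copies counter for the simulation hot loop: `sim` is the
# plain-vector output of .simulate_mapinfo. Annotations there are small
# (tens to hundreds of merged copies), so a vectorised pass per copy
# beats an interval join.
.make_fast_counter <- function(annotation, chrom_names) {
  cp <- annotation$copies
  fams <- annotation$families$family_id
  list(chrom_code = match(cp$chrom, chrom_names),
       cs = cp$start, ce = cp$end,
       fk = match(cp$family_id, fams), fams = fams)
}

.count_families_fast <- function(sim, fc) {
  out <- numeric(length(fc$fams))
  names(out) <- fc$fams
  if (length(sim$draw) == 0L) return(out)
  inv <- 1 / (sim$N_r * sim$L_r)
  for (k in seq_along(fc$cs)) {
    ov <- pmin(sim$end, fc$ce[k]) - pmax(sim$start, fc$cs[k])
    sel <- ov > 0L & sim$chrom_code == fc$chrom_code[k]
    if (any(sel)) {
      out[fc$fk[k]] <- out[fc$fk[k]] + sum(ov[sel] * inv[sel])
    }
  }
  out
}

#' Fractional read-mapping counts per TE family
#'
#' Implements the ambiguity-weighted counting: for every mapping `i` of
#' read `r` and every TE copy `k` it overlaps, the family of `k` gains
#' `l / (N_r * L_r)`, where `l` is the number of reference bases of the
#' mapping overlapping the copy, `N_r` the read's number of mappings and
#' `L_r` its length. A unimapper fully inside one copy contributes
#' exactly 1; for an annotation whose families tile the genome the counts
#' sum to the number of reads.
#'
#' @param library Filtered `MappingLibrary`.
#' @param annotation `TEAnnotation` (copies merged per family).
#' @return A `FamilyCountTable`: `data.table` with `family_id`, `count`,
#'   `n_copies`; the library's read count is in the `total_reads`
#'   attribute.
#' @export
count_family_mappings <- function(library, annotation) {
  stopifnot(inherits(library, "MappingLibrary"),
            inherits(annotation, "TEAnnotation"))
  counts <- .count_families(.mapinfo(library), annotation)
  out <- data.table(family_id = names(counts), count = unname(counts))
  out <- annotation$families[, .(family_id, n_copies)][out, on = "family_id"]
  setattr(out, "total_reads", n_reads(library))
  setattr(out, "class", c("FamilyCountTable", class(out)))
  out[]
}

# read ids with at least one mapping overlapping an annotated TE copy,
# by >= 1 bp (binary overlap; read-level, not fractional)
.reads_touching_te <- function(library, annotation) {
  mp <- library$mappings
  if (nrow(mp) == 0L || nrow(annotation$copies) == 0L) return(character())
  mgr <- .as_granges(mp$chrom, mp$start, mp$end)
  hit <- IRanges::overlapsAny(mgr, annotation$index,
                              ignore.strand = TRUE)
  unique(mp$read_id[hit])
}

#' Library-level uni/multimapper x TE/non-TE composition
#'
#' Assigns each read to exactly one of the four classes
#' {unimapper, multimapper} x {TE, non-TE}; a read is a TE read when at
#' least one of its mappings overlaps an annotated TE copy by one or
#' more bases. The four fractions over a library sum to 1.
#'
#' @param library Filtered `MappingLibrary`.
#' @param annotation `TEAnnotation`.
#' @return An `AmbiguityReport` list: `fractions` (`data.table` with
#'   `class`, `n_reads`, `fraction`) and `per_family` (`data.table` with
#'   `family_id`, `n_reads_touching`, `fraction_multimapper`).
#' @export
mapping_summary <- function(library, annotation) {
  stopifnot(inherits(library, "MappingLibrary"),
            inherits(annotation, "TEAnnotation"))
  reads <- library$reads
  te_ids <- .reads_touching_te(library, annotation)
  is_te <- reads$read_id %in% te_ids
  is_multi <- reads$n_mappings > 1L
  cls <- paste0(ifelse(is_multi, "multi", "uni"), "_",
                ifelse(is_te, "TE", "nonTE"))
  lv <- c("uni_TE", "uni_nonTE", "multi_TE", "multi_nonTE")
  tab <- table(factor(cls, levels = lv))
  fractions <- data.table(
    class = lv, n_reads = as.integer(tab),
    fraction = if (nrow(reads)) as.numeric(tab) / nrow(reads)
               else rep(0, 4L)
  )
  per_family <- .family_ambiguity(library, annotation)
  structure(list(fractions = fractions, per_family = per_family),
            class = "AmbiguityReport")
}

# per family: number of distinct reads touching its copies and the
# multimapper fraction among them
.family_ambiguity <- function(library, annotation) {
  fams <- annotation$families$family_id
  base <- data.table(family_id = fams, n_reads_touching = 0L,
                     fraction_multimapper = NA_real_)
  mp <- library$mappings
  if (nrow(mp) == 0L || nrow(annotation$copies) == 0L) return(base)
  mgr <- .as_granges(mp$chrom, mp$start, mp$end)
  hits <- GenomicRanges::findOverlaps(mgr, annotation$index,
                                      ignore.strand = TRUE)
  if (length(hits) == 0L) return(base)
  pairs <- unique(data.table(
    read_id = mp$read_id[S4Vectors::queryHits(hits)],
    family_id = annotation$copies$family_id[S4Vectors::subjectHits(hits)]
  ))
  pairs <- library$reads[, .(read_id, multi = n_mappings > 1L)][
    pairs, on = "read_id"]
  st <- pairs[, .(n_reads_touching = .N,
                  fraction_multimapper = mean(multi)), by = family_id]
  out <- st[base[, .(family_id)], on = "family_id"]
  out[is.na(n_reads_touching), n_reads_touching := 0L]
  out[]
}

#' Classify families as multimapper- or unimapper-dominated
#'
#' A family is multimapper-dominated when, in every provided library,
#' more than `threshold` (default 90%) of the reads touching its copies
#' are multimappers (strict `>`, following the stricter of the two
#' published wordings; set `inclusive = TRUE` for `>=`), and symmetrically
#' for unimapper-dominated. Families touched by no read in any library
#' are classified `"no-data"`; everything else is `"mixed"`.
#'
#' @param libraries List of `MappingLibrary` objects (samples and input
#'   controls).
#' @param annotation `TEAnnotation`.
#' @param threshold Dominance threshold (default 0.9).
#' @param inclusive Use `>=` instead of strict `>`.
#' @return `data.table` with `family_id`, `class`, and per-library
#'   multimapper fractions in the `fractions` attribute.
#' @export
classify_families_by_ambiguity <- function(libraries, annotation,
                                           threshold = 0.9,
                                           inclusive = FALSE) {
  stopifnot(length(libraries) >= 1L)
  fams <- annotation$families$family_id
  fr <- vapply(libraries, function(lib) {
    fa <- .family_ambiguity(lib, annotation)
    setNames(fa$fraction_multimapper, fa$family_id)[fams]
  }, numeric(length(fams)))
  fr <- matrix(fr, nrow = length(fams),
               dimnames = list(fams, NULL))
  cmp <- function(x, t) if (inclusive) x >= t else x > t
  all_multi <- apply(fr, 1L, function(x) all(!is.na(x) & cmp(x, threshold)))
  all_uni <- apply(fr, 1L, function(x) all(!is.na(x) & cmp(1 - x, threshold)))
  no_data <- apply(fr, 1L, function(x) all(is.na(x)))
  cls <- rep("mixed", length(fams))
  cls[all_multi] <- "multimapper"
  cls[all_uni] <- "unimapper"
  cls[no_data] <- "no-data"
  out <- data.table(family_id = fams, class = cls)
  setattr(out, "fractions", fr)
  out[]
}
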