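# Repeat annotation: parsing, TE filtering, merging of copies, and the
# per-family interval index used by the counting engine.

# Repeat classes that are not transposable elements and are discarded
# before any counting (tandem/simple repeats, low complexity, structural
# RNAs, alignment artefacts). "Unknown" is a TE class here and is kept.
.NON_TE_CLASSES <- c(
  "Simple_repeat", "Low_complexity", "RNA", "tRNA", "rRNA", "snRNA",
  "scRNA", "srpRNA", "snoRNA", "ARTEFACT"
)

.MITO_NAMES <- c("chrM", "chrMT", "MT", "M")

#' Parse a repeat annotation file
#'
#' Reads repeat copies from either the UCSC RepeatMasker table dump
#' (`rmsk_table`, 16 or 17 tab-separated columns, 0-based starts), native
#' RepeatMasker `.out` output (`rm_out`, whitespace table with a 3-line
#' header, 1-based starts), or a BED dialect whose name field encodes
#' `repName:repFamily:repClass` (`bed`). Coordinates are normalised to
#' 0-based half-open.
#'
#' @param path Annotation file.
#' @param dialect One of `"rmsk_table"`, `"rm_out"`, `"bed"`.
#' @return A `data.table` with columns `chrom`, `start`, `end`, `name`,
#'   `rep_class`, `rep_family`, `strand` (one row per annotation record).
#' @export
parse_repeatmasker <- function(path, dialect = c("rmsk_table", "rm_out", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  out <- switch(dialect,
    rmsk_table = .parse_rmsk_table(path),
    rm_out = .parse_rm_out(path),
    bed = .parse_repeat_bed(path)
  )
  if (nrow(out)) {
    bad <- which(!(out$start < out$end) | is.na(out$start) | is.na(out$end) |
                   !nzchar(out$chrom))
    if (length(bad)) {
      stop("malformed annotation row (line ", bad[1L], " of parsed records) in ",
           path)
    }
  }
  setkey(out, chrom, start, end)
  out[]
}

.parse_rmsk_table <- function(path) {
  if (file.size(path) == 0L) return(.empty_records())
  dt <- tryCatch(
    fread(path, header = FALSE, sep = "\t", fill = TRUE),
    error = function(e) stop("cannot parse rmsk table ", path, ": ",
                             conditionMessage(e))
  )
  if (nrow(dt) == 0L) return(.empty_records())
  # With the leading 'bin' column the table has 17 columns; dumps without
  # it have 16. Offset the field indices accordingly.
  off <- if (ncol(dt) >= 17L) 1L else 0L
  if (ncol(dt) < 13L + off) stop("rmsk table ", path, " has too few columns")
  out <- data.table(
    chrom = as.character(dt[[5L + off]]),
    start = as.integer(dt[[6L + off]]),
    end = as.integer(dt[[7L + off]]),
    name = as.character(dt[[10L + off]]),
    rep_class = as.character(dt[[11L + off]]),
    rep_family = as.character(dt[[12L + off]]),
    strand = as.character(dt[[9L + off]])
  )
  out
}

.parse_rm_out <- function(path) {
  lines <- readLines(path)
  # native .out files start with two header lines and a blank line
  if (length(lines) >= 1L && grepl("^\\s*SW\\b|^\\s*score\\b", lines[1L])) {
    lines <- lines[-seq_len(min(3L, length(lines)))]
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) return(.empty_records())
  fields <- strsplit(trimws(lines), "\\s+")
  n <- vapply(fields, length, integer(1L))
  if (any(n < 11L)) {
    stop("malformed .out row at line ", which(n < 11L)[1L], " in ", path)
  }
  cf <- vapply(fields, `[[`, character(1L), 11L)
  cls <- sub("/.*$", "", cf)
  fam <- ifelse(grepl("/", cf), sub("^[^/]*/", "", cf), cls)
  data.table(
    chrom = vapply(fields, `[[`, character(1L), 5L),
    start = as.integer(vapply(fields, `[[`, character(1L), 6L)) - 1L,
    end = as.integer(vapply(fields, `[[`, character(1L), 7L)),
    name = vapply(fields, `[[`, character(1L), 10L),
    rep_class = cls,
    rep_family = fam,
    strand = ifelse(vapply(fields, `[[`, character(1L), 9L) == "C", "-", "+")
  )
}

.parse_repeat_bed <- function(path) {
  if (file.size(path) == 0L) return(.empty_records())
  dt <- tryCatch(
    fread(path, header = FALSE, sep = "\t", fill = TRUE),
    error = function(e) stop("cannot parse BED ", path, ": ",
                             conditionMessage(e))
  )
  if (nrow(dt) == 0L) return(.empty_records())
  if (ncol(dt) < 4L) stop("repeat BED ", path, " needs 4+ columns")
  parts <- strsplit(as.character(dt[[4L]]), ":", fixed = TRUE)
  np <- vapply(parts, length, integer(1L))
  if (any(np < 1L)) stop("malformed BED name at line ", which(np < 1L)[1L])
  pick <- function(i) vapply(parts, function(p) if (length(p) >= i) p[[i]] else NA_character_, character(1L))
  data.table(
    chrom = as.character(dt[[1L]]),
    start = as.integer(dt[[2L]]),
    end = as.integer(dt[[3L]]),
    name = pick(1L),
    rep_class = fifelse(is.na(pick(3L)), "Unknown", pick(3L)),
    rep_family = fifelse(is.na(pick(2L)), pick(1L), pick(2L)),
    strand = if (ncol(dt) >= 6L) as.character(dt[[6L]]) else "*"
  )
}

.empty_records <- function() {
  data.table(chrom = character(), start = integer(), end = integer(),
             name = character(), rep_class = character(),
             rep_family = character(), strand = character())
}

#' Keep transposable-element records only
#'
#' Removes simple repeats (micro-satellites), satellite DNA, low-complexity
#' sequence, structural RNA repeats and other explicitly non-TE classes.
#' Records classified as "Unknown" are retained. Records on the
#' mitochondrial chromosome are dropped to mirror the read-level filters.
#'
#' @param records Output of [parse_repeatmasker()].
#' @return Filtered `data.table` of the same shape.
#' @export
filter_te_records <- function(records) {
  stopifnot(is.data.table(records))
  if (nrow(records) == 0L) return(copy(records))
  strip <- function(x) sub("\\?$", "", x)
  bad_class <- strip(records$rep_class) %in% .NON_TE_CLASSES |
    startsWith(records$rep_class, "Satellite")
  bad_family <- strip(records$rep_family) %in% .NON_TE_CLASSES |
    startsWith(records$rep_family, "Satellite")
  mito <- records$chrom %in% .MITO_NAMES
  records[!(bad_class | bad_family | mito)]
}

#' Merge TE copies into the final per-family annotation
#'
#' Within each family/subfamily and chromosome, overlapping and immediately
#' adjacent (zero-gap in half-open coordinates) copies are unioned. Copies
#' of different families are never merged, so a base may belong to copies
#' of two different families. Family copy counts are recomputed after
#' merging.
#'
#' @param records Filtered records from [filter_te_records()].
#' @param level Counting level: `"name"` uses the repeat name (subfamily,
#'   rmsk `repName`); `"family"` uses the `repFamily` column.
#' @param chrom_sizes Optional named vector; when given, records on
#'   chromosomes absent from it (scaffolds) are dropped.
#' @return A `TEAnnotation` object: merged copies, per-family census, and
#'   a `GRanges` interval index for overlap queries.
#' @export
merge_family_copies <- function(records, level = c("name", "family"),
                                chrom_sizes = NULL) {
  level <- match.arg(level)
  stopifnot(is.data.table(records))
  rec <- copy(records)
  if (!is.null(chrom_sizes)) rec <- rec[chrom %in% names(chrom_sizes)]
  rec[, family_id := if (level == "name") name else rep_family]
  copies <- .merge_intervals_by_family(
    rec[, .(chrom, start, end, family_id)]
  )
  new_te_annotation(copies, level = level, chrom_sizes = chrom_sizes)
}

# Union intervals per (family_id, chrom); zero-gap adjacency merges.
.merge_intervals_by_family <- function(dt) {
  if (nrow(dt) == 0L) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), family_id = character()))
  }
  dt <- copy(dt)
  setorder(dt, family_id, chrom, start, end)
  # a new block starts when an interval begins strictly after the running
  # covered end (half-open: start > cummax(end) means a positive gap)
  dt[, grp := {
    ce <- cummax(end)
    c(0L, cumsum(start[-1L] > ce[-.N]))
  }, by = .(family_id, chrom)]
  out <- dt[, .(start = min(start), end = max(end)),
            by = .(family_id, chrom, grp)]
  out[, .(chrom, start = as.integer(start), end = as.integer(end),
          family_id)]
}

#' Construct a TEAnnotation from merged copies
#'
#' @param copies `data.table` with `chrom`, `start`, `end`, `family_id`
#'   (0-based half-open, already merged within family).
#' @param level Label recording the counting level.
#' @param chrom_sizes Optional named chromosome lengths.
#' @return `TEAnnotation` object.
#' @export
new_te_annotation <- function(copies, level = "name", chrom_sizes = NULL) {
  copies <- as.data.table(copies)[, .(chrom = as.character(chrom),
                                      start = as.integer(start),
                                      end = as.integer(end),
                                      family_id = as.character(family_id))]
  stopifnot(all(copies$start < copies$end) || nrow(copies) == 0L)
  setkey(copies, chrom, start, end)
  families <- copies[, .(n_copies = .N, total_bp = sum(end - start)),
                     by = family_id][order(family_id)]
  gr <- .as_granges(copies$chrom, copies$start, copies$end, chrom_sizes)
  S4Vectors::mcols(gr)$family_id <- copies$family_id
  # keyed closed-interval table for fast point/range overlap joins
  idx_dt <- copies[, .(chrom, s = start, e = end - 1L, c_start = start,
                       c_end = end, family_id)]
  setkey(idx_dt, chrom, s, e)
  structure(
    list(copies = copies, families = families, index = gr, idx_dt = idx_dt,
         level = level, chrom_sizes = chrom_sizes),
    class = "TEAnnotation"
  )
}

#' @export
print.TEAnnotation <- function(x, ...) {
  cat(sprintf("TEAnnotation: %d merged copies, %d families (level = %s)\n",
              nrow(x$copies), nrow(x$families), x$level))
  invisible(x)
}

#' Families with at least a minimum number of merged copies
#'
#' Enrichment statistics are only meaningful for families with enough
#' individual copies; the default threshold is 50 copies.
#'
#' @param annotation `TEAnnotation`.
#' @param min_copies Minimum merged copy count (inclusive).
#' @return Character vector of family ids.
#' @export
eligible_families <- function(annotation, min_copies = 50L) {
  stopifnot(inherits(annotation, "TEAnnotation"))
  annotation$families[n_copies >= min_copies, family_id]
}

#' Per-family annotation census
#'
#' @param annotation `TEAnnotation`.
#' @return `data.table` with `family_id`, `n_copies`, `total_bp`,
#'   `mean_copy_length`.
#' @export
family_census <- function(annotation) {
  stopifnot(inherits(annotation, "TEAnnotation"))
  out <- copy(annotation$families)
  out[, mean_copy_length := total_bp / n_copies]
  out[]
}

#' Write the merged annotation as BED
#'
#' @param annotation `TEAnnotation`.
#' @param path Output path.
#' @export
write_annotation_bed <- function(annotation, path) {
  stopifnot(inherits(annotation, "TEAnnotation"))
  cp <- annotation$copies[order(chrom, start, end, family_id)]
  fwrite(cp[, .(chrom, start, end, family_id)], path, sep = "\t",
         col.names = FALSE)
  invisible(path)
}
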