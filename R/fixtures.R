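# Synthetic fixtures: genomes with planted TE families of controlled
# copy number, divergence and enrichment, and mapping libraries with a
# known multimapping structure. Everything is fully determined by
# (spec, seed), so regeneration is byte-identical.

#' Specification of a synthetic fixture
#'
#' Defines a small genome with planted TE families, the read libraries
#' drawn from it, and optional planted enrichment and artifact loci.
#' Copies of a family with zero divergence are exact duplicates, so a
#' read drawn fully inside one of `m` copies maps to all `m` (ambiguity
#' `N_r = m`); per-copy point substitutions reduce the mapping set of
#' reads overlapping a substituted site, emulating imperfectly conserved
#' copies. The input-control read density is a blocky random field
#' (per-block Gamma weights, mean 1), emulating accessibility and
#' amplification biases; the ChIP-seq sample uses the same density times
#' a per-family enrichment fold.
#'
#' @param chrom_sizes Named integer vector (default one 100 kb
#'   chromosome).
#' @param families `data.frame` with `family_id`, `n_copies`,
#'   `copy_length`, `divergence` (substitution fraction per copy). The
#'   default plants six 8-copy, 250 bp families: three identical
#'   (multimapper) and three at 4% divergence (mostly unimapper).
#' @param read_length Read length in bp (default 50).
#' @param input_reads,sample_reads Library sizes (defaults 20,000 and
#'   10,000).
#' @param enrichment Named numeric vector of per-family fold enrichments
#'   for the sample library (default: 3x at the first family; use
#'   `numeric(0)` for an unenriched sample).
#' @param density `"blocky"` (Gamma block weights, block size 1000 bp)
#'   or `"uniform"`.
#' @param block_size Density block size in bp.
#' @param gamma_shape Shape of the per-block Gamma weights (mean fixed
#'   at 1; smaller shape = rougher density).
#' @param seed Fixture seed.
#' @return A `FixtureSpec` list.
#' @export
fixture_spec <- function(chrom_sizes = c(chr1 = 100000L),
                         families = data.frame(
                           family_id = paste0("TE", 1:6),
                           n_copies = 8L,
                           copy_length = 250L,
                           divergence = rep(c(0, 0.04), each = 3L)
                         ),
                         read_length = 50L,
                         input_reads = 20000L,
                         sample_reads = 10000L,
                         enrichment = NULL,
                         density = c("blocky", "uniform"),
                         block_size = 1000L,
                         gamma_shape = 5,
                         seed = 1L) {
  density <- match.arg(density)
  families <- as.data.table(families)
  # default enrichment plan: 3-fold at the first family
  if (is.null(enrichment)) enrichment <- setNames(3, families$family_id[1L])
  stopifnot(all(c("family_id", "n_copies", "copy_length", "divergence")
                %in% names(families)),
            all(families$n_copies >= 1L),
            all(families$copy_length > read_length),
            all(families$divergence >= 0 & families$divergence < 1),
            length(enrichment) == 0L || all(enrichment >= 1))
  if (length(enrichment) &&
      !all(names(enrichment) %in% families$family_id)) {
    stop("enrichment plan names an unknown family")
  }
  structure(
    list(chrom_sizes = setNames(as.integer(chrom_sizes),
                                names(chrom_sizes)),
         families = families, read_length = as.integer(read_length),
         input_reads = as.integer(input_reads),
         sample_reads = as.integer(sample_reads),
         enrichment = enrichment, density = density,
         block_size = as.integer(block_size), gamma_shape = gamma_shape,
         seed = as.integer(seed)),
    class = "FixtureSpec"
  )
}

.BASES <- c("A", "C", "G", "T")

#' Generate the synthetic genome and its TE annotation
#'
#' Plants every copy of every family at non-overlapping positions
#' (random gaps, minimum 2 bp so distinct copies never merge) on a random
#' background sequence, applies per-copy substitutions, and derives the
#' merged `TEAnnotation`. Also draws the per-block density weights shared
#' by the input and sample library generators.
#'
#' @param spec `FixtureSpec`.
#' @return A `FixtureGenome` list: `genome` (`DNAStringSet`),
#'   `annotation` (`TEAnnotation`), `copies` (with per-copy substitution
#'   sites), `block_weights`, `chrom_sizes`, `spec`.
#' @export
generate_genome_and_annotation <- function(spec) {
  stopifnot(inherits(spec, "FixtureSpec"))
  with_seed(spec$seed, {
    fam <- spec$families
    consensus <- lapply(seq_len(nrow(fam)), function(i) {
      sample(.BASES, fam$copy_length[i], replace = TRUE)
    })
    names(consensus) <- fam$family_id
    copies <- fam[, .(copy_idx = seq_len(n_copies),
                      len = copy_length, divergence = divergence),
                  by = family_id]
    # per-copy substitution sites (0-based, relative to copy start)
    copies[, sites := lapply(seq_len(.N), function(i) {
      ns <- round(divergence[i] * len[i])
      if (ns == 0L) integer() else sort(sample.int(len[i], ns) - 1L)
    })]
    # assign copies to chromosomes proportionally to length, then lay
    # them out left to right with random gaps (>= 2 bp)
    sizes <- spec$chrom_sizes
    copies <- copies[sample.int(nrow(copies))]
    ci <- sample.int(length(sizes), nrow(copies), replace = TRUE,
                     prob = sizes / sum(sizes))
    copies[, chrom := names(sizes)[ci]]
    placed <- copies[, {
      free <- sizes[.BY$chrom] - sum(len) - 2L * (.N + 1L)
      if (free < 0) stop("planted copies do not fit on ", .BY$chrom)
      u <- runif(.N + 1L)
      gaps <- floor(free * u / sum(u)) + 2L
      starts <- cumsum(gaps[seq_len(.N)]) + cumsum(c(0L, head(len, -1L)))
      .(family_id = family_id, copy_idx = copy_idx, len = len,
        sites = sites, start = as.integer(starts))
    }, by = chrom]
    placed[, end := start + len]
    # background sequence, then overwrite the planted copies
    seqs <- lapply(names(sizes), function(cc) {
      g <- sample(.BASES, sizes[cc], replace = TRUE)
      sub <- placed[chrom == cc]
      for (i in seq_len(nrow(sub))) {
        s <- consensus[[sub$family_id[i]]]
        st <- sub$sites[[i]]
        if (length(st)) {
          # substitute with a different base at each site
          s[st + 1L] <- .BASES[((match(s[st + 1L], .BASES) - 1L +
                                   sample.int(3L, length(st),
                                              replace = TRUE)) %% 4L) + 1L]
        }
        g[(sub$start[i] + 1L):sub$end[i]] <- s
      }
      paste(g, collapse = "")
    })
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- names(sizes)
    nblocks <- ceiling(sizes / spec$block_size)
    block_weights <- lapply(names(sizes), function(cc) {
      if (spec$density == "uniform") rep(1, nblocks[cc])
      else stats::rgamma(nblocks[cc], shape = spec$gamma_shape,
                         rate = spec$gamma_shape)
    })
    names(block_weights) <- names(sizes)
    annotation <- new_te_annotation(
      placed[, .(chrom, start, end, family_id)],
      level = "name", chrom_sizes = sizes)
    structure(
      list(genome = genome, annotation = annotation,
           copies = placed[order(chrom, start)],
           block_weights = block_weights, chrom_sizes = sizes,
           spec = spec),
      class = "FixtureGenome"
    )
  })
}

# per-chromosome weights over valid read start positions (0..size-L)
.start_weights <- function(fixture, role) {
  spec <- fixture$spec
  L <- spec$read_length
  lapply(names(fixture$chrom_sizes), function(cc) {
    size <- fixture$chrom_sizes[cc]
    nv <- size - L + 1L
    if (nv <= 0L) return(numeric())
    bw <- fixture$block_weights[[cc]]
    w <- bw[pmin((0:(nv - 1L)) %/% spec$block_size + 1L, length(bw))]
    if (role == "sample" && length(spec$enrichment)) {
      # immunoprecipitation enriches any fragment covering the element,
      # so the fold applies to every start whose read overlaps the copy
      for (ff in names(spec$enrichment)) {
        sub <- fixture$copies[chrom == cc & family_id == ff]
        for (i in seq_len(nrow(sub))) {
          lo <- max(0L, sub$start[i] - L + 1L)
          hi <- min(nv - 1L, sub$end[i] - 1L)
          if (hi >= lo) {
            idx <- (lo:hi) + 1L
            w[idx] <- w[idx] * spec$enrichment[[ff]]
          }
        }
      }
    }
    w
  }) |> setNames(names(fixture$chrom_sizes))
}

#' Generate a mapping library from a fixture genome
#'
#' Draws read start positions from the fixture's density (`input` role)
#' or from the density times the planted per-family enrichment folds
#' (`sample` role). A read falling fully inside one of a family's copies
#' receives the homologous mapping in every copy whose sequence matches
#' the read (identical copies give `N_r = m`; a read window covering a
#' substituted site of a copy excludes that copy); all other reads are
#' unimappers. The true origin of every read is recorded in the
#' `"truth"` attribute for oracle tests.
#'
#' @param fixture `FixtureGenome`.
#' @param role `"input"` or `"sample"`.
#' @param n_reads Library size (defaults to the spec's `input_reads` or
#'   `sample_reads`).
#' @param seed Seed (defaults to the spec seed offset by role).
#' @return `MappingLibrary` with a `"truth"` attribute
#'   (`data.table(read_id, origin_family, origin_copy)`).
#' @export
generate_mapping_library <- function(fixture, role = c("input", "sample"),
                                     n_reads = NULL, seed = NULL) {
  role <- match.arg(role)
  stopifnot(inherits(fixture, "FixtureGenome"))
  spec <- fixture$spec
  L <- spec$read_length
  n <- as.integer(n_reads %||%
                    if (role == "input") spec$input_reads else spec$sample_reads)
  seed <- seed %||% (spec$seed + if (role == "input") 101L else 202L)
  sizes <- fixture$chrom_sizes
  weights <- .start_weights(fixture, role)
  totals <- vapply(weights, sum, numeric(1L))
  with_seed(seed, {
    ci <- sample.int(length(sizes), n, replace = TRUE,
                     prob = totals / sum(totals))
    starts <- integer(n)
    for (k in seq_along(sizes)) {
      idx <- which(ci == k)
      if (!length(idx)) next
      cw <- cumsum(weights[[k]])
      u <- runif(length(idx)) * cw[length(cw)]
      starts[idx] <- findInterval(u, cw)  # 0-based start position
    }
    chroms <- names(sizes)[ci]
    prefix <- if (role == "input") "i" else "c"
    ids <- sprintf("%s%07d", prefix, seq_len(n))
    .build_fixture_library(fixture, ids, chroms, starts, L)
  })
}

# Resolve each read's mapping set from its origin position, honouring
# copy identity/divergence; assemble the MappingLibrary + truth table.
.build_fixture_library <- function(fixture, ids, chroms, starts, L) {
  sizes <- fixture$chrom_sizes
  cp <- fixture$copies
  reads <- data.table(read_id = ids, chrom = chroms, start = starts)
  reads[, origin_family := NA_character_]
  reads[, origin_copy := NA_integer_]
  maps <- vector("list", nrow(cp) + 1L)
  # locate the copy fully containing each read, per chromosome
  for (cc in unique(reads$chrom)) {
    sub <- cp[chrom == cc]
    if (!nrow(sub)) next
    ridx <- which(reads$chrom == cc)
    j <- findInterval(reads$start[ridx], sub$start)
    jj <- pmax(j, 1L)
    inside <- j >= 1L & (reads$start[ridx] + L) <= sub$end[jj]
    reads[ridx[inside], `:=`(
      origin_family = sub$family_id[j[inside]],
      origin_copy = sub$copy_idx[j[inside]]
    )]
  }
  # background reads: a single mapping at the origin
  bg <- reads[is.na(origin_family)]
  maps[[1L]] <- bg[, .(read_id, chrom, start, end = start + L)]
  # TE reads: one mapping per sequence-compatible copy of the family
  te <- reads[!is.na(origin_family)]
  out_idx <- 2L
  if (nrow(te)) {
    for (ff in unique(te$origin_family)) {
      fcp <- cp[family_id == ff]
      sub <- te[origin_family == ff]
      ocp <- match(sub$origin_copy, fcp$copy_idx)
      off <- sub$start - fcp$start[ocp]
      # sites of copy j inside the read window [off, off+L)
      nsites <- function(j) {
        sj <- fcp$sites[[j]]
        if (!length(sj)) return(rep(0L, nrow(sub)))
        findInterval(off + L - 1L, sj) - findInterval(off - 1L, sj)
      }
      clean <- vapply(seq_len(nrow(fcp)), nsites,
                      integer(nrow(sub))) == 0L
      clean <- matrix(clean, nrow = nrow(sub))
      origin_clean <- clean[cbind(seq_len(nrow(sub)), ocp)]
      # read maps to copy j != origin iff both windows are
      # substitution-free; the origin always maps
      keep <- clean & origin_clean
      keep[cbind(seq_len(nrow(sub)), ocp)] <- TRUE
      kidx <- which(keep, arr.ind = TRUE)
      maps[[out_idx]] <- data.table(
        read_id = sub$read_id[kidx[, 1L]],
        chrom = fcp$chrom[kidx[, 2L]],
        start = fcp$start[kidx[, 2L]] + off[kidx[, 1L]]
      )[, end := start + L][]
      out_idx <- out_idx + 1L
    }
  }
  mp <- rbindlist(maps[!vapply(maps, is.null, logical(1L))],
                  use.names = TRUE)
  lib <- new_mapping_library(
    mp, data.table(read_id = ids, length = L), sizes)
  attr(lib, "truth") <- reads[, .(read_id, origin_family, origin_copy)]
  lib
}

#' Plant a stack of artifact reads at one locus
#'
#' Adds `intensity` identical unimapper reads starting at the given
#' position, creating the hot-window signature that
#' [detect_artifact_windows()] is designed to flag. `intensity = 0`
#' returns the library unchanged.
#'
#' @param library `MappingLibrary`.
#' @param chrom Chromosome of the locus.
#' @param position 0-based start of the stacked reads.
#' @param intensity Number of stacked reads.
#' @param read_length Length of the planted reads (default: the
#'   library's most common read length).
#' @return `MappingLibrary` with the planted reads appended.
#' @export
plant_artifact_region <- function(library, chrom, position, intensity,
                                  read_length = NULL) {
  stopifnot(inherits(library, "MappingLibrary"), intensity >= 0)
  if (intensity == 0) return(library)
  L <- as.integer(read_length %||%
                    as.integer(names(sort(table(library$reads$length),
                                          decreasing = TRUE))[1L]))
  size <- library$chrom_sizes[[chrom]]
  if (position < 0 || position + L > size) {
    stop("artifact locus out of chromosome bounds")
  }
  ids <- sprintf("a%07d", seq_len(intensity))
  mp <- rbind(
    library$mappings[, .(read_id, chrom, start, end)],
    data.table(read_id = ids, chrom = chrom, start = as.integer(position),
               end = as.integer(position) + L)
  )
  rl <- rbind(library$reads[, .(read_id, length)],
              data.table(read_id = ids, length = L))
  out <- new_mapping_library(mp, rl, library$chrom_sizes)
  tr <- attr(library, "truth")
  if (!is.null(tr)) {
    attr(out, "truth") <- rbind(
      tr, data.table(read_id = ids, origin_family = NA_character_,
                     origin_copy = NA_integer_))
  }
  out
}

#' Write a fixture library as SAM
#'
#' Emits one record per mapping: the first mapping of each read as the
#' primary record (with its sequence taken from the genome when given),
#' the rest as secondary records with `*` sequences, mirroring an
#' all-mappings mapper output. Round-trips through [load_mappings()].
#'
#' @param library `MappingLibrary` whose mapping spans equal the read
#'   lengths (true for generated fixture libraries).
#' @param path Output SAM path.
#' @param genome Optional `DNAStringSet` for primary-record sequences.
#' @return The path, invisibly.
#' @export
write_sam <- function(library, path, genome = NULL) {
  stopifnot(inherits(library, "MappingLibrary"))
  sizes <- library$chrom_sizes
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(sizes), sizes))
  mp <- copy(library$mappings)
  setorder(mp, read_id, chrom, start, end)
  mp[, primary := seq_len(.N) == 1L, by = read_id]
  seqs <- rep("*", nrow(mp))
  pri <- which(mp$primary)
  if (!is.null(genome)) {
    seqs[pri] <- vapply(pri, function(i) {
      as.character(Biostrings::subseq(genome[[mp$chrom[i]]],
                                      mp$start[i] + 1L, mp$end[i]))
    }, character(1L))
  } else {
    seqs[pri] <- strrep("A", mp$end[pri] - mp$start[pri])
  }
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                 mp$read_id, ifelse(mp$primary, 0L, 256L), mp$chrom,
                 mp$start + 1L, 0L, mp$end - mp$start, seqs)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Write fixture genome files (FASTA, BED, chrom.sizes, truth TSV)
#'
#' @param fixture `FixtureGenome`.
#' @param prefix Output path prefix.
#' @return Named character vector of the written paths.
#' @export
write_fixture_files <- function(fixture, prefix) {
  stopifnot(inherits(fixture, "FixtureGenome"))
  paths <- c(fasta = paste0(prefix, ".fa"),
             bed = paste0(prefix, ".bed"),
             sizes = paste0(prefix, ".chrom.sizes"))
  Biostrings::writeXStringSet(fixture$genome, paths[["fasta"]])
  cp <- fixture$copies[order(chrom, start)]
  fwrite(cp[, .(chrom, start, end,
                name = paste(family_id, family_id, "TE", sep = ":"))],
         paths[["bed"]], sep = "\t", col.names = FALSE)
  fwrite(data.table(chrom = names(fixture$chrom_sizes),
                    size = unname(fixture$chrom_sizes)),
         paths[["sizes"]], sep = "\t", col.names = FALSE)
  paths
}
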