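# Simulated input libraries: inverse-transform position sampling from the
# input-conditioned distribution, read selection with probability
# 1/(cov_n * N_r), and center-shifting of the selected read's mappings.

# Draw n (chromosome, position) pairs from the model. Assumes the RNG
# stream has been set by the caller. Chromosomes are drawn with weight
# w_c, then positions by inverse transform over the positive-coverage
# runs (probability within a run is uniform since coverage is constant
# on a run). Only effective positions can be returned.
.draw_positions <- function(model, n) {
  chrs <- names(model$w_c)
  ci <- sample.int(length(chrs), n, replace = TRUE, prob = model$w_c)
  out <- data.table(draw = seq_len(n), chrom = chrs[ci], pos = NA_integer_)
  for (cc in sort(unique(out$chrom))) {
    idx <- which(out$chrom == cc)
    runs <- model$runs[[cc]]
    total <- runs$cumw[nrow(runs)]
    u <- runif(length(idx)) * total
    ri <- findInterval(u, runs$cumw) + 1L
    ri <- pmin(ri, nrow(runs))
    off <- pmin(as.integer(floor(runif(length(idx)) * runs$run_len[ri])),
                runs$run_len[ri] - 1L)
    out[idx, pos := runs$run_start0[ri] + off]
  }
  out
}

# For each drawn position, pick one overlapping mapping with probability
# proportional to 1/N_r (which normalises to 1/(cov_n * N_r)). Returns
# one row per draw with the selected mapping and its read.
.draw_reads <- function(model, posdt) {
  x <- posdt[, .(draw, chrom, s = pos, e = pos)]
  cand <- foverlaps(x, model$map_idx, by.x = c("chrom", "s", "e"),
                    type = "any", nomatch = NULL)
  if (uniqueN(cand$draw) != nrow(posdt)) {
    stop("internal consistency error: effective position with no reads")
  }
  # exponential race: the candidate with the minimal Exp(1)/weight wins,
  # equivalent to a weighted draw with weight 1/N_r
  cand[, e_race := rexp(.N) * N_r]
  win <- cand[cand[, .I[which.min(e_race)], by = draw]$V1]
  data.table(
    draw = win$draw, chrom = win$chrom, pos = win$i.s,
    read_id = win$read_id, sel_start = win$m_start, sel_end = win$m_end,
    L_r = win$L_r
  )
}

# Full simulation chain on the model's flat arrays. One draw selects an
# (unmasked piece of a) mapping with weight piece_len/N_r and a uniform
# base within it -- jointly equivalent to the position-then-read chain --
# then every mapping of the selected read is translated so that base
# becomes the selected mapping's center. Returns one row per simulated
# mapping as a plain list of parallel vectors.
.simulate_mapinfo <- function(model, sample_size, seed, iteration) {
  n <- as.integer(sample_size)
  total_w <- model$piece_cumw[length(model$piece_cumw)]
  d <- with_seed(.iter_seed(seed, iteration), {
    u <- runif(n) * total_w
    pi <- pmin(findInterval(u, model$piece_cumw) + 1L,
               length(model$piece_cumw))
    off <- pmin(as.integer(floor(runif(n) * model$piece_len[pi])),
                model$piece_len[pi] - 1L)
    list(row = model$piece_row[pi], pos = model$piece_start[pi] + off)
  })
  delta <- d$pos - .mapping_center(model$m_start[d$row],
                                   model$m_end[d$row])
  ri <- model$m_read[d$row]
  nm <- model$read_nmap[ri]
  rows <- model$read_rows[sequence(nm, from = model$read_base[ri] + 1L)]
  draw <- rep.int(seq_len(n), nm)
  dlt <- rep.int(delta, nm)
  s <- pmax(model$m_start[rows] + dlt, 0L)
  e <- pmin(model$m_end[rows] + dlt, model$m_size[rows])
  keep <- e > s
  draw <- draw[keep]
  nr <- tabulate(draw, nbins = n)
  list(
    draw = draw,
    src_row = rows[keep],
    chrom_code = model$m_chrom[rows[keep]],
    start = s[keep],
    end = e[keep],
    N_r = nr[draw],
    L_r = model$m_L[d$row][draw]
  )
}

# 0-based center position of a mapping [start, end): left-of-center for
# even spans.
.mapping_center <- function(start, end) {
  start + (end - start - 1L) %/% 2L
}

#' Draw genomic positions from the background model
#'
#' Chromosome drawn with probability `w_c`, then a position by inverse
#' transform on the cumulative per-position distribution. Only effective
#' (coverage > 0, unmasked) positions can be returned.
#'
#' @param model `ProbabilityModel`.
#' @param n Number of draws.
#' @param seed Optional seed; with `NULL` the current RNG stream is used.
#' @return `data.table` with `chrom` and 0-based `pos`, one row per draw.
#' @export
sample_position <- function(model, n = 1L, seed = NULL) {
  stopifnot(inherits(model, "ProbabilityModel"))
  with_seed(seed, .draw_positions(model, n))[, .(chrom, pos)]
}

#' Draw a read at an effective position
#'
#' Among the reads with a mapping overlapping the position, one is chosen
#' with probability `1 / (cov_n * N_r)`; the probabilities at any
#' effective position sum to one by construction.
#'
#' @param model `ProbabilityModel`.
#' @param chrom,position Parallel vectors of positions (0-based).
#' @param seed Optional seed.
#' @return Character vector of selected read ids.
#' @export
sample_read_at_position <- function(model, chrom, position, seed = NULL) {
  stopifnot(inherits(model, "ProbabilityModel"))
  posdt <- data.table(draw = seq_along(position),
                      chrom = as.character(chrom),
                      pos = as.integer(position))
  win <- with_seed(seed, .draw_reads(model, posdt))
  win[order(draw), read_id]
}

#' Shift a read's mappings so a target position becomes the selected
#' mapping's center
#'
#' The shift `delta = target - center(selected mapping)` (center of a
#' span-`s` mapping is `start + floor((s - 1) / 2)`, left-of-center for
#' even spans) is added to the start of every mapping of the read.
#' Mappings pushed partially out of chromosome bounds are truncated to
#' their in-bounds portion; mappings pushed entirely out are dropped.
#'
#' @param mappings `data.table` with `chrom`, `start`, `end`: the mappings
#'   of one read.
#' @param selected_index Row index of the selected mapping.
#' @param target_position 0-based target position.
#' @param chrom_sizes Named chromosome lengths (for truncation).
#' @return Shifted `data.table` of mappings (possibly fewer rows).
#' @export
center_shift_mappings <- function(mappings, selected_index, target_position,
                                  chrom_sizes) {
  mp <- as.data.table(mappings)
  stopifnot(selected_index >= 1L, selected_index <= nrow(mp))
  delta <- as.integer(target_position) -
    .mapping_center(mp$start[selected_index], mp$end[selected_index])
  out <- mp[, .(chrom, start = start + delta, end = end + delta)]
  out[, `:=`(start = pmax(start, 0L),
             end = pmin(end, chrom_sizes[chrom]))]
  out[end > start]
}

#' Simulate one input library of a given size
#'
#' Repeats the position-draw, read-draw, center-shift chain `sample_size`
#' times (with replacement), producing a simulated library matching the
#' ChIP-seq sample's size. The RNG stream is fully determined by
#' `(seed, iteration)`, so iterations can be computed in any order.
#'
#' @param model `ProbabilityModel` built from the input control.
#' @param sample_size Number of simulated reads (the ChIP-seq sample's
#'   read count).
#' @param seed Base seed.
#' @param iteration Simulation index; the substream seed is
#'   `seed + iteration`.
#' @return `MappingLibrary` of simulated reads. Read ids are
#'   `"s<iteration>_<draw>"`; the source read of each draw is kept in the
#'   `"provenance"` attribute.
#' @export
simulate_library <- function(model, sample_size, seed = 1L, iteration = 1L) {
  stopifnot(inherits(model, "ProbabilityModel"))
  if (sample_size <= 0L) stop("sample_size must be positive")
  mp <- .simulate_mapinfo(model, sample_size, seed, iteration)
  ids <- paste0("s", iteration, "_", mp$draw)
  out_map <- data.table(read_id = ids,
                        chrom = model$chrom_names[mp$chrom_code],
                        start = mp$start, end = mp$end)
  rl <- unique(data.table(read_id = ids, length = mp$L_r))
  lib <- new_mapping_library(out_map, rl, model$chrom_sizes)
  src <- unique(data.table(
    draw = mp$draw,
    source_read_id = model$read_ids[model$m_read[mp$src_row]]))
  attr(lib, "provenance") <- list(seed = seed, iteration = iteration,
                                  source = src[order(draw)])
  lib
}
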