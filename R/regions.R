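#' Hough intercept of a seed hit
#'
#' Collinear seed hits of a read lying on the alignment diagonal share the
#' line `t = q + c` with slope 1; only the intercept `c = t - q` needs to be
#' determined, so each hit casts a vote for its intercept.
#'
#' @param qpos,tpos 0-based positions on the read and reference (vectorized).
#' @return integer vector of intercepts (bases).
#' @export
hough_intercept <- function(qpos, tpos) as.integer(tpos) - as.integer(qpos)

#' Accumulate seed-hit votes over intercept bins
#'
#' The intercept axis is rasterized into partitions of length `L/3` (`L` the
#' read length) so that at least one partition is fully covered by the read;
#' each hit increments the bin holding its intercept, per (reference,
#' strand).  Negative intercepts are clamped to bin 0.  With
#' `smear = TRUE` a hit whose intercept falls within `L/6` of its bin's
#' lower boundary casts an additional boundary vote in the next-lower bin,
#' protecting true locations that straddle a bin edge; boundary votes are
#' tracked separately from the primary counts.
#'
#' @param hits data.frame from [collect_hits()] (columns `qpos`, `tpos`,
#'   `ref`, `strand`).
#' @param read_len read length in bases (>= 3).
#' @param smear logical; cast boundary votes (default `TRUE`).
#' @return An `nm_bins` object: `bin_width` plus a data.frame `votes` with
#'   columns `ref`, `strand`, `bin`, `count` (primary votes) and `count_sel`
#'   (primary + boundary votes, used for selection).
#' @export
vote <- function(hits, read_len, smear = TRUE) {
  stopifnot(read_len >= 3)
  bw <- max(1L, as.integer(read_len) %/% 3L)
  strand_i <- ifelse(hits$strand == "-", 1L, 0L)
  ic <- pmax(0L, hough_intercept(hits$qpos, hits$tpos))
  bin <- ic %/% bw
  key <- paste(hits$ref, strand_i, bin, sep = ":")
  primary <- table(key)
  sel <- primary
  if (smear && nrow(hits)) {
    low <- (ic %% bw) < read_len / 6 & bin > 0L
    if (any(low)) {
      key2 <- paste(hits$ref[low], strand_i[low], bin[low] - 1L, sep = ":")
      extra <- table(key2)
      all_keys <- union(names(sel), names(extra))
      sel <- structure(as.integer(primary[all_keys]), names = all_keys)
      sel[is.na(sel)] <- 0L
      sel[names(extra)] <- sel[names(extra)] + as.integer(extra)
    }
  }
  all_keys <- names(sel)
  parts <- do.call(rbind, strsplit(all_keys, ":", fixed = TRUE))
  cnt <- as.integer(primary[all_keys]); cnt[is.na(cnt)] <- 0L
  votes <- data.frame(ref = as.integer(parts[, 1L]),
                      strand = c("+", "-")[as.integer(parts[, 2L]) + 1L],
                      bin = as.integer(parts[, 3L]),
                      count = cnt,
                      count_sel = as.integer(sel),
                      stringsAsFactors = FALSE)
  votes <- votes[order(votes$ref, votes$strand, votes$bin), , drop = FALSE]
  rownames(votes) <- NULL
  structure(list(bin_width = bw, read_len = as.integer(read_len), votes = votes),
            class = "nm_bins")
}

#' Select candidate regions from the vote accumulator
#'
#' Bins with a (selection) count above 75 percent of the maximum are kept.
#' A bin covering intercepts `[b*w, (b+1)*w)` corresponds to reads occupying
#' up to `(b+1)*w + L` on the reference, so the bin's reference footprint
#' `[b*w, (b+1)*w + L)` is expanded by one read length on both sides to
#' tolerate indel drift, giving `[b*w - L, (b+1)*w + 2L)`.  Overlapping
#' selected bins on the same (reference, strand) are merged into a single
#' region with summed primary votes.  On circular references the region may
#' run across the origin (flagged `wraps`); otherwise it is clipped.
#'
#' @param bins an `nm_bins` from [vote()].
#' @param ref_lens integer vector of reference lengths (by 0-based ref id).
#' @param circular logical (scalar or per-reference): treat references as
#'   circular.
#' @param threshold keep bins with `count_sel` strictly above
#'   `threshold * max(count_sel)` (default 0.75).
#' @return data.frame of regions: `ref`, `strand`, `start`, `end` (0-based
#'   half-open; may extend past the sequence when `wraps`), `votes`, `wraps`.
#' @export
select_regions <- function(bins, ref_lens, circular = FALSE, threshold = 0.75) {
  stopifnot(inherits(bins, "nm_bins"))
  v <- bins$votes
  empty <- data.frame(ref = integer(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      votes = integer(0), wraps = logical(0),
                      stringsAsFactors = FALSE)
  if (nrow(v) == 0L) return(empty)
  keep <- v$count_sel > threshold * max(v$count_sel)
  v <- v[keep, , drop = FALSE]
  if (nrow(v) == 0L) return(empty)
  L <- bins$read_len
  bw <- bins$bin_width
  circ <- rep_len(circular, length(ref_lens))
  out <- empty
  for (grp in split(v, list(v$ref, v$strand), drop = TRUE)) {
    grp <- grp[order(grp$bin), , drop = FALSE]
    rl <- ref_lens[grp$ref[1L] + 1L]
    start <- grp$bin * bw - L
    end <- (grp$bin + 1L) * bw + 2L * L
    # merge overlapping expanded bins
    ms <- start[1L]; me <- end[1L]; mv <- grp$count[1L]
    flush <- function(s, e, vv) {
      wraps <- FALSE
      if (isTRUE(circ[grp$ref[1L] + 1L])) {
        if (e - s >= rl) { s <- 0L; e <- rl }
        else if (s < 0L || e > rl) wraps <- TRUE
      } else {
        s <- max(0L, s); e <- min(rl, e)
      }
      data.frame(ref = grp$ref[1L], strand = grp$strand[1L],
                 start = as.integer(s), end = as.integer(e),
                 votes = as.integer(vv), wraps = wraps,
                 stringsAsFactors = FALSE)
    }
    grp_out <- empty
    if (nrow(grp) > 1L) for (i in 2:nrow(grp)) {
      if (start[i] <= me) { me <- max(me, end[i]); mv <- mv + grp$count[i] }
      else { grp_out <- rbind(grp_out, flush(ms, me, mv))
             ms <- start[i]; me <- end[i]; mv <- grp$count[i] }
    }
    grp_out <- rbind(grp_out, flush(ms, me, mv))
    # on a circle the first and last intervals may meet across the origin
    if (isTRUE(circ[grp$ref[1L] + 1L]) && nrow(grp_out) > 1L) {
      f <- 1L; l <- nrow(grp_out)
      if (grp_out$end[l] >= grp_out$start[f] + rl) {
        s <- grp_out$start[l]; e <- grp_out$end[f] + rl
        merged <- flush(s, min(e, s + rl), grp_out$votes[f] + grp_out$votes[l])
        grp_out <- rbind(merged, grp_out[-c(f, l), , drop = FALSE])
      }
    }
    out <- rbind(out, grp_out)
  }
  rownames(out) <- NULL
  out[order(-out$votes), , drop = FALSE]
}

# extract a region's sequence, wrapping across the origin if needed;
# wrapped regions are always shorter than the reference (see select_regions)
region_sequence <- function(region, refs) {
  seqref <- refs[[region$ref + 1L]]
  rl <- nchar(seqref)
  s <- region$start; e <- region$end
  if (s >= 0L && e <= rl) return(substr(seqref, s + 1L, e))
  s_mod <- ((s %% rl) + rl) %% rl
  substr(paste0(seqref, seqref), s_mod + 1L, s_mod + (e - s))
}
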