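#' Location correctness of an alignment
#'
#' A read is correctly mapped when its clip-adjusted start is within
#' `tol` bases of the simulated location and the strand matches: the number
#' of leading clipped bases is subtracted from the reported position to
#' compensate for the shift.
#'
#' @param aln one alignment record from [map_reads()].
#' @param truth_row matching row of the simulation truth table.
#' @param tol tolerance in bases (default 50).
#' @return logical.
#' @export
location_correct <- function(aln, truth_row, tol = 50L) {
  if (bitwAnd(aln$flag, 4L) > 0L) return(FALSE)
  if (aln$strand != truth_row$strand) return(FALSE)
  if (!identical(aln$ref, truth_row$ref)) return(FALSE)
  runs <- cpp_cigar_runs(aln$cigar, aln$pos)
  clip <- if (nrow(runs) && runs$op[1L] %in% c("S", "H")) runs$len[1L] else 0L
  abs((aln$pos - clip) - truth_row$start) <= tol
}

#' Per-base placement accuracy of an alignment
#'
#' Walks the CIGAR and counts read bases placed at exactly the reference
#' position they were simulated from (mismatched bases count when placed
#' correctly; inserted bases have no true position and can never be
#' correct).  Soft/hard-clipped portions are not taken into account:
#' `eligible` counts the non-clipped read bases, the precision denominator.
#'
#' @inheritParams location_correct
#' @return integer vector `c(correct, placed, eligible, total)`: correctly
#'   placed bases, bases placed on the reference (M/=/X), non-clipped read
#'   bases, and total read bases.
#' @export
base_accuracy <- function(aln, truth_row) {
  tmap <- truth_base_map(truth_row)
  total <- length(tmap)
  if (bitwAnd(aln$flag, 4L) > 0L || !identical(aln$ref, truth_row$ref))
    return(c(correct = 0L, placed = 0L, eligible = 0L, total = total))
  qmap <- cpp_cigar_qmap(aln$cigar, aln$pos)
  runs <- cpp_cigar_runs(aln$cigar, aln$pos)
  clipped <- sum(runs$len[runs$op %in% c("S", "H")])
  eligible <- length(qmap) - clipped
  # qmap is over the reference-orientation query; flip for '-' reads
  if (aln$strand == "-") qmap <- rev(qmap)
  if (aln$strand != truth_row$strand)
    return(c(correct = 0L, placed = sum(!is.na(qmap)), eligible = eligible,
             total = total))
  n <- min(length(qmap), total)
  ok <- !is.na(qmap[seq_len(n)]) & !is.na(tmap[seq_len(n)]) &
        qmap[seq_len(n)] == tmap[seq_len(n)]
  c(correct = sum(ok), placed = sum(!is.na(qmap)), eligible = eligible,
    total = total)
}

#' Location and base-level precision/recall of a mapping run
#'
#' Location metrics follow the clip-adjusted `+-tol` criterion
#' ([location_correct()]); base metrics follow the exact-placement
#' criterion ([base_accuracy()]).  Precision is computed over mapped reads
#' (aligned bases); recall over all simulated reads (bases).
#'
#' @param alignments `nm_alignments` from [map_reads()] (secondary records
#'   are ignored).
#' @param truth truth table from [simulate_reads()].
#' @param tol location tolerance (default 50).
#' @return list of class `nm_eval`: `location_precision`,
#'   `location_recall`, `base_precision`, `base_recall`, plus the
#'   underlying counts.
#' @export
evaluate_alignments <- function(alignments, truth, tol = 50L) {
  prim <- Filter(function(a) bitwAnd(a$flag, 256L) == 0L, alignments)
  byid <- stats::setNames(prim, vapply(prim, `[[`, "", "qname"))
  n_total <- nrow(truth)
  n_mapped <- 0L; n_correct <- 0L
  b_correct <- 0; b_eligible <- 0; b_placed <- 0; b_total <- 0
  for (i in seq_len(n_total)) {
    tr <- truth[i, ]
    a <- byid[[tr$read]]
    b_total <- b_total + nchar(gsub("D", "", tr$edit))
    if (is.null(a) || bitwAnd(a$flag, 4L) > 0L) next
    n_mapped <- n_mapped + 1L
    if (location_correct(a, tr, tol)) n_correct <- n_correct + 1L
    ba <- base_accuracy(a, tr)
    b_correct <- b_correct + ba[["correct"]]
    b_placed <- b_placed + ba[["placed"]]
    b_eligible <- b_eligible + ba[["eligible"]]
  }
  structure(list(
    location_precision = if (n_mapped) n_correct / n_mapped else NA_real_,
    location_recall = n_correct / n_total,
    base_precision = if (b_eligible) b_correct / b_eligible else NA_real_,
    base_recall = if (b_total) b_correct / b_total else NA_real_,
    reads_total = n_total, reads_mapped = n_mapped, reads_correct = n_correct,
    bases_correct = b_correct, bases_placed = b_placed,
    bases_eligible = b_eligible, bases_total = b_total), class = "nm_eval")
}

#' @export
print.nm_eval <- function(x, ...) {
  cat(sprintf(paste0("location precision %.1f%% recall %.1f%% ",
                     "(%d/%d reads correct); base precision %.1f%%\n"),
              100 * x$location_precision, 100 * x$location_recall,
              x$reads_correct, x$reads_total, 100 * x$base_precision))
  invisible(x)
}

#' Majority-vote consensus from a pileup of alignments
#'
#' Per reference position the plurality event among A, C, G, T and deletion
#' is called; ties fall back to the reference base, and positions with
#' coverage below `min_cov` are not called (written as `N`).  An insertion
#' is placed after a position when more than half of the reads covering the
#' junction report one; the most frequent (length, sequence) pair wins.
#'
#' @param alignments `nm_alignments` against a single reference.
#' @param reference the reference sequence (named character or string).
#' @param min_cov minimum coverage to call a position (default 20).
#' @return list: `consensus` (character string, `N` at uncalled positions),
#'   `calls` (data.frame `pos`, `ref_base`, `call`, `cov`) and `n_uncalled`.
#' @export
consensus_call <- function(alignments, reference, min_cov = 20L) {
  s <- toupper(reference[[1L]])
  rl <- nchar(s)
  prim <- Filter(function(a) bitwAnd(a$flag, 4L) == 0L &&
                             bitwAnd(a$flag, 256L) == 0L, alignments)
  if (length(prim) == 0L)
    return(list(consensus = paste(rep("N", rl), collapse = ""),
                calls = NULL, n_uncalled = rl))
  p <- cpp_pileup(vapply(prim, `[[`, 0L, "pos"),
                  vapply(prim, `[[`, "", "cigar"),
                  vapply(prim, `[[`, "", "seq"), rl)
  counts <- p$counts  # rl x 5: A C G T del
  cov <- p$cov
  refch <- strsplit(s, "", fixed = TRUE)[[1L]]
  refcode <- match(refch, c("A", "C", "G", "T"))
  best <- max.col(counts, ties.method = "first")
  bestn <- counts[cbind(seq_len(rl), best)]
  # plurality ties -> reference base
  nbest <- rowSums(counts == bestn & counts > 0L)
  tie <- nbest > 1L & !is.na(refcode)
  tie_ref <- tie & counts[cbind(seq_len(rl), ifelse(is.na(refcode), 1L, refcode))] == bestn
  best[tie_ref] <- refcode[tie_ref]
  call <- c("A", "C", "G", "T", "-")[best]
  call[cov < min_cov] <- "N"
  call[cov == 0L] <- "N"
  # insertions: majority of reads covering the junction
  ins <- character(rl)
  if (length(p$ins_pos)) {
    byp <- split(p$ins_seq, p$ins_pos)
    for (nmp in names(byp)) {
      pos <- as.integer(nmp)
      if (pos < 1L || pos > rl) next
      if (cov[pos] < min_cov) next
      if (length(byp[[nmp]]) * 2L > cov[pos]) {
        tab <- sort(table(byp[[nmp]]), decreasing = TRUE)
        ins[pos] <- names(tab)[1L]
      }
    }
  }
  out <- call
  out[out == "-"] <- ""
  with_ins <- paste0(out, ins)
  consensus <- paste(with_ins, collapse = "")
  list(consensus = consensus,
       calls = data.frame(pos = seq_len(rl) - 1L, ref_base = refch,
                          call = call, cov = cov, stringsAsFactors = FALSE),
       n_uncalled = sum(call == "N"))
}

#' Window-vote structural-variant caller
#'
#' Long indel runs (at least `min_event` bases, to avoid sequencing errors)
#' in spanning alignments vote per reference position; maximal windows where
#' the supporting fraction exceeds `min_frac` with at least `min_reads`
#' supporters are emitted per event type.  Windows closer than the larger of
#' the two window lengths are merged to avoid fragmented events.  The size
#' estimate is the median supporting run length.
#'
#' @param alignments `nm_alignments` against a single reference.
#' @param ref_len reference length.
#' @param min_frac minimum supporting read fraction (default 0.15).
#' @param min_reads minimum supporting reads (default 5).
#' @param min_event minimum indel run length counted as an event (default 20).
#' @return data.frame of calls: `type` (`I`/`D`), `start`, `end` (0-based
#'   half-open window), `size`, `n_reads`, `frac`.
#' @export
sv_call <- function(alignments, ref_len, min_frac = 0.15, min_reads = 5L,
                    min_event = 20L) {
  prim <- Filter(function(a) bitwAnd(a$flag, 4L) == 0L &&
                             bitwAnd(a$flag, 256L) == 0L, alignments)
  events <- list()
  all_events <- list()
  spans <- list()
  for (ai in seq_along(prim)) {
    a <- prim[[ai]]
    runs <- cpp_cigar_runs(a$cigar, a$pos)
    ref_ops <- runs$op %in% c("M", "=", "X", "D")
    spans[[length(spans) + 1L]] <-
      c(a$pos, max(runs$tpos[ref_ops] + runs$len[ref_ops]))
    ind <- runs$op %in% c("I", "D")
    if (any(ind))
      all_events[[length(all_events) + 1L]] <-
        data.frame(type = runs$op[ind], tpos = runs$tpos[ind],
                   len = runs$len[ind], read = ai, stringsAsFactors = FALSE)
    big <- ind & runs$len >= min_event
    if (any(big))
      events[[length(events) + 1L]] <-
        data.frame(type = runs$op[big], tpos = runs$tpos[big],
                   len = runs$len[big], read = ai, stringsAsFactors = FALSE)
  }
  empty <- data.frame(type = character(0), start = integer(0),
                      end = integer(0), size = integer(0),
                      n_reads = integer(0), frac = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(events) == 0L) return(empty)
  ev <- do.call(rbind, events)
  ev_all <- do.call(rbind, all_events)
  spans <- do.call(rbind, spans)
  cov <- IRanges::coverage(IRanges::IRanges(spans[, 1L] + 1L, spans[, 2L]),
                           width = ref_len)
  out <- empty
  for (ty in c("I", "D")) {
    e <- ev[ev$type == ty, , drop = FALSE]
    if (nrow(e) == 0L) next
    # support footprint: D covers its interval, I votes over +-len/2
    if (ty == "D") {
      ir <- IRanges::IRanges(e$tpos + 1L, e$tpos + e$len)
    } else {
      ir <- IRanges::IRanges(pmax(1L, e$tpos - e$len %/% 2L + 1L),
                             pmin(ref_len, e$tpos + e$len %/% 2L))
    }
    sup <- IRanges::coverage(ir, width = ref_len)
    hot <- sup >= min_reads & sup > min_frac * cov
    win <- IRanges::reduce(IRanges::IRanges(hot))
    win <- win[IRanges::width(win) > 0L]
    if (length(win) == 0L) next
    # merge windows closer than the larger of the two lengths
    repeat {
      if (length(win) < 2L) break
      gaps <- IRanges::start(win)[-1L] - IRanges::end(win)[-length(win)] - 1L
      lens <- pmax(IRanges::width(win)[-1L], IRanges::width(win)[-length(win)])
      j <- which(gaps < lens)[1L]
      if (is.na(j)) break
      win <- IRanges::reduce(c(win[seq_len(length(win)) != j + 1L],
                               IRanges::IRanges(IRanges::start(win)[j],
                                                IRanges::end(win)[j + 1L])))
    }
    for (w in seq_along(win)) {
      ws <- IRanges::start(win)[w] - 1L; we <- IRanges::end(win)[w]
      inwin <- if (ty == "D") e$tpos < we & (e$tpos + e$len) > ws
               else e$tpos >= ws - 50L & e$tpos <= we + 50L
      supp <- e[inwin, , drop = FALSE]
      if (length(unique(supp$read)) < min_reads) next
      # Size estimate: alignments split a long event into several runs when
      # stray matches interrupt it, so per supporting read all same-type
      # indel runs inside the window are re-aggregated (short ones
      # included), then the median across reads is taken.
      ea <- ev_all[ev_all$type == ty & ev_all$read %in% supp$read, , drop = FALSE]
      ea <- if (ty == "D") ea[ea$tpos < we & (ea$tpos + ea$len) > ws, , drop = FALSE]
            else ea[ea$tpos >= ws - 50L & ea$tpos <= we + 50L, , drop = FALSE]
      per_read <- vapply(split(ea$len, ea$read), sum, 0)
      wcov <- max(1, round(mean(as.numeric(cov[(ws + 1L):we]))))
      size <- as.integer(round(median(per_read)))
      if (ty == "I") {
        # the window is the voting footprint; the breakpoint estimate is the
        # median supporting junction position
        bp <- as.integer(round(median(supp$tpos)))
        ws <- bp; we <- bp
      } else {
        # deleted interval: median supporting start, extended by the size
        ws <- as.integer(round(median(vapply(split(ea$tpos, ea$read), min, 0))))
        we <- ws + size
      }
      out <- rbind(out, data.frame(
        type = ty, start = ws, end = we, size = size,
        n_reads = length(per_read), frac = length(per_read) / wcov,
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Expected alignment-space signals of injected SV events
#'
#' Reads simulated from the original reference and mapped to the SV
#' reference expose an inserted segment as a deletion run (`D`) covering it
#' and a deleted segment as an insertion run (`I`) at its breakpoint.
#'
#' @param sv_truth truth table from [inject_svs()].
#' @return data.frame `type` (`I`/`D`), `start`, `end`, `size` in SV
#'   reference coordinates.
#' @export
expected_sv_signals <- function(sv_truth) {
  data.frame(
    type = ifelse(sv_truth$type == "insertion", "D", "I"),
    start = sv_truth$pos_sv,
    end = ifelse(sv_truth$type == "insertion",
                 sv_truth$pos_sv + sv_truth$size, sv_truth$pos_sv),
    size = sv_truth$size, stringsAsFactors = FALSE)
}

#' Match SV calls against the truth set
#'
#' Greedy one-to-one matching: a call is a true positive when its size is
#' within a 25 percent margin of the true size and its start and end are
#' each less than 25 percent of the event size away from the true
#' breakpoints.
#'
#' @param calls data.frame from [sv_call()].
#' @param truth data.frame from [expected_sv_signals()].
#' @param margin matching margin (default 0.25).
#' @return list: `precision`, `recall`, `tp`, plus the matched index pairs.
#' @export
sv_match <- function(calls, truth, margin = 0.25) {
  used <- rep(FALSE, nrow(truth))
  matches <- list()
  for (i in seq_len(nrow(calls))) {
    for (j in seq_len(nrow(truth))) {
      if (used[j] || calls$type[i] != truth$type[j]) next
      sz <- truth$size[j]
      if (abs(calls$size[i] - sz) > margin * sz) next
      if (abs(calls$start[i] - truth$start[j]) >= margin * sz) next
      if (abs(calls$end[i] - truth$end[j]) >= margin * sz) next
      used[j] <- TRUE
      matches[[length(matches) + 1L]] <- c(call = i, truth = j)
      break
    }
  }
  tp <- length(matches)
  list(precision = if (nrow(calls)) tp / nrow(calls) else NA_real_,
       recall = if (nrow(truth)) tp / nrow(truth) else NA_real_,
       tp = tp, matches = do.call(rbind, matches))
}
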