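#' Per-base error profile for read simulation
#'
#' Errors are drawn i.i.d. per position from a multinomial over match,
#' mismatch, insertion and deletion.  Presets emulate the two nanopore read
#' classes: `"2D"` (both-strand consensus reads, 80-88 percent raw
#' accuracy) uses rates (5, 4, 8) percent and `"1D"` (single-strand reads,
#' below 65-75 percent accuracy) uses (10, 5, 15) percent.
#'
#' @param name `"2D"`, `"1D"`, or `"custom"` with explicit rates.
#' @param mismatch_rate,ins_rate,del_rate per-base probabilities (each in
#'   `[0, 1)`, summing to less than 1).
#' @return An `nm_profile` list.
#' @export
error_profile <- function(name = c("2D", "1D", "custom"),
                          mismatch_rate = NULL, ins_rate = NULL,
                          del_rate = NULL) {
  name <- match.arg(name)
  rates <- switch(name,
    "2D" = c(0.05, 0.04, 0.08),
    "1D" = c(0.10, 0.05, 0.15),
    "custom" = c(mismatch_rate, ins_rate, del_rate))
  stopifnot(length(rates) == 3, all(rates >= 0), all(rates < 1), sum(rates) < 1)
  structure(list(name = name, mismatch_rate = rates[1L],
                 ins_rate = rates[2L], del_rate = rates[3L]),
            class = "nm_profile")
}

#' Generate a random reference sequence
#'
#' @param length sequence length (>= 1).
#' @param gc GC content (default 0.5).
#' @param seed RNG seed for reproducibility.
#' @param circular mark the reference as circular (carried as an attribute
#'   for the mapper configuration).
#' @param name sequence name.
#' @return named character vector of length 1 with attribute `circular`.
#' @export
make_reference <- function(length, gc = 0.5, seed = NULL, circular = FALSE,
                           name = "ref") {
  stopifnot(length >= 1)
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  s <- paste(sample(c("A", "C", "G", "T"), length, TRUE, prob = p),
             collapse = "")
  structure(stats::setNames(s, name), circular = circular)
}

#' Mutate a reference with SNPs and small indels
#'
#' Emulates the divergence of a draft nanopore-only assembly: SNPs at
#' `snp_rate` per base and indel events at `indel_rate` per base with sizes
#' from a truncated geometric distribution capped at `indel_max`.
#'
#' @param ref named character vector of length 1 (or plain string).
#' @param snp_rate per-base substitution rate (default 6e-4).
#' @param indel_rate per-base indel event rate (default 0.0067).
#' @param indel_max maximum indel size (default 10).
#' @param seed RNG seed.
#' @return list: `seq` (mutated reference, same name) and `variants`
#'   (data.frame `type`, `pos` 0-based on the input, `pos_mut` 0-based on
#'   the mutated sequence, `size`, `ref_allele`, `alt_allele`).
#' @export
mutate_reference <- function(ref, snp_rate = 6e-4, indel_rate = 0.0067,
                             indel_max = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nm <- if (is.null(names(ref))) "ref" else names(ref)[1L]
  s <- toupper(ref[[1L]])
  n <- nchar(s)
  n_snp <- rbinom(1L, n, snp_rate)
  n_ind <- rbinom(1L, n, indel_rate)
  ev <- data.frame(pos = integer(0), type = character(0), size = integer(0),
                   stringsAsFactors = FALSE)
  if (n_snp > 0L)
    ev <- rbind(ev, data.frame(pos = sample.int(n, n_snp) - 1L, type = "snp",
                               size = 1L, stringsAsFactors = FALSE))
  if (n_ind > 0L) {
    sizes <- pmin(1L + rgeom(n_ind, 0.4), indel_max)
    type <- sample(c("ins", "del"), n_ind, TRUE)
    ev <- rbind(ev, data.frame(pos = sample.int(n, n_ind) - 1L, type = type,
                               size = sizes, stringsAsFactors = FALSE))
  }
  ev <- ev[order(ev$pos), , drop = FALSE]
  # drop events overlapping the footprint of the previous one
  if (nrow(ev) > 1L) {
    span <- ifelse(ev$type == "del", ev$size, 1L)
    keep <- rep(TRUE, nrow(ev))
    last_end <- -1L
    for (i in seq_len(nrow(ev))) {
      if (ev$pos[i] <= last_end || ev$pos[i] + span[i] > n) keep[i] <- FALSE
      else last_end <- ev$pos[i] + span[i] - 1L
    }
    ev <- ev[keep, , drop = FALSE]
  }
  bases <- c("A", "C", "G", "T")
  chunks <- character(0)
  vars <- vector("list", nrow(ev))
  cursor <- 0L  # 0-based position on the input consumed so far
  shift <- 0L   # output minus input coordinate
  for (i in seq_len(nrow(ev))) {
    p <- ev$pos[i]; sz <- ev$size[i]; ty <- ev$type[i]
    chunks <- c(chunks, substr(s, cursor + 1L, p))
    if (ty == "snp") {
      old <- substr(s, p + 1L, p + 1L)
      new <- sample(setdiff(bases, old), 1L)
      chunks <- c(chunks, new)
      vars[[i]] <- data.frame(type = "snp", pos = p, pos_mut = p + shift,
                              size = 1L, ref_allele = old, alt_allele = new,
                              stringsAsFactors = FALSE)
      cursor <- p + 1L
    } else if (ty == "ins") {
      new <- paste(sample(bases, sz, TRUE), collapse = "")
      chunks <- c(chunks, new)
      vars[[i]] <- data.frame(type = "ins", pos = p, pos_mut = p + shift,
                              size = sz, ref_allele = "", alt_allele = new,
                              stringsAsFactors = FALSE)
      cursor <- p
      shift <- shift + sz
    } else {
      old <- substr(s, p + 1L, p + sz)
      vars[[i]] <- data.frame(type = "del", pos = p, pos_mut = p + shift,
                              size = sz, ref_allele = old, alt_allele = "",
                              stringsAsFactors = FALSE)
      cursor <- p + sz
      shift <- shift - sz
    }
  }
  chunks <- c(chunks, substr(s, cursor + 1L, n))
  out <- stats::setNames(paste(chunks, collapse = ""), nm)
  list(seq = out, variants = do.call(rbind, vars))
}

#' Structural-variant event set
#'
#' The benchmark set of 20 events: 10 insertions and 10 deletions with sizes
#' 100, 300, 500, 1000, 1500, 2000, 2500, 3000, 3500 and 4000 bp, placed at
#' random non-overlapping positions away from the sequence ends.
#'
#' @param ref_len reference length.
#' @param seed RNG seed.
#' @param sizes event sizes (each used once per type).
#' @param margin minimum distance between events and from the ends.
#' @return data.frame `type` (`insertion`/`deletion`), `pos` (0-based),
#'   `size`, ordered by position.
#' @export
default_sv_events <- function(ref_len, seed = NULL,
                              sizes = c(100L, 300L, 500L, 1000L, 1500L,
                                        2000L, 2500L, 3000L, 3500L, 4000L),
                              margin = 15000L) {
  if (!is.null(seed)) set.seed(seed)
  ev <- data.frame(type = rep(c("insertion", "deletion"), each = length(sizes)),
                   pos = NA_integer_, size = rep(sizes, 2L),
                   stringsAsFactors = FALSE)
  ev <- ev[sample.int(nrow(ev)), , drop = FALSE]
  taken_s <- integer(0); taken_e <- integer(0)
  for (i in seq_len(nrow(ev))) {
    span <- if (ev$type[i] == "deletion") ev$size[i] else 0L
    repeat {
      p <- sample.int(ref_len - span - 2L * margin, 1L) + margin
      if (!any(p - margin < taken_e & p + span + margin > taken_s)) break
    }
    ev$pos[i] <- p
    taken_s <- c(taken_s, p - margin); taken_e <- c(taken_e, p + span + margin)
  }
  ev <- ev[order(ev$pos), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Inject structural variants into a reference
#'
#' @param ref named character vector of length 1.
#' @param events data.frame with `type` (`insertion`/`deletion`), `pos`
#'   (0-based on the input reference) and `size`; deletion footprints must
#'   not overlap.
#' @param seed RNG seed (inserted sequences are random).
#' @return list: `seq` (the SV reference) and `truth` (events with the
#'   additional columns `pos_sv`, the 0-based breakpoint coordinate on the
#'   SV reference, and `seq` for insertions).
#' @export
inject_svs <- function(ref, events, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  nm <- if (is.null(names(ref))) "ref" else names(ref)[1L]
  s <- toupper(ref[[1L]])
  n <- nchar(s)
  ev <- events[order(events$pos), , drop = FALSE]
  span <- ifelse(ev$type == "deletion", ev$size, 0L)
  if (any(ev$pos + span > n)) stop("SV events run past the reference end")
  if (nrow(ev) > 1L && any(ev$pos[-1L] < (ev$pos + span)[-nrow(ev)]))
    stop("SV events overlap")
  chunks <- character(0)
  cursor <- 0L; shift <- 0L
  ev$pos_sv <- NA_integer_; ev$seq <- ""
  for (i in seq_len(nrow(ev))) {
    p <- ev$pos[i]
    chunks <- c(chunks, substr(s, cursor + 1L, p))
    ev$pos_sv[i] <- p + shift
    if (ev$type[i] == "insertion") {
      ins <- paste(sample(c("A", "C", "G", "T"), ev$size[i], TRUE), collapse = "")
      ev$seq[i] <- ins
      chunks <- c(chunks, ins)
      cursor <- p
      shift <- shift + ev$size[i]
    } else {
      cursor <- p + ev$size[i]
      shift <- shift - ev$size[i]
    }
  }
  chunks <- c(chunks, substr(s, cursor + 1L, n))
  rownames(ev) <- NULL
  list(seq = stats::setNames(paste(chunks, collapse = ""), nm), truth = ev)
}

#' Simulate error-prone reads with per-base ground truth
#'
#' Reads are drawn from uniform random positions and strands; each emitted
#' base is generated by an i.i.d. draw over match / mismatch / insertion /
#' deletion at the profile's rates.  The per-read edit string records every
#' event, so the exact reference coordinate of every read base (or `NA` for
#' inserted bases) can be reconstructed with [truth_base_map()].
#'
#' @param ref named character vector of length 1.
#' @param n number of reads.
#' @param min_len,max_len read length range (uniform; defaults 1000-5000).
#' @param profile an [error_profile()].
#' @param seed RNG seed.
#' @param id_prefix read name prefix.
#' @return list: `reads` (named character vector) and `truth` (data.frame
#'   `read`, `ref`, `strand`, `start`, `end` -- 0-based half-open on the
#'   forward reference -- and `edit`, the per-event string over `=XID`).
#' @export
simulate_reads <- function(ref, n, min_len = 1000L, max_len = 5000L,
                           profile = error_profile("2D"), seed = NULL,
                           id_prefix = "read") {
  if (!is.null(seed)) set.seed(seed)
  nm <- if (is.null(names(ref))) "ref" else names(ref)[1L]
  s <- toupper(ref[[1L]])
  rl <- nchar(s)
  stopifnot(rl >= max_len)
  pr <- c(1 - profile$mismatch_rate - profile$ins_rate - profile$del_rate,
          profile$mismatch_rate, profile$ins_rate, profile$del_rate)
  bases <- c("A", "C", "G", "T")
  reads <- character(n); names(reads) <- sprintf("%s%05d", id_prefix, seq_len(n))
  truth <- data.frame(read = names(reads), ref = nm,
                      strand = sample(c("+", "-"), n, TRUE),
                      start = NA_integer_, end = NA_integer_,
                      edit = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    L <- min_len + sample.int(max_len - min_len + 1L, 1L) - 1L
    # sample events until L bases are emitted
    ev <- integer(0)
    repeat {
      need <- L - sum(ev != 4L)
      if (need <= 0L) break
      ev <- c(ev, sample.int(4L, size = ceiling(need / pr[1L]) + 20L,
                             replace = TRUE, prob = pr))
    }
    emitted <- cumsum(ev != 4L)
    ev <- ev[seq_len(which(emitted == L)[1L])]
    consumed <- sum(ev != 3L)  # events consuming a template base
    while (consumed > rl) {   # deletion-heavy draw on a short reference
      ev <- ev[-length(ev)]
      consumed <- sum(ev != 3L)
    }
    start <- sample.int(rl - consumed + 1L, 1L) - 1L
    template <- substr(s, start + 1L, start + consumed)
    if (truth$strand[i] == "-") template <- cpp_revcomp(template)
    tch <- strsplit(template, "", fixed = TRUE)[[1L]]
    toff <- cumsum(c(0L, head(ev != 3L, -1L)))  # template offset per event
    emit <- ev != 4L
    out <- character(sum(emit))
    oe <- ev[emit]; op <- toff[emit]
    is_m <- oe == 1L
    out[is_m] <- tch[op[is_m] + 1L]
    is_x <- oe == 2L
    if (any(is_x)) {  # rotate to one of the three other bases
      code <- match(tch[op[is_x] + 1L], bases)
      out[is_x] <- bases[(code - 1L + sample.int(3L, sum(is_x), TRUE)) %% 4L + 1L]
    }
    is_i <- oe == 3L
    if (any(is_i)) out[is_i] <- sample(bases, sum(is_i), TRUE)
    reads[i] <- paste(out, collapse = "")
    truth$start[i] <- start
    truth$end[i] <- start + consumed
    truth$edit[i] <- paste(c("=", "X", "I", "D")[ev], collapse = "")
  }
  list(reads = reads, truth = truth)
}

#' Reconstruct the per-base truth map of a simulated read
#'
#' @param truth_row one row of the `truth` data.frame of
#'   [simulate_reads()].
#' @return integer vector over read positions: the 0-based forward-strand
#'   reference coordinate each read base was simulated from, or `NA` for
#'   inserted bases.
#' @export
truth_base_map <- function(truth_row) {
  ev <- strsplit(truth_row$edit, "", fixed = TRUE)[[1L]]
  toff <- cumsum(c(0L, head(ev != "I", -1L)))  # template consumed by =/X/D
  emit <- ev != "D"
  tmpl_pos <- ifelse(ev[emit] == "I", NA_integer_, toff[emit])
  if (truth_row$strand == "-") {
    consumed <- truth_row$end - truth_row$start
    ifelse(is.na(tmpl_pos), NA_integer_,
           truth_row$end - 1L - tmpl_pos)
  } else {
    ifelse(is.na(tmpl_pos), NA_integer_, truth_row$start + tmpl_pos)
  }
}

#' Write simulated reads and their truth table to disk
#'
#' @param sim result of [simulate_reads()].
#' @param fasta,truth_tsv output paths (FASTA reads; tab-separated truth
#'   with the per-base map encoded in the edit-string column).
#' @return invisibly, the two paths.
#' @export
write_simulated <- function(sim, fasta, truth_tsv) {
  writeLines(paste0(">", names(sim$reads), "\n", sim$reads), fasta)
  utils::write.table(sim$truth, truth_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta, truth_tsv))
}
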