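#' Mapper options
#'
#' Collects the tunable parameters of the pipeline with their defaults.
#'
#' @param k stage-II kmer length (default 6).
#' @param l graph out-degree / maximum jump (default 9).
#' @param shapes spaced-seed shape patterns for stage I.
#' @param min_walk minimum covered bases for a walk to become anchors
#'   (default 12, the stage-I seed span).
#' @param e expected error rate for L1 filtering and anchored clustering
#'   (default 0.45).
#' @param mode final alignment algorithm: `"myers"` (edit distance,
#'   default), `"gotoh"` (affine gaps) or `"anchor"` (anchored).
#' @param ambiguity ambiguity factor `F` in `[0, 1]`; regions passing the
#'   `n_kmers` rule are also emitted as secondary alignments when `F > 0`.
#' @param evalue_max drop alignments with `ZE` above this (default `Inf`).
#' @param circular treat references as circular.
#' @param max_postings stage-I high-frequency key cap (default 500).
#' @param bin_smear cast boundary votes into the next-lower bin.
#' @param threshold Hough bin selection fraction (default 0.75).
#' @param max_regions process at most this many top-voted regions per read.
#' @param gumbel an [evalue_params()] object.
#' @param chaining run the LCSk chaining and L1 refinement stages (default
#'   `TRUE`).  Disabling them scores regions on the raw, unchained anchor
#'   set; exposed for ablation studies only.
#' @param extended_cigar keep `=`/`X` ops in SAM output instead of `M`.
#' @param threads accepted for interface compatibility; the pipeline is
#'   deterministic and single-threaded, so results never depend on it.
#' @return a named list of options.
#' @export
nm_options <- function(k = 6L, l = 9L, shapes = nm_default_shapes(),
                       min_walk = 12L, e = 0.45,
                       mode = c("myers", "gotoh", "anchor"),
                       ambiguity = 0, evalue_max = Inf, circular = FALSE,
                       max_postings = 500L, bin_smear = TRUE,
                       threshold = 0.75, max_regions = 64L,
                       gumbel = evalue_params(), chaining = TRUE,
                       extended_cigar = FALSE, threads = 1L) {
  list(k = as.integer(k), l = as.integer(l), shapes = shapes,
       min_walk = as.integer(min_walk), e = e, mode = match.arg(mode),
       ambiguity = ambiguity, evalue_max = evalue_max, circular = circular,
       max_postings = as.integer(max_postings), bin_smear = isTRUE(bin_smear),
       threshold = threshold, max_regions = as.integer(max_regions),
       gumbel = gumbel, chaining = isTRUE(chaining),
       extended_cigar = isTRUE(extended_cigar),
       threads = as.integer(threads))
}

#' Map reads against a reference set
#'
#' Runs the full five-stage pipeline for each read: seed collection, Hough
#' region selection, graph-walk anchoring, LCSk chaining, L1 refinement and
#' final alignment of the best-scoring region(s).  Reads with no candidate
#' region or no scoring chain are reported unmapped.
#'
#' @param reads named character vector of read sequences (or
#'   `DNAStringSet`).
#' @param reference an `nm_index` from [build_index()], or the references
#'   themselves (indexed on the fly).
#' @param opts options list from [nm_options()].
#' @param quals optional named character vector of Phred quality strings.
#' @return An `nm_alignments` object: list of alignment records (one or
#'   more per read) with fields `qname`, `flag`, `ref`, `pos` (0-based),
#'   `mapq`, `cigar` (extended ops), `strand`, `edit`, `score` (AS),
#'   `evalue`, `f`, `n_a`, `seq` (reference-orientation sequence), `qual`.
#' @export
map_reads <- function(reads, reference, opts = nm_options(), quals = NULL) {
  index <- if (inherits(reference, "nm_index")) reference
           else build_index(reference, opts$shapes)
  reads <- as_ref_set(reads)
  out <- list()
  for (i in seq_along(reads)) {
    q <- if (!is.null(quals)) quals[[names(reads)[i]]] else NULL
    out <- c(out, map_read_one(reads[[i]], names(reads)[i], index, opts, q))
  }
  structure(out, class = "nm_alignments", ref_names = index$ref_names,
            ref_lens = index$ref_lens)
}

#' @export
print.nm_alignments <- function(x, ...) {
  flags <- vapply(x, `[[`, 0L, "flag")
  cat(sprintf("%d alignment records (%d mapped, %d unmapped, %d secondary)\n",
              length(x), sum(!bitwAnd(flags, 4L) & !bitwAnd(flags, 256L)),
              sum(bitwAnd(flags, 4L) > 0L), sum(bitwAnd(flags, 256L) > 0L)))
  invisible(x)
}

unmapped_record <- function(id, seq, qual) {
  list(qname = id, flag = 4L, ref = NA_character_, pos = 0L, mapq = 0L,
       cigar = "*", strand = "*", edit = NA_integer_, score = NA_integer_,
       evalue = NA_real_, f = 0, n_a = 0L, seq = seq,
       qual = if (is.null(qual)) "*" else qual)
}

map_read_one <- function(read, id, index, opts, qual = NULL) {
  read <- toupper(read)
  L <- nchar(read)
  unmapped <- list(unmapped_record(id, read, qual))
  if (L < max(nchar(vapply(index$shapes, `[[`, "", "pattern")))) return(unmapped)

  hits <- cpp_collect_hits(index$ptr, read, opts$max_postings)
  if (length(hits$qpos) == 0L) return(unmapped)
  hitdf <- data.frame(qpos = hits$qpos, tpos = hits$tpos, ref = hits$ref,
                      strand = c("+", "-")[hits$strand + 1L],
                      stringsAsFactors = FALSE)
  bins <- vote(hitdf, L, smear = opts$bin_smear)
  regions <- select_regions(bins, index$ref_lens, opts$circular, opts$threshold)
  if (nrow(regions) == 0L) return(unmapped)
  if (nrow(regions) > opts$max_regions)
    regions <- regions[seq_len(opts$max_regions), , drop = FALSE]

  rc <- cpp_revcomp(read)
  scores <- vector("list", nrow(regions))
  chains <- vector("list", nrow(regions))
  for (r in seq_len(nrow(regions))) {
    regseq <- region_sequence(regions[r, ], index$refs)
    query <- if (regions$strand[r] == "-") rc else read
    anchors <- filter_walks(graph_walk(query, regseq, opts$k, opts$l),
                            opts$min_walk)
    if (nrow(anchors) == 0L) {
      scores[[r]] <- score_region(lcsk_chain(anchors), L,
                                  index$ref_lens[regions$ref[r] + 1L], opts$e)
      next
    }
    if (opts$chaining) {
      ch <- lcsk_chain(anchors)
      fit <- fit_l1(ch)
      ch2 <- confidence_refilter_and_rechain(band_filter(ch, fit, opts$e, L))
    } else {
      # ablation: score the raw anchor set without monotone selection
      anchors$credit <- anchors$qend - anchors$qstart
      ch2 <- structure(list(anchors = anchors,
                            total_covered = sum(anchors$credit)),
                       class = "nm_chain")
    }
    chains[[r]] <- ch2
    scores[[r]] <- score_region(ch2, L, index$ref_lens[regions$ref[r] + 1L],
                                opts$e)
  }
  fvals <- vapply(scores, `[[`, 0, "f")
  if (all(fvals <= 0)) return(unmapped)

  amb <- ambiguity_count(scores, opts$ambiguity)
  mapq <- mapping_quality(amb$n_a)
  emit <- unique(c(amb$best, if (opts$ambiguity > 0) amb$selected))
  total_ref <- sum(as.numeric(index$ref_lens))
  out <- list()
  for (r in emit) {
    if (is.null(chains[[r]]) || nrow(chains[[r]]$anchors) == 0L) next
    regseq <- region_sequence(regions[r, ], index$refs)
    query <- if (regions$strand[r] == "-") rc else read
    aln <- switch(opts$mode,
      myers = myers_semiglobal(query, regseq),
      gotoh = gotoh_semiglobal(query, regseq, opts$gumbel$scores),
      anchor = anchored_alignment(query, regseq, chains[[r]], opts$e))
    rl <- index$ref_lens[regions$ref[r] + 1L]
    pos <- regions$start[r] + aln$tstart
    if (opts$circular) pos <- ((pos %% rl) + rl) %% rl
    as_score <- alignment_score(aln$cigar, opts$gumbel$scores)
    ze <- evalue_ze(aln$cigar, L, total_ref, opts$gumbel)
    if (ze > opts$evalue_max) next
    secondary <- r != amb$best
    out[[length(out) + 1L]] <- list(
      qname = id,
      flag = (if (regions$strand[r] == "-") 16L else 0L) +
             (if (secondary) 256L else 0L),
      ref = index$ref_names[regions$ref[r] + 1L],
      pos = as.integer(pos), mapq = mapq, cigar = aln$cigar,
      strand = regions$strand[r], edit = aln$edit, score = as_score,
      evalue = ze, f = fvals[r], n_a = amb$n_a,
      seq = query,
      qual = if (is.null(qual)) "*"
             else if (regions$strand[r] == "-") rev_string(qual) else qual)
  }
  has_primary <- any(!vapply(out, function(x) bitwAnd(x$flag, 256L) > 0L, TRUE))
  if (length(out) == 0L || !has_primary) return(unmapped)
  out
}

rev_string <- function(x) paste(rev(strsplit(x, "")[[1L]]), collapse = "")
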