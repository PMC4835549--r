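#' Semi-global alignment with Myers' bit-vector algorithm
#'
#' Aligns the whole read against a region with free gaps at the region ends,
#' minimizing edit distance.  The bit-vector scan locates the optimal window
#' and distance; the CIGAR is reconstructed by a banded dynamic programme
#' whose band slack is derived from that distance, so the reported path is
#' an exact optimum.
#'
#' @param read read sequence (fully consumed by the alignment).
#' @param region_seq region sequence.
#' @return list: `cigar` (extended ops `=`/`X`/`I`/`D`), `edit` (distance),
#'   `tstart`, `tend` (0-based half-open interval on `region_seq`).
#' @export
myers_semiglobal <- function(read, region_seq) {
  r <- cpp_align_semiglobal(toupper(read), toupper(region_seq))
  list(cigar = r$cigar, edit = r$edit, tstart = r$start, tend = r$end)
}

#' Semi-global affine-gap alignment (Gotoh)
#'
#' Score-maximizing alternative to [myers_semiglobal()] with affine gap
#' costs (a gap of length g costs `gap_open + g * gap_extend`).  Uses a full
#' dynamic-programming matrix and is intended for moderate region sizes.
#'
#' @inheritParams myers_semiglobal
#' @param scores named numeric vector with `match`, `mismatch`, `gap_open`,
#'   `gap_extend` (defaults 5, -4, -8, -6).
#' @return list: `cigar`, `score`, `edit` (edit events in the path),
#'   `tstart`, `tend`.
#' @export
gotoh_semiglobal <- function(read, region_seq,
                             scores = c(match = 5, mismatch = -4,
                                        gap_open = -8, gap_extend = -6)) {
  r <- cpp_gotoh_semiglobal(toupper(read), toupper(region_seq),
                            as.integer(scores[["match"]]),
                            as.integer(scores[["mismatch"]]),
                            as.integer(scores[["gap_open"]]),
                            as.integer(scores[["gap_extend"]]))
  runs <- cpp_cigar_runs(r$cigar, 0L)
  list(cigar = r$cigar, score = r$score,
       edit = sum(runs$len[runs$op %in% c("X", "I", "D")]),
       tstart = r$start, tend = r$end)
}

#' Anchored alignment through chained anchors
#'
#' Anchors of the chain are clustered: a neighbour joins the current cluster
#' when the read- and region-side gaps agree, i.e.
#' `|dq - dt| / max(dq, dt, 1) < e/2`.  Clusters covering fewer than
#' `max(30, 2%)` of read bases are discarded.  Each surviving cluster span
#' and each inter-cluster gap is aligned with the edit-distance kernel (a
#' reference-only gap becomes a single long `D` run, the signature of a
#' spanning deletion); extensions to the read ends are soft-clipped.  When
#' every cluster is discarded the whole region is aligned with
#' [myers_semiglobal()].
#'
#' @inheritParams myers_semiglobal
#' @param chain `nm_chain` of the region (non-empty).
#' @param e expected error rate (default 0.45).
#' @return list: `cigar` (may begin/end with `S`), `edit`, `tstart`, `tend`,
#'   `n_clusters`.
#' @export
anchored_alignment <- function(read, region_seq, chain, e = 0.45) {
  a <- chain$anchors
  if (is.null(a) || nrow(a) == 0L) stop("anchored alignment requires a non-empty chain")
  read <- toupper(read); region_seq <- toupper(region_seq)
  rl <- nchar(read)
  # Cluster consecutive anchors.  The gap-ratio rule flags structural
  # discontinuities; discordances up to 20 bases are ordinary sequencing
  # indels (the same convention the SV caller uses) and never split.
  cl <- integer(nrow(a)); cl[1L] <- 1L
  if (nrow(a) > 1L) for (i in 2:nrow(a)) {
    dq <- a$qstart[i] - a$qend[i - 1L]
    dt <- a$tstart[i] - a$tend[i - 1L]
    disc <- abs(dq - dt)
    same <- disc <= 20L || disc / max(dq, dt, 1) < e / 2
    cl[i] <- if (same) cl[i - 1L] else cl[i - 1L] + 1L
  }
  keep_cl <- vapply(split(a$qend - a$qstart, cl), sum, 0) >= max(30, 0.02 * rl)
  if (!any(keep_cl)) {
    r <- myers_semiglobal(read, region_seq)
    return(c(r, list(n_clusters = 0L)))
  }
  a <- a[keep_cl[as.character(cl)], , drop = FALSE]
  cl <- cl[keep_cl[as.character(cl)]]
  st <- cpp_anchored_stitch(read, region_seq,
                            a$qstart, a$qend, a$tstart, a$tend)
  list(cigar = st$cigar, edit = as.integer(st$edit),
       tstart = st$tstart, tend = st$tend,
       n_clusters = length(unique(cl)))
}

# merge adjacent equal-op runs after concatenation
merge_cigar <- function(cigar) cpp_merge_cigar(cigar)

#' Count ambiguous candidate regions
#'
#' With ambiguity factor `F` in `[0, 1]`, regions whose anchor-covered kmer
#' count satisfies `n_kmers >= (1 - F) * n_kmers_best` are considered
#' equally good candidates, where `n_kmers_best` belongs to the region with
#' the maximum quality `f`.  Their count `N_a` drives [mapping_quality()].
#'
#' @param region_scores list of `nm_region_score` objects (at least one).
#' @param ambiguity ambiguity factor `F` (default 0).
#' @return list: `n_a`, `best` (index of the best-f region) and `selected`
#'   (indices passing the ambiguity rule).
#' @export
ambiguity_count <- function(region_scores, ambiguity = 0) {
  stopifnot(length(region_scores) >= 1L)
  f <- vapply(region_scores, `[[`, 0, "f")
  nk <- vapply(region_scores, function(s) as.numeric(s$n_kmers), 0)
  best <- which.max(f)
  sel <- which(nk >= (1 - ambiguity) * nk[best])
  list(n_a = length(sel), best = best, selected = sel)
}

#' Mapping quality from the ambiguity count
#'
#' The probability of a wrong mapping is taken as
#' `p = max(1 - 1/N_a, 1e-4)`, giving the Phred-scaled quality
#' `Q = round(-10 log10 p)` capped at 40: a unique candidate (`N_a = 1`)
#' reports 40, two candidates report 3, many candidates report 0.
#'
#' @param n_a ambiguity count (>= 1).
#' @return integer mapping quality in `[0, 40]`.
#' @export
mapping_quality <- function(n_a) {
  stopifnot(all(n_a >= 1))
  p <- pmax(1 - 1 / n_a, 1e-4)
  as.integer(pmin(40, round(-10 * log10(p))))
}

#' Rescore an alignment for E-value computation
#'
#' `AS = 5 * matches - 4 * mismatches` with each gap run costing
#' `-8 - 6 * length` (open once, extend per gap base).
#'
#' @param cigar extended CIGAR (`=`/`X`/`I`/`D`, `S` ignored).
#' @param scores named vector of `match`, `mismatch`, `gap_open`,
#'   `gap_extend` rescoring parameters.
#' @return integer alignment score.
#' @export
alignment_score <- function(cigar, scores = c(match = 5, mismatch = -4,
                                              gap_open = -8, gap_extend = -6)) {
  runs <- cpp_cigar_runs(cigar, 0L)
  if ("M" %in% runs$op)
    stop("alignment_score needs an extended CIGAR with '='/'X' ops")
  sum(ifelse(runs$op == "=", scores[["match"]] * runs$len,
      ifelse(runs$op == "X", scores[["mismatch"]] * runs$len,
      ifelse(runs$op %in% c("I", "D"),
             scores[["gap_open"]] + scores[["gap_extend"]] * runs$len, 0))))
}

#' Gumbel parameters for E-value computation
#'
#' @param lambda,K Gumbel parameters (defaults 0.192 and 0.176).
#' @param match,mismatch,gap_open,gap_extend rescoring parameters
#'   (defaults 5, -4, -8, -6).
#' @return An `nm_evalue_params` list.
#' @export
evalue_params <- function(lambda = 0.192, K = 0.176,
                          match = 5, mismatch = -4,
                          gap_open = -8, gap_extend = -6) {
  stopifnot(lambda > 0, K > 0)
  structure(list(lambda = lambda, K = K,
                 scores = c(match = match, mismatch = mismatch,
                            gap_open = gap_open, gap_extend = gap_extend)),
            class = "nm_evalue_params")
}

#' BLAST-like E-value of an alignment (the SAM `ZE` tag)
#'
#' The alignment is rescored with [alignment_score()]; the bit score is
#' `(lambda * AS - ln K) / ln 2` and `ZE = m * n * 2^-bitscore` for read
#' length `m` and total reference length `n`.  Non-positive scores report
#' the non-significant value `m * n`.
#'
#' @param cigar extended CIGAR of the alignment.
#' @param m read length.
#' @param n total reference length.
#' @param params an [evalue_params()] object.
#' @return numeric E-value.
#' @export
evalue_ze <- function(cigar, m, n, params = evalue_params()) {
  as <- alignment_score(cigar, params$scores)
  if (as <= 0) return(m * n)
  bits <- (params$lambda * as - log(params$K)) / log(2)
  m * n * 2^(-bits)
}
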