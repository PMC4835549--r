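#' Kmer occurrence lookup of a read
#'
#' Maps every kmer of the read to all of its occurrence positions; identical
#' kmers are kept as separate positions (they are distinct vertices of the
#' kmer mapping graph).  Kmers containing non-ACGT characters are not stored.
#'
#' @param read nucleotide string.
#' @param k kmer length (default 6, the small continuous seed of stage II).
#' @return named list: kmer string -> sorted integer vector of 0-based
#'   positions.  Empty when `k > nchar(read)`.
#' @export
build_read_kmer_lookup <- function(read, k = 6L) {
  read <- toupper(read)
  n <- nchar(read)
  if (k < 1L || k > n) return(list())
  starts <- seq_len(n - k + 1L)
  kmers <- substring(read, starts, starts + k - 1L)
  ok <- !grepl("[^ACGT]", kmers)
  split(starts[ok] - 1L, kmers[ok])
}

#' Vertex-centric walk over the kmer mapping graph
#'
#' The read's kmers form the graph vertices; each vertex has `l` outbound
#' edges to the following `l` read kmers, so a walk can jump over kmers
#' corrupted by errors.  Region kmers are streamed left to right; every hit
#' extends the best (longest) compatible walk or starts a new one, with a
#' constant-work state update per hit.  An extension must advance at most
#' `l` kmers on the read and between 1 and `l` positions on the region.
#'
#' Walks may bridge indels and therefore shift alignment diagonal; each walk
#' is also decomposed into its maximal co-linear segments, which become the
#' exact-match anchors after [filter_walks()].
#'
#' @param read nucleotide string (graph vertices).
#' @param region_seq region sequence driving the traversal.
#' @param k kmer length (default 6).
#' @param l out-degree / maximum jump (default 9).
#' @return list of two data.frames: `walks` (`walk`, `qstart`, `qend`,
#'   `tstart`, `tend`, `walk_length` = bases covered on the read,
#'   `covered_kmers`) and `anchors` (the co-linear segments, with
#'   `covered_bases` and `covered_kmers` per segment).
#' @export
graph_walk <- function(read, region_seq, k = 6L, l = 9L) {
  res <- cpp_graph_walk(toupper(read), toupper(region_seq),
                        as.integer(k), as.integer(l))
  list(walks = as.data.frame(res$walks), anchors = as.data.frame(res$anchors))
}

#' Filter walks and emit anchors
#'
#' Walks covering fewer than `min_span` bases on the read (shorter than the
#' stage-I seeds) are excluded; the surviving walks' co-linear segments are
#' returned as anchors, deduplicated.
#'
#' @param walk_result list from [graph_walk()].
#' @param min_span minimum covered bases (default 12).
#' @return data.frame of anchors: `qstart`, `qend`, `tstart`, `tend`
#'   (0-based half-open, equal spans), `covered_bases`, `covered_kmers`.
#' @export
filter_walks <- function(walk_result, min_span = 12L) {
  keep_walks <- walk_result$walks$walk[walk_result$walks$walk_length >= min_span]
  a <- walk_result$anchors
  a <- a[a$walk %in% keep_walks, setdiff(names(a), "walk"), drop = FALSE]
  a <- a[!duplicated(a[c("qstart", "qend", "tstart", "tend")]), , drop = FALSE]
  if (nrow(a) > 1L) {
    # forked walks retrace shared prefixes; an anchor contained in another
    # anchor on the same diagonal can never change the chain optimum
    d <- a$tstart - a$qstart
    o <- order(d, a$qstart, -a$qend)
    a <- a[o, , drop = FALSE]
    prev_max <- stats::ave(a$qend, d[o], FUN = function(x)
      c(-1L, head(cummax(x), -1L)))
    a <- a[a$qend > prev_max, , drop = FALSE]
  }
  rownames(a) <- NULL
  a
}
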