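#' Chain anchors with variable-length LCSk
#'
#' Selects a subset of anchors that is strictly increasing in both read and
#' region start coordinates and maximizes the total credited covered length
#' -- the longest common subsequence in k-length substrings, relaxed so each
#' substring has the length of its anchor.  Partially overlapping monotone
#' anchors are both kept, but the later anchor's credit is reduced by the
#' larger of its read- and region-side overlaps with its predecessor (never
#' below zero), so matched bases are not double-counted.
#'
#' Ties are broken deterministically (smaller region span, then earliest
#' anchors).
#'
#' @param anchors data.frame with columns `qstart`, `qend`, `tstart`, `tend`
#'   (and optionally `covered_bases`, `covered_kmers`, carried through).
#' @return An `nm_chain`: list with `anchors` (the selected rows, in chain
#'   order, plus a `credit` column) and `total_covered`.
#' @export
lcsk_chain <- function(anchors) {
  if (is.null(anchors) || nrow(anchors) == 0L) {
    return(structure(list(anchors = cbind(anchors, credit = integer(0)),
                          total_covered = 0), class = "nm_chain"))
  }
  res <- cpp_lcsk_chain(anchors$qstart, anchors$qend,
                        anchors$tstart, anchors$tend)
  sel <- anchors[res$index, , drop = FALSE]
  sel$credit <- res$credit
  rownames(sel) <- NULL
  structure(list(anchors = sel, total_covered = res$total), class = "nm_chain")
}

#' @export
print.nm_chain <- function(x, ...) {
  cat(sprintf("anchor chain: %d anchors, %d credited bases\n",
              nrow(x$anchors), as.integer(x$total_covered)))
  invisible(x)
}
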