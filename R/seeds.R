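#' Build gapped spaced-seed indexes of a reference set
#'
#' One hash index per shape: every valid position of every reference is
#' stored under its [index_key()].  Only the forward strand is indexed;
#' [collect_hits()] queries both the read and its reverse complement.
#'
#' @param references named character vector of reference sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param shapes character vector of shape patterns (or list of `nm_shape`);
#'   defaults to the two complementary weight-12 shapes of
#'   [nm_default_shapes()].
#' @return An `nm_index` object holding the C++ index, reference names and
#'   lengths, and the parsed shapes.
#' @export
build_index <- function(references, shapes = nm_default_shapes()) {
  refs <- as_ref_set(references)
  shapes <- lapply(shapes, as_shape)
  empty <- nchar(refs) == 0L
  if (any(empty)) {
    warning(sprintf("skipping %d empty reference sequence(s): %s",
                    sum(empty), paste(names(refs)[empty], collapse = ", ")))
    refs <- refs[!empty]
  }
  if (length(refs) == 0L) stop("no non-empty reference sequences")
  ptr <- cpp_build_index(unname(refs), vapply(shapes, `[[`, "", "pattern"))
  structure(
    list(ptr = ptr, shapes = shapes,
         ref_names = names(refs), ref_lens = nchar(refs),
         refs = refs),
    class = "nm_index")
}

#' @export
print.nm_index <- function(x, ...) {
  cat(sprintf("seed index: %d reference(s), %s bp total, %d shape(s): %s\n",
              length(x$ref_names),
              format(sum(as.numeric(x$ref_lens)), big.mark = ","),
              length(x$shapes),
              paste(vapply(x$shapes, `[[`, "", "pattern"), collapse = ", ")))
  invisible(x)
}

# normalize reference input to a named character vector
as_ref_set <- function(references) {
  if (methods::is(references, "DNAStringSet")) {
    refs <- as.character(references)
  } else if (is.character(references)) {
    refs <- references
  } else stop("references must be a character vector or DNAStringSet")
  if (is.null(names(refs)) || any(!nzchar(names(refs))))
    names(refs) <- paste0("ref", seq_along(refs))
  # keep only the first whitespace-delimited token of each name (SAM rule)
  names(refs) <- sub("\\s.*$", "", names(refs))
  toupper(refs)
}

#' Dump the postings of one shape's index
#'
#' Intended for inspection and testing on small references.
#' @param index an `nm_index`.
#' @param shape 1-based shape number.
#' @return data.frame with columns `key`, `ref` (0-based reference id) and
#'   `pos` (0-based position).
#' @export
seed_index_entries <- function(index, shape = 1L) {
  stopifnot(inherits(index, "nm_index"))
  cpp_index_entries(index$ptr, as.integer(shape) - 1L)
}

#' Collect seed hits of a read against the index
#'
#' Every read position is looked up with the indel-tolerant key set of every
#' shape (see [lookup_keys()]), on the read and on its reverse complement.
#' Keys with more than `max_postings` occurrences in the index are skipped to
#' bound noise votes.
#'
#' @param read nucleotide string.
#' @param index an `nm_index`.
#' @param max_postings skip keys with more postings than this (default 500).
#' @return data.frame of seed hits: `qpos` (0-based position on the read, or
#'   on its reverse complement for `-` hits), `tpos` (0-based reference
#'   position), `ref` (0-based reference id), `strand` (`+`/`-`) and `shape`
#'   (0-based shape id).
#' @export
collect_hits <- function(read, index, max_postings = 500L) {
  stopifnot(inherits(index, "nm_index"))
  h <- cpp_collect_hits(index$ptr, toupper(read), as.integer(max_postings))
  data.frame(qpos = h$qpos, tpos = h$tpos, ref = h$ref,
             strand = c("+", "-")[h$strand + 1L], shape = h$shape,
             stringsAsFactors = FALSE)
}
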