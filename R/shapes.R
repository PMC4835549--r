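#' Parse a spaced-seed shape
#'
#' A shape is a pattern over `{1, 0}` describing which positions of a seed
#' window contribute to the lookup key: `1` marks an inclusive base, `0` a
#' "don't care" (DC) position that may mismatch or absorb a 1 bp indel.  The
#' number of `1`s is the shape's *weight*.  The two default shapes used for
#' region selection are `"1111110111111"` (6-1-6) and `"11110111101111"`
#' (4-1-4-1-4), both of weight 12.
#'
#' @param pattern character scalar over `{1, 0}`, starting and ending in `1`.
#' @return An object of class `nm_shape` with fields `pattern`, `weight`
#'   (count of inclusive positions) and `dc_count` (count of DC positions).
#' @examples
#' parse_shape("1111110111111")  # weight 12, one DC base
#' @export
parse_shape <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || nchar(pattern) == 0L)
    stop("shape pattern must be a single non-empty string")
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% c("0", "1"))
  if (length(bad))
    stop(sprintf("invalid character '%s' at position %d of shape pattern",
                 chars[bad[1L]], bad[1L]))
  if (chars[1L] != "1" || chars[length(chars)] != "1")
    stop("shape pattern must start and end with '1'")
  structure(
    list(pattern = pattern,
         weight = sum(chars == "1"),
         dc_count = sum(chars == "0")),
    class = "nm_shape")
}

#' @export
print.nm_shape <- function(x, ...) {
  cat(sprintf("spaced-seed shape %s (weight %d, %d DC)\n",
              x$pattern, x$weight, x$dc_count))
  invisible(x)
}

as_shape <- function(x) if (inherits(x, "nm_shape")) x else parse_shape(x)

#' Default region-selection shapes
#'
#' The complementary weight-12 shapes used by default: one- and two-gapped
#' layouts so that either can rescue seed positions the other loses.
#' @return character vector of two shape patterns.
#' @export
nm_default_shapes <- function() c("1111110111111", "11110111101111")

#' Index key of a sequence position under a shape
#'
#' Concatenates the bases under the shape's inclusive positions; DC bases are
#' skipped.  This is the key under which reference positions are stored in
#' the seed index.
#'
#' @param seq nucleotide string.
#' @param pos 0-based offset into `seq`.
#' @param shape an `nm_shape` or pattern string.
#' @return The key string (length = shape weight), or `NA` if any inclusive
#'   base is not A/C/G/T.
#' @export
index_key <- function(seq, pos, shape) {
  shape <- as_shape(shape)
  len <- nchar(shape$pattern)
  if (pos < 0L || pos + len > nchar(seq))
    stop(sprintf("position %d out of range for a %d bp shape on a %d bp sequence",
                 pos, len, nchar(seq)))
  offs <- which(strsplit(shape$pattern, "")[[1L]] == "1") - 1L
  bases <- substring(toupper(seq), pos + offs + 1L, pos + offs + 1L)
  if (any(!bases %in% c("A", "C", "G", "T"))) return(NA_character_)
  paste(bases, collapse = "")
}

#' Indel-tolerant lookup keys of a read position under a shape
#'
#' For each DC position, three layouts are enumerated independently:
#' *mismatch* (skip the DC base, as during indexing), *deletion* (do not skip
#' it, consuming one fewer base) and *insertion* (skip the DC base and the
#' following base).  The Cartesian product over DC positions gives `3^d`
#' layouts, deduplicated to the distinct key strings.  Layouts running past
#' the end of the sequence are dropped; when that happens the result carries
#' `attr(, "truncated") = TRUE`.
#'
#' @inheritParams index_key
#' @return character vector of distinct keys (each of length = shape weight).
#' @examples
#' lookup_keys("ACGT", 0, "101")  # "AG" (mismatch), "AC" (deletion), "AT" (insertion)
#' @export
lookup_keys <- function(seq, pos, shape) {
  shape <- as_shape(shape)
  chars <- strsplit(shape$pattern, "")[[1L]]
  d <- shape$dc_count
  seq <- toupper(seq)
  n <- nchar(seq)
  keys <- character(0)
  truncated <- FALSE
  combos <- if (d == 0L) list(integer(0)) else
    do.call(expand.grid, rep(list(0:2), d))
  combos <- if (is.data.frame(combos)) asplit(as.matrix(combos), 1L) else combos
  for (choice in combos) {
    offs <- integer(0)
    shift <- 0L
    dci <- 1L
    for (i in seq_along(chars)) {
      if (chars[i] == "1") {
        offs <- c(offs, i - 1L + shift)
      } else {
        shift <- shift + c(0L, -1L, 1L)[choice[dci] + 1L]
        dci <- dci + 1L
      }
    }
    if (pos + max(offs) + 1L > n) { truncated <- TRUE; next }
    bases <- substring(seq, pos + offs + 1L, pos + offs + 1L)
    if (any(!bases %in% c("A", "C", "G", "T"))) next
    keys <- c(keys, paste(bases, collapse = ""))
  }
  keys <- unique(keys)
  if (truncated) attr(keys, "truncated") <- TRUE
  keys
}
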