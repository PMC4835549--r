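# Independent brute-force oracles and small fixture builders.
# These deliberately use plain dynamic programmes / exhaustive enumeration so
# the fast implementations are checked against something they do not share
# code with.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# semi-global edit distance (free text gaps at both ends, query consumed)
ed_semiglobal_oracle <- function(q, t) {
  m <- nchar(q); n <- nchar(t)
  qq <- strsplit(q, "")[[1L]]; tt <- strsplit(t, "")[[1L]]
  D <- matrix(0L, m + 1L, n + 1L)
  D[, 1L] <- 0:m
  D[1L, ] <- 0L
  if (m > 0 && n > 0)
    for (i in 2:(m + 1L)) for (j in 2:(n + 1L))
      D[i, j] <- min(D[i - 1L, j - 1L] + (qq[i - 1L] != tt[j - 1L]),
                     D[i - 1L, j] + 1L, D[i, j - 1L] + 1L)
  min(D[m + 1L, ])
}

# affine-gap semi-global score maximum (gap of g costs open + g * extend)
gotoh_oracle <- function(q, t, ma = 5, mi = -4, go = -8, ge = -6) {
  m <- nchar(q); n <- nchar(t)
  qq <- strsplit(q, "")[[1L]]; tt <- strsplit(t, "")[[1L]]
  NEG <- -1e9
  M <- matrix(NEG, m + 1L, n + 1L); X <- M; Y <- M
  M[1L, ] <- 0
  for (i in 2:(m + 1L)) X[i, 1L] <- go + ge * (i - 1L)
  for (i in 2:(m + 1L)) for (j in 1:(n + 1L)) {
    if (j > 1L) {
      s <- if (qq[i - 1L] == tt[j - 1L]) ma else mi
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L], Y[i - 1L, j - 1L]) + s
      Y[i, j] <- max(M[i, j - 1L] + go + ge, X[i, j - 1L] + go + ge,
                     Y[i, j - 1L] + ge)
    }
    X[i, j] <- max(M[i - 1L, j] + go + ge, Y[i - 1L, j] + go + ge,
                   X[i - 1L, j] + ge)
  }
  max(M[m + 1L, ], X[m + 1L, ], Y[m + 1L, ])
}

# exhaustive optimum of the variable-length LCSk objective over all anchor
# subsets (monotone in both starts; credited with the overlap-trim rule)
lcsk_bruteforce <- function(anchors) {
  n <- nrow(anchors)
  if (n == 0L) return(0)
  best <- 0
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0L)
    if (length(idx) == 0L) next
    a <- anchors[idx, , drop = FALSE]
    a <- a[order(a$qstart, a$tstart), , drop = FALSE]
    if (nrow(a) > 1L &&
        (any(diff(a$qstart) <= 0L) || any(diff(a$tstart) <= 0L))) next
    tot <- a$qend[1L] - a$qstart[1L]
    ok <- TRUE
    if (nrow(a) > 1L) for (i in 2:nrow(a)) {
      pen <- max(0L, a$qend[i - 1L] - a$qstart[i], a$tend[i - 1L] - a$tstart[i])
      tot <- tot + max(0L, (a$qend[i] - a$qstart[i]) - pen)
    }
    if (ok && tot > best) best <- tot
  }
  best
}

rand_anchors <- function(n, span = 200L) {
  len <- sample(5:30, n, TRUE)
  qs <- sample.int(span, n, TRUE) - 1L
  ts <- sample.int(span, n, TRUE) - 1L
  data.frame(qstart = qs, qend = qs + len, tstart = ts, tend = ts + len)
}

# synthetic alignment record in the shape map_reads() emits
fake_aln <- function(qname, pos, cigar, seq = NULL, flag = 0L, ref = "ref",
                     strand = "+") {
  if (is.null(seq)) {
    runs <- nanomapr:::cpp_cigar_runs(cigar, pos)
    ql <- sum(runs$len[runs$op %in% c("M", "=", "X", "I", "S")])
    seq <- paste(rep("A", ql), collapse = "")
  }
  list(qname = qname, flag = flag, ref = ref, pos = pos, mapq = 40L,
       cigar = cigar, strand = strand, edit = 0L, score = 0L,
       evalue = 0, f = 1, n_a = 1L, seq = seq, qual = "*")
}

as_alignments <- function(records, ref_names = "ref", ref_lens = 10000L) {
  structure(records, class = "nm_alignments",
            ref_names = ref_names, ref_lens = ref_lens)
}

# genome with divergent repeat copies (ablation benchmark)
repeat_genome <- function(bg_len = 300000L, motif_len = 2000L, copies = 25L,
                          divergence = 0.02, seed = 77L) {
  bg <- make_reference(bg_len, seed = seed, name = "g")
  motif <- make_reference(motif_len, seed = seed + 1L)[[1L]]
  set.seed(seed + 23L)
  g <- bg[[1L]]
  pos <- as.integer(seq(10000L, bg_len - motif_len - 10000L, length.out = copies))
  for (p in pos) {
    ch <- strsplit(motif, "")[[1L]]
    k <- rbinom(1L, length(ch), divergence)
    if (k > 0L) {
      i <- sample(length(ch), k)
      ch[i] <- vapply(ch[i], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    }
    substr(g, p, p + motif_len - 1L) <- paste(ch, collapse = "")
  }
  structure(stats::setNames(g, "g"), circular = FALSE)
}
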