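test_that("parse_shape computes weight and DC count and rejects malformed patterns", {
  s <- parse_shape("1111110111111")
  expect_equal(s$weight, 12L)
  expect_equal(s$dc_count, 1L)
  s2 <- parse_shape("11110111101111")
  expect_equal(s2$weight, 12L)
  expect_equal(s2$dc_count, 2L)
  s3 <- parse_shape("1")
  expect_equal(s3$weight, 1L)
  expect_equal(s3$dc_count, 0L)
  expect_error(parse_shape("11a01"), "position 3")
  expect_error(parse_shape("0111"), "start and end")
  expect_error(parse_shape("1110"), "start and end")
  expect_error(parse_shape(""), "non-empty")
})

test_that("index_key skips DC bases and refuses ambiguous or out-of-range input", {
  expect_equal(index_key("ACGTACG", 0, "101"), "AG")
  expect_equal(index_key("ACGTACG", 0, "1111"), "ACGT")
  expect_true(is.na(index_key("ACNTACG", 0, "111")))
  expect_error(index_key("ACGT", 2, "111"), "out of range")
  # case-insensitive
  expect_equal(index_key("acgtacg", 1, "11"), "CG")
})

test_that("lookup_keys enumerates the mismatch, deletion and insertion layouts", {
  expect_setequal(lookup_keys("ACGT", 0, "101"), c("AG", "AC", "AT"))
  # homopolymer collapses all layouts to one key
  expect_equal(lookup_keys("AAAA", 0, "101"), "AA")
  # no DC position: exactly the index key
  expect_equal(lookup_keys("ACGT", 0, "11"), "AC")
  # truncation near the sequence end drops only the layouts that do not fit
  k <- lookup_keys("ACG", 0, "101")
  expect_true("AG" %in% k && "AC" %in% k)
  expect_false("AT" %in% k)  # insertion layout needs a 4th base
  expect_true(isTRUE(attr(k, "truncated")))
})

test_that("lookup_keys takes the Cartesian product of layouts over DC positions", {
  # two DC positions: up to 3^2 = 9 layouts before deduplication
  set.seed(42)
  for (r in 1:20) {
    s <- rand_seq(20)
    kr <- lookup_keys(s, 0, "101101")
    kc <- nanomapr:::cpp_lookup_keys(s, 0L, "101101")
    expect_setequal(as.character(kr), as.character(kc))
    expect_lte(length(kr), 9L)
  }
})

test_that("build_index stores every valid position under its index key", {
  ref <- c(r1 = "ACGTACGTACGTACGTACGT")  # 20 bp
  idx <- build_index(ref, shapes = "11")
  e <- seed_index_entries(idx, 1)
  expect_equal(nrow(e), 19L)
  idx2 <- build_index(c(r = "ACGTACGT"), shapes = "1111")
  e2 <- seed_index_entries(idx2, 1)
  expect_setequal(e2$pos[e2$key == "ACGT"], c(0L, 4L))
  # one separate index per shape
  idx3 <- build_index(ref, shapes = c("11", "1111"))
  expect_equal(length(idx3$shapes), 2L)
  expect_gt(nrow(seed_index_entries(idx3, 1)), nrow(seed_index_entries(idx3, 2)))
})

test_that("index round-trip: every stored (key, position) reproduces its key", {
  set.seed(7)
  ref <- c(a = rand_seq(300), b = rand_seq(150))
  for (pat in nm_default_shapes()) {
    idx <- build_index(ref, shapes = pat)
    e <- seed_index_entries(idx, 1)
    recomputed <- vapply(seq_len(nrow(e)), function(i)
      index_key(ref[[e$ref[i] + 1L]], e$pos[i], pat), "")
    expect_equal(recomputed, e$key)
  }
})

test_that("empty references are skipped with a warning", {
  expect_warning(idx <- build_index(c(a = "ACGTACGTACGTACGT", b = "")),
                 "empty")
  expect_equal(idx$ref_names, "a")
  expect_error(suppressWarnings(build_index(c(x = ""))), "no non-empty")
})

test_that("collect_hits finds the exact diagonal of a contained read", {
  set.seed(8)
  ref <- c(g = rand_seq(400))
  idx <- build_index(ref, shapes = "111")
  read <- substr(ref[[1]], 101, 200)
  h <- collect_hits(read, idx)
  fwd <- h[h$strand == "+", ]
  expect_gte(sum(fwd$tpos - fwd$qpos == 100), 98L)
})

test_that("a reverse-complement read hits only the minus strand", {
  set.seed(9)
  ref <- c(g = rand_seq(500))
  idx <- build_index(ref)
  rc <- nanomapr:::cpp_revcomp(substr(ref[[1]], 201, 340))
  h <- collect_hits(rc, idx)
  diag_hits <- h[abs(h$tpos - h$qpos - 200) < 5, ]
  expect_gt(nrow(diag_hits), 50L)
  expect_true(all(diag_hits$strand == "-"))
})

test_that("indel-tolerant layouts recover hits the mismatch layout misses", {
  # reference spans one full 6-1-6 seed; the read deletes the base under the
  # DC position, so only the deletion layout can recover the hit
  set.seed(10)
  ref <- rand_seq(13)
  read_del <- paste0(substr(ref, 1, 6), substr(ref, 8, 13))
  keys <- lookup_keys(read_del, 0, "1111110111111")
  expect_true(index_key(ref, 0, "1111110111111") %in% keys)
})

test_that("every single 1 bp edit at a DC position is recovered by some layout", {
  # exhaustive over all DC positions of both default shapes on a 50 bp sequence
  set.seed(11)
  ref <- rand_seq(50)
  for (pat in nm_default_shapes()) {
    chars <- strsplit(pat, "")[[1]]
    dcs <- which(chars == "0") - 1L
    span <- nchar(pat)
    for (p in 0:(50 - span - 1)) {
      true_key <- index_key(ref, p, pat)
      for (dc in dcs) {
        edit_pos <- p + dc  # 0-based position of the DC base on the reference
        # substitution
        old <- substr(ref, edit_pos + 1, edit_pos + 1)
        sub <- ref
        substr(sub, edit_pos + 1, edit_pos + 1) <- setdiff(c("A","C","G","T"), old)[1]
        expect_true(true_key %in% lookup_keys(sub, p, pat))
        # 1 bp deletion at the DC position
        del <- paste0(substr(ref, 1, edit_pos), substr(ref, edit_pos + 2, 50))
        expect_true(true_key %in% lookup_keys(del, p, pat))
        # 1 bp insertion immediately after the DC position
        ins <- paste0(substr(ref, 1, edit_pos + 1), "A",
                      substr(ref, edit_pos + 2, 50))
        expect_true(true_key %in% lookup_keys(ins, p, pat))
      }
    }
  }
})

test_that("high-frequency keys are skipped during lookup", {
  ref <- c(g = paste(rep("ACGT", 200), collapse = ""))
  idx <- build_index(ref, shapes = "1111")
  h_capped <- collect_hits("ACGTACGTACGT", idx, max_postings = 10)
  h_open <- collect_hits("ACGTACGTACGT", idx, max_postings = 10000)
  expect_equal(nrow(h_capped), 0L)
  expect_gt(nrow(h_open), 1000L)
})
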