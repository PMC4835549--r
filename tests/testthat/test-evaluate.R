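truth_row <- function(read = "r1", start, edit, strand = "+", ref = "ref") {
  data.frame(read = read, ref = ref, strand = strand, start = start,
             end = start + nchar(gsub("I", "", edit)), edit = edit,
             stringsAsFactors = FALSE)
}

test_that("location correctness uses the clip-adjusted +-50 bp rule", {
  tr <- truth_row(start = 1000L, edit = strrep("=", 200))
  expect_true(location_correct(fake_aln("r1", 1000L, "200="), tr))
  # clipped bases are subtracted from the reported position
  expect_true(location_correct(fake_aln("r1", 1030L, "30S170="), tr))
  expect_true(location_correct(fake_aln("r1", 1050L, "200="), tr))
  expect_false(location_correct(fake_aln("r1", 1051L, "200="), tr))
  # strand mismatches never count
  expect_false(location_correct(fake_aln("r1", 1000L, "200=", strand = "-"), tr))
  expect_false(location_correct(fake_aln("r1", 1000L, "*", flag = 4L), tr))
})

test_that("base accuracy counts exact placements and excludes clips", {
  tr <- truth_row(start = 100L, edit = strrep("=", 50))
  ba <- base_accuracy(fake_aln("r1", 100L, "50="), tr)
  expect_equal(unname(ba), c(50L, 50L, 50L, 50L))
  # one-base shift misplaces everything downstream of the false gap
  ba2 <- base_accuracy(fake_aln("r1", 99L, "25=1D25="), tr)
  expect_equal(ba2[["correct"]], 25L)
  # fully soft-clipped bases leave nothing eligible
  ba3 <- base_accuracy(fake_aln("r1", 100L, "50S"), tr)
  expect_equal(ba3[["eligible"]], 0L)
  # insertions in the read are eligible but can never be correct
  tr4 <- truth_row(start = 100L, edit = paste0(strrep("=", 20), "II",
                                               strrep("=", 20)))
  ba4 <- base_accuracy(fake_aln("r1", 100L, "20=2I20="), tr4)
  expect_equal(ba4[["correct"]], 40L)
  expect_equal(ba4[["eligible"]], 42L)
})

test_that("per-base accuracy agrees with an exhaustive position comparison", {
  # brute-force: enumerate every read base's reference position from the
  # CIGAR and the truth edit string independently, then compare
  set.seed(81)
  ref <- make_reference(4000, seed = 81, name = "ref")
  sim <- simulate_reads(ref, 4, 80, 100, error_profile("2D"), seed = 82)
  idx <- build_index(ref, shapes = "111111")
  aln <- map_reads(sim$reads, idx)
  for (i in 1:4) {
    a <- aln[[i]]; tr <- sim$truth[i, ]
    if (bitwAnd(a$flag, 4L)) next
    ba <- base_accuracy(a, tr)
    tmap <- truth_base_map(tr)
    qmap <- nanomapr:::cpp_cigar_qmap(a$cigar, a$pos)
    if (a$strand == "-") qmap <- rev(qmap)
    brute <- sum(vapply(seq_along(tmap), function(p)
      !is.na(tmap[p]) && !is.na(qmap[p]) && tmap[p] == qmap[p], TRUE))
    expect_equal(ba[["correct"]], if (a$strand == tr$strand) brute else 0L)
  }
})

test_that("the precision * mapped = correct count identity holds", {
  ref <- make_reference(30000, seed = 83, name = "g")
  idx <- build_index(ref)
  sim <- simulate_reads(ref, 15, 400, 1500, error_profile("1D"), seed = 84)
  ev <- evaluate_alignments(map_reads(sim$reads, idx), sim$truth)
  expect_equal(ev$location_precision * ev$reads_mapped, ev$reads_correct)
  expect_equal(ev$location_recall * ev$reads_total, ev$reads_correct)
})

test_that("consensus of identical error-free reads is the read itself", {
  ref <- make_reference(500, seed = 85, name = "ref")
  recs <- lapply(1:30, function(i)
    fake_aln(paste0("r", i), 0L, "500=", seq = ref[[1]]))
  aln <- as_alignments(recs, "ref", 500L)
  cc <- consensus_call(aln, ref, min_cov = 20)
  expect_equal(cc$consensus, ref[[1]])
  expect_equal(cc$n_uncalled, 0L)
  # idempotence: a pileup of one repeated (different) sequence returns it
  alt <- nanomapr:::cpp_revcomp(ref[[1]])
  recs2 <- lapply(1:25, function(i) fake_aln(paste0("q", i), 0L, "500=", seq = alt))
  cc2 <- consensus_call(as_alignments(recs2, "ref", 500L), ref, min_cov = 20)
  expect_equal(cc2$consensus, alt)
})

test_that("positions below 20x coverage are not called", {
  ref <- make_reference(300, seed = 86, name = "ref")
  recs <- lapply(1:19, function(i) fake_aln(paste0("r", i), 0L, "300=",
                                            seq = ref[[1]]))
  cc <- consensus_call(as_alignments(recs, "ref", 300L), ref, min_cov = 20)
  expect_equal(cc$n_uncalled, 300L)
  cc20 <- consensus_call(as_alignments(c(recs, list(fake_aln("r20", 0L, "300=",
                                                             seq = ref[[1]]))),
                                       "ref", 300L), ref, min_cov = 20)
  expect_equal(cc20$n_uncalled, 0L)
})

test_that("majority vote fixes per-read errors at high coverage", {
  ref <- make_reference(20000, seed = 87, name = "r")
  idx <- build_index(ref)
  sim <- simulate_reads(ref, 220, 2000, 4000, error_profile("2D"), seed = 88)
  aln <- map_reads(sim$reads, idx)
  cc <- consensus_call(aln, ref, min_cov = 20)
  called <- cc$calls[cc$calls$call != "N", ]
  # errors at called positions: disagreement with the reference (the truth
  # here), at least 10-fold below the per-read error rate
  err <- mean(called$call != called$ref_base)
  per_read <- mean(vapply(aln, function(a)
    if (bitwAnd(a$flag, 4L)) NA_real_ else a$edit / nchar(a$seq), 0),
    na.rm = TRUE)
  expect_gt(nrow(called), 10000)
  expect_lt(err, per_read / 10)
})

test_that("sv_call is quiet without long indel runs and permutation-invariant", {
  recs <- lapply(1:30, function(i)
    fake_aln(paste0("r", i), (i - 1L) * 10L, "400=5I395="))
  aln <- as_alignments(recs, "ref", 2000L)
  expect_equal(nrow(sv_call(aln, 2000L)), 0L)  # runs < 20 ignored
  # a clean 500 bp deletion supported by 30 spanning reads
  recs2 <- lapply(1:30, function(i)
    fake_aln(paste0("r", i), (i - 1L) * 10L, "400=500D400="))
  aln2 <- as_alignments(recs2, "ref", 3000L)
  calls <- sv_call(aln2, 3000L)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$type, "D")
  expect_lte(abs(calls$size - 500), 50)
  # order of reads does not matter
  calls_r <- sv_call(as_alignments(rev(recs2), "ref", 3000L), 3000L)
  expect_equal(calls, calls_r)
})

test_that("sv_call requires the >15% / >=5 reads support rule", {
  # 4 supporting reads among 30 spanning: below the read minimum
  support <- lapply(1:4, function(i) fake_aln(paste0("s", i), 0L, "400=100D400="))
  plain <- lapply(1:26, function(i) fake_aln(paste0("p", i), 0L, "900="))
  expect_equal(nrow(sv_call(as_alignments(c(support, plain), "ref", 2000L),
                            2000L)), 0L)
  # 6 supporting reads among 30: passes both thresholds
  support6 <- lapply(1:6, function(i) fake_aln(paste0("s", i), 0L, "400=100D400="))
  calls <- sv_call(as_alignments(c(support6, plain[1:24]), "ref", 2000L), 2000L)
  expect_equal(nrow(calls), 1L)
})

test_that("sv_match applies the 25% size and position margins", {
  truth <- data.frame(type = "D", start = 1000L, end = 1500L, size = 500L,
                      stringsAsFactors = FALSE)
  call <- function(s, e, sz) data.frame(type = "D", start = s, end = e,
                                        size = sz, stringsAsFactors = FALSE)
  expect_equal(sv_match(call(1000L, 1500L, 500L), truth)$recall, 1)
  # size off by 2x never matches
  expect_equal(sv_match(call(1000L, 1200L, 200L),
                        data.frame(type = "D", start = 1000L, end = 1100L,
                                   size = 100L))$tp, 0L)
  # jitter strictly inside the margins always matches
  set.seed(89)
  for (r in 1:25) {
    sz <- sample(c(100L, 500L, 2000L), 1)
    truth_r <- data.frame(type = "D", start = 5000L, end = 5000L + sz, size = sz)
    jit <- function(x) as.integer(x + sample((-as.integer(0.2 * sz)):(as.integer(0.2 * sz)), 1))
    got <- sv_match(call(jit(5000L), jit(5000L + sz),
                         as.integer(sz * runif(1, 0.8, 1.2))), truth_r)
    expect_equal(got$tp, 1L)
  }
  # type mismatch never matches
  expect_equal(sv_match(data.frame(type = "I", start = 1000L, end = 1000L,
                                   size = 500L), truth)$tp, 0L)
})

test_that("expected_sv_signals swaps event polarity into alignment space", {
  tr <- data.frame(type = c("insertion", "deletion"), pos = c(100L, 900L),
                   size = c(50L, 70L), pos_sv = c(100L, 950L),
                   seq = c("X", ""), stringsAsFactors = FALSE)
  sig <- expected_sv_signals(tr)
  expect_equal(sig$type, c("D", "I"))
  expect_equal(sig$end, c(150L, 950L))
})
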