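test_that("make_reference is reproducible and honours GC content", {
  r1 <- make_reference(1000, seed = 7)
  r2 <- make_reference(1000, seed = 7)
  expect_identical(r1, r2)
  gc <- make_reference(500, gc = 1, seed = 8)
  expect_false(grepl("[AT]", gc[[1]]))
  expect_true(attr(make_reference(10, seed = 1, circular = TRUE), "circular"))
})

test_that("mutate_reference at rate zero is the identity", {
  ref <- make_reference(2000, seed = 9, name = "m")
  out <- mutate_reference(ref, snp_rate = 0, indel_rate = 0, seed = 10)
  expect_identical(out$seq[[1]], ref[[1]])
  expect_null(out$variants)
})

test_that("mutation counts match their rates within binomial noise", {
  n <- 300000L
  ref <- make_reference(n, seed = 11, name = "m")
  out <- mutate_reference(ref, snp_rate = 6e-4, indel_rate = 0.0067,
                          indel_max = 10, seed = 12)
  v <- out$variants
  n_snp <- sum(v$type == "snp")
  n_ind <- sum(v$type != "snp")
  expect_lt(abs(n_snp - n * 6e-4), 3 * sqrt(n * 6e-4) + 3)
  expect_lt(abs(n_ind - n * 0.0067), 3 * sqrt(n * 0.0067) + 3)
  expect_true(all(v$size <= 10))
  # variant records reconstruct both coordinate systems
  i <- which(v$type == "snp")[1]
  expect_equal(substr(ref[[1]], v$pos[i] + 1, v$pos[i] + 1), v$ref_allele[i])
  expect_equal(substr(out$seq[[1]], v$pos_mut[i] + 1, v$pos_mut[i] + 1),
               v$alt_allele[i])
})

test_that("inject_svs applies events and records breakpoints in both frames", {
  ref <- make_reference(50000, seed = 13, name = "s")
  del <- data.frame(type = "deletion", pos = 20000L, size = 100L)
  out <- inject_svs(ref, del, seed = 14)
  expect_equal(nchar(out$seq[[1]]), 50000L - 100L)
  # symmetric insertion/deletion set leaves the length unchanged
  ev <- default_sv_events(50000L, seed = 15, sizes = c(100L, 300L, 500L),
                          margin = 3000L)
  expect_equal(nrow(ev), 6L)
  out2 <- inject_svs(ref, ev, seed = 16)
  expect_equal(nchar(out2$seq[[1]]), 50000L)
  # flanks of each event are recoverable by exact search at the breakpoint
  tr <- out2$truth
  for (i in seq_len(nrow(tr))) {
    flank <- substr(ref[[1]], tr$pos[i] - 29, tr$pos[i])
    expect_equal(substr(out2$seq[[1]], tr$pos_sv[i] - 29, tr$pos_sv[i]), flank)
  }
  expect_error(inject_svs(ref, data.frame(type = c("deletion", "deletion"),
                                          pos = c(100L, 150L),
                                          size = c(100L, 100L))), "overlap")
})

test_that("zero-error profiles give exact substrings with exact truth", {
  ref <- make_reference(20000, seed = 17, name = "z")
  sim <- simulate_reads(ref, 10, 500, 1500,
                        error_profile("custom", 0, 0, 0), seed = 18)
  for (i in 1:10) {
    tr <- sim$truth[i, ]
    seg <- substr(ref[[1]], tr$start + 1, tr$end)
    if (tr$strand == "-") seg <- nanomapr:::cpp_revcomp(seg)
    expect_identical(sim$reads[[i]], seg)
    tm <- truth_base_map(tr)
    expect_equal(length(tm), nchar(sim$reads[[i]]))
    expect_true(all(diff(tm) == (if (tr$strand == "-") -1L else 1L)))
  }
})

test_that("measured error rates match the profile within binomial noise", {
  ref <- make_reference(60000, seed = 19, name = "e")
  pr <- error_profile("1D")
  sim <- simulate_reads(ref, 12, 3000, 3000, pr, seed = 20)
  ev <- paste(sim$truth$edit, collapse = "")
  n <- nchar(ev)
  for (op in c("X", "I", "D")) {
    rate <- switch(op, X = pr$mismatch_rate, I = pr$ins_rate, D = pr$del_rate)
    k <- lengths(regmatches(ev, gregexpr(op, ev, fixed = TRUE)))
    expect_lt(abs(k - n * rate), 3 * sqrt(n * rate * (1 - rate)))
  }
  # both strands are drawn
  big <- simulate_reads(ref, 200, 100, 200, pr, seed = 21)
  nminus <- sum(big$truth$strand == "-")
  expect_lt(abs(nminus - 100), 3 * sqrt(200 * 0.25) + 1)
})

test_that("the recorded edit string reproduces each read from the reference", {
  ref <- make_reference(30000, seed = 22, name = "c")
  sim <- simulate_reads(ref, 6, 800, 1600, error_profile("2D"), seed = 23)
  for (i in 1:6) {
    tr <- sim$truth[i, ]
    tmpl <- substr(ref[[1]], tr$start + 1, tr$end)
    if (tr$strand == "-") tmpl <- nanomapr:::cpp_revcomp(tmpl)
    ev <- strsplit(tr$edit, "")[[1]]
    tch <- strsplit(tmpl, "")[[1]]
    read <- strsplit(sim$reads[[i]], "")[[1]]
    toff <- 0L; qoff <- 0L
    for (e in ev) {
      if (e == "=") {
        expect_identical(read[qoff + 1L], tch[toff + 1L])
        toff <- toff + 1L; qoff <- qoff + 1L
      } else if (e == "X") {
        expect_false(identical(read[qoff + 1L], tch[toff + 1L]))
        toff <- toff + 1L; qoff <- qoff + 1L
      } else if (e == "I") qoff <- qoff + 1L
      else toff <- toff + 1L
    }
    expect_equal(qoff, length(read))
    expect_equal(toff, length(tch))
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  ref <- make_reference(10000, seed = 24, name = "d")
  s1 <- simulate_reads(ref, 5, 300, 800, error_profile("2D"), seed = 25)
  s2 <- simulate_reads(ref, 5, 300, 800, error_profile("2D"), seed = 25)
  expect_identical(s1, s2)
  d <- tempfile(); t <- tempfile()
  write_simulated(s1, d, t)
  expect_identical(read_fasta(d), s1$reads)
  tt <- utils::read.delim(t, stringsAsFactors = FALSE)
  expect_equal(tt$start, s1$truth$start)
})

test_that("error_profile validates its rates", {
  expect_error(error_profile("custom", 0.5, 0.4, 0.3))
  p <- error_profile("2D")
  expect_equal(p$mismatch_rate + p$ins_rate + p$del_rate, 0.17)
})
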