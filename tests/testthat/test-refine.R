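chain_of <- function(qs, qe, ts, te, credit = NULL) {
  a <- data.frame(qstart = qs, qend = qe, tstart = ts, tend = te)
  if (!is.null(credit)) a$credit <- credit
  structure(list(anchors = a, total_covered = sum(qe - qs)),
            class = "nm_chain")
}

test_that("fit_l1 recovers a clean diagonal and the weighted median", {
  ch <- chain_of(c(0L, 20L, 50L), c(10L, 30L, 60L),
                 c(50L, 70L, 100L), c(60L, 80L, 110L))
  f <- fit_l1(ch)
  expect_equal(f$intercept, 50L)
  expect_equal(f$residuals, rep(0, 3))
  # unit-weight anchors at intercepts 10, 10, 40 -> median 10
  ch2 <- chain_of(c(0L, 5L, 10L), c(1L, 6L, 11L),
                  c(10L, 15L, 50L), c(11L, 16L, 51L), credit = c(1L, 1L, 1L))
  expect_equal(fit_l1(ch2)$intercept, 10L)
  expect_error(fit_l1(lcsk_chain(NULL)), "empty")
})

test_that("the weighted-median intercept minimizes total weighted L1 deviation", {
  set.seed(61)
  for (r in 1:20) {
    n <- sample(3:12, 1)
    ic <- sample(0:300, n, TRUE)
    w <- sample(1:20, n, TRUE)
    ch <- chain_of(rep(0L, n), rep(1L, n), ic, ic + 1L, credit = w)
    fit <- fit_l1(ch)
    obj <- function(c0) sum(w * abs(ic - c0))
    # grid over all candidate intercepts (an optimum lies on a data point)
    expect_equal(obj(fit$intercept), min(vapply(ic, obj, 0)))
  }
})

test_that("band_filter keeps anchors within e*T of the line", {
  ch <- chain_of(c(0L, 10L, 20L), c(5L, 15L, 25L),
                 c(0L, 10L, 2000L), c(5L, 15L, 2005L))
  fit <- fit_l1(ch)
  # all residuals zero -> nothing removed
  ch0 <- chain_of(c(0L, 10L), c(5L, 15L), c(7L, 17L), c(12L, 22L))
  bf0 <- band_filter(ch0, fit_l1(ch0), e = 0.45, read_len = 100)
  expect_equal(nrow(bf0$anchors), 2L)
  # an anchor at twice the band distance is removed
  bf <- band_filter(ch, fit, e = 0.45, read_len = 1000)
  expect_equal(nrow(bf$anchors), 2L)
  # e = 0: only anchors exactly on the line survive
  bf_null <- band_filter(ch, fit, e = 0, read_len = 1000)
  expect_true(all(bf_null$residuals == 0))
})

test_that("the confidence refilter implements the 3-sigma-style rule", {
  # residuals {0, 0, 0, 10}: conf = 3 * sqrt(mean(d^2)) = 15, all survive
  f <- list(anchors = data.frame(qstart = c(0L, 10L, 20L, 30L),
                                 qend = c(5L, 15L, 25L, 35L),
                                 tstart = c(0L, 10L, 20L, 44L),
                                 tend = c(5L, 15L, 25L, 49L)),
            residuals = c(0, 0, 0, 10))
  ch <- confidence_refilter_and_rechain(f)
  expect_equal(nrow(ch$anchors), 4L)
  # a single anchor always survives its own confidence interval
  f1 <- list(anchors = data.frame(qstart = 0L, qend = 20L,
                                  tstart = 3L, tend = 23L), residuals = 2.1)
  expect_equal(nrow(confidence_refilter_and_rechain(f1)$anchors), 1L)
  # no survivors -> empty chain
  f0 <- list(anchors = f$anchors[0, ], residuals = numeric(0))
  expect_equal(confidence_refilter_and_rechain(f0)$total_covered, 0)
})

test_that("band then confidence filtering never increases the residual spread", {
  set.seed(62)
  for (r in 1:10) {
    a <- rand_anchors(20, span = 400L)
    ch <- lcsk_chain(a)
    if (nrow(ch$anchors) < 3) next
    fit <- fit_l1(ch)
    s0 <- sqrt(mean(fit$residuals^2))
    bf <- band_filter(ch, fit, e = 0.45, read_len = 200)
    ch2 <- confidence_refilter_and_rechain(bf)
    if (nrow(ch2$anchors) == 0) next
    s1 <- sqrt(mean(fit_l1(ch2)$residuals^2))
    expect_lte(s1, s0 + 1e-9)
  }
})

test_that("score_region normalizes the four scores and multiplies them", {
  # perfect full-length match: mlen, ncb and sigma scores are all 1 and the
  # quality reduces to the read-length score
  ch <- chain_of(0L, 1000L, 0L, 1000L)
  ch$anchors$covered_bases <- 1000L
  ch$anchors$covered_kmers <- 995L
  s <- score_region(ch, read_len = 1000, ref_len = 1000)
  expect_equal(s$norm_mlen, 1)
  expect_equal(s$norm_ncb, 1)
  expect_equal(s$norm_sigma, 1)
  expect_equal(s$f, s$norm_readlen)
  expect_equal(s$n_kmers, 995L)
  # half-covered read bounds f by the mlen score
  ch2 <- chain_of(0L, 500L, 0L, 500L)
  s2 <- score_region(ch2, read_len = 1000, ref_len = 1000)
  expect_equal(s2$norm_mlen, 0.5)
  expect_lte(s2$f, 0.5)
  # empty chain scores zero
  expect_equal(score_region(lcsk_chain(NULL), 1000, 1000)$f, 0)
  # all normalized scores stay in [0, 1]
  set.seed(63)
  for (r in 1:10) {
    ch3 <- lcsk_chain(rand_anchors(10))
    s3 <- score_region(ch3, 150, 5000)
    expect_true(all(unlist(s3[c("norm_mlen", "norm_ncb", "norm_sigma",
                                "norm_readlen")]) >= 0))
    expect_true(all(unlist(s3[c("norm_mlen", "norm_ncb", "norm_sigma",
                                "norm_readlen")]) <= 1))
    expect_gte(s3$f, 0); expect_lte(s3$f, 1)
  }
})

test_that("the true region outscores a partial decoy on a simulated read", {
  ref <- make_reference(40000, seed = 64, name = "g")
  # decoy: first half of the read's source segment copied elsewhere
  g <- ref[[1]]
  src <- substr(g, 10001, 12000)
  decoy <- paste0(substr(src, 1, 900), substr(make_reference(1100, seed = 65), 1, 1100))
  substr(g, 30001, 32000) <- decoy
  sim <- simulate_reads(stats::setNames(substr(g, 9001, 14000), "w"), 1,
                        1800, 1800, error_profile("2D"), seed = 66)
  read <- sim$reads[[1]]
  if (sim$truth$strand == "-") read <- nanomapr:::cpp_revcomp(read)
  score_at <- function(regstart, regend) {
    anch <- filter_walks(graph_walk(read, substr(g, regstart, regend)))
    ch <- lcsk_chain(anch)
    if (nrow(ch$anchors) == 0) return(0)
    fit <- fit_l1(ch)
    ch2 <- confidence_refilter_and_rechain(
      band_filter(ch, fit, 0.45, nchar(read)))
    score_region(ch2, nchar(read), nchar(g))$f
  }
  true_f <- score_at(9001 + sim$truth$start - 1800, 9001 + sim$truth$end + 1800)
  decoy_f <- score_at(28000, 34000)
  expect_gt(true_f, decoy_f)
})
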