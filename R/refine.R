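#' Fit the 45-degree L1 line through a chain of anchors
#'
#' Chained anchors should be collinear in read-region space with slope 1;
#' deviations are indel noise.  The least-absolute-deviation fit with fixed
#' slope reduces to the weighted median of the anchor intercepts
#' `tstart - qstart`, weighted by credited length.  Residuals are reported
#' as perpendicular distances to the line (the factor `1/sqrt(2)` converts
#' from reference-coordinate offsets).
#'
#' @param chain an `nm_chain` from [lcsk_chain()] (non-empty).
#' @return An `nm_l1fit`: `intercept` (bases) and `residuals` (one
#'   perpendicular distance per chain anchor).
#' @export
fit_l1 <- function(chain) {
  a <- chain$anchors
  if (is.null(a) || nrow(a) == 0L) stop("cannot fit an L1 line to an empty chain")
  ic <- a$tstart - a$qstart
  w <- if ("credit" %in% names(a)) pmax(1, a$credit) else a$qend - a$qstart
  o <- order(ic)
  cw <- cumsum(w[o])
  intercept <- ic[o][which(cw >= sum(w) / 2)[1L]]
  structure(list(intercept = intercept,
                 residuals = abs(ic - intercept) / sqrt(2)),
            class = "nm_l1fit")
}

#' Remove anchors far from the L1 line
#'
#' Keeps anchors within `e * T` of the line in reference coordinates, i.e.
#' a perpendicular distance of at most `e * T / sqrt(2)`, where `e` is the
#' expected error rate (conservatively 45 percent by default) and `T` the
#' read length.
#'
#' @param chain an `nm_chain`.
#' @param fit its [fit_l1()] result.
#' @param e expected error rate (default 0.45).
#' @param read_len read length `T` (bases).
#' @return list with the surviving `anchors` (data.frame) and their
#'   `residuals`.
#' @export
band_filter <- function(chain, fit, e = 0.45, read_len) {
  keep <- fit$residuals <= e * read_len / sqrt(2)
  list(anchors = chain$anchors[keep, , drop = FALSE],
       residuals = fit$residuals[keep])
}

#' Confidence-interval refilter and re-chain
#'
#' From the band-filtered anchors a confidence half-width
#' `conf = 3 * sqrt(mean(d_i^2))` is computed (the constant 3 mimicking a
#' 3-sigma rule); anchors within `conf` of the line are re-chained with
#' [lcsk_chain()] to close gaps opened by the filtering.
#'
#' @param filtered result of [band_filter()].
#' @return An `nm_chain` (empty when no anchors survive; such a region
#'   scores 0).
#' @export
confidence_refilter_and_rechain <- function(filtered) {
  a <- filtered$anchors
  d <- filtered$residuals
  if (is.null(a) || nrow(a) == 0L) return(lcsk_chain(a))
  conf <- 3 * sqrt(mean(d^2))
  lcsk_chain(a[d <= conf, , drop = FALSE])
}

#' Score the quality of a candidate region
#'
#' Five empirically motivated scores describe a refined chain: the exact
#' kmers covered by the anchors (`n_kmers`), the standard deviation `sigma`
#' of anchors around the L1 line, the matched query span `m_len`, the bases
#' covered by anchors (`n_cb`) and the read length.  The last four are
#' normalized to `[0, 1]`:
#' \deqn{norm_{mlen} = \min(1, m_{len}/T)}
#' \deqn{norm_{ncb} = \min(1, n_{cb}/\max(1, m_{len}))}
#' \deqn{norm_{\sigma} = \max(0, 1 - \sigma/(eT))}
#' \deqn{norm_{readlen} = T/(T + \min(Q, 10^4))}
#' and the region quality `f` is their product.  `n_kmers` is reserved for
#' the ambiguity rule of [ambiguity_count()].
#'
#' @param chain the re-chained `nm_chain` of the region.
#' @param read_len read length `T`.
#' @param ref_len length `Q` of the region's reference sequence.
#' @param e expected error rate (default 0.45).
#' @return An `nm_region_score` list: raw scores, the four normalized
#'   scores, and `f` (0 for an empty chain).
#' @export
score_region <- function(chain, read_len, ref_len, e = 0.45) {
  a <- chain$anchors
  tl <- read_len
  if (is.null(a) || nrow(a) == 0L) {
    return(structure(list(n_kmers = 0L, sigma = NA_real_, m_len = 0L,
                          n_cb = 0L, read_len = tl, ref_len = ref_len,
                          norm_mlen = 0, norm_ncb = 0, norm_sigma = 0,
                          norm_readlen = 0, f = 0),
                     class = "nm_region_score"))
  }
  fit <- fit_l1(chain)
  sigma <- sqrt(mean(fit$residuals^2))
  n_kmers <- if ("covered_kmers" %in% names(a)) sum(a$covered_kmers) else nrow(a)
  m_len <- max(a$qend) - min(a$qstart)
  n_cb <- if ("covered_bases" %in% names(a)) sum(a$covered_bases)
          else sum(a$qend - a$qstart)
  norm_mlen <- min(1, m_len / tl)
  norm_ncb <- min(1, n_cb / max(1, m_len))
  norm_sigma <- max(0, 1 - sigma / (e * tl))
  norm_readlen <- tl / (tl + min(ref_len, 10000))
  structure(list(n_kmers = n_kmers, sigma = sigma, m_len = m_len,
                 n_cb = n_cb, read_len = tl, ref_len = ref_len,
                 norm_mlen = norm_mlen, norm_ncb = norm_ncb,
                 norm_sigma = norm_sigma, norm_readlen = norm_readlen,
                 f = norm_mlen * norm_ncb * norm_sigma * norm_readlen),
            class = "nm_region_score")
}
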