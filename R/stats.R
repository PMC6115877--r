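#' Per-site ABBA/BABA pattern weights
#'
#' At a polarized biallelic site with derived-allele frequencies
#' (p1, p2, p3, p4) for (P1, P2, P3, O), the frequency-weighted pattern
#' counts are
#' \deqn{C_{ABBA} = (1-p_1)\,p_2\,p_3\,(1-p_4), \qquad
#'       C_{BABA} = p_1\,(1-p_2)\,p_3\,(1-p_4).}
#' For haploid single-genome taxa every frequency is 0 or 1 and the weights
#' reduce to indicator counts of the two discordant site patterns.
#'
#' @param p1,p2,p3,p4 Numeric vectors of derived-allele frequencies in
#'   \[0,1\], recycled to a common length; or `p1` may be a data.frame (or
#'   `quartet_sites` object) carrying columns `p1`..`p4`.
#' @return A data.frame with columns `c_abba` and `c_baba`, one row per site.
#' @examples
#' site_weights(0, 1, 1, 0)        # fixed ABBA site: weight (1, 0)
#' site_weights(0.2, 0.8, 0.6, 0)  # frequency-weighted: (0.384, 0.024)
#' @export
site_weights <- function(p1, p2 = NULL, p3 = NULL, p4 = NULL) {
  if (inherits(p1, "quartet_sites")) p1 <- p1$sites
  if (is.data.frame(p1)) {
    df <- p1
    p1 <- df$p1; p2 <- df$p2; p3 <- df$p3; p4 <- df$p4
  }
  data.frame(c_abba = (1 - p1) * p2 * p3 * (1 - p4),
             c_baba = p1 * (1 - p2) * p3 * (1 - p4))
}

sites_frame <- function(sites) {
  if (inherits(sites, "quartet_sites")) sites$sites else as.data.frame(sites)
}

#' Patterson's D over a set of polarized sites
#'
#' Sums the per-site ABBA and BABA weights and forms
#' \deqn{D = \frac{\sum C_{ABBA} - \sum C_{BABA}}
#'                {\sum C_{ABBA} + \sum C_{BABA}}.}
#' Under lineage sorting alone the two discordant patterns are equally
#' frequent and D is expected to be 0; an excess of ABBA (D > 0) indicates
#' gene flow between P2 and P3.
#'
#' @param sites A `quartet_sites` object or data.frame with columns
#'   `p1`..`p4` (empty input allowed).
#' @return A list with elements `d`, `abba`, `baba`, `n_informative` (sites
#'   with positive total weight) and `n_sites`. `d` is `NA` when
#'   `abba + baba == 0`.
#' @seealso [d_ztest()] for the block-jackknife significance test.
#' @export
d_stat <- function(sites) {
  s <- sites_frame(sites)
  w <- site_weights(s$p1, s$p2, s$p3, s$p4)
  abba <- sum(w$c_abba)
  baba <- sum(w$c_baba)
  tot <- abba + baba
  list(d = if (tot > 0) (abba - baba) / tot else NA_real_,
       abba = abba, baba = baba,
       n_informative = sum(w$c_abba + w$c_baba > 0),
       n_sites = nrow(s))
}

#' Block-jackknife z-test for Patterson's D
#'
#' Estimates the standard error of D by a delete-one jackknife over
#' contiguous blocks of sites (sites are assumed sorted by position, so
#' blocks respect linkage), then tests D = 0 with a two-sided z-test.
#'
#' Degenerate cases are reported explicitly rather than silently: with fewer
#' than two informative blocks `se`, `z` and `p` are `NA` and
#' `degenerate = TRUE`; with `se == 0` the test collapses to `p = 1` when
#' `d == 0` and `p = 0` (flagged degenerate) when `d != 0`, the latter
#' arising e.g. when every site in a window is a fixed ABBA pattern.
#'
#' @inheritParams d_stat
#' @param n_blocks Number of contiguous jackknife blocks (capped at the
#'   number of sites; at least 2 informative blocks are required).
#' @return The [d_stat()] list extended with `se`, `z`, `p`,
#'   `n_blocks_used` and `degenerate`.
#' @export
d_ztest <- function(sites, n_blocks = 20) {
  s <- sites_frame(sites)
  res <- d_stat(s)
  res$se <- NA_real_; res$z <- NA_real_; res$p <- NA_real_
  res$n_blocks_used <- 0L; res$degenerate <- FALSE
  if (is.na(res$d)) return(res)

  w <- site_weights(s$p1, s$p2, s$p3, s$p4)
  nb <- max(2L, min(as.integer(n_blocks), nrow(s)))
  grp <- ceiling(seq_len(nrow(s)) / (nrow(s) / nb))
  ca <- as.vector(rowsum(w$c_abba, grp))
  cb <- as.vector(rowsum(w$c_baba, grp))
  inf <- which(ca + cb > 0)
  if (length(inf) < 2L) {
    res$degenerate <- TRUE
    return(res)
  }
  A <- res$abba; B <- res$baba
  # leave-one-out replicates over informative blocks
  num <- (A - ca[inf]) - (B - cb[inf])
  den <- (A - ca[inf]) + (B - cb[inf])
  ok <- den > 0
  if (sum(ok) < 2L) {
    res$degenerate <- TRUE
    return(res)
  }
  theta <- num[ok] / den[ok]
  g <- length(theta)
  res$n_blocks_used <- g
  res$se <- sqrt((g - 1) / g * sum((theta - mean(theta))^2))
  if (res$se == 0) {
    if (res$d == 0) {
      res$z <- 0; res$p <- 1
    } else {
      res$z <- sign(res$d) * Inf; res$p <- 0; res$degenerate <- TRUE
    }
  } else {
    res$z <- res$d / res$se
    res$p <- 2 * stats::pnorm(-abs(res$z))
  }
  res
}

#' The f_d admixture-fraction statistic
#'
#' Confirms candidate introgression windows by comparing the observed
#' ABBA-BABA excess with the excess expected under complete introgression.
#' The numerator is \eqn{S(P_1,P_2,P_3,O) = \sum (C_{ABBA} - C_{BABA})}; the
#' denominator is the same sum with the per-site donor frequency
#' \eqn{P_D = \max(p_2, p_3)} substituted for both P2 and P3:
#' \deqn{f_d = S(P_1, P_2, P_3, O) / S(P_1, P_D, P_D, O).}
#' The statistic is only meaningful for windows with an ABBA excess, so
#' `fd` is `NA` whenever the numerator is non-positive (or the denominator
#' is zero); such windows can never pass the f_d filter.
#'
#' @inheritParams d_stat
#' @return A list with `s_num`, `s_den` and `fd`.
#' @export
fd_stat <- function(sites) {
  s <- sites_frame(sites)
  w <- site_weights(s$p1, s$p2, s$p3, s$p4)
  s_num <- sum(w$c_abba - w$c_baba)
  if (nrow(s)) {
    pd <- pmax(s$p2, s$p3)
    wd <- site_weights(s$p1, pd, pd, s$p4)
    s_den <- sum(wd$c_abba - wd$c_baba)
  } else s_den <- 0
  list(s_num = s_num, s_den = s_den,
       fd = if (s_num > 0 && s_den > 0) s_num / s_den else NA_real_)
}

#' Mean pairwise sequence divergence d_xy between two taxa
#'
#' \deqn{d_{xy} = \frac{1}{n} \sum_{i=1}^{n}
#'       \left[\hat p_{ix}(1-\hat p_{iy}) + \hat p_{iy}(1-\hat p_{ix})\right]}
#' over allele frequencies of taxa x and y. Monomorphic positions contribute
#' 0, so the sum may run over variant sites only provided the divisor `n`
#' still counts every comparable position: `n` is the number of retained
#' aligned sites when alignment input is available, or the region length in
#' bp otherwise. The same convention must be used for candidate windows and
#' their scaffold background.
#'
#' @param px,py Equal-length numeric vectors of allele frequencies in \[0,1\]
#'   at the variant sites of the region.
#' @param n Divisor: total number of comparable positions in the region
#'   (variant + invariant). Must be >= 1 for a defined value.
#' @return A list with `dxy` (NA with `undefined = TRUE` when `n < 1`),
#'   `n_sites` (variant sites summed) and `n` (the divisor).
#' @export
dxy_stat <- function(px, py, n) {
  if (length(px) != length(py))
    stop("px and py must have equal length")
  if (is.na(n) || n < 1)
    return(list(dxy = NA_real_, n_sites = length(px), n = n, undefined = TRUE))
  num <- sum(px * (1 - py) + py * (1 - px))
  list(dxy = num / n, n_sites = length(px), n = n, undefined = FALSE)
}

#' One-sided z-test for reduced window d_xy
#'
#' Compares a window's d_xy with the scaffold-wide background (mean and
#' standard error over all same-size windows on that scaffold). Introgression
#' replaces the recipient's haplotype with the donor's, so a true
#' introgressed window shows divergence significantly LOWER than background;
#' the test is one-sided in the lower tail. Incomplete lineage sorting, by
#' contrast, involves ancestral variation and does not reduce d_xy, which is
#' what this filter exploits.
#'
#' @param window_dxy Window d_xy value (or the list from [dxy_stat()]).
#' @param mean_dxy,se Scaffold background mean and standard error.
#' @return A list with `z` and one-sided `p`; both `NA` with
#'   `undefined = TRUE` when `se` is 0 or not available.
#' @export
dxy_ztest <- function(window_dxy, mean_dxy, se) {
  if (is.list(window_dxy)) window_dxy <- window_dxy$dxy
  if (is.na(window_dxy) || is.na(mean_dxy) || is.na(se) || se <= 0)
    return(list(z = NA_real_, p = NA_real_, undefined = TRUE))
  z <- (window_dxy - mean_dxy) / se
  list(z = z, p = stats::pnorm(z), undefined = FALSE)
}
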