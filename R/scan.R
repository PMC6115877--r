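#' Significance criteria for the introgression filter cascade
#'
#' Bundles the thresholds of the three-stage window filter: the compound
#' D-significance rule (`p < p_threshold`, `|D| > abs_d_min`,
#' `|ABBA - BABA| > min_abba_baba_gap`), the genome-wide f_d percentile kept
#' at stage 2, and the one-sided d_xy p-value of stage 3. The
#' `|ABBA - BABA|` gap is evaluated on the frequency-weighted sums, which
#' equal plain pattern counts for haploid single-genome taxa.
#'
#' @param p_threshold Two-sided D z-test p-value cutoff (default 1e-3).
#' @param abs_d_min Minimum |D| (default 0.59); set to `NA` to disable this
#'   component of the compound rule.
#' @param min_abba_baba_gap Minimum |ABBA - BABA| weight gap (default 10).
#' @param fd_percentile Stage-2 retention percentile of genome-wide f_d
#'   (default 90: only windows in the top decile are kept).
#' @param dxy_p One-sided lower-tail p-value cutoff for the stage-3 d_xy
#'   z-test (default 0.01).
#' @param bh_correct Apply Benjamini-Hochberg correction to the stage-1
#'   window p-values before thresholding (default `FALSE`: raw per-window
#'   thresholds).
#' @return An object of class `scan_criteria`.
#' @export
scan_criteria <- function(p_threshold = 1e-3, abs_d_min = 0.59,
                          min_abba_baba_gap = 10, fd_percentile = 90,
                          dxy_p = 0.01, bh_correct = FALSE) {
  stopifnot(p_threshold > 0, is.na(abs_d_min) || abs_d_min > 0,
            min_abba_baba_gap > 0,
            fd_percentile > 0, fd_percentile < 100, dxy_p > 0)
  structure(list(p_threshold = p_threshold, abs_d_min = abs_d_min,
                 min_abba_baba_gap = min_abba_baba_gap,
                 fd_percentile = fd_percentile, dxy_p = dxy_p,
                 bh_correct = bh_correct),
            class = "scan_criteria")
}

#' @export
print.scan_criteria <- function(x, ...) {
  cat("Introgression scan criteria:\n")
  cat(sprintf("  stage 1 (D):    p < %g, |D| > %s, |ABBA-BABA| > %g%s\n",
              x$p_threshold,
              if (is.na(x$abs_d_min)) "(off)" else format(x$abs_d_min),
              x$min_abba_baba_gap,
              if (x$bh_correct) " [BH-corrected p]" else ""))
  cat(sprintf("  stage 2 (f_d):  keep f_d >= genome-wide %gth percentile\n",
              x$fd_percentile))
  cat(sprintf("  stage 3 (d_xy): one-sided lower p < %g vs scaffold background\n",
              x$dxy_p))
  invisible(x)
}

#' Stage 1: compound Patterson's D significance filter
#'
#' Retains windows whose block-jackknife z-test rejects D = 0 at
#' `p < p_threshold` with `|D| > abs_d_min` and an absolute ABBA-BABA weight
#' gap above `min_abba_baba_gap`. Windows with undefined D (no informative
#' sites, or an unusable jackknife) never pass.
#'
#' @param windows Window statistics table from [window_stats()].
#' @param criteria A [scan_criteria()] object.
#' @return Logical vector, one element per window row.
#' @export
stage1_d_filter <- function(windows, criteria = scan_criteria()) {
  p <- windows$p
  if (criteria$bh_correct) p <- stats::p.adjust(p, method = "BH")
  pass <- !is.na(windows$d) & !is.na(p) & p < criteria$p_threshold &
    abs(windows$abba - windows$baba) > criteria$min_abba_baba_gap
  if (!is.na(criteria$abs_d_min))
    pass <- pass & abs(windows$d) > criteria$abs_d_min
  pass
}

#' Stage 2: top-decile f_d retention
#'
#' Computes the `fd_percentile`-th percentile of f_d over ALL windows with a
#' defined f_d genome-wide (linear-interpolation quantile, R type 7) and
#' keeps candidates at or above that cutoff. This controls for heterogeneity
#' in genetic variation: windows whose D signal is not matched by a strong
#' admixture-fraction estimate are excluded. Candidates with undefined f_d
#' (non-positive ABBA-BABA excess) never pass.
#'
#' @param candidates Logical vector of stage-1 survivors (or row indices).
#' @param windows Full window statistics table (the percentile reference
#'   set).
#' @param criteria A [scan_criteria()] object.
#' @return Logical vector, one element per window row; attribute
#'   `fd_cutoff` carries the percentile value used.
#' @export
stage2_fd_filter <- function(candidates, windows, criteria = scan_criteria()) {
  cand <- to_logical_index(candidates, nrow(windows))
  fd_all <- windows$fd[!is.na(windows$fd)]
  if (!length(fd_all))
    stop("no window has a defined f_d; cannot compute the percentile cutoff")
  cutoff <- stats::quantile(fd_all, criteria$fd_percentile / 100,
                            type = 7, names = FALSE)
  pass <- cand & !is.na(windows$fd) & windows$fd >= cutoff
  attr(pass, "fd_cutoff") <- cutoff
  pass
}

#' Stage 3: d_xy reduction filter against the scaffold background
#'
#' Tests each candidate window's d_xy against its scaffold's background mean
#' and standard error ([scaffold_background()]) with a one-sided lower-tail
#' z-test, retaining windows significantly LESS divergent than the scaffold.
#' Candidates on scaffolds with an unusable background (fewer than two
#' windows, or zero spread) are dropped and flagged, never silently passed.
#'
#' @param candidates Logical vector of stage-2 survivors (or row indices).
#' @param windows Full window statistics table.
#' @param backgrounds data.frame from [scaffold_background()].
#' @param criteria A [scan_criteria()] object.
#' @return Logical vector per window row, with attributes `dxy_z`, `dxy_p`
#'   (per-window test results, NA outside candidates) and
#'   `dropped_no_background` (candidate rows lost to unusable backgrounds).
#' @export
stage3_dxy_filter <- function(candidates, windows, backgrounds,
                              criteria = scan_criteria()) {
  cand <- to_logical_index(candidates, nrow(windows))
  z <- rep(NA_real_, nrow(windows))
  p <- rep(NA_real_, nrow(windows))
  pass <- rep(FALSE, nrow(windows))
  dropped <- integer(0)
  bg <- backgrounds[match(windows$scaffold, backgrounds$scaffold), ]
  for (i in which(cand)) {
    if (is.na(bg$usable[i]) || !bg$usable[i]) {
      dropped <- c(dropped, i)
      next
    }
    t <- dxy_ztest(windows$dxy[i], bg$mean_dxy[i], bg$se[i])
    z[i] <- t$z; p[i] <- t$p
    pass[i] <- !t$undefined && t$p < criteria$dxy_p
  }
  attr(pass, "dxy_z") <- z
  attr(pass, "dxy_p") <- p
  attr(pass, "dropped_no_background") <- dropped
  pass
}

to_logical_index <- function(x, n) {
  if (is.logical(x)) {
    stopifnot(length(x) == n)
    x & !is.na(x)
  } else {
    v <- rep(FALSE, n)
    v[x] <- TRUE
    v
  }
}

#' Genome-wide windowed introgression scan
#'
#' The package's main entry point: tiles the genome into windows, computes
#' ABBA/BABA weight sums, Patterson's D with a block-jackknife z-test, f_d
#' and d_xy per window, then applies the three-stage filter cascade —
#' (1) compound D significance, (2) retention of the genome-wide top f_d
#' decile, (3) significantly reduced d_xy relative to the scaffold
#' background — to call introgressed regions. Stage sets are nested by
#' construction: stage 3 output is a subset of stage 2, which is a subset of
#' stage 1.
#'
#' @param sites A `quartet_sites` object (see [read_quartet_vcf()],
#'   [read_aligned_fasta()], [read_snp_table()], [simulate_quartet()]).
#' @param window_size Window size in bp (default 5000).
#' @param step Step in bp (default `window_size`: adjacent windows).
#' @param criteria A [scan_criteria()] object.
#' @param dxy_taxa Divergence pair for d_xy, default `c("p2", "p3")`.
#' @param n_blocks Jackknife blocks per window.
#' @param exclude_candidates_from_background If `TRUE`, stage-1 candidate
#'   windows are excluded from the scaffold d_xy background (default
#'   `FALSE`: the background is the whole scaffold).
#' @return An object of class `introgression_scan`: a list with elements
#'   `windows` (per-window statistics and stage flags), `regions`
#'   (windows surviving all three stages, with stage provenance),
#'   `background` (per-scaffold d_xy background), `criteria`, `attrition`
#'   (windows tested -> stage1 -> stage2 -> stage3), `fd_cutoff`,
#'   `window_size`, `step`, `dxy_mode`, and the matched `call`.
#' @examples
#' sim <- simulate_quartet(sim_config(genome_length = 2e5, seed = 1,
#'                                    tracts = NULL))
#' scan <- introgression_scan(sim$sites, window_size = 5000)
#' scan
#' @export
introgression_scan <- function(sites, window_size = 5000, step = window_size,
                               criteria = scan_criteria(),
                               dxy_taxa = c("p2", "p3"), n_blocks = 20,
                               exclude_candidates_from_background = FALSE) {
  stopifnot(inherits(sites, "quartet_sites"))
  win <- make_windows(sites, window_size, step)
  w <- window_stats(sites, win, dxy_taxa = dxy_taxa, n_blocks = n_blocks)

  s1 <- stage1_d_filter(w, criteria)
  s2 <- stage2_fd_filter(s1, w, criteria)
  bg <- scaffold_background(w, exclude = if (exclude_candidates_from_background) s1)
  s3 <- stage3_dxy_filter(s2, w, bg, criteria)

  w$stage1 <- s1
  w$stage2 <- as.logical(s2)
  w$stage3 <- as.logical(s3)
  w$dxy_z <- attr(s3, "dxy_z")
  w$dxy_p <- attr(s3, "dxy_p")

  regions <- w[w$stage3, , drop = FALSE]
  if (nrow(regions))
    regions$stages <- "D_ztest;fd_top_decile;dxy_reduced"
  rownames(regions) <- NULL

  structure(list(
    windows = w,
    regions = regions,
    background = bg,
    criteria = criteria,
    fd_cutoff = attr(s2, "fd_cutoff"),
    attrition = c(windows = nrow(w), stage1 = sum(s1),
                  stage2 = sum(s2), stage3 = sum(s3)),
    dropped_no_background = attr(s3, "dropped_no_background"),
    window_size = window_size, step = step,
    dxy_mode = attr(w, "dxy_mode"), dxy_taxa = dxy_taxa,
    n_blocks = n_blocks,
    call = match.call()
  ), class = "introgression_scan")
}

#' @export
print.introgression_scan <- function(x, ...) {
  cat(sprintf("Introgression scan: %d windows of %s bp (step %s) on %d scaffold(s)\n",
              x$attrition[["windows"]],
              format(x$window_size, big.mark = ","),
              format(x$step, big.mark = ","),
              length(unique(x$windows$scaffold))))
  cat(sprintf("  filter cascade: %d windows -> %d (D z-test) -> %d (f_d top %g%%) -> %d (d_xy reduced)\n",
              x$attrition[["windows"]], x$attrition[["stage1"]],
              x$attrition[["stage2"]], 100 - x$criteria$fd_percentile,
              x$attrition[["stage3"]]))
  gw <- d_stat_from_windows(x$windows)
  if (!is.na(gw))
    cat(sprintf("  genome-wide D (pooled windows): %.4f\n", gw))
  cat(sprintf("  d_xy pair (%s, %s), divisor mode: %s\n",
              x$dxy_taxa[1], x$dxy_taxa[2], x$dxy_mode))
  if (length(x$dropped_no_background))
    cat(sprintf("  %d candidate(s) dropped: unusable scaffold background\n",
                length(x$dropped_no_background)))
  invisible(x)
}

d_stat_from_windows <- function(w) {
  tot <- sum(w$abba) + sum(w$baba)
  if (tot > 0) (sum(w$abba) - sum(w$baba)) / tot else NA_real_
}

#' @export
summary.introgression_scan <- function(object, ...) {
  x <- object
  cat("Windowed ABBA-BABA introgression scan\n\n")
  print(x$criteria)
  cat(sprintf("\nAttrition: %s\n",
              paste(sprintf("%s=%d", names(x$attrition), x$attrition),
                    collapse = " -> ")))
  cat(sprintf("f_d stage-2 cutoff (%gth percentile): %s\n",
              x$criteria$fd_percentile,
              if (is.null(x$fd_cutoff)) "NA" else format(x$fd_cutoff, digits = 4)))
  cat("\nScaffold d_xy background:\n")
  print(x$background, row.names = FALSE)
  if (nrow(x$regions)) {
    cat("\nIntrogressed regions:\n")
    cols <- c("scaffold", "start", "end", "n_sites", "abba", "baba",
              "d", "p", "fd", "dxy", "dxy_p")
    print(format(x$regions[, cols], digits = 3), row.names = FALSE)
  } else cat("\nNo introgressed regions called.\n")
  invisible(x)
}

#' @export
as.data.frame.introgression_scan <- function(x, ...) x$windows

#' Plot the windowed D track of a scan
#'
#' Base-graphics track of per-window Patterson's D along each scaffold, with
#' introgressed regions (stage-3 survivors) highlighted.
#'
#' @param x An `introgression_scan` object.
#' @param scaffold Scaffold to plot (default: first).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the plotted window subset.
#' @export
plot.introgression_scan <- function(x, scaffold = NULL, ...) {
  w <- x$windows
  if (is.null(scaffold)) scaffold <- w$scaffold[1]
  w <- w[w$scaffold == scaffold, ]
  mid <- (w$start + w$end) / 2
  graphics::plot(mid / 1e3, w$d, type = "h", ylim = c(-1, 1),
                 xlab = sprintf("%s position (kb)", scaffold),
                 ylab = "Patterson's D",
                 main = sprintf("Windowed D (%s bp windows)",
                                format(x$window_size, big.mark = ",")), ...)
  graphics::abline(h = 0, col = "grey60")
  if (any(w$stage3))
    graphics::points(mid[w$stage3] / 1e3, w$d[w$stage3], col = "firebrick",
                     pch = 19)
  invisible(w)
}

#' Clade-level summary of D-significant windows across quartets
#'
#' Summarizes, per scanned quartet, how many windows carry a significant
#' D-statistic. Intended for coarse clade-level comparison at the 500-kb
#' scale; it deliberately uses only the stage-1 D-significance filter (the
#' f_d and d_xy confirmation stages are per-locus refinements, not
#' clade-level rates).
#'
#' @param scans Named list of `introgression_scan` objects, one per quartet.
#' @return data.frame with columns `quartet`, `n_windows_tested`,
#'   `n_windows_significant`, `fraction`.
#' @export
clade_summary <- function(scans) {
  if (inherits(scans, "introgression_scan")) scans <- list(scans)
  stopifnot(length(scans) >= 1)
  nm <- names(scans)
  if (is.null(nm)) nm <- paste0("quartet_", seq_along(scans))
  rows <- lapply(seq_along(scans), function(i) {
    x <- scans[[i]]
    stopifnot(inherits(x, "introgression_scan"))
    n <- x$attrition[["windows"]]
    k <- x$attrition[["stage1"]]
    data.frame(quartet = nm[i], n_windows_tested = n,
               n_windows_significant = k,
               fraction = if (n > 0) k / n else 0)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
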