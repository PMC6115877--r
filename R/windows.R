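#' Tile scaffolds into genomic windows
#'
#' Windows are 0-based half-open intervals tiled from position 0 of each
#' scaffold. The final window of a scaffold may be shorter than `size`; it is
#' retained but flagged `partial` (partial windows are excluded from the
#' d_xy background estimate, where their shorter length would inflate the
#' variance). With `step < size` the tiling is a true sliding scan; the
#' default `step = size` gives adjacent (tumbling) windows.
#'
#' @param scaffold_lengths Named numeric vector of scaffold lengths in bp,
#'   or a `quartet_sites` object.
#' @param size Window size in bp (presets used in practice: 5e3, 5e4, 1e5,
#'   5e5).
#' @param step Step between window starts in bp; `0 < step <= size`.
#' @return data.frame with columns `scaffold`, `start`, `end` (0-based
#'   half-open) and `partial`.
#' @export
make_windows <- function(scaffold_lengths, size, step = size) {
  if (inherits(scaffold_lengths, "quartet_sites"))
    scaffold_lengths <- scaffold_lengths$scaffold_lengths
  stopifnot(size > 0, step > 0, step <= size)
  out <- lapply(names(scaffold_lengths), function(sc) {
    len <- scaffold_lengths[[sc]]
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + size, len)
    data.frame(scaffold = sc, start = starts, end = ends,
               partial = ends - starts < size)
  })
  do.call(rbind, out)
}

# Index ranges of (sorted) site positions falling in [start, end), 0-based,
# for 1-based site coordinates pos.
window_site_index <- function(pos0, start, end) {
  lo <- findInterval(start - 0.5, pos0) + 1L
  hi <- findInterval(end - 0.5, pos0)
  if (hi < lo) integer(0) else seq.int(lo, hi)
}

#' Compute per-window ABBA-BABA statistics
#'
#' Fills a window table (from [make_windows()]) with the site counts, ABBA /
#' BABA weight sums, Patterson's D with its block-jackknife z-test, f_d, and
#' d_xy for the chosen taxon pair. A site at 1-based position `pos` belongs
#' to every window containing its 0-based coordinate `pos - 1`.
#'
#' The d_xy divisor per window is the number of callable aligned positions
#' when the site table carries them (aligned FASTA input), otherwise the
#' window length in bp with monomorphic positions contributing 0; the mode
#' used is returned as attribute `dxy_mode` and must match the background.
#'
#' @param sites A `quartet_sites` object.
#' @param windows data.frame from [make_windows()]; defaults to 5-kb
#'   adjacent windows.
#' @param dxy_taxa Length-2 character vector naming the frequency columns of
#'   the divergence pair; default `c("p2", "p3")`, the donor/recipient pair
#'   whose divergence introgression reduces.
#' @param n_blocks Jackknife blocks per window, see [d_ztest()].
#' @return The window data.frame extended with statistic columns
#'   (`n_sites`, `abba`, `baba`, `d`, `se`, `z`, `p`, `degenerate`,
#'   `fd_num`, `fd_den`, `fd`, `dxy`, `dxy_n`).
#' @export
window_stats <- function(sites, windows = make_windows(sites, 5000),
                         dxy_taxa = c("p2", "p3"), n_blocks = 20) {
  stopifnot(inherits(sites, "quartet_sites"))
  stopifnot(all(dxy_taxa %in% c("p1", "p2", "p3", "p4")), length(dxy_taxa) == 2)
  s <- sites$sites
  nw <- nrow(windows)
  cols <- list(n_sites = integer(nw), abba = numeric(nw), baba = numeric(nw),
               d = rep(NA_real_, nw), se = rep(NA_real_, nw),
               z = rep(NA_real_, nw), p = rep(NA_real_, nw),
               degenerate = logical(nw),
               fd_num = numeric(nw), fd_den = numeric(nw),
               fd = rep(NA_real_, nw),
               dxy = rep(NA_real_, nw), dxy_n = rep(NA_real_, nw))
  by_sc <- split(seq_len(nrow(s)), s$scaffold)
  dxy_mode <- if (is.null(sites$callable)) "bp" else "aligned"

  for (i in seq_len(nw)) {
    sc <- windows$scaffold[i]
    idx <- by_sc[[sc]]
    sub <- if (is.null(idx)) s[0, ] else {
      j <- window_site_index(s$pos[idx] - 1, windows$start[i], windows$end[i])
      s[idx[j], ]
    }
    cols$n_sites[i] <- nrow(sub)
    dz <- d_ztest(sub, n_blocks = n_blocks)
    cols$abba[i] <- dz$abba; cols$baba[i] <- dz$baba
    cols$d[i] <- dz$d; cols$se[i] <- dz$se; cols$z[i] <- dz$z
    cols$p[i] <- dz$p; cols$degenerate[i] <- dz$degenerate
    fd <- fd_stat(sub)
    cols$fd_num[i] <- fd$s_num; cols$fd_den[i] <- fd$s_den; cols$fd[i] <- fd$fd
    n_div <- if (dxy_mode == "aligned") {
      cp <- sites$callable[[sc]]
      if (is.null(cp)) 0 else length(window_site_index(cp - 1, windows$start[i], windows$end[i]))
    } else windows$end[i] - windows$start[i]
    dx <- dxy_stat(sub[[dxy_taxa[1]]], sub[[dxy_taxa[2]]], n_div)
    cols$dxy[i] <- dx$dxy; cols$dxy_n[i] <- dx$n
  }
  out <- cbind(windows, as.data.frame(cols))
  attr(out, "dxy_mode") <- dxy_mode
  attr(out, "dxy_taxa") <- dxy_taxa
  out
}

#' Scaffold-level d_xy background
#'
#' Mean and standard error of window d_xy per scaffold, estimated over all
#' full-size windows on the scaffold (candidate windows included — the
#' background is the whole scaffold; set `exclude` to drop specific window
#' rows). The standard error is the SEM over windows,
#' `sd(dxy) / sqrt(n_windows)`. Backgrounds estimated from fewer than two
#' windows, or with zero spread, are flagged unusable.
#'
#' @param windows Window statistics table from [window_stats()].
#' @param exclude Optional logical/integer index of window rows to exclude.
#' @return data.frame with one row per scaffold: `scaffold`, `mean_dxy`,
#'   `se`, `n_windows`, `usable`.
#' @export
scaffold_background <- function(windows, exclude = NULL) {
  keep <- !windows$partial & !is.na(windows$dxy)
  if (!is.null(exclude)) {
    drop <- rep(FALSE, nrow(windows))
    drop[exclude] <- TRUE
    keep <- keep & !drop
  }
  w <- windows[keep, ]
  res <- lapply(split(w$dxy, w$scaffold), function(v) {
    n <- length(v)
    se <- if (n >= 2) stats::sd(v) / sqrt(n) else NA_real_
    data.frame(mean_dxy = mean(v), se = se, n_windows = n,
               usable = n >= 2 && !is.na(se) && se > 0)
  })
  out <- do.call(rbind, res)
  out <- cbind(data.frame(scaffold = names(res)), out)
  rownames(out) <- NULL
  out
}
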