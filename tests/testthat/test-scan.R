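test_that("window tiling arithmetic, partial windows and overlapping steps", {
  w <- make_windows(c(sc1 = 12000), 5000)
  expect_equal(w$start, c(0, 5000, 10000))
  expect_equal(w$end, c(5000, 10000, 12000))
  expect_equal(w$partial, c(FALSE, FALSE, TRUE))
  w2 <- make_windows(c(sc1 = 10000), 5000, step = 2500)
  expect_equal(nrow(w2), 4L)
  expect_equal(w2$start, c(0, 2500, 5000, 7500))
  expect_error(make_windows(c(sc1 = 1e4), 5000, step = 6000))
})

test_that("sites land in every window containing their 0-based coordinate", {
  df <- data.frame(scaffold = "sc1", pos = c(1, 5000, 5001, 9999, 10000),
                   p1 = 0, p2 = 1, p3 = 1, p4 = 0)
  x <- quartet_sites(df, c(sc1 = 10000))
  w <- window_stats(x, make_windows(c(sc1 = 10000), 5000))
  # pos 5000 has 0-based coord 4999: first window; 5001 -> second
  expect_equal(w$n_sites, c(2L, 3L))
  # overlapping windows see interior sites size/step times
  wo <- window_stats(x, make_windows(c(sc1 = 10000), 5000, step = 2500))
  expect_equal(sum(wo$n_sites), 2 * nrow(df) - 1)  # pos 1 is edge-covered once
  # a siteless scaffold still yields windows
  e <- window_stats(quartet_sites(df[0, ], c(sc1 = 10000)),
                    make_windows(c(sc1 = 10000), 5000))
  expect_equal(e$n_sites, c(0L, 0L))
  expect_true(all(is.na(e$d)))
})

fake_windows <- function(d, p, abba, baba, fd = 1, dxy = 0.05,
                         scaffold = "sc1") {
  n <- length(d)
  data.frame(scaffold = scaffold, start = (seq_len(n) - 1) * 5000,
             end = seq_len(n) * 5000, partial = FALSE, n_sites = 50,
             abba = abba, baba = baba, d = d, se = 0.05, z = d / 0.05,
             p = p, degenerate = FALSE, fd_num = 1, fd_den = 1, fd = fd,
             dxy = dxy, dxy_n = 5000)
}

test_that("stage 1 applies the compound D-significance rule", {
  w <- fake_windows(d = c(0, 0.9, 0.9, 0.9, 0.9, NA),
                    p = c(0.5, 1e-5, 0.5, 1e-5, 1e-5, NA),
                    abba = c(25, 60, 60, 60, 15, 0),
                    baba = c(25, 10, 10, 45, 3, 0))
  crit <- scan_criteria()
  # rejected: D=0; retained: all three criteria; rejected: p; rejected via
  # |D| (0.9 but |abba-baba|=15 ok, p ok -> retained); gap 12 ... check each
  got <- stage1_d_filter(w, crit)
  expect_identical(got, c(FALSE, TRUE, FALSE, TRUE, TRUE, FALSE))
  # gap below 10 fails even with perfect p and D
  w2 <- fake_windows(0.95, 1e-8, abba = 9, baba = 0)
  expect_false(stage1_d_filter(w2, crit))
  # |D| criterion can be disabled
  w3 <- fake_windows(0.3, 1e-8, abba = 40, baba = 20)
  expect_false(stage1_d_filter(w3, crit))
  expect_true(stage1_d_filter(w3, scan_criteria(abs_d_min = NA)))
})

test_that("stage 2 keeps the genome-wide top f_d decile with >= ties", {
  fd <- c(seq(0.01, 1, by = 0.01))
  w <- fake_windows(rep(0.9, 100), rep(1e-5, 100), rep(60, 100),
                    rep(10, 100), fd = fd)
  keep <- stage2_fd_filter(rep(TRUE, 100), w, scan_criteria())
  # type-7 percentile of 0.01..1.00 at 90%: 0.901; windows 91..100 pass
  expect_equal(attr(keep, "fd_cutoff"), 0.901)
  expect_equal(which(keep), 91:100)
  # equal f_d everywhere: cutoff equals the common value, all retained
  w_eq <- fake_windows(rep(0.9, 5), rep(1e-5, 5), rep(60, 5), rep(10, 5),
                       fd = 0.4)
  expect_true(all(stage2_fd_filter(rep(TRUE, 5), w_eq, scan_criteria())))
  # undefined f_d is never retained
  w_na <- w_eq; w_na$fd[2] <- NA
  expect_identical(as.logical(stage2_fd_filter(rep(TRUE, 5), w_na,
                                               scan_criteria())),
                   c(TRUE, FALSE, TRUE, TRUE, TRUE))
  w_allna <- w_eq; w_allna$fd <- NA
  expect_error(stage2_fd_filter(rep(TRUE, 5), w_allna, scan_criteria()),
               "no window has a defined f_d")
})

test_that("stage 3 retains only significantly reduced d_xy", {
  w <- fake_windows(rep(0.9, 3), rep(1e-5, 3), rep(60, 3), rep(10, 3),
                    dxy = c(0.05, 0, 0.02))
  bg <- data.frame(scaffold = "sc1", mean_dxy = 0.05, se = 0.005,
                   n_windows = 50, usable = TRUE)
  keep <- stage3_dxy_filter(rep(TRUE, 3), w, bg, scan_criteria())
  expect_identical(as.logical(keep), c(FALSE, TRUE, TRUE))
  expect_equal(attr(keep, "dxy_p")[1], 0.5)
  expect_equal(attr(keep, "dxy_z")[2], -10)
  # unusable background drops candidates loudly, not silently
  bg0 <- transform(bg, usable = FALSE)
  k0 <- stage3_dxy_filter(rep(TRUE, 3), w, bg0, scan_criteria())
  expect_false(any(k0))
  expect_equal(attr(k0, "dropped_no_background"), 1:3)
})

test_that("scaffold background uses full windows and flags unusable cases", {
  w <- data.frame(scaffold = "sc1", start = c(0, 5000, 10000),
                  end = c(5000, 10000, 12000),
                  partial = c(FALSE, FALSE, TRUE),
                  dxy = c(0.04, 0.06, 0.5))
  bg <- scaffold_background(w)
  expect_equal(bg$mean_dxy, 0.05)       # partial window excluded
  expect_equal(bg$n_windows, 2L)
  expect_equal(bg$se, sd(c(0.04, 0.06)) / sqrt(2))
  one <- scaffold_background(w[c(1, 3), ])
  expect_false(one$usable)
})

test_that("the cascade is monotone and the scan is deterministic", {
  sim <- simulate_quartet(sim_config(genome_length = 3e5, seed = 21))
  scan <- introgression_scan(sim$sites)
  w <- scan$windows
  expect_true(all(w$stage3 <= w$stage2))
  expect_true(all(w$stage2 <= w$stage1))
  a <- scan$attrition
  expect_true(all(diff(a) <= 0))
  expect_identical(scan$regions$start,
                   w$start[w$stage1 & w$stage2 & w$stage3])
  # byte-identical outputs for identical inputs
  d1 <- tempfile(); d2 <- tempfile()
  run_scan(sim$sites, out_dir = d1, window_sizes = c(5000, 50000))
  run_scan(sim$sites, out_dir = d2, window_sizes = c(5000, 50000))
  for (f in c("windows_5000.tsv", "regions_5000.bed", "windows_50000.tsv")) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
  }
})

test_that("planted 5-kb tracts pass stage 1 and are recovered by the cascade", {
  sim <- simulate_quartet(sim_config(seed = 1))
  scan <- introgression_scan(sim$sites)
  w <- scan$windows
  truth <- sim$truth
  overlaps_tract <- function(start, end)
    any(start < truth$end & truth$start < end)
  tract_win <- mapply(overlaps_tract, w$start, w$end)
  # every tract-overlapping 5-kb window carries a stage-1 significant D
  expect_true(all(w$stage1[tract_win]))
  # recovered regions show top-decile f_d and significant d_xy reduction
  r <- scan$regions
  expect_true(all(r$fd >= scan$fd_cutoff))
  expect_true(all(r$dxy_p < scan$criteria$dxy_p))
  # recall and precision against the truth tracts
  recovered <- vapply(seq_len(nrow(truth)), function(i)
    any(r$start < truth$end[i] & truth$start[i] < r$end), TRUE)
  expect_gte(mean(recovered), 0.8)
  hits <- vapply(seq_len(nrow(r)), function(i)
    overlaps_tract(r$start[i], r$end[i]), TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("clade summary reports per-quartet significant-window fractions", {
  sim1 <- simulate_quartet(sim_config(genome_length = 5e5, seed = 31))
  sim0 <- simulate_quartet(sim_config(genome_length = 5e5, seed = 32,
                                      tracts = NULL))
  scans <- list(with_flow = introgression_scan(sim1$sites, 5e5),
                null = introgression_scan(sim0$sites, 5e5))
  cs <- clade_summary(scans)
  expect_equal(nrow(cs), 2L)
  expect_equal(cs$quartet, c("with_flow", "null"))
  expect_equal(cs$fraction,
               cs$n_windows_significant / cs$n_windows_tested)
  expect_equal(cs$n_windows_significant[2], 0L,
               ignore_attr = TRUE)
})

test_that("scan methods print, summarize, plot and coerce", {
  sim <- simulate_quartet(sim_config(genome_length = 1e5, seed = 41,
                                     tracts = data.frame(
                                       scaffold = "sc1", start = 50000,
                                       end = 55000, donor = "P3",
                                       recipient = "P2",
                                       residual_divergence = 0.01)))
  scan <- introgression_scan(sim$sites)
  expect_output(print(scan), "filter cascade")
  expect_output(summary(scan), "Attrition")
  expect_s3_class(as.data.frame(scan), "data.frame")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(scan))
})
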