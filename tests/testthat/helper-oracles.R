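# Shared fixtures and independent brute-force oracles. The oracles
# deliberately use naive per-site loops and explicit arithmetic, independent
# of the package's vectorized implementations.

test_quartet <- function() quartet_config("P1", "P2", "P3", "O")

# A quartet_sites object from a bare frequency data.frame.
sites_obj <- function(df, len = NULL, ...) {
  if (is.null(df$scaffold)) df$scaffold <- "sc1"
  if (is.null(df$pos)) df$pos <- seq_len(nrow(df))
  if (is.null(len)) len <- max(df$pos, 1)
  quartet_sites(df, stats::setNames(len, df$scaffold[1] %||% "sc1"), ...)
}
`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

random_site_table <- function(n, haploid = FALSE, strict_p4 = TRUE) {
  draw <- function() if (haploid) sample(0:1, n, TRUE) else stats::runif(n)
  data.frame(scaffold = "sc1", pos = sort(sample.int(10 * n, n)),
             p1 = draw(), p2 = draw(), p3 = draw(),
             p4 = if (strict_p4) rep(0, n) else draw() / 4)
}

naive_d <- function(df) {
  abba <- 0; baba <- 0
  for (i in seq_len(nrow(df))) {
    abba <- abba + (1 - df$p1[i]) * df$p2[i] * df$p3[i] * (1 - df$p4[i])
    baba <- baba + df$p1[i] * (1 - df$p2[i]) * df$p3[i] * (1 - df$p4[i])
  }
  if (abba + baba > 0) (abba - baba) / (abba + baba) else NA_real_
}

naive_fd <- function(df) {
  num <- 0; den <- 0
  for (i in seq_len(nrow(df))) {
    num <- num + (1 - df$p1[i]) * df$p2[i] * df$p3[i] * (1 - df$p4[i]) -
      df$p1[i] * (1 - df$p2[i]) * df$p3[i] * (1 - df$p4[i])
    pd <- max(df$p2[i], df$p3[i])
    den <- den + (1 - df$p1[i]) * pd * pd * (1 - df$p4[i]) -
      df$p1[i] * (1 - pd) * pd * (1 - df$p4[i])
  }
  if (num > 0 && den > 0) num / den else NA_real_
}

naive_dxy <- function(px, py, n) {
  s <- 0
  for (i in seq_along(px))
    s <- s + px[i] * (1 - py[i]) + py[i] * (1 - px[i])
  s / n
}

# All-pairs interval intersection (0-based half-open) for the annotation
# oracle: returns sorted unique (gene_id, region index) pairs.
brute_overlap_pairs <- function(genes, regions) {
  out <- character(0)
  for (i in seq_len(nrow(genes))) for (j in seq_len(nrow(regions))) {
    if (genes$scaffold[i] == regions$scaffold[j] &&
        genes$start[i] < regions$end[j] && regions$start[j] < genes$end[i])
      out <- c(out, paste(genes$gene_id[i], j))
  }
  sort(out)
}

# Small fast simulation configs for unit tests.
small_null_config <- function(seed, L = 1e5)
  sim_config(genome_length = L, tracts = NULL, seed = seed)

write_lines_tmp <- function(lines, ext = ".txt") {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# Minimal hand-written VCF for reader tests.
mini_vcf <- function(records, samples = c("P1", "P2", "P3", "O"),
                     contigs = c(sc1 = 10000)) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records)
}
vcf_rec <- function(chrom, pos, ref, alt, gts)
  paste(c(chrom, pos, ".", ref, alt, ".", ".", ".", "GT", gts),
        collapse = "\t")
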