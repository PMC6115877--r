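# Deterministic numeric formatting for text outputs: fixed significant
# digits, never scientific for integers, "NA" for missing.
fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), "NA", formatC(x, digits = digits, format = "g"))
}

#' Write per-window scan statistics as TSV
#'
#' One row per window: `scaffold start end n_sites abba baba D se z p fd dxy
#' stage_flags` (0-based half-open coordinates; `stage_flags` is a
#' three-character string such as `TTF` for the three cascade stages, with
#' `P` appended for partial terminal windows). Output is byte-deterministic
#' for identical scans.
#'
#' @param scan An `introgression_scan` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_window_tsv <- function(scan, path) {
  stopifnot(inherits(scan, "introgression_scan"))
  w <- scan$windows
  flags <- paste0(ifelse(w$stage1, "T", "F"), ifelse(w$stage2, "T", "F"),
                  ifelse(w$stage3, "T", "F"), ifelse(w$partial, "P", ""))
  lines <- c(paste(c("scaffold", "start", "end", "n_sites", "abba", "baba",
                     "D", "se", "z", "p", "fd", "dxy", "stage_flags"),
                   collapse = "\t"),
             paste(w$scaffold, w$start, w$end, w$n_sites,
                   fmt_num(w$abba), fmt_num(w$baba), fmt_num(w$d),
                   fmt_num(w$se), fmt_num(w$z), fmt_num(w$p),
                   fmt_num(w$fd), fmt_num(w$dxy), flags, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write introgressed regions as BED6
#'
#' Stage-3 surviving windows, 0-based half-open, with `score = |D|` scaled
#' to 0-1000.
#'
#' @param scan An `introgression_scan` object (or its `regions`
#'   data.frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(scan, path) {
  r <- if (inherits(scan, "introgression_scan")) scan$regions else scan
  lines <- if (nrow(r)) {
    name <- sprintf("introgressed_%03d", seq_len(nrow(r)))
    score <- round(pmin(1, abs(r$d)) * 1000)
    paste(r$scaffold, r$start, r$end, name, score, ".", sep = "\t")
  } else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write BED6 intervals
#'
#' @param df data.frame with `scaffold`, `start`, `end` (0-based half-open)
#'   and optionally `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  name <- if ("name" %in% names(df)) df$name else
    sprintf("region_%03d", seq_len(nrow(df)))
  score <- if ("score" %in% names(df)) df$score else 0
  strand <- if ("strand" %in% names(df)) df$strand else "."
  lines <- if (nrow(df))
    paste(df$scaffold, df$start, df$end, name, score, strand, sep = "\t")
  else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED file of intervals
#'
#' Accepts BED3-BED6; returns 0-based half-open intervals, exactly as
#' written by [write_bed()] (truth tracts round-trip losslessly).
#'
#' @param path BED file (plain or gzip).
#' @return data.frame with `scaffold`, `start`, `end` and, when present,
#'   `name`, `score`, `strand`.
#' @export
read_bed <- function(path) {
  con <- gzfile(path, "rt"); on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (!length(lines))
    return(data.frame(scaffold = character(0), start = numeric(0),
                      end = numeric(0)))
  f <- strsplit(lines, "\t")
  nf <- min(lengths(f))
  if (nf < 3) stop("BED line with fewer than 3 fields")
  m <- do.call(rbind, lapply(f, `[`, seq_len(nf)))
  out <- data.frame(scaffold = m[, 1], start = as.numeric(m[, 2]),
                    end = as.numeric(m[, 3]))
  if (nf >= 4) out$name <- m[, 4]
  if (nf >= 5) out$score <- suppressWarnings(as.numeric(m[, 5]))
  if (nf >= 6) out$strand <- m[, 6]
  out
}

#' Write gene models as GFF3
#'
#' @param genes data.frame as from [simulate_gene_models()] or [load_gff()]
#'   (0-based half-open coordinates; written as GFF3 1-based closed).
#' @param path Output path.
#' @param source Value for the GFF source column.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path, source = "abbascan_sim") {
  lines <- c("##gff-version 3",
             if (nrow(genes))
               paste(genes$scaffold, source, "gene", genes$start + 1,
                     genes$end, ".", genes$strand, ".", genes$attributes,
                     sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write the gene report of [genes_in_regions()] as TSV
#'
#' @param report data.frame from [genes_in_regions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write the clade-level summary as TSV
#'
#' @param summary data.frame from [clade_summary()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clade_summary <- function(summary, path) {
  lines <- c(paste(names(summary), collapse = "\t"),
             paste(summary$quartet, summary$n_windows_tested,
                   summary$n_windows_significant,
                   fmt_num(summary$fraction), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

# Simulator file writers ------------------------------------------------

write_sim_outputs <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim$config
  files <- list()
  for (sc in names(cfg$scaffold_lengths)) {
    p <- file.path(out_dir, paste0(sc, ".fa"))
    ss <- Biostrings::DNAStringSet(sim$sequences[[sc]])
    Biostrings::writeXStringSet(ss, p, width = 80)
    files[[paste0("fasta_", sc)]] <- p
  }
  files$vcf <- write_sim_vcf(sim, file.path(out_dir, "quartet.vcf"))
  if (!is.null(sim$truth)) {
    tb <- sim$truth
    tb$score <- 0
    tb$strand <- "."
    files$truth_bed <- write_bed(tb, file.path(out_dir, "truth.bed"))
  }
  manifest <- list(
    tool = "abbascan", version = package_version_string(),
    config = list(scaffold_lengths = as.list(cfg$scaffold_lengths),
                  split_p1p2 = cfg$split_p1p2, split_p3 = cfg$split_p3,
                  split_outgroup = cfg$split_outgroup,
                  ils_block_length = cfg$ils_block_length,
                  ils_prob = cfg$ils_prob,
                  mutation_model = cfg$mutation_model, seed = cfg$seed,
                  labels = as.list(cfg$labels)),
    tracts = if (is.null(sim$truth)) list() else sim$truth,
    n_sites = nrow(sim$sites$sites),
    drop_counters = as.list(sim$sites$drops),
    outputs = lapply(files, basename))
  mf <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  files$manifest <- mf
  files
}

# Minimal haploid VCF 4.2 writer for simulator output: every polymorphic
# column (including >2-allele sites, emitted as multiallelic records so
# readers exercise their drop logic), REF = outgroup allele.
write_sim_vcf <- function(sim, path) {
  cfg <- sim$config
  header <- c("##fileformat=VCFv4.2",
              "##source=abbascan simulate_quartet",
              sprintf("##contig=<ID=%s,length=%d>",
                      names(cfg$scaffold_lengths),
                      as.integer(cfg$scaffold_lengths)),
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", cfg$labels), collapse = "\t"))
  recs <- character(0)
  for (sc in names(cfg$scaffold_lengths)) {
    chars <- lapply(sim$sequences[[sc]], function(s) strsplit(s, "")[[1]])
    m <- do.call(cbind, chars)          # L x 4, order P1 P2 P3 O
    var <- which(!(m[, 1] == m[, 2] & m[, 1] == m[, 3] & m[, 1] == m[, 4]))
    if (!length(var)) next
    rows <- vapply(var, function(i) {
      ref <- m[i, 4]
      alts <- sort(setdiff(unique(m[i, 1:3]), ref))
      gt <- match(m[i, ], c(ref, alts)) - 1L
      paste(sc, i, ".", ref, paste(alts, collapse = ","), ".", ".", ".",
            "GT", gt[1], gt[2], gt[3], gt[4], sep = "\t")
    }, "")
    recs <- c(recs, rows)
  }
  writeLines(c(header, recs), path)
  invisible(path)
}

package_version_string <- function() {
  as.character(utils::packageVersion("abbascan"))
}
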