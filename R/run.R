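#' Run the simulator and write its outputs
#'
#' Thin orchestration wrapper used by the `simulate` subcommand: simulates
#' per [simulate_quartet()] and writes FASTA/VCF/truth BED plus a JSON run
#' manifest to `out_dir`.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Output directory.
#' @return The `quartet_sim` object, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  sim <- simulate_quartet(config, out_dir = out_dir)
  invisible(sim)
}

guess_input_format <- function(path) {
  p <- sub("\\.gz$", "", path)
  if (grepl("\\.vcf$", p)) "vcf"
  else if (grepl("\\.(fa|fasta|fna)$", p)) "fasta"
  else if (grepl("\\.(tsv|snps|txt)$", p)) "snp_table"
  else stop("cannot guess input format of ", path,
            "; expected .vcf, .fa/.fasta or .tsv[.gz]")
}

#' Run the windowed scan cascade and write its outputs
#'
#' Reads four-taxon variant input (VCF, aligned FASTA or tabular SNP
#' format, auto-detected from the extension), runs [introgression_scan()]
#' at each requested window size, and writes per-window TSVs
#' (`windows_<size>.tsv`), introgressed-region BEDs (`regions_<size>.bed`)
#' and a JSON run manifest with input checksums, per-stage attrition counts
#' and drop-reason counters.
#'
#' @param input Input file path, or a ready `quartet_sites` object.
#' @param quartet A [quartet_config()] (required for file input).
#' @param out_dir Output directory.
#' @param window_sizes Numeric vector of window sizes in bp.
#' @param step Step in bp, or `NULL` for adjacent windows at every size.
#' @param criteria A [scan_criteria()] object.
#' @param dxy_taxa,n_blocks Passed to [introgression_scan()].
#' @param format Input format override (`"vcf"`, `"fasta"`, `"snp_table"`).
#' @return Named list of `introgression_scan` objects (one per window
#'   size), invisibly.
#' @export
run_scan <- function(input, quartet = NULL, out_dir,
                     window_sizes = 5000, step = NULL,
                     criteria = scan_criteria(), dxy_taxa = c("p2", "p3"),
                     n_blocks = 20, format = NULL) {
  if (inherits(input, "quartet_sites")) {
    sites <- input
    input_path <- NULL
  } else {
    stopifnot(is.character(input), file.exists(input))
    if (is.null(quartet))
      stop("file input requires a quartet_config")
    format <- format %||% guess_input_format(input)
    sites <- switch(format,
                    vcf = read_quartet_vcf(input, quartet),
                    fasta = read_aligned_fasta(input, quartet),
                    snp_table = read_snp_table(input, quartet),
                    stop("unknown input format: ", format))
    input_path <- input
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  scans <- list()
  outputs <- list()
  attrition <- list()
  for (size in window_sizes) {
    scan <- introgression_scan(sites, window_size = size,
                               step = if (is.null(step)) size else step,
                               criteria = criteria, dxy_taxa = dxy_taxa,
                               n_blocks = n_blocks)
    key <- format(size, scientific = FALSE)
    scans[[key]] <- scan
    tsv <- file.path(out_dir, sprintf("windows_%s.tsv", key))
    bed <- file.path(out_dir, sprintf("regions_%s.bed", key))
    write_window_tsv(scan, tsv)
    write_regions_bed(scan, bed)
    outputs[[paste0("windows_", key)]] <- basename(tsv)
    outputs[[paste0("regions_", key)]] <- basename(bed)
    attrition[[key]] <- as.list(scan$attrition)
  }
  manifest <- list(
    tool = "abbascan", version = package_version_string(),
    config = list(window_sizes = window_sizes,
                  step = step %||% "adjacent",
                  quartet = if (is.null(quartet)) NULL else
                    as.list(quartet$labels),
                  criteria = unclass(criteria),
                  dxy_taxa = dxy_taxa, n_blocks = n_blocks,
                  dxy_mode = scans[[1]]$dxy_mode),
    input = if (is.null(input_path)) "in-memory site table" else
      list(path = input_path,
           md5 = unname(tools::md5sum(input_path))),
    attrition = attrition,
    drop_counters = as.list(sites$drops),
    outputs = outputs)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(scans)
}

#' Annotate introgressed regions against GFF3 gene models
#'
#' Orchestration wrapper for the `annotate` subcommand: reads a BED of
#' introgressed regions and a GFF3 of gene models, reports every gene
#' overlapping a region ([genes_in_regions()]) and writes the report TSV.
#'
#' @param bed Regions BED path (or a regions data.frame /
#'   `introgression_scan`).
#' @param gff GFF3 path (or a gene-model data.frame).
#' @param out Output TSV path.
#' @param feature_type GFF3 feature type to use.
#' @param mode Overlap mode, see [genes_in_regions()].
#' @return The report data.frame, invisibly.
#' @export
run_annotate <- function(bed, gff, out, feature_type = "gene",
                         mode = "overlap") {
  regions <- if (is.character(bed)) read_bed(bed) else bed
  genes <- if (is.character(gff)) load_gff(gff, feature_type) else gff
  report <- genes_in_regions(genes, regions, mode = mode)
  write_gene_report(report, out)
  invisible(report)
}

#' Summarize D-significant window fractions across quartet scans
#'
#' Orchestration wrapper for the `summarize` subcommand: accepts scan
#' outputs — `introgression_scan` objects or per-window TSV paths written
#' by [run_scan()] — and writes the clade-level summary table of
#' [clade_summary()].
#'
#' @param scans Named list of `introgression_scan` objects, or a named
#'   character vector of `windows_*.tsv` paths.
#' @param out Output TSV path.
#' @return The summary data.frame, invisibly.
#' @export
run_summarize <- function(scans, out) {
  if (is.character(scans)) {
    nm <- names(scans) %||% basename(scans)
    rows <- lapply(seq_along(scans), function(i) {
      w <- utils::read.delim(scans[[i]])
      sig <- startsWith(w$stage_flags, "T")
      data.frame(quartet = nm[i], n_windows_tested = nrow(w),
                 n_windows_significant = sum(sig),
                 fraction = if (nrow(w)) sum(sig) / nrow(w) else 0)
    })
    summary <- do.call(rbind, rows)
  } else {
    summary <- clade_summary(scans)
  }
  write_clade_summary(summary, out)
  invisible(summary)
}
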