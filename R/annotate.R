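#' Load gene models from a GFF3 file
#'
#' Imports features of the requested type (default `gene`), converting
#' coordinates from GFF3 1-based closed to the package's 0-based half-open
#' convention and sorting genes per scaffold.
#'
#' @param path GFF3 file (plain or gzip).
#' @param feature_type Feature type to extract (e.g. `"gene"`, `"mRNA"`).
#' @return data.frame with columns `gene_id`, `scaffold`, `start`, `end`
#'   (0-based half-open), `strand`, `attributes` (the raw `key=value`
#'   attribute text). Zero matching features raises a warning.
#' @export
load_gff <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  if (!length(gr)) {
    warning("no '", feature_type, "' features found in ", path)
    return(data.frame(gene_id = character(0), scaffold = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), attributes = character(0)))
  }
  id <- gr$ID
  if (is.null(id)) id <- sprintf("%s_%06d", feature_type, seq_along(gr))
  id[is.na(id)] <- sprintf("%s_%06d", feature_type, which(is.na(id)))
  meta <- S4Vectors::mcols(gr)
  attr_cols <- setdiff(colnames(meta), c("source", "type", "score", "phase"))
  attributes <- vapply(seq_along(gr), function(i) {
    kv <- vapply(attr_cols, function(k) {
      v <- meta[[k]][[i]]
      if (is.null(v) || all(is.na(v))) ""
      else paste0(k, "=", paste(unlist(v), collapse = ","))
    }, "")
    paste(kv[nzchar(kv)], collapse = ";")
  }, "")
  out <- data.frame(gene_id = id,
                    scaffold = as.character(GenomicRanges::seqnames(gr)),
                    start = GenomicRanges::start(gr) - 1,
                    end = as.numeric(GenomicRanges::end(gr)),
                    strand = as.character(GenomicRanges::strand(gr)),
                    attributes = attributes)
  out <- out[order(out$scaffold, out$start), ]
  rownames(out) <- NULL
  if (any(out$start >= out$end)) stop("gene with non-positive width in GFF")
  out
}

#' Report genes overlapping introgressed regions
#'
#' A gene is reported iff it overlaps at least one bp of at least one region
#' (half-open interval intersection: abutting intervals do not overlap);
#' with `mode = "contained"` the stricter rule is applied that the gene must
#' lie entirely inside a region. One row per (gene, region) pair.
#'
#' @param genes Gene models from [load_gff()] (or any data.frame with
#'   `gene_id`, `scaffold`, `start`, `end`, 0-based half-open).
#' @param regions Introgressed regions: the `regions` element of an
#'   [introgression_scan()], an `introgression_scan` object itself, or any
#'   data.frame with `scaffold`, `start`, `end`.
#' @param mode `"overlap"` (>= 1 bp, default) or `"contained"`.
#' @return data.frame with one row per (gene, region) pair: `gene_id`,
#'   `scaffold`, gene and region coordinates, `overlap_bp`, `strand` and
#'   `attributes` (carried through from the GFF so external functional
#'   annotations can be joined downstream).
#' @export
genes_in_regions <- function(genes, regions, mode = c("overlap", "contained")) {
  mode <- match.arg(mode)
  if (inherits(regions, "introgression_scan")) regions <- regions$regions
  empty <- data.frame(gene_id = character(0), scaffold = character(0),
                      gene_start = numeric(0), gene_end = numeric(0),
                      region_start = numeric(0), region_end = numeric(0),
                      overlap_bp = numeric(0), strand = character(0),
                      attributes = character(0))
  if (!nrow(genes) || !nrow(regions)) return(empty)
  gr_gene <- GenomicRanges::GRanges(
    genes$scaffold, IRanges::IRanges(genes$start + 1, genes$end))
  gr_reg <- GenomicRanges::GRanges(
    regions$scaffold, IRanges::IRanges(regions$start + 1, regions$end))
  hits <- GenomicRanges::findOverlaps(
    gr_gene, gr_reg,
    type = if (mode == "contained") "within" else "any")
  if (!length(hits)) return(empty)
  gi <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  ov <- pmin(genes$end[gi], regions$end[ri]) -
    pmax(genes$start[gi], regions$start[ri])
  out <- data.frame(gene_id = genes$gene_id[gi],
                    scaffold = genes$scaffold[gi],
                    gene_start = genes$start[gi], gene_end = genes$end[gi],
                    region_start = regions$start[ri],
                    region_end = regions$end[ri],
                    overlap_bp = ov,
                    strand = if ("strand" %in% names(genes))
                      genes$strand[gi] else ".",
                    attributes = if ("attributes" %in% names(genes))
                      genes$attributes[gi] else "")
  out <- unique(out)
  out <- out[order(out$scaffold, out$gene_start, out$region_start), ]
  rownames(out) <- NULL
  out
}
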