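#' Read four-taxon variant data from a VCF
#'
#' Consumes a (possibly gzipped) VCF 4.x holding the four quartet samples
#' and builds the polarized per-scaffold site table. Only biallelic SNP
#' records are used; multiallelic, indel and missing-genotype records are
#' dropped and counted, never imputed. Haploid genotypes contribute allele
#' identity (frequency 0/1); diploid genotypes contribute allele dosage / 2.
#'
#' Polarization follows the strict outgroup rule: the outgroup allele is
#' ancestral, the derived frequency of each taxon is its frequency of the
#' non-outgroup allele, and `p4 = 0` at every retained site. Records where
#' the outgroup is polymorphic (heterozygous) are dropped under the strict
#' rule; `strict_outgroup = FALSE` retains them, taking the outgroup's major
#' allele as ancestral with fractional `p4`.
#'
#' @param path VCF file (plain or gzip).
#' @param quartet A [quartet_config()]; `sample_map` values must match VCF
#'   sample names.
#' @param strict_outgroup Apply the strict polarization rule (default TRUE).
#' @return A `quartet_sites` object (empty, with a warning, when the VCF has
#'   no usable variant records).
#' @export
read_quartet_vcf <- function(path, quartet, strict_outgroup = TRUE) {
  stopifnot(inherits(quartet, "quartet_config"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  samples <- colnames(vcf@gt)[-1]
  missing <- setdiff(quartet$sample_map, samples)
  if (length(missing))
    stop("VCF is missing quartet sample(s): ", paste(missing, collapse = ", "))

  scaffold_lengths <- contig_lengths_from_meta(vcf@meta)
  fix <- vcf@fix
  if (nrow(fix) == 0) {
    warning("VCF contains no variant records")
    return(quartet_sites(
      data.frame(scaffold = character(0), pos = integer(0), p1 = numeric(0),
                 p2 = numeric(0), p3 = numeric(0), p4 = numeric(0)),
      scaffold_lengths %||% c(unknown = 1), source = "vcf"))
  }
  pos <- as.integer(fix[, "POS"])
  chrom <- fix[, "CHROM"]
  for (sc in unique(chrom))
    if (is.unsorted(pos[chrom == sc]))
      stop("VCF is not coordinate-sorted (scaffold ", sc, ")")

  drops <- empty_drops()
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  snp <- nchar(ref) == 1L & nchar(alt) == 1L & !is.na(alt)
  drops["multiallelic"] <- sum(multi)
  drops["non_snp"] <- sum(!multi & !snp)
  keep <- !multi & snp

  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[, quartet$sample_map, drop = FALSE]
  freq <- gt_to_alt_freq(gt)        # records x 4, NA for missing calls

  miss <- rowSums(is.na(freq)) > 0
  drops["missing"] <- sum(keep & miss)
  keep <- keep & !miss

  p_o <- freq[, 4]
  if (strict_outgroup) {
    poly_o <- p_o > 0 & p_o < 1
    drops["outgroup_polymorphic"] <- sum(keep & poly_o)
    keep <- keep & !poly_o
    anc_is_ref <- p_o == 0
  } else {
    anc_is_ref <- p_o <= 0.5
  }
  der <- freq
  flip <- which(!anc_is_ref)
  der[flip, ] <- 1 - freq[flip, , drop = FALSE]

  mono <- der[, 1] == 0 & der[, 2] == 0 & der[, 3] == 0 & der[, 4] == 0
  drops["monomorphic"] <- sum(keep & mono)
  keep <- keep & !mono

  kept <- which(keep)
  sites <- data.frame(scaffold = chrom[kept], pos = pos[kept],
                      p1 = der[kept, 1], p2 = der[kept, 2],
                      p3 = der[kept, 3], p4 = der[kept, 4])
  sites <- sites[order(match(sites$scaffold, unique(chrom)), sites$pos), ]
  rownames(sites) <- NULL
  if (is.null(scaffold_lengths)) {
    scaffold_lengths <- tapply(pos, chrom, max)
    scaffold_lengths <- stats::setNames(as.numeric(scaffold_lengths),
                                        names(scaffold_lengths))
  }
  quartet_sites(sites, scaffold_lengths, drops = drops, source = "vcf")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

contig_lengths_from_meta <- function(meta) {
  m <- grep("^##contig=", meta, value = TRUE)
  if (!length(m)) return(NULL)
  ids <- sub('.*ID=([^,>]+).*', "\\1", m)
  lens <- suppressWarnings(as.numeric(sub('.*length=([0-9]+).*', "\\1", m)))
  if (anyNA(lens)) return(NULL)
  stats::setNames(lens, ids)
}

# ALT-allele frequency per genotype string: haploid "0"/"1", or "/"|"|"
# separated dosage; NA for "." or malformed calls.
gt_to_alt_freq <- function(gt) {
  u <- unique(as.vector(gt))
  lut <- vapply(u, function(g) {
    if (is.na(g) || g == ".") return(NA_real_)
    a <- strsplit(g, "[/|]")[[1]]
    if (any(a == ".") || !all(grepl("^[0-9]+$", a))) return(NA_real_)
    mean(as.numeric(a) > 0)
  }, 0)
  matrix(lut[match(as.vector(gt), u)], nrow = nrow(gt))
}

#' Read a four-taxon aligned FASTA into a polarized site table
#'
#' Alternative entry point replacing an external whole-genome-alignment SNP
#' call: a per-scaffold alignment of exactly four equal-length records, one
#' per quartet taxon. Columns with a gap or ambiguity code in any taxon are
#' skipped (and counted), as are monomorphic and >2-allele columns;
#' remaining biallelic columns are polarized with the outgroup allele as
#' ancestral. Coordinates are reported in ungapped outgroup-sequence space,
#' anchoring all windows to one reference frame. The positions at which all
#' four taxa were cleanly aligned (variant or not) are retained as the
#' table's `callable` set, which the scan then uses as the d_xy divisor.
#'
#' @param path Aligned FASTA (plain or gzip), four records of equal length.
#' @param quartet A [quartet_config()]; `sample_map` values must match
#'   record ids (first word of each header).
#' @param scaffold Scaffold name for the table (default: file name without
#'   extension).
#' @return A `quartet_sites` object for one scaffold.
#' @export
read_aligned_fasta <- function(path, quartet, scaffold = NULL) {
  stopifnot(inherits(quartet, "quartet_config"))
  aln <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(aln))
  if (length(aln) != 4L)
    stop("alignment must contain exactly four records, got ", length(aln))
  if (length(unique(Biostrings::width(aln))) != 1L)
    stop("aligned records must have equal length")
  missing <- setdiff(quartet$sample_map, ids)
  if (length(missing))
    stop("alignment is missing quartet record(s): ",
         paste(missing, collapse = ", "))
  if (is.null(scaffold))
    scaffold <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))

  mat <- do.call(cbind, lapply(quartet$sample_map, function(id)
    strsplit(toupper(as.character(aln[[match(id, ids)]])), "")[[1]]))
  o_notgap <- mat[, 4] != "-"
  opos <- cumsum(o_notgap)                     # ungapped outgroup coordinate
  clean <- matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))
  callable <- rowSums(clean) == 4L
  drops <- empty_drops()
  drops["gap_or_ambiguous"] <- sum(!callable)

  cand <- which(callable)
  pol <- polarize_allele_matrix(mat[cand, , drop = FALSE])
  drops <- drops + count_drops(pol$reason)
  kept <- cand[pol$keep]
  sites <- data.frame(scaffold = rep(scaffold, length(kept)), pos = opos[kept],
                      p1 = pol$freqs[, 1], p2 = pol$freqs[, 2],
                      p3 = pol$freqs[, 3], p4 = pol$freqs[, 4])
  lens <- stats::setNames(sum(o_notgap), scaffold)
  callable_pos <- list(opos[callable & o_notgap])
  names(callable_pos) <- scaffold
  quartet_sites(sites, lens, drops = drops, callable = callable_pos,
                source = "aligned_fasta")
}

#' Read a tabular four-taxon SNP file
#'
#' A simple whitespace/tab-delimited dialect in the style of MUMmer
#' `show-snps` output reshaped to one row per quartet site: a header line
#' `scaffold pos <P1> <P2> <P3> <O>` (sample names per the quartet's
#' `sample_map`) followed by one single-base allele call per taxon per row.
#' The polarization contract is the same as [read_quartet_vcf()]'s strict
#' rule.
#'
#' @param path SNP table (plain or gzip).
#' @param quartet A [quartet_config()].
#' @param scaffold_lengths Optional named scaffold lengths; defaults to the
#'   maximum observed position per scaffold.
#' @return A `quartet_sites` object (empty with a warning for a header-only
#'   file).
#' @seealso [write_snp_table()] for the exact-round-trip writer.
#' @export
read_snp_table <- function(path, quartet, scaffold_lengths = NULL) {
  stopifnot(inherits(quartet, "quartet_config"))
  con <- gzfile(path, "rt"); on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("SNP table is empty (no header)")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(header) < 6 || header[1] != "scaffold" || header[2] != "pos")
    stop("SNP table header must be: scaffold pos <P1> <P2> <P3> <O>")
  col <- match(quartet$sample_map, header)
  if (anyNA(col))
    stop("SNP table header is missing sample(s): ",
         paste(quartet$sample_map[is.na(col)], collapse = ", "))

  body <- lines[-1]
  if (!length(body)) {
    warning("SNP table contains no data rows")
    return(quartet_sites(
      data.frame(scaffold = character(0), pos = integer(0), p1 = numeric(0),
                 p2 = numeric(0), p3 = numeric(0), p4 = numeric(0)),
      scaffold_lengths %||% c(unknown = 1), source = "snp_table"))
  }
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  bad <- which(nf != length(header))
  if (length(bad))
    stop("malformed SNP table row at line ", bad[1] + 1L,
         ": expected ", length(header), " fields, got ", nf[bad[1]])
  m <- do.call(rbind, fields)
  pos <- suppressWarnings(as.integer(m[, 2]))
  if (anyNA(pos))
    stop("malformed SNP table row at line ", which(is.na(pos))[1] + 1L,
         ": non-integer position")
  scf <- m[, 1]
  alle <- m[, col, drop = FALSE]

  pol <- polarize_allele_matrix(alle)
  drops <- count_drops(pol$reason)
  sites <- data.frame(scaffold = scf[pol$keep], pos = pos[pol$keep],
                      p1 = pol$freqs[, 1], p2 = pol$freqs[, 2],
                      p3 = pol$freqs[, 3], p4 = pol$freqs[, 4])
  sites <- sites[order(match(sites$scaffold, unique(scf)), sites$pos), ]
  rownames(sites) <- NULL
  if (is.null(scaffold_lengths)) {
    scaffold_lengths <- tapply(pos, scf, max)
    scaffold_lengths <- stats::setNames(as.numeric(scaffold_lengths),
                                        names(scaffold_lengths))
  }
  quartet_sites(sites, scaffold_lengths, drops = drops, source = "snp_table")
}

#' Write a haploid polarized site table to the tabular SNP dialect
#'
#' Inverse of [read_snp_table()] for haploid (0/1 frequency) tables: each
#' site is written as ancestral allele `A` / derived allele `G`, a lossless
#' encoding of the polarized frequencies, so write-then-read reproduces the
#' table exactly.
#'
#' @param sites A `quartet_sites` object with all frequencies in \{0, 1\}.
#' @param path Output path (plain text; `.gz` for gzip).
#' @param sample_names Column names for the four taxa (default P1 P2 P3 O).
#' @return `path`, invisibly.
#' @export
write_snp_table <- function(sites, path,
                            sample_names = c("P1", "P2", "P3", "O")) {
  stopifnot(inherits(sites, "quartet_sites"))
  s <- sites$sites
  fr <- as.matrix(s[, c("p1", "p2", "p3", "p4")])
  if (nrow(s) && !all(fr %in% c(0, 1)))
    stop("the tabular dialect encodes haploid tables only (frequencies 0/1)")
  alle <- matrix("A", nrow(s), 4)
  alle[fr == 1] <- "G"
  lines <- c(paste(c("scaffold", "pos", sample_names), collapse = "\t"),
             if (nrow(s)) paste(s$scaffold, s$pos, alle[, 1], alle[, 2],
                                alle[, 3], alle[, 4], sep = "\t"))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}
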