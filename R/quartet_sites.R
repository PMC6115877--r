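#' Define the four-taxon quartet of an ABBA-BABA comparison
#'
#' A quartet names the three ingroup taxa and the outgroup of the site-pattern
#' tests: `P1` and `P2` are the sister pair, `P3` the candidate donor/recipient
#' of gene flow with `P2`, and the outgroup `O` supplies the ancestral allele
#' at each site (polarization).
#'
#' @param p1,p2,p3,outgroup Taxon labels (character scalars, all distinct).
#' @param sample_map Optional named character vector mapping each taxon label
#'   to the sample/record identifier used in the input file (VCF sample name,
#'   FASTA record id, SNP-table column). Defaults to the labels themselves.
#' @return An object of class `quartet_config`.
#' @examples
#' quartet_config("E_gansuensis", "E_festucae", "E_aotearoae", "C_purpurea")
#' @export
quartet_config <- function(p1, p2, p3, outgroup, sample_map = NULL) {
  labels <- c(P1 = p1, P2 = p2, P3 = p3, O = outgroup)
  if (!is.character(labels) || length(labels) != 4L || anyNA(labels))
    stop("quartet labels must be four character scalars")
  if (anyDuplicated(labels))
    stop("quartet labels must be distinct: ", paste(labels, collapse = ", "))
  if (is.null(sample_map)) {
    sample_map <- labels
    names(sample_map) <- labels
  }
  if (!all(labels %in% names(sample_map)))
    stop("sample_map must name every quartet label")
  sample_map <- sample_map[labels]
  if (anyDuplicated(sample_map))
    stop("each taxon must map to a distinct input sample")
  structure(list(labels = labels, sample_map = unname(sample_map)),
            class = "quartet_config")
}

#' @export
print.quartet_config <- function(x, ...) {
  cat("Four-taxon quartet (((P1,P2),P3),O):\n")
  for (i in seq_len(4L)) {
    cat(sprintf("  %-3s %s", names(x$labels)[i], x$labels[i]))
    if (x$labels[i] != x$sample_map[i])
      cat(" [sample: ", x$sample_map[i], "]", sep = "")
    cat("\n")
  }
  invisible(x)
}

DROP_REASONS <- c("monomorphic", "multiallelic", "outgroup_polymorphic",
                  "missing", "gap_or_ambiguous", "non_snp")

empty_drops <- function() {
  d <- integer(length(DROP_REASONS))
  names(d) <- DROP_REASONS
  d
}

#' Construct a polarized site table
#'
#' The central per-site container of the package: one row per retained
#' biallelic site, holding the derived-allele frequency of each quartet taxon
#' (`p1`..`p4`, outgroup last). Under strict outgroup polarization the
#' outgroup allele defines the ancestral state, so `p4 = 0` at every retained
#' site and, for single-genome (haploid) inputs, all frequencies are 0 or 1.
#'
#' @param sites data.frame with columns `scaffold`, `pos` (1-based), `p1`,
#'   `p2`, `p3`, `p4`; rows sorted by scaffold then position.
#' @param scaffold_lengths Named numeric vector of scaffold lengths in bp.
#'   Must cover every scaffold present in `sites`.
#' @param drops Named integer vector of per-reason dropped-site counters.
#' @param callable Optional named list (per scaffold) of sorted 1-based
#'   positions at which all four taxa were confidently aligned (used as the
#'   d_xy divisor when available, e.g. from aligned FASTA input).
#' @param source Character tag recording the reader that produced the table.
#' @return An object of class `quartet_sites`.
#' @seealso [read_quartet_vcf()], [read_aligned_fasta()], [read_snp_table()]
#' @export
quartet_sites <- function(sites, scaffold_lengths, drops = empty_drops(),
                          callable = NULL, source = "manual") {
  stopifnot(is.data.frame(sites))
  need <- c("scaffold", "pos", "p1", "p2", "p3", "p4")
  if (!all(need %in% names(sites)))
    stop("sites must have columns: ", paste(need, collapse = ", "))
  sites <- sites[, need]
  sites$scaffold <- as.character(sites$scaffold)
  if (is.null(names(scaffold_lengths)))
    stop("scaffold_lengths must be named")
  obj <- structure(list(sites = sites,
                        scaffold_lengths = scaffold_lengths,
                        drops = drops,
                        callable = callable,
                        source = source),
                   class = "quartet_sites")
  validate_quartet_sites(obj)
  obj
}

#' Check the invariants of a polarized site table
#'
#' Asserts frequencies in \[0,1\], strictly increasing positions per scaffold,
#' positions within scaffold bounds, and known scaffolds. Called by all
#' constructors; exported so property tests can scan arbitrary tables.
#'
#' @param x A `quartet_sites` object.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_quartet_sites <- function(x) {
  s <- x$sites
  fr <- as.matrix(s[, c("p1", "p2", "p3", "p4")])
  if (nrow(s)) {
    if (anyNA(fr) || any(fr < 0) || any(fr > 1))
      stop("derived-allele frequencies must lie in [0,1]")
    if (!all(s$scaffold %in% names(x$scaffold_lengths)))
      stop("sites reference scaffolds absent from scaffold_lengths")
    for (sc in unique(s$scaffold)) {
      pos <- s$pos[s$scaffold == sc]
      if (is.unsorted(pos, strictly = TRUE))
        stop("positions must be strictly increasing within scaffold ", sc)
      if (pos[length(pos)] > x$scaffold_lengths[[sc]])
        stop("position beyond scaffold length on ", sc)
      if (pos[1] < 1) stop("positions are 1-based; got pos < 1 on ", sc)
    }
  }
  invisible(x)
}

#' @export
print.quartet_sites <- function(x, ...) {
  cat(sprintf("Polarized quartet site table (%s): %d sites on %d scaffold(s), %s bp\n",
              x$source, nrow(x$sites), length(x$scaffold_lengths),
              format(sum(x$scaffold_lengths), big.mark = ",", scientific = FALSE)))
  dropped <- x$drops[x$drops > 0]
  if (length(dropped))
    cat("  dropped sites: ",
        paste(sprintf("%s=%d", names(dropped), dropped), collapse = ", "), "\n")
  if (!is.null(x$callable))
    cat("  callable positions tracked (aligned d_xy divisor available)\n")
  invisible(x)
}

#' @export
as.data.frame.quartet_sites <- function(x, ...) x$sites

# Polarize a character allele matrix (rows = sites, 4 columns = P1,P2,P3,O)
# under the strict outgroup rule. Returns frequency rows for retained sites
# and a drop-reason factor for the rest. Shared by the FASTA, SNP-table and
# simulator paths so all inputs obey one polarization contract.
polarize_allele_matrix <- function(mat) {
  stopifnot(ncol(mat) == 4L)
  mat <- toupper(mat)
  ok_base <- matrix(mat %in% c("A", "C", "G", "T"), nrow = nrow(mat))
  reason <- rep(NA_character_, nrow(mat))
  reason[!rowSums(ok_base) == 4L] <- "gap_or_ambiguous"

  same12 <- mat[, 1] == mat[, 2]
  same23 <- mat[, 2] == mat[, 3]
  same34 <- mat[, 3] == mat[, 4]
  mono <- same12 & same23 & same34
  reason[is.na(reason) & mono] <- "monomorphic"

  # allele count per row among the four calls
  nall <- integer(nrow(mat))
  idx <- which(is.na(reason))
  for (i in idx) nall[i] <- length(unique(mat[i, ]))
  reason[is.na(reason) & nall > 2L] <- "multiallelic"

  keep <- which(is.na(reason))
  p <- matrix(numeric(0), ncol = 4)
  if (length(keep)) {
    anc <- mat[keep, 4]
    p <- matrix(0, nrow = length(keep), ncol = 4)
    for (j in 1:3) p[, j] <- as.numeric(mat[keep, j] != anc)
    # p4 = 0 by construction: the outgroup allele is ancestral
  }
  list(keep = keep, freqs = p, reason = reason)
}

count_drops <- function(reason) {
  d <- empty_drops()
  tab <- table(reason[!is.na(reason)])
  d[names(tab)] <- as.integer(tab)
  d
}
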