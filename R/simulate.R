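BASES <- c("A", "C", "G", "T")

#' Configure the four-taxon genome simulator
#'
#' The simulator emulates the statistical structure the windowed ABBA-BABA
#' tests assume: four haploid single-genome taxa related by the species tree
#' (((P1,P2),P3),O), background topology discordance mimicking incomplete
#' lineage sorting (ILS), and localized donor-to-recipient introgression
#' tracts. Sequences evolve under JC69 along a clock-like tree; ILS is
#' emulated by block-wise genealogy resampling — each block of
#' `ils_block_length` bp is concordant with probability `1 - ils_prob`, and
#' otherwise takes one of the two discordant topologies (P2,P3) or (P1,P3)
#' with equal probability, so ABBA and BABA are exactly equally frequent in
#' expectation outside tracts. Introgression is modelled as tract
#' replacement: within each tract the recipient's sequence is re-derived
#' from the donor's final sequence with `residual_divergence`
#' substitutions/site, which simultaneously creates the ABBA excess and the
#' reduced donor-recipient d_xy the filter cascade screens for.
#'
#' Defaults describe a desk-scale analogue of a fungal genome comparison:
#' one 1-Mb scaffold; split depths 0.01 (P1,P2), 0.05 (+P3) and 0.10 (+O)
#' substitutions/site — i.e. roughly 2%, 10% and 20% pairwise divergence;
#' discordance probability 0.2 drawn independently per site
#' (`ils_block_length = 1`); ten 5-kb tracts with residual divergence 0.01,
#' about a tenth of the ~0.1 background d_xy(P2,P3).
#'
#' The default per-site topology draw makes discordant sites statistically
#' independent, which is the null the windowed block-jackknife z-test
#' assumes; longer `ils_block_length` values introduce linkage between
#' discordant sites and are useful for studying how topology clustering
#' inflates window-level D variance, but the scan's per-window test is not
#' calibrated once the discordance correlation length approaches the
#' jackknife block span.
#'
#' @param genome_length Total genome length in bp (used when
#'   `scaffold_lengths` is NULL: a single scaffold `sc1`).
#' @param scaffold_lengths Named numeric vector of scaffold lengths.
#' @param split_p1p2,split_p3,split_outgroup Split depths in
#'   substitutions/site for the (P1,P2) split, the P3 split and the root
#'   (outgroup) respectively; must be non-decreasing.
#' @param ils_block_length Genealogy block length in bp.
#' @param ils_prob Probability a block's genealogy is discordant.
#' @param tracts Introgression tracts: a data.frame with columns `scaffold`,
#'   `start`, `end` (0-based half-open), `donor`, `recipient` (each "P2" or
#'   "P3") and `residual_divergence`; `"default"` for ten 5-kb P3-to-P2
#'   tracts every 100 kb; `NULL` for a pure null (no introgression) genome.
#' @param labels Taxon labels used as FASTA record ids / VCF sample names.
#' @param seed Integer RNG seed; mandatory, so every simulation is
#'   reproducible and byte-identical under a fixed configuration.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6, scaffold_lengths = NULL,
                       split_p1p2 = 0.01, split_p3 = 0.05,
                       split_outgroup = 0.10,
                       ils_block_length = 1, ils_prob = 0.2,
                       tracts = "default",
                       labels = c(P1 = "P1", P2 = "P2", P3 = "P3", O = "O"),
                       seed) {
  if (missing(seed) || is.null(seed))
    stop("sim_config requires an explicit integer seed")
  if (is.null(scaffold_lengths))
    scaffold_lengths <- c(sc1 = genome_length)
  stopifnot(all(scaffold_lengths >= 1),
            split_p1p2 >= 0, split_p3 >= split_p1p2,
            split_outgroup >= split_p3,
            ils_block_length >= 1, ils_prob >= 0, ils_prob <= 1)
  if (identical(tracts, "default"))
    tracts <- default_tracts(scaffold_lengths)
  if (!is.null(tracts)) {
    need <- c("scaffold", "start", "end", "donor", "recipient",
              "residual_divergence")
    stopifnot(is.data.frame(tracts), all(need %in% names(tracts)))
    stopifnot(all(tracts$donor %in% c("P2", "P3")),
              all(tracts$recipient %in% c("P2", "P3")),
              all(tracts$donor != tracts$recipient),
              all(tracts$residual_divergence >= 0),
              all(tracts$scaffold %in% names(scaffold_lengths)),
              all(tracts$start >= 0), all(tracts$start < tracts$end),
              all(tracts$end <= scaffold_lengths[tracts$scaffold]))
    for (sc in unique(tracts$scaffold)) {
      t <- tracts[tracts$scaffold == sc, ]
      t <- t[order(t$start), ]
      if (nrow(t) > 1 && any(t$start[-1] < t$end[-nrow(t)]))
        stop("tracts overlap on scaffold ", sc)
    }
  }
  structure(list(scaffold_lengths = scaffold_lengths,
                 split_p1p2 = split_p1p2, split_p3 = split_p3,
                 split_outgroup = split_outgroup,
                 ils_block_length = ils_block_length, ils_prob = ils_prob,
                 tracts = tracts, labels = labels,
                 mutation_model = "JC69",
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Default planted-tract layout for the simulator
#'
#' Ten 5-kb donor(P3)-to-recipient(P2) tracts at 100-kb intervals starting
#' at 50 kb (window-aligned at the 5-kb scan scale), residual divergence
#' 0.01 substitutions/site, truncated to what fits the first scaffold.
#'
#' @param scaffold_lengths Named scaffold lengths.
#' @param n Maximum number of tracts.
#' @param width Tract width in bp.
#' @param residual_divergence Donor-recipient residual divergence.
#' @return A tract data.frame as accepted by [sim_config()], or `NULL` when
#'   none fit.
#' @export
default_tracts <- function(scaffold_lengths, n = 10, width = 5000,
                           residual_divergence = 0.01) {
  sc <- names(scaffold_lengths)[1]
  len <- scaffold_lengths[[1]]
  starts <- seq(50000, by = 100000, length.out = n)
  starts <- starts[starts + width <= len]
  if (!length(starts)) return(NULL)
  data.frame(scaffold = sc, start = starts, end = starts + width,
             donor = "P3", recipient = "P2",
             residual_divergence = residual_divergence)
}

# JC69 endpoint evolution of an integer-coded (1..4) sequence over branch
# length d (substitutions/site): substitution prob 3/4(1-exp(-4d/3)), new
# base uniform over the other three.
jc69_evolve <- function(x, d) {
  if (d <= 0) return(x)
  q <- 0.75 * (1 - exp(-4 * d / 3))
  m <- stats::runif(length(x)) < q
  k <- sum(m)
  if (k) x[m] <- ((x[m] - 1L + sample.int(3L, k, replace = TRUE)) %% 4L) + 1L
  x
}

#' Simulate a four-taxon genome with planted introgression tracts
#'
#' Runs the generative model described in [sim_config()] and returns, in one
#' consistent object: the aligned sequences, the polarized site table (built
#' with the same strict outgroup polarization the file readers use), the
#' truth tract table with realized site counts, and the per-block genealogy.
#' When `out_dir` is given, writes one aligned FASTA per scaffold
#' (`<scaffold>.fa`), a combined haploid VCF (`quartet.vcf`), the truth
#' tracts as BED6 (`truth.bed`), and a JSON run manifest — all mutually
#' consistent (the VCF is derived from the same sequences as the FASTA), and
#' byte-identical across runs with the same config.
#'
#' @param config A [sim_config()] object.
#' @param out_dir Optional output directory (created if needed).
#' @return An object of class `quartet_sim`: list with `sites`
#'   (`quartet_sites`), `sequences` (per scaffold, named character vector of
#'   the four aligned sequences), `truth` (tract data.frame with realized
#'   `n_sites` per tract), `topology` (per scaffold, integer per block:
#'   1 = concordant, 2 = (P2,P3) discordant, 3 = (P1,P3) discordant),
#'   `config`, and `files` (paths, when written).
#' @export
simulate_quartet <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  t1 <- config$split_p1p2; t2 <- config$split_p3; T0 <- config$split_outgroup
  seqs <- list(); topo_blocks <- list()
  all_sites <- list(); drops <- empty_drops()

  for (sc in names(config$scaffold_lengths)) {
    L <- as.integer(config$scaffold_lengths[[sc]])
    nb <- ceiling(L / config$ils_block_length)
    topo <- sample.int(3L, nb, replace = TRUE,
                       prob = c(1 - config$ils_prob, config$ils_prob / 2,
                                config$ils_prob / 2))
    pos_topo <- rep(topo, each = config$ils_block_length)[seq_len(L)]

    z <- sample.int(4L, L, replace = TRUE)       # ancestral (root) sequence
    o <- jc69_evolve(z, T0)
    g <- jc69_evolve(z, T0 - t2)                 # ingroup ancestor
    k <- jc69_evolve(g, t2 - t1)                 # sister-pair ancestor
    lone <- jc69_evolve(g, t2)                   # odd taxon out
    tip_a <- jc69_evolve(k, t1)
    tip_b <- jc69_evolve(k, t1)

    p1 <- ifelse(pos_topo == 2L, lone, tip_a)
    p2 <- ifelse(pos_topo == 1L, tip_b, ifelse(pos_topo == 2L, tip_a, lone))
    p3 <- ifelse(pos_topo == 1L, lone, tip_b)

    tr <- config$tracts
    if (!is.null(tr)) {
      tr <- tr[tr$scaffold == sc, , drop = FALSE]
      for (j in seq_len(nrow(tr))) {
        idx <- (tr$start[j] + 1L):tr$end[j]
        donor <- if (tr$donor[j] == "P3") p3[idx] else p2[idx]
        repl <- jc69_evolve(donor, tr$residual_divergence[j])
        if (tr$recipient[j] == "P2") p2[idx] <- repl else p3[idx] <- repl
      }
    }

    seqs[[sc]] <- vapply(list(p1, p2, p3, o),
                         function(x) paste(BASES[x], collapse = ""), "")
    names(seqs[[sc]]) <- config$labels
    topo_blocks[[sc]] <- topo

    var <- which(!(p1 == p2 & p1 == p3 & p1 == o))
    if (length(var)) {
      mat <- cbind(BASES[p1[var]], BASES[p2[var]], BASES[p3[var]],
                   BASES[o[var]])
      pol <- polarize_allele_matrix(mat)
      drops <- drops + count_drops(pol$reason)
      if (length(pol$keep))
        all_sites[[sc]] <- data.frame(scaffold = sc, pos = var[pol$keep],
                                      p1 = pol$freqs[, 1], p2 = pol$freqs[, 2],
                                      p3 = pol$freqs[, 3], p4 = pol$freqs[, 4])
    }
  }

  sites_df <- if (length(all_sites)) do.call(rbind, all_sites) else
    data.frame(scaffold = character(0), pos = integer(0), p1 = numeric(0),
               p2 = numeric(0), p3 = numeric(0), p4 = numeric(0))
  rownames(sites_df) <- NULL
  sites <- quartet_sites(sites_df, config$scaffold_lengths, drops = drops,
                         source = "simulated")

  truth <- config$tracts
  if (!is.null(truth)) {
    truth$name <- sprintf("tract_%02d", seq_len(nrow(truth)))
    truth$n_sites <- vapply(seq_len(nrow(truth)), function(j) {
      sub <- sites_df[sites_df$scaffold == truth$scaffold[j], ]
      sum(sub$pos - 1 >= truth$start[j] & sub$pos - 1 < truth$end[j])
    }, 0L)
  }

  sim <- structure(list(sites = sites, sequences = seqs, truth = truth,
                        topology = topo_blocks, config = config,
                        files = NULL),
                   class = "quartet_sim")
  if (!is.null(out_dir)) sim$files <- write_sim_outputs(sim, out_dir)
  sim
}

#' @export
print.quartet_sim <- function(x, ...) {
  cat(sprintf("Simulated four-taxon genome: %s bp, %d scaffold(s), seed %d\n",
              format(sum(x$config$scaffold_lengths), big.mark = ","),
              length(x$config$scaffold_lengths), x$config$seed))
  cat(sprintf("  splits (subst/site): P1P2 %.3g, P3 %.3g, outgroup %.3g; ILS prob %.3g (%d-bp blocks)\n",
              x$config$split_p1p2, x$config$split_p3, x$config$split_outgroup,
              x$config$ils_prob, x$config$ils_block_length))
  if (is.null(x$truth)) cat("  no introgression tracts (null regime)\n")
  else cat(sprintf("  %d planted tract(s), %s bp total\n", nrow(x$truth),
                   format(sum(x$truth$end - x$truth$start), big.mark = ",")))
  print(x$sites)
  invisible(x)
}

#' Per-position regime labels of a simulated scaffold
#'
#' Expands a simulation's per-block genealogy and tract layout to a
#' per-position regime factor, used to validate observed site-pattern counts
#' against [expected_pattern_rates()].
#'
#' @param sim A `quartet_sim` object.
#' @param scaffold Scaffold name (default: first).
#' @return Factor of length `scaffold_length` with levels
#'   `concordant`, `discordant_p2p3`, `discordant_p1p3` and their
#'   `tract_`-prefixed counterparts.
#' @export
position_regimes <- function(sim, scaffold = names(sim$config$scaffold_lengths)[1]) {
  L <- as.integer(sim$config$scaffold_lengths[[scaffold]])
  topo <- rep(sim$topology[[scaffold]],
              each = sim$config$ils_block_length)[seq_len(L)]
  base <- c("concordant", "discordant_p2p3", "discordant_p1p3")[topo]
  tr <- sim$config$tracts
  if (!is.null(tr)) {
    tr <- tr[tr$scaffold == scaffold, , drop = FALSE]
    for (j in seq_len(nrow(tr))) {
      idx <- (tr$start[j] + 1L):tr$end[j]
      base[idx] <- paste0("tract_", base[idx])
    }
  }
  factor(base, levels = c("concordant", "discordant_p2p3", "discordant_p1p3",
                          "tract_concordant", "tract_discordant_p2p3",
                          "tract_discordant_p1p3"))
}

# JC69 transition matrix for branch length d.
jc69_P <- function(d) {
  same <- 0.25 + 0.75 * exp(-4 * d / 3)
  diff <- 0.25 - 0.25 * exp(-4 * d / 3)
  m <- matrix(diff, 4, 4)
  diag(m) <- same
  m
}

# Exact ABBA/BABA site-pattern probabilities for a rooted tree given as an
# edge list (child, parent, len). Leaves P1, P2, P3, O; root Z with uniform
# base prior. A node may be both a leaf and a parent (tract trees: the
# recipient hangs off the donor tip). Enumerates internal-node states.
pattern_rates_tree <- function(edges) {
  leaves <- c("P1", "P2", "P3", "O")
  parents <- unique(edges$parent)
  Pm <- lapply(seq_len(nrow(edges)), function(i) jc69_P(edges$len[i]))
  names(Pm) <- edges$child
  parent_of <- stats::setNames(edges$parent, edges$child)

  k <- length(parents)
  grid <- as.matrix(expand.grid(rep(list(1:4), k)))
  colnames(grid) <- parents
  e_abba <- 0; e_baba <- 0
  enumerated_edges <- which(edges$child %in% parents)
  for (r in seq_len(nrow(grid))) {
    st <- grid[r, ]
    w <- 0.25
    for (i in enumerated_edges)
      w <- w * Pm[[edges$child[i]]][st[[edges$parent[i]]], st[[edges$child[i]]]]
    if (w == 0) next
    ld <- lapply(leaves, function(lf) {
      if (lf %in% parents) {
        v <- numeric(4); v[st[[lf]]] <- 1; v
      } else Pm[[lf]][st[[parent_of[[lf]]]], ]
    })
    names(ld) <- leaves
    A <- ld$P1 * ld$O; B <- ld$P2 * ld$P3
    e_abba <- e_abba + w * (sum(A) * sum(B) - sum(A * B))
    A2 <- ld$P2 * ld$O; B2 <- ld$P1 * ld$P3
    e_baba <- e_baba + w * (sum(A2) * sum(B2) - sum(A2 * B2))
  }
  c(e_abba = e_abba, e_baba = e_baba)
}

regime_tree <- function(config, topology, tract = FALSE,
                        donor = "P3", recipient = "P2",
                        residual_divergence = 0) {
  t1 <- config$split_p1p2; t2 <- config$split_p3; T0 <- config$split_outgroup
  pair <- switch(topology,
                 concordant = c("P1", "P2"),
                 discordant_p2p3 = c("P2", "P3"),
                 discordant_p1p3 = c("P1", "P3"))
  lone <- setdiff(c("P1", "P2", "P3"), pair)
  edges <- data.frame(
    child = c("O", "G", "K", pair, lone),
    parent = c("Z", "Z", "G", "K", "K", "G"),
    len = c(T0, T0 - t2, t2 - t1, t1, t1, t2))
  if (tract) {
    edges <- edges[edges$child != recipient, ]
    edges <- rbind(edges, data.frame(child = recipient, parent = donor,
                                     len = residual_divergence))
  }
  edges
}

#' Exact expected ABBA/BABA site densities per simulation regime
#'
#' Closed-form per-site probabilities of the exact ABBA (P1=O, P2=P3,
#' derived shared by P2 and P3) and BABA site patterns under the
#' simulator's JC69 model, computed by enumerating internal-node states of
#' each regime's genealogy — no simulation involved, so this serves as an
#' independent oracle for the generator. Outside tracts the two discordant
#' topologies are equiprobable and the background mixture satisfies
#' `e_abba == e_baba` exactly; within tracts the donor-recipient replacement
#' creates an ABBA excess.
#'
#' @param config A [sim_config()] object.
#' @return data.frame with one row per regime (`concordant`,
#'   `discordant_p2p3`, `discordant_p1p3`, the `tract_`-prefixed
#'   counterparts when tracts are configured, and the `background` and
#'   `tract` ILS-weighted mixtures), with per-site `e_abba` and `e_baba`.
#' @export
expected_pattern_rates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  topos <- c("concordant", "discordant_p2p3", "discordant_p1p3")
  wts <- c(1 - config$ils_prob, config$ils_prob / 2, config$ils_prob / 2)
  rows <- lapply(topos, function(tp)
    pattern_rates_tree(regime_tree(config, tp)))
  out <- data.frame(regime = topos, do.call(rbind, rows))
  bg <- colSums(out[, c("e_abba", "e_baba")] * wts)
  out <- rbind(out, data.frame(regime = "background",
                               e_abba = bg[1], e_baba = bg[2]))
  tr <- config$tracts
  if (!is.null(tr) && nrow(tr)) {
    rd <- unique(tr[, c("donor", "recipient", "residual_divergence")])
    if (nrow(rd) > 1)
      warning("multiple tract parameterizations; using the first for tract rates")
    rows_t <- lapply(topos, function(tp)
      pattern_rates_tree(regime_tree(config, tp, tract = TRUE,
                                     donor = rd$donor[1],
                                     recipient = rd$recipient[1],
                                     residual_divergence = rd$residual_divergence[1])))
    out_t <- data.frame(regime = paste0("tract_", topos),
                        do.call(rbind, rows_t))
    mx <- colSums(out_t[, c("e_abba", "e_baba")] * wts)
    out <- rbind(out, out_t,
                 data.frame(regime = "tract", e_abba = mx[1], e_baba = mx[2]))
  }
  rownames(out) <- NULL
  out
}

#' Deterministic synthetic gene models for a simulated genome
#'
#' Tiles each scaffold with fixed-width gene models (synthetic — these are
#' layout fixtures for exercising the annotation step, not predicted genes),
#' alternating strand, with stable IDs, so that the genes overlapping planted
#' tracts are known exactly.
#'
#' @param config A [sim_config()] object.
#' @param gene_length Gene width in bp.
#' @param spacing Distance between successive gene starts in bp.
#' @return data.frame of gene models with 0-based half-open `start`, `end`.
#' @export
simulate_gene_models <- function(config, gene_length = 1000, spacing = 2500) {
  stopifnot(inherits(config, "sim_config"), gene_length >= 1,
            spacing >= gene_length)
  out <- lapply(names(config$scaffold_lengths), function(sc) {
    L <- config$scaffold_lengths[[sc]]
    starts <- seq(0, L - gene_length, by = spacing)
    k <- seq_along(starts)
    data.frame(gene_id = sprintf("gene_%s_%04d", sc, k),
               scaffold = sc, start = starts, end = starts + gene_length,
               strand = ifelse(k %% 2 == 1, "+", "-"),
               attributes = sprintf("ID=gene_%s_%04d;Name=synthetic_gene_%04d",
                                    sc, k, k))
  })
  do.call(rbind, out)
}
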