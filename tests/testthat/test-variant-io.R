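test_that("quartet_config enforces distinct labels and resolvable samples", {
  q <- quartet_config("a", "b", "c", "d",
                      sample_map = c(a = "s1", b = "s2", c = "s3", d = "s4"))
  expect_s3_class(q, "quartet_config")
  expect_identical(q$sample_map, c("s1", "s2", "s3", "s4"))
  expect_error(quartet_config("a", "a", "c", "d"), "distinct")
  expect_error(quartet_config("a", "b", "c", "d",
                              sample_map = c(a = "s", b = "s", c = "t", d = "u")),
               "distinct input sample")
  expect_error(quartet_config("a", "b", "c", "d", sample_map = c(a = "s1")),
               "sample_map")
})

test_that("site-table invariants are enforced by the constructor", {
  good <- data.frame(scaffold = "sc1", pos = c(5, 10), p1 = 0, p2 = 1,
                     p3 = 1, p4 = 0)
  expect_silent(quartet_sites(good, c(sc1 = 100)))
  bad_freq <- transform(good, p2 = 1.5)
  expect_error(quartet_sites(bad_freq, c(sc1 = 100)), "\\[0,1\\]")
  expect_error(quartet_sites(good[c(2, 1), ], c(sc1 = 100)), "increasing")
  expect_error(quartet_sites(good, c(sc1 = 8)), "beyond scaffold length")
  expect_error(quartet_sites(good, c(other = 100)), "absent")
})

test_that("SNP table rows polarize by the outgroup allele", {
  p <- write_lines_tmp(c("scaffold\tpos\tP1\tP2\tP3\tO",
                         "sc1\t500\tA\tG\tG\tA",   # fixed ABBA
                         "sc1\t600\tG\tA\tG\tA",   # fixed BABA
                         "sc1\t700\tC\tC\tC\tC",   # monomorphic: dropped
                         "sc1\t800\tA\tG\tC\tA"),  # triallelic: dropped
                       ".tsv")
  x <- read_snp_table(p, test_quartet())
  expect_equal(x$sites$pos, c(500, 600))
  expect_equal(unlist(x$sites[1, c("p1", "p2", "p3", "p4")], use.names = FALSE),
               c(0, 1, 1, 0))
  expect_equal(unlist(x$sites[2, c("p1", "p2", "p3", "p4")], use.names = FALSE),
               c(1, 0, 1, 0))
  expect_equal(unname(x$drops["monomorphic"]), 1L)
  expect_equal(unname(x$drops["multiallelic"]), 1L)
})

test_that("SNP table errors and warnings name the problem", {
  hdr <- "scaffold\tpos\tP1\tP2\tP3\tO"
  expect_warning(x <- read_snp_table(write_lines_tmp(hdr, ".tsv"),
                                     test_quartet()), "no data rows")
  expect_equal(nrow(x$sites), 0L)
  expect_error(read_snp_table(write_lines_tmp(c(hdr, "sc1\t5\tA\tG"), ".tsv"),
                              test_quartet()), "line 2")
  expect_error(read_snp_table(write_lines_tmp(c(hdr, "sc1\txx\tA\tG\tG\tA"),
                                              ".tsv"), test_quartet()),
               "line 2")
  bad_hdr <- "scaffold\tpos\tP1\tP2\tP3\tOUT"
  expect_error(read_snp_table(write_lines_tmp(c(bad_hdr, "sc1\t5\tA\tG\tG\tA"),
                                              ".tsv"), test_quartet()),
               "missing sample")
})

test_that("haploid tables round-trip exactly through the tabular dialect", {
  set.seed(5)
  df <- random_site_table(40, haploid = TRUE)
  df <- df[!(df$p1 == 0 & df$p2 == 0 & df$p3 == 0), ]  # drop monomorphic
  rownames(df) <- NULL
  x <- sites_obj(df, len = 1000)
  p <- tempfile(fileext = ".tsv")
  write_snp_table(x, p)
  y <- read_snp_table(p, test_quartet(), scaffold_lengths = c(sc1 = 1000))
  expect_equal(y$sites, x$sites)
  # and identically through gzip
  pz <- tempfile(fileext = ".tsv.gz")
  write_snp_table(x, pz)
  expect_equal(read_snp_table(pz, test_quartet(),
                              scaffold_lengths = c(sc1 = 1000))$sites, x$sites)
  expect_error(write_snp_table(sites_obj(random_site_table(5)), tempfile()),
               "haploid")
})

fasta_tmp <- function(seqs) {
  write_lines_tmp(unlist(lapply(names(seqs), function(n)
    c(paste0(">", n), seqs[[n]]))), ".fa")
}

test_that("aligned FASTA columns polarize and skip gaps/triallelic sites", {
  p <- fasta_tmp(list(P1 = "AAACA-TA", P2 = "AGACAGTC", P3 = "AGACAGCC",
                      O  = "AAAC-GTA"))
  # cols: 1 mono; 2 ABBA; 3 mono; 4 mono; 5 gap in O; 6 gap in P1;
  # 7 triallelic (T,T,C? -> P1=T P2=T P3=C O=T biallelic!) ... col7: T T C T
  # is biallelic with P3 derived; col8: A C C A -> ABBA
  x <- read_aligned_fasta(p, test_quartet())
  expect_equal(x$scaffold_lengths[[1]], 7)  # one gap column in O
  # outgroup-space coordinates: col2 -> pos 2; col7 -> pos 6; col8 -> pos 7
  expect_equal(x$sites$pos, c(2, 6, 7))
  expect_equal(unlist(x$sites[1, c("p1", "p2", "p3", "p4")], use.names = FALSE),
               c(0, 1, 1, 0))
  expect_equal(unlist(x$sites[2, c("p1", "p2", "p3", "p4")], use.names = FALSE),
               c(0, 0, 1, 0))
  expect_equal(unname(x$drops["gap_or_ambiguous"]), 2L)
  # callable excludes the two gap columns
  expect_equal(x$callable[[1]], c(1, 2, 3, 4, 6, 7))
})

test_that("aligned FASTA input validation", {
  expect_error(read_aligned_fasta(
    fasta_tmp(list(P1 = "AAA", P2 = "AAA", P3 = "AAA")), test_quartet()),
    "four records")
  expect_error(read_aligned_fasta(
    fasta_tmp(list(P1 = "AAAA", P2 = "AAA", P3 = "AAA", O = "AAA")),
    test_quartet()), "equal length")
  expect_error(read_aligned_fasta(
    fasta_tmp(list(P1 = "AAA", P2 = "AAA", P3 = "AAA", X = "AAA")),
    test_quartet()), "missing quartet record")
  ident <- read_aligned_fasta(
    fasta_tmp(list(P1 = strrep("ACGT", 25), P2 = strrep("ACGT", 25),
                   P3 = strrep("ACGT", 25), O = strrep("ACGT", 25))),
    test_quartet())
  expect_equal(nrow(ident$sites), 0L)
  # triallelic column is counted, not silently lost
  tri <- read_aligned_fasta(
    fasta_tmp(list(P1 = "AA", P2 = "AG", P3 = "AC", O = "AA")),
    test_quartet())
  expect_equal(nrow(tri$sites), 0L)
  expect_equal(unname(tri$drops["multiallelic"]), 1L)
})

test_that("VCF records polarize, drop and count like the other readers", {
  p <- write_lines_tmp(mini_vcf(c(
    vcf_rec("sc1", 100, "A", "G", c(0, 1, 1, 0)),    # fixed ABBA
    vcf_rec("sc1", 200, "A", "G", c(1, 0, 1, 0)),    # fixed BABA
    vcf_rec("sc1", 300, "A", "G,C", c(0, 1, 2, 0)),  # multiallelic: dropped
    vcf_rec("sc1", 400, "A", "GT", c(0, 1, 1, 0)),   # indel: dropped
    vcf_rec("sc1", 500, "A", "G", c(0, 1, ".", 0)),  # missing call: dropped
    vcf_rec("sc1", 600, "G", "A", c(1, 0, 0, 1)))),  # O carries ALT=ancestral
    ".vcf")
  x <- read_quartet_vcf(p, test_quartet())
  expect_equal(x$sites$pos, c(100, 200, 600))
  expect_equal(unlist(x$sites[1, c("p1", "p2", "p3", "p4")], use.names = FALSE),
               c(0, 1, 1, 0))
  expect_equal(unlist(x$sites[2, c("p1", "p2", "p3", "p4")], use.names = FALSE),
               c(1, 0, 1, 0))
  # REF/ALT orientation is irrelevant after outgroup polarization
  expect_equal(unlist(x$sites[3, c("p1", "p2", "p3", "p4")], use.names = FALSE),
               c(0, 1, 1, 0))
  expect_equal(unname(x$drops["multiallelic"]), 1L)
  expect_equal(unname(x$drops["non_snp"]), 1L)
  expect_equal(unname(x$drops["missing"]), 1L)
  # contig header supplies scaffold lengths
  expect_equal(x$scaffold_lengths, c(sc1 = 10000))
})

test_that("VCF diploid dosages and outgroup polymorphism modes", {
  recs <- c(vcf_rec("sc1", 10, "A", "G", c("0/1", "1/1", "1|1", "0/0")),
            vcf_rec("sc1", 20, "A", "G", c("0/0", "1/1", "1/1", "0/1")))
  p <- write_lines_tmp(mini_vcf(recs), ".vcf")
  strict <- read_quartet_vcf(p, test_quartet())
  expect_equal(nrow(strict$sites), 1L)
  expect_equal(unlist(strict$sites[1, c("p1", "p2", "p3", "p4")],
                      use.names = FALSE), c(0.5, 1, 1, 0))
  expect_equal(unname(strict$drops["outgroup_polymorphic"]), 1L)
  perm <- read_quartet_vcf(p, test_quartet(), strict_outgroup = FALSE)
  expect_equal(nrow(perm$sites), 2L)
  expect_equal(perm$sites$p4[perm$sites$pos == 20], 0.5)
})

test_that("VCF error paths: missing sample, unsorted file, empty file", {
  recs <- vcf_rec("sc1", 100, "A", "G", c(0, 1, 1, 0))
  p <- write_lines_tmp(mini_vcf(recs, samples = c("P1", "P2", "P3", "OUT")),
                       ".vcf")
  expect_error(read_quartet_vcf(p, test_quartet()), "missing quartet sample.*O")
  un <- write_lines_tmp(mini_vcf(c(vcf_rec("sc1", 200, "A", "G", c(0, 1, 1, 0)),
                                   vcf_rec("sc1", 100, "A", "G", c(0, 1, 1, 0)))),
                        ".vcf")
  expect_error(read_quartet_vcf(un, test_quartet()), "not coordinate-sorted")
  empty <- write_lines_tmp(mini_vcf(character(0)), ".vcf")
  expect_warning(x <- read_quartet_vcf(empty, test_quartet()),
                 "no variant records")
  expect_equal(nrow(x$sites), 0L)
})

test_that("every reader output satisfies the site-table invariants", {
  sim <- simulate_quartet(sim_config(genome_length = 2e4, seed = 9,
                                     tracts = NULL),
                          out_dir = tempfile())
  vcf <- read_quartet_vcf(sim$files$vcf, test_quartet())
  fa <- read_aligned_fasta(sim$files$fasta_sc1, test_quartet())
  expect_silent(validate_quartet_sites(vcf))
  expect_silent(validate_quartet_sites(fa))
  expect_silent(validate_quartet_sites(sim$sites))
})

test_that("FASTA and VCF derived from one simulation yield identical tables", {
  sim <- simulate_quartet(sim_config(genome_length = 5e4, seed = 4),
                          out_dir = tempfile())
  vcf <- read_quartet_vcf(sim$files$vcf, test_quartet())
  fa <- read_aligned_fasta(sim$files$fasta_sc1, test_quartet())
  expect_equal(fa$sites, vcf$sites)
  expect_equal(fa$sites, sim$sites$sites)
  expect_equal(vcf$scaffold_lengths, c(sc1 = 5e4))
})
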