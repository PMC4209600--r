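test_that("seed motifs are the reverse complement of miRNA positions 2-8", {
  # expected strings computed by hand and frozen after cross-checking with
  # an independent reverse-complement routine
  m155 <- derive_seed_motifs(mature_mirna("hsa-miR-155-5p",
                                          "UUAAUGCUAAUCGUGAUAGGGGU"))
  expect_equal(m155$motif_8mer, "AGCAUUAA")
  expect_equal(m155$motif_7mer_m8, "AGCAUUA")
  expect_equal(m155$motif_7mer_A1, "GCAUUAA")

  homo <- derive_seed_motifs(mature_mirna("homopolymer", "AAAAAAAA"))
  expect_equal(unname(unlist(homo[1:3])),
               c("UUUUUUUA", "UUUUUUU", "UUUUUUA"))

  let7 <- derive_seed_motifs(mature_mirna("hsa-let-7a-5p",
                                          "UGAGGUAGUAGGUUGUAUAGUU"))
  expect_equal(unname(unlist(let7[1:3])),
               c("CUACCUCA", "CUACCUC", "UACCUCA"))

  # structural invariants of the motif set
  expect_equal(m155$motif_8mer, paste0(m155$motif_7mer_m8, "A"))
  expect_equal(m155$motif_7mer_A1,
               paste0(substr(m155$motif_7mer_m8, 2, 7), "A"))
})

test_that("miRNA validation rejects short or malformed sequences", {
  expect_error(mature_mirna("tiny", "UUAAUGC"), "tiny")
  expect_error(mature_mirna("bad", "UUAAUGCXAAU"), "X")
  # DNA input is normalized, not rejected
  expect_equal(mature_mirna("dna", "TTAATGCTAATCGTGATAGGGGT")$sequence,
               "UUAAUGCUAAUCGUGAUAGGGGU")
})

test_that("scan_utr reports maximal-type sites at 0-based offsets", {
  m <- mir155_motifs()
  hit <- scan_utr("AAGCAUUAAGG", m)
  expect_equal(hit$start, 1L)
  expect_equal(hit$end, 9L)
  expect_equal(hit$site_type, "8mer")

  expect_equal(nrow(scan_utr("", m)), 0L)

  # trailing base G blocks the 8mer; the 7mer-m8 remains
  hit <- scan_utr("AGCAUUAG", m)
  expect_equal(hit[, c("start", "end", "site_type")],
               data.frame(start = 0L, end = 7L, site_type = "7mer-m8"))

  # the 7mer-A1 embedded in a full 8mer is not reported separately
  hit <- scan_utr("AGCAUUAA", m)
  expect_equal(hit$site_type, "8mer")

  # a free-standing 7mer-A1 is
  hit <- scan_utr("CGCAUUAACC", m)
  expect_equal(hit$site_type, "7mer-A1")
  expect_equal(hit$start, 1L)

  # N never matches
  expect_equal(nrow(scan_utr("AGCAUUNA", m)), 0L)
})

test_that("scanning a sequence and its T-for-U substitution gives identical sites", {
  m <- mir155_motifs()
  set.seed(42)
  for (i in 1:25) {
    s <- random_rna_seq(120)
    expect_identical(scan_utr(s, m), scan_utr(chartr("U", "T", s), m))
  }
})

test_that("scan_utr matches the exhaustive offset oracle on random sequences", {
  m <- mir155_motifs()
  set.seed(7)
  for (i in 1:200) {
    s <- random_rna_seq(sample(10:400, 1))
    got <- scan_utr(s, m)[, c("start", "end", "site_type")]
    rownames(got) <- NULL
    expect_identical(got, brute_scan(s, m), label = sprintf("seq %d", i))
  }
})

test_that("every reported 8mer starts with the 7mer-m8 motif", {
  m <- mir155_motifs()
  set.seed(11)
  seqs <- replicate(120, random_rna_seq(300))
  sites <- scan_utr_set(stats::setNames(seqs, sprintf("tx%03d", 1:120)), m)
  e8 <- sites[sites$site_type == "8mer", ]
  prefix <- substr(seqs[match(e8$transcript_id, sprintf("tx%03d", 1:120))],
                   e8$start + 1, e8$start + 7)
  expect_true(all(prefix == m$motif_7mer_m8))
})

test_that("count_sites pools isoforms, deduplicates positions and splits 7/8mer", {
  sites <- data.frame(
    transcript_id = c("t1", "t1", "t1", "t2", "t2", "t3"),
    start = c(3L, 40L, 100L, 100L, 3L, 10L),
    end = c(10L, 47L, 108L, 108L, 10L, 18L),
    site_type = c("7mer-m8", "7mer-A1", "8mer", "8mer", "7mer-m8", "8mer"),
    stringsAsFactors = FALSE)
  # t1 and t2 are isoforms of geneA: the duplicated 8mer@100 and
  # 7mer-m8@3 collapse to single sites
  counts <- count_sites(sites, gene_map = c(t1 = "geneA", t2 = "geneA",
                                            t3 = "geneB", t4 = "geneC"))
  expect_equal(counts$n_7mer[counts$gene == "geneA"], 2L)
  expect_equal(counts$n_8mer[counts$gene == "geneA"], 1L)
  expect_equal(counts$n_8mer[counts$gene == "geneB"], 1L)
  # mapped gene with no sites reports zeros
  expect_equal(counts$n_7mer[counts$gene == "geneC"] +
               counts$n_8mer[counts$gene == "geneC"], 0L)
})

test_that("m8_only scanning drops 7mer-A1 sites", {
  m <- mir155_motifs()
  both <- scan_utr("CGCAUUAACCAGCAUUAGC", m)
  only <- scan_utr("CGCAUUAACCAGCAUUAGC", m, seven_mer = "m8_only")
  expect_setequal(both$site_type, c("7mer-A1", "7mer-m8"))
  expect_equal(only$site_type, "7mer-m8")
})

test_that("extract_utrs honours blocks and reverse-complements minus-strand models", {
  utr_plus <- "ACGGAUCCAAGCAUUAAGG"
  dna_plus <- chartr("U", "T", utr_plus)
  dna_minus <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(dna_plus)))
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste0("TTTT", dna_plus, "GGGG"),
    chr2 = paste0("AA", dna_minus, "CC")))
  models <- GenomicRanges::GRanges(
    c("chr1", "chr2"),
    IRanges::IRanges(c(5, 3), width = nchar(dna_plus)),
    strand = c("+", "-"))
  models$name <- c("txA", "txB")
  utrs <- extract_utrs(genome, models)
  expect_equal(unname(utrs["txA"]), dna_plus)
  expect_equal(unname(utrs["txB"]), dna_plus)
  # both orientations carry the same 8mer site after extraction
  sites <- scan_utr_set(utrs, mir155_motifs())
  expect_equal(sites$site_type, c("8mer", "8mer"))
})
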