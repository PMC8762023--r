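test_that("published genomic-to-cDNA pairs map exactly on the fixture model", {
  m <- glk_gene_model()
  r1 <- genomic_to_cdna(39477124, "A", "G", m)
  expect_equal(r1$cdna_pos, 3320)
  expect_equal(r1$cdna_ref, "T")
  expect_equal(r1$cdna_alt, "C")
  r2 <- genomic_to_cdna(39477115, "T", "G", m)
  expect_equal(r2$cdna_pos, 3329)
  expect_equal(r2$cdna_ref, "A")
  expect_equal(r2$cdna_alt, "C")
  expect_equal(genomic_to_cdna(39519957, "C", "T", m)$cdna_pos, 1228)
  expect_equal(genomic_to_cdna(39499448, "T", "C", m)$cdna_pos, 1949)
  expect_error(genomic_to_cdna(1000, "A", "G", m),
               class = "vafscreen_out_of_model_error")
})

test_that("genomic/cDNA mapping round-trips on 1000 random in-model positions", {
  m <- glk_gene_model()
  withr::with_seed(101, {
    all_cdna <- unlist(purrr::map2(m$blocks$cdna_anchor, m$blocks$length,
                                   ~ .x:(.x + .y - 1)))
    pos <- sample(all_cdna, 1000, replace = TRUE)
    genomic <- cdna_to_genomic(pos, m)
    back <- genomic_to_cdna(genomic, rep("A", 1000), rep("G", 1000), m)
    expect_equal(back$cdna_pos, pos)
  })
})

test_that("complementation is an involution and minus-strand offsets invert", {
  for (b in c("A", "C", "G", "T")) {
    expect_equal(complement_base(complement_base(b)), b)
  }
  expect_error(complement_base("N"), class = "vafscreen_input_error")
  # genomic distance equals cDNA distance with opposite sign within a block
  expect_equal(39477124 - 39477115, 3329 - 3320)
  m <- glk_gene_model()
  expect_equal(cdna_to_genomic(3320, m) - cdna_to_genomic(3329, m), 9)
})

test_that("cDNA-to-UTR continuation numbering subtracts the CDS length", {
  m <- glk_gene_model()
  expect_equal(cdna_to_utr3(3320, m), 635L)
  expect_equal(cdna_to_utr3(3329, m), 644L)
  expect_equal(cdna_to_utr3(2686, m), 1L)
  expect_error(cdna_to_utr3(2685, m), class = "vafscreen_not_in_utr_error")
})

test_that("codon-change annotation reproduces the published protein labels", {
  m <- glk_gene_model()
  expect_equal(annotate_codon_change(1228, "G", "A", "GCA", m), "p.Ala410Thr")
  expect_equal(annotate_codon_change(800, "T", "A", "TTA", m), "p.Leu267Ter")
  expect_equal(annotate_codon_change(1949, "A", "G", "AAA", m), "p.Lys650Arg")
  # synonymous and error paths
  expect_equal(annotate_codon_change(6, "G", "A", "CTG", m), "p.(=)")
  expect_error(annotate_codon_change(1228, "C", "A", "GCA", m),
               class = "vafscreen_ref_mismatch_error")
  expect_error(annotate_codon_change(9999, "A", "G", "AAA", m),
               class = "vafscreen_input_error")
})

test_that("codon-change annotation agrees with a translation oracle on random sites", {
  m <- glk_gene_model()
  cds <- glk_cds_fixture()
  code <- Biostrings::GENETIC_CODE
  aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
           E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
           M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
           Y = "Tyr", V = "Val", `*` = "Ter")
  withr::with_seed(202, {
    positions <- sample(seq_len(m$cds_length), 100)
    for (pos in positions) {
      ci <- ceiling(pos / 3)
      codon <- substr(cds, 3 * (ci - 1) + 1, 3 * ci)
      off <- (pos - 1) %% 3 + 1
      ref <- substr(codon, off, off)
      for (alt in setdiff(c("A", "C", "G", "T"), ref)) {
        mut <- codon
        substr(mut, off, off) <- alt
        expected <- if (code[[codon]] == code[[mut]]) "p.(=)" else
          sprintf("p.%s%d%s", aa3[[code[[codon]]]], ci, aa3[[code[[mut]]]])
        expect_equal(annotate_codon_change(pos, ref, alt, cds, m), expected)
      }
    }
  })
})

test_that("out-of-frame insertions get frameshift labels; in-frame ones signal", {
  m <- glk_gene_model()
  expect_equal(annotate_insertion(c(1942, 1943), "A", glk_cds_fixture(), m),
               "p.Ala648fs")
  expect_equal(annotate_insertion(c(3, 4), "T", glk_cds_fixture(), m),
               "p.Ala2fs")
  expect_error(annotate_insertion(c(1942, 1943), "AAA", glk_cds_fixture(), m),
               class = "vafscreen_unsupported_annotation")
  expect_error(annotate_insertion(c(10, 12), "A", glk_cds_fixture(), m),
               class = "vafscreen_input_error")
})

test_that("gene model construction rejects overlapping blocks and bad CDS", {
  expect_error(gene_model("-", 10, tibble::tibble(
    genomic_anchor = 100, cdna_anchor = 1, length = 10)),
    class = "vafscreen_config_error")  # cds not multiple of 3
  expect_error(gene_model("-", 9, tibble::tibble(
    genomic_anchor = c(100, 95), cdna_anchor = c(1, 20),
    length = c(10, 10))), class = "vafscreen_config_error")  # genomic overlap
  expect_error(gene_model("-", 9, tibble::tibble(
    genomic_anchor = c(100, 200), cdna_anchor = c(1, 5),
    length = c(10, 10))), class = "vafscreen_config_error")  # cDNA overlap
})
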