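test_that("motif sets are validated, upper-cased and deduplicated", {
  f <- withr::local_tempfile(lines = c("gaagaa", "GAAGAA", "ACGTAC"))
  m <- read_sre_motifs(ese = f)
  expect_equal(sort(m$ESE), c("ACGTAC", "GAAGAA"))
  expect_equal(m$ISE, character(0))
  expect_error(sre_motifs(ESE = "ACGT"), "invalid hexamer")
  expect_error(sre_motifs(ISE = "ACGTAN"), "invalid hexamer")
})

test_that("variant positions classify as exonic/intronic with strict span bounds", {
  unit <- define_splicing_unit(toy_model(), 2)
  expect_equal(classify_region(350, unit), "exonic")      # target exon
  expect_equal(classify_region(101, unit), "exonic")      # upstream exon edge
  expect_equal(classify_region(600, unit), "exonic")      # downstream exon edge
  expect_equal(classify_region(250, unit), "intronic")
  expect_equal(classify_region(450, unit), "intronic")
  expect_error(classify_region(601, unit), "outside")
  expect_error(classify_region(100, unit), "outside")
})

test_that("hexamer windows enumerate all 6-mers overlapping the SNV", {
  seq <- "AAAATGAAGAACCCCC"  # GAAGAA at 6..11
  win <- hexamer_windows(seq, 8, "A", "C")
  expect_equal(nrow(win), 6L)
  expect_equal(win$offset, -5:0)
  # offset -2 window is GAAGAA -> GACGAA after the A>C substitution
  expect_equal(win$ref_hexamer[win$offset == -2], "GAAGAA")
  expect_equal(win$alt_hexamer[win$offset == -2], "GACGAA")
  # every alt hexamer differs from its ref hexamer at exactly the SNV slot
  expect_true(all(win$ref_hexamer != win$alt_hexamer))

  # truncation: SNV at the 3rd base leaves 3 windows
  win2 <- hexamer_windows(seq, 3, "A", "G")
  expect_equal(nrow(win2), 3L)
  expect_equal(win2$offset, -2:0)

  expect_error(hexamer_windows(seq, 8, "G", "C"), "does not match FASTA")
  expect_error(hexamer_windows(seq, 8, "AT", "C"), "SNVs only")
})

test_that("minus-strand windows are oriented to the transcribed strand", {
  seq <- "AAAATGAAGAACCCCC"
  win_plus <- hexamer_windows(seq, 8, "A", "C", strand = "+")
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  pos_rc <- nchar(seq) - 8 + 1
  win_rc <- hexamer_windows(rc, pos_rc, "T", "G", strand = "-")
  expect_equal(win_rc, win_plus)
})

test_that("annotation flags exactly SRE-losing SNVs", {
  model <- gene_model("g", "chrT", "+",
                      data.frame(start = c(1, 10, 30),
                                 end = c(8, 20, 40)))
  unit <- define_splicing_unit(model, 2)
  #         12345678901234567890
  seq <- "ACGTATGAAGAATTTTTTTTCCCCCCCCCGGGGGGGGGGG"
  motifs <- sre_motifs(ESE = "GAAGAA")
  # exonic SNV destroying the planted ESE (GAAGAA at 7..12)
  ann <- annotate_variant(list(id = "v1", pos = 11, ref = "A", alt = "C"),
                          seq, unit, motifs)
  expect_true(ann$functional)
  expect_equal(ann$region_class, "exonic")
  expect_equal(ann$n_lost, 1L)
  lost <- ann$lost_motifs[[1]]
  expect_equal(lost$ref_hexamer, "GAAGAA")
  expect_equal(lost$class_label, "ESE")

  # no motif in any ref window -> non-functional
  ann2 <- annotate_variant(list(id = "v2", pos = 35, ref = "G", alt = "T"),
                           seq, unit, motifs)
  expect_false(ann2$functional)

  # intronic SNV is checked against ISE only: empty ISE set -> non-functional
  ann3 <- annotate_variant(list(id = "v3", pos = 9, ref = "A", alt = "C"),
                           seq, unit, motifs)
  expect_equal(ann3$region_class, "intronic")
  expect_false(ann3$functional)

  # ref and alt windows both matching a motif contribute no loss
  motifs4 <- sre_motifs(ESE = c("GAAGAA", "GAAGCA"))
  win <- hexamer_windows(seq, 11, "A", "C")
  expect_equal(nrow(hexamer_losses(win, motifs4, "ESE")), 0L)

  # indels are logged and marked non-functional
  expect_warning(
    ann5 <- annotate_variant(list(id = "v5", pos = 11, ref = "AG",
                                  alt = "A"), seq, unit, motifs),
    "not an SNV")
  expect_false(ann5$functional)
})

test_that("annotate_all preserves variant order and handles the empty case", {
  cfg <- sim_config(seed = 9, n_samples = 30, n_genes_expr = 10,
                    n_planted_degs = 0)
  sim <- simulate_dataset(cfg)
  ann <- annotate_all(sim$gm, sim$seq, sim$unit, sim$motifs)
  expect_equal(ann$variant_id, sim$gm$variants$id)
  # functional => at least one recorded loss whose ref hexamer is in a set
  for (i in which(ann$functional)) {
    lost <- ann$lost_motifs[[i]]
    expect_gt(nrow(lost), 0)
    expect_true(all(mapply(function(h, cl) h %in% sim$motifs[[cl]],
                           lost$ref_hexamer, lost$class_label)))
    expect_true(all(mapply(function(h, cl) !(h %in% sim$motifs[[cl]]),
                           lost$alt_hexamer, lost$class_label)))
  }
  empty <- genotype_matrix(sim$gm$samples,
                           sim$gm$variants[0, ],
                           sim$gm$calls[, 0, drop = FALSE])
  expect_equal(nrow(annotate_all(empty, sim$seq, sim$unit, sim$motifs)), 0L)
})

test_that("scanner agrees with the brute-force substring oracle on random cases", {
  set.seed(401)
  unit_of <- function(len) {
    third <- len %/% 3
    define_splicing_unit(
      gene_model("g", "c", "+",
                 data.frame(start = c(1, third + 6, 2 * third + 11),
                            end = c(third, 2 * third + 5, len))), 2)
  }
  for (i in 1:200) {
    len <- sample(40:90, 1)
    seq <- random_dna(len)
    motifs <- sre_motifs(ESE = random_hexamers(sample(3:25, 1)),
                         ESS = random_hexamers(sample(0:10, 1)),
                         ISE = random_hexamers(sample(3:25, 1)))
    unit <- unit_of(len)
    pos <- sample(len, 1)
    ref <- substr(seq, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    region <- classify_region(pos, unit)
    got <- annotate_variant(list(id = "x", pos = pos, ref = ref, alt = alt),
                            seq, unit, motifs)
    want <- oracle_sre_loss(seq, pos, ref, alt, motifs,
                            applicable_classes(region))
    expect_identical(got$functional, want$functional)
    expect_identical(got$n_lost, want$n_lost)
  }
})

test_that("minus-strand annotation equals plus-strand annotation of the reverse complement", {
  set.seed(402)
  for (i in 1:40) {
    len <- 60
    seq <- random_dna(len)
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(seq)))
    motifs <- sre_motifs(ESE = random_hexamers(10), ISE = random_hexamers(10))
    # exon/intron layout symmetric about the center so the unit maps onto
    # itself under coordinate reflection
    model_minus <- gene_model("g", "c", "-",
                              data.frame(start = c(1, 25, 46),
                                         end = c(15, 36, 60)))
    model_plus <- gene_model("g", "c", "+",
                             data.frame(start = c(1, 25, 46),
                                        end = c(15, 36, 60)))
    unit_minus <- define_splicing_unit(model_minus, 2)
    unit_plus <- define_splicing_unit(model_plus, 2)
    pos <- sample(len, 1)
    ref <- substr(seq, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    a_minus <- annotate_variant(list(id = "v", pos = pos, ref = ref,
                                     alt = alt), seq, unit_minus, motifs)
    comp <- function(b) chartr("ACGT", "TGCA", b)
    a_plus <- annotate_variant(list(id = "v", pos = len - pos + 1,
                                    ref = comp(ref), alt = comp(alt)),
                               rc, unit_plus, motifs)
    expect_identical(a_minus$functional, a_plus$functional)
    expect_identical(a_minus$n_lost, a_plus$n_lost)
  }
})
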