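test_that("the integration module places the arms in reverse order around AscI/FseI", {
  loc <- target_locus("AAAACCCC", split = 4)
  mod <- design_integration_module(loc, min_arm = 4, design_primers = FALSE)
  expect_equal(mod$sequence$bases, "CCCCGGCGCGCCGGCCGGCCAAAA")
  expect_equal(mod$linearization_enzyme, "AscI")
  expect_equal(count_sites(mod$sequence, gg_enzymes()$AscI), 1L)
  expect_equal(count_sites(mod$sequence, gg_enzymes()$FseI), 1L)
})

test_that("AscI inside the arms switches linearization to FseI; both is fatal", {
  loc_a <- target_locus(paste0("GGCGCGCC", strrep("AT", 10), strrep("CT", 10)),
                        split = 24)
  mod <- design_integration_module(loc_a, min_arm = 4, design_primers = FALSE)
  expect_equal(mod$linearization_enzyme, "FseI")
  loc_b <- target_locus(paste0("GGCGCGCCAAAA", "GGCCGGCCTTTT"), split = 12)
  expect_error(design_integration_module(loc_b, min_arm = 4, design_primers = FALSE),
               class = "gg_design_error")
  expect_error(design_integration_module(target_locus("ACGTACGT", split = 4),
                                         min_arm = 50),
               class = "gg_value_error")  # arms too short
})

test_that("linearize cuts a unique site and splits it across the ends", {
  set.seed(83)
  b <- paste0(rand_dna(200), "GGCGCGCC", rand_dna(200))
  v <- nuc_seq(b, name = "v", topology = "circular")
  lin <- linearize(v, gg_enzymes()$AscI)
  expect_equal(lin$topology, "linear")
  expect_equal(seq_length(lin), seq_length(v))
  expect_true(startsWith(lin$bases, "CGCGCC"))  # site half at the new start
  expect_true(endsWith(lin$bases, "GG"))
  expect_error(linearize(nuc_seq(rand_dna(100), topology = "circular"),
                         gg_enzymes()$AscI),
               class = "gg_site_count_error")
  expect_error(linearize(nuc_seq(paste0(b, "TTGGCGCGCCTT"), topology = "circular"),
                         gg_enzymes()$AscI),
               class = "gg_site_count_error")
})

make_toy_system <- function(arm_len = 40) {
  # toy genome with a unique locus; inverted-arm vector carrying a payload
  genome <- nuc_seq(paste0(rand_dna(300), rand_dna(2 * arm_len), rand_dna(300)),
                    name = "toy_genome")
  locus <- target_locus(substr(genome$bases, 301, 300 + 2 * arm_len),
                        chromosome = "toy", split = arm_len)
  mod <- design_integration_module(locus, min_arm = 20, design_primers = FALSE)
  payload_rest <- rand_dna(500)  # rest of the assembled plasmid
  vec <- nuc_seq(paste0(mod$sequence$bases, payload_rest),
                 name = "vector", topology = "circular")
  list(genome = genome, locus = locus, vec = vec)
}

test_that("inverted-arm integration preserves homology copy number (replacement)", {
  set.seed(89)
  for (i in 1:5) {
    sys <- make_toy_system(arm_len = sample(20:60, 1))
    lin <- linearize(sys$vec, gg_enzymes()$AscI)
    out <- simulate_integration(sys$genome, lin,
                                c(sys$locus$arm5, sys$locus$arm3))
    expect_equal(out$integration_mode, "replacement")
    expect_equal(out$homology_copies$post, c(1L, 1L))
    expect_equal(out$homology_copies$pre, out$homology_copies$post)
    # payload round-trip: the sequence between the arms is the vector payload
    g <- out$integrated_genome$bases
    i5 <- regexpr(sys$locus$arm5, g, fixed = TRUE)
    i3 <- regexpr(sys$locus$arm3, g, fixed = TRUE)
    extracted <- substr(g, i5 + nchar(sys$locus$arm5), i3 - 1)
    expect_equal(extracted, out$payload)
  }
})

test_that("sequential replacement integrations never accumulate copies", {
  set.seed(97)
  sys <- make_toy_system()
  lin <- linearize(sys$vec, gg_enzymes()$AscI)
  arms <- c(sys$locus$arm5, sys$locus$arm3)
  g1 <- simulate_integration(sys$genome, lin, arms)
  g2 <- simulate_integration(g1$integrated_genome, lin, arms)
  expect_equal(g2$integration_mode, "replacement")
  expect_equal(g2$homology_copies$post, c(1L, 1L))
  # replacement, not accumulation: the genome does not keep growing
  expect_equal(seq_length(g2$integrated_genome), seq_length(g1$integrated_genome))
})

test_that("marker-cut integration duplicates the homology region", {
  set.seed(101)
  marker <- rand_dna(80)
  genome <- nuc_seq(paste0(rand_dna(250), marker, rand_dna(250)), name = "g")
  # plasmid carries the contiguous marker; cut inside it (EcoRV-style model:
  # split the homology region in the middle)
  plasmid_rest <- rand_dna(400)
  arm5 <- substr(marker, 1, 40); arm3 <- substr(marker, 41, 80)
  lin <- nuc_seq(paste0(arm3, plasmid_rest, arm5), name = "lin_marker_cut")
  out <- simulate_integration(genome, lin, c(arm5, arm3))
  expect_equal(out$integration_mode, "duplication")
  expect_equal(out$homology_copies$post, c(2L, 2L))
  # the full homology region is now present twice, enabling further integration
  expect_equal(stringi::stri_count_fixed(out$integrated_genome$bases, marker), 2L)
})

test_that("integration preconditions are enforced", {
  set.seed(103)
  genome <- nuc_seq(rand_dna(500))
  lin <- nuc_seq(rand_dna(300))
  expect_error(simulate_integration(genome, lin, c("ACGTACGTACGT", "TTTTGGGGCCCC")),
               class = "gg_value_error")
})

test_that("an assembled integration vector linearizes genome-collinearly", {
  lib <- build_library(seed = 7)
  ids <- c("pMV46", "pMV1", "pMV3", "pMV5", "pMV6", "pMV10")
  res <- assemble(lib$sequences$pDV, lib$sequences[ids])
  lin <- linearize(res$product, gg_enzymes()$AscI)
  loc <- lib$loci$chrVI
  # after cutting between the inverted arms, arm5 and arm3 appear in
  # genome-collinear order and orientation on the linear molecule
  i5 <- regexpr(loc$arm5, lin$bases, fixed = TRUE)
  i3 <- regexpr(loc$arm3, lin$bases, fixed = TRUE)
  expect_gt(i5, 0); expect_gt(i3, 0)
  expect_lt(i5, i3)
  out <- simulate_integration(lib$genomes$chrVI, lin, c(loc$arm5, loc$arm3))
  expect_equal(out$integration_mode, "replacement")
  expect_equal(out$homology_copies$post, c(1L, 1L))
})

test_that("check_locus measures spans and distances against the criteria", {
  set.seed(107)
  loc <- target_locus(rand_dna(151), chromosome = "chrVI",
                      start = 260998, end = 261148)
  expect_equal(loc$end - loc$start + 1L, 151L)
  ann <- tibble::tibble(
    chrom = "chrVI",
    start = c(1, 240000, 262100, 261050, 100000),
    end = c(10000, 259900, 263000, 261080, 100500),
    type = c("telomere", "ORF", "ORF", "binding_site", "centromere")
  )
  rep <- check_locus(loc, ann)
  expect_equal(rep$criterion,
               c("landmark_distance", "orf_free_region", "clean_region"))
  # ORF-free gap: 259901..262099 = 2199 bp -> pass
  expect_equal(rep$observed_bp[2], 2199)
  expect_true(rep$pass[2])
  # overlapping binding site -> clean-region fail
  expect_false(rep$pass[3])
  expect_true(rep$pass[1])  # 151 kb from the nearest landmark

  # a 900-bp ORF-free gap fails the 1000-bp criterion
  ann2 <- tibble::tibble(chrom = "chrVI",
                         start = c(260500, 261410), end = c(260509, 261500),
                         type = c("ORF", "ORF"))
  rep2 <- check_locus(loc, ann2)
  expect_equal(rep2$observed_bp[2], 900)
  expect_false(rep2$pass[2])
})
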