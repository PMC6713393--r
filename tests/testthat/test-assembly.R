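# fixtures: one library shared across this file
lib <- build_library(seed = 101)
ot <- overhang_table()

test_that("digesting a module plasmid releases the insert with its overhangs", {
  frags <- digest(lib$sequences$pMV14)  # position 1
  expect_length(frags, 2)
  insert <- Filter(function(f) count_sites(nuc_seq(f$bases)) == 0, frags)[[1]]
  expect_equal(insert$left_overhang, "ATCC")
  expect_equal(insert$right_overhang, "TATG")  # revcomp of position-1 reverse CATA
})

test_that("digesting the destination vector yields backbone and stuffer", {
  frags <- digest(lib$sequences$pDV)
  expect_length(frags, 2)
  backbone <- Filter(function(f) count_sites(nuc_seq(f$bases)) == 0, frags)[[1]]
  stuffer <- Filter(function(f) count_sites(nuc_seq(f$bases)) > 0, frags)[[1]]
  expect_equal(backbone$left_overhang, "CCAT")
  expect_equal(backbone$right_overhang, "ATCC")
  expect_equal(count_sites(nuc_seq(stuffer$bases)), 2L)  # sites go with the stuffer
})

test_that("religating all fragments of a plasmid regenerates it up to rotation", {
  for (id in c("pMV1", "pMV7", "pDV")) {
    pl <- lib$sequences[[id]]
    frags <- digest(pl)
    back <- ligate_fragments(frags, circular = TRUE)
    expect_true(is_rotation_of(back$bases, pl$bases))
  }
})

test_that("digestion without a site returns the molecule with a no-cut flag", {
  res <- digest(lib$sequences$pUC57)
  expect_true(attr(res, "no_cut"))
  expect_equal(res[[1]]$bases, lib$sequences$pUC57$bases)
})

test_that("a full six-module reaction yields the unique expected product", {
  ids <- c("pMV8", "pMV2", "pMV4", "pMV23", "pMV6", "pMV10")
  res <- assemble(lib$sequences$pDV, lib$sequences[ids])
  expect_equal(res$junctions,
               c("ATCC", "TATG", "GAAC", "CGCA", "CAGG", "AGCA", "CCAT"))
  expect_equal(res$diagnostics$bsai_sites_in_product, 0L)
  expect_false(res$diagnostics$stuffer_present)
  expect_equal(res$diagnostics$modules_in_order, ids)
  expect_equal(res$product$topology, "circular")
  # conservation: every fragment base used, each junction 4-mer counted once
  expect_equal(seq_length(res$product), sum(res$fragment_bp) - 4L * 7L)
  # the product is refractory to re-digestion
  expect_true(attr(digest(res$product), "no_cut"))
})

test_that("assembly is invariant to module input order", {
  ids <- c("pMV13", "pMV17", "pMV22", "pMV42", "pMV6", "pMV16")
  a <- assemble(lib$sequences$pDV, lib$sequences[ids])
  b <- assemble(lib$sequences$pDV, lib$sequences[rev(ids)])
  expect_equal(a$product$bases, b$product$bases)
  expect_equal(a$diagnostics$modules_in_order, b$diagnostics$modules_in_order)
})

test_that("missing and duplicated positions are first-class errors", {
  ids5 <- c("pMV14", "pMV1", "pMV4", "pMV23", "pMV7")  # no position 5
  expect_error(assemble(lib$sequences$pDV, lib$sequences[ids5]),
               class = "gg_incomplete_path")
  expect_error(assemble(lib$sequences$pDV, lib$sequences[ids5]),
               regexp = "position.*5")
  ids7 <- c("pMV14", "pMV1", "pMV2", "pMV4", "pMV23", "pMV6", "pMV7")
  expect_error(assemble(lib$sequences$pDV, lib$sequences[ids7]),
               class = "gg_ambiguous_assembly")
})

test_that("a corrupted overhang gives a no-closure error", {
  pl <- lib$sequences$pMV6
  b <- pl$bases
  # mutate the reverse-cassette overhang of the position-5 module
  # (top strand AGCA|A|GAGACC -> AGTA|A|GAGACC), so the released insert can
  # no longer ligate to the position-6 module
  i <- regexpr("AGCAAGAGACC", b, fixed = TRUE)
  expect_gt(i, 0)
  substr(b, i + 2, i + 2) <- "T"
  broken <- nuc_seq(b, name = "pMV6_broken", topology = "circular")
  mods <- c(lib$sequences[c("pMV14", "pMV1", "pMV4", "pMV23")], list(broken),
            lib$sequences["pMV7"])
  expect_error(assemble(lib$sequences$pDV, mods), class = "gg_no_closure")
})

test_that("verify_product confirms order, site loss, and the diagnostic digest", {
  ids <- c("pMV46", "pMV19", "pMV3", "pMV5", "pMV6", "pMV12")
  res <- assemble(lib$sequences$pDV, lib$sequences[ids])
  rep <- verify_product(res, expected = ids)
  expect_true(all(rep$pass))
  # wrong expectation is caught
  expect_false(all(verify_product(res, expected = rev(ids))$pass))
  # re-inserting a recognition site makes the BsaI check fail
  doped <- res
  doped$diagnostics$bsai_sites_in_product <- 1L
  expect_false(all(verify_product(doped, expected = ids)$pass))
  # EcoRV diagnostic sizes match brute-force site arithmetic
  sizes <- attr(rep, "diagnostic_fragments_bp")
  ecorv <- gg_enzymes()$EcoRV
  pos <- find_sites(res$product, ecorv)$position
  expect_equal(sum(sizes), if (length(pos)) seq_length(res$product) else 0L)
  expect_length(sizes, length(pos))
})

test_that("the dilution formula and its inverse are exact", {
  expect_equal(dilution_fmol(100, 3800), 40)
  expect_equal(dilution_fmol(0, 5000), 0)
  set.seed(79)
  for (i in 1:10) {
    ng <- runif(1, 10, 500); bp <- sample(1000:10000, 1)
    expect_equal(dilution_ng(dilution_fmol(ng, bp), bp), ng)
  }
  expect_error(dilution_fmol(10, 0), class = "gg_value_error")
})
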