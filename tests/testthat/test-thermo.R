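test_that("perfect-match duplex energy equals the independent parameter sum", {
  # frozen values computed with an independent table-lookup sum over the
  # published unified parameters for this 20-mer
  e <- duplex_energy("AGCGTCTGAATTCCAGGCAT", revcomp("AGCGTCTGAATTCCAGGCAT"))
  expect_equal(e$dH, -153.7, tolerance = 1e-9)
  expect_equal(e$dS, -412.9, tolerance = 1e-9)
  expect_equal(e$n_mismatches, 0L)
})

test_that("duplex_energy rejects invalid input", {
  expect_error(duplex_energy("ACGTACG", "CGTACGT"), class = "gg_value_error")     # < 8 nt
  expect_error(duplex_energy("ACGTACGTA", "ACGTACGT"), class = "gg_value_error")  # lengths
  expect_error(duplex_energy("ACGTNCGTA", revcomp("ACGTNCGTA")),
               class = "gg_ambiguity_error")
  # a primer against itself is far from complementary: rejected, never "more stable"
  p <- "AGCGTCTGAATTCCAGGCAT"
  res <- try(duplex_energy(p, p), silent = TRUE)
  if (!inherits(res, "try-error")) {
    expect_gt(duplex_dG(res), duplex_dG(duplex_energy(p, revcomp(p))))
  } else {
    expect_s3_class(attr(res, "condition"), "error")
  }
})

test_that("a single internal mismatch destabilizes the duplex", {
  set.seed(5)
  for (i in 1:25) {
    p <- rand_dna(20)
    t_pm <- revcomp(p)
    e_pm <- duplex_energy(p, t_pm)
    j <- sample(3:18, 1)             # internal position on the template
    cur <- substr(t_pm, j, j)
    repl <- setdiff(c("A", "C", "G", "T"), c(cur, revcomp(substr(p, 21 - j, 21 - j))))[1]
    t_mm <- t_pm
    substr(t_mm, j, j) <- repl
    e_mm <- duplex_energy(p, t_mm)
    expect_equal(e_mm$n_mismatches, 1L)
    expect_gt(duplex_dG(e_mm), duplex_dG(e_pm))
    expect_gt(primer_tm(p)$tm_C, primer_tm(p, t_mm)$tm_C)
  }
})

test_that("Tm matches an independent implementation within 0.5 C", {
  # frozen spot check (independent implementation of the same parameter set)
  cond0 <- reaction_conditions(monovalent_mM = 50, divalent_mM = 0,
                               dNTP_mM = 0, primer_nM = 500)
  expect_equal(primer_tm("CGGTGCGCCTTGTTCGTGCT", cond = cond0)$tm_C,
               63.9749, tolerance = 1e-3)
  set.seed(17)
  for (i in 1:100) {
    p <- rand_dna(sample(18:25, 1))
    expect_equal(primer_tm(p, cond = cond0)$tm_C,
                 oracle_tm(p, na_mM = 50, mg_mM = 0, dntp_mM = 0, ct_nM = 500),
                 tolerance = 0.5)
  }
  # and under the default divalent-containing conditions
  cond1 <- reaction_conditions()
  set.seed(18)
  for (i in 1:20) {
    p <- rand_dna(20)
    expect_equal(primer_tm(p, cond = cond1)$tm_C,
                 oracle_tm(p, na_mM = 50, mg_mM = 1.5, dntp_mM = 0.2, ct_nM = 500),
                 tolerance = 0.5)
  }
})

test_that("Tm increases monotonically with monovalent salt", {
  p <- "AGCGTCTGAATTCCAGGCAT"
  tms <- vapply(c(10, 25, 50, 100, 150, 200), function(na) {
    primer_tm(p, cond = reaction_conditions(monovalent_mM = na, divalent_mM = 0,
                                            dNTP_mM = 0))$tm_C
  }, 0)
  expect_true(all(diff(tms) > 0))
})

test_that("the Taq annealing recommendation is exactly 7 C below Q5", {
  set.seed(29)
  for (i in 1:20) {
    tm <- primer_tm(rand_dna(sample(15:30, 1)))
    ann <- tm$annealing_C_by_polymerase
    expect_equal(ann$taq, ann$q5 - 7)
    expect_lte(ann$q5, 72)
  }
})

test_that("zero primer concentration is rejected", {
  expect_error(primer_tm("AGCGTCTGAATTCCAGGCAT",
                         cond = reaction_conditions(primer_nM = 0)),
               class = "gg_value_error")
})

test_that("pair_tm_difference is symmetric, zero on identity, and compositional", {
  set.seed(31)
  tmpl <- nuc_seq(rand_dna(300), name = "tmpl")
  f <- substr(tmpl$bases, 21, 40)
  r <- revcomp(substr(tmpl$bases, 241, 260))
  expect_equal(pair_tm_difference(f, f, tmpl), 0)
  expect_equal(pair_tm_difference(f, r, tmpl), pair_tm_difference(r, f, tmpl))
  expect_equal(pair_tm_difference(f, r, tmpl),
               abs(primer_tm(f)$tm_C - primer_tm(r)$tm_C))
  expect_error(pair_tm_difference(strrep("ACGT", 5), r, tmpl),
               class = "gg_value_error")
})
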