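test_that("the overhang table matches the published grammar and chains", {
  ot <- overhang_table()
  expect_equal(ot$fwd_overhang, c("ATCC", "TATG", "GAAC", "CGCA", "CAGG", "AGCA"))
  expect_equal(ot$rev_overhang, c("CATA", "GTTC", "TGCG", "CCTG", "TGCT", "ATGG"))
  for (i in 1:5) expect_equal(revcomp(ot$fwd_overhang[i + 1]), ot$rev_overhang[i])
})

test_that("add_tails builds the published tail anatomy and is lossless", {
  set.seed(41)
  cf <- rand_dna(20); cr <- rand_dna(22)
  p <- add_tails(cf, cr, position = 1)
  expect_match(p$fwd$full_sequence, "GGTCTCGATCC", fixed = TRUE)
  expect_match(p$rev$full_sequence, "GGTCTCTCATA", fixed = TRUE)
  # tail segment sits immediately before the core
  expect_equal(p$fwd$full_sequence,
               paste0(p$fwd$segments$mcs_tail, "GGTCTCGATCC", cf))
  expect_equal(strip_tails(p$fwd), cf)
  expect_equal(strip_tails(p$rev), cr)
  expect_equal(nchar(p$fwd$segments$mcs_tail), 25L)
  # segments concatenate to the full sequence for every position
  for (pos in 1:6) {
    tp <- add_tails(cf, cr, pos)
    for (pr in tp) {
      expect_equal(paste(unlist(pr$segments), collapse = ""), pr$full_sequence)
    }
  }
  expect_error(add_tails(cf, cr, position = 7), class = "gg_value_error")
  expect_error(add_tails(rand_dna(10), cr, position = 1), class = "gg_value_error")
})

test_that("complementarity scoring follows the +1/-1 local alignment convention", {
  expect_equal(complementarity_score(strrep("A", 20), strrep("A", 20)), 0)
  p <- "ACGTACGTGGCC"
  expect_equal(complementarity_score(p, revcomp(p)), nchar(p))  # perfect dimer
  # exhaustive offset-scan oracle on random pairs
  score_oracle <- function(a, b) {
    x <- strsplit(a, "")[[1]]; y <- strsplit(rc_oracle(b), "")[[1]]
    best <- 0
    for (sh in -(length(y) - 1):(length(x) - 1)) {
      for (i in max(1, 1 + sh):min(length(x), length(y) + sh)) {
        run <- 0
        for (j in i:min(length(x), length(y) + sh)) {
          run <- run + if (x[j] == y[j - sh]) 1 else -1
          best <- max(best, run)
        }
      }
    }
    best
  }
  set.seed(43)
  for (i in 1:10) {
    a <- rand_dna(sample(8:15, 1)); b <- rand_dna(sample(8:15, 1))
    expect_equal(complementarity_score(a, b), score_oracle(a, b))
  }
})

test_that("qc_pair always reports exactly the 13 published metrics, in order", {
  metrics <- c("primer_tm", "length", "self_complementarity",
               "three_prime_complementarity", "matrix_complementarity",
               "three_prime_matrix_complementarity", "gc_percent", "gc_clamp",
               "three_prime_stability", "three_prime_gc_percent",
               "pair_tm_difference", "cross_complementarity",
               "cross_three_prime_complementarity")
  set.seed(47)
  tmpl <- nuc_seq(rand_dna(400), name = "t")
  f <- substr(tmpl$bases, 1, 20)
  r <- revcomp(substr(tmpl$bases, 381, 400))
  qc <- qc_pair(f, r, tmpl)
  expect_equal(qc$metric, metrics)
  # a primer pair that is a perfect dimer must hard-fail
  qc_dimer <- qc_pair(f, revcomp(f), tmpl)
  expect_equal(qc_dimer$value[qc_dimer$metric == "cross_complementarity"], 20)
  expect_equal(qc_overall(qc_dimer), "fail")
  expect_equal(nrow(qc_dimer), 13L)
  # determinism: identical inputs give identical reports
  expect_identical(tidy(qc), tidy(qc_pair(f, r, tmpl)))
})

test_that("cores missing from the template flag the matrix metrics and fail", {
  set.seed(49)
  tmpl <- nuc_seq(rand_dna(300))
  qc <- qc_pair(rand_dna(20), rand_dna(20), tmpl)
  expect_equal(qc_overall(qc), "fail")
  expect_false(qc$pass[qc$metric == "matrix_complementarity"])
})

test_that("design_core_primers returns in-range cores that pass QC", {
  set.seed(53)
  tmpl <- nuc_seq(rand_dna(500), name = "fixture")
  d <- design_core_primers(tmpl)
  expect_gte(nchar(d$core_fwd), 15); expect_lte(nchar(d$core_fwd), 25)
  expect_gte(nchar(d$core_rev), 15); expect_lte(nchar(d$core_rev), 25)
  expect_true(d$feasible)
  qc <- qc_pair(d$core_fwd, d$core_rev, tmpl)
  expect_true(qc_overall(qc) != "fail")
  expect_error(design_core_primers(nuc_seq(rand_dna(39))), class = "gg_design_error")
})

test_that("the designed pair is brute-force optimal on a 60-nt toy template", {
  set.seed(59)
  tmpl <- nuc_seq(rand_dna(60))
  d <- design_core_primers(tmpl)
  lens <- qc_thresholds()$design_len_range
  pens <- c()
  for (lf in lens[1]:lens[2]) {
    for (lr in lens[1]:lens[2]) {
      cf <- substr(tmpl$bases, 1, lf)
      cr <- revcomp(substr(tmpl$bases, 60 - lr + 1, 60))
      pens <- c(pens, pair_penalty(cf, cr)$penalty)
    }
  }
  expect_equal(d$penalty, min(pens))
})

test_that("design_module_primers composes design, tails, QC and Tm", {
  set.seed(61)
  promoter <- nuc_seq(rand_dna(450), name = "promoter_fixture")
  rep2 <- design_module_primers(promoter, position = 2)
  expect_equal(rep2$primers$fwd$segments$overhang, "TATG")
  expect_equal(rep2$primers$rev$segments$overhang, "GTTC")
  expect_equal(rep2$annealing_C_by_polymerase$taq,
               rep2$annealing_C_by_polymerase$q5 - 7)
  expect_equal(nrow(rep2$qc), 13L)

  # CDS containing one BsaI site: a 1-edit plan, and the simulated amplicon's
  # insert region carries no BsaI site beyond the two added cassettes
  cds <- cds_with_sites(n_codons = 120, n_sites = 1)
  rep3 <- design_module_primers(nuc_seq(cds, name = "cds"), position = 3, frame = 0)
  expect_equal(nrow(rep3$domestication$edits), 1L)
  expect_equal(rep3$domestication$residual_sites, 0L)
  expect_equal(count_sites(rep3$amplicon), 2L)  # only the tail cassettes remain

  # unremovable site in a noncoding module: warn + fusion-PCR suggestion
  nc <- rand_dna(200)
  substr(nc, 100, 105) <- "GGTCTC"
  repn <- design_module_primers(nuc_seq(nc, name = "nc"), position = 2,
                                frame = "noncoding")
  expect_equal(repn$domestication$strategy, "fusion_pcr_suggested")
  expect_equal(repn$status, "warn")
})

test_that("digesting a designed amplicon releases the position-specific overhangs", {
  set.seed(67)
  ot <- overhang_table()
  rand_dna_nosite <- function(n) {
    repeat {
      s <- rand_dna(n)
      if (count_sites(nuc_seq(s)) == 0L) return(s)
    }
  }
  for (pos in 1:6) {
    target <- nuc_seq(rand_dna_nosite(300), name = sprintf("t%d", pos))
    rep <- design_module_primers(target, position = pos)
    amp <- rep$amplicon
    frags <- digest(amp)
    insert <- Filter(function(f) !is.na(f$left_overhang) &&
                       !is.na(f$right_overhang), frags)
    # the released insert carries fwd(p) on its left and revcomp(rev(p)) on
    # its right, both read on the top strand in product orientation
    expect_length(insert, 1)
    expect_equal(insert[[1]]$left_overhang, ot$fwd_overhang[pos])
    expect_equal(insert[[1]]$right_overhang, revcomp(ot$rev_overhang[pos]))
  }
})
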