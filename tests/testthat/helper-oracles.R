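# Independent oracles used across the suite. These deliberately do not share
# code (or data-file parsing) with the package: the thermodynamic oracle
# carries its own copy of the published unified nearest-neighbor constants
# and its own Tm formula; the site-scan oracle is a naive substring scan.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rc_oracle <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(s, "")[[1]]]), collapse = "")
}

# --- thermodynamic oracle ---------------------------------------------------

ORACLE_NN <- list(
  "AA/TT" = c(-7.9, -22.2), "AT/TA" = c(-7.2, -20.4), "TA/AT" = c(-7.2, -21.3),
  "CA/GT" = c(-8.5, -22.7), "GT/CA" = c(-8.4, -22.4), "CT/GA" = c(-7.8, -21.0),
  "GA/CT" = c(-8.2, -22.2), "CG/GC" = c(-10.6, -27.2), "GC/CG" = c(-9.8, -24.4),
  "GG/CC" = c(-8.0, -19.9)
)
ORACLE_INIT <- list("A" = c(2.3, 4.1), "T" = c(2.3, 4.1),
                    "G" = c(0.1, -2.8), "C" = c(0.1, -2.8))

oracle_tm <- function(primer, na_mM = 50, mg_mM = 0, dntp_mM = 0, ct_nM = 500) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  p <- strsplit(primer, "")[[1]]
  n <- length(p)
  dH <- 0; dS <- 0
  for (i in 1:(n - 1)) {
    key <- paste0(p[i], p[i + 1], "/", comp[p[i]], comp[p[i + 1]])
    v <- ORACLE_NN[[key]]
    if (is.null(v)) {
      # read the stack from the opposite strand
      key2 <- paste0(comp[p[i + 1]], comp[p[i]], "/", p[i + 1], p[i])
      v <- ORACLE_NN[[key2]]
    }
    dH <- dH + v[1]; dS <- dS + v[2]
  }
  for (b in c(p[1], p[n])) {
    dH <- dH + ORACLE_INIT[[b]][1]; dS <- dS + ORACLE_INIT[[b]][2]
  }
  if (primer == rc_oracle(primer)) dS <- dS - 1.4
  na_eq <- na_mM + 120 * sqrt(max(mg_mM - dntp_mM, 0))
  dS_salt <- dS + 0.368 * (n - 1) * log(na_eq / 1000)
  x <- if (primer == rc_oracle(primer)) 1 else 4
  1000 * dH / (dS_salt + 1.987 * log(ct_nM * 1e-9 / x)) - 273.15
}

# --- site-scan oracle -------------------------------------------------------

scan_count_oracle <- function(bases, motif, circular = FALSE) {
  hits <- function(hay, needle) {
    n <- 0L
    for (i in seq_len(nchar(hay) - nchar(needle) + 1L)) {
      if (substr(hay, i, i + nchar(needle) - 1L) == needle) n <- n + 1L
    }
    n
  }
  h <- if (circular) paste0(bases, substr(bases, 1, nchar(motif) - 1L)) else bases
  rc <- rc_oracle(motif)
  if (motif == rc) hits(h, motif) else hits(h, motif) + hits(h, rc)
}

# --- domestication oracle ---------------------------------------------------

# does any single-codon synonymous substitution destroy every BsaI site?
synonymous_escape_exists <- function(bases, frame = 0) {
  gc <- Biostrings::GENETIC_CODE
  repeat {
    sites <- find_sites(nuc_seq(bases), gg_enzymes()$BsaI)
    if (nrow(sites) == 0L) return(TRUE)
    p0 <- sites$position[1]
    cods <- ((p0 - frame) %/% 3):((p0 + 5 - frame) %/% 3)
    cods <- cods[cods >= 0 & (frame + 3 * (cods + 1)) <= nchar(bases)]
    fixed <- FALSE
    for (k in cods) {
      off <- frame + 3 * k + 1
      old <- substr(bases, off, off + 2)
      syn <- names(gc)[gc == gc[[old]]]
      for (new in setdiff(syn, old)) {
        b2 <- bases
        substr(b2, off, off + 2) <- new
        if (nrow(find_sites(nuc_seq(b2), gg_enzymes()$BsaI)) < nrow(sites)) {
          bases <- b2; fixed <- TRUE; break
        }
      }
      if (fixed) break
    }
    if (!fixed) return(FALSE)
  }
}

# CDS fixture with GGTCTC implanted at codon-aligned positions (GGT CTC =
# Gly Leu, so the frame stays stop-free and a synonymous escape exists)
cds_with_sites <- function(n_codons, n_sites) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  repeat {
    s <- paste0("ATG", paste(sample(sense, n_codons - 2, TRUE), collapse = ""), "TAA")
    if (!grepl("GGTCTC", s, fixed = TRUE) && !grepl("GAGACC", s, fixed = TRUE)) break
  }
  slots <- seq(2, n_codons - 3, by = 4)  # codon indices, well separated
  for (k in sample(slots, n_sites)) {
    off <- 3 * k + 1
    substr(s, off, off + 5) <- "GGTCTC"
  }
  s
}

# --- assembly helpers -------------------------------------------------------

is_rotation_of <- function(a, b) {
  nchar(a) == nchar(b) && grepl(a, paste0(b, b), fixed = TRUE)
}
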