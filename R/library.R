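#' Metadata of the shipped module collection
#'
#' The 28-record collection: 26 position-committed modules (5 plasmid-type,
#' 7 promoter, 4 reporter/NLS, 4 fusion/stop, 1 terminator, 5 selection
#' marker), the destination vector (pDV, CmR) and the module cloning vector
#' (pUC57, AmpR). Reporter/NLS modules in position 3 carry no stop codon so
#' they can be fused to position 4.
#'
#' @return Tibble with `id`, `position`, `type_label`, `description`,
#'   `backbone`, `resistance`, `stop_codon_present`.
#' @export
library_metadata <- function() {
  tribble_rows <- list(
    list("pMV14", 1L, "plasmid type", "2u", TRUE),
    list("pMV8",  1L, "plasmid type", "linker (Yip)", TRUE),
    list("pMV13", 1L, "plasmid type", "CEN", TRUE),
    list("pMV46", 1L, "plasmid type", "VI260998 (Yip)", TRUE),
    list("pMV47", 1L, "plasmid type", "IX301997 (Yip)", TRUE),
    list("pMV1",  2L, "Promoter", "GAL1P", TRUE),
    list("pMV2",  2L, "Promoter", "MET25p", TRUE),
    list("pMV17", 2L, "Promoter", "ACT1p", TRUE),
    list("pMV19", 2L, "Promoter", "ADH1p", TRUE),
    list("pMV20", 2L, "Promoter", "CYC1p", TRUE),
    list("pMV21", 2L, "Promoter", "TEF1p", TRUE),
    list("pMV48", 2L, "Promoter", "TDH3p", TRUE),
    list("pMV3",  3L, "Reporter gene", "sfGFP", FALSE),
    list("pMV4",  3L, "Reporter gene", "mCherry", FALSE),
    list("pMV22", 3L, "Reporter gene", "Venus", FALSE),
    list("pMV45", 3L, "NLS sequence", "3SV40NLS", FALSE),
    list("pMV5",  4L, "Cln2-PEST Degron", "CLN2-PEST", TRUE),
    list("pMV23", 4L, "STOP codon", "STOP", TRUE),
    list("pMV42", 4L, "Reporter gene", "mCherry-STOP", TRUE),
    list("pMV44", 4L, "Reporter gene", "sfGFP-STOP", TRUE),
    list("pMV6",  5L, "Terminator", "ADH1t", TRUE),
    list("pMV7",  6L, "Selection marker", "TRP1", TRUE),
    list("pMV10", 6L, "Selection marker", "URA3", TRUE),
    list("pMV12", 6L, "Selection marker", "NatMX", TRUE),
    list("pMV16", 6L, "Selection marker", "LEU2", TRUE),
    list("pMV18", 6L, "Selection marker", "KanMX", TRUE),
    list("pDV",   NA_integer_, "Destination Vector",
         "pUC57 with 2 BsaI sites flanking a LacZ cassette and carrying an SV40 polyA signal",
         TRUE),
    list("pUC57", NA_integer_, "Module Cloning Vector",
         "pUC57 with no BsaI sites and carrying a LacZ cassette", TRUE)
  )
  out <- bind_rows(lapply(tribble_rows, function(r) {
    tibble(id = r[[1]], position = r[[2]], type_label = r[[3]],
           description = r[[4]], stop_codon_present = r[[5]])
  }))
  out$backbone <- "pUC57"
  out$resistance <- ifelse(out$id == "pDV", "CmR", "AmpR")
  out[, c("id", "position", "type_label", "description", "backbone",
          "resistance", "stop_codon_present")]
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# motifs kept out of all generated fixture sequence: BsaI on either strand
# plus the rare AscI/FseI sites (rare by design in the real toolbox, so the
# linearization site of an assembled integration vector stays unique)
FORBIDDEN_MOTIFS <- c("GGTCTC", "GAGACC", "GGCGCGCC", "GGCCGGCC")

random_dna_clean <- function(n, forbid = FORBIDDEN_MOTIFS) {
  repeat {
    s <- random_dna(n)
    if (!any(vapply(forbid, function(m) grepl(m, s, fixed = TRUE), TRUE))) return(s)
  }
}

# random ORF: ATG + clean sense codons (+ stop), free of BsaI
random_orf <- function(n_codons, stop = TRUE) {
  codons <- names(Biostrings::GENETIC_CODE)
  sense <- codons[Biostrings::GENETIC_CODE != "*"]
  stops <- codons[Biostrings::GENETIC_CODE == "*"]
  repeat {
    s <- paste0("ATG", paste(sample(sense, n_codons - 1L, replace = TRUE), collapse = ""),
                if (stop) sample(stops, 1L) else "")
    if (!any(vapply(FORBIDDEN_MOTIFS, function(m) grepl(m, s, fixed = TRUE), TRUE))) return(s)
  }
}

insert_for_entry <- function(entry, loci) {
  d <- entry$description
  switch(entry$type_label,
    "plasmid type" = {
      if (d == "2u") random_dna_clean(1350)
      else if (d == "CEN") random_dna_clean(500)
      else if (d == "linker (Yip)") random_dna_clean(60)
      else {  # targeted-integration modules built from the synthetic loci
        key <- if (grepl("^VI", d)) "chrVI" else "chrIX"
        design_integration_module(loci[[key]], design_primers = FALSE)$sequence$bases
      }
    },
    "Promoter" = random_dna_clean(sample(400:800, 1L)),
    "Reporter gene" = random_orf(240, stop = entry$stop_codon_present),
    "NLS sequence" = random_orf(21, stop = FALSE),
    "Cln2-PEST Degron" = random_orf(180, stop = TRUE),
    "STOP codon" = paste0("TAA", random_dna_clean(24), "TGA"),
    "Terminator" = random_dna_clean(250),
    "Selection marker" = random_orf(sample(250:400, 1L), stop = TRUE),
    abort(sprintf("no sequence generator for type '%s'", entry$type_label))
  )
}

module_plasmid <- function(id, position, insert, backbone_bases, spec) {
  left <- paste0(spec$mcs_tail_fwd, BSAI_MOTIF, spec$spacer_fwd, spec$fwd_overhang)
  right <- paste0(revcomp(spec$rev_overhang), "A", revcomp(BSAI_MOTIF),
                  revcomp(spec$mcs_tail_rev))
  bases <- paste0(backbone_bases, left, insert, right)
  ins_start <- nchar(backbone_bases) + nchar(left) + 1L
  nuc_seq(bases, name = id, topology = "circular",
          features = tibble(
            type = c("backbone", "module_insert"),
            start = c(1L, ins_start),
            end = c(nchar(backbone_bases), ins_start + nchar(insert) - 1L),
            strand = "+",
            label = c("AmpR", id)))
}

#' Build the synthetic module library
#'
#' Deterministically (for a given seed) generates structurally valid
#' placeholder sequences for the whole collection: every module plasmid is a
#' BsaI-free pUC57-like backbone carrying its insert between two convergent
#' BsaI cassettes with the position-specific overhangs; the destination
#' vector carries exactly two BsaI sites flanking a LacZ stuffer, with the
#' SV40 polyA and CmR marker on the backbone. The two targeted-integration
#' modules are built from synthetic 151-bp loci embedded in toy chromosome
#' segments, which are returned alongside for integration simulations.
#' User-supplied real sequences can be injected per id via `sequences`.
#'
#' @param seed Integer RNG seed.
#' @param sequences Optional named list of circular [nuc_seq()] overrides
#'   keyed by library id.
#' @return An object of class `gg_library`: `entries` (metadata tibble),
#'   `sequences` (named list of circular [nuc_seq()]s), `loci` (named list
#'   of [target_locus()] plus toy genome segments), `seed`.
#' @export
build_library <- function(seed = 1L, sequences = list()) {
  entries <- library_metadata()
  lib <- withr::with_seed(as.integer(seed), {
    backbone <- random_dna_clean(2500)
    pdv_backbone <- random_dna_clean(2400)

    loci <- list()
    genomes <- list()
    for (chr in c("chrVI", "chrIX")) {
      coords <- if (chr == "chrVI") c(260998L, 261148L) else c(301997L, 302147L)
      segment <- random_dna_clean(3000)
      locus_seq <- substr(segment, 1425L, 1575L)  # 151 bp at the segment centre
      loci[[chr]] <- target_locus(locus_seq, chromosome = chr,
                                  start = coords[1], end = coords[2])
      genomes[[chr]] <- nuc_seq(segment, name = paste0(chr, "_segment"))
    }

    seqs <- list()
    for (i in seq_len(nrow(entries))) {
      entry <- entries[i, ]
      if (entry$id %in% names(sequences)) {
        seqs[[entry$id]] <- as_nuc_seq(sequences[[entry$id]])
      } else if (entry$id == "pDV") {
        # junction bases can, rarely, complete an unintended recognition site;
        # resample the variable parts until the molecule has exactly 2
        repeat {
          lacz <- random_dna_clean(800)
          polyA <- random_dna_clean(120)
          bases <- paste0(pdv_backbone, "ATCC", "A", revcomp(BSAI_MOTIF),
                          lacz, BSAI_MOTIF, "G", "CCAT", polyA)
          pdv <- nuc_seq(bases, name = "pDV", topology = "circular",
            features = tibble(
              type = c("backbone", "stuffer", "polyA"),
              start = c(1L, nchar(pdv_backbone) + 1L,
                        nchar(bases) - nchar(polyA) + 1L),
              end = c(nchar(pdv_backbone),
                      nchar(bases) - nchar(polyA), nchar(bases)),
              strand = "+", label = c("CmR", "LacZ", "SV40_polyA")))
          if (count_sites(pdv) == 2L) break
        }
        seqs[[entry$id]] <- pdv
      } else if (entry$id == "pUC57") {
        repeat {
          cassette <- random_dna_clean(800)
          puc <- nuc_seq(paste0(backbone, cassette), name = "pUC57",
                         topology = "circular",
                         features = tibble(
                           type = c("backbone", "lacZ"),
                           start = c(1L, nchar(backbone) + 1L),
                           end = c(nchar(backbone), nchar(backbone) + nchar(cassette)),
                           strand = "+", label = c("AmpR", "LacZ")))
          if (count_sites(puc) == 0L) break
        }
        seqs[[entry$id]] <- puc
      } else {
        repeat {
          insert <- insert_for_entry(entry, loci)
          pl <- module_plasmid(entry$id, entry$position, insert, backbone,
                               position_tail_spec(entry$position))
          if (count_sites(pl) == 2L) break
        }
        seqs[[entry$id]] <- pl
      }
    }
    list(seqs = seqs, loci = loci, genomes = genomes)
  })
  structure(list(entries = entries, sequences = lib$seqs, loci = lib$loci,
                 genomes = lib$genomes, seed = as.integer(seed)),
            class = "gg_library")
}

#' @export
print.gg_library <- function(x, ...) {
  n_mod <- sum(!is.na(x$entries$position))
  cat(sprintf("<module library> %d records (%d modules + pDV + pUC57), seed %d\n",
              nrow(x$entries), n_mod, x$seed))
  counts <- table(factor(x$entries$position, levels = 1:6))
  cat("modules per position:", paste(as.integer(counts), collapse = " "), "\n")
  invisible(x)
}

#' Number of distinct six-module expression vectors
#'
#' Product over positions 1-6 of the number of available modules. An empty
#' position makes assembly impossible, so the count is 0 (with a warning).
#'
#' @param lib A `gg_library`.
#' @return Integer combination count.
#' @export
count_combinations <- function(lib) {
  stopifnot(inherits(lib, "gg_library"))
  counts <- vapply(1:6, function(p) sum(lib$entries$position %in% p), 0L)
  if (any(counts == 0L)) {
    warn(sprintf("no modules available for position%s %s",
                 if (sum(counts == 0L) > 1L) "s" else "",
                 paste(which(counts == 0L), collapse = ", ")))
    return(0L)
  }
  prod(counts)
}

#' Modules available at each position
#' @param lib A `gg_library`.
#' @param position Position 1-6.
#' @return Character vector of module ids.
#' @export
modules_at <- function(lib, position) {
  lib$entries$id[lib$entries$position %in% position]
}

#' Assemble one combination from the library
#'
#' Convenience wrapper: picks one module id per position (defaulting to the
#' first listed) and runs [assemble()] against the library's destination
#' vector.
#'
#' @param lib A `gg_library`.
#' @param ids Character vector of six module ids covering positions 1-6.
#' @return A `gg_assembly`.
#' @export
assemble_combination <- function(lib, ids = vapply(1:6, function(p) modules_at(lib, p)[1L], "")) {
  stopifnot(inherits(lib, "gg_library"))
  assemble(lib$sequences$pDV, lib$sequences[ids])
}
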