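#' PCR reaction conditions
#'
#' Ion and strand concentrations used by the melting-temperature model.
#' Divalent cations are converted to an equivalent monovalent concentration
#' after subtracting dNTPs (which chelate Mg2+ nearly stoichiometrically):
#' `Na_eq = monovalent + 120 * sqrt(max(divalent - dNTP, 0))`, all in mM.
#'
#' Defaults are ordinary PCR conditions: 50 mM monovalent salt, 1.5 mM Mg2+,
#' 0.2 mM dNTPs, 500 nM of each primer.
#'
#' @param monovalent_mM,divalent_mM,dNTP_mM Concentrations in mM.
#' @param primer_nM Total primer strand concentration in nM.
#' @return An object of class `gg_conditions`.
#' @export
reaction_conditions <- function(monovalent_mM = 50, divalent_mM = 1.5,
                                dNTP_mM = 0.2, primer_nM = 500) {
  vals <- c(monovalent_mM, divalent_mM, dNTP_mM, primer_nM)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("reaction conditions must be finite and non-negative", class = "gg_value_error")
  }
  structure(list(monovalent_mM = monovalent_mM, divalent_mM = divalent_mM,
                 dNTP_mM = dNTP_mM, primer_nM = primer_nM),
            class = "gg_conditions")
}

effective_monovalent_mM <- function(cond) {
  free_div <- max(cond$divalent_mM - cond$dNTP_mM, 0)
  cond$monovalent_mM + 120 * sqrt(free_div)
}

nn_tables <- function() {
  if (is.null(the$nn)) {
    read_tbl <- function(f) {
      d <- utils::read.delim(system.file("extdata", f, package = "goldenr"),
                             comment.char = "#", stringsAsFactors = FALSE)
      stats::setNames(lapply(seq_len(nrow(d)), function(i) c(d$dH[i], d$dS[i])), d$key)
    }
    the$nn <- read_tbl("nn_unified.tsv")
    the$imm <- read_tbl("nn_mismatch.tsv")
  }
  list(nn = the$nn, imm = the$imm)
}

lookup_stack <- function(key, tab) {
  v <- tab[[key]]
  if (is.null(v)) {
    # same duplex read from the other strand: XY/ZW == WZ/YX
    p <- strsplit(key, "/")[[1]]
    rkey <- paste0(stringi::stri_reverse(p[2]), "/", stringi::stri_reverse(p[1]))
    v <- tab[[rkey]]
  }
  v
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

#' Nearest-neighbor duplex energy
#'
#' Sums unified nearest-neighbor enthalpy/entropy terms (plus initiation, and
#' the symmetry term for self-complementary duplexes) over the duplex formed
#' by `primer` and `template`. `template` is the strand the primer anneals
#' to, written 5'->3'; a perfect match therefore means
#' `template == revcomp(primer)`. Stacks containing a single internal
#' mismatch use the published single-mismatch parameters; terminal or
#' adjacent mismatches and more than 3 mismatches are rejected.
#'
#' @param primer,template Equal-length DNA strings, >= 8 nt, no `N`.
#' @return An object of class `gg_duplex_energy` with elements `dH`
#'   (kcal/mol), `dS` (cal/(mol K)) and `source_terms` (tibble of stacked-pair
#'   contributions including initiation).
#' @export
duplex_energy <- function(primer, template) {
  primer <- toupper(primer); template <- toupper(template)
  check_dna(primer); check_dna(template)
  if (grepl("N", primer) || grepl("N", template)) {
    abort("N not allowed in thermodynamic calculations", class = "gg_ambiguity_error")
  }
  n <- nchar(primer)
  if (nchar(template) != n) abort("primer and template lengths differ", class = "gg_value_error")
  if (n < 8L) abort("duplex shorter than 8 nt", class = "gg_value_error")

  p <- strsplit(primer, "")[[1]]
  # the paired (bottom) strand aligned under the primer, 3'->5'
  q <- rev(strsplit(template, "")[[1]])
  matched <- q == comp_base[p]
  n_mm <- sum(!matched)
  if (n_mm > 3L) abort("more than 3 mismatches", class = "gg_value_error")
  if (!matched[1L] || !matched[n]) {
    abort("terminal mismatches are not supported", class = "gg_value_error")
  }
  tabs <- nn_tables()
  terms <- vector("list", n + 1L)
  term_key <- character(n + 1L)
  for (i in seq_len(n - 1L)) {
    key <- paste0(p[i], p[i + 1L], "/", q[i], q[i + 1L])
    if (matched[i] && matched[i + 1L]) {
      v <- lookup_stack(key, tabs$nn)
    } else if (matched[i] || matched[i + 1L]) {
      v <- lookup_stack(key, tabs$imm)
    } else {
      abort("adjacent mismatches are not supported", class = "gg_value_error")
    }
    if (is.null(v)) abort(sprintf("no parameters for stack %s", key), class = "gg_value_error")
    terms[[i]] <- v; term_key[i] <- key
  }
  init1 <- if (p[1L] %in% c("A", "T")) "init_A/T" else "init_G/C"
  init2 <- if (p[n] %in% c("A", "T")) "init_A/T" else "init_G/C"
  terms[[n]] <- tabs$nn[[init1]]; term_key[n] <- init1
  terms[[n + 1L]] <- tabs$nn[[init2]]; term_key[n + 1L] <- init2
  if (n_mm == 0L && primer == revcomp(primer)) {
    terms <- c(terms, list(tabs$nn[["sym"]])); term_key <- c(term_key, "sym")
  }
  dH <- sum(vapply(terms, `[`, 0, 1L))
  dS <- sum(vapply(terms, `[`, 0, 2L))
  structure(list(
    dH = dH, dS = dS, n_mismatches = n_mm,
    self_complementary = n_mm == 0L && primer == revcomp(primer),
    source_terms = tibble(term = term_key,
                          dH = vapply(terms, `[`, 0, 1L)[seq_along(term_key)],
                          dS = vapply(terms, `[`, 0, 2L)[seq_along(term_key)])
  ), class = "gg_duplex_energy")
}

#' Free energy of a duplex at a given temperature
#' @param energy A `gg_duplex_energy`.
#' @param temp_C Temperature in Celsius (default 37).
#' @return dG in kcal/mol.
#' @export
duplex_dG <- function(energy, temp_C = 37) {
  energy$dH - (temp_C + 273.15) * energy$dS / 1000
}

GAS_CONSTANT <- 1.987  # cal/(mol K)

#' Melting temperature with salt correction
#'
#' Two-state nearest-neighbor Tm:
#' `Tm = 1000*dH / (dS_salt + R*ln(CT/x)) - 273.15`, where `x` is 4 for
#' non-self-complementary duplexes (each strand at CT/2) and 1 for
#' self-complementary primers, and the entropy is salt-corrected with the
#' divalent-aware monovalent equivalent:
#' `dS_salt = dS + 0.368 * (N-1) * ln([Na_eq])`.
#'
#' Annealing recommendations for both supported polymerase profiles are
#' reported: the Q5 recommendation is `min(Tm) + 1` capped at 72 C (a
#' documented heuristic), and the Taq recommendation is exactly 7 C lower.
#'
#' @param primer Primer sequence 5'->3'.
#' @param template Strand the primer anneals to, 5'->3'; `NULL` means the
#'   perfect complement.
#' @param cond A [reaction_conditions()] object.
#' @return An object of class `gg_tm` with `tm_C`, `dH`, `dS` and
#'   `annealing_C_by_polymerase` (named list with `q5` and `taq`).
#' @export
primer_tm <- function(primer, template = NULL, cond = reaction_conditions()) {
  stopifnot(inherits(cond, "gg_conditions"))
  if (cond$primer_nM <= 0) abort("primer concentration must be positive", class = "gg_value_error")
  if (is.null(template)) template <- revcomp(primer)
  en <- duplex_energy(primer, template)
  n <- nchar(primer)
  na_eq <- effective_monovalent_mM(cond)
  if (na_eq <= 0) abort("effective monovalent concentration must be positive", class = "gg_value_error")
  dS_salt <- en$dS + 0.368 * (n - 1L) * log(na_eq / 1000)
  ct <- cond$primer_nM * 1e-9
  x <- if (en$self_complementary) 1 else 4
  tm_C <- 1000 * en$dH / (dS_salt + GAS_CONSTANT * log(ct / x)) - 273.15
  q5 <- min(tm_C + 1, 72)
  structure(list(tm_C = tm_C, dH = en$dH, dS = en$dS, dS_salt = dS_salt,
                 n_mismatches = en$n_mismatches,
                 annealing_C_by_polymerase = list(q5 = q5, taq = q5 - 7)),
            class = "gg_tm")
}

#' @export
print.gg_tm <- function(x, ...) {
  cat(sprintf("Tm = %.2f C (dH %.1f kcal/mol, dS %.1f cal/mol/K)\n",
              x$tm_C, x$dH, x$dS))
  cat(sprintf("annealing: Q5 %.1f C, Taq %.1f C\n",
              x$annealing_C_by_polymerase$q5, x$annealing_C_by_polymerase$taq))
  invisible(x)
}

locate_primer <- function(primer, template, max_mismatch = 3L) {
  # best annealing site of `primer` on either strand of `template`;
  # returns the top-strand segment the primer's duplex covers
  tmpl <- as_nuc_seq(template)
  b <- tmpl$bases
  n <- nchar(primer)
  best <- NULL
  for (strand in c("+", "-")) {
    s <- if (strand == "+") b else revcomp(b)
    L <- nchar(s)
    if (L < n) next
    hit <- stri_starts(s, primer)
    if (length(hit)) {
      cand <- list(start = hit[1], strand = strand, mismatches = 0L,
                   site = substr(s, hit[1], hit[1] + n - 1L))
    } else {
      pv <- strsplit(primer, "")[[1]]
      sv <- strsplit(s, "")[[1]]
      mm <- vapply(seq_len(L - n + 1L), function(i) {
        sum(sv[i:(i + n - 1L)] != pv)
      }, 0L)
      i <- which.min(mm)
      if (mm[i] > max_mismatch) next
      cand <- list(start = i, strand = strand, mismatches = mm[i],
                   site = substr(s, i, i + n - 1L))
    }
    if (is.null(best) || cand$mismatches < best$mismatches) best <- cand
  }
  best
}

#' Tm difference of a primer pair on a template
#'
#' Each primer is located on its strand of the template (exact match first,
#' then mismatch-tolerant up to 3 mismatches) and its Tm computed against the
#' genomic site; the absolute difference is returned.
#'
#' @param fwd,rev Primer sequences 5'->3'.
#' @param template A [nuc_seq()] (or character string).
#' @param cond A [reaction_conditions()] object.
#' @return Absolute Tm difference in Celsius.
#' @export
pair_tm_difference <- function(fwd, rev, template, cond = reaction_conditions()) {
  tms <- vapply(c(fwd, rev), function(p) {
    loc <- locate_primer(p, template)
    if (is.null(loc)) {
      abort("primer not found on template (more than 3 mismatches everywhere)",
            class = "gg_value_error")
    }
    primer_tm(p, revcomp(loc$site), cond)$tm_C
  }, 0)
  abs(tms[[1]] - tms[[2]])
}
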