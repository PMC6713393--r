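#' Sequence primitives and a generic type IIS restriction model
#'
#' `nuc_seq()` is the package's basic sequence record: a named DNA string with
#' an explicit topology. Topology is never inferred -- circular plasmids must
#' be declared circular, since restriction scanning and digestion treat the
#' origin-spanning region differently.
#'
#' @param bases Character scalar over the alphabet `A`, `C`, `G`, `T`, `N`.
#' @param name Identifier for the sequence.
#' @param topology `"linear"` or `"circular"`.
#' @param features Optional tibble of annotations with columns
#'   `type`, `start`, `end`, `strand`, `label` (1-based inclusive coordinates).
#' @return An object of class `nuc_seq`.
#' @examples
#' p <- nuc_seq("ATGGGTCTCTAA", name = "toy", topology = "linear")
#' seq_length(p)
#' @export
nuc_seq <- function(bases, name = "seq", topology = c("linear", "circular"),
                    features = NULL) {
  topology <- match.arg(topology)
  if (!is.character(bases) || length(bases) != 1L) {
    abort("`bases` must be a single character string", class = "gg_alphabet_error")
  }
  bases <- toupper(bases)
  check_dna(bases)
  if (!nzchar(bases)) abort("empty sequence", class = "gg_value_error")
  if (is.null(features)) {
    features <- tibble(type = character(), start = integer(), end = integer(),
                       strand = character(), label = character())
  }
  structure(list(name = name, bases = bases, topology = topology,
                 features = as_tibble(features)),
            class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  cat(sprintf("<nuc_seq> %s: %d bp, %s", x$name, nchar(x$bases), x$topology))
  if (nrow(x$features)) cat(sprintf(", %d features", nrow(x$features)))
  cat("\n")
  b <- x$bases
  cat(" ", if (nchar(b) > 60) paste0(substr(b, 1, 57), "...") else b, "\n")
  invisible(x)
}

#' Coerce to a nuc_seq
#'
#' Character strings become linear sequences; `nuc_seq` objects pass through.
#' @param x A character scalar or `nuc_seq`.
#' @param ... Passed to [nuc_seq()] for character input.
#' @return A `nuc_seq`.
#' @export
as_nuc_seq <- function(x, ...) {
  if (inherits(x, "nuc_seq")) return(x)
  if (is.character(x) && length(x) == 1L) return(nuc_seq(x, ...))
  abort("cannot coerce to nuc_seq", class = "gg_value_error")
}

#' @rdname nuc_seq
#' @param x A `nuc_seq` or character scalar.
#' @export
seq_bases <- function(x) if (inherits(x, "nuc_seq")) x$bases else x

#' @rdname nuc_seq
#' @export
seq_length <- function(x) nchar(seq_bases(x))

check_dna <- function(x, allow_n = TRUE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  bad <- !grepl(pat, x)
  if (any(bad)) {
    abort(sprintf("non-IUPAC character in sequence (allowed: ACGT%s)",
                  if (allow_n) "N" else ""),
          class = "gg_alphabet_error")
  }
  invisible(x)
}

#' Reverse complement
#'
#' @param seq Character vector of DNA strings (alphabet `ACGTN`).
#' @return Character vector of reverse complements. The operation is an
#'   involution: `revcomp(revcomp(x)) == x`.
#' @examples
#' revcomp("TATG")  # "CATA"
#' @export
revcomp <- function(seq) {
  seq <- toupper(seq)
  check_dna(seq)
  stringi::stri_reverse(chartr("ACGTN", "TGCAN", seq))
}

#' GC content
#'
#' @param seq Character vector of non-empty DNA strings.
#' @return Percentage of G+C bases (0-100). `N` counts toward length only.
#' @examples
#' gc_content("ATGC")  # 50
#' @export
gc_content <- function(seq) {
  seq <- toupper(seq)
  check_dna(seq)
  if (any(!nzchar(seq))) abort("empty sequence", class = "gg_value_error")
  gc <- stringi::stri_count_regex(seq, "[GC]")
  100 * gc / nchar(seq)
}

#' Translate a DNA sequence
#'
#' Standard genetic code; stops are written `*`; a trailing partial codon is
#' dropped. Ambiguous bases (`N`) inside a used codon are rejected, because a
#' synonymous-substitution plan must know the exact protein it preserves.
#'
#' @param seq DNA string or `nuc_seq`.
#' @param frame Reading frame offset 0, 1 or 2.
#' @return Amino-acid string.
#' @examples
#' translate_dna("ATGGGTCTCTAA")  # "MGL*"
#' @export
translate_dna <- function(seq, frame = 0) {
  b <- toupper(seq_bases(seq))
  check_dna(b)
  if (!frame %in% 0:2) abort("frame must be 0, 1 or 2", class = "gg_value_error")
  b <- substr(b, frame + 1L, nchar(b))
  if (nchar(b) < 3L) abort("sequence too short to translate in this frame",
                           class = "gg_value_error")
  b <- substr(b, 1L, 3L * (nchar(b) %/% 3L))
  if (grepl("N", b)) abort("ambiguous base (N) within a codon", class = "gg_ambiguity_error")
  codons <- stringi::stri_sub(b, seq(1L, nchar(b), 3L), length = 3L)
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

#' Restriction enzyme definitions
#'
#' A minimal enzyme model covering the two geometries the toolbox needs:
#' type IIS outside cutters (BsaI: recognition `GGTCTC`, 1-nt spacer, 4-nt
#' 5' overhang) and ordinary palindromic cutters (AscI, FseI, EcoRV), for
#' which only the top-strand cut offset within the site matters here.
#'
#' @param name Enzyme name.
#' @param recognition Recognition sequence (top strand, 5'->3').
#' @param type `"type_iis"` or `"palindromic"`.
#' @param spacer_len Nucleotides between recognition end and the top-strand
#'   cut (type IIS only).
#' @param overhang_len Overhang length in nt (type IIS only).
#' @param cut_offset Top-strand cut offset from recognition start
#'   (palindromic only).
#' @return An object of class `gg_enzyme`.
#' @export
enzyme <- function(name, recognition, type = c("type_iis", "palindromic"),
                   spacer_len = NA_integer_, overhang_len = NA_integer_,
                   cut_offset = NA_integer_) {
  type <- match.arg(type)
  recognition <- toupper(recognition)
  check_dna(recognition, allow_n = FALSE)
  structure(list(name = name, recognition = recognition, type = type,
                 spacer_len = as.integer(spacer_len),
                 overhang_len = as.integer(overhang_len),
                 overhang_kind = if (type == "type_iis") "five_prime" else NA_character_,
                 cut_offset = as.integer(cut_offset)),
            class = "gg_enzyme")
}

#' @rdname enzyme
#' @return `gg_enzymes()` returns the named list of built-in enzymes:
#'   BsaI, AscI, FseI, EcoRV.
#' @export
gg_enzymes <- function() {
  list(
    BsaI  = enzyme("BsaI",  "GGTCTC",   "type_iis", spacer_len = 1L, overhang_len = 4L),
    AscI  = enzyme("AscI",  "GGCGCGCC", "palindromic", cut_offset = 2L),
    FseI  = enzyme("FseI",  "GGCCGGCC", "palindromic", cut_offset = 6L),
    EcoRV = enzyme("EcoRV", "GATATC",   "palindromic", cut_offset = 3L)
  )
}

#' Find recognition sites on both strands
#'
#' Scans the top strand for the recognition motif and its reverse complement.
#' Circular sequences are scanned across the origin; positions are reported
#' modulo the sequence length. Palindromic motifs are reported once, on the
#' plus strand.
#'
#' @param seq A `nuc_seq` (or character, treated as linear).
#' @param enz A `gg_enzyme`.
#' @return Tibble with `position` (0-based offset of the recognition start on
#'   the top strand) and `strand` (`+`/`-`), sorted by position.
#' @examples
#' find_sites(nuc_seq("AAGGTCTCAA"), gg_enzymes()$BsaI)
#' @export
find_sites <- function(seq, enz) {
  stopifnot(inherits(enz, "gg_enzyme"))
  s <- as_nuc_seq(seq)
  motif <- enz$recognition
  rc <- revcomp(motif)
  b <- s$bases
  L <- nchar(b)
  scan_b <- if (s$topology == "circular" && L >= nchar(motif)) {
    paste0(b, substr(b, 1L, nchar(motif) - 1L))
  } else b
  hits_fwd <- stri_starts(scan_b, motif)
  if (motif == rc) {
    pos <- hits_fwd
    strand <- rep("+", length(pos))
  } else {
    hits_rev <- stri_starts(scan_b, rc)
    pos <- c(hits_fwd, hits_rev)
    strand <- c(rep("+", length(hits_fwd)), rep("-", length(hits_rev)))
  }
  keep <- pos <= L  # starts within the sequence proper (1-based)
  pos <- pos[keep]; strand <- strand[keep]
  out <- tibble(position = as.integer(pos - 1L), strand = strand)
  arrange(out, .data$position)
}

stri_starts <- function(x, pattern) {
  m <- stringi::stri_locate_all_fixed(x, pattern, overlap = TRUE)[[1]]
  if (is.na(m[1, 1])) integer() else m[, 1]
}

#' Count sites of an enzyme
#' @inheritParams find_sites
#' @return Integer site count (both strands).
#' @export
count_sites <- function(seq, enz = gg_enzymes()$BsaI) nrow(find_sites(seq, enz))

circ_substr <- function(b, start, len) {
  # 1-based start on a circular string; start may exceed nchar(b)
  L <- nchar(b)
  start <- ((start - 1L) %% L) + 1L
  if (start + len - 1L <= L) return(substr(b, start, start + len - 1L))
  paste0(substr(b, start, L), substr(strrep(b, ceiling(len / L)), 1L, start + len - 1L - L))
}
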