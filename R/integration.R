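#' A genomic target locus for single-copy integration
#'
#' Records a locus (1-based inclusive genomic coordinates) together with its
#' 5' and 3' halves, the homology arms used by the inverted-arm integration
#' design. The split point defaults to the midpoint.
#'
#' @param sequence The locus sequence (character or [nuc_seq()]).
#' @param chromosome Chromosome identifier.
#' @param start,end 1-based inclusive genomic coordinates; when both are
#'   given, `end - start + 1` must equal the sequence length.
#' @param split Length of the 5' arm (default: floor of half the locus).
#' @return An object of class `gg_locus` with `arm5`, `arm3` and metadata.
#' @export
target_locus <- function(sequence, chromosome = NA_character_,
                         start = NA_integer_, end = NA_integer_, split = NULL) {
  s <- as_nuc_seq(sequence)
  L <- seq_length(s)
  if (!is.na(start) && !is.na(end) && end - start + 1L != L) {
    abort(sprintf("coordinate span %d does not match sequence length %d",
                  end - start + 1L, L), class = "gg_value_error")
  }
  split <- split %||% (L %/% 2L)
  if (split < 1L || split >= L) abort("split must leave both arms non-empty",
                                      class = "gg_value_error")
  structure(list(chromosome = chromosome, start = as.integer(start),
                 end = as.integer(end), sequence = s,
                 arm5 = substr(s$bases, 1L, split),
                 arm3 = substr(s$bases, split + 1L, L)),
            class = "gg_locus")
}

#' @export
print.gg_locus <- function(x, ...) {
  cat(sprintf("<target locus> %s:%s-%s (%d bp; arms %d + %d nt)\n",
              x$chromosome, x$start, x$end, seq_length(x$sequence),
              nchar(x$arm5), nchar(x$arm3)))
  invisible(x)
}

#' Design the position-1 single-copy integration module
#'
#' Builds the inverted-arm module: the locus halves placed in reverse order
#' (3' arm upstream of the 5' arm) separated by the rare AscI and FseI
#' sites, so that linearizing the assembled vector between the arms yields a
#' molecule whose terminal homology segments are genome-collinear and whose
#' recombination replaces, rather than duplicates, the target. Arms are
#' reordered but not reverse-complemented. Linearization uses AscI unless
#' AscI already occurs in the arms, in which case FseI; if both rare sites
#' occur in the arms the design fails. Position-1 tailed primers for
#' amplifying the module are designed when the module is long enough
#' (>= 40 nt).
#'
#' @param locus A [target_locus()].
#' @param min_arm Minimum arm length in nt (default 50).
#' @param design_primers Design position-1 tailed primers for the module?
#' @param ... Passed to [design_module_primers()].
#' @return An object of class `gg_integration_module`: `sequence` (the
#'   module [nuc_seq()]), `arm5`, `arm3`, `linearization_enzyme`
#'   (`"AscI"` or `"FseI"`) and optionally `primers` (a
#'   `gg_primer_report`).
#' @examples
#' loc <- target_locus("AAAACCCC", split = 4)
#' design_integration_module(loc, min_arm = 4, design_primers = FALSE)$sequence$bases
#' @export
design_integration_module <- function(locus, min_arm = 50L,
                                      design_primers = TRUE, ...) {
  stopifnot(inherits(locus, "gg_locus"))
  if (nchar(locus$arm5) < min_arm || nchar(locus$arm3) < min_arm) {
    abort(sprintf("homology arms must be >= %d nt (got %d and %d)",
                  min_arm, nchar(locus$arm5), nchar(locus$arm3)),
          class = "gg_value_error")
  }
  enzymes <- gg_enzymes()
  arms <- paste0(locus$arm5, locus$arm3)
  if (count_sites(nuc_seq(arms), enzymes$BsaI) > 0L) {
    abort("homology arms contain a BsaI site; domesticate the locus or move the split",
          class = "gg_design_error")
  }
  has_ascii <- count_sites(nuc_seq(arms), enzymes$AscI) > 0L
  has_fsei <- count_sites(nuc_seq(arms), enzymes$FseI) > 0L
  if (has_ascii && has_fsei) {
    abort("both AscI and FseI occur in the homology arms; no linearization enzyme available",
          class = "gg_design_error")
  }
  lin <- if (has_ascii) "FseI" else "AscI"
  lens <- c(nchar(locus$arm3), 8L, 8L, nchar(locus$arm5))
  nm <- locus$chromosome
  module <- nuc_seq(paste0(locus$arm3, enzymes$AscI$recognition,
                           enzymes$FseI$recognition, locus$arm5),
                    name = paste0("integration_",
                                  if (is.na(nm)) "locus" else nm),
                    features = tibble(
                      type = c("arm3", "AscI", "FseI", "arm5"),
                      start = as.integer(cumsum(c(1L, lens[-4L]))),
                      end = as.integer(cumsum(lens)),
                      strand = "+", label = NA_character_))
  primers <- NULL
  if (design_primers && seq_length(module) >= 40L) {
    primers <- design_module_primers(module, position = 1L, ...)
  }
  structure(list(sequence = module, arm5 = locus$arm5, arm3 = locus$arm3,
                 linearization_enzyme = lin, locus = locus, primers = primers),
            class = "gg_integration_module")
}

#' @export
print.gg_integration_module <- function(x, ...) {
  cat(sprintf("<integration module> %s: %d bp (arm3 + AscI + FseI + arm5), linearize with %s\n",
              x$sequence$name, seq_length(x$sequence), x$linearization_enzyme))
  invisible(x)
}

#' Linearize a circular vector at a unique site
#'
#' Cuts a circular molecule at the single recognition site of an ordinary
#' (palindromic) enzyme and returns the linear molecule starting at the cut.
#' For an assembled vector carrying the inverted-arm module, cutting with
#' AscI (or FseI) falls between the inverted arms, so the 5' arm sits near
#' one end and the 3' arm near the other in genome-collinear order.
#'
#' @param vector A circular [nuc_seq()].
#' @param enz A palindromic [enzyme()] with a single site in `vector`.
#' @return A linear [nuc_seq()].
#' @export
linearize <- function(vector, enz) {
  v <- as_nuc_seq(vector)
  if (v$topology != "circular") abort("vector must be circular", class = "gg_value_error")
  if (enz$type != "palindromic") abort("linearize() expects an ordinary palindromic cutter",
                                       class = "gg_value_error")
  sites <- find_sites(v, enz)
  if (nrow(sites) != 1L) {
    abort(sprintf("%s cuts %d times in %s; exactly one site required",
                  enz$name, nrow(sites), v$name),
          class = "gg_site_count_error")
  }
  cut <- (sites$position[1L] + enz$cut_offset) %% seq_length(v)
  b <- v$bases
  nuc_seq(paste0(substr(b, cut + 1L, nchar(b)), substr(b, 1L, cut)),
          name = paste0(v$name, "_linear"), topology = "linear")
}

#' Simulate homologous recombination of a linearized vector at a locus
#'
#' Models integration as an exact double-crossover at the two homology arms:
#' the genome between (and including) the arms is replaced by
#' `arm5 + payload + arm3`, where the payload is the vector sequence between
#' its arm copies. For the inverted-arm design (arm5 before arm3 on the
#' linear vector) the arm copy number is conserved -- mode `replacement`;
#' re-integration then swaps the existing payload rather than accumulating.
#' For a marker-cut design (vector cut inside a contiguous homology region,
#' so the 3' part precedes the 5' part on the linear molecule) the whole
#' vector inserts between the duplicated homology halves -- mode
#' `duplication`, which leaves twice as many homologous regions available
#' for further integration.
#'
#' @param genome A [nuc_seq()] (chromosome or chromosome segment).
#' @param linear_vector A linear [nuc_seq()] from [linearize()].
#' @param arms `c(arm5, arm3)` homology arm sequences as they occur, in
#'   order, in the pre-integration genome.
#' @return An object of class `gg_recombination`: `integrated_genome`,
#'   `homology_copies` (tibble with pre/post substring counts per arm),
#'   `integration_mode` (`replacement`/`duplication`) and `payload`.
#' @export
simulate_integration <- function(genome, linear_vector, arms) {
  g <- as_nuc_seq(genome)
  v <- as_nuc_seq(linear_vector)
  arm5 <- toupper(arms[[1]]); arm3 <- toupper(arms[[2]])
  gb <- g$bases; vb <- v$bases

  count <- function(hay, needle) stringi::stri_count_fixed(hay, needle)
  g5 <- stri_starts(gb, arm5); g3 <- stri_starts(gb, arm3)
  if (length(g5) == 0L || length(g3) == 0L) {
    abort("homology arm not found in genome", class = "gg_value_error")
  }
  g5 <- g5[1L]
  g3 <- g3[g3 >= g5 + nchar(arm5)]
  if (length(g3) == 0L) {
    abort("arms are not in genome order (arm3 must follow arm5)",
          class = "gg_value_error")
  }
  g3 <- g3[1L]

  v5 <- stri_starts(vb, arm5); v3 <- stri_starts(vb, arm3)
  if (length(v5) == 0L || length(v3) == 0L) {
    abort("homology arm not found on the linear vector", class = "gg_value_error")
  }
  v5 <- v5[1L]; v3 <- v3[length(v3)]

  left <- substr(gb, 1L, g5 - 1L)
  right <- substr(gb, g3 + nchar(arm3), nchar(gb))
  if (v5 + nchar(arm5) <= v3) {
    # inverted-arm design: arm5 ... payload ... arm3 on the linear molecule
    payload <- substr(vb, v5 + nchar(arm5), v3 - 1L)
    integrated <- paste0(left, arm5, payload, arm3, right)
  } else {
    # marker-cut design: the vector was cut inside the contiguous homology
    # region, so the whole linear molecule inserts between the duplicated
    # homology halves
    payload <- vb
    integrated <- paste0(left, arm5, vb, arm3, right)
  }
  ig <- nuc_seq(integrated, name = paste0(g$name, "_integrated"),
                topology = g$topology)
  copies <- tibble(
    arm = c("arm5", "arm3"),
    pre = c(count(gb, arm5), count(gb, arm3)),
    post = c(count(integrated, arm5), count(integrated, arm3))
  )
  mode <- if (all(copies$post == copies$pre)) "replacement" else "duplication"
  structure(list(integrated_genome = ig, homology_copies = copies,
                 integration_mode = mode, payload = payload,
                 arms = c(arm5 = arm5, arm3 = arm3)),
            class = "gg_recombination")
}

#' @export
print.gg_recombination <- function(x, ...) {
  cat(sprintf("<recombination> mode %s; genome %d bp\n", x$integration_mode,
              seq_length(x$integrated_genome)))
  print(x$homology_copies)
  invisible(x)
}

#' Locus-selection criteria
#'
#' Thresholds for [check_locus()]: a usable integration locus must sit far
#' from telomeres and centromeres, inside an ORF-free region of at least
#' 1000 bp, and inside a stretch of at least 200 bp devoid of protein
#' binding sites and noncoding RNAs. The landmark-distance threshold is not
#' a published value and defaults to 20 kb.
#'
#' @param min_orf_free_bp,min_clean_bp,min_landmark_distance_bp Thresholds in bp.
#' @return Named list of thresholds.
#' @export
locus_criteria <- function(min_orf_free_bp = 1000L, min_clean_bp = 200L,
                           min_landmark_distance_bp = 20000L) {
  list(min_orf_free_bp = min_orf_free_bp, min_clean_bp = min_clean_bp,
       min_landmark_distance_bp = min_landmark_distance_bp)
}

#' Check a candidate locus against the selection criteria
#'
#' @param locus A [target_locus()] with genomic coordinates.
#' @param annotations Tibble of genomic intervals (1-based inclusive) with
#'   columns `chrom`, `start`, `end`, `type`; recognised types are `ORF`,
#'   `binding_site`, `ncRNA`, `telomere`, `centromere` (see
#'   [read_annotations()]).
#' @param criteria A [locus_criteria()] list.
#' @param chrom_length Optional chromosome length for a bounds check.
#' @return Tibble with `criterion`, `required_bp`, `observed_bp`, `pass`.
#' @export
check_locus <- function(locus, annotations, criteria = locus_criteria(),
                        chrom_length = NULL) {
  stopifnot(inherits(locus, "gg_locus"))
  if (is.na(locus$start) || is.na(locus$end)) {
    abort("locus must carry genomic coordinates", class = "gg_value_error")
  }
  if (locus$start < 1L || (!is.null(chrom_length) && locus$end > chrom_length)) {
    abort("locus outside annotated chromosome bounds", class = "gg_value_error")
  }
  ann <- annotations[annotations$chrom == locus$chromosome, , drop = FALSE]
  s <- locus$start; e <- locus$end

  gap_around <- function(iv) {
    # largest interval-free stretch containing the locus; 0 if overlapped
    if (nrow(iv) == 0L) return(Inf)
    if (any(iv$start <= e & iv$end >= s)) return(0)
    lo <- iv$end[iv$end < s]
    hi <- iv$start[iv$start > e]
    left <- if (length(lo)) max(lo) + 1L else -Inf
    right <- if (length(hi)) min(hi) - 1L else Inf
    right - left + 1
  }
  landmark <- ann[ann$type %in% c("telomere", "centromere"), , drop = FALSE]
  dist <- if (nrow(landmark) == 0L) Inf else {
    min(pmax(0, pmax(landmark$start - e, s - landmark$end)))
  }
  orf_gap <- gap_around(ann[ann$type == "ORF", , drop = FALSE])
  clean_gap <- gap_around(ann[ann$type %in% c("binding_site", "ncRNA"), , drop = FALSE])

  tibble(
    criterion = c("landmark_distance", "orf_free_region", "clean_region"),
    required_bp = c(criteria$min_landmark_distance_bp, criteria$min_orf_free_bp,
                    criteria$min_clean_bp),
    observed_bp = c(dist, orf_gap, clean_gap),
    pass = c(dist >= criteria$min_landmark_distance_bp,
             orf_gap >= criteria$min_orf_free_bp,
             clean_gap >= criteria$min_clean_bp)
  )
}
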