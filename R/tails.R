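#' Position-specific overhang table
#'
#' The six cloning positions of the expression-vector architecture each use a
#' fixed pair of 4-nt BsaI overhangs. The forward overhang of position i+1 is
#' the reverse complement of the reverse overhang of position i, which is what
#' chains neighbouring modules together in order; position 1 forward (ATCC)
#' and the reverse complement of position 6 reverse (ATGG -> CCAT) are the
#' two junctions to the destination-vector backbone.
#'
#' @return Tibble with `position`, `fwd_overhang`, `rev_overhang`.
#' @export
overhang_table <- function() {
  tibble(
    position = 1:6,
    fwd_overhang = c("ATCC", "TATG", "GAAC", "CGCA", "CAGG", "AGCA"),
    rev_overhang = c("CATA", "GTTC", "TGCG", "CCTG", "TGCT", "ATGG")
  )
}

BSAI_MOTIF <- "GGTCTC"

# default 25-bp multiple-cloning-site tails (pUC57 polylinker ends); the real
# library's tails are project configuration -- these defaults are structural
# placeholders with the documented length and no BsaI site.
MCS_TAIL_FWD_DEFAULT <- "GAATTCGAGCTCGGTACCTCGCGAA"
MCS_TAIL_REV_DEFAULT <- "AAGCTTGCATGCAGGCCTCTGCAGT"

#' Tail specification for a cloning position
#'
#' Bundles everything [add_tails()] prepends to a core primer: the 25-bp MCS
#' tail, the BsaI motif, the one-base spacer (`G` on forward sites, `T` on
#' reverse sites, as published) and the position-specific 4-nt overhang.
#'
#' @param position Cloning position 1-6.
#' @param mcs_tail_fwd,mcs_tail_rev 25-nt MCS tail sequences (defaults are the
#'   shipped pUC57-style tails; override per project).
#' @return An object of class `gg_tail_spec`.
#' @export
position_tail_spec <- function(position,
                               mcs_tail_fwd = MCS_TAIL_FWD_DEFAULT,
                               mcs_tail_rev = MCS_TAIL_REV_DEFAULT) {
  if (!(length(position) == 1L && position %in% 1:6)) {
    abort("position must be a single integer in 1..6", class = "gg_value_error")
  }
  for (t in c(mcs_tail_fwd, mcs_tail_rev)) {
    check_dna(t, allow_n = FALSE)
    if (nchar(t) != 25L) abort("MCS tails must be 25 nt", class = "gg_value_error")
  }
  ot <- overhang_table()
  structure(list(position = as.integer(position),
                 fwd_overhang = ot$fwd_overhang[position],
                 rev_overhang = ot$rev_overhang[position],
                 mcs_tail_fwd = mcs_tail_fwd,
                 mcs_tail_rev = mcs_tail_rev,
                 spacer_fwd = "G", spacer_rev = "T"),
            class = "gg_tail_spec")
}

new_tailed_primer <- function(mcs_tail, spacer, overhang, core, direction, position) {
  segments <- list(mcs_tail = mcs_tail, bsai = BSAI_MOTIF, spacer = spacer,
                   overhang = overhang, core = core)
  structure(list(segments = segments,
                 full_sequence = paste(unlist(segments), collapse = ""),
                 direction = direction, position = position),
            class = "gg_tailed_primer")
}

#' @export
print.gg_tailed_primer <- function(x, ...) {
  s <- x$segments
  cat(sprintf("<tailed primer> position %d %s (%d nt)\n", x$position,
              x$direction, nchar(x$full_sequence)))
  cat(sprintf("  %s | %s | %s | %s | %s\n", s$mcs_tail, s$bsai, s$spacer,
              s$overhang, s$core))
  invisible(x)
}

#' Add position-specific tails to core primers
#'
#' Builds the full tailed primers
#' `MCS tail + GGTCTC + spacer + overhang + core` for a cloning position.
#' The operation is lossless: segment boundaries are retained on the result
#' and [strip_tails()] recovers the cores exactly.
#'
#' @param core_fwd,core_rev Core primer sequences (15-25 nt), 5'->3'; the
#'   reverse core is given on the bottom strand as is conventional.
#' @param position Cloning position 1-6.
#' @param spec A [position_tail_spec()]; defaults to the shipped tails for
#'   `position`.
#' @return List with elements `fwd` and `rev`, each a `gg_tailed_primer`.
#' @examples
#' p <- add_tails("ATGACCGTTACCGGTAAGCT", "TTAGGCATCGGCAATCCGGT", position = 1)
#' p$fwd$segments$overhang  # "ATCC"
#' @export
add_tails <- function(core_fwd, core_rev, position, spec = position_tail_spec(position)) {
  stopifnot(inherits(spec, "gg_tail_spec"))
  if (spec$position != position) abort("spec position disagrees with `position`",
                                       class = "gg_value_error")
  for (core in c(core_fwd, core_rev)) {
    check_dna(core, allow_n = FALSE)
    if (nchar(core) < 15L || nchar(core) > 25L) {
      abort(sprintf("core length %d outside 15..25", nchar(core)),
            class = "gg_value_error")
    }
  }
  list(
    fwd = new_tailed_primer(spec$mcs_tail_fwd, spec$spacer_fwd, spec$fwd_overhang,
                            toupper(core_fwd), "forward", spec$position),
    rev = new_tailed_primer(spec$mcs_tail_rev, spec$spacer_rev, spec$rev_overhang,
                            toupper(core_rev), "reverse", spec$position)
  )
}

#' Recover the core from a tailed primer
#' @param primer A `gg_tailed_primer`.
#' @return The core sequence.
#' @export
strip_tails <- function(primer) {
  stopifnot(inherits(primer, "gg_tailed_primer"))
  primer$segments$core
}

primer_seq <- function(x) {
  if (inherits(x, "gg_tailed_primer")) x$full_sequence else toupper(x)
}

primer_core <- function(x) {
  if (inherits(x, "gg_tailed_primer")) x$segments$core else toupper(x)
}
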