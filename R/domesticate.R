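#' Yeast codon preference weights
#'
#' Relative adaptiveness of each codon in S. cerevisiae (the `sc` column of
#' `seqinr::caitab`), used as the deterministic tie-break when several
#' synonymous substitutions can destroy a BsaI site.
#'
#' @return Named numeric vector over the 64 codons (uppercase).
#' @export
codon_weights <- function() {
  if (is.null(the$codon_w)) {
    caitab <- NULL
    utils::data("caitab", package = "seqinr", envir = environment())
    w <- caitab$sc
    names(w) <- toupper(rownames(caitab))
    the$codon_w <- w
  }
  the$codon_w
}

synonymous_codons <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[[codon]]
  setdiff(names(gc)[gc == aa], codon)
}

#' Remove internal BsaI sites by synonymous substitution
#'
#' Detects BsaI recognition sites on both strands of a target sequence and,
#' for coding targets, plans single-codon synonymous substitutions that
#' destroy each site without changing the protein. Candidate edits are all
#' synonymous codons of every codon the site overlaps; among candidates that
#' destroy the site (and create no new site) the edit with the fewest
#' nucleotide changes is chosen, ties broken by the highest yeast codon
#' preference ([codon_weights()]), then alphabetically. Noncoding targets
#' cannot be edited silently, so their site list is returned with strategy
#' `fusion_pcr_suggested`. If some coding site admits no synonymous escape
#' the strategy is `impossible` and the residual count is positive.
#'
#' @param seq A [nuc_seq()] or character string.
#' @param frame `0`, `1`, `2` (CDS offset) or `"noncoding"`.
#' @return An object of class `gg_domestication`: list with `sites`
#'   (tibble of detected sites in the input), `edits` (tibble with `offset`
#'   = 1-based codon start, `old_codon`, `new_codon`, `amino_acid`),
#'   `residual_sites`, `strategy`, and `sequence` (the edited [nuc_seq()]).
#' @examples
#' plan <- domesticate("ATGGGTCTCTAA", frame = 0)
#' plan$residual_sites  # 0
#' @export
domesticate <- function(seq, frame = "noncoding") {
  s <- as_nuc_seq(seq)
  bsai <- gg_enzymes()$BsaI
  sites0 <- find_sites(s, bsai)
  empty_edits <- tibble(offset = integer(), old_codon = character(),
                        new_codon = character(), amino_acid = character())

  if (nrow(sites0) == 0L) {
    return(structure(list(sites = sites0, edits = empty_edits,
                          residual_sites = 0L, strategy = "silent_substitution",
                          sequence = s),
                     class = "gg_domestication"))
  }
  if (identical(frame, "noncoding")) {
    return(structure(list(sites = sites0, edits = empty_edits,
                          residual_sites = nrow(sites0),
                          strategy = "fusion_pcr_suggested", sequence = s),
                     class = "gg_domestication"))
  }
  if (!frame %in% 0:2) abort("frame must be 0, 1, 2 or \"noncoding\"",
                             class = "gg_value_error")

  aa <- translate_dna(s, frame)
  if (grepl("\\*.", aa)) {
    warn("translation contains internal stop codons; treating input as CDS anyway")
  }

  b <- s$bases
  L <- nchar(b)
  w <- codon_weights()
  edits <- list()
  stuck <- character()

  repeat {
    cur <- nuc_seq(b, name = s$name, topology = s$topology)
    sites <- find_sites(cur, bsai)
    sites <- sites[!paste(sites$position, sites$strand) %in% stuck, , drop = FALSE]
    if (nrow(sites) == 0L) break
    p0 <- sites$position[1]                      # 0-based recognition start
    ci <- ((p0 - frame) %/% 3L):((p0 + 5L - frame) %/% 3L)
    ci <- ci[ci >= 0L & (frame + 3L * (ci + 1L)) <= L]
    cand <- list()
    for (k in ci) {
      off <- frame + 3L * k + 1L                 # 1-based codon start
      old <- substr(b, off, off + 2L)
      if (grepl("N", old)) next
      for (new in synonymous_codons(old)) {
        b2 <- b
        substr(b2, off, off + 2L) <- new
        n_after <- nrow(find_sites(nuc_seq(b2, topology = s$topology), bsai))
        if (n_after < nrow(find_sites(cur, bsai))) {
          cand[[length(cand) + 1L]] <- list(
            offset = off, old_codon = old, new_codon = new,
            amino_acid = Biostrings::GENETIC_CODE[[old]],
            n_changes = sum(strsplit(old, "")[[1]] != strsplit(new, "")[[1]]),
            weight = unname(w[new]), bases = b2)
        }
      }
    }
    if (length(cand) == 0L) {
      stuck <- c(stuck, paste(sites$position[1], sites$strand[1]))
      next
    }
    ord <- order(vapply(cand, `[[`, 0L, "n_changes"),
                 -vapply(cand, `[[`, 0, "weight"),
                 vapply(cand, `[[`, "", "new_codon"))
    pick <- cand[[ord[1]]]
    b <- pick$bases
    edits[[length(edits) + 1L]] <- pick[c("offset", "old_codon", "new_codon", "amino_acid")]
  }

  edited <- nuc_seq(b, name = s$name, topology = s$topology)
  residual <- nrow(find_sites(edited, bsai))
  structure(list(
    sites = sites0,
    edits = if (length(edits)) bind_rows(lapply(edits, as_tibble)) else empty_edits,
    residual_sites = residual,
    strategy = if (residual == 0L) "silent_substitution" else "impossible",
    sequence = edited
  ), class = "gg_domestication")
}

#' @export
print.gg_domestication <- function(x, ...) {
  cat(sprintf("<domestication> %d site(s) detected, %d edit(s), %d residual; strategy: %s\n",
              nrow(x$sites), nrow(x$edits), x$residual_sites, x$strategy))
  if (nrow(x$edits)) print(x$edits)
  invisible(x)
}
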