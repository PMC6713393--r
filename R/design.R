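#' Penalty of a candidate core pair
#'
#' The weighted penalty minimised by [design_core_primers()]. Per primer:
#' distance of Tm, length and GC% from their optima, plus any excess of the
#' self- and 3'-complementarity scores over their thresholds; the pair adds
#' the Tm difference and the two cross-complementarity excesses. Hard
#' violations (length bound, dimer scores above threshold) add a large fixed
#' penalty so they are only ever chosen when no clean candidate exists.
#'
#' @param core_fwd,core_rev Candidate cores, 5'->3'.
#' @param cond A [reaction_conditions()] object.
#' @param thresholds A [qc_thresholds()] list.
#' @param weights Named list of penalty weights.
#' @return List with `penalty` (numeric) and `feasible` (no hard violation).
#' @export
pair_penalty <- function(core_fwd, core_rev, cond = reaction_conditions(),
                         thresholds = qc_thresholds(),
                         weights = design_weights()) {
  th <- thresholds; w <- weights
  HARD <- 1e6
  per_primer <- function(core) {
    tm <- primer_tm(core, cond = cond)$tm_C
    self <- complementarity_score(core, core)
    tp <- complementarity_score(three_prime_window(core), core)
    pen <- w$tm * abs(tm - th$tm_opt) +
      w$len * abs(nchar(core) - th$len_opt) +
      w$gc * abs(gc_content(core) - th$gc_opt) +
      w$self * max(0, self - th$self_max) +
      w$three_prime * max(0, tp - th$three_prime_max)
    hard <- nchar(core) < th$len_range[1] || nchar(core) > th$len_range[2] ||
      self > th$self_max || tp > th$three_prime_max
    list(pen = pen, tm = tm, hard = hard)
  }
  f <- per_primer(core_fwd); r <- per_primer(core_rev)
  cross <- complementarity_score(core_fwd, core_rev)
  cross3 <- max(complementarity_score(three_prime_window(core_fwd), core_rev),
                complementarity_score(three_prime_window(core_rev), core_fwd))
  hard <- f$hard || r$hard || cross > th$self_max || cross3 > th$three_prime_max
  pen <- f$pen + r$pen + w$pair_tm * abs(f$tm - r$tm) +
    w$self * max(0, cross - th$self_max) +
    w$three_prime * max(0, cross3 - th$three_prime_max) +
    if (hard) HARD else 0
  list(penalty = pen, feasible = !hard)
}

#' @rdname pair_penalty
#' @param ... Named overrides.
#' @export
design_weights <- function(...) {
  utils::modifyList(list(tm = 1, len = 0.25, gc = 0.02, self = 0.5,
                         three_prime = 1, pair_tm = 1), list(...))
}

#' Automated design of core primers for a target span
#'
#' Exhaustively enumerates forward cores starting at the span's first base
#' and reverse cores ending at its last base over the allowed design lengths,
#' scores every pair with [pair_penalty()], and returns the minimum-penalty
#' pair. The search is exhaustive, so the returned pair is brute-force
#' optimal, and deterministic (ties break toward shorter forward, then
#' shorter reverse cores).
#'
#' @param template A [nuc_seq()] or character string.
#' @param target_span 1-based inclusive `c(start, end)` of the region the
#'   amplicon must cover; defaults to the whole template. Must be >= 40 nt.
#' @param cond A [reaction_conditions()] object.
#' @param thresholds A [qc_thresholds()] list; `design_len_range` bounds the
#'   enumerated core lengths.
#' @param weights A [design_weights()] list.
#' @return List with `core_fwd`, `core_rev`, `penalty`, `feasible`.
#' @export
design_core_primers <- function(template, target_span = NULL,
                                cond = reaction_conditions(),
                                thresholds = qc_thresholds(),
                                weights = design_weights()) {
  tmpl <- as_nuc_seq(template)
  b <- tmpl$bases
  if (is.null(target_span)) target_span <- c(1L, nchar(b))
  s <- target_span[1]; e <- target_span[2]
  if (s < 1L || e > nchar(b) || e < s) {
    abort("target_span outside template", class = "gg_value_error")
  }
  if (e - s + 1L < 40L) {
    abort("target span shorter than 40 nt", class = "gg_design_error")
  }
  lens <- seq(thresholds$design_len_range[1], thresholds$design_len_range[2])
  lens <- lens[lens <= e - s + 1L]
  best <- NULL
  for (lf in lens) {
    cf <- substr(b, s, s + lf - 1L)
    for (lr in lens) {
      cr <- revcomp(substr(b, e - lr + 1L, e))
      p <- pair_penalty(cf, cr, cond, thresholds, weights)
      if (is.null(best) || p$penalty < best$penalty) {
        best <- list(core_fwd = cf, core_rev = cr, penalty = p$penalty,
                     feasible = p$feasible)
      }
    }
  }
  if (!best$feasible) {
    qc <- qc_pair(best$core_fwd, best$core_rev, tmpl, cond, thresholds)
    bad <- qc$metric[qc$hard & !qc$pass]
    abort(paste0("no candidate core pair satisfies the hard constraints; ",
                 "violated: ", paste(bad, collapse = ", ")),
          class = "gg_design_error")
  }
  best
}

#' Full primer-design report for a new module
#'
#' The end-to-end path for adding a module to the library: domesticate the
#' target (silent removal of internal BsaI sites when a reading frame is
#' given), design optimal core primers for the whole target, add the
#' position-specific tails, run the thirteen-metric QC battery and compute
#' annealing recommendations. The simulated amplicon (tailed primers plus
#' target interior) is included so digestion behaviour can be checked
#' directly.
#'
#' @param target A [nuc_seq()] or character string (>= 40 nt).
#' @param position Cloning position 1-6.
#' @param frame `0`, `1`, `2` for coding targets or `"noncoding"`.
#' @param cond A [reaction_conditions()] object.
#' @param thresholds A [qc_thresholds()] list.
#' @param spec A [position_tail_spec()].
#' @return An object of class `gg_primer_report`: list with `primers`
#'   (tailed pair), `qc`, `domestication`, `annealing_C_by_polymerase`,
#'   `amplicon`, `status` (`pass`/`warn`/`fail`).
#' @export
design_module_primers <- function(target, position, frame = "noncoding",
                                  cond = reaction_conditions(),
                                  thresholds = qc_thresholds(),
                                  spec = position_tail_spec(position)) {
  tgt <- as_nuc_seq(target)
  dom <- domesticate(tgt, frame)
  tmpl <- dom$sequence
  cores <- design_core_primers(tmpl, cond = cond, thresholds = thresholds)
  primers <- add_tails(cores$core_fwd, cores$core_rev, position, spec)
  qc <- qc_pair(primers$fwd, primers$rev, tmpl, cond, thresholds)
  tm_f <- primer_tm(cores$core_fwd, cond = cond)
  tm_r <- primer_tm(cores$core_rev, cond = cond)
  q5 <- min(min(tm_f$tm_C, tm_r$tm_C) + 1, 72)
  L <- seq_length(tmpl)
  lf <- nchar(cores$core_fwd); lr <- nchar(cores$core_rev)
  amplicon <- nuc_seq(paste0(primers$fwd$full_sequence,
                             substr(tmpl$bases, lf + 1L, L - lr),
                             revcomp(primers$rev$full_sequence)),
                      name = paste0(tgt$name, "_amplicon"))
  status <- if (qc_overall(qc) == "fail") "fail"
            else if (qc_overall(qc) == "warn" ||
                     dom$strategy != "silent_substitution") "warn" else "pass"
  structure(list(primers = primers, qc = qc, domestication = dom,
                 annealing_C_by_polymerase = list(q5 = q5, taq = q5 - 7),
                 core_tm = c(fwd = tm_f$tm_C, rev = tm_r$tm_C),
                 amplicon = amplicon, position = position, status = status),
            class = "gg_primer_report")
}

#' @export
print.gg_primer_report <- function(x, ...) {
  cat(sprintf("Module primer design, position %d: %s\n", x$position, x$status))
  print(x$primers$fwd); print(x$primers$rev)
  cat(sprintf("core Tm: fwd %.1f C, rev %.1f C; annealing Q5 %.1f / Taq %.1f C\n",
              x$core_tm[["fwd"]], x$core_tm[["rev"]],
              x$annealing_C_by_polymerase$q5, x$annealing_C_by_polymerase$taq))
  cat(sprintf("domestication: %s (%d edit(s), %d residual site(s)); QC: %s\n",
              x$domestication$strategy, nrow(x$domestication$edits),
              x$domestication$residual_sites, qc_overall(x$qc)))
  invisible(x)
}
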