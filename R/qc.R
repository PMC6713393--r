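#' Ungapped complementarity score between two primers
#'
#' Scores the best antiparallel duplex two oligos can form: `a` is aligned
#' against `revcomp(b)` at every offset and the best contiguous run is scored
#' with +1 per complementary pair and -1 per mismatch (floor 0). This is the
#' convention behind all the `*_complementarity` quality metrics.
#'
#' @param a,b Primer sequences 5'->3'.
#' @return Non-negative integer score.
#' @examples
#' complementarity_score("ACGTACGT", "ACGTACGT")  # self-dimer potential
#' @export
complementarity_score <- function(a, b) {
  x <- strsplit(toupper(a), "")[[1]]
  y <- strsplit(revcomp(b), "")[[1]]
  n <- length(x); m <- length(y)
  best <- 0L
  for (shift in (-(m - 1L)):(n - 1L)) {
    i0 <- max(1L, 1L + shift); i1 <- min(n, m + shift)
    if (i1 < i0) next
    sc <- ifelse(x[i0:i1] == y[(i0 - shift):(i1 - shift)], 1L, -1L)
    run <- 0L
    for (v in sc) {
      run <- max(0L, run + v)
      if (run > best) best <- run
    }
  }
  best
}

three_prime_window <- function(primer, k = 5L) {
  n <- nchar(primer)
  substr(primer, max(1L, n - k + 1L), n)
}

#' Template (matrix) complementarity of a primer
#'
#' Mispriming potential: the best duplex the primer can form with either
#' strand of the template, with the intended annealing footprint masked out.
#'
#' @param primer Primer sequence (full tailed sequence is appropriate).
#' @param template A [nuc_seq()] or character string.
#' @param exclude Optional 1-based inclusive `c(start, end)` interval on the
#'   top strand to mask (the intended site).
#' @return Non-negative integer score.
#' @export
matrix_complementarity <- function(primer, template, exclude = NULL) {
  b <- seq_bases(as_nuc_seq(template))
  if (!is.null(exclude)) {
    mask <- strrep("N", exclude[2] - exclude[1] + 1L)
    substr(b, exclude[1], exclude[2]) <- mask
  }
  max(complementarity_score(primer, b), complementarity_score(primer, revcomp(b)))
}

#' Default quality thresholds for primer cores
#'
#' Conventional optimisation windows: Tm 57-63 C (optimum 60), auto-designed
#' core length 18-25 (hard bound 15-25, optimum 20), GC 30-70% (optimum 50),
#' self-complementarity <= 8, 3'-complementarity <= 3 (3' = terminal 5 nt),
#' pair Tm difference <= 3 C, at least one G/C among the last 5 nt, 3' GC% of
#' the last 5 nt <= 60, 3' stability (dG37 of the terminal 5-nt stacks)
#' >= -9 kcal/mol, template mispriming score <= 12 (<= 4 for the 3' window).
#'
#' @param ... Named overrides of any listed element.
#' @return Named list of thresholds.
#' @export
qc_thresholds <- function(...) {
  defaults <- list(
    tm_range = c(57, 63), tm_opt = 60,
    len_range = c(15, 25), design_len_range = c(18, 25), len_opt = 20,
    gc_range = c(30, 70), gc_opt = 50,
    self_max = 8, three_prime_max = 3,
    matrix_max = 12, three_prime_matrix_max = 4,
    gc_clamp_min = 1, three_prime_gc_max = 60,
    three_prime_stability_min = -9,
    pair_tm_max = 3
  )
  utils::modifyList(defaults, list(...))
}

# dG37 of the duplex formed by the terminal 5 nt (4 stacks, no initiation)
three_prime_stability <- function(core) {
  w <- three_prime_window(core, 5L)
  if (nchar(w) < 2L) return(0)
  tabs <- nn_tables()
  p <- strsplit(w, "")[[1]]
  dH <- 0; dS <- 0
  for (i in seq_len(length(p) - 1L)) {
    key <- paste0(p[i], p[i + 1L], "/",
                  comp_base[p[i]], comp_base[p[i + 1L]])
    v <- lookup_stack(key, tabs$nn)
    dH <- dH + v[1]; dS <- dS + v[2]
  }
  dH - 310.15 * dS / 1000
}

worse_from <- function(vals, center) vals[which.max(abs(vals - center))]

#' Thirteen-metric quality report for a primer pair
#'
#' Runs the full battery on a primer pair against its template. Tm, length,
#' GC and 3'-end metrics are computed on the annealing cores; dimer
#' (complementarity) metrics on the full tailed sequences; template metrics
#' with the intended footprints masked. The report always contains exactly
#' the thirteen named metrics, in their published order. `overall` is
#' `"fail"` iff a hard metric fails: core length, the two 3'-anchored dimer
#' metrics (a complementary 3' end primes extension artefacts), or cores not
#' locatable on the template. Whole-molecule dimer scores are soft (warn)
#' because the 25-bp MCS tails are palindrome-rich by construction and
#' inflate them for every tailed primer.
#'
#' @param fwd,rev `gg_tailed_primer` objects or plain core sequences.
#' @param template A [nuc_seq()] or character string.
#' @param cond A [reaction_conditions()] object.
#' @param thresholds A [qc_thresholds()] list.
#' @return A tibble of class `gg_qc` with columns `metric`, `value`,
#'   `threshold`, `pass`, `hard`, and attributes `overall` and `tm`.
#' @export
qc_pair <- function(fwd, rev, template, cond = reaction_conditions(),
                    thresholds = qc_thresholds()) {
  th <- thresholds
  full_f <- primer_seq(fwd); full_r <- primer_seq(rev)
  core_f <- primer_core(fwd); core_r <- primer_core(rev)
  tmpl <- as_nuc_seq(template)

  loc_f <- locate_primer(core_f, tmpl)
  loc_r <- locate_primer(core_r, tmpl)
  cores_found <- !is.null(loc_f) && !is.null(loc_r)

  tm_f <- tm_r <- NA_real_
  if (cores_found) {
    tm_f <- primer_tm(core_f, revcomp(loc_f$site), cond)$tm_C
    tm_r <- primer_tm(core_r, revcomp(loc_r$site), cond)$tm_C
  } else {
    tm_f <- primer_tm(core_f, cond = cond)$tm_C
    tm_r <- primer_tm(core_r, cond = cond)$tm_C
  }

  excl <- function(loc, core) {
    if (is.null(loc)) return(NULL)
    s <- if (loc$strand == "+") loc$start else seq_length(tmpl) - (loc$start + nchar(core) - 1L) + 1L
    c(s, s + nchar(core) - 1L)
  }

  vals <- list(
    primer_tm = worse_from(c(tm_f, tm_r), th$tm_opt),
    length = worse_from(c(nchar(core_f), nchar(core_r)), th$len_opt),
    self_complementarity = max(complementarity_score(full_f, full_f),
                               complementarity_score(full_r, full_r)),
    three_prime_complementarity = max(
      complementarity_score(three_prime_window(full_f), full_f),
      complementarity_score(three_prime_window(full_r), full_r)),
    matrix_complementarity = if (cores_found) max(
      matrix_complementarity(full_f, tmpl, excl(loc_f, core_f)),
      matrix_complementarity(full_r, tmpl, excl(loc_r, core_r))) else NA_real_,
    three_prime_matrix_complementarity = if (cores_found) max(
      matrix_complementarity(three_prime_window(full_f), tmpl, excl(loc_f, core_f)),
      matrix_complementarity(three_prime_window(full_r), tmpl, excl(loc_r, core_r))) else NA_real_,
    gc_percent = worse_from(c(gc_content(core_f), gc_content(core_r)), th$gc_opt),
    gc_clamp = min(stringi::stri_count_regex(three_prime_window(core_f), "[GC]"),
                   stringi::stri_count_regex(three_prime_window(core_r), "[GC]")),
    three_prime_stability = min(three_prime_stability(core_f),
                                three_prime_stability(core_r)),
    three_prime_gc_percent = max(gc_content(three_prime_window(core_f)),
                                 gc_content(three_prime_window(core_r))),
    pair_tm_difference = abs(tm_f - tm_r),
    cross_complementarity = complementarity_score(full_f, full_r),
    cross_three_prime_complementarity = max(
      complementarity_score(three_prime_window(full_f), full_r),
      complementarity_score(three_prime_window(full_r), full_f))
  )

  in_range <- function(v, r) !is.na(v) && v >= r[1] && v <= r[2]
  spec <- list(
    primer_tm = list(sprintf("%g..%g C", th$tm_range[1], th$tm_range[2]),
                     in_range(vals$primer_tm, th$tm_range) &&
                       in_range(c(tm_f, tm_r)[1], th$tm_range) &&
                       in_range(c(tm_f, tm_r)[2], th$tm_range), FALSE),
    length = list(sprintf("%g..%g nt", th$len_range[1], th$len_range[2]),
                  in_range(nchar(core_f), th$len_range) &&
                    in_range(nchar(core_r), th$len_range), TRUE),
    self_complementarity = list(sprintf("<= %g", th$self_max),
                                vals$self_complementarity <= th$self_max, FALSE),
    three_prime_complementarity = list(sprintf("<= %g", th$three_prime_max),
                                       vals$three_prime_complementarity <= th$three_prime_max, TRUE),
    matrix_complementarity = list(sprintf("<= %g", th$matrix_max),
                                  cores_found && vals$matrix_complementarity <= th$matrix_max,
                                  !cores_found),
    three_prime_matrix_complementarity = list(sprintf("<= %g", th$three_prime_matrix_max),
                                              cores_found && vals$three_prime_matrix_complementarity <= th$three_prime_matrix_max,
                                              !cores_found),
    gc_percent = list(sprintf("%g..%g%%", th$gc_range[1], th$gc_range[2]),
                      in_range(gc_content(core_f), th$gc_range) &&
                        in_range(gc_content(core_r), th$gc_range), FALSE),
    gc_clamp = list(sprintf(">= %g G/C in last 5 nt", th$gc_clamp_min),
                    vals$gc_clamp >= th$gc_clamp_min, FALSE),
    three_prime_stability = list(sprintf(">= %g kcal/mol", th$three_prime_stability_min),
                                 vals$three_prime_stability >= th$three_prime_stability_min, FALSE),
    three_prime_gc_percent = list(sprintf("<= %g%%", th$three_prime_gc_max),
                                  vals$three_prime_gc_percent <= th$three_prime_gc_max, FALSE),
    pair_tm_difference = list(sprintf("<= %g C", th$pair_tm_max),
                              !is.na(vals$pair_tm_difference) &&
                                vals$pair_tm_difference <= th$pair_tm_max, FALSE),
    cross_complementarity = list(sprintf("<= %g", th$self_max),
                                 vals$cross_complementarity <= th$self_max, FALSE),
    cross_three_prime_complementarity = list(sprintf("<= %g", th$three_prime_max),
                                             vals$cross_three_prime_complementarity <= th$three_prime_max, TRUE)
  )

  report <- tibble(
    metric = names(vals),
    value = unname(vapply(vals, function(v) as.numeric(v[1]), 0)),
    threshold = vapply(spec, function(s) s[[1]], ""),
    pass = vapply(spec, function(s) isTRUE(s[[2]]), TRUE),
    hard = vapply(spec, function(s) isTRUE(s[[3]]), TRUE)
  )
  overall <- if (any(report$hard & !report$pass)) "fail"
             else if (any(!report$pass)) "warn" else "pass"
  structure(report, class = c("gg_qc", class(report)),
            overall = overall, tm = c(fwd = tm_f, rev = tm_r),
            cores_found = cores_found)
}

#' Overall verdict of a QC report
#' @param report A `gg_qc` report.
#' @return `"pass"`, `"warn"` or `"fail"`.
#' @export
qc_overall <- function(report) attr(report, "overall")

#' @export
print.gg_qc <- function(x, ...) {
  cat(sprintf("Primer pair QC: %s\n", attr(x, "overall")))
  NextMethod()
}
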