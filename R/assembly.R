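#' Double-stranded fragment with 4-nt end overhangs
#'
#' The currency of digestion/ligation. `bases` is the top strand written so
#' that each terminal overhang 4-mer appears exactly once (the first four and
#' last four bases); `left_overhang`/`right_overhang` record those 4-mers in
#' product orientation (`NA` for a blunt end). Two fragment ends ligate iff
#' their top-strand overhang representations are equal.
#'
#' @param bases Top-strand sequence.
#' @param left_overhang,right_overhang 4-nt top-strand overhangs or `NA`.
#' @param id Fragment identifier.
#' @param source Name of the parent molecule.
#' @return An object of class `ds_fragment`.
#' @export
ds_fragment <- function(bases, left_overhang = NA_character_,
                        right_overhang = NA_character_,
                        id = "frag", source = NA_character_) {
  check_dna(bases)
  for (ov in c(left_overhang, right_overhang)) {
    if (!is.na(ov) && nchar(ov) != 4L) {
      abort("overhangs must be exactly 4 nt", class = "gg_value_error")
    }
  }
  structure(list(bases = toupper(bases), left_overhang = left_overhang,
                 right_overhang = right_overhang, id = id, source = source),
            class = "ds_fragment")
}

#' @export
print.ds_fragment <- function(x, ...) {
  cat(sprintf("<ds_fragment> %s (%d nt) [%s ... %s]\n", x$id, nchar(x$bases),
              if (is.na(x$left_overhang)) "blunt" else x$left_overhang,
              if (is.na(x$right_overhang)) "blunt" else x$right_overhang))
  invisible(x)
}

#' Digest a plasmid with a type IIS enzyme
#'
#' Cuts at every recognition site on both strands. For BsaI (recognition
#' `GGTCTC`, 1-nt spacer) the top strand is cut one base after the
#' recognition end and the bottom strand five bases after, leaving 4-nt
#' 5' extensions; each fragment records the overhang 4-mers at both ends in
#' top-strand product orientation. Because the enzyme cuts outside its site,
#' every recognition site stays on the fragment that carries it. A circular
#' molecule with k sites yields k fragments; a linear one k+1 (blunt outer
#' ends). A circular molecule with no site is returned as a single fragment
#' flagged `no_cut`.
#'
#' @param plasmid A [nuc_seq()].
#' @param enz A type IIS [enzyme()] (default BsaI).
#' @return List of [ds_fragment()]s; attribute `no_cut` is `TRUE` when no
#'   site was found.
#' @export
digest <- function(plasmid, enz = gg_enzymes()$BsaI) {
  s <- as_nuc_seq(plasmid)
  if (enz$type != "type_iis") {
    abort("digest() models type IIS enzymes; use linearize() for ordinary cutters",
          class = "gg_value_error")
  }
  b <- s$bases
  L <- nchar(b)
  sites <- find_sites(s, enz)
  if (nrow(sites) == 0L) {
    frag <- ds_fragment(b, id = paste0(s$name, ".0"), source = s$name)
    out <- list(frag)
    attr(out, "no_cut") <- TRUE
    return(out)
  }
  reclen <- nchar(enz$recognition)
  ov_start <- ifelse(sites$strand == "+",
                     sites$position + reclen + enz$spacer_len,
                     sites$position - enz$spacer_len - enz$overhang_len)
  if (s$topology == "circular") {
    ov_start <- ov_start %% L
  } else {
    # cuts falling off a linear molecule's ends cannot happen
    ov_start <- ov_start[ov_start >= 0L & ov_start + enz$overhang_len <= L]
    if (length(ov_start) == 0L) {
      frag <- ds_fragment(b, id = paste0(s$name, ".0"), source = s$name)
      out <- list(frag)
      attr(out, "no_cut") <- TRUE
      return(out)
    }
  }
  ov_start <- sort(unique(ov_start))
  k <- length(ov_start)
  frags <- vector("list", if (s$topology == "circular") k else k + 1L)
  if (s$topology == "circular") {
    for (i in seq_len(k)) {
      nxt <- ov_start[if (i == k) 1L else i + 1L]
      len <- ((nxt - ov_start[i]) %% L) + enz$overhang_len
      bases <- circ_substr(b, ov_start[i] + 1L, len)
      frags[[i]] <- ds_fragment(bases,
                                left_overhang = substr(bases, 1L, enz$overhang_len),
                                right_overhang = substr(bases, len - enz$overhang_len + 1L, len),
                                id = paste0(s$name, ".", i), source = s$name)
    }
  } else {
    bounds <- c(0L, ov_start, L)
    for (i in seq_len(k + 1L)) {
      from <- bounds[i] + 1L
      to <- min(bounds[i + 1L] + if (i <= k) enz$overhang_len else 0L, L)
      bases <- substr(b, from, to)
      frags[[i]] <- ds_fragment(
        bases,
        left_overhang = if (i == 1L) NA_character_ else substr(bases, 1L, enz$overhang_len),
        right_overhang = if (i == k + 1L) NA_character_
                         else substr(bases, nchar(bases) - enz$overhang_len + 1L, nchar(bases)),
        id = paste0(s$name, ".", i), source = s$name)
    }
  }
  attr(frags, "no_cut") <- FALSE
  frags
}

flip_fragment <- function(f) {
  ds_fragment(revcomp(f$bases),
              left_overhang = if (is.na(f$right_overhang)) NA_character_ else revcomp(f$right_overhang),
              right_overhang = if (is.na(f$left_overhang)) NA_character_ else revcomp(f$left_overhang),
              id = f$id, source = f$source)
}

#' Ligate an ordered run of fragments
#'
#' Joins fragments whose adjacent overhangs match exactly, counting each
#' junction 4-mer once. With `circular = TRUE` the last fragment's right
#' overhang must equal the first fragment's left overhang and the joined
#' sequence is returned as a circular [nuc_seq()] starting at the first
#' fragment's first base.
#'
#' @param frags List of [ds_fragment()]s in product order.
#' @param circular Close the product into a circle?
#' @param name Name for the product sequence.
#' @return A [nuc_seq()].
#' @export
ligate_fragments <- function(frags, circular = TRUE, name = "ligation") {
  stopifnot(length(frags) >= 1L)
  for (i in seq_along(frags)[-1L]) {
    if (!identical(frags[[i - 1L]]$right_overhang, frags[[i]]$left_overhang) ||
        is.na(frags[[i]]$left_overhang)) {
      abort(sprintf("overhang mismatch between %s and %s",
                    frags[[i - 1L]]$id, frags[[i]]$id),
            class = "gg_no_closure")
    }
  }
  parts <- c(frags[[1L]]$bases,
             vapply(frags[-1L], function(f) substr(f$bases, 5L, nchar(f$bases)), ""))
  joined <- paste(parts, collapse = "")
  if (circular) {
    if (!identical(frags[[length(frags)]]$right_overhang, frags[[1L]]$left_overhang)) {
      abort("cannot close circle: terminal overhangs do not match",
            class = "gg_no_closure")
    }
    joined <- substr(joined, 1L, nchar(joined) - 4L)  # closing junction counted once
    nuc_seq(joined, name = name, topology = "circular")
  } else {
    nuc_seq(joined, name = name, topology = "linear")
  }
}

# all distinct circular products formable from the given fragments (each used
# at most once, either orientation); returns list of lists of oriented frags
enumerate_circles <- function(frags) {
  n <- length(frags)
  if (n == 0L) return(list())
  oriented <- lapply(frags, function(f) list(F = f, R = flip_fragment(f)))
  found <- list()
  canon <- character()
  path <- integer(); orient <- character()

  extend <- function(start_i) {
    # DFS over fragments with index >= start_i, start fragment fixed at start_i
    rec <- function() {
      last <- oriented[[path[length(path)]]][[orient[length(orient)]]]
      first <- oriented[[path[1L]]][[orient[1L]]]
      # try closing
      if (length(path) > 1L &&
          identical(last$right_overhang, first$left_overhang) &&
          !is.na(first$left_overhang)) {
        key_fwd <- paste(paste0(path, orient), collapse = ",")
        rev_orient <- rev(ifelse(orient == "F", "R", "F"))
        key_rev <- paste(paste0(rev(path), rev_orient), collapse = ",")
        key <- min(canon_rot(key_fwd), canon_rot(key_rev))
        if (!key %in% canon) {
          canon <<- c(canon, key)
          found[[length(found) + 1L]] <<- lapply(seq_along(path), function(j) {
            oriented[[path[j]]][[orient[j]]]
          })
        }
      }
      for (j in seq_len(n)) {
        if (j %in% path || j < start_i) next
        for (o in c("F", "R")) {
          nxt <- oriented[[j]][[o]]
          if (!is.na(last$right_overhang) &&
              identical(last$right_overhang, nxt$left_overhang)) {
            path <<- c(path, j); orient <<- c(orient, o)
            rec()
            path <<- path[-length(path)]; orient <<- orient[-length(orient)]
          }
        }
      }
    }
    for (o in c("F", "R")) {
      path <<- start_i; orient <<- o
      rec()
    }
    path <<- integer(); orient <<- character()
  }
  for (i in seq_len(n)) extend(i)
  found
}

canon_rot <- function(key) {
  parts <- strsplit(key, ",")[[1]]
  n <- length(parts)
  rots <- vapply(seq_len(n), function(i) {
    paste(parts[c(i:n, seq_len(i - 1L))[seq_len(n)]], collapse = ",")
  }, "")
  min(rots)
}

#' One-pot Golden Gate assembly
#'
#' Simulates simultaneous digestion/ligation of the destination vector and a
#' set of module plasmids: all molecules are digested with BsaI, fragments
#' still carrying a recognition site are discarded (in the pot they are
#' re-cut whenever they religate), and every distinct circular product
#' formable from the remaining fragments by exact 4-nt overhang matching is
#' enumerated. A correct reaction yields exactly one product: backbone then
#' modules 1-6, with the seven junction overhangs
#' ATCC, TATG, GAAC, CGCA, CAGG, AGCA, CCAT and no remaining BsaI site.
#'
#' @param pdv Destination vector: a circular [nuc_seq()] with exactly two
#'   BsaI sites flanking its stuffer.
#' @param modules List of module plasmids (circular [nuc_seq()]s, one per
#'   position, each with two convergent BsaI sites flanking its insert).
#' @param enz The type IIS [enzyme()] (default BsaI).
#' @return An object of class `gg_assembly`: `product` (circular
#'   [nuc_seq()], rotation normalised to the backbone's first base, with
#'   module and junction features), `junctions` (the 7 overhangs in order),
#'   `diagnostics` (list: `bsai_sites_in_product`, `stuffer_present`,
#'   `modules_in_order`), and `modules` (tibble).
#' @export
assemble <- function(pdv, modules, enz = gg_enzymes()$BsaI) {
  pdv <- as_nuc_seq(pdv)
  modules <- lapply(modules, as_nuc_seq)
  ot <- overhang_table()

  all_frags <- c(digest(pdv, enz), unlist(lapply(modules, digest, enz = enz),
                                          recursive = FALSE))
  clean <- keep(all_frags, function(f) {
    !is.na(f$left_overhang) && !is.na(f$right_overhang) &&
      count_sites(nuc_seq(f$bases), enz) == 0L
  })

  # inserts are recognised by their forward (left) overhang; the pDV backbone
  # by its source molecule
  frag_pos <- vapply(clean, function(f) {
    i <- match(f$left_overhang, ot$fwd_overhang)
    if (!is.na(i) && f$source != pdv$name) i else NA_integer_
  }, 0L)
  positions <- frag_pos[!is.na(frag_pos)]
  missing <- setdiff(1:6, positions)
  dup <- unique(positions[duplicated(positions)])

  circles <- enumerate_circles(clean)
  if (length(circles) == 0L) {
    if (length(missing)) {
      abort(sprintf("incomplete assembly path: no module for position%s %s",
                    if (length(missing) > 1L) "s" else "",
                    paste(missing, collapse = ", ")),
            class = "gg_incomplete_path")
    }
    abort("no circular product can be closed from the supplied fragments",
          class = "gg_no_closure")
  }
  if (length(circles) > 1L) {
    msg <- if (length(dup)) {
      sprintf("ambiguous assembly: %d distinct circular products (duplicated position%s %s)",
              length(circles), if (length(dup) > 1L) "s" else "",
              paste(sort(dup), collapse = ", "))
    } else {
      sprintf("ambiguous assembly: %d distinct circular products", length(circles))
    }
    abort(msg, class = "gg_ambiguous_assembly")
  }
  if (length(missing)) {
    abort(sprintf("incomplete assembly path: no module for position%s %s",
                  if (length(missing) > 1L) "s" else "",
                  paste(missing, collapse = ", ")),
          class = "gg_incomplete_path")
  }

  cyc <- circles[[1L]]
  bi <- which(vapply(cyc, function(f) f$source == pdv$name, TRUE))
  if (length(bi) != 1L) {
    abort("product does not contain the destination-vector backbone exactly once",
          class = "gg_no_closure")
  }
  cyc <- cyc[c(bi:length(cyc), seq_len(bi - 1L))]
  # orient so the backbone runs forward (junction to module 1 = ATCC on its right)
  if (!identical(cyc[[1L]]$right_overhang, ot$fwd_overhang[1L])) {
    cyc <- c(cyc[1L], rev(cyc[-1L]))
    cyc <- lapply(cyc, flip_fragment)
  }
  product <- ligate_fragments(cyc, circular = TRUE,
                              name = paste0(pdv$name, "_assembly"))
  # junction list starts at backbone->module1: the backbone's right overhang,
  # then each module's right overhang, ending with module6->backbone
  junctions <- vapply(cyc, `[[`, "", "right_overhang")

  stuffer <- keep(digest(pdv, enz), function(f) count_sites(nuc_seq(f$bases), enz) > 0L)
  stuffer_core <- if (length(stuffer)) {
    s <- stuffer[[1L]]$bases
    substr(s, 5L, nchar(s) - 4L)
  } else NULL

  # spans tile the circle exactly: each part covers its bases minus the
  # junction 4-mer it shares with the next part
  lens <- vapply(cyc, function(f) nchar(f$bases), 0L)
  starts <- cumsum(c(1L, (lens - 4L)[-length(lens)]))
  feats <- tibble(
    type = c("backbone", rep("module", length(cyc) - 1L)),
    start = starts,
    end = starts + lens - 4L - 1L,
    strand = "+",
    label = vapply(cyc, `[[`, "", "source")
  )
  product$features <- feats

  mods <- tibble(
    position = vapply(cyc[-1L], function(f) match(f$left_overhang, ot$fwd_overhang), 0L),
    id = vapply(cyc[-1L], `[[`, "", "source"),
    insert_bp = vapply(cyc[-1L], function(f) nchar(f$bases), 0L)
  )
  diagnostics <- list(
    bsai_sites_in_product = count_sites(product, enz),
    stuffer_present = !is.null(stuffer_core) &&
      grepl(stuffer_core, product$bases, fixed = TRUE),
    modules_in_order = mods$id
  )
  structure(list(product = product, junctions = junctions,
                 diagnostics = diagnostics, modules = mods,
                 fragment_bp = lens),
            class = "gg_assembly")
}

#' @export
print.gg_assembly <- function(x, ...) {
  cat(sprintf("<assembly> %s: %d bp circular, %d modules, %d BsaI site(s)\n",
              x$product$name, seq_length(x$product), nrow(x$modules),
              x$diagnostics$bsai_sites_in_product))
  cat("junctions:", paste(x$junctions, collapse = " "), "\n")
  print(x$modules)
  invisible(x)
}

#' Verify an assembled expression vector
#'
#' In-silico analogue of the diagnostic restriction digest: confirms module
#' order against expectation, absence of BsaI sites, loss of the stuffer,
#' and reports the fragment sizes of a diagnostic digest with an ordinary
#' enzyme.
#'
#' @param result A `gg_assembly`.
#' @param expected Character vector of module ids in position order.
#' @param diag_enzyme An ordinary (palindromic) [enzyme()] for the simulated
#'   diagnostic digest (default EcoRV).
#' @return Tibble with `check`, `pass`, `detail`; attribute
#'   `diagnostic_fragments_bp` holds the simulated digest sizes.
#' @export
verify_product <- function(result, expected,
                           diag_enzyme = gg_enzymes()$EcoRV) {
  stopifnot(inherits(result, "gg_assembly"))
  got <- result$diagnostics$modules_in_order
  checks <- tibble(
    check = c("module_order", "bsai_sites_zero", "stuffer_absent"),
    pass = c(identical(as.character(got), as.character(expected)),
             result$diagnostics$bsai_sites_in_product == 0L,
             !result$diagnostics$stuffer_present),
    detail = c(paste(got, collapse = " > "),
               sprintf("%d site(s)", result$diagnostics$bsai_sites_in_product),
               if (result$diagnostics$stuffer_present) "stuffer detected" else "ok")
  )
  sites <- find_sites(result$product, diag_enzyme)
  sizes <- if (nrow(sites) == 0L) integer() else {
    cuts <- sort((sites$position + diag_enzyme$cut_offset) %% seq_length(result$product))
    as.integer(diff(c(cuts, cuts[1L] + seq_length(result$product))))
  }
  attr(checks, "diagnostic_fragments_bp") <- sizes
  attr(checks, "diag_enzyme") <- diag_enzyme$name
  checks
}

#' Plasmid concentration conversions for the one-pot reaction
#'
#' The assembly protocol wants every plasmid at 40 fmol/ul; concentration in
#' fmol/ul is `ng_per_ul * 1520 / size_bp`, and [dilution_ng()] is the exact
#' algebraic inverse giving the ng/ul needed for a target molarity.
#'
#' @param ng_per_ul Mass concentration (ng/ul), >= 0.
#' @param size_bp Plasmid size in bp, > 0.
#' @return fmol/ul.
#' @examples
#' dilution_fmol(100, 3800)  # 40
#' @export
dilution_fmol <- function(ng_per_ul, size_bp) {
  if (any(size_bp <= 0)) abort("size_bp must be positive", class = "gg_value_error")
  if (any(ng_per_ul < 0)) abort("ng_per_ul must be >= 0", class = "gg_value_error")
  ng_per_ul * 1520 / size_bp
}

#' @rdname dilution_fmol
#' @param fmol_per_ul Target molar concentration (fmol/ul).
#' @export
dilution_ng <- function(fmol_per_ul, size_bp) {
  if (any(size_bp <= 0)) abort("size_bp must be positive", class = "gg_value_error")
  fmol_per_ul * size_bp / 1520
}
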