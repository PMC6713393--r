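#' Read a multi-record FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()]. Topology is taken
#' from a `[topology=circular]` token in the header if present (FASTA itself
#' has no topology field), otherwise linear.
#'
#' @param path File path.
#' @return Named list of [nuc_seq()] records.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(set), function(i) {
    header <- names(set)[i]
    topo <- if (grepl("\\[topology=circular\\]", header)) "circular" else "linear"
    nm <- sub("\\s.*$", "", header)
    nuc_seq(as.character(set[[i]]), name = nm, topology = topo)
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' Write sequences to FASTA
#'
#' Records are wrapped at 70 columns; circular records carry a
#' `[topology=circular]` token in the header so a round-trip preserves
#' topology.
#'
#' @param seqs A `nuc_seq` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "nuc_seq")) seqs <- list(seqs)
  headers <- vapply(seqs, function(s) {
    paste0(s$name, if (s$topology == "circular") " [topology=circular]" else "")
  }, "")
  set <- Biostrings::DNAStringSet(vapply(seqs, `[[`, "", "bases"))
  names(set) <- headers
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read a GenBank flat file
#'
#' A minimal parser for the records this package writes and for plain
#' single-record GenBank files: it preserves the sequence, the
#' linear/circular topology flag from the LOCUS line, and simple
#' `start..end` / `complement(start..end)` feature locations with their
#' qualifiers. Compound (join) locations are not supported.
#'
#' @param path File path.
#' @return A [nuc_seq()] with its `features` tibble populated.
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) != 1L) {
    abort(sprintf("malformed GenBank record: expected one LOCUS line, found %d",
                  length(locus_i)),
          class = "gg_parse_error")
  }
  locus <- lines[locus_i]
  name <- strsplit(trimws(sub("^LOCUS", "", locus)), "\\s+")[[1]][1]
  topology <- if (grepl("\\bcircular\\b", locus)) "circular" else "linear"

  feat <- tibble(type = character(), start = integer(), end = integer(),
                 strand = character(), label = character())
  fstart <- grep("^FEATURES", lines)
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart) != 1L) {
    abort(sprintf("malformed GenBank record: missing ORIGIN (line %d expected)",
                  length(lines)), class = "gg_parse_error")
  }
  if (length(fstart) == 1L) {
    block <- lines[(fstart + 1L):(ostart - 1L)]
    cur <- NULL
    rows <- list()
    for (i in seq_along(block)) {
      ln <- block[i]
      if (grepl("^ {5}\\S", ln)) {
        parts <- strsplit(trimws(ln), "\\s+")[[1]]
        loc <- parts[2]
        strand <- if (grepl("^complement\\(", loc)) "-" else "+"
        loc <- gsub("complement\\(|\\)", "", loc)
        se <- strsplit(loc, "\\.\\.")[[1]]
        if (length(se) != 2L || anyNA(suppressWarnings(as.integer(se)))) {
          abort(sprintf("unsupported feature location '%s' at line %d",
                        parts[2], fstart + i),
                class = "gg_parse_error")
        }
        cur <- list(type = parts[1], start = as.integer(se[1]),
                    end = as.integer(se[2]), strand = strand, label = NA_character_)
        rows[[length(rows) + 1L]] <- cur
      } else if (grepl("^\\s+/(label|gene|note)=", ln) && length(rows)) {
        val <- sub('^\\s+/(label|gene|note)="?([^"]*)"?\\s*$', "\\2", ln)
        if (is.na(rows[[length(rows)]]$label)) rows[[length(rows)]]$label <- val
      }
    }
    if (length(rows)) feat <- bind_rows(lapply(rows, as_tibble))
  }
  seq_lines <- lines[(ostart + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  bases <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  nuc_seq(bases, name = name, topology = topology, features = feat)
}

#' Write a GenBank flat file
#'
#' @param seq A [nuc_seq()]; its `features` tibble is written as
#'   `misc_feature` entries (or the tibble's own `type`) with `/label`
#'   qualifiers.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(seq, path) {
  stopifnot(inherits(seq, "nuc_seq"))
  L <- nchar(seq$bases)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    DNA     %-8s SYN %s",
                     seq$name, L, seq$topology,
                     format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s.", seq$name), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", L), con)
  if (nrow(seq$features)) {
    for (i in seq_len(nrow(seq$features))) {
      f <- seq$features[i, ]
      loc <- sprintf("%d..%d", f$start, f$end)
      if (identical(f$strand, "-")) loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-15s %s", f$type, loc), con)
      if (!is.na(f$label)) writeLines(sprintf('                     /label="%s"', f$label), con)
    }
  }
  writeLines("ORIGIN", con)
  idx <- seq(1L, L, by = 60L)
  for (i in idx) {
    chunk <- substr(seq$bases, i, min(i + 59L, L))
    tens <- stringi::stri_sub(chunk, seq(1L, nchar(chunk), 10L), length = 10L)
    writeLines(sprintf("%9d %s", i, tolower(paste(tens, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read genomic annotations from BED
#'
#' BED is 0-based half-open; coordinates are converted to the 1-based
#' inclusive convention used throughout this package. The BED name column is
#' interpreted as the annotation type label (`ORF`, `binding_site`, `ncRNA`,
#' `telomere`, `centromere`).
#'
#' @param path BED file path.
#' @return Tibble with `chrom`, `start`, `end` (1-based inclusive), `type`.
#' @export
read_annotations <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("rtracklayer is required to read BED files", class = "gg_value_error")
  }
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  tibble(
    chrom = as.character(df$seqnames),
    start = as.integer(df$start),
    end = as.integer(df$end),
    type = if ("name" %in% names(df)) as.character(df$name) else NA_character_
  )
}
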