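#' Tidy an assembly result
#'
#' One row per constituent (backbone then modules 1-6) with its span on the
#' product and the junction overhang that follows it.
#'
#' @param x A `gg_assembly`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.gg_assembly <- function(x, ...) {
  f <- x$product$features
  tibble(part = f$label, type = f$type, start = f$start, end = f$end,
         junction_after = x$junctions)
}

#' @rdname tidy.gg_assembly
#' @export
glance.gg_assembly <- function(x, ...) {
  tibble(product_bp = seq_length(x$product),
         n_modules = nrow(x$modules),
         bsai_sites = x$diagnostics$bsai_sites_in_product,
         stuffer_present = x$diagnostics$stuffer_present)
}

#' @rdname tidy.gg_assembly
#' @param object A `gg_assembly`.
#' @export
autoplot.gg_assembly <- function(object, ...) {
  d <- tidy(object)
  d$part <- factor(d$part, levels = d$part)
  ggplot(d, aes(xmin = .data$start, xmax = .data$end,
                ymin = 0, ymax = 1, fill = .data$part)) +
    ggplot2::geom_rect(colour = "grey20") +
    ggplot2::geom_text(aes(x = (.data$start + .data$end) / 2, y = 0.5,
                           label = .data$part), angle = 90, size = 3) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL) +
    ggplot2::labs(x = "position on product (bp)",
                  title = sprintf("%s (%d bp)", object$product$name,
                                  seq_length(object$product))) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Tidy a QC report
#'
#' @param x A `gg_qc` report.
#' @param ... Unused.
#' @return The underlying metric tibble.
#' @export
tidy.gg_qc <- function(x, ...) as_tibble(x)

#' @rdname tidy.gg_qc
#' @export
glance.gg_qc <- function(x, ...) {
  tibble(overall = attr(x, "overall"),
         n_pass = sum(x$pass), n_fail = sum(!x$pass),
         tm_fwd = attr(x, "tm")[["fwd"]], tm_rev = attr(x, "tm")[["rev"]])
}

#' @rdname tidy.gg_qc
#' @param object A `gg_qc` report.
#' @export
autoplot.gg_qc <- function(object, ...) {
  d <- tidy(object)
  d$metric <- factor(d$metric, levels = rev(d$metric))
  ggplot(d, aes(x = .data$value, y = .data$metric, fill = .data$pass)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "#2e7d32", `FALSE` = "#c62828")) +
    ggplot2::labs(x = "metric value", y = NULL,
                  title = sprintf("Primer pair QC: %s", attr(object, "overall"))) +
    ggplot2::theme_minimal()
}

#' Tidy a domestication plan
#' @param x A `gg_domestication`.
#' @param ... Unused.
#' @return The edits tibble.
#' @export
tidy.gg_domestication <- function(x, ...) x$edits

#' @rdname tidy.gg_domestication
#' @export
glance.gg_domestication <- function(x, ...) {
  tibble(sites_detected = nrow(x$sites), edits = nrow(x$edits),
         residual_sites = x$residual_sites, strategy = x$strategy)
}

#' Tidy a module library
#' @param x A `gg_library`.
#' @param ... Unused.
#' @return The entries tibble with sequence lengths attached.
#' @export
tidy.gg_library <- function(x, ...) {
  x$entries |>
    mutate(size_bp = map_int(.data$id, function(i) seq_length(x$sequences[[i]])))
}

#' @rdname tidy.gg_library
#' @export
glance.gg_library <- function(x, ...) {
  tibble(records = nrow(x$entries),
         modules = sum(!is.na(x$entries$position)),
         combinations = count_combinations(x),
         seed = x$seed)
}
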