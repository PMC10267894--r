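# broom-style tidiers and ggplot2 visualisations for the result objects

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a spectral library
#'
#' @param x `ir_library`.
#' @param ... Unused.
#' @return Entries tibble without the spectrum list-columns.
#' @method tidy ir_library
#' @export
tidy.ir_library <- function(x, ...) {
  x$entries[, c("entry_id", "molecule_id", "adduct", "site", "variant",
                "relative_energy", "formula", "adduct_mz")]
}

#' @rdname tidy.ir_library
#' @method glance ir_library
#' @export
glance.ir_library <- function(x, ...) {
  tibble::tibble(
    n_entries = nrow(x$entries),
    n_molecules = length(unique(x$entries$molecule_id)),
    n_ions = nrow(unique(x$entries[, c("molecule_id", "adduct")])),
    scale = x$params$scale,
    fwhm = x$params$fwhm,
    grid_start = x$params$grid[1],
    grid_stop = x$params$grid[2],
    grid_step = x$params$grid[3],
    energy_filter = x$params$energy_filter
  )
}

#' Tidy an evaluation report
#'
#' @param x `iris_eval` from [evaluation_report()].
#' @param ... Unused.
#' @return Long tibble of the top-k curves: columns `mode`, `k`, `percent`.
#' @method tidy iris_eval
#' @export
tidy.iris_eval <- function(x, ...) {
  purrr::imap_dfr(x$topk, function(t, m) {
    tibble::tibble(mode = m, k = t$k, percent = t$percent)
  })
}

#' @rdname tidy.iris_eval
#' @method glance iris_eval
#' @export
glance.iris_eval <- function(x, ...) {
  tibble::tibble(
    n_records = x$n_records,
    n_metabolites = x$n_metabolites,
    isomer_top1 = x$topk$isomer$percent[1],
    isomer_combined_top1 = x$topk$isomer_combined$percent[1],
    unsupervised_top1 = x$topk$unsupervised$percent[1],
    unsupervised_combined_top1 = x$topk$unsupervised_combined$percent[1],
    isomer_rp = x$rank_products[["isomer"]],
    unsupervised_rp = x$rank_products[["unsupervised"]]
  )
}

#' Plot a grid spectrum
#'
#' @param object An `ir_grid_spectrum`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ir_grid_spectrum
#' @export
autoplot.ir_grid_spectrum <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$wavenumber, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(wavenumber ~ (cm^-1)), y = "intensity") +
    ggplot2::theme_minimal()
}

#' Plot top-k identification curves of an evaluation report
#'
#' Solid traces per search mode plus the dashed random-annotation baselines.
#'
#' @param object `iris_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot iris_eval
#' @export
autoplot.iris_eval <- function(object, ...) {
  curves <- tidy(object)
  base <- purrr::imap_dfr(object$baseline, function(b, m) {
    tibble::tibble(mode = paste0(m, "_random"), k = b$k, percent = b$percent)
  })
  ggplot2::ggplot(curves,
                  ggplot2::aes(x = .data$k, y = .data$percent,
                               colour = .data$mode)) +
    ggplot2::geom_step() +
    ggplot2::geom_step(data = base, linetype = "dashed") +
    ggplot2::labs(x = "k", y = "% correct in top k", colour = NULL) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Overlay a query spectrum with a library entry
#'
#' @param lib `ir_library`.
#' @param spectrum Query grid spectrum (tibble) or intensity vector on the
#'   library axis.
#' @param entry_id Library entry to overlay.
#' @return A ggplot with the query in grey and the computed spectrum in
#'   orange, both area-normalized.
#' @export
plot_match <- function(lib, spectrum, entry_id) {
  e <- lib$entries[lib$entries$entry_id == entry_id, ]
  stopifnot(nrow(e) == 1L)
  q <- query_on_axis(lib, spectrum)
  norm <- function(v) if (sum(v) > 0) v / sum(v) else v
  d <- dplyr::bind_rows(
    tibble::tibble(wavenumber = lib$wavenumber, intensity = norm(q$intensity),
                   trace = "query"),
    tibble::tibble(wavenumber = lib$wavenumber,
                   intensity = norm(e$grid[[1]]), trace = e$entry_id)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wavenumber, y = .data$intensity,
                                  colour = .data$trace)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = stats::setNames(
      c("grey40", "darkorange"), c("query", e$entry_id))) +
    ggplot2::labs(x = expression(wavenumber ~ (cm^-1)),
                  y = "normalized intensity", colour = NULL) +
    ggplot2::theme_minimal()
}
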