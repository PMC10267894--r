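# Library build pipeline and persistence.

LIBRARY_SCHEMA <- "irisearch-library/1"

#' Filter ion geometries by relative energy
#'
#' Relative energies are re-zeroed to the minimum of each
#' (molecule, adduct) group, then geometries lying more than `threshold`
#' kJ/mol above the group minimum are discarded (retention is inclusive at
#' the threshold). The minimum-energy geometry always survives.
#'
#' @param candidates Tibble with at least columns `molecule_id`, `adduct`,
#'   `relative_energy` (finite, one row per geometry).
#' @param threshold Energy cutoff in kJ/mol (default 40).
#' @return The retained rows, with `relative_energy` re-zeroed per group.
#' @export
#' @examples
#' filter_geometries(tibble::tibble(molecule_id = "m", adduct = "protonated",
#'                                  relative_energy = c(0, 39.9, 40, 40.1)))
filter_geometries <- function(candidates, threshold = 40) {
  if (!is.data.frame(candidates) || nrow(candidates) == 0L) {
    stop("no candidate geometries to filter", call. = FALSE)
  }
  stopifnot(all(is.finite(candidates$relative_energy)))
  candidates |>
    dplyr::group_by(.data$molecule_id, .data$adduct) |>
    dplyr::mutate(relative_energy =
                    .data$relative_energy - min(.data$relative_energy)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$relative_energy <= threshold)
}

#' Build a searchable spectral library
#'
#' Ingests per-ion computed frequency tables, validates them against the
#' adduct ions enumerable from each molecule, re-zeroes and filters relative
#' energies, convolves every retained stick spectrum onto the matching grid,
#' and attaches theoretical adduct m/z values. The build is deterministic:
#' the same inputs always produce an identical library.
#'
#' @param molecules Molecules tibble from [parse_molecules()].
#' @param freq_tables Tibble with one row per ion geometry and columns
#'   `molecule_id`, `adduct`, `site` (atom index), `variant` (geometry tag),
#'   `relative_energy` (kJ/mol) and `stick` (list of [stick_spectrum()]).
#' @param scale,fwhm Convolution parameters (defaults 0.975 and 45 cm^-1).
#' @param grid Matching grid as `c(start, stop, step)` (default 600--1850 at
#'   1 cm^-1).
#' @param energy_filter Relative-energy cutoff in kJ/mol (default 40).
#' @return An object of class `ir_library`: a list with `molecules`,
#'   `entries` (tibble incl. list-columns `stick` and `grid`), `params`,
#'   and the `wavenumber` axis.
#' @export
build_library <- function(molecules, freq_tables,
                          scale = default_scale, fwhm = default_fwhm,
                          grid = c(600, 1850, 1), energy_filter = 40) {
  stopifnot(is.data.frame(molecules), is.data.frame(freq_tables))
  need <- c("molecule_id", "adduct", "site", "variant", "relative_energy",
            "stick")
  stopifnot(all(need %in% names(freq_tables)))
  freq_tables$adduct <- vapply(freq_tables$adduct, match_adduct, character(1))

  orphans <- setdiff(freq_tables$molecule_id, molecules$id)
  if (length(orphans) > 0L) {
    stop("frequency tables reference unknown molecule(s): ",
         paste(unique(orphans), collapse = ", "), call. = FALSE)
  }
  # validate sites against the enumerable adduct ions
  for (ad in unique(freq_tables$adduct)) {
    sites <- enumerate_adduct_ions(molecules, ad)
    ft <- freq_tables[freq_tables$adduct == ad, ]
    key_ft <- paste(ft$molecule_id, ft$site)
    key_ok <- paste(sites$molecule_id, sites$site)
    bad <- setdiff(key_ft, key_ok)
    if (length(bad) > 0L) {
      stop("frequency tables reference sites not enumerable for adduct ",
           ad, ": ", paste(bad, collapse = "; "), call. = FALSE)
    }
  }

  kept <- filter_geometries(freq_tables, energy_filter)
  kept$entry_id <- paste(kept$molecule_id, kept$adduct, kept$site,
                         kept$variant, sep = "|")
  if (anyDuplicated(kept$entry_id)) {
    stop("duplicate (molecule, adduct, site, variant) geometry rows",
         call. = FALSE)
  }
  axis <- ir_grid(grid[1], grid[2], grid[3])
  kept$grid <- lapply(kept$stick, function(s) {
    scale_and_broaden(s, scale, fwhm, axis)$intensity
  })
  mol_idx <- match(kept$molecule_id, molecules$id)
  kept$formula <- molecules$formula[mol_idx]
  kept$adduct_mz <- vapply(seq_len(nrow(kept)), function(i) {
    adduct_mz(molecules$monoisotopic_mass[mol_idx[i]], kept$adduct[i])
  }, numeric(1))
  kept <- kept[order(kept$entry_id),
               c("entry_id", "molecule_id", "adduct", "site", "variant",
                 "relative_energy", "formula", "adduct_mz", "stick", "grid")]

  # derived scoring cache: square-root grid matrix and per-entry intensity
  # sums (denormalizable; rebuilt whenever the library is rebuilt or loaded)
  gm <- matrix(unlist(kept$grid), nrow = nrow(kept), byrow = TRUE)
  rownames(gm) <- kept$entry_id

  structure(
    list(
      molecules = molecules,
      entries = tibble::as_tibble(kept),
      params = list(scale = as.numeric(scale), fwhm = as.numeric(fwhm),
                    grid = as.numeric(grid[1:3]),
                    energy_filter = as.numeric(energy_filter)),
      wavenumber = as.numeric(axis),
      sqrt_grid = sqrt(gm),
      grid_sums = rowSums(gm)
    ),
    class = "ir_library"
  )
}

#' Subset library entries by adduct and formula
#'
#' @param lib `ir_library` object.
#' @param adduct Optional adduct constraint.
#' @param formula Optional molecular formula constraint.
#' @return Entries tibble.
#' @export
library_entries <- function(lib, adduct = NULL, formula = NULL) {
  e <- lib$entries
  if (!is.null(adduct)) e <- e[e$adduct == match_adduct(adduct), ]
  if (!is.null(formula)) e <- e[e$formula == formula, ]
  e
}

#' @export
print.ir_library <- function(x, ...) {
  cat("<ir_library> ", nrow(x$entries), " spectra / ",
      length(unique(x$entries$molecule_id)), " molecules\n", sep = "")
  cat("  grid: ", x$params$grid[1], "-", x$params$grid[2], " cm-1, step ",
      x$params$grid[3], "; scale ", x$params$scale, "; fwhm ",
      x$params$fwhm, " cm-1; energy filter ", x$params$energy_filter,
      " kJ/mol\n", sep = "")
  tab <- table(x$entries$adduct)
  cat("  entries by adduct: ",
      paste(names(tab), tab, sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Save / load a spectral library
#'
#' The on-disk format is a single JSON document: a metadata header (schema
#' version and build parameters) plus per-molecule and per-entry blocks.
#' Stick spectra are stored at full precision; grid spectra are
#' denormalizable caches and are recomputed from the sticks on load, so a
#' loaded library always satisfies the stick-to-grid reproducibility
#' invariant.
#'
#' @param lib `ir_library` object.
#' @param path Destination file.
#' @return `save_library` returns `path` invisibly; `load_library` returns
#'   the restored `ir_library`.
#' @export
save_library <- function(lib, path) {
  stopifnot(inherits(lib, "ir_library"))
  mols <- lapply(seq_len(nrow(lib$molecules)), function(i) {
    g <- lib$molecules$graph[[i]]
    list(
      id = lib$molecules$id[i],
      smiles = lib$molecules$smiles[i],
      formula = lib$molecules$formula[i],
      monoisotopic_mass = lib$molecules$monoisotopic_mass[i],
      fingerprint = as.integer(lib$molecules$fingerprint[[i]]),
      graph = list(elements = g$elements,
                   bonds = if (nrow(g$bonds)) unclass(as.data.frame(g$bonds)) else NULL,
                   heavy = as.integer(g$heavy), n_h = as.integer(g$n_h))
    )
  })
  entries <- lapply(seq_len(nrow(lib$entries)), function(i) {
    e <- lib$entries[i, ]
    list(
      entry_id = e$entry_id, molecule_id = e$molecule_id, adduct = e$adduct,
      site = e$site, variant = e$variant,
      relative_energy = e$relative_energy,
      stick = list(frequency = e$stick[[1]]$frequency,
                   intensity = e$stick[[1]]$intensity)
    )
  })
  doc <- list(schema = LIBRARY_SCHEMA, params = lib$params,
              molecules = mols, entries = entries)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname save_library
#' @export
load_library <- function(path) {
  stopifnot(file.exists(path))
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                  error = function(e) {
                    stop("cannot read library file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (!identical(doc$schema, LIBRARY_SCHEMA)) {
    stop("library schema mismatch: found '", doc$schema %||% "<none>",
         "', expected '", LIBRARY_SCHEMA, "'", call. = FALSE)
  }
  molecules <- tibble::tibble(
    id = vapply(doc$molecules, `[[`, character(1), "id"),
    smiles = vapply(doc$molecules, `[[`, character(1), "smiles"),
    formula = vapply(doc$molecules, `[[`, character(1), "formula"),
    monoisotopic_mass = vapply(doc$molecules, `[[`, numeric(1),
                               "monoisotopic_mass"),
    fingerprint = lapply(doc$molecules,
                         function(m) as.integer(unlist(m$fingerprint))),
    graph = lapply(doc$molecules, function(m) {
      b <- m$graph$bonds
      bonds <- if (is.null(b)) {
        matrix(integer(), 0, 3)
      } else {
        cbind(as.integer(unlist(b$V1)), as.integer(unlist(b$V2)),
              as.integer(unlist(b$V3)))
      }
      list(elements = as.character(unlist(m$graph$elements)),
           bonds = bonds,
           heavy = as.integer(unlist(m$graph$heavy)),
           n_h = as.integer(unlist(m$graph$n_h)))
    })
  )
  freq_tables <- tibble::tibble(
    molecule_id = vapply(doc$entries, `[[`, character(1), "molecule_id"),
    adduct = vapply(doc$entries, `[[`, character(1), "adduct"),
    site = vapply(doc$entries, function(e) as.integer(e$site), integer(1)),
    variant = vapply(doc$entries, function(e) as.character(e$variant),
                     character(1)),
    relative_energy = vapply(doc$entries, `[[`, numeric(1),
                             "relative_energy"),
    stick = lapply(doc$entries, function(e) {
      stick_spectrum(as.numeric(unlist(e$stick$frequency)),
                     as.numeric(unlist(e$stick$intensity)))
    })
  )
  p <- doc$params
  build_library(molecules, freq_tables,
                scale = p$scale, fwhm = p$fwhm,
                grid = as.numeric(unlist(p$grid)),
                energy_filter = p$energy_filter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
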