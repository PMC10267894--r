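# Spectral similarity scoring and library search modes.

#' Square-root cosine spectral similarity
#'
#' The spectral similarity score used for retrieval:
#' \deqn{S_{spec} = 1000 \cdot \frac{\sum_i \sqrt{a_i b_i}}
#'   {\sqrt{(\sum_i a_i)(\sum_i b_i)}}}
#' i.e. the cosine similarity of the elementwise square-root-transformed
#' spectra, on a 0--1000 scale. The square-root transform damps the large
#' intensity deviations common in IRMPD-based measurements, weighting
#' frequency overlap more heavily than intensity agreement. The score is
#' symmetric and invariant to positive rescaling of either spectrum.
#'
#' @param a,b Grid spectra on a common axis (as tibbles from
#'   [grid_spectrum()]) or bare non-negative numeric vectors of equal length.
#' @return Score in \[0, 1000\].
#' @export
#' @examples
#' s_spec(c(1, 0), c(1, 1)) # 1000/sqrt(2)
s_spec <- function(a, b) {
  av <- if (is.data.frame(a)) a$intensity else a
  bv <- if (is.data.frame(b)) b$intensity else b
  stopifnot(length(av) == length(bv))
  if (any(av < 0) || any(bv < 0)) {
    stop("spectra must be non-negative; preprocess before scoring",
         call. = FALSE)
  }
  sa <- sum(av); sb <- sum(bv)
  if (sa == 0 || sb == 0) {
    stop("all-zero spectrum: cosine similarity undefined", call. = FALSE)
  }
  1000 * sum(sqrt(av * bv)) / sqrt(sa * sb)
}

# score one query vector against a list of grid intensity vectors,
# restricted to the index mask (query spectral coverage)
score_against <- function(q, grids, mask = NULL) {
  if (!is.null(mask)) {
    q <- q[mask]
    grids <- lapply(grids, function(g) g[mask])
  }
  sq <- sqrt(q)
  sa <- sum(q)
  if (sa == 0) stop("all-zero query spectrum over scored range", call. = FALSE)
  vapply(grids, function(g) {
    sb <- sum(g)
    if (sb == 0) return(0)
    1000 * sum(sq * sqrt(g)) / sqrt(sa * sb)
  }, numeric(1))
}

#' Best spectrum per ion within an energy tolerance
#'
#' Given the library entries of one (molecule, adduct) group, scores the
#' query against every geometry whose relative energy is within
#' `energy_tol` of the group's lowest-energy geometry and keeps the best
#' match. `energy_tol = 0` scores only the lowest-energy spectrum;
#' `energy_tol = Inf` considers all tautomers/conformers.
#'
#' @param entries Entries tibble (rows of `lib$entries` sharing molecule and
#'   adduct).
#' @param spectrum Query intensities: numeric vector on the library axis.
#' @param energy_tol Energy tolerance in kJ/mol, >= 0.
#' @param mask Optional logical mask restricting the scored wavenumber range.
#' @return One-row tibble with `molecule_id`, `adduct`, `entry_id`,
#'   `relative_energy` (of the best-matching geometry), `s_spec`,
#'   `n_considered`.
#' @export
select_spectra <- function(entries, spectrum, energy_tol = 0, mask = NULL) {
  stopifnot(nrow(entries) >= 1L, energy_tol >= 0)
  consider <- entries[entries$relative_energy <= energy_tol, , drop = FALSE]
  if (nrow(consider) == 0L) {
    consider <- entries[which.min(entries$relative_energy), , drop = FALSE]
  }
  sc <- score_against(spectrum, consider$grid, mask)
  ord <- order(-sc, consider$relative_energy, consider$entry_id)
  best <- ord[1]
  tibble::tibble(
    molecule_id = consider$molecule_id[best],
    adduct = consider$adduct[best],
    entry_id = consider$entry_id[best],
    relative_energy = consider$relative_energy[best],
    s_spec = sc[best],
    n_considered = nrow(consider)
  )
}

# resolve a query spectrum to intensities on the library axis plus the
# coverage mask over which scoring is performed
query_on_axis <- function(lib, spectrum) {
  x <- lib$wavenumber
  if (is.data.frame(spectrum)) {
    cov <- range(spectrum$wavenumber)
    y <- stats::approx(spectrum$wavenumber, spectrum$intensity, xout = x,
                       yleft = 0, yright = 0)$y
    mask <- x >= cov[1] & x <= cov[2]
  } else {
    stopifnot(length(spectrum) == length(x))
    y <- spectrum
    mask <- rep(TRUE, length(x))
  }
  if (any(y < 0)) stop("query spectrum has negative intensities", call. = FALSE)
  list(intensity = y, mask = mask)
}

#' Search a spectral library with an experimental IR spectrum
#'
#' Two search modes are provided. An *isomer search* restricts candidates to
#' entries of the query's adduct whose theoretical m/z matches the measured
#' precursor m/z within a ppm window (the practical equivalent of an exact
#' chemical-formula constraint). An *unsupervised search* retains only the
#' adduct constraint and ranks the whole library partition, which surfaces
#' structural analogues of compounds absent from the library. In both modes
#' each molecule contributes its best-matching geometry within `energy_tol`
#' (see [select_spectra()]), and hits are ranked by descending score with
#' deterministic tie-breaking (ascending relative energy, then entry id).
#'
#' @param lib Spectral library from [build_library()].
#' @param spectrum Query spectrum: a preprocessed grid spectrum tibble, or a
#'   numeric intensity vector on the library axis. Scoring is restricted to
#'   the intersection of the query's coverage and the library grid.
#' @param adduct Adduct constraint; see [adduct_mz()].
#' @param mode `"isomer"` or `"unsupervised"`.
#' @param precursor_mz Measured precursor m/z in Th (required for isomer
#'   mode unless `formula` is given).
#' @param tol_ppm m/z matching window in ppm (default 10).
#' @param formula Optional formula string for formula-exact isomer matching
#'   instead of the m/z window.
#' @param energy_tol Energy tolerance in kJ/mol (default 0: lowest-energy
#'   geometry only).
#' @return Hits tibble with columns `rank`, `molecule_id`, `entry_id`,
#'   `s_spec`, `relative_energy`, `formula`, `adduct_mz`, sorted by rank.
#'   Zero rows when no candidate matches.
#' @export
search_library <- function(lib, spectrum, adduct,
                           mode = c("isomer", "unsupervised"),
                           precursor_mz = NULL, tol_ppm = 10,
                           formula = NULL, energy_tol = 0) {
  mode <- match.arg(mode)
  adduct <- match_adduct(adduct)
  q <- query_on_axis(lib, spectrum)
  cand <- lib$entries[lib$entries$adduct == adduct, , drop = FALSE]
  if (mode == "isomer") {
    if (!is.null(formula)) {
      cand <- cand[cand$formula == formula, , drop = FALSE]
    } else {
      if (is.null(precursor_mz)) {
        stop("isomer search requires precursor_mz (or formula)", call. = FALSE)
      }
      stopifnot(precursor_mz > 0)
      keep <- abs(cand$adduct_mz - precursor_mz) / precursor_mz <= tol_ppm * 1e-6
      cand <- cand[keep, , drop = FALSE]
    }
  }
  rank_candidates(lib, cand, q, energy_tol)
}

# score candidate entries molecule-by-molecule (vectorized over the
# library's square-root grid cache) and assemble the ranked hit table;
# deterministic under any input entry order
rank_candidates <- function(lib, cand, q, energy_tol) {
  empty <- tibble::tibble(rank = integer(), molecule_id = character(),
                          entry_id = character(), s_spec = numeric(),
                          relative_energy = numeric(), formula = character(),
                          adduct_mz = numeric())
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(cand$entry_id), , drop = FALSE]
  # geometries within the energy tolerance; the 0 kJ/mol geometry of every
  # (molecule, adduct) group always qualifies because energies are re-zeroed
  consider <- cand[cand$relative_energy <= energy_tol, , drop = FALSE]
  qv <- q$intensity
  full <- all(q$mask)
  if (full) {
    sq <- sqrt(qv)
    sa <- sum(qv)
    num <- as.vector(lib$sqrt_grid[consider$entry_id, , drop = FALSE] %*% sq)
    sb <- lib$grid_sums[consider$entry_id]
  } else {
    sq <- sqrt(qv[q$mask])
    sa <- sum(qv[q$mask])
    sub <- lib$sqrt_grid[consider$entry_id, q$mask, drop = FALSE]
    num <- as.vector(sub %*% sq)
    sb <- rowSums(sub^2)
  }
  if (sa == 0) stop("all-zero query spectrum over scored range", call. = FALSE)
  sc <- unname(ifelse(sb == 0, 0, 1000 * num / sqrt(sa * sb)))

  ord <- order(-sc, consider$relative_energy, consider$entry_id)
  best <- ord[!duplicated(consider$molecule_id[ord])]
  hits <- tibble::tibble(
    molecule_id = consider$molecule_id[best],
    entry_id = consider$entry_id[best],
    s_spec = sc[best],
    relative_energy = consider$relative_energy[best],
    formula = consider$formula[best],
    adduct_mz = consider$adduct_mz[best]
  )
  hits <- hits[order(-hits$s_spec, hits$relative_energy, hits$entry_id), ]
  hits$rank <- seq_len(nrow(hits))
  hits[, c("rank", "molecule_id", "entry_id", "s_spec", "relative_energy",
           "formula", "adduct_mz")]
}

#' Combine ranked hit lists from multiple adducts
#'
#' When IR spectra of several adducts of the same metabolite are available,
#' their evidence is combined by ranking candidates on the product of the
#' per-adduct spectral similarity scores. Only molecules present in every
#' supplied hit list are candidates, keeping the products comparable.
#'
#' @param hit_lists A list of hits tibbles from [search_library()] (one per
#'   adduct).
#' @return Tibble with columns `rank`, `molecule_id`, `combined_score`,
#'   `n_adducts`. With a single list the ranking is unchanged.
#' @export
combine_adducts <- function(hit_lists) {
  stopifnot(is.list(hit_lists), length(hit_lists) >= 1L)
  common <- Reduce(intersect, lapply(hit_lists, function(h) h$molecule_id))
  if (length(common) == 0L) {
    return(tibble::tibble(rank = integer(), molecule_id = character(),
                          combined_score = numeric(), n_adducts = integer()))
  }
  score <- rep(1, length(common))
  for (h in hit_lists) {
    score <- score * h$s_spec[match(common, h$molecule_id)]
  }
  ord <- order(-score, common)
  tibble::tibble(
    rank = seq_along(common),
    molecule_id = common[ord],
    combined_score = score[ord],
    n_adducts = length(hit_lists)
  )
}

#' Rank of a molecule in a hit list
#'
#' @param hits Hits tibble from [search_library()] or [combine_adducts()].
#' @param molecule_id Molecule identifier to look up.
#' @return 1-based rank (integer).
#' @export
rank_of <- function(hits, molecule_id) {
  i <- which(hits$molecule_id == molecule_id)
  if (length(i) == 0L) {
    stop("molecule '", molecule_id, "' not present in hit list", call. = FALSE)
  }
  as.integer(hits$rank[min(i)])
}
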