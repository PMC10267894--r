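# Spectrum containers and transforms. A stick spectrum is a tibble of
# computed normal modes (frequency, intensity); a grid spectrum is a tibble
# (wavenumber, intensity) on a regular wavenumber axis.

#' Construct a stick spectrum
#'
#' @param frequency Harmonic frequencies in cm^-1, strictly positive.
#' @param intensity IR intensities in km/mol, non-negative.
#' @return A tibble of class `ir_stick` with columns `frequency`, `intensity`,
#'   sorted by frequency. An empty stick spectrum is allowed but carries an
#'   `empty` attribute (degenerate ingested data).
#' @export
stick_spectrum <- function(frequency = numeric(), intensity = numeric()) {
  stopifnot(length(frequency) == length(intensity))
  if (length(frequency) > 0L) {
    stopifnot(all(frequency > 0), all(intensity >= 0))
  }
  ord <- order(frequency)
  out <- tibble::tibble(frequency = as.numeric(frequency[ord]),
                        intensity = as.numeric(intensity[ord]))
  class(out) <- c("ir_stick", class(out))
  attr(out, "empty") <- length(frequency) == 0L
  out
}

#' Construct a grid spectrum
#'
#' @param wavenumber Regularly spaced wavenumber axis in cm^-1 (as from
#'   [ir_grid()]).
#' @param intensity Intensities (arbitrary units), same length.
#' @return A tibble of class `ir_grid_spectrum` with columns `wavenumber`,
#'   `intensity`.
#' @export
grid_spectrum <- function(wavenumber, intensity) {
  stopifnot(length(wavenumber) == length(intensity), length(wavenumber) >= 2L)
  d <- diff(wavenumber)
  stopifnot(all(d > 0))
  if (max(d) - min(d) > 1e-8 * max(d)) {
    stop("wavenumber axis must be regularly spaced", call. = FALSE)
  }
  out <- tibble::tibble(wavenumber = as.numeric(wavenumber),
                        intensity = as.numeric(intensity))
  class(out) <- c("ir_grid_spectrum", class(out))
  out
}

grid_axis <- function(spectrum) spectrum$wavenumber

as_grid_vector <- function(grid) {
  if (length(grid) == 3L && is.null(attr(grid, "step"))) {
    ir_grid(grid[1], grid[2], grid[3])
  } else {
    grid
  }
}

#' IRMPD yield from parent and fragment ion counts
#'
#' The infrared multiple-photon dissociation yield at one laser wavelength,
#' using the first-order survival form
#' \eqn{Y = -\ln(\mathrm{parent} / (\mathrm{parent} + \sum \mathrm{fragments}))}.
#' A simple fragment-fraction form
#' \eqn{Y = \sum \mathrm{fragments} / (\mathrm{parent} + \sum \mathrm{fragments})}
#' is available via `form = "fraction"`.
#'
#' @param parent Precursor ion intensity (counts, > 0).
#' @param fragments Numeric vector of fragment ion intensities (counts, >= 0).
#' @param form `"survival"` (default) or `"fraction"`.
#' @return Dimensionless yield >= 0.
#' @export
#' @examples
#' irmpd_yield(50, c(25, 25)) # -log(1/2)
irmpd_yield <- function(parent, fragments = numeric(),
                        form = c("survival", "fraction")) {
  form <- match.arg(form)
  stopifnot(is.numeric(parent), length(parent) == 1L)
  if (parent <= 0) stop("parent intensity must be > 0; yield undefined",
                        call. = FALSE)
  stopifnot(all(fragments >= 0))
  total <- parent + sum(fragments)
  if (form == "survival") -log(parent / total) else sum(fragments) / total
}

#' Read a laser power curve
#'
#' Two-column text (wavenumber in cm^-1, pulse energy in mJ), whitespace- or
#' comma-separated.
#'
#' @param path File path.
#' @return A tibble with columns `wavenumber`, `pulse_energy`, sorted.
#' @export
read_power_curve <- function(path) {
  d <- utils::read.table(path, header = FALSE, sep = "",
                         comment.char = "#",
                         col.names = c("wavenumber", "pulse_energy"))
  power_curve(d$wavenumber, d$pulse_energy)
}

#' @rdname read_power_curve
#' @param wavenumber,pulse_energy Numeric vectors; pulse energies must be
#'   strictly positive.
#' @export
power_curve <- function(wavenumber, pulse_energy) {
  stopifnot(length(wavenumber) == length(pulse_energy),
            all(pulse_energy > 0))
  ord <- order(wavenumber)
  out <- tibble::tibble(wavenumber = as.numeric(wavenumber[ord]),
                        pulse_energy = as.numeric(pulse_energy[ord]))
  class(out) <- c("ir_power_curve", class(out))
  out
}

#' Correct a spectrum for frequency-dependent laser power
#'
#' First-order linear correction: each intensity is divided by the pulse
#' energy linearly interpolated at its wavenumber. The grid is unchanged.
#'
#' @param spectrum Grid spectrum.
#' @param power Power curve from [power_curve()]/[read_power_curve()]; must
#'   span the spectrum's wavenumber range.
#' @return Corrected grid spectrum.
#' @export
power_correct <- function(spectrum, power) {
  e <- stats::approx(power$wavenumber, power$pulse_energy,
                     xout = spectrum$wavenumber, rule = 2)$y
  if (any(e <= 0)) stop("non-positive interpolated pulse energy", call. = FALSE)
  rng <- range(spectrum$wavenumber)
  if (min(power$wavenumber) > rng[1] || max(power$wavenumber) < rng[2]) {
    stop("power curve does not span the spectrum's wavenumber range",
         call. = FALSE)
  }
  grid_spectrum(spectrum$wavenumber, spectrum$intensity / e)
}

#' Scale and broaden a stick spectrum onto a grid
#'
#' Multiplies every harmonic frequency by `scale` (default 0.975, the
#' empirical correction for anharmonicity at the level of theory the library
#' ingests) and convolves the scaled sticks with a unit-area Gaussian profile
#' of the given full width at half maximum (default 45 cm^-1). Gaussians are
#' truncated at +/- 5 FWHM; the neglected area is below 1e-7 of a band.
#'
#' @param stick Stick spectrum from [stick_spectrum()].
#' @param scale Dimensionless frequency scaling factor, > 0.
#' @param fwhm Gaussian full width at half maximum in cm^-1, > 0.
#' @param grid Wavenumber axis from [ir_grid()], or `c(start, stop, step)`.
#' @return Grid spectrum. An empty stick spectrum yields an all-zero grid and
#'   a warning.
#' @export
#' @examples
#' s <- stick_spectrum(1000, 1)
#' g <- scale_and_broaden(s)          # peak at 975 cm^-1
#' g$wavenumber[which.max(g$intensity)]
scale_and_broaden <- function(stick, scale = default_scale,
                              fwhm = default_fwhm,
                              grid = ir_grid()) {
  stopifnot(scale > 0, fwhm > 0)
  x <- as_grid_vector(grid)
  y <- numeric(length(x))
  if (nrow(stick) == 0L) {
    warning("empty stick spectrum: returning all-zero grid spectrum")
    return(grid_spectrum(x, y))
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  centers <- scale * stick$frequency
  norm <- 1 / (sigma * sqrt(2 * pi))
  cutoff <- 5 * fwhm
  for (k in seq_along(centers)) {
    lo <- findInterval(centers[k] - cutoff, x) + 1L
    hi <- findInterval(centers[k] + cutoff, x)
    if (hi < lo) next
    idx <- lo:hi
    y[idx] <- y[idx] +
      stick$intensity[k] * norm * exp(-(x[idx] - centers[k])^2 / (2 * sigma^2))
  }
  grid_spectrum(x, y)
}

#' Resample a grid spectrum onto a new grid
#'
#' Linear interpolation inside the source coverage, zero outside.
#'
#' @param spectrum Grid spectrum.
#' @param grid Target axis from [ir_grid()] or `c(start, stop, step)`.
#' @return Grid spectrum on the target axis.
#' @export
resample_spectrum <- function(spectrum, grid) {
  x <- as_grid_vector(grid)
  src <- range(spectrum$wavenumber)
  if (max(x) < src[1] || min(x) > src[2]) {
    stop("target grid does not overlap the source spectrum", call. = FALSE)
  }
  y <- stats::approx(spectrum$wavenumber, spectrum$intensity, xout = x,
                     yleft = 0, yright = 0)$y
  grid_spectrum(x, y)
}

#' Preprocess an experimental IR spectrum for scoring
#'
#' Sorts the points, applies the laser power correction when a power curve is
#' supplied, clips negative (baseline-noise) intensities to zero, and
#' resamples onto the matching grid. The square-root transform used in
#' scoring requires the non-negativity.
#'
#' @param points Data frame or tibble with the first two columns interpreted
#'   as wavenumber (cm^-1) and intensity; at least 2 points.
#' @param power Optional power curve.
#' @param grid Target axis (default [ir_grid()]).
#' @return Grid spectrum ready for [s_spec()].
#' @export
preprocess_experimental <- function(points, power = NULL, grid = ir_grid()) {
  stopifnot(is.data.frame(points), nrow(points) >= 2L)
  wn <- as.numeric(points[[1]])
  y <- as.numeric(points[[2]])
  ord <- order(wn)
  wn <- wn[ord]; y <- y[ord]
  keep <- !duplicated(wn)
  spec <- grid_spectrum_irregular(wn[keep], y[keep])
  if (!is.null(power)) spec <- power_correct_irregular(spec, power)
  spec$intensity <- pmax(spec$intensity, 0)
  x <- as_grid_vector(grid)
  yg <- stats::approx(spec$wavenumber, spec$intensity, xout = x,
                      yleft = 0, yright = 0)$y
  grid_spectrum(x, yg)
}

# internal: tolerate irregular experimental axes before resampling
grid_spectrum_irregular <- function(wavenumber, intensity) {
  stopifnot(all(diff(wavenumber) > 0))
  tibble::tibble(wavenumber = wavenumber, intensity = intensity)
}

power_correct_irregular <- function(spec, power) {
  e <- stats::approx(power$wavenumber, power$pulse_energy,
                     xout = spec$wavenumber, rule = 2)$y
  if (any(e <= 0)) stop("non-positive interpolated pulse energy", call. = FALSE)
  spec$intensity <- spec$intensity / e
  spec
}

#' Read a two-column experimental spectrum
#'
#' Whitespace- or comma-separated text with wavenumber (cm^-1) and intensity
#' columns; lines starting with `#` are ignored.
#'
#' @param path File path.
#' @return Tibble with columns `wavenumber`, `intensity` (unsorted raw
#'   points; feed to [preprocess_experimental()]).
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  lines <- gsub(",", " ", lines, fixed = TRUE)
  parts <- strsplit(trimws(lines), "[ \t]+")
  tibble::tibble(
    wavenumber = vapply(parts, function(p) as.numeric(p[1]), numeric(1)),
    intensity = vapply(parts, function(p) as.numeric(p[2]), numeric(1))
  )
}

#' Read a JCAMP-DX infrared spectrum
#'
#' Minimal reader for JCAMP-DX files in `(X++(Y..Y))` AFFN form (the common
#' export of IR instruments): honours `XFACTOR`/`YFACTOR` and `DELTAX`
#' implied by `FIRSTX`/`LASTX`/`NPOINTS`.
#'
#' @param path File path.
#' @return Tibble with columns `wavenumber`, `intensity`.
#' @export
read_jcamp <- function(path) {
  lines <- readLines(path)
  get_field <- function(name, default = NA_real_) {
    rx <- paste0("^##", name, "=")
    hit <- grep(rx, lines, value = TRUE)
    if (length(hit) == 0L) return(default)
    as.numeric(sub(rx, "", hit[1]))
  }
  xfac <- get_field("XFACTOR", 1)
  yfac <- get_field("YFACTOR", 1)
  firstx <- get_field("FIRSTX")
  lastx <- get_field("LASTX")
  npoints <- get_field("NPOINTS")
  start <- grep("^##XYDATA=", lines)
  if (length(start) == 0L) stop("no ##XYDATA block in ", path, call. = FALSE)
  end <- grep("^##END=", lines)
  end <- min(end[end > start[1]], length(lines) + 1L)
  block <- lines[(start[1] + 1L):(end - 1L)]
  xs <- c(); ys <- c()
  for (ln in block) {
    vals <- as.numeric(strsplit(trimws(ln), "[ \t]+")[[1]])
    if (length(vals) < 2L || anyNA(vals[1])) next
    xs <- c(xs, vals[1])
    ys <- c(ys, vals[-1])
  }
  if (!is.na(npoints) && !is.na(firstx) && !is.na(lastx) && npoints > 1) {
    x <- seq(firstx, lastx, length.out = npoints) * xfac
    y <- ys[seq_len(npoints)] * yfac
  } else {
    # fall back: first value per line is x of the first y; assume uniform
    # in-line spacing from consecutive line starts
    x <- xs[1] * xfac + seq(0, length.out = length(ys)) *
      (if (length(xs) > 1) (xs[2] - xs[1]) / max(1, length(ys) / length(xs)) else 1) * xfac
    y <- ys * yfac
  }
  ord <- order(x)
  tibble::tibble(wavenumber = x[ord], intensity = y[ord])
}

#' Read a computed stick-spectrum table
#'
#' Tabular text with a metadata header of `# key: value` lines followed by
#' whitespace-separated columns `mode_index frequency_cm-1 intensity_km_mol`
#' (a header row is allowed). Header keys used by the library build:
#' `molecule_id`, `adduct`, `site`, `variant`, `relative_energy_kj_mol`.
#'
#' @param path File path.
#' @return A [stick_spectrum()] with a `meta` attribute (named list of header
#'   fields).
#' @export
read_stick_table <- function(path) {
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^#\\s*", "", ml)
    if (!grepl(":", kv, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  body <- body[!grepl("[A-Za-z]", body)]  # drop a column-name header row
  parts <- lapply(strsplit(trimws(body), "[ \t,]+"), as.numeric)
  freq <- vapply(parts, function(p) p[length(p) - 1L], numeric(1))
  inten <- vapply(parts, function(p) p[length(p)], numeric(1))
  out <- stick_spectrum(freq, inten)
  attr(out, "meta") <- meta
  out
}
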