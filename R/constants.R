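# Physical constants and adduct definitions. All masses in Da.

#' Monoisotopic atomic masses
#'
#' Fixed internal table of monoisotopic masses (most abundant isotope) for the
#' elements handled by the package, in Da. Values follow the 2021 AME/CODATA
#' recommendations truncated to ten significant figures.
#'
#' @format Named numeric vector, element symbol to mass in Da.
#' @export
atomic_masses <- c(
  H  = 1.007825032,
  C  = 12.0,
  N  = 14.003074005,
  O  = 15.994914620,
  F  = 18.998403163,
  Na = 22.989769280,
  P  = 30.973761998,
  S  = 31.972071174,
  Cl = 34.968852682,
  Br = 78.918337600,
  I  = 126.904471900
)

#' Mass of the electron in Da
#' @export
electron_mass <- 0.000548580

# proton mass = H atom minus one electron; the value the field quotes for
# [M+H]+ / [M-H]- shifts
proton_mass <- 1.007276

#' Adduct types
#'
#' The three electrospray adducts handled throughout the package:
#' protonated \eqn{[M+H]^+}, deprotonated \eqn{[M-H]^-} and sodiated
#' \eqn{[M+Na]^+}. Mass shifts include the electron-mass convention: the shift
#' for sodiation is the mass of Na minus one electron.
#'
#' @format A tibble with columns `adduct` (label), `charge` (+1 or -1) and
#'   `mass_shift` (Da, signed).
#' @export
adduct_types <- tibble::tibble(
  adduct     = c("protonated", "deprotonated", "sodiated"),
  label      = c("[M+H]+", "[M-H]-", "[M+Na]+"),
  charge     = c(1L, -1L, 1L),
  mass_shift = c(1.007276, -1.007276, 22.989221)
)

# resolve a user-supplied adduct name ("protonated" or "[M+H]+") to the
# canonical label; errors on anything else
match_adduct <- function(adduct) {
  stopifnot(length(adduct) == 1L, is.character(adduct))
  hit <- adduct_types$adduct[adduct_types$adduct == adduct |
                               adduct_types$label == adduct]
  if (length(hit) != 1L) {
    stop("unknown adduct '", adduct, "'; expected one of ",
         paste(adduct_types$adduct, collapse = ", "),
         " (or the bracket labels ", paste(adduct_types$label, collapse = ", "), ")",
         call. = FALSE)
  }
  hit
}

#' Default spectral matching grid
#'
#' Regular wavenumber axis used for library and query spectra. The default
#' covers the 600--1850 cm\eqn{^{-1}} fingerprint region at 1 cm\eqn{^{-1}}
#' spacing.
#'
#' @param start,stop Range in cm^-1.
#' @param step Grid spacing in cm^-1, > 0.
#' @return Numeric vector of wavenumbers with attributes `start`, `stop`, `step`.
#' @export
ir_grid <- function(start = 600, stop = 1850, step = 1) {
  stopifnot(is.numeric(start), is.numeric(stop), is.numeric(step),
            step > 0, stop > start)
  x <- seq(from = start, to = stop, by = step)
  structure(x, start = start, stop = stop, step = step)
}

# default scaling factor applied to harmonic frequencies and Gaussian FWHM
# used for band convolution
default_scale <- 0.975
default_fwhm <- 45
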