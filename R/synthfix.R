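# Synthetic benchmark generator: molecule families from a fragment grammar,
# functional-group-determined mock stick spectra, noise models emulating
# experimental IRIS spectra, and an end-to-end benchmark builder.

# deterministic 31-bit hash of any combination of strings/numbers; used to
# derive independent per-molecule/per-record RNG seeds from one master seed
stable_hash <- function(...) {
  s <- paste(vapply(list(...), function(x) paste(format(x), collapse = ","),
                    character(1)), collapse = "|")
  h <- 17
  for (v in utf8ToInt(s)) h <- (h * 31 + v) %% 2147483647
  as.integer(h)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a structurally related molecule family
#'
#' Draws `n` distinct small molecules from a fragment grammar: benzene-ring
#' and alkyl-chain scaffolds decorated with hydroxyl, carboxyl, amino,
#' carbonyl and methoxy substituents. Members sharing scaffolds and
#' substituents are structurally similar (Tanimoto well above 0.5) while
#' ring-versus-chain pairs are dissimilar, giving the graded
#' structure-similarity range a retrieval benchmark needs. Deterministic per
#' seed.
#'
#' @param n Number of molecules (>= 1).
#' @param seed Integer RNG seed.
#' @return Molecules tibble, as from [parse_molecules()], with ids
#'   `synth001`, `synth002`, ...
#' @export
generate_family <- function(n, seed = 42) {
  stopifnot(n >= 1)
  ring_subs <- c("O", "C(=O)O", "CC(=O)O", "N", "OC", "C(C)=O", "CO", "C")
  chain_subs <- c("O", "C(=O)O", "N", "OC", "CO")
  hetero <- function(s) grepl("[ON]", s)
  smiles <- character(0)
  with_seed(seed, {
    tries <- 0
    while (length(smiles) < n && tries < 200 * n) {
      tries <- tries + 1
      if (stats::runif(1) < 0.55) {
        # benzene scaffold with 1-3 substituents
        k <- sample(1:3, 1)
        pos <- sort(sample(1:6, k))
        subs <- sample(ring_subs, k, replace = TRUE)
        if (!any(hetero(subs))) subs[1] <- sample(ring_subs[hetero(ring_subs)], 1)
        br <- rep("", 6)
        br[pos] <- paste0("(", subs, ")")
        tail6 <- ""
        if (nzchar(br[6])) { tail6 <- subs[length(subs)]; br[6] <- "" }
        smi <- paste0("c1", br[1], "c", br[2], "c", br[3], "c", br[4],
                      "c", br[5], "c1", tail6)
      } else {
        # alkyl chain of 2-6 carbons with 1-3 substituents
        len <- sample(2:6, 1)
        k <- sample(1:min(3, len), 1)
        pos <- sort(sample(seq_len(len), k))
        subs <- sample(chain_subs, k, replace = TRUE)
        if (!any(hetero(subs))) subs[1] <- sample(chain_subs[hetero(chain_subs)], 1)
        atoms <- rep("C", len)
        for (j in seq_len(k)) {
          atoms[pos[j]] <- paste0("C(", subs[j], ")")
        }
        smi <- paste0(atoms, collapse = "")
      }
      can <- tryCatch(suppressWarnings(ob_canonical_smiles(smi)),
                      error = function(e) character(0))
      if (length(can) == 1L && nzchar(can) && !(can %in% smiles)) {
        smiles <- c(smiles, can)
      }
    }
  })
  if (length(smiles) < n) {
    stop("fragment grammar exhausted before generating ", n,
         " unique structures", call. = FALSE)
  }
  parse_molecules(data.frame(
    smiles = smiles,
    id = sprintf("synth%03d", seq_len(n))
  ))
}

#' Diagnostic band rules for mock stick spectra
#'
#' A curated table mapping substructures (SMARTS, matched on the molecular
#' graph) and adducts to characteristic mid-IR bands with
#' literature-plausible centers: carboxylate O-C-O stretches near 1300 and
#' 1650 cm^-1, O-H bend near 1450 cm^-1, carbonyl stretches at 1700-1750
#' cm^-1, phenoxide C-O near 1600 cm^-1, and generic aromatic/aliphatic
#' modes. The purpose of the table is to induce a structure-spectrum
#' correlation in the synthetic benchmark, not chemical accuracy.
#'
#' @return Tibble with columns `rule_id`, `smarts`, `adduct` (`NA` = any),
#'   `center` (cm^-1), `center_spread` (cm^-1), `intensity_mean`,
#'   `intensity_spread` (lognormal sigma).
#' @export
band_rules <- function() {
  tibble::tribble(
    ~rule_id,          ~smarts,                      ~adduct,        ~center, ~center_spread, ~intensity_mean, ~intensity_spread,
    "carboxylate_sym", "[CX3](=O)[OX2H1]",           "deprotonated", 1300,    10,             260,             0.25,
    "carboxylate_asym","[CX3](=O)[OX2H1]",           "deprotonated", 1650,    10,             300,             0.25,
    "cooh_co",         "[CX3](=O)[OX2H1]",           "protonated",   1750,    8,              280,             0.25,
    "cooh_co_na",      "[CX3](=O)[OX2H1]",           "sodiated",     1720,    8,              240,             0.25,
    "cooh_c_o",        "[CX3](=O)[OX2H1]",           NA,             1180,    12,             150,             0.3,
    "oh_bend",         "[OX2H]",                     NA,             1450,    12,             110,             0.3,
    "phenol_co",       "[OX2H][c]",                  NA,             1250,    10,             130,             0.3,
    "phenoxide_co",    "[OX2H][c]",                  "deprotonated", 1600,    10,             180,             0.3,
    "alcohol_co",      "[OX2H][CX4]",                NA,             1060,    12,             100,             0.3,
    "amine_scissor",   "[NX3H2]",                    NA,             1615,    10,             95,              0.3,
    "amine_cn",        "[NX3H2]",                    NA,             1080,    12,             70,              0.3,
    "ether_coc",       "[OX2]([CH3])[#6]",           NA,             1105,    10,             140,             0.3,
    "ketone_co",       "[#6][CX3](=[OX1])[#6]",      NA,             1712,    8,              250,             0.25,
    "aldehyde_co",     "[CX3H1]=[OX1]",              NA,             1725,    8,              220,             0.25,
    "aromatic_cc1",    "c1ccccc1",                   NA,             1600,    8,              80,              0.3,
    "aromatic_cc2",    "c1ccccc1",                   NA,             1500,    8,              90,              0.3,
    "aromatic_ch",     "c1ccccc1",                   NA,             1160,    10,             45,              0.35,
    "ch2_bend",        "[CX4H2]",                    NA,             1455,    8,              35,              0.35,
    "skeletal_cc",     "[CX4][CX4]",                 NA,             980,     20,             40,              0.35
  )
}

# number of unique SMARTS matches per molecule, computed once per rule table
rule_match_matrix <- function(molecules, rules) {
  patterns <- unique(rules$smarts)
  sdfset <- molecules_sdfset(molecules)
  m <- vapply(patterns,
              function(p) count_smarts_matches(molecules, p, sdfset),
              integer(nrow(molecules)))
  matrix(m, nrow = nrow(molecules),
         dimnames = list(molecules$id, patterns))
}

#' Mock stick spectrum of an adduct ion
#'
#' Builds the union of the bands of every matching rule, with deterministic
#' per-(molecule, adduct, rule) center offsets and intensity factors drawn
#' from the rule's stated spreads, plus three weak molecule-specific
#' skeletal modes in the 650-1350 cm^-1 region so that even molecules with
#' identical rule sets remain distinguishable. Band intensities scale with
#' the substructure match count. Identical (molecule, adduct, rules, seed)
#' always yield the identical spectrum.
#'
#' @param molecule One-row molecules tibble.
#' @param adduct Adduct label.
#' @param rules Band-rule table, see [band_rules()].
#' @param seed Master integer seed.
#' @param variant Geometry tag; different variants of the same ion get
#'   different offsets (emulating tautomer/conformer spectra).
#' @param match_counts Optional precomputed named match-count vector (one
#'   per unique SMARTS in `rules`) to avoid repeated substructure searches.
#' @return A [stick_spectrum()]; empty (with a warning flag) when no rule
#'   matches.
#' @export
synth_stick <- function(molecule, adduct, rules = band_rules(), seed = 42,
                        variant = "g0", match_counts = NULL) {
  adduct <- match_adduct(adduct)
  if (is.null(match_counts) && nrow(rules) > 0L) {
    mm <- rule_match_matrix(molecule, rules)
    match_counts <- mm[1, ]
  }
  freq <- numeric(0); inten <- numeric(0)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if (!is.na(r$adduct) && r$adduct != adduct) next
    cnt <- match_counts[[r$smarts]]
    if (cnt == 0L) next
    off <- with_seed(stable_hash(seed, molecule$id, adduct, r$rule_id, variant), {
      list(dc = stats::rnorm(1, 0, r$center_spread),
           fi = exp(stats::rnorm(1, 0, r$intensity_spread)))
    })
    freq <- c(freq, r$center + off$dc)
    inten <- c(inten, r$intensity_mean * off$fi * cnt)
  }
  # molecule-specific weak skeletal modes
  sk <- with_seed(stable_hash(seed, molecule$id, adduct, "skeletal", variant), {
    list(f = stats::runif(3, 650, 1350), i = stats::runif(3, 15, 45))
  })
  freq <- c(freq, sk$f); inten <- c(inten, sk$i)
  if (length(freq) == 0L) {
    warning("no band rule matches molecule ", molecule$id,
            ": empty stick spectrum")
    return(stick_spectrum())
  }
  stick_spectrum(freq, inten)
}

#' Noise model for synthetic query spectra
#'
#' Describes the perturbations applied to a truth spectrum to emulate an
#' experimental IRIS measurement: Gaussian jitter of band positions,
#' lognormal multiplicative intensity noise (the dominant deviation in
#' IRMPD-based measurements), extra Gaussian broadening, and an additive
#' smooth baseline.
#'
#' @param frequency_jitter Per-band frequency jitter sigma in cm^-1 (>= 0).
#' @param intensity_sigma Lognormal sigma of per-band intensity factors
#'   (>= 0).
#' @param broadening Multiplicative broadening factor on the convolution
#'   FWHM (>= 1).
#' @param baseline Additive baseline amplitude as a fraction of the spectrum
#'   maximum (>= 0).
#' @param seed Mandatory integer seed.
#' @return Object of class `iris_noise_model`.
#' @export
noise_model <- function(frequency_jitter = 0, intensity_sigma = 0,
                        broadening = 1, baseline = 0, seed) {
  stopifnot(frequency_jitter >= 0, intensity_sigma >= 0, broadening >= 1,
            baseline >= 0, !missing(seed))
  structure(list(frequency_jitter = frequency_jitter,
                 intensity_sigma = intensity_sigma,
                 broadening = broadening,
                 baseline = baseline,
                 seed = as.integer(seed)),
            class = "iris_noise_model")
}

#' Perturb a spectrum with a noise model
#'
#' For a stick spectrum, each mode's frequency receives Gaussian jitter and
#' each intensity a lognormal factor. For a grid spectrum, the whole
#' spectrum is shifted by one Gaussian draw, convolved with the extra
#' broadening kernel, and given an additive smooth baseline, then clipped at
#' zero. A zero-parameter model returns its input unchanged. Deterministic
#' given the model's seed.
#'
#' @param x A stick or grid spectrum.
#' @param noise An [noise_model()] object.
#' @param ... Unused.
#' @return Perturbed spectrum of the same type.
#' @export
perturb <- function(x, noise, ...) UseMethod("perturb")

#' @rdname perturb
#' @export
perturb.ir_stick <- function(x, noise, ...) {
  stopifnot(inherits(noise, "iris_noise_model"))
  if (nrow(x) == 0L) return(x)
  if (noise$frequency_jitter == 0 && noise$intensity_sigma == 0) return(x)
  n <- nrow(x)
  draws <- with_seed(noise$seed, {
    list(df = stats::rnorm(n, 0, max(noise$frequency_jitter, 1e-12)),
         fi = exp(stats::rnorm(n, 0, max(noise$intensity_sigma, 1e-12))))
  })
  f <- x$frequency + if (noise$frequency_jitter > 0) draws$df else 0
  i <- x$intensity * if (noise$intensity_sigma > 0) draws$fi else 1
  stick_spectrum(pmax(f, 1e-6), i)
}

#' @rdname perturb
#' @export
perturb.ir_grid_spectrum <- function(x, noise, ...) {
  stopifnot(inherits(noise, "iris_noise_model"))
  y <- x$intensity
  wn <- x$wavenumber
  step <- wn[2] - wn[1]
  draws <- with_seed(noise$seed + 1L, {
    list(shift = stats::rnorm(1, 0, max(noise$frequency_jitter, 1e-12)),
         knots = stats::runif(8))
  })
  if (noise$frequency_jitter > 0) {
    y <- stats::approx(wn + draws$shift, y, xout = wn,
                       yleft = 0, yright = 0)$y
  }
  if (noise$broadening > 1) {
    # kernel chosen so a band of the default FWHM widens to broadening * FWHM
    sigma <- sqrt(noise$broadening^2 - 1) * default_fwhm / (2 * sqrt(2 * log(2)))
    half <- ceiling(5 * sigma / step)
    k <- stats::dnorm(seq(-half, half) * step, sd = sigma)
    k <- k / sum(k)
    y <- stats::filter(c(rep(0, half), y, rep(0, half)), k, sides = 2)
    y <- as.numeric(y[(half + 1):(half + length(wn))])
    y[is.na(y)] <- 0
  }
  if (noise$baseline > 0) {
    kx <- seq(min(wn), max(wn), length.out = length(draws$knots))
    base <- stats::spline(kx, draws$knots, xout = wn)$y
    y <- y + noise$baseline * max(y) * pmax(base, 0)
  }
  grid_spectrum(wn, pmax(y, 0))
}

# noise model with a derived seed (per-record reproducibility)
reseed_noise <- function(noise, ...) {
  noise$seed <- stable_hash(noise$seed, ...)
  noise
}

#' Build an end-to-end synthetic benchmark
#'
#' Generates a molecule family, mock stick spectra for every enumerable
#' (molecule, adduct, site) ion with one to three tautomer/conformer
#' variants and re-zeroed relative energies, builds the spectral library
#' through the standard [build_library()] path, and produces one validation
#' query per (molecule, adduct): the lowest-energy truth spectrum perturbed
#' by the noise model. Everything is deterministic given `(n, noise, seed)`.
#'
#' @param n Number of molecules (>= 10).
#' @param noise A [noise_model()]. Its seed is re-derived per record.
#' @param seed Master seed controlling family, sticks, variants and
#'   energies.
#' @param rules Band-rule table.
#' @param scale,fwhm,grid,energy_filter Library build parameters, as in
#'   [build_library()].
#' @param molecules Optional pre-generated molecules tibble (skips
#'   [generate_family()]); used to sweep noise levels over one family.
#' @return List with elements `library` (`ir_library`) and `records`
#'   (tibble: `record_id`, `metabolite_id`, `molecule_id`, `adduct`,
#'   `precursor_mz`, `spectrum` list-column of intensities on the library
#'   axis).
#' @export
build_synthetic_benchmark <- function(n = 150, noise = noise_model(seed = 1),
                                      seed = 42, rules = band_rules(),
                                      scale = default_scale,
                                      fwhm = default_fwhm,
                                      grid = c(600, 1850, 1),
                                      energy_filter = 40,
                                      molecules = NULL) {
  lib <- build_benchmark_library(n, seed = seed, rules = rules,
                                 scale = scale, fwhm = fwhm, grid = grid,
                                 energy_filter = energy_filter,
                                 molecules = molecules)
  list(library = lib, records = benchmark_queries(lib, noise))
}

#' @rdname build_synthetic_benchmark
#' @export
build_benchmark_library <- function(n = 150, seed = 42,
                                    rules = band_rules(),
                                    scale = default_scale,
                                    fwhm = default_fwhm,
                                    grid = c(600, 1850, 1),
                                    energy_filter = 40,
                                    molecules = NULL) {
  stopifnot(n >= 10 || !is.null(molecules))
  if (is.null(molecules)) molecules <- generate_family(n, seed)
  mm <- rule_match_matrix(molecules, rules)

  rows <- list()
  for (i in seq_len(nrow(molecules))) {
    mol <- molecules[i, ]
    for (ad in adduct_types$adduct) {
      sites <- enumerate_adduct_ions(mol, ad)
      if (nrow(sites) == 0L) next
      n_var <- 1L + stable_hash(seed, mol$id, ad, "nvar") %% 3L
      for (s in seq_len(nrow(sites))) {
        for (v in seq_len(n_var)) {
          # first site, first variant is the reference geometry at 0 kJ/mol
          energy <- if (s == 1L && v == 1L) 0 else {
            3 + (stable_hash(seed, mol$id, ad, sites$site[s], v, "energy") %%
                   5700) / 100
          }
          rows[[length(rows) + 1L]] <- tibble::tibble(
            molecule_id = mol$id, adduct = ad,
            site = sites$site[s], variant = paste0("g", v),
            relative_energy = energy,
            stick = list(synth_stick(mol, ad, rules, seed,
                                     variant = paste0("s", sites$site[s], "v", v),
                                     match_counts = mm[mol$id, ]))
          )
        }
      }
    }
  }
  freq_tables <- dplyr::bind_rows(rows)
  build_library(molecules, freq_tables, scale = scale, fwhm = fwhm,
                grid = grid, energy_filter = energy_filter)
}

#' @rdname build_synthetic_benchmark
#' @param lib A benchmark library from `build_benchmark_library()`.
#' @export
benchmark_queries <- function(lib, noise) {
  stopifnot(inherits(lib, "ir_library"), inherits(noise, "iris_noise_model"))
  scale <- lib$params$scale
  fwhm <- lib$params$fwhm
  truth <- lib$entries[lib$entries$relative_energy == 0, ]
  axis <- lib$wavenumber
  records <- purrr::map_dfr(seq_len(nrow(truth)), function(j) {
    e <- truth[j, ]
    nm <- reseed_noise(noise, e$molecule_id, e$adduct, "record")
    qstick <- perturb(e$stick[[1]], nm)
    qgrid <- scale_and_broaden(qstick, scale, fwhm * noise$broadening, axis)
    qgrid <- perturb(qgrid, noise_model(baseline = noise$baseline,
                                        seed = nm$seed))
    tibble::tibble(
      record_id = paste0(e$molecule_id, ":", e$adduct),
      metabolite_id = e$molecule_id,
      molecule_id = e$molecule_id,
      adduct = e$adduct,
      precursor_mz = e$adduct_mz,
      spectrum = list(pmax(qgrid$intensity, 0))
    )
  })
  records
}
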