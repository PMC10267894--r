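brute_sspec <- function(a, b) {
  num <- 0
  for (i in seq_along(a)) num <- num + sqrt(a[i] * b[i])
  1000 * num / sqrt(sum(a) * sum(b))
}

test_that("s_spec matches brute-force evaluation on random vector pairs", {
  set.seed(123)
  for (rep in seq_len(1000)) {
    n <- sample(3:30, 1)
    a <- stats::runif(n) * sample(c(1, 100, 1e4), 1)
    b <- stats::runif(n)
    if (rep %% 3 == 0) a[sample(n, 1)] <- 0
    expect_lt(abs(s_spec(a, b) - brute_sspec(a, b)), 1e-9)
  }
})

test_that("s_spec has cosine limits, symmetry and scale invariance", {
  a <- c(1, 2, 3, 0, 5)
  expect_equal(s_spec(a, a), 1000)
  expect_equal(s_spec(a, 7.3 * a), 1000)
  expect_equal(s_spec(c(1, 0, 2), c(0, 5, 0)), 0)
  expect_equal(s_spec(c(1, 0), c(1, 1)), 707.107, tolerance = 1e-6)
  b <- c(0.5, 1, 0, 1, 2)
  expect_identical(s_spec(a, b), s_spec(b, a))
  expect_true(s_spec(a, b) >= 0 && s_spec(a, b) <= 1000)
  expect_error(s_spec(c(0, 0), c(1, 1)), "all-zero")
  expect_error(s_spec(c(-1, 1), c(1, 1)), "non-negative")
})

test_that("energy tolerance selects the best geometry within the window", {
  lib <- tiny_library()
  gly <- lib$entries[lib$entries$molecule_id == "gly" &
                       lib$entries$adduct == "deprotonated", ]
  expect_identical(nrow(gly), 2L)  # geometries at 0 and 8 kJ/mol
  q <- gly$grid[[which(gly$relative_energy == 8)]]
  t0 <- select_spectra(gly, q, energy_tol = 0)
  expect_identical(t0$n_considered, 1L)
  expect_identical(t0$relative_energy, 0)
  t10 <- select_spectra(gly, q, energy_tol = 10)
  expect_identical(t10$n_considered, 2L)
  expect_equal(t10$s_spec, 1000)  # the higher-energy geometry matches itself
  # score is monotone non-decreasing in the tolerance
  expect_gte(t10$s_spec, t0$s_spec)
  tin <- select_spectra(gly, q, energy_tol = Inf)
  expect_gte(tin$s_spec, t10$s_spec)
})

test_that("isomer search retrieves the query's own molecule at rank 1", {
  lib <- tiny_library()
  e <- lib$entries[lib$entries$entry_id ==
                     lib$entries$entry_id[lib$entries$molecule_id == "gly" &
                                            lib$entries$relative_energy == 0 &
                                            lib$entries$adduct == "deprotonated"][1], ]
  hits <- search_library(lib, e$grid[[1]], "deprotonated", mode = "isomer",
                         precursor_mz = e$adduct_mz)
  expect_identical(hits$molecule_id[1], "gly")
  expect_equal(hits$s_spec[1], 1000)
  expect_sorted_hits(hits)
  # glycine and alanine are not isomers: the window excludes alanine
  expect_false("ala" %in% hits$molecule_id)
  # far-off precursor mass yields an empty result, not an error
  none <- search_library(lib, e$grid[[1]], "deprotonated", mode = "isomer",
                         precursor_mz = 999.9)
  expect_identical(nrow(none), 0L)
  # formula-exact mode agrees with the m/z window here
  hf <- search_library(lib, e$grid[[1]], "deprotonated", mode = "isomer",
                       formula = "C2H5NO2")
  expect_identical(hf$molecule_id, hits$molecule_id)
})

test_that("isomer hits are an ordered subset of unsupervised hits", {
  lib <- tiny_library()
  e <- lib$entries[lib$entries$molecule_id == "ala", ][1, ]
  iso <- search_library(lib, e$grid[[1]], e$adduct, mode = "isomer",
                        precursor_mz = e$adduct_mz)
  uns <- search_library(lib, e$grid[[1]], e$adduct, mode = "unsupervised")
  expect_true(all(iso$molecule_id %in% uns$molecule_id))
  # identical relative ordering and scores
  sub <- uns[uns$molecule_id %in% iso$molecule_id, ]
  expect_identical(sub$molecule_id, iso$molecule_id)
  expect_equal(sub$s_spec, iso$s_spec)
  # candidate count equals distinct molecules carrying the adduct
  expect_identical(nrow(uns),
                   length(unique(lib$entries$molecule_id[
                     lib$entries$adduct == e$adduct])))
})

test_that("combining adducts multiplies scores and can rescue the truth", {
  one <- tibble::tibble(rank = 1:2, molecule_id = c("decoy", "true"),
                        entry_id = c("a", "b"), s_spec = c(950, 900),
                        relative_energy = c(0, 0), formula = c("f", "f"),
                        adduct_mz = c(1, 1))
  expect_identical(combine_adducts(list(one))$molecule_id, one$molecule_id)

  two <- tibble::tibble(rank = 1:2, molecule_id = c("true", "decoy"),
                        entry_id = c("a", "b"), s_spec = c(900, 100),
                        relative_energy = c(0, 0), formula = c("f", "f"),
                        adduct_mz = c(1, 1))
  comb <- combine_adducts(list(one, two))
  expect_identical(comb$molecule_id[1], "true")
  expect_equal(comb$combined_score[comb$molecule_id == "true"], 810000)
  expect_equal(comb$combined_score[comb$molecule_id == "decoy"], 95000)
})

test_that("a molecule ranked 10th/20th/6th per adduct can rank 1st combined", {
  # constructed instance mirroring the acetylglycine adduct pattern: the
  # same 30 molecules in every list; decoys that outrank the truth in one
  # adduct score poorly in the others
  pool <- c("truth", paste0("d", sprintf("%02d", 1:29)))
  make_hits <- function(ahead) {
    score <- stats::setNames(rep(50, 30), pool)
    score["truth"] <- 900
    score[ahead] <- seq(990, 910, length.out = length(ahead))
    ord <- order(-score, names(score))
    tibble::tibble(rank = seq_along(pool), molecule_id = names(score)[ord],
                   entry_id = paste0("e", seq_along(pool)),
                   s_spec = unname(score[ord]),
                   relative_energy = 0, formula = "f", adduct_mz = 1)
  }
  h1 <- make_hits(paste0("d", sprintf("%02d", 1:9)))
  h2 <- make_hits(paste0("d", sprintf("%02d", 10:28)))
  h3 <- make_hits(paste0("d", sprintf("%02d", c(1, 5, 10, 15, 29))))
  expect_identical(rank_of(h1, "truth"), 10L)
  expect_identical(rank_of(h2, "truth"), 20L)
  expect_identical(rank_of(h3, "truth"), 6L)
  comb <- combine_adducts(list(h1, h2, h3))
  expect_identical(comb$molecule_id[comb$rank == 1], "truth")
})

test_that("ranks are deterministic under entry order and break ties stably", {
  hits <- tibble::tibble(rank = 1:3, molecule_id = c("a", "b", "c"),
                         entry_id = c("x", "y", "z"), s_spec = c(9, 5, 5),
                         relative_energy = c(0, 0, 0), formula = "f",
                         adduct_mz = 1)
  expect_identical(rank_of(hits, "a"), 1L)
  expect_error(rank_of(hits, "zz"), "not present")

  lib <- tiny_library()
  e <- lib$entries[1, ]
  base <- search_library(lib, e$grid[[1]], e$adduct, mode = "unsupervised")
  for (rep in 1:5) {
    shuf <- lib
    idx <- sample(nrow(lib$entries))
    shuf$entries <- lib$entries[idx, ]
    shuf$sqrt_grid <- lib$sqrt_grid[idx, , drop = FALSE]
    shuf$grid_sums <- lib$grid_sums[idx]
    again <- search_library(shuf, e$grid[[1]], e$adduct, mode = "unsupervised")
    expect_identical(again, base)
  }
})

test_that("tied scores order by relative energy, then entry id", {
  mols <- tiny_library()$molecules
  site <- enumerate_adduct_ions(mols[mols$id == "gly", ], "protonated")$site
  # two molecules with identical spectra, plus tied geometries in one
  ft <- tibble::tibble(
    molecule_id = c("gly", "gly", "ala"),
    adduct = "protonated",
    site = c(site[1], site[2],
             enumerate_adduct_ions(mols[mols$id == "ala", ], "protonated")$site[1]),
    variant = "g1",
    relative_energy = c(5, 0, 0),
    stick = list(stick_spectrum(1000, 1), stick_spectrum(1000, 1),
                 stick_spectrum(1000, 1))
  )
  lib <- build_library(mols, ft)
  q <- lib$entries$grid[[1]]
  hits <- search_library(lib, q, "protonated", mode = "unsupervised",
                         energy_tol = Inf)
  expect_equal(hits$s_spec, c(1000, 1000))
  # per molecule, the 0 kJ/mol geometry wins the within-molecule tie;
  # between molecules, entry ids break the tie lexicographically
  expect_identical(hits$relative_energy, c(0, 0))
  expect_identical(hits$molecule_id, sort(hits$molecule_id))
})
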