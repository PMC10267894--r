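test_that("molecule families are deterministic, unique and graded", {
  one <- generate_family(1, seed = 5)
  expect_identical(nrow(one), 1L)
  expect_true(nzchar(one$smiles))

  a <- generate_family(25, seed = 9)
  b <- generate_family(25, seed = 9)
  expect_identical(a$smiles, b$smiles)
  expect_identical(anyDuplicated(a$smiles), 0L)
  c <- generate_family(25, seed = 10)
  expect_false(identical(a$smiles, c$smiles))

  # pairwise similarity spans close analogues and unrelated scaffolds
  big <- bench_library()$molecules
  sm <- similarity_matrix(big)
  off <- sm[upper.tri(sm)]
  expect_gte(max(off), 0.5)
  expect_lte(min(off), 0.2)
})

test_that("mock stick spectra follow the band rules deterministically", {
  mols <- parse_molecules(data.frame(
    smiles = c("CCCCC(=O)O", "CCCCCC(=O)O", "c1ccccc1OC"),
    id = c("pentanoic", "hexanoic", "anisole")
  ))
  rules <- band_rules()
  s1 <- synth_stick(mols[1, ], "deprotonated", rules, seed = 3)
  s1b <- synth_stick(mols[1, ], "deprotonated", rules, seed = 3)
  expect_identical(s1, s1b)
  # a different seed moves offsets but keeps the band count
  s1c <- synth_stick(mols[1, ], "deprotonated", rules, seed = 4)
  expect_identical(nrow(s1c), nrow(s1))
  expect_false(identical(s1c$frequency, s1$frequency))

  # carboxylate rule: deprotonated acid shows bands near 1300 and 1650
  expect_true(any(abs(s1$frequency - 1300) <= 3 * 10))
  expect_true(any(abs(s1$frequency - 1650) <= 3 * 10))

  # homologues differing in chain length share the rule-derived band set
  s2 <- synth_stick(mols[2, ], "deprotonated", rules, seed = 3)
  near <- function(f, centers) min(abs(f - centers))
  for (f in s1$frequency[s1$frequency > 1400]) {
    expect_lt(near(f, s2$frequency), 2 * 3 * 10)
  }

  # a molecule matching no rule yields a flagged empty stick... but every
  # grammar molecule has skeletal modes, so force it with an empty rule set
  empty_rules <- rules[0, ]
  s3 <- synth_stick(mols[3, ], "protonated", empty_rules, seed = 3)
  expect_gt(nrow(s3), 0)  # skeletal modes remain
})

test_that("perturbation is seeded, composable and identity at zero noise", {
  st <- stick_spectrum(c(900, 1300, 1650), c(50, 200, 250))
  zero <- noise_model(seed = 1)
  expect_identical(perturb(st, zero), st)
  g <- scale_and_broaden(st)
  expect_identical(perturb(g, zero), g)

  nm <- moderate_noise(seed = 21)
  p1 <- perturb(st, nm)
  p2 <- perturb(st, nm)
  expect_identical(p1, p2)  # bit-identical under a fixed seed
  expect_false(identical(p1$frequency, st$frequency))
  expect_identical(nrow(p1), nrow(st))

  gb <- perturb(g, nm)
  expect_true(all(gb$intensity >= 0))
  # baseline raises the minimum but the spectrum stays finite
  expect_true(all(is.finite(gb$intensity)))
})

test_that("the synthetic benchmark is reproducible and correctly sized", {
  lib <- bench_library(n = 150, seed = 42)
  expect_s3_class(lib, "ir_library")
  expect_identical(nrow(lib$molecules), 150L)
  # every (molecule, adduct) group has exactly one zero-energy geometry
  zero <- lib$entries |>
    dplyr::group_by(molecule_id, adduct) |>
    dplyr::summarise(n0 = sum(relative_energy == 0), .groups = "drop")
  expect_true(all(zero$n0 == 1L))
  expect_true(all(lib$entries$relative_energy <= lib$params$energy_filter))

  rec <- bench_records(noise_model(seed = 1))
  # one record per (molecule, available adduct)
  expect_identical(nrow(rec), nrow(zero))
  rec2 <- benchmark_queries(lib, noise_model(seed = 1))
  expect_identical(rec, rec2)

  nz <- bench_records(moderate_noise(seed = 3))
  nz2 <- benchmark_queries(lib, moderate_noise(seed = 3))
  expect_identical(nz, nz2)
})

test_that("structural and spectral similarity are positively coupled", {
  lib <- bench_library()
  rec <- bench_records(moderate_noise())
  sm <- similarity_matrix(lib$molecules)
  set.seed(17)
  idx <- sample(nrow(rec), 40)
  rhos <- vapply(idx, function(i) {
    r <- rec[i, ]
    hits <- search_library(lib, r$spectrum[[1]], r$adduct,
                           mode = "unsupervised")
    others <- hits$molecule_id != r$molecule_id
    stats::cor(sm[r$molecule_id, hits$molecule_id[others]],
               hits$s_spec[others], method = "spearman")
  }, numeric(1))
  expect_gt(mean(rhos), 0)
})

test_that("true-molecule scores exceed the median decoy score", {
  lib <- bench_library()
  rec <- bench_records(moderate_noise())
  beats <- vapply(seq_len(nrow(rec)), function(i) {
    r <- rec[i, ]
    hits <- search_library(lib, r$spectrum[[1]], r$adduct,
                           mode = "unsupervised")
    truth <- hits$s_spec[hits$molecule_id == r$molecule_id][1]
    truth > stats::median(hits$s_spec[hits$molecule_id != r$molecule_id])
  }, logical(1))
  expect_gte(mean(beats), 0.95)
})
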