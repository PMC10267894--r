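# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# small panel of known molecules used across chem/search tests
test_molecules <- function() {
  cached("mols", parse_molecules(data.frame(
    smiles = c("O", "NCC(=O)O", "OC(=O)CC1=CC=C(O)C(O)=C1", "CC(=O)C",
               "C", "CCO", "CCCO", "OC1=CC=C(O)C=C1", "CCCC(O)CC(=O)O"),
    id = c("water", "glycine", "DOPAC", "acetone", "methane", "ethanol",
           "propanol", "hydroquinone", "hydroxyhexanoic")
  )))
}

# the benchmark study conditions: moderate experimental noise
moderate_noise <- function(seed = 7) {
  noise_model(frequency_jitter = 5, intensity_sigma = 0.3,
              broadening = 1.1, baseline = 0.02, seed = seed)
}

bench_library <- function(n = 150, seed = 42) {
  cached(paste0("lib_", n, "_", seed),
         build_benchmark_library(n, seed = seed))
}

bench_records <- function(noise, n = 150, seed = 42) {
  benchmark_queries(bench_library(n, seed), noise)
}

# tiny handmade library: three molecules, two adducts, handcrafted sticks
tiny_library <- function() {
  cached("tiny_lib", {
    mols <- parse_molecules(data.frame(
      smiles = c("NCC(=O)O", "CC(N)C(=O)O", "CCO"),
      id = c("gly", "ala", "eth")
    ))
    site1 <- function(id, ad) {
      enumerate_adduct_ions(mols[mols$id == id, ], ad)$site[1]
    }
    ft <- tibble::tibble(
      molecule_id = c("gly", "gly", "ala", "eth", "gly", "ala"),
      adduct = c("deprotonated", "deprotonated", "deprotonated",
                 "deprotonated", "protonated", "protonated"),
      site = vapply(seq_len(6), function(i) {
        site1(c("gly", "gly", "ala", "eth", "gly", "ala")[i],
              c("deprotonated", "deprotonated", "deprotonated",
                "deprotonated", "protonated", "protonated")[i])
      }, integer(1)),
      variant = c("g1", "g2", "g1", "g1", "g1", "g1"),
      relative_energy = c(0, 8, 0, 0, 0, 0),
      stick = list(
        stick_spectrum(c(1300, 1650), c(200, 250)),
        stick_spectrum(c(1350, 1600), c(180, 260)),
        stick_spectrum(c(1310, 1645, 900), c(190, 240, 60)),
        stick_spectrum(c(1050, 1420), c(120, 80)),
        stick_spectrum(c(1750, 1180), c(280, 150)),
        stick_spectrum(c(1740, 1200, 1615), c(260, 140, 90))
      )
    )
    build_library(mols, ft)
  })
}

# permute the storage order of a library's entries (and its scoring caches)
shuffle_library <- function(lib, seed = 1) {
  idx <- withr::with_seed(seed, sample(nrow(lib$entries)))
  lib$entries <- lib$entries[idx, ]
  lib$sqrt_grid <- lib$sqrt_grid[idx, , drop = FALSE]
  lib$grid_sums <- lib$grid_sums[idx]
  lib
}

expect_sorted_hits <- function(hits) {
  expect_true(all(diff(hits$s_spec) <= 1e-12))
  expect_identical(hits$rank, seq_len(nrow(hits)))
}
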