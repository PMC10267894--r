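# Molecular structure handling: parsing, formulas, monoisotopic masses,
# adduct m/z, protonation/deprotonation site enumeration, Tanimoto similarity.
# Structure perception (SMILES canonicalization, hydrogen placement, SMARTS)
# is delegated to Open Babel via ChemmineOB/ChemmineR.

ob_canonical_smiles <- function(smiles) {
  out <- ChemmineOB::convertFormat("SMI", "CAN", paste0(smiles, "\n"))
  out <- strsplit(out, "\n", fixed = TRUE)[[1]]
  out <- sub("\t.*$", "", out)
  out[nzchar(out)]
}

# SMILES -> SDF text with explicit hydrogens (so bond-less molecules like
# water still produce a valid connection table)
ob_sdf_with_h <- function(smiles, ids) {
  src <- paste0(paste(smiles, ids), "\n", collapse = "")
  ChemmineOB::convertFormat("SMI", "SDF", src,
                            options = data.frame(names = "h", args = ""))
}

# parse one molecule's explicit-H SDF block into a light graph structure
sdf_graph <- function(sdf) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  bonds <- cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  heavy <- which(elements != "H")
  n_h <- vapply(seq_along(elements), function(i) {
    nb <- c(bonds[bonds[, 1] == i, 2], bonds[bonds[, 2] == i, 1])
    sum(elements[nb] == "H")
  }, integer(1))
  list(elements = elements, bonds = bonds, heavy = heavy, n_h = n_h)
}

# Morgan-style iterative neighbourhood refinement; returns an integer symmetry
# class per atom. Atoms in the same class are graph-equivalent, so adduct
# sites on them yield identical ion structures.
atom_symmetry_classes <- function(graph) {
  lab <- match(graph$elements, unique(graph$elements))
  n_class <- length(unique(lab))
  adj <- lapply(seq_along(graph$elements), function(i) {
    rows <- graph$bonds[, 1] == i | graph$bonds[, 2] == i
    b <- graph$bonds[rows, , drop = FALSE]
    nb <- ifelse(b[, 1] == i, b[, 2], b[, 1])
    cbind(nb, b[, 3])
  })
  repeat {
    key <- vapply(seq_along(lab), function(i) {
      nb <- adj[[i]]
      env <- paste(sort(paste(nb[, 2], lab[nb[, 1]], sep = ":")), collapse = ",")
      paste(lab[i], env, sep = "|")
    }, character(1))
    new_lab <- match(key, unique(key))
    if (length(unique(new_lab)) == n_class) return(new_lab)
    lab <- new_lab
    n_class <- length(unique(lab))
  }
}

formula_from_elements <- function(elements) {
  counts <- table(elements)
  syms <- names(counts)
  hill <- c(intersect(c("C", "H"), syms), sort(setdiff(syms, c("C", "H"))))
  paste0(hill, ifelse(counts[hill] > 1, counts[hill], ""), collapse = "")
}

#' Parse a formula string into element counts
#'
#' @param formula Molecular formula string in Hill notation, e.g. `"C8H8O4"`.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  if (sum(nchar(parts)) != nchar(formula)) {
    stop("cannot parse formula '", formula, "'", call. = FALSE)
  }
  syms <- sub("[0-9]*$", "", parts)
  n <- as.integer(ifelse(grepl("[0-9]+$", parts), sub("^[A-Za-z]+", "", parts), 1L))
  tapply(n, factor(syms, levels = unique(syms)), sum)[unique(syms)]
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums the most-abundant-isotope mass of every atom, using the internal
#' [atomic_masses] table.
#'
#' @param formula Either a formula string (`"C2H5NO2"`) or a named numeric
#'   vector of element counts. An empty formula has mass 0.
#' @return Mass in Da.
#' @export
#' @examples
#' monoisotopic_mass("H2O")
#' monoisotopic_mass(c(C = 6, H = 12, O = 3))
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  if (length(counts) == 0L) return(0)
  stopifnot(!is.null(names(counts)))
  unknown <- setdiff(names(counts), names(atomic_masses))
  if (length(unknown) > 0L) {
    stop("no monoisotopic mass tabulated for element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  sum(atomic_masses[names(counts)] * as.numeric(counts))
}

#' Parse molecular structures from SMILES
#'
#' Canonicalizes each SMILES, derives the molecular formula (including
#' implicit hydrogens), the monoisotopic mass, a 1024-bit path-based (Open
#' Babel FP2) fingerprint for structural similarity, and a light molecular
#' graph used for adduct-site enumeration.
#'
#' @param structures Data frame with columns `smiles` and `id`, or a character
#'   vector of SMILES (ids are taken from names or auto-generated).
#' @return A tibble with one row per molecule and columns `id`, `smiles`
#'   (canonical), `formula`, `monoisotopic_mass`, `fingerprint` (list of set
#'   bit positions) and `graph` (list).
#' @export
#' @examples
#' parse_molecules(data.frame(smiles = "NCC(=O)O", id = "glycine"))
parse_molecules <- function(structures) {
  if (is.character(structures)) {
    ids <- names(structures)
    if (is.null(ids)) ids <- paste0("mol", seq_along(structures))
    structures <- data.frame(smiles = unname(structures), id = ids)
  }
  stopifnot(is.data.frame(structures),
            all(c("smiles", "id") %in% names(structures)))
  smiles <- as.character(structures$smiles)
  ids <- as.character(structures$id)
  if (anyDuplicated(ids)) stop("duplicate molecule ids", call. = FALSE)
  if (any(!nzchar(smiles))) stop("empty SMILES string", call. = FALSE)

  can <- suppressWarnings(
    ob_canonical_smiles(paste(smiles, collapse = "\n"))
  )
  if (length(can) != length(smiles)) {
    # at least one structure failed to parse: identify it
    for (i in seq_along(smiles)) {
      ci <- suppressWarnings(ob_canonical_smiles(smiles[i]))
      if (length(ci) != 1L || !nzchar(ci)) {
        stop("cannot parse structure '", smiles[i], "' (id: ", ids[i], ")",
             call. = FALSE)
      }
    }
    stop("structure canonicalization failed", call. = FALSE)
  }

  sdf_txt <- ob_sdf_with_h(can, ids)
  sdfset <- ChemmineR::read.SDFset(strsplit(sdf_txt, "\n", fixed = TRUE)[[1]])
  if (length(sdfset) != length(ids)) {
    stop("structure conversion dropped molecules; check input SMILES",
         call. = FALSE)
  }
  graphs <- lapply(seq_along(ids), function(i) sdf_graph(sdfset[[i]]))

  fp <- ChemmineR::fingerprintOB(sdfset, "FP2")
  fpm <- fp@fpma
  fingerprints <- lapply(seq_len(nrow(fpm)), function(i) which(fpm[i, ] != 0))

  formulas <- vapply(graphs, function(g) formula_from_elements(g$elements),
                     character(1))
  tibble::tibble(
    id = ids,
    smiles = can,
    formula = formulas,
    monoisotopic_mass = vapply(formulas, monoisotopic_mass, numeric(1),
                               USE.NAMES = FALSE),
    fingerprint = fingerprints,
    graph = graphs
  )
}

#' @rdname parse_molecules
#' @param smiles A single SMILES string.
#' @param id Molecule identifier.
#' @export
parse_molecule <- function(smiles, id = "mol1") {
  parse_molecules(data.frame(smiles = smiles, id = id))
}

#' Theoretical m/z of an adduct ion
#'
#' Applies the adduct mass shift (proton mass 1.007276 Da for
#' protonation/deprotonation, 22.989221 Da for sodiation; electron mass
#' included) to the neutral monoisotopic mass.
#'
#' @param mass Neutral monoisotopic mass in Da, or a molecules tibble from
#'   [parse_molecules()] (its `monoisotopic_mass` column is used).
#' @param adduct One of `"protonated"`, `"deprotonated"`, `"sodiated"` (or the
#'   bracket labels `"[M+H]+"`, `"[M-H]-"`, `"[M+Na]+"`).
#' @return m/z in Th (vectorized over `mass`).
#' @export
#' @examples
#' adduct_mz(monoisotopic_mass("C6H12O3"), "deprotonated")
adduct_mz <- function(mass, adduct) {
  if (is.data.frame(mass)) mass <- mass$monoisotopic_mass
  stopifnot(is.numeric(mass), all(mass > 0))
  adduct <- match_adduct(adduct)
  shift <- adduct_types$mass_shift[adduct_types$adduct == adduct]
  mass + shift
}

#' Enumerate candidate adduct ions of a molecule
#'
#' Every nitrogen, oxygen and sulfur atom is a candidate site for H+/Na+
#' addition; removal (deprotonation) additionally requires at least one
#' hydrogen on the heteroatom. Graph-equivalent sites (determined by
#' iterative neighbourhood refinement) produce identical ion structures and
#' are merged to a single entry.
#'
#' @param molecules Molecules tibble from [parse_molecules()].
#' @param adduct Adduct type; see [adduct_mz()].
#' @return Tibble with columns `molecule_id`, `adduct`, `site` (atom index in
#'   the hydrogen-explicit structure), `element`, `n_h` (hydrogens on the
#'   site), `n_equivalent` (merged equivalent sites). Zero rows when the
#'   molecule cannot form the adduct.
#' @export
enumerate_adduct_ions <- function(molecules, adduct) {
  adduct <- match_adduct(adduct)
  res <- purrr::map2_dfr(molecules$id, molecules$graph, function(id, g) {
    het <- g$heavy[g$elements[g$heavy] %in% c("N", "O", "S")]
    if (adduct == "deprotonated") het <- het[g$n_h[het] >= 1L]
    if (length(het) == 0L) return(NULL)
    cls <- atom_symmetry_classes(g)[het]
    keep <- !duplicated(cls)
    tibble::tibble(
      molecule_id = id,
      adduct = adduct,
      site = het[keep],
      element = g$elements[het[keep]],
      n_h = g$n_h[het[keep]],
      n_equivalent = as.integer(table(cls)[as.character(cls[keep])])
    )
  })
  if (nrow(res) == 0L) {
    res <- tibble::tibble(molecule_id = character(), adduct = character(),
                          site = integer(), element = character(),
                          n_h = integer(), n_equivalent = integer())
  }
  res
}

tanimoto_bits <- function(a, b, identical_structure = FALSE) {
  inter <- length(intersect(a, b))
  uni <- length(union(a, b))
  if (uni == 0L) return(if (identical_structure) 1 else 0)
  inter / uni
}

#' Structural similarity of two molecules
#'
#' Tanimoto coefficient of the molecules' 1024-bit FP2 path fingerprints.
#' Identical canonical structures score 1 even when the fingerprint is empty
#' (single-heavy-atom molecules).
#'
#' @param a,b One-row molecule tibbles (rows of a [parse_molecules()] result).
#' @return Similarity in \[0, 1\]; symmetric.
#' @export
structural_similarity <- function(a, b) {
  stopifnot(is.data.frame(a), is.data.frame(b), nrow(a) == 1L, nrow(b) == 1L)
  tanimoto_bits(a$fingerprint[[1]], b$fingerprint[[1]],
                identical_structure = identical(a$smiles, b$smiles))
}

#' Pairwise structural similarity matrix
#'
#' @param molecules Molecules tibble.
#' @param other Optional second molecules tibble; default compares
#'   `molecules` with itself.
#' @return Numeric matrix of Tanimoto similarities with molecule ids as
#'   dimnames.
#' @export
similarity_matrix <- function(molecules, other = molecules) {
  bits_a <- fingerprint_matrix(molecules)
  bits_b <- fingerprint_matrix(other)
  inter <- bits_a %*% t(bits_b)
  na <- rowSums(bits_a)
  nb <- rowSums(bits_b)
  uni <- outer(na, nb, "+") - inter
  sim <- ifelse(uni == 0, 0, inter / pmax(uni, 1))
  empty_a <- which(na == 0)
  for (i in empty_a) {
    sim[i, ] <- as.numeric(molecules$smiles[i] == other$smiles)
  }
  empty_b <- which(nb == 0)
  for (j in empty_b) {
    sim[, j] <- as.numeric(molecules$smiles == other$smiles[j])
  }
  dimnames(sim) <- list(molecules$id, other$id)
  sim
}

fingerprint_matrix <- function(molecules, nbits = 1024L) {
  m <- matrix(0, nrow(molecules), nbits)
  for (i in seq_len(nrow(molecules))) m[i, molecules$fingerprint[[i]]] <- 1
  m
}

#' Count SMARTS pattern matches
#'
#' Unique substructure match counts per molecule, via Open Babel.
#'
#' @param molecules Molecules tibble.
#' @param smarts A single SMARTS pattern.
#' @return Integer vector of match counts, one per molecule.
#' @export
count_smarts_matches <- function(molecules, smarts, sdfset = NULL) {
  if (is.null(sdfset)) sdfset <- molecules_sdfset(molecules)
  as.integer(ChemmineR::smartsSearchOB(sdfset, smarts, uniqueMatches = TRUE))
}

# hydrogen-explicit SDFset for a molecules tibble (one Open Babel round trip)
molecules_sdfset <- function(molecules) {
  sdf_txt <- ob_sdf_with_h(molecules$smiles, molecules$id)
  ChemmineR::read.SDFset(strsplit(sdf_txt, "\n", fixed = TRUE)[[1]])
}

#' Read structures from a SMILES or SDF file
#'
#' SMILES files are tab- or whitespace-separated `smiles<TAB>id` lines; SDF
#' files are read via ChemmineR and converted.
#'
#' @param path File path; format chosen by extension (`.smi`/`.txt` vs
#'   `.sdf`).
#' @return Molecules tibble, as from [parse_molecules()].
#' @export
read_structures <- function(path) {
  stopifnot(file.exists(path))
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    sdfset <- ChemmineR::read.SDFset(path)
    smi <- ChemmineR::sdf2smiles(sdfset)
    df <- data.frame(smiles = as.character(ChemmineR::smiles(smi)),
                     id = ChemmineR::sdfid(sdfset))
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
    parts <- strsplit(trimws(lines), "[\t ]+")
    df <- data.frame(
      smiles = vapply(parts, `[`, character(1), 1L),
      id = vapply(parts, function(p) {
        if (length(p) >= 2L) p[2L] else NA_character_
      }, character(1))
    )
    missing_id <- is.na(df$id)
    df$id[missing_id] <- paste0("mol", which(missing_id))
  }
  parse_molecules(df)
}
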