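#' @title Molecule-quality metrics: bonds, stability, validity, novelty
#' @name metrics
#' @description
#' The metric suite follows the implicit-bond scoring convention: bonds are
#' inferred from inter-atomic distances and atom types against a reference
#' table of covalent bond lengths (in pm) with per-order margins, an atom is
#' *stable* when its summed bond orders equal the element's allowed valence,
#' and a molecule is *stable* when every atom is. Validity is judged by
#' RDKit sanitization of the inferred bond graph; canonical SMILES of the
#' largest fragment feed the uniqueness and novelty counts.
NULL

#' Load a reference bond table
#'
#' The default table ships with the package and follows the standard
#' equivariant-generation scoring convention: reference covalent bond
#' lengths per element pair and order (pm), decision margins of 10/5/3 pm
#' for orders 1/2/3, and per-element allowed valences, optionally
#' charge-adjusted.
#'
#' @param name "qm9" (the shipped default, which also covers the
#'   GEOM-Drugs elements) or a path to a CSV with columns
#'   `elem1,elem2,order,length_pm`.
#' @param margins numeric length-3 vector of margins in pm for orders 1-3.
#' @param charge_aware use charge-adjusted valences where tabulated.
#' @return object of class `bond_table`.
#' @export
bond_table <- function(name = "qm9", margins = c(10, 5, 3),
                       charge_aware = TRUE) {
  path <- if (file.exists(name)) name
          else system.file("extdata", paste0("bond_lengths_", name, ".csv"),
                           package = "gcdiff", mustWork = TRUE)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  vpath <- system.file("extdata", "valencies.csv", package = "gcdiff",
                       mustWork = TRUE)
  vtab <- utils::read.csv(vpath, stringsAsFactors = FALSE)
  lengths <- list()
  for (i in seq_len(nrow(tab))) {
    for (key in c(paste(tab$elem1[i], tab$elem2[i], tab$order[i], sep = "|"),
                  paste(tab$elem2[i], tab$elem1[i], tab$order[i], sep = "|")))
      lengths[[key]] <- tab$length_pm[i]
  }
  val <- list()
  for (i in seq_len(nrow(vtab)))
    val[[paste(vtab$element[i], vtab$charge[i], sep = "|")]] <-
      as.integer(strsplit(vtab$valences[i], "|", fixed = TRUE)[[1]])
  structure(list(lengths = lengths, margins = margins, valences = val,
                 charge_aware = isTRUE(charge_aware)),
            class = "bond_table")
}

ref_length <- function(table, e1, e2, order) {
  table$lengths[[paste(e1, e2, order, sep = "|")]]
}

allowed_valences <- function(table, element, charge = 0L) {
  if (table$charge_aware) {
    v <- table$valences[[paste(element, charge, sep = "|")]]
    if (!is.null(v)) return(v)
  }
  table$valences[[paste(element, 0L, sep = "|")]]
}

#' Infer bond orders from geometry
#'
#' For each atom pair the bond order is the highest order whose reference
#' length plus margin exceeds the observed distance; pairs farther than the
#' single-bond envelope (or absent from the table) get order 0. Depends only
#' on distances and types, hence invariant under rotation, translation and
#' consistent permutation.
#'
#' @param mol a `molecule` (coordinates in Angstrom).
#' @param table a `bond_table`.
#' @return symmetric integer N x N matrix of bond orders, zero diagonal.
#' @export
infer_bonds <- function(mol, table = bond_table()) {
  n <- n_atoms(mol)
  dmat <- as.matrix(stats::dist(mol$coords)) * 100  # pm
  orders <- matrix(0L, n, n)
  if (n < 2L) return(orders)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    o <- 0L
    for (k in 1:3) {
      ref <- ref_length(table, mol$types[i], mol$types[j], k)
      if (!is.null(ref) && dmat[i, j] < ref + table$margins[k]) o <- k
    }
    orders[i, j] <- orders[j, i] <- o
  }
  orders
}

#' Fraction of atoms with the correct valency
#'
#' @param mol a `molecule`.
#' @param table a `bond_table`.
#' @param bonds optional precomputed bond-order matrix.
#' @return fraction in `[0, 1]`.
#' @export
atom_stability <- function(mol, table = bond_table(), bonds = NULL) {
  bonds <- bonds %||% infer_bonds(mol, table)
  sums <- rowSums(bonds)
  ok <- vapply(seq_len(n_atoms(mol)), function(i) {
    allowed <- allowed_valences(table, mol$types[i], mol$charges[i])
    !is.null(allowed) && sums[i] %in% allowed
  }, logical(1))
  mean(ok)
}

#' Is every atom of the molecule stable?
#' @inheritParams atom_stability
#' @return logical flag: TRUE iff [atom_stability()] is exactly 1.
#' @export
molecule_stability <- function(mol, table = bond_table(), bonds = NULL) {
  atom_stability(mol, table, bonds) == 1
}

#' RDKit validity and canonical SMILES
#'
#' Builds the inferred bond graph as an RDKit molecule and sanitizes it (the
#' standard cheminformatics validity check); on success returns the
#' canonical SMILES of the largest fragment. Runs in a batch subprocess of
#' the python RDKit backend; an explicit capability error is raised when the
#' backend is unavailable.
#'
#' @param mols a `molecule` or list of molecules.
#' @param table a `bond_table`.
#' @return data.frame with columns `valid` (logical) and `smiles`
#'   (character, NA when invalid).
#' @export
validity <- function(mols, table = bond_table()) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  payload <- lapply(mols, function(m) {
    b <- infer_bonds(m, table)
    idx <- which(upper.tri(b) & b > 0L, arr.ind = TRUE)
    list(types = m$types, charges = m$charges,
         bonds = if (nrow(idx)) lapply(seq_len(nrow(idx)), function(r)
           c(idx[r, 1] - 1L, idx[r, 2] - 1L, b[idx[r, 1], idx[r, 2]]))
           else list())
  })
  res <- chem_backend("sanitize", payload)
  data.frame(valid = vapply(res, function(r) isTRUE(r$valid), logical(1)),
             smiles = vapply(res, function(r)
               if (is.null(r$smiles)) NA_character_ else r$smiles,
               character(1)),
             stringsAsFactors = FALSE)
}

#' Fraction of distinct canonical strings
#' @param strings character vector of canonical SMILES.
#' @return `|distinct| / |list|`.
#' @export
uniqueness <- function(strings) {
  if (!length(strings)) stop("uniqueness of an empty list is undefined")
  length(unique(strings)) / length(strings)
}

#' Fraction of strings absent from a reference set
#'
#' Inputs must be canonicalized identically (both through [validity()]).
#'
#' @param strings canonical SMILES of the valid-and-unique generated set.
#' @param reference character vector/set of training canonical SMILES.
#' @export
novelty <- function(strings, reference) {
  if (!length(strings)) return(NA_real_)
  mean(!(strings %in% reference))
}

#' Conformer energy ratio
#'
#' Ratio of the input conformation's UFF energy to the mean UFF energy of
#' `n_conformers` freshly ETKDGv3-embedded conformers of the same molecular
#' graph; ratios above 7 flag a highly unlikely conformation.
#'
#' @param mol a `molecule`.
#' @param table a `bond_table` (the molecular graph is the inferred one).
#' @param n_conformers number of reference conformers (default 50).
#' @param seed RNG seed for the embedder.
#' @return list with `ratio` (NA on embedding failure), `flagged`
#'   (ratio > 7) and `reason` for missing values.
#' @export
energy_ratio <- function(mol, table = bond_table(), n_conformers = 50L,
                         seed = 0L) {
  b <- infer_bonds(mol, table)
  idx <- which(upper.tri(b) & b > 0L, arr.ind = TRUE)
  payload <- list(list(
    types = mol$types, charges = mol$charges,
    coords = apply(mol$coords, 1, as.numeric, simplify = FALSE),
    bonds = if (nrow(idx)) lapply(seq_len(nrow(idx)), function(r)
      c(idx[r, 1] - 1L, idx[r, 2] - 1L, b[idx[r, 1], idx[r, 2]]))
      else list(),
    n_conformers = n_conformers, seed = seed))
  res <- chem_backend("energy_ratio", payload)[[1]]
  ratio <- if (is.null(res$ratio)) NA_real_ else res$ratio
  list(ratio = ratio, flagged = isTRUE(ratio > 7),
       reason = res$reason %||% NA_character_)
}

#' Aggregate quality report over a set of molecules
#'
#' @param mols list of `molecule` objects.
#' @param table a `bond_table`.
#' @param reference optional set of training canonical SMILES; when given,
#'   novelty over the valid-and-unique subset is included.
#' @param with_validity set FALSE to skip the RDKit-backed validity columns
#'   (the stability metrics need no external backend).
#' @return one-row data.frame with percentages `atom_stable`, `mol_stable`,
#'   `valid`, `valid_unique`, `novel` and the count `n`.
#' @export
batch_report <- function(mols, table = bond_table(), reference = NULL,
                         with_validity = TRUE) {
  if (!length(mols)) stop("empty molecule list")
  bonds <- lapply(mols, infer_bonds, table = table)
  as_frac <- mapply(function(m, b) atom_stability(m, table, b), mols, bonds)
  natoms <- vapply(mols, n_atoms, integer(1))
  as_pct <- 100 * sum(as_frac * natoms) / sum(natoms)
  ms_pct <- 100 * mean(as_frac == 1)
  out <- data.frame(n = length(mols), atom_stable = as_pct,
                    mol_stable = ms_pct, valid = NA_real_,
                    valid_unique = NA_real_, novel = NA_real_)
  if (with_validity) {
    v <- validity(mols, table)
    out$valid <- 100 * mean(v$valid)
    vs <- v$smiles[v$valid]
    out$valid_unique <- 100 * length(unique(vs)) / length(mols)
    if (!is.null(reference) && length(vs))
      out$novel <- 100 * novelty(unique(vs), reference)
  }
  out
}

# --- python RDKit backend -----------------------------------------------

chem_backend_path <- function() {
  system.file("python", "chem_backend.py", package = "gcdiff")
}

chem_backend_available <- function() {
  py <- Sys.which("python")
  if (!nzchar(py)) return(FALSE)
  isTRUE(tryCatch(
    system2(py, c("-c", shQuote("import rdkit")), stdout = NULL,
            stderr = NULL) == 0L,
    error = function(e) FALSE))
}

chem_backend <- function(mode, payload) {
  py <- Sys.which("python")
  script <- chem_backend_path()
  if (!nzchar(py) || !nzchar(script) || !file.exists(script))
    stop("cheminformatics backend unavailable: needs python with RDKit ",
         "on the PATH", call. = FALSE)
  fin <- tempfile(fileext = ".json"); fout <- tempfile(fileext = ".json")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  jsonlite::write_json(payload, fin, auto_unbox = TRUE, digits = NA,
                       null = "null")
  code <- system2(py, c(script, mode, fin, fout), stdout = "", stderr = "")
  if (code != 0L || !file.exists(fout))
    stop("cheminformatics backend failed (exit ", code, ")", call. = FALSE)
  jsonlite::read_json(fout)
}
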