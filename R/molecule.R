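#' @title Molecule objects
#' @name molecule
#' @description
#' A `molecule` is the basic datum of the package: an N x 3 matrix of Cartesian
#' atom coordinates (in Angstrom), a character vector of element symbols drawn
#' from a fixed vocabulary, integer formal charges, and an optional named list
#' of real-valued property labels. Atom types are stored as element symbols;
#' the one-hot encoding over the active vocabulary is produced on demand by
#' [encode_features()].
NULL

#' Default atom-type vocabulary (QM9 convention)
#' @export
QM9_VOCAB <- c("H", "C", "N", "O", "F")

#' GEOM-Drugs atom-type vocabulary
#' @export
GEOM_VOCAB <- c("H", "B", "C", "N", "O", "F", "Al", "Si", "P", "S",
                "Cl", "As", "Br", "I", "Hg", "Bi")

#' Construct a molecule
#'
#' @param coords numeric N x 3 matrix of coordinates in Angstrom.
#' @param types character vector of element symbols, length N.
#' @param charges integer formal charges, length N (default all 0).
#' @param props optional named list of scalar property labels.
#' @return an object of class `molecule`.
#' @export
molecule <- function(coords, types, charges = NULL, props = NULL) {
  coords <- as.matrix(coords)
  if (!is.numeric(coords) || ncol(coords) != 3L)
    stop("coords must be a numeric N x 3 matrix")
  n <- nrow(coords)
  if (n < 1L) stop("a molecule needs at least one atom")
  if (!all(is.finite(coords))) stop("coords must be finite")
  types <- as.character(types)
  if (length(types) != n) stop("types length must match nrow(coords)")
  if (is.null(charges)) charges <- integer(n)
  charges <- as.integer(charges)
  if (length(charges) != n) stop("charges length must match nrow(coords)")
  dimnames(coords) <- NULL
  structure(list(coords = coords, types = types, charges = charges,
                 props = props),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule> %d atoms: %s\n", n_atoms(x),
              paste(x$types, collapse = " ")))
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol a `molecule`.
#' @export
n_atoms <- function(mol) nrow(mol$coords)

#' Validate a molecule against a vocabulary
#'
#' @param mol a `molecule`.
#' @param vocab character vector of allowed element symbols.
#' @return `mol`, invisibly; errors if an element is outside `vocab`.
#' @export
check_vocab <- function(mol, vocab = QM9_VOCAB) {
  bad <- setdiff(unique(mol$types), vocab)
  if (length(bad))
    stop("element(s) outside vocabulary: ", paste(bad, collapse = ", "))
  invisible(mol)
}

#' Remove the centre of mass from a coordinate matrix
#'
#' Projects coordinates onto the zero-centre-of-mass subspace by subtracting
#' the (unweighted) column means. Pairwise distances are unchanged and the
#' operation is idempotent. All latent coordinates in the diffusion and
#' denoiser modules live on this subspace, which is what makes the model's
#' likelihood translation-invariant.
#'
#' @param coords numeric N x 3 matrix.
#' @return N x 3 matrix whose column sums are zero.
#' @export
remove_com <- function(coords) {
  coords <- as.matrix(coords)
  sweep(coords, 2L, colMeans(coords), "-")
}

#' Centre a molecule's coordinates
#' @param mol a `molecule`.
#' @return the molecule with CoM-centred coordinates.
#' @export
center_molecule <- function(mol) {
  mol$coords <- remove_com(mol$coords)
  mol
}

#' One-hot / scaled feature encoding of a molecule
#'
#' Builds the N x (K+1) invariant feature block diffused jointly with the
#' coordinates: K one-hot columns over `vocab` scaled by `onehot_scale` and a
#' final charge column scaled by `charge_scale`. The scalings (0.25 and 0.1)
#' follow the standard equivariant-diffusion data processing convention so
#' that feature channels and unit-variance noise live on comparable scales.
#'
#' @param mol a `molecule`.
#' @param vocab element vocabulary.
#' @param onehot_scale multiplier applied to the one-hot block.
#' @param charge_scale multiplier applied to the integer charge column.
#' @return numeric N x (length(vocab)+1) matrix.
#' @export
encode_features <- function(mol, vocab = QM9_VOCAB,
                            onehot_scale = 0.25, charge_scale = 0.1) {
  check_vocab(mol, vocab)
  n <- n_atoms(mol)
  k <- length(vocab)
  h <- matrix(0, n, k + 1L)
  h[cbind(seq_len(n), match(mol$types, vocab))] <- onehot_scale
  h[, k + 1L] <- mol$charges * charge_scale
  h
}

#' Decode a feature block back to types and charges
#'
#' Inverse of [encode_features()] for noisy/generated features: atom type is
#' the argmax over the one-hot block, charge the nearest integer after
#' unscaling.
#'
#' @param h numeric N x (K+1) feature matrix.
#' @inheritParams encode_features
#' @return list with `types` (character) and `charges` (integer).
#' @export
decode_features <- function(h, vocab = QM9_VOCAB,
                            onehot_scale = 0.25, charge_scale = 0.1) {
  k <- length(vocab)
  idx <- max.col(h[, seq_len(k), drop = FALSE], ties.method = "first")
  list(types = vocab[idx],
       charges = as.integer(round(h[, k + 1L] / charge_scale)))
}

#' Empirical molecule-size distribution
#'
#' Fits the empirical distribution of atom counts over a training set; sizes
#' of generated molecules are drawn from it, following the convention of
#' sampling ligand sizes from the training-set size distribution.
#'
#' @param mols list of `molecule` objects.
#' @return object of class `size_distribution` with `support` and `probs`.
#' @export
fit_size_distribution <- function(mols) {
  if (!length(mols)) stop("cannot fit a size distribution to an empty list")
  sizes <- vapply(mols, n_atoms, integer(1))
  tab <- table(sizes)
  structure(list(support = as.integer(names(tab)),
                 probs = as.numeric(tab) / length(sizes)),
            class = "size_distribution")
}

#' Construct a size distribution directly
#' @param support positive integer sizes.
#' @param probs matching probabilities (normalized internally).
#' @export
size_distribution <- function(support, probs) {
  support <- as.integer(support)
  if (any(support < 1L)) stop("sizes must be positive integers")
  if (length(support) != length(probs) || any(probs < 0))
    stop("probs must be nonnegative and match support")
  structure(list(support = support, probs = probs / sum(probs)),
            class = "size_distribution")
}

#' Sample molecule sizes from a size distribution
#' @param dist a `size_distribution`.
#' @param n number of draws.
#' @return integer vector of sizes.
#' @export
sample_size <- function(dist, n = 1L) {
  if (length(dist$support) == 1L) return(rep(dist$support, n))
  sample(dist$support, n, replace = TRUE, prob = dist$probs)
}

#' Log-probability of a size under a size distribution
#' @inheritParams sample_size
#' @param n_atoms integer size queried.
#' @export
log_prob_size <- function(dist, n_atoms) {
  i <- match(n_atoms, dist$support)
  if (is.na(i)) return(-Inf)
  log(dist$probs[i])
}
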