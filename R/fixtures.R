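#' @title Synthetic molecular fixtures
#' @name fixtures
#' @description
#' Small rigid molecular templates with physically sensible geometry —
#' tetrahedral methane-like, bent water-like, linear hydrogen-cyanide-like,
#' and a chiral five-atom scaffold (a carbon bearing four distinct
#' substituents) whose mirror image is not superimposable — plus a sampler
#' that jitters, rotates and labels them. Every template is constructed so
#' that all bonded distances fall inside the toy bond-table envelopes and
#' all non-bonded distances outside, hence templates score AS = MS = 1 by
#' construction. The generator defines the package's desk-scale study
#' conditions: 2,000 molecules, coordinate jitter 0.05 Angstrom, seed 0.
NULL

tetra_dirs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)) /
  sqrt(3)

#' Rigid molecular templates
#'
#' @return list of `template` objects: `name`, CoM-centred `coords`,
#'   `types`, and `property_fn` (the name of the toy property attached to
#'   sampled molecules).
#' @export
make_templates <- function() {
  t1 <- list(name = "methane",
             coords = rbind(c(0, 0, 0), 1.09 * tetra_dirs),
             types = c("C", "H", "H", "H", "H"))
  ang <- 104.5 * pi / 180
  t2 <- list(name = "water",
             coords = rbind(c(0, 0, 0),
                            0.96 * c(sin(ang / 2), cos(ang / 2), 0),
                            0.96 * c(-sin(ang / 2), cos(ang / 2), 0)),
             types = c("O", "H", "H"))
  t3 <- list(name = "hydrogen_cyanide",
             coords = rbind(c(-1.07, 0, 0), c(0, 0, 0), c(1.16, 0, 0)),
             types = c("H", "C", "N"))
  t4 <- list(name = "chiral_center",
             coords = rbind(c(0, 0, 0),
                            1.09 * tetra_dirs[1, ],
                            1.47 * tetra_dirs[2, ],
                            1.43 * tetra_dirs[3, ],
                            1.35 * tetra_dirs[4, ]),
             types = c("C", "H", "N", "O", "F"))
  lapply(list(t1, t2, t3, t4), function(tp) {
    tp$coords <- remove_com(tp$coords)
    tp$property_fn <- "radius_of_gyration"
    class(tp) <- "template"
    tp
  })
}

#' Toy bond table consistent with the templates
#'
#' A strict subset of the full reference table restricted to the element
#' pairs the templates bond, plus toy valences for N and O that admit the
#' chiral scaffold's single-substituent bonding, so the construction
#' invariant (ideal templates are perfectly stable, non-bonded pairs are
#' outside every envelope) holds exactly. Test-only convenience; real
#' scoring uses [bond_table()].
#' @return a `bond_table`.
#' @export
toy_bond_table <- function() {
  full <- bond_table("qm9")
  keep <- c("H|C|1", "C|H|1", "H|O|1", "O|H|1", "C|N|1", "N|C|1",
            "C|N|3", "N|C|3", "C|O|1", "O|C|1", "C|F|1", "F|C|1")
  full$lengths <- full$lengths[intersect(keep, names(full$lengths))]
  full$valences[["N|0"]] <- c(1L, 3L)
  full$valences[["O|0"]] <- c(1L, 2L)
  # margins sized to 3 sigma of the generator's jitter-induced bond-length
  # spread (sqrt(2) * 0.05 A * 100 pm/A * 3 ~ 21 pm) so that the default
  # jitter leaves molecules overwhelmingly stable; envelopes of different
  # orders still do not overlap for the template pairs
  full$margins <- c(21, 21, 21)
  full
}

#' Draw a uniform random proper rotation
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Sample a synthetic training set from the templates
#'
#' Each molecule is a uniformly chosen template with isotropic Gaussian
#' coordinate jitter, a uniform random proper rotation, and re-centring;
#' its property label is the template's toy property evaluated on the
#' jittered geometry.
#'
#' @param templates list of templates from [make_templates()].
#' @param n number of molecules.
#' @param jitter_sd coordinate jitter standard deviation in Angstrom.
#' @param seed RNG seed.
#' @return list of `molecule` objects with `props` filled.
#' @export
sample_dataset <- function(templates = make_templates(), n = 2000L,
                           jitter_sd = 0.05, seed = 0L) {
  if (n < 1L) stop("n must be >= 1")
  if (jitter_sd < 0) stop("jitter_sd must be >= 0")
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    tp <- templates[[sample.int(length(templates), 1L)]]
    nn <- nrow(tp$coords)
    x <- tp$coords + matrix(stats::rnorm(nn * 3L, sd = jitter_sd), nn, 3L)
    x <- remove_com(x %*% t(random_rotation()))
    m <- molecule(x, tp$types)
    m$props <- stats::setNames(list(toy_property(m, tp$property_fn)),
                               tp$property_fn)
    m$props$template <- match(tp$name, vapply(templates, `[[`, "",
                                              "name"))
    m
  })
}

#' Toy molecular properties
#'
#' Deterministic rotation-invariant stand-ins for quantum-chemical
#' properties: `radius_of_gyration` = sqrt(mean squared distance from the
#' centroid); `dipole_like` = norm of the pseudo-charge-weighted coordinate
#' sum, with fixed per-element pseudo-charges (Pauling electronegativities).
#'
#' @param mol a `molecule`.
#' @param name property name.
#' @return scalar property value.
#' @export
toy_property <- function(mol, name = c("radius_of_gyration", "dipole_like")) {
  name <- match.arg(name)
  x <- remove_com(mol$coords)
  switch(name,
    radius_of_gyration = sqrt(mean(rowSums(x^2))),
    dipole_like = {
      en <- c(H = 2.20, C = 2.55, N = 3.04, O = 3.44, F = 3.98)
      q <- en[mol$types]
      if (anyNA(q)) stop("no pseudo-charge for element(s): ",
                         paste(setdiff(mol$types, names(en)), collapse = ","))
      sqrt(sum(colSums(q * x)^2))
    })
}

#' Mirror a molecule
#' @param mol a `molecule`.
#' @return the molecule reflected through the yz-plane.
#' @export
mirror_molecule <- function(mol) {
  mol$coords[, 1] <- -mol$coords[, 1]
  mol
}

# --- alignment oracles ---------------------------------------------------

#' RMSD under the optimal proper rotation (Kabsch)
#'
#' Both point sets are centred; the minimizing rotation is restricted to
#' det +1 so mirror images are *not* superimposed.
#'
#' @param a,b N x 3 coordinate matrices in corresponding order.
#' @return root-mean-square deviation in Angstrom.
#' @export
kabsch_rmsd <- function(a, b) {
  a <- remove_com(a); b <- remove_com(b)
  sv <- svd(crossprod(b, a))
  d <- sign(det(sv$u) * det(sv$v))
  rot <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  sqrt(mean(rowSums((a - b %*% rot)^2)))
}

perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  unlist(lapply(seq_along(v), function(i)
    lapply(perms(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
}

#' Composition- and symmetry-aware aligned RMSD to a template
#'
#' Minimizes the Kabsch RMSD over all assignments of the molecule's atoms to
#' template atoms of the same element (exhaustive over within-element
#' permutations; intended for the small fixture templates).
#'
#' @param mol a `molecule`.
#' @param template a template (or any list with `coords` and `types`).
#' @return RMSD in Angstrom, or `Inf` when the composition differs.
#' @export
aligned_rmsd <- function(mol, template) {
  if (!composition_matches(mol, template)) return(Inf)
  groups <- split(seq_along(template$types), template$types)
  mol_groups <- split(seq_along(mol$types), mol$types)
  best <- Inf
  group_perms <- lapply(names(groups), function(el) perms(mol_groups[[el]]))
  grid <- expand_perm_grid(group_perms)
  for (assign in grid) {
    ord <- integer(length(mol$types))
    ord[unlist(groups)] <- unlist(assign)
    r <- kabsch_rmsd(template$coords, mol$coords[ord, , drop = FALSE])
    if (r < best) best <- r
  }
  best
}

expand_perm_grid <- function(lists) {
  out <- list(list())
  for (l in lists) {
    out <- unlist(lapply(out, function(acc)
      lapply(l, function(p) c(acc, list(p)))), recursive = FALSE)
  }
  out
}

#' Does a molecule have the same element multiset as a template?
#' @inheritParams aligned_rmsd
#' @export
composition_matches <- function(mol, template) {
  identical(sort(mol$types), sort(template$types))
}

#' Match each molecule to a template by composition
#'
#' @param mols list of molecules.
#' @param templates list of templates.
#' @return data.frame with `template` (index or NA) and `rmsd` (aligned
#'   RMSD to the matched template, Inf when unmatched).
#' @export
template_match <- function(mols, templates = make_templates()) {
  res <- lapply(mols, function(m) {
    hit <- which(vapply(templates, composition_matches, logical(1),
                        mol = m))
    if (!length(hit)) return(c(NA_integer_, Inf))
    c(hit[1], aligned_rmsd(m, templates[[hit[1]]]))
  })
  data.frame(template = vapply(res, `[`, numeric(1), 1L),
             rmsd = vapply(res, `[`, numeric(1), 2L))
}
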