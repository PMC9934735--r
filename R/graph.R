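#' @title Fully-connected molecular graphs and graph batching
#' @name mol_graph
#' @description
#' A `mol_graph` is the fully-connected directed graph over a molecule's atoms
#' (no self-loops), carrying scalar and vector feature channels for nodes and
#' edges. Scalar channels are rotation-invariant, vector channels rotate with
#' the molecule; the initial channels built here (one-hot/charge scalars,
#' position and displacement vectors) satisfy that split by construction.
#' Batched graphs concatenate several molecules into one edge list so the
#' denoiser can process a whole batch with flat matrix operations.
NULL

#' Directed edge list of a fully-connected graph
#'
#' @param n number of nodes.
#' @return integer matrix with columns `src`, `dst`; `n*(n-1)` rows,
#'   zero rows when `n = 1`.
#' @export
full_edges <- function(n) {
  if (n < 2L) return(matrix(integer(0), 0L, 2L,
                            dimnames = list(NULL, c("src", "dst"))))
  g <- expand.grid(src = seq_len(n), dst = seq_len(n))
  g <- g[g$src != g$dst, c("src", "dst")]
  as.matrix(g)
}

#' Build the fully-connected graph of one molecule
#'
#' @param mol a `molecule`.
#' @param vocab element vocabulary for the scalar features.
#' @param centered if TRUE (default) coordinates pass [remove_com()] first.
#' @param cutoff optional distance cutoff in Angstrom: edges longer than this
#'   are dropped (fully-connected when NULL, the default used everywhere in
#'   the diffusion pipeline).
#' @return object of class `mol_graph` with fields `coords`, `edges`,
#'   `node_scalars` (one-hot + scaled charge), `node_vectors`
#'   (N x 1 x 3 position-from-CoM channel), `edge_scalars` (distances) and
#'   `edge_vectors` (E x 1 x 3 displacement channel, `x_src - x_dst`).
#' @export
build_graph <- function(mol, vocab = QM9_VOCAB, centered = TRUE,
                        cutoff = NULL) {
  x <- if (centered) remove_com(mol$coords) else mol$coords
  n <- nrow(x)
  e <- full_edges(n)
  disp <- x[e[, "src"], , drop = FALSE] - x[e[, "dst"], , drop = FALSE]
  d <- sqrt(rowSums(disp^2))
  if (!is.null(cutoff)) {
    keep <- d <= cutoff
    e <- e[keep, , drop = FALSE]; disp <- disp[keep, , drop = FALSE]
    d <- d[keep]
  }
  nv <- array(x, dim = c(n, 1L, 3L))
  ev <- array(disp, dim = c(nrow(e), 1L, 3L))
  structure(list(coords = x, edges = e,
                 node_scalars = encode_features(mol, vocab),
                 node_vectors = nv,
                 edge_scalars = matrix(d, ncol = 1L),
                 edge_vectors = ev),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph> %d nodes, %d directed edges\n",
              nrow(x$coords), nrow(x$edges)))
  invisible(x)
}

# --- batching -----------------------------------------------------------

# A graph batch holds several molecules of possibly different sizes as one
# flat node set. Fields: sizes, n_mol, mol_of (node -> molecule index),
# src/dst (global node indices), edge_mol, deg (incoming edges per node).
make_batch <- function(sizes) {
  sizes <- as.integer(sizes)
  n_mol <- length(sizes)
  offs <- cumsum(c(0L, sizes))[seq_len(n_mol)]
  mol_of <- rep(seq_len(n_mol), sizes)
  src <- integer(0); dst <- integer(0)
  for (m in seq_len(n_mol)) {
    e <- full_edges(sizes[m])
    src <- c(src, e[, "src"] + offs[m])
    dst <- c(dst, e[, "dst"] + offs[m])
  }
  list(sizes = sizes, n_mol = n_mol, n_nodes = sum(sizes),
       offsets = offs, mol_of = mol_of, src = src, dst = dst,
       edge_mol = mol_of[dst], deg = pmax(sizes[mol_of] - 1L, 1L))
}

# Per-molecule CoM projection on a batched coordinate/noise matrix.
project_zero_com <- function(x, batch) {
  means <- rowsum(x, batch$mol_of, reorder = TRUE) / batch$sizes
  x - means[batch$mol_of, , drop = FALSE]
}

# Split a batched node matrix back into a per-molecule list.
unbatch_nodes <- function(x, batch) {
  lapply(seq_len(batch$n_mol), function(m) {
    i <- batch$offsets[m] + seq_len(batch$sizes[m])
    x[i, , drop = FALSE]
  })
}
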