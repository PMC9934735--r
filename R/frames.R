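#' @title Chirality-aware local frames and scalarization
#' @name local_frames
#' @description
#' Per directed edge (i, j) of a CoM-centred point cloud, a geometry-complete
#' local frame is the orthonormal triple
#' \deqn{a = \frac{x_i-x_j}{\lVert x_i-x_j\rVert},\quad
#'       b = \frac{x_i\times x_j}{\lVert x_i\times x_j\rVert},\quad
#'       c = a\times b.}
#' Under a proper rotation all three axes rotate; under reflection `b` and
#' `c` flip handedness (the cross product is a pseudo-vector), so projections
#' onto them are chirality-sensitive scalars: frames make the network able to
#' distinguish mirror images. Because the axes span 3-space, projecting a
#' vector onto a non-degenerate frame loses no directional information
#' ("geometry-complete"). Degenerate configurations (coincident points, or
#' points collinear with the origin, where the cross product vanishes) fall
#' back to zeroed axes with a flag so scalarized features are zeros, never
#' NaN.
NULL

#' Build the local frame of one directed edge
#'
#' @param xi,xj 3-vectors: CoM-centred coordinates of the edge endpoints.
#' @param eps_guard degeneracy threshold on the norms (default 1e-8).
#' @return object of class `local_frame`: list with unit 3-vectors `a`, `b`,
#'   `c` and logical `degenerate`.
#' @export
build_frames <- function(xi, xj, eps_guard = 1e-8) {
  if (!all(is.finite(c(xi, xj)))) stop("non-finite coordinates")
  d <- xi - xj
  nd <- sqrt(sum(d^2))
  cr <- cross3(xi, xj)
  ncr <- sqrt(sum(cr^2))
  if (nd < eps_guard || ncr < eps_guard) {
    a <- if (nd < eps_guard) c(0, 0, 0) else d / nd
    return(structure(list(a = a, b = c(0, 0, 0), c = c(0, 0, 0),
                          degenerate = TRUE), class = "local_frame"))
  }
  a <- d / nd
  b <- cr / ncr
  structure(list(a = a, b = b, c = cross3(a, b), degenerate = FALSE),
            class = "local_frame")
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

#' Scalarize vectors in a local frame
#'
#' Projects each row of `vectors` onto the frame axes, giving rotation-
#' invariant scalars \eqn{(\langle v,a\rangle, \langle v,b\rangle,
#' \langle v,c\rangle)} per vector. The `b`/`c` components flip sign when the
#' generating coordinates and the vectors are mirrored (chirality
#' sensitivity); degenerate frames scalarize to zeros.
#'
#' @param vectors k x 3 matrix (a single 3-vector is accepted).
#' @param frame a `local_frame`.
#' @return k x 3 matrix of projections, columns (a, b, c).
#' @export
scalarize <- function(vectors, frame) {
  v <- matrix(vectors, ncol = 3L)
  cbind(v %*% frame$a, v %*% frame$b, v %*% frame$c)
}

#' Initial equivariant vector channels from noisy coordinates
#'
#' The denoiser's vector track is seeded directly from the noisy coordinates:
#' each node's position-from-CoM vector becomes the first vector channel
#' (remaining channels start at zero and are populated by message passing);
#' per-edge displacement vectors enter through the frames. Rotating the
#' input rotates every output vector identically.
#'
#' @param zx N x 3 zero-CoM coordinate matrix.
#' @param n_channels number of vector channels to allocate.
#' @return N x n_channels x 3 array.
#' @export
vectorize_positions <- function(zx, n_channels = 1L) {
  if (max(abs(colSums(zx))) > 1e-6) stop("coordinates must be centred")
  out <- array(0, dim = c(nrow(zx), n_channels, 3L))
  out[, 1L, ] <- zx
  out
}

# --- batched frames (internal) ------------------------------------------
# Computes a, b, c for every edge of a batch at once. Returns E x 3 matrices
# plus the edge length d. With use_frames = FALSE the chiral axes b, c are
# zeroed: geometry then enters only through lengths and the true vector a,
# which leaves the network reflection-equivariant (no chirality).
edge_frames <- function(zx, src, dst, use_frames = TRUE, eps_guard = 1e-8) {
  xi <- zx[src, , drop = FALSE]
  xj <- zx[dst, , drop = FALSE]
  d <- xi - xj
  nd <- sqrt(rowSums(d^2))
  a <- d / pmax(nd, eps_guard)
  a[nd < eps_guard, ] <- 0
  if (use_frames) {
    cr <- cbind(xi[, 2] * xj[, 3] - xi[, 3] * xj[, 2],
                xi[, 3] * xj[, 1] - xi[, 1] * xj[, 3],
                xi[, 1] * xj[, 2] - xi[, 2] * xj[, 1])
    ncr <- sqrt(rowSums(cr^2))
    b <- cr / pmax(ncr, eps_guard)
    bad <- ncr < eps_guard | nd < eps_guard
    b[bad, ] <- 0
    cc <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
                a[, 3] * b[, 1] - a[, 1] * b[, 3],
                a[, 1] * b[, 2] - a[, 2] * b[, 1])
  } else {
    b <- matrix(0, nrow(a), 3L)
    cc <- b
  }
  list(a = a, b = b, c = cc, d = nd)
}
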