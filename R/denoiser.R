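#' @title Geometry-complete chirality-aware denoising network
#' @name denoiser
#' @description
#' The denoiser maintains two feature tracks per node: invariant scalars and
#' equivariant 3-vector channels. Each message-passing layer builds per-edge
#' messages from both endpoint scalars, radial basis features of the edge
#' length, and the endpoint vector channels scalarized in the edge's local
#' frame (see [build_frames()]); a learned sigmoid gate per edge (scalar
#' message attention, SMA) multiplies each message. Vector channels are
#' updated only by linear combinations of existing vector channels and frame
#' axes, which preserves rotation equivariance by construction; because the
#' `b`/`c` axes are pseudo-vectors, the network is chirality-aware when
#' frames are enabled and exactly reflection-invariant when they are
#' disabled. The noise heads read out one 3-vector per node (a scalar-gated
#' sum of vector channels, CoM-projected) and the invariant feature noise.
NULL

#' Denoiser configuration
#'
#' @param n_layers number of message-passing layers (default 9, the
#'   full-scale setting; toy models use 4).
#' @param node_scalar_dim invariant node feature width (default 256).
#' @param node_vector_channels number of equivariant 3-vector channels per
#'   node (default 64).
#' @param edge_scalar_dim number of radial basis features per edge
#'   (default 32).
#' @param edge_vector_channels reserved width of the per-edge vector track;
#'   the frame axes and displacement provide these channels (default 16).
#' @param use_sma enable scalar message attention gates (default TRUE).
#' @param use_frames enable chiral local frames (default TRUE); disabling
#'   them removes the `b`/`c` axes and reduces the layer to an invariant
#'   (reflection-blind) update, the "no frames" ablation.
#' @param condition_dim 0 for unconditional models, 1 to append a
#'   standardized scalar property condition to every node.
#' @param self_cond optionally feed the previous reverse step's clean-sample
#'   estimate back as input (features into the scalar track, norm-clipped
#'   coordinates as an extra vector channel), trained with 50% dropout of
#'   that input and no gradient through it. Off by default; see the methods
#'   vignette.
#' @param rbf_max upper end of the radial-basis grid in Angstrom.
#' @param hidden_dim width of the message and node-update MLP hidden layers
#'   (default: equal to `node_scalar_dim`).
#' @return object of class `denoiser_config`.
#' @export
denoiser_config <- function(n_layers = 9L, node_scalar_dim = 256L,
                            node_vector_channels = 64L, edge_scalar_dim = 32L,
                            edge_vector_channels = 16L, use_sma = TRUE,
                            use_frames = TRUE, condition_dim = 0L,
                            rbf_max = 5, self_cond = FALSE,
                            hidden_dim = NULL) {
  cfg <- list(n_layers = as.integer(n_layers),
              node_scalar_dim = as.integer(node_scalar_dim),
              node_vector_channels = as.integer(node_vector_channels),
              edge_scalar_dim = as.integer(edge_scalar_dim),
              edge_vector_channels = as.integer(edge_vector_channels),
              use_sma = isTRUE(use_sma), use_frames = isTRUE(use_frames),
              condition_dim = as.integer(condition_dim), rbf_max = rbf_max,
              self_cond = isTRUE(self_cond),
              hidden_dim = as.integer(hidden_dim %||% node_scalar_dim))
  if (any(vapply(cfg[c(1:5)], function(d) d < 1L, logical(1))))
    stop("all dimensions must be positive")
  structure(cfg, class = "denoiser_config")
}

#' Initialize a denoiser network
#'
#' Variance-scaled Gaussian initialization; by default the output heads are
#' zero-initialized so an untrained network predicts zero noise, which
#' stabilizes early training. Tests of equivariance use `head_init =
#' "random"` so outputs are nonzero at initialization.
#'
#' @param config a `denoiser_config`.
#' @param vocab atom-type vocabulary (fixes the feature width).
#' @param seed RNG seed for the initialization.
#' @param head_init "zero" or "random".
#' @param T_ref diffusion step count used to normalize the time input.
#' @return object of class `denoiser_network`.
#' @export
denoiser_network <- function(config = denoiser_config(), vocab = QM9_VOCAB,
                             seed = 0L, head_init = c("zero", "random"),
                             T_ref = 1000L) {
  head_init <- match.arg(head_init)
  f <- length(vocab) + 1L
  h <- config$node_scalar_dim
  hid <- config$hidden_dim %||% h
  m <- config$node_vector_channels
  e <- config$edge_scalar_dim
  d_in <- 2L * h + e + 6L * m
  old <- .Random.seed_save()
  set.seed(seed)
  gm <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
  params <- list(
    embed = list(W = gm(3L * f + TIME_DIM + config$condition_dim +
                          (if (config$self_cond) f else 0L), h),
                 b = numeric(h)),
    layers = lapply(seq_len(config$n_layers), function(l) list(
      W1 = gm(d_in, hid), b1 = numeric(hid),
      W2 = gm(hid, hid), b2 = numeric(hid),
      wg = gm(hid, 1L), bg = 1,      # gates open (~0.73) at init
      Ws = gm(hid, h),
      Wv = gm(hid, 4L * m) * 0.1,
      Wn1 = gm(3L * h, hid), bn1 = numeric(hid),
      Wn2 = gm(hid, h), bn2 = numeric(h),
      M = matrix(0, m, m))),
    head = list(
      Wox = if (head_init == "zero") matrix(0, h, m) else gm(h, m),
      Woh = if (head_init == "zero") matrix(0, h, f) else gm(h, f),
      boh = numeric(f)))
  .Random.seed_restore(old)
  structure(list(config = config, params = params, vocab = vocab,
                 T_ref = as.integer(T_ref), cond_stats = NULL),
            class = "denoiser_network")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.denoiser_network <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(paste0("<denoiser_network> %d layers, %d scalar / %d vector",
                     " channels, SMA=%s, frames=%s, cond_dim=%d\n"),
              cfg$n_layers, cfg$node_scalar_dim, cfg$node_vector_channels,
              cfg$use_sma, cfg$use_frames, cfg$condition_dim))
  invisible(x)
}

# Sinusoidal embedding of the normalized time t/T: the raw scalar plus three
# harmonic pairs give the network enough resolution to specialize across the
# noise scale, which a single linear feature cannot.
TIME_DIM <- 7L
time_features <- function(tnorm) {
  cbind(tnorm,
        sin(pi * tnorm), cos(pi * tnorm),
        sin(2 * pi * tnorm), cos(2 * pi * tnorm),
        sin(4 * pi * tnorm), cos(4 * pi * tnorm))
}

addb <- function(mat, b) mat + rep(b, each = nrow(mat))

rbf_expand <- function(d, e_dim, rbf_max) {
  centers <- seq(0, rbf_max, length.out = e_dim)
  w <- if (e_dim > 1L) centers[2] - centers[1] else rbf_max
  exp(-outer(d, centers, "-")^2 / (2 * w^2))
}

# columnwise per-group maximum (groups 1..n_groups, contiguous)
group_max <- function(mat, group, n_groups = max(group)) {
  group_max_cpp(mat, group - 1L, n_groups)
}

# One message-passing layer: thin wrapper over the C++ core. S: Nn x h
# scalars; V: Nn x 3m vector channels stored as [x | y | z] blocks.
layer_forward <- function(p, S, V, fr, R, invd, batch, cfg) {
  gcp_forward_cpp(S, V, p, batch$src - 1L, batch$dst - 1L,
                  fr$a, fr$b, fr$c, invd, R, batch$deg,
                  batch$mol_of - 1L, as.numeric(batch$sizes),
                  cfg$use_sma)
}

#' Apply one geometry-complete message-passing layer
#'
#' Exposed for inspection and layer-level property tests: applies layer
#' `layer` of `net` to an explicit feature state.
#'
#' @param net a `denoiser_network`.
#' @param zx N x 3 zero-CoM coordinates defining frames and edge lengths.
#' @param S N x h invariant node scalars.
#' @param V N x m x 3 array (or list of three N x m slices) of vector
#'   channels.
#' @param batch optional precomputed batch (single molecule assumed if NULL).
#' @param layer layer index.
#' @return list with updated `S` and `V` (N x m x 3 array).
#' @export
gcp_layer <- function(net, zx, S, V, batch = NULL, layer = 1L) {
  cfg <- net$config
  if (is.null(batch)) batch <- make_batch(nrow(zx))
  if (is.array(V) && length(dim(V)) == 3L) {
    m <- dim(V)[2]
    Vm <- matrix(0, dim(V)[1], 3L * m)
    for (d in 1:3) Vm[, (d - 1L) * m + seq_len(m)] <- V[, , d]
    V <- Vm
  }
  fr <- edge_frames(zx, batch$src, batch$dst, cfg$use_frames)
  R <- rbf_expand(fr$d, cfg$edge_scalar_dim, cfg$rbf_max)
  invd <- 1 / (1 + fr$d)
  out <- layer_forward(net$params$layers[[layer]], S, V, fr, R, invd,
                       batch, cfg)
  m <- ncol(out$V) / 3L
  Varr <- array(0, dim = c(nrow(S), m, 3L))
  for (d in 1:3) Varr[, , d] <- out$V[, (d - 1L) * m + seq_len(m)]
  list(S = out$S, V = Varr)
}

# Assemble the embedding-level inputs of the network: scalar features plus
# time harmonics, set-level context (feature means and winner-take-all
# margins), optional self-conditioning and property condition; the initial
# vector channels; and the edge geometry (frames, radial features).
assemble_inputs <- function(net, zx, zh, t_mol, batch, condition = NULL,
                            z0_est = NULL) {
  cfg <- net$config
  p <- net$params
  Nn <- nrow(zx)
  m <- cfg$node_vector_channels
  tnorm <- (t_mol / net$T_ref)[batch$mol_of]
  # per-molecule mean of the noisy features: a noise-averaged estimate of
  # the composition count vector, which lets the network commit to one
  # template mode instead of hybrid compositions
  zh_mean <- rowsum(zh, batch$mol_of, reorder = TRUE) / batch$sizes
  # winner-take-all margins: distance to the within-molecule maximum per
  # channel (the current "winner" sits at 0) — an explicit competitive
  # signal for exclusive categorical assignments
  zh_margin <- zh - group_max(zh, batch$mol_of)[batch$mol_of, , drop = FALSE]
  Xin <- cbind(zh, time_features(tnorm),
               zh_mean[batch$mol_of, , drop = FALSE], zh_margin)
  if (cfg$self_cond) {
    # clamp the estimate: near t = T it is 1/alpha_t-amplified and
    # meaningless; invariant features clip elementwise, coordinates by row
    # norm (which preserves equivariance)
    sc_h <- if (is.null(z0_est)) matrix(0, Nn, ncol(zh))
            else pmin(pmax(z0_est$zh, -4), 4)
    Xin <- cbind(Xin, sc_h)
  }
  if (cfg$condition_dim > 0L) {
    if (is.null(condition)) stop("conditional network needs a condition value")
    cs <- net$cond_stats %||% list(mean = 0, sd = 1)
    cvec <- ((condition - cs$mean) / cs$sd)[batch$mol_of]
    Xin <- cbind(Xin, matrix(cvec, ncol = cfg$condition_dim))
  }
  S0 <- addb(Xin %*% p$embed$W, p$embed$b)
  V0 <- matrix(0, Nn, 3L * m)
  for (d in 1:3) V0[, (d - 1L) * m + 1L] <- zx[, d]
  if (cfg$self_cond && !is.null(z0_est) && m >= 2L) {
    r <- sqrt(rowSums(z0_est$zx^2))
    fac <- pmin(1, 4 / pmax(r, 1e-12))
    for (d in 1:3) V0[, (d - 1L) * m + 2L] <- z0_est$zx[, d] * fac
  }
  fr <- edge_frames(zx, batch$src, batch$dst, cfg$use_frames)
  list(Xin = Xin, S0 = S0, V0 = V0, fr = fr,
       R = rbf_expand(fr$d, cfg$edge_scalar_dim, cfg$rbf_max),
       invd = 1 / (1 + fr$d))
}

# Full network forward: predicted noise for a batched latent state.
denoiser_forward <- function(net, zx, zh, t_mol, batch, condition = NULL,
                             z0_est = NULL) {
  inp <- assemble_inputs(net, zx, zh, t_mol, batch, condition, z0_est)
  dn_forward_cpp(inp$S0, inp$V0, net$params$layers, net$params$head,
                 batch$src - 1L, batch$dst - 1L,
                 inp$fr$a, inp$fr$b, inp$fr$c, inp$invd, inp$R,
                 batch$deg, batch$mol_of - 1L, as.numeric(batch$sizes),
                 net$config$use_sma)
}

#' Denoise a noisy sample: predict the injected noise
#'
#' @param net a `denoiser_network`.
#' @param zt a `noisy_sample`.
#' @param t integer step in `1..T_ref`.
#' @param condition optional raw condition value (standardized internally
#'   with the network's stored statistics).
#' @param z0_est optional self-conditioning input (list with `zx`, `zh`).
#' @return list with `ex` (zero-CoM coordinate noise) and `eh`.
#' @export
denoise <- function(net, zt, t, condition = NULL, z0_est = NULL) {
  if (t < 1L || t > net$T_ref) stop("t out of range")
  batch <- make_batch(nrow(zt$zx))
  denoiser_forward(net, zt$zx, zt$zh, t, batch, condition, z0_est = z0_est)
}

#' @export
predict_noise.denoiser_network <- function(model, zx, zh, t_mol, batch,
                                           condition = NULL,
                                           z0_est = NULL) {
  denoiser_forward(model, zx, zh, t_mol, batch, condition, z0_est = z0_est)
}
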