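#' @title Joint molecular diffusion: forward noising, posterior, reverse steps
#' @name diffusion
#' @description
#' Variance-preserving joint diffusion over atom coordinates and invariant
#' atom features. The latent state at step `t` is \eqn{z_t=[z^{(x)}, z^{(h)}]}
#' with the coordinate part constrained to the zero-centre-of-mass subspace:
#' every Gaussian touching \eqn{z^{(x)}} (forward noise, reverse noise, prior)
#' is drawn in full space then CoM-projected, which is the projected standard
#' normal on that subspace. The reverse process is \eqn{\epsilon}-parametrized:
#' the denoiser predicts the injected noise, the clean sample is recovered
#' algebraically, and the true posterior of the forward chain is applied with
#' that plug-in estimate.
NULL

#' Construct a joint noisy sample
#'
#' @param zx numeric N x 3 coordinate latent, zero-CoM.
#' @param zh numeric N x f feature latent.
#' @param t integer step in `0..T`.
#' @param check if TRUE, verify the zero-CoM invariant.
#' @return object of class `noisy_sample`.
#' @export
noisy_sample <- function(zx, zh, t = 0L, check = TRUE) {
  zx <- as.matrix(zx); zh <- as.matrix(zh)
  if (check && max(abs(colSums(zx))) > 1e-6)
    stop("coordinate latent is not on the zero-CoM subspace")
  structure(list(zx = zx, zh = zh, t = as.integer(t)),
            class = "noisy_sample")
}

#' Encode a molecule as the t = 0 latent
#' @param mol a `molecule`.
#' @param vocab element vocabulary.
#' @return a `noisy_sample` at t = 0.
#' @export
encode_molecule <- function(mol, vocab = QM9_VOCAB) {
  noisy_sample(remove_com(mol$coords), encode_features(mol, vocab), 0L)
}

#' Decode a latent into a molecule
#' @param z a `noisy_sample` (typically at t = 0).
#' @param vocab element vocabulary.
#' @return a `molecule` with zero-CoM coordinates.
#' @export
decode_molecule <- function(z, vocab = QM9_VOCAB) {
  dec <- decode_features(z$zh, vocab)
  molecule(remove_com(z$zx), dec$types, dec$charges)
}

# Draw joint standard noise: coordinate part CoM-projected.
sample_joint_noise <- function(n, f, batch = NULL) {
  ex <- matrix(stats::rnorm(n * 3L), n, 3L)
  ex <- if (is.null(batch)) remove_com(ex) else project_zero_com(ex, batch)
  list(ex = ex, eh = matrix(stats::rnorm(n * f), n, f))
}

#' Forward-noise a clean latent to step t
#'
#' Draws \eqn{z_t = \alpha_{t|0} z_0 + \sigma_{t|0}\epsilon} with the
#' coordinate noise CoM-projected, so \eqn{z_t^{(x)}} stays on the zero-CoM
#' subspace.
#'
#' @param z0 a `noisy_sample` at t = 0 (coordinates centred).
#' @param t target step, `1..T` (t = 0 returns `z0` with zero noise).
#' @param schedule a `noise_schedule`.
#' @return list with `zt` (a `noisy_sample`) and `eps` (list `ex`, `eh`).
#' @export
forward_sample <- function(z0, t, schedule) {
  if (max(abs(colSums(z0$zx))) > 1e-6) stop("z0 coordinates must be centred")
  if (t < 0 || t > schedule$T) stop("t out of range")
  n <- nrow(z0$zx)
  eps <- sample_joint_noise(n, ncol(z0$zh))
  a <- sched_alpha(schedule, t); s <- sched_sigma(schedule, t)
  zt <- noisy_sample(a * z0$zx + s * eps$ex, a * z0$zh + s * eps$eh, t,
                     check = FALSE)
  list(zt = zt, eps = eps)
}

#' True-posterior parameters of the reverse transition
#'
#' Mean and standard deviation of \eqn{q(z_s | z_t, z_0)}:
#' \deqn{\mu = \frac{\alpha_s\sigma_{t|s}^2}{\sigma_t^2} z_0 +
#'       \frac{\alpha_{t|s}\sigma_s^2}{\sigma_t^2} z_t,\qquad
#'       \sigma_{t\to s} = \frac{\sigma_{t|s}\sigma_s}{\sigma_t}.}
#'
#' @param zt,z0 latent matrices (or `noisy_sample`s) at steps t and 0.
#' @param s,t steps with `0 <= s < t`.
#' @param schedule a `noise_schedule`.
#' @return list with `mu` (same shape as the inputs) and `sigma` (scalar).
#' @export
posterior_params <- function(zt, z0, s, t, schedule) {
  if (s >= t) stop("need s < t")
  tc <- transition_coeffs(schedule, s, t)
  s_t <- sched_sigma(schedule, t); s_s <- sched_sigma(schedule, s)
  a_s <- sched_alpha(schedule, s)
  c0 <- a_s * tc$sigma_ts^2 / s_t^2
  ct <- tc$alpha_ts * s_s^2 / s_t^2
  get <- function(z, part) if (inherits(z, "noisy_sample")) z[[part]] else z
  if (inherits(zt, "noisy_sample")) {
    mu <- list(zx = c0 * z0$zx + ct * zt$zx, zh = c0 * z0$zh + ct * zt$zh)
  } else {
    mu <- c0 * z0 + ct * zt
  }
  list(mu = mu, sigma = tc$sigma_ts * s_s / s_t, coef_z0 = c0, coef_zt = ct)
}

#' Recover the clean latent from a noise prediction
#'
#' Algebraic inversion of the forward marginal:
#' \eqn{\tilde z_0 = z_t/\alpha_t - \hat\epsilon\,\sigma_t/\alpha_t},
#' applied jointly to coordinate and feature parts.
#'
#' @param zt a `noisy_sample` at step t.
#' @param eps_hat predicted noise, list with `ex` and `eh`.
#' @param t step, `>= 1`.
#' @param schedule a `noise_schedule`.
#' @return a `noisy_sample` at t = 0 (approximate clean latent).
#' @export
predict_clean <- function(zt, eps_hat, t, schedule) {
  a <- sched_alpha(schedule, t)
  if (a < 1e-12) stop("alpha_t underflow: cannot invert the forward marginal")
  s <- sched_sigma(schedule, t)
  noisy_sample(zt$zx / a - eps_hat$ex * s / a,
               zt$zh / a - eps_hat$eh * s / a, 0L, check = FALSE)
}

#' One reverse diffusion step
#'
#' Applies the true posterior with the plug-in clean estimate from
#' [predict_clean()], adding CoM-projected Gaussian noise scaled by
#' \eqn{\sigma_{t\to s}}. The final step to s = 0 is deterministic
#' (mean only) unless `final_noise = TRUE`.
#'
#' @param zt a `noisy_sample` at step t.
#' @param eps_hat predicted noise (`ex` zero-CoM).
#' @param s,t steps with `s < t`.
#' @param schedule a `noise_schedule`.
#' @param final_noise add noise even when s = 0.
#' @return a `noisy_sample` at step s.
#' @export
reverse_step <- function(zt, eps_hat, s, t, schedule, final_noise = FALSE) {
  if (max(abs(colSums(eps_hat$ex))) > 1e-6)
    stop("predicted coordinate noise must be zero-CoM")
  z0t <- predict_clean(zt, eps_hat, t, schedule)
  pp <- posterior_params(zt, z0t, s, t, schedule)
  zx <- pp$mu$zx; zh <- pp$mu$zh
  if (pp$sigma > 0 && (s > 0 || final_noise)) {
    xi <- sample_joint_noise(nrow(zx), ncol(zh))
    zx <- zx + pp$sigma * xi$ex
    zh <- zh + pp$sigma * xi$eh
  }
  noisy_sample(zx, zh, s, check = FALSE)
}

#' Noise-prediction training loss
#'
#' \eqn{\mathcal{L}_t = \tfrac12 w(t)\,\lVert\epsilon-\hat\epsilon\rVert^2}
#' with default weight \eqn{w(t)=1}, the weighting that was found to give the
#' best generation quality.
#'
#' @param eps,eps_hat noise and prediction, lists with `ex` and `eh`.
#' @param weight scalar weight `w(t)`.
#' @return nonnegative scalar.
#' @export
diffusion_loss <- function(eps, eps_hat, weight = 1) {
  0.5 * weight * (sum((eps$ex - eps_hat$ex)^2) + sum((eps$eh - eps_hat$eh)^2))
}

# --- sampling ------------------------------------------------------------

#' Predict noise with a denoising model
#'
#' Generic dispatch so tests can supply plain-function oracles while the
#' package supplies the geometry-complete network. Implementations receive
#' batched latents and must return a list with `ex` (zero-CoM) and `eh`.
#'
#' @param model a denoiser (see [denoiser_network()]) or a function
#'   `f(zx, zh, t_of_node, batch, condition)`.
#' @param zx,zh batched latent matrices.
#' @param t_mol integer step per molecule.
#' @param batch a graph batch (see internals) or NULL for one molecule.
#' @param condition optional numeric condition value(s), one per molecule.
#' @param z0_est optional previous clean-sample estimate (self-conditioning
#'   input; list with `zx`, `zh`).
#' @return list with `ex`, `eh`.
#' @export
predict_noise <- function(model, zx, zh, t_mol, batch, condition = NULL,
                          z0_est = NULL) {
  UseMethod("predict_noise")
}

#' @export
predict_noise.function <- function(model, zx, zh, t_mol, batch,
                                   condition = NULL, z0_est = NULL) {
  model(zx, zh, t_mol, batch, condition)
}

#' Sample molecules by iterative denoising
#'
#' Draws \eqn{z_T} from the joint standard normal (coordinates CoM-projected),
#' runs the reverse chain on a time grid from `T` down to 0, and decodes:
#' atom type by argmax over the one-hot block, charge by rounding. With
#' `n_steps < T` the chain runs on a uniformly subsampled grid
#' (time-scaled generation), taking larger jumps with the exact transition
#' coefficients between non-adjacent grid points.
#'
#' @param model denoising model (see [predict_noise()]).
#' @param n_mols number of molecules to draw.
#' @param sizes integer vector of atom counts (recycled), or NULL to draw
#'   from `size_dist`.
#' @param size_dist a `size_distribution` (used when `sizes` is NULL).
#' @param schedule a `noise_schedule`.
#' @param vocab element vocabulary.
#' @param n_steps number of reverse steps (default `schedule$T`).
#' @param condition optional condition value, scalar or one per molecule.
#' @param trace_fn optional callback `function(zx, batch, t)` invoked at every
#'   grid point (used by invariant-checking tests).
#' @return list of `molecule` objects.
#' @export
sample_molecules <- function(model, n_mols, sizes = NULL, size_dist = NULL,
                             schedule, vocab = QM9_VOCAB,
                             n_steps = schedule$T, condition = NULL,
                             trace_fn = NULL) {
  if (is.null(sizes)) {
    if (is.null(size_dist)) stop("give sizes or size_dist")
    sizes <- sample_size(size_dist, n_mols)
  } else sizes <- rep(as.integer(sizes), length.out = n_mols)
  if (any(sizes < 1L)) stop("sizes must be >= 1")
  if (n_steps < 1L || n_steps > schedule$T) stop("n_steps must be in 1..T")
  f <- length(vocab) + 1L
  batch <- make_batch(sizes)
  if (!is.null(condition)) condition <- rep(condition, length.out = n_mols)

  z <- sample_joint_noise(batch$n_nodes, f, batch)
  zx <- z$ex; zh <- z$eh
  z0_est <- NULL
  grid <- unique(round(seq(schedule$T, 0, length.out = n_steps + 1L)))
  for (k in seq_len(length(grid) - 1L)) {
    t <- grid[k]; s <- grid[k + 1L]
    if (!is.null(trace_fn)) trace_fn(zx, batch, t)
    eh <- predict_noise(model, zx, zh, rep(t, batch$n_mol), batch, condition,
                        z0_est = z0_est)
    a <- sched_alpha(schedule, t); sg <- sched_sigma(schedule, t)
    z0_est <- list(zx = project_zero_com(zx / a - eh$ex * sg / a, batch),
                   zh = zh / a - eh$eh * sg / a)
    step <- reverse_step_batched(zx, zh, eh, s, t, schedule, batch)
    zx <- step$zx; zh <- step$zh
  }
  if (!is.null(trace_fn)) trace_fn(zx, batch, 0L)
  zx <- project_zero_com(zx, batch)
  xs <- unbatch_nodes(zx, batch); hs <- unbatch_nodes(zh, batch)
  lapply(seq_len(batch$n_mol), function(m) {
    dec <- decode_features(hs[[m]], vocab)
    molecule(remove_com(xs[[m]]), dec$types, dec$charges)
  })
}

# Batched reverse step (all molecules share t -> s).
reverse_step_batched <- function(zx, zh, eps_hat, s, t, schedule, batch,
                                 final_noise = FALSE) {
  a <- sched_alpha(schedule, t); sg <- sched_sigma(schedule, t)
  z0x <- zx / a - eps_hat$ex * sg / a
  z0h <- zh / a - eps_hat$eh * sg / a
  pp <- posterior_params(zt = 0, z0 = 0, s = s, t = t, schedule = schedule)
  mux <- pp$coef_z0 * z0x + pp$coef_zt * zx
  muh <- pp$coef_z0 * z0h + pp$coef_zt * zh
  if (pp$sigma > 0 && (s > 0 || final_noise)) {
    xi <- sample_joint_noise(nrow(zx), ncol(zh), batch)
    mux <- mux + pp$sigma * xi$ex
    muh <- muh + pp$sigma * xi$eh
  }
  list(zx = project_zero_com(mux, batch), zh = muh)
}
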