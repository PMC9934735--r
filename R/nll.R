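#' @title Variational negative log-likelihood
#' @name nll
#' @description
#' The model assigns a likelihood to a molecule through the standard
#' variational bound of the diffusion chain: a prior term at step `T`, a sum
#' of per-step KL terms expressed in noise-prediction form, a discretized
#' reconstruction term at the end of the chain, and the size term
#' `-log p(N)` from the empirical size distribution. Coordinate Gaussians
#' live on the zero-centre-of-mass subspace, so their effective
#' dimensionality is `3(N-1)`; this is what makes the bound
#' translation-invariant. Rotation invariance holds because the denoiser is
#' rotation-equivariant; the estimator additionally canonicalizes the
#' molecule's orientation first so that the Monte-Carlo estimate itself (not
#' only its expectation) is invariant.
NULL

# Deterministic canonical orientation: principal axes of the second-moment
# matrix, signs fixed by third moments, third axis by cross product so the
# frame is always proper. Degenerate (symmetric) molecules keep an arbitrary
# but valid frame.
canonical_orientation <- function(x) {
  x <- remove_com(x)
  if (nrow(x) < 3L) return(x)
  eg <- eigen(crossprod(x), symmetric = TRUE)
  v1 <- eg$vectors[, 1]; v2 <- eg$vectors[, 2]
  fix <- function(v) {
    sk <- sum((x %*% v)^3)
    if (abs(sk) > 1e-8) return(v * sign(sk))
    j <- which.max(abs(v))
    v * sign(v[j])
  }
  v1 <- fix(v1); v2 <- fix(v2)
  v3 <- cross3(v1, v2)
  x %*% cbind(v1, v2, v3)
}

# KL(N(mu, sigma^2 I_d) || N(0, I_d)) summed over d dims.
gauss_kl_std <- function(mu_sq, sigma2, d) {
  0.5 * (d * sigma2 + mu_sq - d - d * log(sigma2))
}

# log of a discretized Gaussian: integral of N(z, s^2) over (v-0.5, v+0.5).
log_discretized_gauss <- function(v, z, s) {
  p <- stats::pnorm((v + 0.5 - z) / s) - stats::pnorm((v - 0.5 - z) / s)
  log(pmax(p, 1e-30))
}

#' Variational bound on the negative log-likelihood of a molecule
#'
#' Computes the bound on \eqn{-\log p(x, h, N)}: prior KL at `T`, the
#' diffusion KL sum in noise-prediction form (Monte-Carlo over uniformly
#' sampled steps, or the full sum over `t` when `exact = TRUE`), the
#' discretized reconstruction term at the end of the chain, and
#' \eqn{-\log p(N)}.
#'
#' @param model a denoiser (see [predict_noise()]).
#' @param mol a `molecule`.
#' @param schedule a `noise_schedule`.
#' @param size_dist a `size_distribution`; a size outside its support
#'   contributes `+Inf`, flagged with a warning.
#' @param n_mc Monte-Carlo draws over the step index (default 1).
#' @param exact sum over every step instead of sampling (small `T` only).
#' @param vocab element vocabulary.
#' @param onehot_scale,charge_scale feature scalings (must match training).
#' @return scalar bound in nats; components attached as attribute `"terms"`.
#' @export
nll <- function(model, mol, schedule, size_dist, n_mc = 1L, exact = FALSE,
                vocab = QM9_VOCAB, onehot_scale = 0.25, charge_scale = 0.1) {
  check_vocab(mol, vocab)
  n <- n_atoms(mol)
  f <- length(vocab) + 1L
  x <- canonical_orientation(remove_com(mol$coords))
  h <- encode_features(mol, vocab, onehot_scale, charge_scale)
  batch <- make_batch(n)
  dx <- 3 * (n - 1L)
  dh <- n * f
  Tm <- schedule$T

  log_pN <- log_prob_size(size_dist, n)
  if (!is.finite(log_pN))
    warning("molecule size ", n, " is outside the size distribution support")

  # prior KL at T, coordinate part on the (N-1) x 3 subspace
  aT <- sched_alpha(schedule, Tm); sT <- sched_sigma(schedule, Tm)
  prior <- gauss_kl_std(aT^2 * sum(x^2), sT^2, dx) +
           gauss_kl_std(aT^2 * sum(h^2), sT^2, dh)

  # diffusion KL terms: 0.5 (SNR(t-1)/SNR(t) - 1) E ||eps - eps_hat||^2
  snr <- schedule$alphas^2 / schedule$sigmas^2
  kl_t <- function(t) {
    a <- sched_alpha(schedule, t); s <- sched_sigma(schedule, t)
    eps <- sample_joint_noise(n, f, batch)
    zx <- a * x + s * eps$ex
    zh <- a * h + s * eps$eh
    eh <- predict_noise(model, zx, zh, t, batch, NULL)
    w <- snr[t] / snr[t + 1L] - 1   # SNR(t-1)/SNR(t) - 1
    0.5 * w * (sum((eps$ex - eh$ex)^2) + sum((eps$eh - eh$eh)^2))
  }
  if (exact) {
    l_diff <- sum(vapply(seq_len(Tm), kl_t, numeric(1)))
  } else {
    ts <- sample.int(Tm, n_mc, replace = TRUE)
    l_diff <- Tm * mean(vapply(ts, kl_t, numeric(1)))
  }

  # reconstruction at the end of the chain: z_0 is still slightly noisy
  a0 <- sched_alpha(schedule, 0L); s0 <- sched_sigma(schedule, 0L)
  eps0 <- sample_joint_noise(n, f, batch)
  # coordinates: -log N(x | z0/a0, (s0/a0)^2) on the subspace reduces to
  # 0.5 dx log(2 pi s0^2/a0^2) + 0.5 ||eps_x||^2
  l0_x <- 0.5 * dx * log(2 * pi * s0^2 / a0^2) + 0.5 * sum(eps0$ex^2)
  # features: discretized Gaussians around the integer-valued unscaled data
  z0h <- a0 * h + s0 * eps0$eh
  k <- length(vocab)
  scales <- c(rep(onehot_scale, k), charge_scale)
  v_un <- sweep(h, 2L, scales, "/")        # 0/1 one-hots, integer charges
  z_un <- sweep(z0h / a0, 2L, scales, "/")
  s_un <- (s0 / a0) / scales
  l0_h <- -sum(log_discretized_gauss(v_un, z_un,
                                     matrix(s_un, n, f, byrow = TRUE)))

  total <- prior + l_diff + l0_x + l0_h - log_pN
  attr(total, "terms") <- list(prior = prior, diffusion = l_diff,
                               recon_x = l0_x, recon_h = l0_h,
                               log_pN = log_pN)
  total
}
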