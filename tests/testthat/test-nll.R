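test_that("the size term is zero for a degenerate size distribution", {
  sch <- make_schedule("polynomial", 20L)
  net <- tiny_net(seed = 1, T_ref = 20L)
  mol <- random_test_molecule(5, 2)
  d5 <- size_distribution(5L, 1)
  set.seed(1)
  v <- nll(net, mol, sch, d5, n_mc = 1L)
  expect_equal(attr(v, "terms")$log_pN, 0)
  # a size off the support contributes +Inf, with an explicit warning
  d9 <- size_distribution(9L, 1)
  set.seed(1)
  expect_warning(v2 <- nll(net, mol, sch, d9), "support")
  expect_equal(as.numeric(v2), Inf)
})

test_that("coordinate Gaussians use 3(N-1) degrees of freedom (N = 2 oracle)", {
  sch <- make_schedule("polynomial", 20L)
  net <- tiny_net(seed = 2, T_ref = 20L)
  mol <- molecule(rbind(c(0.4, -0.1, 0.7), c(-0.4, 0.1, -0.7)), c("O", "O"))
  set.seed(3)
  v <- nll(net, mol, sch, size_distribution(2L, 1))
  terms <- attr(v, "terms")
  # oracle: the zero-CoM subspace of two atoms at +/-v is 3-dimensional with
  # orthonormal coordinate w = sqrt(2) v; integrate the prior KL numerically
  # per dimension and add the analytic feature-part KL
  aT <- sch$alphas[21]; sT <- sch$sigmas[21]
  w0 <- sqrt(2) * remove_com(mol$coords)[1, ]
  kl1 <- function(m, s) {
    stats::integrate(function(w)
      dnorm(w, m, s) * (dnorm(w, m, s, log = TRUE) - dnorm(w, log = TRUE)),
      m - 12, m + 12)$value
  }
  klx_oracle <- sum(vapply(aT * w0, kl1, numeric(1), s = sT))
  h <- encode_features(mol)
  klh <- 0.5 * (length(h) * sT^2 + aT^2 * sum(h^2) -
                length(h) - length(h) * log(sT^2))
  expect_equal(terms$prior, klx_oracle + klh, tolerance = 1e-6)
})

test_that("the variational bound dominates the exact NLL of a linear toy model", {
  # a zero-noise-prediction denoiser makes the reverse chain linear-Gaussian,
  # so the exact marginal likelihood is available in closed form; the bound
  # must lie above the exact -log p(x, h, N).
  T_steps <- 40L
  sch <- make_schedule("polynomial", T_steps)
  zero_model <- function(zx, zh, t_mol, batch, condition)
    list(ex = zx * 0, eh = zh * 0)
  mol <- molecule(matrix(0, 1, 3), "C")   # one atom: features only
  sdist <- size_distribution(1L, 1)
  # exact: propagate the reverse-chain variance down to z_0
  V <- 1
  for (t in seq(T_steps, 1L)) {
    s <- t - 1L
    pp <- posterior_params(0, 0, s, t, sch)
    cz <- pp$coef_z0 / sch$alphas[t + 1L] + pp$coef_zt
    V <- cz^2 * V + (if (s > 0) pp$sigma^2 else 0)
  }
  a0 <- sch$alphas[1]; s0 <- sch$sigmas[1]
  f <- length(QM9_VOCAB) + 1L
  scales <- c(rep(0.25, length(QM9_VOCAB)), 0.1)
  v_un <- encode_features(mol)[1, ] / scales
  sd_un <- sqrt(V / (a0 * scales)^2 + (s0 / (a0 * scales))^2)
  p_chan <- pnorm((v_un + 0.5) / sd_un) - pnorm((v_un - 0.5) / sd_un)
  exact <- -sum(log(p_chan))
  set.seed(5)
  bounds <- replicate(20, as.numeric(nll(zero_model, mol, sch, sdist,
                                         exact = TRUE)))
  expect_gt(mean(bounds), exact)
})

test_that("the likelihood estimate is rotation-invariant", {
  sch <- make_schedule("polynomial", 50L)
  net <- tiny_net(seed = 8, T_ref = 50L)
  mol <- random_test_molecule(6, 17)
  sdist <- size_distribution(6L, 1)
  set.seed(9)
  base <- as.numeric(nll(net, mol, sch, sdist, n_mc = 2L))
  for (i in 1:3) {
    rotated <- mol
    rotated$coords <- mol$coords %*% t(random_rotation()) + i
    set.seed(9)
    v <- as.numeric(nll(net, rotated, sch, sdist, n_mc = 2L))
    expect_lt(abs(v - base), 1e-4)
  }
})
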