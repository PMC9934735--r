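make_z0 <- function(n = 4L, f = 6L, seed = 1L) {
  set.seed(seed)
  noisy_sample(remove_com(matrix(rnorm(n * 3), n, 3)),
               matrix(rnorm(n * f), n, f), 0L)
}

test_that("forward noising matches its stated moments and stays zero-CoM", {
  sch <- make_schedule("polynomial", 100L)
  z0 <- make_z0()
  # noiseless limit t = 0 (alpha ~ 1, sigma ~ 0 up to the precision clamp)
  fs <- forward_sample(z0, 0L, sch)
  expect_lt(max(abs(fs$zt$zx - z0$zx)), 1e-2)
  # zero-CoM closure at every t
  for (t in c(1L, 50L, 100L)) {
    fs <- forward_sample(z0, t, sch)
    expect_lt(max(abs(colSums(fs$zt$zx))), 1e-8)
  }
  # empirical mean and sd of one latent entry over many draws
  t <- 60L
  a <- sched_alpha(sch, t); s <- sched_sigma(sch, t)
  set.seed(9)
  draws <- replicate(1e4, forward_sample(z0, t, sch)$zt$zh[1, 1])
  expect_lt(abs(mean(draws) - a * z0$zh[1, 1]), 3 * s / sqrt(1e4))
  expect_lt(abs(sd(draws) - s), 3 * s / sqrt(2e4))
  # uncentred input is rejected
  bad <- noisy_sample(matrix(1, 2, 3), matrix(0, 2, 6), check = FALSE)
  expect_error(forward_sample(bad, 10L, sch), "centred")
})

test_that("posterior parameters match a numeric Bayes oracle on a grid", {
  sch <- make_schedule("polynomial", 50L)
  s <- 12L; t <- 30L
  z0v <- 0.8; ztv <- -0.4
  pp <- posterior_params(ztv, z0v, s, t, sch)
  # 1-D oracle: prior is the marginal q(z_s|z_0) = N(alpha_s z_0, sigma_s^2),
  # likelihood the transition q(z_t|z_s); posterior moments by dense
  # quadrature
  tcst <- transition_coeffs(sch, s, t)
  post_moments <- function(grid) {
    logw <- dnorm(grid, sched_alpha(sch, s) * z0v, sched_sigma(sch, s),
                  log = TRUE) +
            dnorm(ztv, tcst$alpha_ts * grid, tcst$sigma_ts, log = TRUE)
    w <- exp(logw - max(logw)); w <- w / sum(w)
    mu <- sum(w * grid)
    c(mu, sqrt(sum(w * (grid - mu)^2)))
  }
  coarse <- post_moments(seq(-10, 10, by = 1e-3))
  fine <- post_moments(seq(coarse[1] - 12 * coarse[2],
                           coarse[1] + 12 * coarse[2],
                           length.out = 200001L))
  mu_num <- fine[1]; sd_num <- fine[2]
  expect_lt(abs(pp$mu - mu_num), 1e-6)
  expect_lt(abs(pp$sigma - sd_num), 1e-6)
  expect_error(posterior_params(ztv, z0v, 30L, 12L, sch), "s < t")
})

test_that("posterior collapses to alpha_s z0 when sigma_s = 0", {
  hand <- structure(list(kind = "manual", T = 2L, precision = 0,
                         alphas = c(1, 0.95, 0.6),
                         sigmas = c(0, sqrt(1 - 0.95^2), 0.8)),
                    class = "noise_schedule")
  pp <- posterior_params(zt = 2.5, z0 = 1.2, s = 0L, t = 2L, hand)
  expect_equal(pp$mu, 1 * 1.2)
  expect_equal(pp$sigma, 0)
})

test_that("noise prediction inverts the forward marginal", {
  sch <- make_schedule("polynomial", 100L)
  z0 <- make_z0(5L)
  set.seed(3)
  fs <- forward_sample(z0, 70L, sch)
  rec <- predict_clean(fs$zt, fs$eps, 70L, sch)
  expect_lt(max(abs(rec$zx - z0$zx)), 1e-8)
  expect_lt(max(abs(rec$zh - z0$zh)), 1e-8)
  # scalar spot check: zt = 1, alpha = 0.5, sigma = 0.8660, eps = 0.2
  hand <- structure(list(kind = "manual", T = 1L, precision = 0,
                         alphas = c(1, 0.5), sigmas = c(0, 0.8660)),
                    class = "noise_schedule")
  z <- noisy_sample(matrix(0, 1, 3), matrix(1.0, 1, 1), 1L)
  eh <- list(ex = matrix(0, 1, 3), eh = matrix(0.2, 1, 1))
  out <- predict_clean(z, eh, 1L, hand)
  expect_equal(out$zh[1, 1], 1.6536, tolerance = 1e-4)
})

test_that("reverse steps are deterministic at sigma = 0 and stay on the subspace", {
  sch <- make_schedule("polynomial", 100L)
  z0 <- make_z0(4L)
  set.seed(8)
  fs <- forward_sample(z0, 40L, sch)
  eh <- list(ex = fs$eps$ex, eh = fs$eps$eh)
  # final decode step adds no noise: repeated calls agree exactly
  a <- reverse_step(fs$zt, eh, 0L, 40L, sch)
  b <- reverse_step(fs$zt, eh, 0L, 40L, sch)
  expect_equal(a$zx, b$zx)
  expect_lt(max(abs(colSums(a$zx))), 1e-8)
  zs <- reverse_step(fs$zt, eh, 20L, 40L, sch)
  expect_lt(max(abs(colSums(zs$zx))), 1e-8)
  bad <- list(ex = matrix(1, 4, 3), eh = fs$eps$eh)
  expect_error(reverse_step(fs$zt, bad, 20L, 40L, sch), "zero-CoM")
})

test_that("a perfect-denoiser chain recovers the data moments (1-D oracle)", {
  # one-atom molecules: the coordinate part is pinned to zero and each of
  # many independent feature channels runs a scalar diffusion whose optimal
  # denoiser is available in closed form for Gaussian data.
  sch <- make_schedule("polynomial", 200L)
  mu0 <- 0.8; s0 <- 0.5
  f <- 2000L
  oracle <- function(zx, zh, t_mol, batch, condition) {
    t <- t_mol[1]
    a <- sched_alpha(sch, t); s <- sched_sigma(sch, t)
    list(ex = zx * 0, eh = s * (zh - a * mu0) / (a^2 * s0^2 + s^2))
  }
  set.seed(31)
  batch <- make_batch(1L)
  zh <- matrix(rnorm(f), 1L, f)
  zx <- matrix(0, 1L, 3L)
  for (t in seq(200L, 1L)) {
    eh <- oracle(zx, zh, t, batch, NULL)
    st <- gcdiff:::reverse_step_batched(zx, zh, eh, t - 1L, t, sch, batch)
    zx <- st$zx; zh <- st$zh
  }
  expect_lt(abs(mean(zh) - mu0), 4 * s0 / sqrt(f))
  expect_lt(abs(sd(zh) - s0), 5 * s0 / sqrt(2 * f))
})

test_that("the loss is the weighted squared residual", {
  eps <- list(ex = matrix(1, 2, 3), eh = matrix(2, 2, 2))
  expect_equal(diffusion_loss(eps, eps), 0)
  zero <- list(ex = matrix(0, 2, 3), eh = matrix(0, 2, 2))
  l1 <- diffusion_loss(eps, zero)
  expect_equal(l1, 0.5 * (6 * 1 + 4 * 4))
  dbl <- list(ex = matrix(2, 2, 3), eh = matrix(4, 2, 2))
  expect_equal(diffusion_loss(dbl, zero), 4 * l1)  # quadratic form
  expect_equal(diffusion_loss(eps, zero, weight = 3), 3 * l1)
})

test_that("sampling is seed-reproducible and decodes on the subspace", {
  sch <- make_schedule("polynomial", 30L)
  model <- gaussian_oracle_model(sch, s0 = 0.8)
  set.seed(77)
  a <- sample_molecules(model, 3L, sizes = c(3L, 4L, 5L), schedule = sch)
  set.seed(77)
  b <- sample_molecules(model, 3L, sizes = c(3L, 4L, 5L), schedule = sch)
  expect_identical(a, b)
  for (m in a) {
    expect_lt(max(abs(colSums(m$coords))), 1e-8)
    expect_true(all(m$types %in% QM9_VOCAB))
  }
  # degenerate zero-noise model still satisfies the loop's shape contract
  zero_model <- function(zx, zh, t_mol, batch, condition)
    list(ex = zx * 0, eh = zh * 0)
  set.seed(1)
  out <- sample_molecules(zero_model, 2L, sizes = 4L, schedule = sch)
  expect_length(out, 2L)
  expect_equal(n_atoms(out[[1]]), 4L)
})
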