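test_that("analytic gradients match finite differences", {
  sch <- make_schedule("polynomial", 50L)
  # self-conditioning is deliberately gradient-stopped, so the exactness
  # check runs on a network without it
  net <- tiny_net(seed = 3, T_ref = 50L, self_cond = FALSE)
  batch <- make_batch(c(4L, 3L))
  set.seed(2)
  z0x <- project_zero_com(matrix(rnorm(21), 7, 3), batch)
  z0h <- matrix(rnorm(42), 7, 6)
  t_mol <- c(10L, 30L)
  set.seed(42)
  lg <- gcdiff:::batch_loss_grad(net, z0x, z0h, t_mol, batch, sch)
  # the flat gradient is ordered like the flattened parameter tree
  grads <- gcdiff:::unflatten_tree(lg$grad,
                                   gcdiff:::tree_skeleton(net$params))
  loss_at <- function(n2) {
    set.seed(42)
    gcdiff:::batch_loss_grad(n2, z0x, z0h, t_mol, batch, sch)$loss
  }
  eps <- 1e-5
  check <- function(get, set, ana) {
    np <- net; np <- set(np, get(np) + eps); up <- loss_at(np)
    nm <- net; nm <- set(nm, get(nm) - eps); dn <- loss_at(nm)
    num <- (up - dn) / (2 * eps)
    expect_lt(abs(num - ana) / max(abs(num), abs(ana), 1e-6), 1e-4)
  }
  check(function(n) n$params$embed$W[3],
        function(n, v) { n$params$embed$W[3] <- v; n },
        grads$embed$W[3])
  check(function(n) n$params$layers[[1]]$W1[5],
        function(n, v) { n$params$layers[[1]]$W1[5] <- v; n },
        grads$layers[[1]]$W1[5])
  check(function(n) n$params$layers[[2]]$Wv[9],
        function(n, v) { n$params$layers[[2]]$Wv[9] <- v; n },
        grads$layers[[2]]$Wv[9])
  check(function(n) n$params$layers[[1]]$wg[2],
        function(n, v) { n$params$layers[[1]]$wg[2] <- v; n },
        grads$layers[[1]]$wg[2])
  check(function(n) n$params$layers[[2]]$M[3],
        function(n, v) { n$params$layers[[2]]$M[3] <- v; n },
        grads$layers[[2]]$M[3])
  check(function(n) n$params$layers[[1]]$Wn1[11],
        function(n, v) { n$params$layers[[1]]$Wn1[11] <- v; n },
        grads$layers[[1]]$Wn1[11])
  check(function(n) n$params$head$Wox[7],
        function(n, v) { n$params$head$Wox[7] <- v; n },
        grads$head$Wox[7])
})

test_that("the denoiser is rotation-equivariant and zero-CoM closed", {
  sch <- make_schedule("polynomial", 100L)
  for (seed in 1:5) {
    net <- tiny_net(seed = seed, T_ref = 100L)
    n <- sample(2:12, 1)
    set.seed(seed + 100)
    zx <- remove_com(matrix(rnorm(n * 3), n, 3))
    zh <- matrix(rnorm(n * 6), n, 6)
    z <- noisy_sample(zx, zh, 50L)
    out <- denoise(net, z, 50L)
    expect_lt(max(abs(colSums(out$ex))), 1e-8)
    R <- random_rotation()
    outR <- denoise(net, noisy_sample(zx %*% t(R), zh, 50L), 50L)
    expect_lt(max(abs(outR$ex - out$ex %*% t(R))), 1e-4)
    expect_lt(max(abs(outR$eh - out$eh)), 1e-4)
  }
})

test_that("frames make the network chirality-aware; without them it is blind", {
  chiral <- make_templates()[[4]]
  zx <- remove_com(chiral$coords)
  zh <- encode_features(molecule(zx, chiral$types))
  zxm <- zx; zxm[, 1] <- -zxm[, 1]        # mirror image
  run <- function(net) {
    o <- denoise(net, noisy_sample(zx, zh, 10L), 10L)
    om <- denoise(net, noisy_sample(zxm, zh, 10L), 10L)
    max(abs(o$eh - om$eh))                 # invariant outputs only
  }
  net_frames <- tiny_net(seed = 9, T_ref = 100L, use_frames = TRUE)
  net_blind <- tiny_net(seed = 9, T_ref = 100L, use_frames = FALSE)
  expect_gt(run(net_frames), 1e-6)
  expect_lt(run(net_blind), 1e-10)
})

test_that("ablation flags wire through: SMA off ignores the gate parameters", {
  z <- noisy_sample(remove_com(matrix(rnorm(12), 4, 3)),
                    matrix(rnorm(24), 4, 6), 20L)
  net <- tiny_net(seed = 5, T_ref = 100L, use_sma = FALSE)
  out1 <- denoise(net, z, 20L)
  net2 <- net
  for (l in seq_along(net2$params$layers)) {
    net2$params$layers[[l]]$wg[] <- rnorm(length(net2$params$layers[[l]]$wg))
    net2$params$layers[[l]]$bg <- 99
  }
  out2 <- denoise(net2, z, 20L)
  expect_equal(out1, out2)
  # with SMA on, the gate parameters matter
  net3 <- tiny_net(seed = 5, T_ref = 100L, use_sma = TRUE)
  net4 <- net3
  for (l in seq_along(net4$params$layers)) net4$params$layers[[l]]$bg <- -30
  expect_gt(max(abs(denoise(net3, z, 20L)$eh - denoise(net4, z, 20L)$eh)), 0)
})

test_that("one gcp layer keeps scalars invariant and vectors equivariant", {
  net <- tiny_net(seed = 13, T_ref = 100L)
  n <- 6L
  set.seed(13)
  zx <- remove_com(matrix(rnorm(n * 3), n, 3))
  S <- matrix(rnorm(n * 16), n, 16)
  V <- vectorize_positions(zx, 4L)
  out <- gcp_layer(net, zx, S, V)
  R <- random_rotation()
  VR <- V
  for (k in 1:4) VR[, k, ] <- V[, k, ] %*% t(R)
  outR <- gcp_layer(net, zx %*% t(R), S, VR)
  expect_lt(max(abs(outR$S - out$S)), 1e-5)
  for (k in 1:4)
    expect_lt(max(abs(outR$V[, k, ] - out$V[, k, ] %*% t(R))), 1e-5)
})

test_that("time and range contracts are enforced", {
  net <- tiny_net(T_ref = 100L)
  z <- noisy_sample(remove_com(matrix(rnorm(9), 3, 3)), matrix(0, 3, 6), 1L)
  expect_error(denoise(net, z, 0L), "out of range")
  expect_error(denoise(net, z, 101L), "out of range")
  cnet <- tiny_net(T_ref = 100L, condition_dim = 1L)
  expect_error(denoise(cnet, z, 10L), "condition")
})

test_that("training reduces the loss and resumes deterministically", {
  mols <- sample_dataset(n = 60L, jitter_sd = 0.05, seed = 2L)
  sch <- make_schedule("polynomial", 50L)
  net0 <- tiny_net(seed = 0, head_init = "zero", T_ref = 50L)
  net <- train_denoiser(mols, net0, sch, epochs = 6L, batch_size = 20L,
                        seed = 0L)
  expect_lt(mean(tail(net$loss_history, 2)), net$loss_history[1])
  # uninterrupted 6 epochs == 3 epochs + resume for 3 more
  half <- train_denoiser(mols, net0, sch, epochs = 3L, batch_size = 20L,
                         seed = 0L)
  full <- train_denoiser(mols, half, sch, epochs = 3L, batch_size = 20L,
                         seed = 0L, resume = TRUE)
  expect_equal(full$params, net$params, tolerance = 1e-12)
  expect_lt(abs(tail(full$loss_history, 1) - tail(net$loss_history, 1)), 1e-6)
})

test_that("checkpoints round-trip bit-exactly", {
  net <- tiny_net(seed = 21, T_ref = 50L)
  sch <- make_schedule("cosine", 50L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(net, sch, path, meta = list(seed = 21L))
  ck <- load_checkpoint(path)
  expect_identical(ck$net$params, net$params)
  expect_identical(ck$schedule$alphas, sch$alphas)
  expect_identical(ck$meta$seed, 21L)
})
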