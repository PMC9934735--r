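# Shared fixtures for the test suite. Heavy trained models are built once
# per session and memoized here so the generative-recovery and optimization
# tests (and nothing else) pay the training cost exactly once.

.model_cache <- new.env(parent = emptyenv())

tiny_config <- function(...) {
  denoiser_config(n_layers = 2L, node_scalar_dim = 16L,
                  node_vector_channels = 4L, edge_scalar_dim = 8L,
                  edge_vector_channels = 2L, ...)
}

tiny_net <- function(seed = 1L, head_init = "random", T_ref = 100L, ...) {
  denoiser_network(tiny_config(...), seed = seed, head_init = head_init,
                   T_ref = T_ref)
}

random_test_molecule <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  molecule(matrix(stats::rnorm(n * 3), n, 3),
           sample(QM9_VOCAB, n, replace = TRUE))
}

# Study conditions of the toy generative-recovery experiment: 2,000
# molecules at jitter 0.05, seed 0, T = 500; 4 layers x 64 scalars with 16
# vector channels and 128-wide MLPs; Adam at 1e-3 decaying geometrically,
# batch 32, 150 epochs (45 for the conditional model).
toy_schedule <- function() make_schedule("polynomial", 500L)

toy_train_config <- function(conditional = FALSE) {
  denoiser_config(n_layers = 4L, node_scalar_dim = 64L,
                  node_vector_channels = 16L, edge_scalar_dim = 32L,
                  edge_vector_channels = 8L, hidden_dim = 128L,
                  self_cond = FALSE,
                  condition_dim = if (conditional) 1L else 0L)
}

toy_trained_model <- function() {
  if (!is.null(.model_cache$uncond)) return(.model_cache$uncond)
  mols <- sample_dataset(make_templates(), n = 2000L, jitter_sd = 0.05,
                         seed = 0L)
  sch <- toy_schedule()
  net <- denoiser_network(toy_train_config(), seed = 0L, T_ref = sch$T)
  net <- train_denoiser(mols, net, sch, epochs = 150L, batch_size = 32L,
                        lr = 1e-3, lr_final = 1e-4, seed = 0L)
  .model_cache$uncond <- list(net = net, schedule = sch, train = mols)
  .model_cache$uncond
}

toy_conditional_model <- function() {
  if (!is.null(.model_cache$cond)) return(.model_cache$cond)
  mols <- sample_dataset(make_templates(), n = 2000L, jitter_sd = 0.05,
                         seed = 0L)
  sch <- toy_schedule()
  net <- denoiser_network(toy_train_config(conditional = TRUE), seed = 0L,
                          T_ref = sch$T)
  net <- train_denoiser(mols, net, sch, epochs = 45L, batch_size = 32L,
                        lr = 1e-3, lr_final = 2e-4, seed = 0L,
                        property = "radius_of_gyration")
  .model_cache$cond <- list(net = net, schedule = sch, train = mols)
  .model_cache$cond
}

# Closed-form optimal denoiser for zero-mean Gaussian data with variance
# s0^2 per channel: eps_hat = sigma_t z_t / (alpha_t^2 s0^2 + sigma_t^2).
# Keeps the reverse chain bounded, so loop-level contracts can be tested
# without training. `cond_gain` adds a condition-proportional drift to the
# feature noise so conditional plumbing is observable.
gaussian_oracle_model <- function(schedule, s0 = 1, cond_gain = 0) {
  function(zx, zh, t_mol, batch, condition) {
    t <- t_mol[1]
    a <- schedule$alphas[t + 1L]; s <- schedule$sigmas[t + 1L]
    k <- s / (a^2 * s0^2 + s^2)
    eh <- k * zh
    if (cond_gain != 0 && !is.null(condition))
      eh <- eh + cond_gain * condition[batch$mol_of]
    list(ex = project_zero_com(k * zx, batch), eh = eh)
  }
}

# Exact water geometry (O-H 0.96 A, H-O-H 104.5 deg).
water_molecule <- function() {
  ang <- 104.5 * pi / 180
  molecule(rbind(c(0, 0, 0),
                 0.96 * c(sin(ang / 2), cos(ang / 2), 0),
                 0.96 * c(-sin(ang / 2), cos(ang / 2), 0)),
           c("O", "H", "H"))
}
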