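#' @title Training: hand-derived backpropagation and Adam
#' @name training
#' @description
#' The denoiser is trained by noise prediction: draw a step `t` uniformly per
#' molecule, forward-noise the clean latent, and regress the injected noise
#' with the unweighted quadratic objective (`w(t) = 1`). Gradients are
#' hand-derived for the message-passing architecture and verified against
#' central finite differences in the test suite; parameters are updated with
#' Adam. Frames, radial features and all other functions of the *inputs* are
#' constants with respect to the parameters, so backpropagation only
#' traverses the learned linear maps and their nonlinearities.
NULL

# --- tree utilities over nested parameter lists -------------------------

# Loss and parameter gradients for one minibatch of encoded molecules.
# z0x/z0h are batched clean latents; t_mol a step per molecule.
batch_loss_grad <- function(net, z0x, z0h, t_mol, batch, schedule,
                            condition = NULL) {
  a <- sched_alpha(schedule, t_mol)[batch$mol_of]
  s <- sched_sigma(schedule, t_mol)[batch$mol_of]
  eps <- sample_joint_noise(batch$n_nodes, ncol(z0h), batch)
  zx <- a * z0x + s * eps$ex
  zh <- a * z0h + s * eps$eh
  z0_est <- NULL
  if (net$config$self_cond && stats::runif(1) < 0.5) {
    # self-conditioning pass: predict once without the estimate, feed the
    # resulting clean-sample estimate back in (no gradient through it)
    pre <- denoiser_forward(net, zx, zh, t_mol, batch, condition)
    z0_est <- list(zx = project_zero_com(zx / a - pre$ex * s / a, batch),
                   zh = zh / a - pre$eh * s / a)
  }
  inp <- assemble_inputs(net, zx, zh, t_mol, batch, condition, z0_est)
  res <- dn_loss_grad_cpp(inp$Xin, inp$S0, inp$V0, net$params$layers,
                          net$params$head, eps$ex, eps$eh,
                          batch$src - 1L, batch$dst - 1L,
                          inp$fr$a, inp$fr$b, inp$fr$c, inp$invd, inp$R,
                          batch$deg, batch$mol_of - 1L,
                          as.numeric(batch$sizes), net$config$use_sma)
  # the flat gradient is ordered exactly like flatten_tree(net$params)
  list(loss = res$loss, grad = res$grad)
}

# The optimizer works on a flat parameter vector (one `unlist` order shared
# by parameters and gradients); the tree is rebuilt once per step for the
# forward pass. This avoids reallocating every parameter matrix a dozen
# times per update.
flatten_tree <- function(tree) unlist(tree, use.names = FALSE)

tree_skeleton <- function(tree) {
  if (is.list(tree)) return(lapply(tree, tree_skeleton))
  if (is.matrix(tree)) dim(tree) else length(tree)
}

unflatten_tree <- function(flat, skel, pos = 1L) {
  rebuild <- function(sk) {
    if (is.list(sk)) return(lapply(sk, rebuild))
    n <- if (length(sk) == 2L) sk[1] * sk[2] else sk
    vals <- flat[pos:(pos + n - 1L)]
    pos <<- pos + n
    if (length(sk) == 2L) matrix(vals, sk[1], sk[2]) else vals
  }
  rebuild(skel)
}

adam_init <- function(params) {
  flat <- flatten_tree(params)
  list(m = flat * 0, v = flat * 0, step = 0L)
}

# fused C++ Adam step; the moment buffers and the EMA vector are updated
# in place (they are owned exclusively by the training loop)
adam_update_flat <- function(flat_p, flat_g, state, ema, lr = 1e-3,
                             beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                             clip = 10, ema_decay = 0) {
  state$step <- state$step + 1L
  p <- adam_step_cpp(flat_p, flat_g, state$m, state$v, ema, state$step,
                     lr, beta1, beta2, eps, clip, ema_decay)
  list(params = p, state = state)
}

#' Train a denoiser by noise prediction
#'
#' Minimizes the unweighted noise-matching objective over uniformly sampled
#' steps with Adam. When `property` names an entry of the molecules'
#' `props`, the network is trained conditionally: the property value is
#' standardized with training-set statistics and appended to every node's
#' scalar features (the network must have `condition_dim = 1`).
#'
#' @param mols list of `molecule` objects (training set).
#' @param net a `denoiser_network` (freshly initialized or resumed).
#' @param schedule a `noise_schedule`; its `T` becomes the network's time
#'   normalization constant.
#' @param epochs number of passes over the data.
#' @param batch_size molecules per gradient step.
#' @param lr Adam learning rate.
#' @param seed RNG seed controlling batching and noise draws.
#' @param property optional property name for conditional training.
#' @param verbose print the epoch losses.
#' @param resume continue from the optimizer and RNG state stored in the
#'   network by a previous call (checkpointed training is then bit-for-bit
#'   identical to an uninterrupted run).
#' @param lr_final final learning rate of a geometric per-epoch decay
#'   (default: equal to `lr`, i.e. constant).
#' @param ema_decay exponential-moving-average factor for the evaluation
#'   weights (0 disables averaging). The returned network carries the
#'   averaged parameters; the raw optimizer trajectory is kept in its
#'   training state for exact resumption.
#' @param onehot_scale,charge_scale feature scalings applied when encoding
#'   the training molecules; stored on the network so downstream decoding
#'   and likelihoods can match.
#' @return the trained network, with `loss_history` (mean loss per epoch),
#'   the fitted training `size_dist`, and condition statistics attached.
#' @export
train_denoiser <- function(mols, net, schedule, epochs = 50L,
                           batch_size = 64L, lr = 1e-3, seed = 0L,
                           property = NULL, verbose = FALSE,
                           resume = FALSE, lr_final = lr,
                           ema_decay = 0.995, onehot_scale = 0.25,
                           charge_scale = 0.1) {
  vocab <- net$vocab
  net$T_ref <- schedule$T
  n <- length(mols)
  enc_x <- lapply(mols, function(m) remove_com(m$coords))
  enc_h <- lapply(mols, function(m)
    encode_features(m, vocab, onehot_scale, charge_scale))
  net$scales <- list(onehot = onehot_scale, charge = charge_scale)
  sizes <- vapply(mols, n_atoms, integer(1))
  condv <- NULL
  if (!is.null(property)) {
    if (net$config$condition_dim < 1L)
      stop("network has condition_dim = 0; rebuild it with condition_dim = 1")
    condv <- vapply(mols, function(m) as.numeric(m$props[[property]]),
                    numeric(1))
    if (anyNA(condv)) stop("missing property labels: ", property)
    net$cond_stats <- list(mean = mean(condv), sd = stats::sd(condv),
                           property = property)
  }
  skel <- tree_skeleton(net$params)
  if (resume && !is.null(net$train_state)) {
    opt <- net$train_state$opt
    # the C++ optimizer updates its buffers in place: copy them so the
    # caller's stored training state is not mutated
    opt$m <- opt$m + 0; opt$v <- opt$v + 0
    net$params <- net$train_state$raw_params   # optimizer weights, not EMA
    flat_p <- flatten_tree(net$params)
    flat_ema <- net$train_state$ema_flat + 0
    assign(".Random.seed", net$train_state$rng, envir = globalenv())
  } else {
    opt <- adam_init(net$params)
    flat_p <- flatten_tree(net$params)
    flat_ema <- flat_p + 0     # own buffer: the C++ step writes in place
    set.seed(seed)
  }
  history <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    lr_ep <- lr * (lr_final / lr)^(if (epochs > 1L) (ep - 1L) / (epochs - 1L)
                                   else 0)
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1L, n)]
      batch <- make_batch(sizes[idx])
      z0x <- do.call(rbind, enc_x[idx])
      z0h <- do.call(rbind, enc_h[idx])
      t_mol <- sample.int(schedule$T, length(idx), replace = TRUE)
      lg <- batch_loss_grad(net, z0x, z0h, t_mol, batch, schedule,
                            condition = if (!is.null(condv)) condv[idx])
      res <- adam_update_flat(flat_p, lg$grad, opt, flat_ema, lr = lr_ep,
                              ema_decay = ema_decay)
      flat_p <- res$params; opt <- res$state
      net$params <- unflatten_tree(flat_p, skel)
      losses <- c(losses, lg$loss)
    }
    history[ep] <- mean(losses)
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f", ep, history[ep]))
  }
  net$loss_history <- c(net$loss_history, history)
  net$size_dist <- fit_size_distribution(mols)
  net$train_state <- list(opt = opt, raw_params = unflatten_tree(flat_p, skel),
                          ema_flat = flat_ema,
                          rng = get(".Random.seed", envir = globalenv()))
  if (ema_decay > 0) net$params <- unflatten_tree(flat_ema, skel)
  net
}
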