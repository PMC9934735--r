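test_that("condition embedding standardizes, broadcasts, and is linear", {
  stats <- list(mean = 2, sd = 4)
  cond <- property_condition("radius_of_gyration", 2, stats)
  expect_equal(embed_condition(cond, 3L), matrix(0, 3, 1))
  c1 <- embed_condition(property_condition("p", 6, stats), 5L)
  expect_equal(c1, matrix(1, 5, 1))           # (6-2)/4, same for every node
  c2 <- embed_condition(property_condition("p", 10, stats), 5L)
  expect_equal(c2 - c1, (10 - 6) / 4 * matrix(1, 5, 1))  # linearity
  expect_error(property_condition("p", 1, list(mean = 0, sd = 0)), "positive")
})

test_that("conditional sampling responds to the condition; unconditional ignores it", {
  sch <- make_schedule("polynomial", 30L)
  cond_model <- gaussian_oracle_model(sch, s0 = 0.8, cond_gain = 1)
  set.seed(5)
  a <- sample_molecules(cond_model, 2L, sizes = 4L, schedule = sch,
                        condition = -2)
  set.seed(5)
  b <- sample_molecules(cond_model, 2L, sizes = 4L, schedule = sch,
                        condition = 2)
  expect_false(identical(a, b))
  # the denoiser itself responds to the condition value
  cnet <- tiny_net(seed = 2, T_ref = 30L, condition_dim = 1L,
                   head_init = "random")
  cnet$cond_stats <- list(mean = 0, sd = 1)
  z <- noisy_sample(remove_com(matrix(rnorm(12), 4, 3)),
                    matrix(rnorm(24), 4, 6), 10L)
  d1 <- denoise(cnet, z, 10L, condition = -2)
  d2 <- denoise(cnet, z, 10L, condition = 2)
  expect_gt(max(abs(d1$eh - d2$eh)), 0)
  # an unconditional model ignores the condition slot entirely
  uncond_model <- gaussian_oracle_model(sch, s0 = 0.8, cond_gain = 0)
  set.seed(5)
  u1 <- sample_molecules(uncond_model, 2L, sizes = 4L, schedule = sch,
                         condition = -2)
  set.seed(5)
  u2 <- sample_molecules(uncond_model, 2L, sizes = 4L, schedule = sch,
                         condition = 2)
  expect_identical(u1, u2)
})

test_that("the time-scaled grid degenerates correctly at its ends", {
  sch <- make_schedule("polynomial", 40L)
  model <- gaussian_oracle_model(sch, s0 = 0.9)
  set.seed(11)
  full <- sample_molecules(model, 2L, sizes = 3L, schedule = sch)
  set.seed(11)
  ts <- timescaled_generate(model, 2L, sizes = 3L, n_steps = 40L,
                            schedule = sch)
  expect_identical(full, ts)
  # a single step is one jump from z_T followed by decoding
  set.seed(11)
  one <- timescaled_generate(model, 2L, sizes = 3L, n_steps = 1L,
                             schedule = sch)
  expect_length(one, 2L)
  expect_equal(n_atoms(one[[1]]), 3L)
  expect_error(timescaled_generate(model, 1L, sizes = 3L, n_steps = 41L,
                                   schedule = sch), "1..T")
})

test_that("a zero-step optimization plan is the identity and runs are seeded", {
  sch <- make_schedule("polynomial", 30L)
  cnet <- tiny_net(seed = 7, T_ref = 30L, condition_dim = 1L)
  cnet$cond_stats <- list(mean = 1, sd = 0.5)
  mols <- sample_dataset(n = 4L, jitter_sd = 0.05, seed = 9L)
  plan0 <- optimization_plan(n_opt_steps = 0L,
                             target = list(name = "rg", value = 1))
  expect_identical(optimize_molecules(mols, cnet, plan0, sch), mols)
  plan <- optimization_plan(n_opt_steps = 10L,
                            target = list(name = "rg", value = 1))
  set.seed(3)
  o1 <- optimize_molecules(mols, cnet, plan, sch)
  set.seed(3)
  o2 <- optimize_molecules(mols, cnet, plan, sch)
  expect_identical(o1, o2)
  # atom counts preserved
  expect_equal(vapply(o1, n_atoms, integer(1)),
               vapply(mols, n_atoms, integer(1)))
  expect_error(optimize_molecules(mols, cnet,
                                  optimization_plan(n_opt_steps = 31L,
                                                    target = plan$target),
                                  sch), "0..T")
})

test_that("optimization evaluation matches hand-computed deltas", {
  mols <- sample_dataset(n = 3L, jitter_sd = 0.05, seed = 13L)
  targets <- c(0.5, 0.7, 0.9)
  oracle <- function(m) toy_property(m, "radius_of_gyration")
  ev <- evaluate_optimization(mols, mols, oracle, targets, toy_bond_table())
  expect_equal(ev$delta_mae, 0)
  expect_equal(ev$delta_ms, 0)
  expect_equal(ev$mae_before,
               mean(abs(vapply(mols, oracle, numeric(1)) - targets)))
  expect_equal(ev$ms_after - ev$ms_before, ev$delta_ms)
  expect_equal(nrow(ev$detail), 3L)
  expect_error(evaluate_optimization(mols, mols[1:2], oracle, targets),
               "paired")
})
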