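test_that("frames match the hand-computed cross products", {
  fr <- build_frames(c(1, 0, 0), c(0, 1, 0))
  expect_equal(fr$a, c(1, -1, 0) / sqrt(2), tolerance = 1e-4)
  expect_equal(fr$b, c(0, 0, 1), tolerance = 1e-4)
  expect_equal(fr$c, c(-1, -1, 0) / sqrt(2), tolerance = 1e-4)
  expect_false(fr$degenerate)
  # orthonormality and the c = a x b identity
  M <- rbind(fr$a, fr$b, fr$c)
  expect_lt(max(abs(M %*% t(M) - diag(3))), 1e-6)
})

test_that("frames rotate with the points and degenerate cases are guarded", {
  set.seed(4)
  for (i in 1:20) {
    xi <- rnorm(3); xj <- rnorm(3)
    R <- random_rotation()
    fr <- build_frames(xi, xj)
    frR <- build_frames(as.numeric(R %*% xi), as.numeric(R %*% xj))
    expect_lt(max(abs(frR$a - as.numeric(R %*% fr$a))), 1e-6)
    expect_lt(max(abs(frR$b - as.numeric(R %*% fr$b))), 1e-6)
    expect_lt(max(abs(frR$c - as.numeric(R %*% fr$c))), 1e-6)
  }
  # collinear-with-origin points have no cross product: flagged, zeroed
  fr <- build_frames(c(1, 0, 0), c(2, 0, 0))
  expect_true(fr$degenerate)
  expect_equal(fr$b, c(0, 0, 0))
  expect_equal(fr$c, c(0, 0, 0))
  expect_true(build_frames(c(1, 1, 1), c(1, 1, 1))$degenerate)
  expect_error(build_frames(c(NA, 0, 0), c(0, 1, 0)), "finite")
})

test_that("scalarization is invariant under rotation and flips under reflection", {
  fr <- build_frames(c(1, 0, 0), c(0, 1, 0))
  expect_equal(as.numeric(scalarize(fr$a, fr)), c(1, 0, 0), tolerance = 1e-10)
  set.seed(12)
  xi <- rnorm(3); xj <- rnorm(3); v <- rnorm(3)
  base <- as.numeric(scalarize(v, build_frames(xi, xj)))
  R <- random_rotation()
  rot <- as.numeric(scalarize(as.numeric(R %*% v),
                              build_frames(as.numeric(R %*% xi),
                                           as.numeric(R %*% xj))))
  expect_lt(max(abs(base - rot)), 1e-6)
  # mirror the generating coordinates and the vector: the displacement axis
  # a and the double cross product c are reflection-even, while the
  # cross-product axis b is a pseudo-vector, so exactly the b-component
  # flips sign — this is the chirality-sensitive channel
  mir <- function(u) c(-u[1], u[2], u[3])
  ref <- as.numeric(scalarize(mir(v), build_frames(mir(xi), mir(xj))))
  expect_lt(abs(ref[1] - base[1]), 1e-6)
  expect_lt(abs(ref[2] + base[2]), 1e-6)
  expect_lt(abs(ref[3] - base[3]), 1e-6)
})

test_that("position vectorization is linear, equivariant, and guarded", {
  x <- remove_com(matrix(rnorm(12), 4, 3))
  V <- vectorize_positions(x, 3L)
  expect_equal(dim(V), c(4L, 3L, 3L))
  expect_equal(V[, 1, ], x)
  expect_true(all(V[, 2:3, ] == 0))
  R <- random_rotation()
  VR <- vectorize_positions(x %*% t(R), 3L)
  expect_lt(max(abs(VR[, 1, ] - x %*% t(R))), 1e-12)
  expect_equal(vectorize_positions(matrix(0, 2, 3))[, 1, ], matrix(0, 2, 3))
  # symmetric pair: node vectors are negatives of each other
  pair <- rbind(c(1, 2, 3), c(-1, -2, -3))
  Vp <- vectorize_positions(pair)
  expect_equal(Vp[1, 1, ], -Vp[2, 1, ])
  expect_error(vectorize_positions(matrix(1, 2, 3)), "centred")
})
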