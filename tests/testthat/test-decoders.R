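test_that("hard decoding matches worked distance computations", {
  ovr <- ovr_matrix(4)
  for (k in 1:4) {
    g <- as.numeric(ovr[k, ] == 1L)
    expect_identical(as.integer(decode_hard(ovr, g)), k)
  }

  ap3 <- ap_matrix(3)
  res <- decode_hard(ap3, c(1, 1, 0))
  expect_identical(as.integer(res), 1L)
  expect_equal(attr(res, "distances"), c(0.5, 2.5, 1.5))

  # OVR K = 2, binarized (1, 1): both rows at distance 1, tie -> class 1
  expect_identical(as.integer(decode_hard(ovr_matrix(2), c(1, 1))), 1L)

  expect_error(decode_hard(ap3, c(1, 1)), "length")
  expect_error(decode_hard(ap3, c(1, 1, 0), cutoff = 1), "cutoff")
})

test_that("naive decoding reproduces the all-pairs worked example", {
  ap3 <- ap_matrix(3)
  p <- decode_naive(ap3, c(0.2, 0.5, 0.9))
  # class masses 0.2*0.5, 0.8*0.9, 0.5*0.1 normalized by 0.87; the class-2
  # mass is (1 - g1) * g3
  expect_equal(as.numeric(p), c(0.10, 0.72, 0.05) / 0.87, tolerance = 1e-12)
  expect_equal(p[2], (1 - 0.2) * 0.9 / 0.87, tolerance = 1e-12)
  expect_equal(sum(p), 1)
})

test_that("naive decoding degenerates correctly on symmetric and binary cases", {
  for (K in c(3, 5)) {
    p <- decode_naive(ovr_matrix(K), rep(0.5, K))
    expect_equal(as.numeric(p), rep(1 / K, K))
  }
  two <- coding_matrix(matrix(c(1L, 0L), ncol = 1))
  for (g1 in c(0.1, 0.5, 0.83)) {
    expect_equal(as.numeric(decode_naive(two, g1)), c(g1, 1 - g1), tolerance = 1e-12)
  }
})

test_that("naive decoding equals the product-space oracle on random instances", {
  set.seed(77)
  for (rep in 1:200) {
    K <- sample(2:6, 1)
    L <- sample(max(2, ceiling(log2(K))):15, 1)
    inst <- random_decode_instance(K, L, sample(c("dense", "sparse"), 1))
    expect_equal(
      as.numeric(decode_naive(inst$code, inst$g)),
      naive_oracle(inst$code, inst$g),
      tolerance = 1e-12
    )
  }
})

test_that("raising a binary output raises every positively-coded class posterior", {
  set.seed(88)
  for (rep in 1:20) {
    inst <- random_decode_instance(4, 8, "sparse")
    i <- sample(ncol(inst$code), 1)
    g_lo <- inst$g
    g_hi <- inst$g
    g_lo[i] <- 0.3
    g_hi[i] <- 0.7
    p_lo <- as.numeric(decode_naive(inst$code, g_lo))
    p_hi <- as.numeric(decode_naive(inst$code, g_hi))
    pos <- which(inst$code[, i] == 1L)
    expect_true(all(p_hi[pos] > p_lo[pos]))
  }
})

test_that("decoders are equivariant under class permutation", {
  set.seed(99)
  for (rep in 1:20) {
    inst <- random_decode_instance(4, 8, "dense")
    perm <- sample(4)
    permuted <- coding_matrix(unclass(inst$code)[perm, ])
    p <- as.numeric(decode_naive(inst$code, inst$g))
    p_perm <- as.numeric(decode_naive(permuted, inst$g))
    expect_equal(p_perm, p[perm], tolerance = 1e-12)

    k <- as.integer(decode_hard(inst$code, inst$g))
    k_perm <- as.integer(decode_hard(permuted, inst$g))
    # permuted winner maps back to the original winner unless ties moved
    d <- attr(decode_hard(inst$code, inst$g), "distances")
    if (sum(d == min(d)) == 1L) expect_identical(perm[k_perm], k)

    gp <- decode_gbt(gbt_problem(inst$code, inst$g))$posterior
    gp_perm <- decode_gbt(gbt_problem(permuted, inst$g))$posterior
    expect_equal(gp_perm, gp[perm], tolerance = 1e-9)
  }
})

test_that("generalized Bradley-Terry solves the exactly solvable binary case", {
  two <- coding_matrix(matrix(c(1L, 0L), ncol = 1))
  res <- decode_gbt(gbt_problem(two, 0.7))
  expect_equal(res$posterior, c(0.7, 0.3), tolerance = 1e-8)
  expect_true(res$converged)

  # all-pairs, equal weights, uninformative outputs -> uniform fixed point
  ap4 <- ap_matrix(4)
  res_u <- decode_gbt(gbt_problem(ap4, rep(0.5, ncol(ap4))))
  expect_equal(res_u$posterior, rep(0.25, 4), tolerance = 1e-8)
})

test_that("consistent observations are recovered and the likelihood never worsens", {
  p_star <- c(0.5, 0.3, 0.2)
  prob <- consistent_gbt_observations(p_star, ap_matrix(3))
  expect_equal(prob$observations, c(0.625, 5 / 7, 0.6), tolerance = 1e-12)
  res <- decode_gbt(prob)
  expect_lt(max(abs(res$posterior - p_star)), 1e-4)
  expect_true(all(diff(res$objective) <= 1e-10))
})

test_that("all three decoders agree on the binary argmax", {
  two <- coding_matrix(matrix(c(1L, 0L), ncol = 1))
  for (g1 in c(0.05, 0.4, 0.6, 0.99)) {
    naive_k <- which.max(as.numeric(decode_naive(two, g1)))
    gbt_k <- which.max(decode_gbt(gbt_problem(two, g1))$posterior)
    hard_k <- as.integer(decode_hard(two, g1))
    expect_identical(naive_k, hard_k)
    expect_identical(gbt_k, hard_k)
  }
})

test_that("naive decoding work grows linearly in the number of columns", {
  # dense codes: the instrumented operation count must be exactly affine in
  # L for fixed K, so second differences over a doubling ladder vanish
  K <- 6
  Ls <- c(5L, 10L, 20L, 40L)
  ops <- vapply(Ls, function(L) {
    code <- random_code_matrix(K, L, "dense", n_candidates = 1, seed = L)
    attr(decode_naive(code, rep(0.5, L)), "ops")
  }, numeric(1))
  slopes <- diff(ops) / diff(Ls)
  expect_true(all(abs(diff(slopes)) < 1e-12))
  expect_equal(ops, K * Ls + K)
})
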