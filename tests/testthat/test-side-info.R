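rmFrom <- function(values, mask, drugs = NULL, cells = NULL) {
  drugs <- drugs %||% paste0("d", seq_len(nrow(values)))
  cells <- cells %||% paste0("c", seq_len(ncol(values)))
  methods::new("ResponseMatrix", values = values * mask, mask = mask,
               drugIndex = drugs, cellIndex = cells)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("a fully observed rank-1 matrix factorizes to near-zero loss", {
  u <- c(1, -0.5, 2, 0.3, -1.2)
  v <- c(0.8, -0.4, 1.5, 0.6)
  R <- rmFrom(outer(u, v), matrix(1, 5, 4))
  f <- factorizeResponses(R, rank = 1, iters = 3000, lr = 0.05, seed = 2)
  expect_lt(f@objective, 1e-6)
})

test_that("the objective equals an independent entry-wise recomputation", {
  set.seed(5)
  V <- matrix(rnorm(20), 5, 4)
  M <- matrix(rbinom(20, 1, 0.6), 5, 4)
  if (sum(M) == 0) M[1, 1] <- 1
  R <- rmFrom(V, M)
  f <- factorizeResponses(R, rank = 2, iters = 50, seed = 3)
  acc <- 0
  for (i in 1:5) for (j in 1:4) {
    if (M[i, j] == 1) {
      acc <- acc + ((V * M)[i, j] - sum(f@I[, i] * f@J[, j]))^2 / 2
    }
  }
  expect_equal(f@objective, acc, tolerance = 1e-10)
  # factors initialized at the truth give objective zero
  expect_equal(maskedObjective(outer(1:3, 1:2), matrix(1, 3, 2),
                               matrix(1:3, 1), matrix(1:2, 1)), 0)
})

test_that("the objective trace is non-increasing", {
  set.seed(6)
  V <- matrix(rnorm(40), 8, 5)
  M <- matrix(rbinom(40, 1, 0.7), 8, 5)
  f <- factorizeResponses(rmFrom(V, M), rank = 2, iters = 100, seed = 1)
  h <- attr(f, "history")
  expect_true(all(diff(h) <= 1e-12))
})

test_that("held-out entries of a noiseless rank-2 matrix are recovered", {
  set.seed(21)
  A <- matrix(rnorm(20), 2, 10)
  B <- matrix(rnorm(16), 2, 8)
  V <- t(A) %*% B
  M <- matrix(rbinom(80, 1, 0.5), 10, 8)
  M[1, 1] <- 1
  f <- factorizeResponses(rmFrom(V, M), rank = 2, iters = 4000, lr = 0.05,
                          seed = 4)
  pred <- t(f@I) %*% f@J
  held <- M == 0
  expect_gt(sum(held), 0)
  expect_lt(sqrt(mean((pred[held] - V[held])^2)), 0.1)
})

test_that("identical seeds give identical factors", {
  set.seed(7)
  V <- matrix(rnorm(24), 6, 4)
  M <- matrix(1, 6, 4)
  f1 <- factorizeResponses(rmFrom(V, M), rank = 2, iters = 40, seed = 9)
  f2 <- factorizeResponses(rmFrom(V, M), rank = 2, iters = 40, seed = 9)
  expect_identical(f1@I, f2@I)
  expect_identical(f1@J, f2@J)
})

test_that("alternating least squares and the svd variant also fit", {
  set.seed(8)
  V <- outer(rnorm(6), rnorm(5))
  R <- rmFrom(V, matrix(1, 6, 5))
  fa <- factorizeResponses(R, rank = 1, iters = 50, seed = 1,
                           method = "als")
  expect_lt(fa@objective, 1e-6)
  fs <- factorizeResponses(R, rank = 1, seed = 1, method = "svd")
  expect_lt(fs@objective, 1e-6)
})

test_that("an all-zero mask is rejected", {
  expect_error(factorizeResponses(rmFrom(matrix(0, 2, 2),
                                         matrix(0, 2, 2)), rank = 1),
               "no training responses")
})

test_that("full observation at sufficient rank reconstructs the matrix", {
  set.seed(10)
  V <- t(matrix(rnorm(6), 2, 3)) %*% matrix(rnorm(8), 2, 4)
  f <- factorizeResponses(rmFrom(V, matrix(1, 3, 4)), rank = 3,
                          iters = 5000, lr = 0.05, seed = 2)
  rel <- norm(t(f@I) %*% f@J - V, "F") / norm(V, "F")
  expect_lt(rel, 1e-4)
})

test_that("the identity transform returns the transposed factors", {
  set.seed(11)
  V <- matrix(rnorm(12), 4, 3)
  f <- factorizeResponses(rmFrom(V, matrix(1, 4, 3)), rank = 2,
                          iters = 20, seed = 1)
  side <- transformFactors(f, params = NULL)
  expect_equal(side@drugInfo, t(f@I))
  expect_equal(side@cellInfo, t(f@J))
})

test_that("zero transform weights give constant rows", {
  set.seed(12)
  V <- matrix(rnorm(12), 4, 3)
  f <- factorizeResponses(rmFrom(V, matrix(1, 4, 3)), rank = 2,
                          iters = 20, seed = 1)
  p <- sideTransformInit(2, 3)
  p$sdW1 <- p$sdW1 * 0
  p$sdW2 <- p$sdW2 * 0
  p$sdB2 <- matrix(c(1, 2, 3), 1)
  side <- transformFactors(f, p, batchnorm = FALSE)
  for (i in seq_len(nrow(side@drugInfo))) {
    expect_equal(unname(side@drugInfo[i, ]), c(1, 2, 3))
  }
})

test_that("a toy transform matches the hand-computed affine maps", {
  f <- methods::new("SideFactors", I = matrix(c(1, 2, -1, 0.5), 2, 2),
                    J = matrix(c(0.3, -0.6), 2, 1), rank = 2L,
                    objective = 0, drugIndex = c("d1", "d2"),
                    cellIndex = "c1")
  p <- list(sdW1 = matrix(c(1, 0, 0, 1), 2, 2), sdB1 = matrix(c(1, -1), 1),
            sdGamma = c(1, 1), sdBeta = c(0, 0),
            sdW2 = matrix(c(2, 0, 0, 0.5), 2, 2),
            sdB2 = matrix(c(0, 0.25), 1))
  side <- transformFactors(f, p, batchnorm = FALSE, slope = 1)
  # row for d1: x = (1, 2); layer1 = x + (1,-1) = (2, 1); layer2 = (4, .75)
  expect_equal(unname(side@drugInfo[1, ]), c(4, 0.75))
  # row for d2: x = (-1, 0.5) -> (0, -0.5) -> (0, 0)
  expect_equal(unname(side@drugInfo[2, ]), c(0, 0))
})

test_that("cold entities look up zero vectors with a raised flag", {
  set.seed(13)
  V <- matrix(rnorm(12), 4, 3)
  M <- matrix(1, 4, 3)
  M[2, ] <- 0      # drug d2 unobserved
  M[, 3] <- 0      # cell c3 unobserved
  f <- factorizeResponses(rmFrom(V, M), rank = 2, iters = 20, seed = 1)
  side <- transformFactors(f, params = NULL)
  warm <- lookupSideInfo(side, "d1", "c1")
  expect_false(warm$coldDrug || warm$coldCell)
  expect_equal(warm$drug, side@drugInfo[1, ])
  cold <- lookupSideInfo(side, "d2", "c3")
  expect_true(cold$coldDrug && cold$coldCell)
  expect_equal(cold$drug, numeric(2))
  unknown <- lookupSideInfo(side, "dX", "c1")
  expect_true(unknown$coldDrug)
  # a batch with one unseen entity flags exactly one lookup
  flags <- vapply(c("d1", "d3", "dX"), function(d) {
    lookupSideInfo(side, d, "c1")$coldDrug
  }, logical(1))
  expect_equal(sum(flags), 1L)
})

test_that("factors persist as delimited matrices with entity headers", {
  set.seed(14)
  V <- matrix(rnorm(12), 4, 3)
  f <- factorizeResponses(rmFrom(V, matrix(1, 4, 3)), rank = 2,
                          iters = 10, seed = 1)
  dp <- tempfile(fileext = ".csv")
  cp <- tempfile(fileext = ".csv")
  writeSideFactors(f, dp, cp)
  back <- read.csv(dp)
  expect_equal(back$drug_id, f@drugIndex)
  expect_equal(as.matrix(back[, -1]), t(f@I), tolerance = 1e-6,
               ignore_attr = TRUE)
})
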