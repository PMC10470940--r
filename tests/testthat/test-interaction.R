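randomMap <- function(m, n, seed = 1) {
  set.seed(seed)
  methods::new("InteractionMap",
               scores = matrix(runif(m * n, 0.1, 0.9), m, n),
               rowLabels = paste0("f", seq_len(m)),
               colLabels = paste0("s", seq_len(n)))
}

test_that("bilinear scores pass through the logistic function", {
  D <- matrix(0, 2, 3)
  C <- matrix(rnorm(6), 2, 3)
  omega <- matrix(0, 3, 3)
  map <- scoreInteractions(D, C, omega)
  expect_true(all(interactionScores(map) == 0.5))
  # a single pair with logit ln 3 scores 3/4
  d <- matrix(1, 1, 1)
  c1 <- matrix(1, 1, 1)
  expect_equal(interactionScores(
    scoreInteractions(d, c1, matrix(log(3), 1, 1)))[1, 1], 0.75)
})

test_that("scores equal an element-wise hand computation", {
  set.seed(8)
  D <- matrix(rnorm(6), 3, 2)
  C <- matrix(rnorm(4), 2, 2)
  omega <- matrix(rnorm(4), 2, 2)
  map <- scoreInteractions(D, C, omega)
  for (i in 1:3) for (j in 1:2) {
    z <- sum(outer(D[i, ], C[j, ]) * omega)
    expect_equal(map@scores[i, j], 1 / (1 + exp(-z)), tolerance = 1e-12)
  }
})

test_that("padded fragment rows are removed from the map", {
  D <- matrix(rnorm(8), 4, 2)
  C <- matrix(rnorm(4), 2, 2)
  omega <- diag(2)
  map <- scoreInteractions(D, C, omega, padMask = c(1, 1, 0, 0))
  expect_equal(dim(map@scores), c(2, 2))
})

test_that("width mismatches raise shape errors", {
  expect_error(scoreInteractions(matrix(0, 2, 3), matrix(0, 2, 2),
                                 matrix(0, 2, 2)), "shape")
})

test_that("map entries stay strictly inside (0, 1)", {
  D <- matrix(c(100, -100), 2, 1)
  C <- matrix(c(100, -100), 2, 1)
  map <- scoreInteractions(D, C, matrix(1, 1, 1))
  s <- map@scores
  expect_true(all(s > 0 & s < 1))
})

test_that("the bipartite graph has the right shape and attributes", {
  g <- buildInteractionGraph(randomMap(2, 3))
  expect_equal(g$nNodes, 5)
  expect_equal(sum(g$weights[upper.tri(g$weights)] > 0), 6)
  expect_equal(g$X, diag(1, 5, 5))
  expect_equal(g$q, c(4, 4, 3, 3, 3))     # drug nodes see 3, cells see 2
  g1 <- buildInteractionGraph(randomMap(1, 1))
  expect_equal(g1$nNodes, 2)
  expect_equal(g1$weights[1, 2], randomMap(1, 1)@scores[1, 1])
  empty <- methods::new("InteractionMap",
                        scores = matrix(numeric(0), 0, 0),
                        rowLabels = character(0),
                        colLabels = character(0))
  expect_error(buildInteractionGraph(empty), "empty")
})

test_that("a 1x1 graph propagation matches the hand-derived closed form", {
  map <- randomMap(1, 1)
  w <- map@scores[1, 1]
  g <- buildInteractionGraph(map)
  Z <- gcnForward(g, list(diag(2)), slope = 1)   # linear activation
  # q = (2, 2); z_v = z_v / 4 + w z_u / 4
  want <- rbind(c(1 / 4, w / 4), c(w / 4, 1 / 4))
  expect_equal(unname(Z), want, tolerance = 1e-12)
})

test_that("propagation matches a brute-force sum over neighbours", {
  bruteGcn <- function(graph, thetas, slope, norm) {
    Z <- graph$X
    V <- graph$nNodes
    for (th in thetas) {
      P <- matrix(0, V, ncol(th))
      for (v in seq_len(V)) {
        for (u in seq_len(V)) {
          a <- if (u == v) 1 else graph$weights[v, u]
          if (a == 0) next
          den <- graph$q[v] * graph$q[u]
          if (norm == "sqrt") den <- sqrt(den)
          P[v, ] <- P[v, ] + (a / den) * drop(Z[u, ] %*% th)
        }
      }
      Z <- ifelse(P > 0, P, slope * P)
    }
    Z
  }
  for (dims in list(c(2, 3), c(3, 3), c(1, 4))) {
    g <- buildInteractionGraph(randomMap(dims[1], dims[2],
                                         seed = sum(dims)))
    set.seed(11)
    thetas <- list(matrix(rnorm(g$nNodes * 3), g$nNodes, 3),
                   matrix(rnorm(9), 3, 3))
    for (norm in c("product", "sqrt")) {
      got <- gcnForward(g, thetas, slope = 0.01, norm = norm)
      want <- bruteGcn(g, thetas, 0.01, norm)
      expect_equal(unname(got), unname(want), tolerance = 1e-8)
    }
  }
})

test_that("zero layer weights give zero embeddings", {
  g <- buildInteractionGraph(randomMap(2, 2))
  Z <- gcnForward(g, list(matrix(0, 4, 3), matrix(0, 3, 3)))
  expect_true(all(Z == 0))
})

test_that("propagation is equivariant to node relabelling", {
  map <- randomMap(2, 3, seed = 5)
  g <- buildInteractionGraph(map)
  set.seed(2)
  thetas <- list(matrix(rnorm(g$nNodes * 4), g$nNodes, 4),
                 matrix(rnorm(16), 4, 4))
  Z <- gcnForward(g, thetas)
  perm <- c(2, 1, 3, 5, 4)    # swap the two drug nodes and two cell nodes
  g2 <- g
  g2$weights <- g$weights[perm, perm]
  g2$X <- g$X[perm, ]
  g2$degree <- g$degree[perm]
  g2$q <- g$q[perm]
  Z2 <- gcnForward(g2, thetas)
  expect_equal(unname(Z2), unname(Z[perm, ]), tolerance = 1e-10)
  expect_equal(poolEmbeddings(Z2), poolEmbeddings(Z), tolerance = 1e-10)
})

test_that("pooling concatenates column-wise max and mean", {
  Z <- rbind(c(0, 2), c(4, 0))
  expect_equal(poolEmbeddings(Z), c(4, 2, 2, 1))
  z1 <- matrix(c(1.5, -2), 1, 2)
  expect_equal(poolEmbeddings(z1), c(1.5, -2, 1.5, -2))
  expect_equal(poolEmbeddings(Z[2:1, ]), poolEmbeddings(Z))
})

test_that("scaling the bilinear matrix moves scores away from one half", {
  set.seed(3)
  D <- matrix(rnorm(6), 3, 2)
  C <- matrix(rnorm(4), 2, 2)
  omega <- matrix(rnorm(4), 2, 2)
  s1 <- scoreInteractions(D, C, omega)@scores
  s2 <- scoreInteractions(D, C, 2 * omega)@scores
  expect_true(all(abs(s2 - 0.5) >= abs(s1 - 0.5) - 1e-12))
  expect_true(all(sign(s2 - 0.5) == sign(s1 - 0.5)))
})

test_that("permuting drug fragments permutes map rows", {
  set.seed(9)
  D <- matrix(rnorm(8), 4, 2)
  C <- matrix(rnorm(6), 3, 2)
  omega <- matrix(rnorm(4), 2, 2)
  perm <- c(3, 1, 4, 2)
  m1 <- scoreInteractions(D, C, omega)@scores
  m2 <- scoreInteractions(D[perm, ], C, omega)@scores
  expect_equal(m2, m1[perm, ], tolerance = 1e-12)
})

test_that("graph edge lists round-trip through the export", {
  map <- randomMap(2, 3)
  path <- tempfile(fileext = ".csv")
  df <- writeGraphEdges(map, path)
  back <- read.csv(path)
  expect_equal(back$weight, df$weight, tolerance = 1e-12)
  expect_equal(nrow(back), 6)
})
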