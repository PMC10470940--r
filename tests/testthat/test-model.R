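test_that("configuration validation rejects bad settings", {
  expect_error(cdrConfig(huberDelta = 0), "huberDelta")
  expect_error(cdrConfig(lr = -1), "learning rate")
  expect_error(cdrConfig(ablation = "nope"), "nope")
  cfg <- cdrConfig()
  expect_equal(cfg$hidden, 64)
  expect_equal(cfg$gruLayers, 2)
  expect_equal(cfg$lr, 1e-4)
})

test_that("the decoder reduces to closed forms for degenerate weights", {
  p <- list(decW1 = matrix(0, 3, 4), decB1 = matrix(0, 1, 4),
            decW2 = matrix(0, 4, 2), decB2 = matrix(0, 1, 2),
            decW3 = matrix(0, 2, 1), decB3 = matrix(0, 1, 1))
  expect_equal(decodeResponse(c(1, 2, 3), params = p), 0)
  expect_equal(decodeResponse(c(1, 2, 3), params = p,
                              task = "classification"), 0.5)
  expect_error(decodeResponse(c(1, 2), params = p), "shape")
})

test_that("a hand-set linear decoder computes the expected affine value", {
  p <- list(decW1 = matrix(c(1, 0, 0,
                             0, 1, 0), 3, 2), decB1 = matrix(c(1, -1), 1),
            decW2 = matrix(c(2, 0, 0, 1), 2, 2), decB2 = matrix(0, 1, 2),
            decW3 = matrix(c(1, 3), 2, 1), decB3 = matrix(0.5, 1, 1))
  # with slope 1 the rectifiers are identities:
  # u = (h1, h2, h3); a1 = (h1 + 1, h2 - 1); a2 = (2 a11, a12)
  # out = 2 a11 + 3 a12 + 0.5
  h <- c(0.2, -0.7, 9)
  want <- 2 * (h[1] + 1) + 3 * (h[2] - 1) + 0.5
  expect_equal(decodeResponse(h, params = p, slope = 1), want,
               tolerance = 1e-12)
})

test_that("the Huber loss takes its closed-form values", {
  expect_equal(huberLoss(0, 0), 0)
  expect_equal(huberLoss(0.5, 0), 0.125)
  expect_equal(huberLoss(2, 0), 1.5)
  # continuity at |e| = delta: both branches give delta^2 / 2
  d <- 1
  expect_equal(0.5 * d^2, d * d - 0.5 * d^2)
  eps <- 1e-9
  expect_equal(huberLoss(d + eps, 0), huberLoss(d - eps, 0),
               tolerance = 1e-8)
  # batch reduction is the mean
  expect_equal(huberLoss(c(0.5, 2), c(0, 0)), mean(c(0.125, 1.5)))
})

test_that("the Huber gradient magnitude never exceeds delta", {
  e <- seq(-5, 5, by = 0.01)
  g <- huberGrad(e, 0, delta = 1)
  expect_lte(max(abs(g)), 1)
  # quadratic region is linear in the error
  expect_equal(huberGrad(0.3, 0), 0.3)
  expect_equal(huberGrad(-3, 0), -1)
  # the loss is once-differentiable: finite-difference check across the knee
  h <- 1e-6
  num <- (huberLoss(1 + h, 0) - huberLoss(1 - h, 0)) / (2 * h)
  expect_equal(num, huberGrad(1, 0), tolerance = 1e-6)
})

test_that("metrics agree with independent references on toy vectors", {
  set.seed(31)
  truth <- rnorm(40)
  pred <- truth + rnorm(40, sd = 0.5)
  expect_equal(rmse(pred, truth), sqrt(sum((pred - truth)^2) / 40),
               tolerance = 1e-12)
  expect_equal(pcc(pred, truth),
               sum(scale(pred)[, 1] * scale(truth)[, 1]) / 39,
               tolerance = 1e-10)
  expect_equal(rsq(pred, truth),
               1 - sum((truth - pred)^2) / sum((truth - mean(truth))^2),
               tolerance = 1e-12)
  labels <- rbinom(40, 1, 0.4)
  scores <- runif(40)
  skip_if_not_installed("pROC")
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(aucScore(scores, labels), ref, tolerance = 1e-10)
  # average-precision oracle computed pairwise
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  ap <- 0
  for (k in which(lab == 1)) ap <- ap + sum(lab[1:k]) / k
  expect_equal(auprScore(scores, labels), ap / sum(lab),
               tolerance = 1e-10)
})

test_that("metric edge cases behave as documented", {
  expect_equal(rmse(1:4, 1:4), 0)
  expect_equal(pcc(1:4, 1:4), 1)
  expect_equal(rsq(1:4, 1:4), 1)
  expect_equal(pcc(c(-2, -1, 1, 2), c(2, 1, -1, -2)), -1)
  expect_equal(aucScore(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_warning(a <- aucScore(c(0.2, 0.4), c(1, 1)), "single-class")
  expect_true(is.na(a))
})

test_that("analytic gradients match finite differences end to end", {
  w <- tinyWorld()
  inst <- tinyInstances()[seq(1, 20, by = 2), ]
  for (abl in list(character(0), "gated_graph", "no_subcomponents")) {
    cfg <- tinyConfig(ablation = abl)
    corpus <- tinyCorpus()
    factors <- NULL
    if (!("no_side_info" %in% abl)) {
      R <- buildResponseMatrix(inst, corpus$drugIndex, corpus$cellIndex)
      factors <- factorizeResponses(R, rank = 2, iters = 20, seed = 11)
    }
    env <- fragCDR:::.trainEnv(inst, corpus, cfg, factors)
    p0 <- fragCDR:::withSeed(11, fragCDR:::.initParams(cfg, corpus))
    batch <- seq_len(nrow(inst))
    bp <- fragCDR:::.batchPass(p0, batch, env, training = FALSE)
    lossAt <- function(p) {
      fragCDR:::.batchPass(p, batch, env, training = FALSE)$loss /
        length(batch)
    }
    set.seed(42)
    for (probe in 1:12) {
      nm <- sample(names(p0), 1)
      k <- sample(length(p0[[nm]]), 1)
      h <- 1e-5
      pp <- p0; pp[[nm]][k] <- pp[[nm]][k] + h
      pm <- p0; pm[[nm]][k] <- pm[[nm]][k] - h
      num <- (lossAt(pp) - lossAt(pm)) / (2 * h)
      ana <- if (is.null(bp$grads[[nm]])) 0 else bp$grads[[nm]][k]
      expect_lt(abs(num - ana),
                1e-6 + 1e-3 * max(abs(num), abs(ana)),
                label = sprintf("grad %s[%d] (%s)", nm, k,
                                paste(abl, collapse = "+")))
    }
  }
})

test_that("training is bitwise repeatable under one seed", {
  inst <- tinyInstances()[1:12, ]
  cfg <- tinyConfig(epochs = 2, dropout = 0.2)
  m1 <- trainCdrModel(inst, tinyCorpus(), cfg)
  m2 <- trainCdrModel(inst, tinyCorpus(), cfg)
  expect_identical(lossHistory(m1), lossHistory(m2))
  expect_identical(m1@params, m2@params)
  m3 <- trainCdrModel(inst, tinyCorpus(), tinyConfig(epochs = 2,
                                                     dropout = 0.2,
                                                     seed = 6))
  expect_false(identical(lossHistory(m1), lossHistory(m3)))
})

test_that("zero-epoch training returns the seeded initialisation", {
  inst <- tinyInstances()[1:10, ]
  cfg <- tinyConfig(epochs = 0)
  m <- trainCdrModel(inst, tinyCorpus(), cfg)
  expect_length(lossHistory(m), 0)
  want <- fragCDR:::withSeed(cfg$seed, fragCDR:::.initParams(cfg,
                                                             tinyCorpus()))
  expect_identical(m@params, want)
  expect_true(is.finite(predictResponses(m, inst[1, ])))
})

test_that("every ablation variant trains and records finite losses", {
  inst <- tinyInstances()[1:10, ]
  for (abl in list("no_side_info", "no_sequence_encoders", "no_graph",
                   "gated_graph", "no_subcomponents")) {
    m <- trainCdrModel(inst, tinyCorpus(), tinyConfig(ablation = abl))
    expect_length(lossHistory(m), 2)
    expect_true(all(is.finite(lossHistory(m))),
                label = paste(abl, collapse = "+"))
    expect_true(all(is.finite(predictResponses(m, inst))))
  }
})

test_that("the classification head trains on binarized labels", {
  inst <- binarizeResponses(tinyInstances()[1:12, ],
                            threshold = 2.4)
  m <- trainCdrModel(inst, tinyCorpus(),
                     tinyConfig(task = "classification"))
  p <- predictResponses(m, inst)
  expect_true(all(p > 0 & p < 1))
})

test_that("evaluation reports task metrics and per-group breakdowns", {
  m <- tinyModel()
  inst <- tinyInstances()[1:24, ]
  inst$grp <- rep(c("a", "b"), each = 12)
  rep1 <- evaluateModel(m, inst, groupBy = "grp")
  expect_true(all(c("rmse", "pcc", "r2") %in% names(rep1)))
  expect_gte(rep1$rmse, 0)
  expect_named(rep1$byGroup, c("a", "b"))
  # single-class groups are flagged undefined for classification
  instC <- binarizeResponses(inst, threshold = -10)
  suppressWarnings(rep2 <- evaluateModel(m, instC,
                                         task = "classification"))
  expect_true(rep2$undefined)
  p <- tempfile(fileext = ".json")
  writeMetricsJson(rep1, p)
  expect_true(jsonlite::fromJSON(p)$rmse > 0)
})

test_that("prediction rejects entities outside the corpus", {
  m <- tinyModel()
  expect_error(predictResponses(m, data.frame(drug_id = "Dxx",
                                              cell_id = "C001")), "Dxx")
})
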