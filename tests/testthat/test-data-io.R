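# Hand-built toy tables: 3 drugs x 4 cells, 10 unique measured pairs plus
# one duplicated pair, so the full grid has one unmeasured combination.

writeToyTables <- function(dir, extraRow = NULL, breakSchema = FALSE,
                           badNumeric = FALSE) {
  dir.create(dir, showWarnings = FALSE)
  pairs <- expand.grid(drug_id = c("d1", "d2", "d3"),
                       cell_id = c("c1", "c2", "c3", "c4"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[-12, ]                      # one grid cell unmeasured
  pairs$ln_ic50 <- seq(-3, 2, length.out = nrow(pairs))
  dup <- data.frame(drug_id = "d1", cell_id = "c1", ln_ic50 = NA)
  dup$ln_ic50 <- 2.5
  pairs$ln_ic50[pairs$drug_id == "d1" & pairs$cell_id == "c1"] <- 1.0
  resp <- rbind(pairs, dup)
  if (!is.null(extraRow)) resp <- rbind(resp, extraRow)
  if (badNumeric) resp$ln_ic50[3] <- "oops"
  if (breakSchema) names(resp)[3] <- "value"
  write.csv(resp, file.path(dir, "response.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(drug_id = c("d1", "d2", "d3"),
                       smiles = c("CCO", "CCN", "CCOCC")),
            file.path(dir, "smiles.csv"), row.names = FALSE, quote = FALSE)
  expr <- data.frame(cell_id = c("c1", "c2", "c3", "c4"),
                     g1 = rnorm(4), g2 = rnorm(4), g3 = rnorm(4),
                     g4 = rnorm(4), g5 = rnorm(4), g6 = rnorm(4))
  write.csv(expr, file.path(dir, "expression.csv"), row.names = FALSE,
            quote = FALSE)
  write.csv(data.frame(gene = paste0("g", 1:6),
                       category = c("A", "A", "A", "B", "B", "C"),
                       tumour_types = "T1;T2"),
            file.path(dir, "gene_annot.csv"), row.names = FALSE,
            quote = TRUE)
  write.csv(data.frame(cell_id = c("c1", "c2", "c3", "c4"),
                       tumour_type = c("T1", "T1", "T2", "T2")),
            file.path(dir, "cell_annot.csv"), row.names = FALSE,
            quote = FALSE)
  file.path(dir, c("response.csv", "smiles.csv", "expression.csv",
                   "gene_annot.csv", "cell_annot.csv"))
}

loadToy <- function(...) {
  p <- writeToyTables(tempfile("toy"), ...)
  loadTables(p[1], p[2], p[3], p[4], p[5])
}

test_that("duplicated pairs collapse to the highest response", {
  out <- loadToy()
  expect_equal(nrow(out$instances), 11)
  kept <- out$instances$response[out$instances$drug_id == "d1" &
                                   out$instances$cell_id == "c1"]
  expect_equal(kept, 2.5)
  expect_equal(out$report$duplicatesCollapsed, 1)
})

test_that("tables without duplicates keep every row", {
  p <- writeToyTables(tempfile("toy"))
  resp <- read.csv(p[1])
  resp <- resp[!duplicated(paste(resp$drug_id, resp$cell_id)), ]
  write.csv(resp, p[1], row.names = FALSE, quote = FALSE)
  out <- loadTables(p[1], p[2], p[3], p[4], p[5])
  expect_equal(nrow(out$instances), nrow(resp))
  expect_equal(out$report$duplicatesCollapsed, 0)
})

test_that("rows for cells without expression are dropped and reported", {
  out <- loadToy(extraRow = data.frame(drug_id = "d2", cell_id = "c9",
                                       ln_ic50 = 0.1))
  expect_equal(out$report$droppedNoExpression, 1)
  expect_false("c9" %in% out$instances$cell_id)
})

test_that("schema and numeric errors are informative", {
  expect_error(loadToy(breakSchema = TRUE), "ln_ic50")
  expect_error(loadToy(badNumeric = TRUE), "row")
})

test_that("collapsing duplicates is idempotent", {
  out <- loadToy()
  dir2 <- tempfile("toy2")
  dir.create(dir2)
  write.csv(data.frame(drug_id = out$instances$drug_id,
                       cell_id = out$instances$cell_id,
                       ln_ic50 = out$instances$response),
            file.path(dir2, "response.csv"), row.names = FALSE,
            quote = FALSE)
  p <- writeToyTables(tempfile("toy3"))
  out2 <- loadTables(file.path(dir2, "response.csv"), p[2], p[3], p[4],
                     p[5])
  o1 <- out$instances[order(out$instances$drug_id, out$instances$cell_id), ]
  o2 <- out2$instances[order(out2$instances$drug_id,
                             out2$instances$cell_id), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("the response matrix fills values and mask from instances", {
  out <- loadToy()
  R <- buildResponseMatrix(out$instances, c("d1", "d2", "d3"),
                           c("c1", "c2", "c3", "c4"))
  expect_equal(sum(responseMask(R)), 11)
  expect_equal(sum(responseMask(R) == 0), 1)
  expect_true(all(responseValues(R)[responseMask(R) == 0] == 0))
  # masked entries recover exactly the instance responses
  i <- match(out$instances$drug_id, drugIndex(R))
  j <- match(out$instances$cell_id, cellIndex(R))
  expect_equal(responseValues(R)[cbind(i, j)], out$instances$response)
})

test_that("an empty instance list gives an all-zero mask", {
  R <- buildResponseMatrix(data.frame(drug_id = character(0),
                                      cell_id = character(0),
                                      response = numeric(0)),
                           c("d1", "d2"), c("c1", "c2"))
  expect_equal(sum(responseMask(R)), 0)
})

test_that("unknown instance ids are named in the error", {
  expect_error(
    buildResponseMatrix(data.frame(drug_id = "dX", cell_id = "c1",
                                   response = 1), c("d1"), c("c1")),
    "dX")
})

test_that("binarization uses strict inequality at the threshold", {
  inst <- data.frame(drug_id = "d", cell_id = "c",
                     response = c(-2.5, -2.0, 0.3))
  lab <- binarizeResponses(inst)$label
  expect_equal(lab, c(1L, 0L, 0L))
  expect_equal(binarizeResponses(inst, threshold = -Inf)$label,
               c(0L, 0L, 0L))
  # the default threshold corresponds to about 0.135 uM
  expect_equal(round(exp(-2.0), 3), 0.135)
})

test_that("warm folds split instances into near-equal parts", {
  inst <- data.frame(drug_id = rep(paste0("d", 1:10), 10),
                     cell_id = rep(paste0("c", 1:10), each = 10),
                     response = 0)
  fa <- makeFolds(inst, "warm", k = 5, seed = 3)
  sizes <- vapply(folds(fa), function(f) length(f$test), integer(1))
  expect_equal(sizes, rep(20L, 5))
  for (f in folds(fa)) {
    expect_equal(sort(c(f$train, f$test)), 1:100)
  }
})

test_that("cold folds keep their entity out of training", {
  inst <- data.frame(drug_id = rep(paste0("d", 1:10), 4),
                     cell_id = rep(paste0("c", 1:4), each = 10),
                     response = 0)
  for (scen in c("cold_drug", "cold_cell")) {
    k <- if (scen == "cold_drug") 5 else 4
    fa <- makeFolds(inst, scen, k = k, seed = 9)
    col <- if (scen == "cold_drug") "drug_id" else "cell_id"
    for (f in folds(fa)) {
      expect_length(intersect(unique(inst[[col]][f$train]),
                              unique(inst[[col]][f$test])), 0)
      expect_equal(sort(c(f$train, f$test)), seq_len(nrow(inst)))
    }
  }
})

test_that("folds are deterministic given the seed", {
  inst <- tinyInstances()
  a <- makeFolds(inst, "warm", k = 5, seed = 42)
  b <- makeFolds(inst, "warm", k = 5, seed = 42)
  expect_identical(folds(a), folds(b))
  c2 <- makeFolds(inst, "warm", k = 5, seed = 43)
  expect_false(identical(folds(a), folds(c2)))
})

test_that("too few entities for a cold split is an error", {
  inst <- data.frame(drug_id = c("d1", "d2", "d3"),
                     cell_id = c("c1", "c1", "c1"), response = 0)
  expect_error(makeFolds(inst, "cold_drug", k = 5, seed = 1), "folds")
})

test_that("the holdout split is seeded and partitions the data", {
  inst <- tinyInstances()
  sp <- splitHoldout(inst, testFraction = 0.1, seed = 2)
  expect_equal(nrow(sp$test), round(0.1 * nrow(inst)))
  expect_equal(nrow(sp$cv) + nrow(sp$test), nrow(inst))
  sp2 <- splitHoldout(inst, testFraction = 0.1, seed = 2)
  expect_identical(sp$test, sp2$test)
})
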