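# Shared small fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

tinyWorld <- function() {
  memo("tinyWorld", generateWorld(nDrugs = 8, nCells = 6, nGenes = 24,
                                  nSubsets = 3, noiseSd = 0, seed = 7))
}

worldGeneAnnot <- function(world) {
  cat <- world@catalog
  data.frame(gene = cat$genes,
             category = unname(cat$subsetOf[cat$genes]),
             tumour_types = vapply(cat$tumourTypes[cat$genes], paste,
                                   character(1), collapse = ";"),
             stringsAsFactors = FALSE)
}

tinyConfig <- function(...) {
  base <- list(hidden = 4, fpWidth = 32, decoderWidths = c(8, 4),
               rank = 2, epochs = 2, batchSize = 16, lr = 1e-3,
               dropout = 0, mfIters = 30, seed = 5)
  do.call(cdrConfig, utils::modifyList(base, list(...)))
}

tinyCorpus <- function() {
  memo("tinyCorpus", {
    w <- tinyWorld()
    prepareCorpus(w@drugs, w@expression, worldGeneAnnot(w), w@cellTypes,
                  tinyConfig())
  })
}

tinyInstances <- function() {
  memo("tinyInstances", generateResponses(tinyWorld()))
}

# a small trained model shared by interpretation tests
tinyModel <- function() {
  memo("tinyModel", {
    w <- tinyWorld()
    trainCdrModel(tinyInstances()[1:24, ], tinyCorpus(),
                  tinyConfig(epochs = 3))
  })
}

# toy gene catalog with three categories of sizes 3, 2, 1
toyCatalog <- function() {
  buildGeneCatalog(data.frame(
    gene = paste0("g", 1:6),
    category = c("A", "A", "A", "B", "B", "C"),
    tumour_types = c("T1;T2", "T1", "T1;T2", "T2", "T1;T2", "T1"),
    stringsAsFactors = FALSE))
}

toyExpressionRow <- function() {
  stats::setNames(c(1.5, -0.5, 2.0, 0.25, -1.0, 3.0), paste0("g", 1:6))
}
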