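# Reading and validating the five delimited input tables, response-matrix
# assembly, binarization and cross-validation splits.

.requireColumns <- function(df, cols, what) {
  missing <- setdiff(cols, colnames(df))
  if (length(missing)) {
    stop("schema error in ", what, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

.readTable <- function(path, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Load and validate the five input tables
#'
#' Reads the response triples, drug SMILES, expression matrix, gene
#' annotation and cell annotation tables; collapses ambiguous (duplicated)
#' drug-cell pairs keeping the highest log-IC50; collapses drugs that share
#' one SMILES to a single id; and drops response rows whose cell line has no
#' expression profile. A load report with kept/dropped counts is attached.
#'
#' @param responsePath CSV with columns `drug_id,cell_id,ln_ic50`
#' @param smilesPath CSV with columns `drug_id,smiles`
#' @param expressionPath CSV whose first column is the cell id, remaining
#'   columns one gene each
#' @param geneAnnotPath CSV with columns `gene,category,tumour_types`
#'   (tumour types semicolon-separated)
#' @param cellAnnotPath CSV with columns `cell_id,tumour_type`
#' @return list with `instances` (data.frame drug_id, cell_id, response),
#'   `drugs`, `expression` (matrix, cells x genes), `geneAnnot`, `cellAnnot`
#'   and `report`
#' @export
loadTables <- function(responsePath, smilesPath, expressionPath,
                       geneAnnotPath, cellAnnotPath) {
  resp <- .readTable(responsePath, "response")
  .requireColumns(resp, c("drug_id", "cell_id", "ln_ic50"), "response table")
  drugs <- .readTable(smilesPath, "drug")
  .requireColumns(drugs, c("drug_id", "smiles"), "drug table")
  exprTab <- .readTable(expressionPath, "expression")
  if (ncol(exprTab) < 2) {
    stop("schema error in expression table: needs cell id column plus genes",
         call. = FALSE)
  }
  geneAnnot <- .readTable(geneAnnotPath, "gene annotation")
  .requireColumns(geneAnnot, c("gene", "category", "tumour_types"),
                  "gene annotation table")
  cellAnnot <- .readTable(cellAnnotPath, "cell annotation")
  .requireColumns(cellAnnot, c("cell_id", "tumour_type"),
                  "cell annotation table")

  suppressWarnings(val <- as.numeric(resp$ln_ic50))
  bad <- which(!is.finite(val))
  if (length(bad)) {
    stop("unparseable numeric in response table at data row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  resp$ln_ic50 <- val

  report <- list(responseRows = nrow(resp))

  # drugs sharing one compound (identical SMILES) collapse to one id
  canon <- drugs$smiles
  firstId <- tapply(drugs$drug_id, canon, `[`, 1)
  idMap <- stats::setNames(unname(firstId[canon]), drugs$drug_id)
  report$drugsCollapsed <- sum(idMap != names(idMap))
  drugs <- drugs[!duplicated(idMap[drugs$drug_id]), , drop = FALSE]
  drugs$drug_id <- unname(idMap[drugs$drug_id])

  unknownDrug <- !(resp$drug_id %in% names(idMap))
  if (any(unknownDrug)) {
    stop("response rows reference unknown drug id(s): ",
         paste(unique(resp$drug_id[unknownDrug]), collapse = ", "),
         call. = FALSE)
  }
  resp$drug_id <- unname(idMap[resp$drug_id])

  exprMat <- as.matrix(exprTab[, -1, drop = FALSE])
  rownames(exprMat) <- as.character(exprTab[[1]])
  storage.mode(exprMat) <- "double"

  # cells without expression rows are dropped
  hasExpr <- resp$cell_id %in% rownames(exprMat)
  report$droppedNoExpression <- sum(!hasExpr)
  resp <- resp[hasExpr, , drop = FALSE]

  # ambiguous instances: duplicated (drug, cell) pairs keep the max response
  key <- paste(resp$drug_id, resp$cell_id, sep = "\r")
  report$duplicatesCollapsed <- nrow(resp) - length(unique(key))
  ord <- order(key, -resp$ln_ic50)
  resp <- resp[ord, , drop = FALSE]
  resp <- resp[!duplicated(key[ord]), , drop = FALSE]
  rownames(resp) <- NULL

  instances <- data.frame(drug_id = resp$drug_id, cell_id = resp$cell_id,
                          response = resp$ln_ic50,
                          stringsAsFactors = FALSE)
  report$instancesKept <- nrow(instances)

  list(instances = instances, drugs = drugs, expression = exprMat,
       geneAnnot = geneAnnot, cellAnnot = cellAnnot, report = report)
}

#' Assemble the training response matrix
#'
#' @param instances data.frame with `drug_id`, `cell_id`, `response`
#'   (training partition only)
#' @param drugIndex ordered drug id list (matrix rows)
#' @param cellIndex ordered cell id list (matrix columns)
#' @return a [ResponseMatrix-class]
#' @export
buildResponseMatrix <- function(instances, drugIndex, cellIndex) {
  stopIfNot(!anyDuplicated(drugIndex) && !anyDuplicated(cellIndex),
            "index lists must contain no duplicates")
  i <- match(instances$drug_id, drugIndex)
  j <- match(instances$cell_id, cellIndex)
  if (anyNA(i)) {
    stop("instance drug id not in index: ",
         instances$drug_id[which(is.na(i))[1]], call. = FALSE)
  }
  if (anyNA(j)) {
    stop("instance cell id not in index: ",
         instances$cell_id[which(is.na(j))[1]], call. = FALSE)
  }
  values <- matrix(0, length(drugIndex), length(cellIndex))
  mask <- matrix(0, length(drugIndex), length(cellIndex))
  idx <- cbind(i, j)
  values[idx] <- instances$response
  mask[idx] <- 1
  methods::new("ResponseMatrix", values = values, mask = mask,
               drugIndex = as.character(drugIndex),
               cellIndex = as.character(cellIndex))
}

#' Binarize responses into sensitive/resistant labels
#'
#' An instance is sensitive (label 1) iff its log-IC50 lies strictly below
#' the threshold; -2.0 corresponds to an IC50 of about 0.135 uM.
#'
#' @param instances data.frame with a `response` column
#' @param threshold log-IC50 cutoff (default -2.0)
#' @return the instances with an added binary `label` column
#' @export
binarizeResponses <- function(instances, threshold = -2.0) {
  stopIfNot(all(is.finite(instances$response)),
            "responses must be finite")
  instances$label <- as.integer(instances$response < threshold)
  instances
}

#' Construct cross-validation folds for a scenario
#'
#' Warm start shuffles instances into k near-equal parts. Cold starts split
#' the entity set (cell lines or drugs) into k parts, instances following
#' their entity, so fold test sets contain only unseen entities.
#'
#' @param instances data.frame with `drug_id`, `cell_id`
#' @param scenario `"warm"`, `"cold_cell"` or `"cold_drug"`
#' @param k number of folds (default 5)
#' @param seed integer seed; the split is deterministic given the seed
#' @return a [FoldAssignment-class]
#' @export
makeFolds <- function(instances, scenario = c("warm", "cold_cell",
                                              "cold_drug"),
                      k = 5, seed = 1) {
  scenario <- match.arg(scenario)
  stopIfNot(k >= 2, "k must be at least 2")
  n <- nrow(instances)
  foldList <- withSeed(seed, {
    if (scenario == "warm") {
      perm <- sample.int(n)
      grp <- rep(seq_len(k), length.out = n)
      lapply(seq_len(k), function(f) {
        test <- sort(perm[grp == f])
        list(train = setdiff(seq_len(n), test), test = test)
      })
    } else {
      col <- if (scenario == "cold_cell") "cell_id" else "drug_id"
      entities <- unique(instances[[col]])
      if (length(entities) < k) {
        stop("fewer ", if (col == "cell_id") "cell lines" else "drugs",
             " (", length(entities), ") than folds (", k, ")",
             call. = FALSE)
      }
      perm <- sample(entities)
      grp <- rep(seq_len(k), length.out = length(perm))
      lapply(seq_len(k), function(f) {
        test <- which(instances[[col]] %in% perm[grp == f])
        list(train = setdiff(seq_len(n), test), test = test)
      })
    }
  })
  methods::new("FoldAssignment", scenario = scenario, folds = foldList,
               seed = as.integer(seed))
}

#' Seeded random split into cross-validation and independent test sets
#'
#' @param instances instance data.frame
#' @param testFraction fraction held out (default 0.1)
#' @param seed integer seed
#' @return list with `cv` and `test` instance data.frames
#' @export
splitHoldout <- function(instances, testFraction = 0.1, seed = 1) {
  n <- nrow(instances)
  nTest <- round(testFraction * n)
  testIdx <- withSeed(seed, sort(sample.int(n, nTest)))
  list(cv = instances[setdiff(seq_len(n), testIdx), , drop = FALSE],
       test = instances[testIdx, , drop = FALSE])
}
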