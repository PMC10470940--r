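# Central S4 containers.

#' ResponseMatrix: drugs x cell lines training responses with observation mask
#'
#' Holds the known log-IC50 responses of the training partition on a full
#' drug-by-cell grid. Unmeasured combinations store the sentinel 0 with mask
#' 0; consumers must always consult the mask, never the sentinel.
#'
#' @slot values numeric matrix (drugs x cells) of log-IC50 values
#' @slot mask binary matrix of the same shape; 1 = measured
#' @slot drugIndex ordered drug identifiers (rows)
#' @slot cellIndex ordered cell-line identifiers (columns)
#' @export
setClass("ResponseMatrix",
  representation(values = "matrix", mask = "matrix",
                 drugIndex = "character", cellIndex = "character"),
  validity = function(object) {
    msg <- character(0)
    if (!all(dim(object@values) == dim(object@mask)))
      msg <- c(msg, "values and mask must have identical shape")
    if (nrow(object@values) != length(object@drugIndex) ||
        ncol(object@values) != length(object@cellIndex))
      msg <- c(msg, "index lengths must match matrix shape")
    if (anyDuplicated(object@drugIndex) || anyDuplicated(object@cellIndex))
      msg <- c(msg, "index lists must contain no duplicates")
    if (!all(object@mask %in% c(0, 1)))
      msg <- c(msg, "mask must be binary")
    if (any(object@values[object@mask == 0] != 0))
      msg <- c(msg, "unmeasured entries must carry the sentinel 0")
    if (length(msg)) msg else TRUE
  })

#' FoldAssignment: cross-validation folds for one evaluation scenario
#'
#' @slot scenario one of `"warm"`, `"cold_cell"`, `"cold_drug"`
#' @slot folds list of `list(train =, test =)` integer instance indices
#' @slot seed integer seed the split was drawn with
#' @export
setClass("FoldAssignment",
  representation(scenario = "character", folds = "list", seed = "integer"),
  validity = function(object) {
    if (!object@scenario %in% c("warm", "cold_cell", "cold_drug"))
      return("scenario must be warm, cold_cell or cold_drug")
    for (f in object@folds) {
      if (!all(c("train", "test") %in% names(f)))
        return("each fold needs train and test components")
      if (length(intersect(f$train, f$test)) > 0)
        return("train and test must be disjoint")
    }
    TRUE
  })

#' SubcomponentSequence: ordered drug fragments with fingerprint features
#'
#' @slot fragments fragment SMILES in scan order (length m)
#' @slot features numeric matrix `tMax` x `Fd`; rows beyond m are zero padding
#' @slot padMask binary vector of length `tMax`, leading ones mark real
#'   fragments
#' @slot tMax corpus-wide maximum fragment count
#' @export
setClass("SubcomponentSequence",
  representation(fragments = "character", features = "matrix",
                 padMask = "numeric", tMax = "integer"),
  validity = function(object) {
    m <- length(object@fragments)
    if (m > object@tMax) return("more fragments than tMax")
    if (nrow(object@features) != object@tMax)
      return("features must have tMax rows")
    if (length(object@padMask) != object@tMax)
      return("padMask must have length tMax")
    if (!all(object@padMask == c(rep(1, m), rep(0, object@tMax - m))))
      return("padMask must have exactly m leading ones")
    if (m < object@tMax &&
        any(object@features[(m + 1):object@tMax, ] != 0))
      return("padded feature rows must be zero")
    TRUE
  })

#' CellSubsetProfile: masked gene-subset expression vectors of one cell line
#'
#' @slot cellId cell-line identifier
#' @slot subsets numeric matrix n x `tc`; row i is subset i zero-padded to
#'   the widest subset
#' @slot subsetNames the n subset labels
#' @slot maskApplied binary vector over catalog genes (1 = gene relevant to
#'   the cell's tumour type)
#' @export
setClass("CellSubsetProfile",
  representation(cellId = "character", subsets = "matrix",
                 subsetNames = "character", maskApplied = "numeric"),
  validity = function(object) {
    if (nrow(object@subsets) != length(object@subsetNames))
      return("one row per subset required")
    if (!all(object@maskApplied %in% c(0, 1)))
      return("maskApplied must be binary")
    TRUE
  })

#' InteractionMap: sigmoid-scored subcomponent interactions of one instance
#'
#' @slot scores numeric matrix, fragments x gene subsets, entries in (0,1)
#' @slot rowLabels fragment SMILES
#' @slot colLabels gene-subset names
#' @export
setClass("InteractionMap",
  representation(scores = "matrix", rowLabels = "character",
                 colLabels = "character"),
  validity = function(object) {
    if (any(object@scores <= 0) || any(object@scores >= 1))
      return("scores must lie strictly between 0 and 1")
    if (nrow(object@scores) != length(object@rowLabels) ||
        ncol(object@scores) != length(object@colLabels))
      return("label lengths must match score shape")
    TRUE
  })

#' SideFactors: low-rank factors of the masked training response matrix
#'
#' @slot I rank x drugs factor matrix
#' @slot J rank x cells factor matrix
#' @slot rank factorization rank
#' @slot objective final value of the masked least-squares objective
#' @slot drugIndex drug identifiers (columns of I)
#' @slot cellIndex cell identifiers (columns of J)
#' @export
setClass("SideFactors",
  representation(I = "matrix", J = "matrix", rank = "integer",
                 objective = "numeric", drugIndex = "character",
                 cellIndex = "character"),
  validity = function(object) {
    if (nrow(object@I) != object@rank || nrow(object@J) != object@rank)
      return("factor matrices must have `rank` rows")
    if (ncol(object@I) != length(object@drugIndex) ||
        ncol(object@J) != length(object@cellIndex))
      return("factor columns must match entity indices")
    if (object@objective < 0) return("objective must be non-negative")
    TRUE
  })

#' SideInfo: transformed side-information vectors for drugs and cells
#'
#' @slot drugInfo drugs x width matrix; row i belongs to `drugIndex[i]`
#' @slot cellInfo cells x width matrix
#' @slot drugIndex drug identifiers
#' @slot cellIndex cell identifiers
#' @slot drugObserved logical; `TRUE` where the drug had at least one
#'   measured response in the training matrix
#' @slot cellObserved logical counterpart for cell lines
#' @export
setClass("SideInfo",
  representation(drugInfo = "matrix", cellInfo = "matrix",
                 drugIndex = "character", cellIndex = "character",
                 drugObserved = "logical", cellObserved = "logical"),
  validity = function(object) {
    if (nrow(object@drugInfo) != length(object@drugIndex) ||
        nrow(object@cellInfo) != length(object@cellIndex))
      return("rows must match entity indices")
    if (length(object@drugObserved) != length(object@drugIndex) ||
        length(object@cellObserved) != length(object@cellIndex))
      return("observed flags must match entity indices")
    TRUE
  })

#' HeatmapExport: a normalised interaction map ready for plotting
#'
#' @slot normalized softmax-normalised scores; entries sum to 1 over the
#'   chosen axis
#' @slot axis `"map"`, `"row"` or `"column"`
#' @slot rowLabels fragment SMILES
#' @slot colLabels gene-subset names
#' @slot instanceId free-form instance identifier
#' @export
setClass("HeatmapExport",
  representation(normalized = "matrix", axis = "character",
                 rowLabels = "character", colLabels = "character",
                 instanceId = "character"),
  validity = function(object) {
    s <- object@normalized
    tol <- 1e-8
    ok <- switch(object@axis,
      map = abs(sum(s) - 1) < tol,
      row = all(abs(rowSums(s) - 1) < tol),
      column = all(abs(colSums(s) - 1) < tol),
      FALSE)
    if (!ok) return("normalized entries must sum to 1 over the axis")
    TRUE
  })

#' CdrModel: a trained subcomponent-interaction response model
#'
#' @slot params named list of parameter matrices
#' @slot config model configuration list (see [cdrConfig()])
#' @slot corpus precomputed drug sequences / cell profiles and index metadata
#' @slot sideFactors [SideFactors-class] used for side information (may be
#'   empty under the `no_side_info` ablation)
#' @slot sideInfo cached transformed side information
#' @slot history numeric vector of per-epoch training losses
#' @export
setClass("CdrModel",
  representation(params = "list", config = "list", corpus = "list",
                 sideFactors = "ANY", sideInfo = "ANY", history = "numeric"))

#' SyntheticWorld: a fully synthetic study population
#'
#' @slot drugs named character vector, drug id -> SMILES
#' @slot catalog gene catalog (list with genes, subsetOf, tumourTypes)
#' @slot expression cells x genes expression matrix
#' @slot cellTypes named character vector, cell id -> tumour type
#' @slot planted data.frame of planted (fragment, subset, effect) signals
#' @slot noiseSd response noise standard deviation
#' @slot baseline baseline log-IC50
#' @slot seed generator seed
#' @export
setClass("SyntheticWorld",
  representation(drugs = "character", catalog = "list",
                 expression = "matrix", cellTypes = "character",
                 planted = "data.frame", noiseSd = "numeric",
                 baseline = "numeric", seed = "integer"))

setMethod("show", "ResponseMatrix", function(object) {
  cat(sprintf(
    "ResponseMatrix: %d drugs x %d cell lines, %d measured (%.2f%%)\n",
    nrow(object@values), ncol(object@values), sum(object@mask),
    100 * mean(object@mask)))
})

setMethod("show", "FoldAssignment", function(object) {
  cat(sprintf("FoldAssignment: %s scenario, %d folds, seed %d\n",
              object@scenario, length(object@folds), object@seed))
})

setMethod("show", "SubcomponentSequence", function(object) {
  cat(sprintf("SubcomponentSequence: %d fragment(s), padded to %d, F_d = %d\n",
              length(object@fragments), object@tMax, ncol(object@features)))
  cat("  ", paste(object@fragments, collapse = " | "), "\n")
})

setMethod("show", "InteractionMap", function(object) {
  cat(sprintf("InteractionMap: %d fragments x %d subsets\n",
              nrow(object@scores), ncol(object@scores)))
  print(round(object@scores, 3))
})

setMethod("show", "CdrModel", function(object) {
  cat(sprintf(
    "CdrModel: %d drugs x %d cells, F = %d, task = %s, %d epoch(s) trained\n",
    length(object@corpus$drugIndex), length(object@corpus$cellIndex),
    object@config$hidden, object@config$task, length(object@history)))
  if (length(object@config$ablation))
    cat("  ablation:", paste(object@config$ablation, collapse = ", "), "\n")
})

setMethod("show", "SyntheticWorld", function(object) {
  cat(sprintf(
    "SyntheticWorld: %d drugs, %d cells, %d genes in %d subsets, seed %d\n",
    length(object@drugs), nrow(object@expression),
    length(object@catalog$genes), length(unique(object@catalog$subsetOf)),
    object@seed))
})

# ---- accessors ----

#' @describeIn ResponseMatrix-class measured-value matrix
#' @param object a `ResponseMatrix`
#' @export
responseValues <- function(object) object@values

#' @describeIn ResponseMatrix-class observation mask
#' @export
responseMask <- function(object) object@mask

#' @describeIn ResponseMatrix-class drug identifiers
#' @export
drugIndex <- function(object) object@drugIndex

#' @describeIn ResponseMatrix-class cell identifiers
#' @export
cellIndex <- function(object) object@cellIndex

#' @describeIn SubcomponentSequence-class fragment SMILES in scan order
#' @param object a `SubcomponentSequence`
#' @export
fragments <- function(object) object@fragments

#' @describeIn SubcomponentSequence-class padding mask
#' @export
padMask <- function(object) object@padMask

#' @describeIn InteractionMap-class score matrix with labels attached
#' @param object an `InteractionMap`
#' @export
interactionScores <- function(object) {
  s <- object@scores
  dimnames(s) <- list(object@rowLabels, object@colLabels)
  s
}

#' @describeIn FoldAssignment-class list of train/test index pairs
#' @param object a `FoldAssignment`
#' @export
folds <- function(object) object@folds

#' @describeIn CdrModel-class per-epoch training loss history
#' @param object a `CdrModel`
#' @export
lossHistory <- function(object) object@history
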