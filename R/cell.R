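# Cell-line subcomponents: partition of cancer-census genes into disjoint
# category subsets, tumour-type masking, and the convolutional encoder.

#' Build a gene catalog from an annotation table
#'
#' The annotation table is taken as ground truth: each distinct `category`
#' string becomes one subset (overlapping roles are expected to arrive as
#' their own combined category, e.g. `"oncogene,TSG"`), so the subsets are
#' disjoint by construction and their union is the full gene list.
#'
#' @param geneAnnot data.frame with columns `gene`, `category`,
#'   `tumour_types` (semicolon-separated)
#' @return a catalog list: `genes`, `subsetOf` (named character),
#'   `tumourTypes` (named list), `subsets` (labels in first-appearance
#'   order), `typeUniverse`
#' @export
buildGeneCatalog <- function(geneAnnot) {
  stopIfNot(!anyDuplicated(geneAnnot$gene),
            "duplicate gene in annotation table")
  genes <- as.character(geneAnnot$gene)
  subsetOf <- stats::setNames(as.character(geneAnnot$category), genes)
  tumourTypes <- stats::setNames(
    strsplit(as.character(geneAnnot$tumour_types), ";", fixed = TRUE), genes)
  tumourTypes <- lapply(tumourTypes, function(x) trimws(x[nzchar(trimws(x))]))
  list(genes = genes, subsetOf = subsetOf, tumourTypes = tumourTypes,
       subsets = unique(unname(subsetOf)),
       typeUniverse = sort(unique(unlist(tumourTypes))))
}

#' Partition an expression row into disjoint gene-subset vectors
#'
#' @param catalog a catalog from [buildGeneCatalog()]
#' @param expressionRow named numeric vector covering all catalog genes
#' @return named list of n numeric vectors, one per subset, genes in catalog
#'   order
#' @export
partitionGenes <- function(catalog, expressionRow) {
  missing <- setdiff(catalog$genes, names(expressionRow))
  if (length(missing)) {
    stop("gene missing from expression row: ", missing[1], call. = FALSE)
  }
  lapply(stats::setNames(nm = catalog$subsets), function(s) {
    g <- catalog$genes[catalog$subsetOf[catalog$genes] == s]
    expressionRow[g]
  })
}

#' Apply the tumour-type gene mask to an expression row
#'
#' Genes annotated as relevant to the cell's tumour type keep their value;
#' all other catalog genes are zeroed.
#'
#' @param expressionRow named numeric vector over catalog genes
#' @param tumourType the cell line's tumour type
#' @param catalog a catalog from [buildGeneCatalog()]
#' @param unknownType `"strict"` (error on a tumour type absent from the
#'   catalog) or `"lenient"` (all-ones mask)
#' @return the masked expression row, with the binary mask attached as
#'   attribute `"mask"`
#' @export
applyTumourMask <- function(expressionRow, tumourType, catalog,
                            unknownType = c("strict", "lenient")) {
  unknownType <- match.arg(unknownType)
  if (!tumourType %in% catalog$typeUniverse) {
    if (unknownType == "strict") {
      stop("unknown tumour type: ", tumourType, call. = FALSE)
    }
    mask <- stats::setNames(rep(1, length(catalog$genes)), catalog$genes)
  } else {
    mask <- vapply(catalog$tumourTypes[catalog$genes],
                   function(tt) as.numeric(tumourType %in% tt), numeric(1))
    names(mask) <- catalog$genes
  }
  out <- expressionRow
  out[catalog$genes] <- expressionRow[catalog$genes] * mask
  attr(out, "mask") <- mask
  out
}

#' Build the masked, padded subset profile of one cell line
#'
#' @param cellId cell identifier
#' @param expressionRow named numeric vector over catalog genes
#' @param tumourType the cell's tumour type
#' @param catalog a catalog from [buildGeneCatalog()]
#' @param tc pad width; defaults to the catalog's largest subset
#' @param unknownType passed to [applyTumourMask()]
#' @return a [CellSubsetProfile-class]
#' @export
buildCellProfile <- function(cellId, expressionRow, tumourType, catalog,
                             tc = NULL, unknownType = "strict") {
  masked <- applyTumourMask(expressionRow, tumourType, catalog,
                            unknownType = unknownType)
  parts <- partitionGenes(catalog, masked)
  tc <- tc %||% max(vapply(parts, length, integer(1)))
  subs <- t(vapply(parts, function(v) c(unname(v), rep(0, tc - length(v))),
                   numeric(tc)))
  methods::new("CellSubsetProfile", cellId = as.character(cellId),
               subsets = subs, subsetNames = catalog$subsets,
               maskApplied = unname(attr(masked, "mask")))
}

#' Export the gene-to-subset assignment for auditing
#'
#' @param catalog a catalog from [buildGeneCatalog()]
#' @param path output CSV path (`gene,subset_label`)
#' @return the assignment data.frame, invisibly
#' @export
writeSubsetAssignment <- function(catalog, path) {
  df <- data.frame(gene = catalog$genes,
                   subset_label = unname(catalog$subsetOf[catalog$genes]),
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(df)
}

#' Widest-subset pad width of a catalog
#' @param catalog a catalog from [buildGeneCatalog()]
#' @return integer `t_c`
#' @export
subsetPadWidth <- function(catalog) {
  max(table(catalog$subsetOf))
}

#' Initialise cell-encoder parameters
#'
#' @param n number of subsets (convolution channels)
#' @param tc subset pad width
#' @param hidden output width F (must match the drug encoder)
#' @param layers number of convolution layers (default 2)
#' @param kernel kernel size (default 3)
#' @return parameter list for [encodeCell()]
#' @export
cellEncoderInit <- function(n, tc, hidden, layers = 2, kernel = 3) {
  p <- list()
  for (l in seq_len(layers)) {
    p[[paste0("convK", l)]] <- .glorot(n, kernel)
    p[[paste0("convB", l)]] <- matrix(0, n, 1)
  }
  p$projW <- .glorot(tc, hidden)
  p$projB <- matrix(0, 1, hidden)
  p$layers <- layers
  p
}

# internal forward with caches; X = profile matrix (n x tc)
.cellForward <- function(X, p, slope = 0.01, activation = "leaky") {
  caches <- list(X = X)
  A <- X
  for (l in seq_len(p$layers)) {
    pre <- conv1dForward(A, p[[paste0("convK", l)]],
                         drop(p[[paste0("convB", l)]]))
    caches[[paste0("in", l)]] <- A
    caches[[paste0("pre", l)]] <- pre
    A <- if (activation == "leaky") leakyRelu(pre, slope) else pre
  }
  caches$convOut <- A
  out <- if (is.null(p$projW)) A else
    sweep(A %*% p$projW, 2, drop(p$projB), `+`)
  caches$out <- out
  caches
}

.cellBackward <- function(cache, p, dOut, slope = 0.01,
                          activation = "leaky") {
  g <- list()
  if (is.null(p$projW)) {
    dA <- dOut
  } else {
    g$projW <- t(cache$convOut) %*% dOut
    g$projB <- matrix(colSums(dOut), 1)
    dA <- dOut %*% t(p$projW)
  }
  for (l in rev(seq_len(p$layers))) {
    pre <- cache[[paste0("pre", l)]]
    dPre <- if (activation == "leaky") dA * leakyReluGrad(pre, slope) else dA
    cb <- conv1dBackward(cache[[paste0("in", l)]], p[[paste0("convK", l)]],
                         dPre)
    g[[paste0("convK", l)]] <- cb$dK
    g[[paste0("convB", l)]] <- matrix(cb$dBias, ncol = 1)
    dA <- cb$dX
  }
  list(grads = g, dX = dA)
}

#' Encode a cell profile into latent subset features
#'
#' Applies the depthwise 1D convolution stack (kernel per subset channel,
#' stride 1, same padding) followed by a shared linear projection to the
#' common feature width F, so cell subcomponents are dimensionally
#' consistent with drug subcomponents.
#'
#' @param profile a [CellSubsetProfile-class]
#' @param params parameters from [cellEncoderInit()] (set `projW` to `NULL`
#'   to keep the convolution output width)
#' @param activation `"leaky"` (default) or `"linear"`
#' @param slope negative slope of the leaky rectifier
#' @return numeric matrix, n x F
#' @export
encodeCell <- function(profile, params, activation = "leaky", slope = 0.01) {
  X <- profile@subsets
  if (!is.null(params$projW) && ncol(X) != nrow(params$projW)) {
    stop("shape error: profile width ", ncol(X), " does not match encoder (",
         nrow(params$projW), ")", call. = FALSE)
  }
  out <- .cellForward(X, params, slope = slope, activation = activation)$out
  rownames(out) <- profile@subsetNames
  out
}
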