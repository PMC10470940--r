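# Drug subcomponents: fragment sequences, fingerprint features and the
# gated-recurrent sequence encoder.

#' Build the padded subcomponent sequence of a drug
#'
#' Decomposes the SMILES with BRICS, embeds each fragment as a circular
#' fingerprint, and zero-pads the feature sequence at the tail to the
#' corpus-wide maximum fragment count. Drugs with more fragments than
#' `tMax` are truncated tail-first with a warning.
#'
#' @param smiles drug SMILES string
#' @param tMax corpus-wide maximum fragment count; defaults to this drug's
#'   own count
#' @param radius fingerprint radius (default 2)
#' @param width fingerprint width (default 512)
#' @param includeDummies include attachment dummies in fingerprint
#'   environments (default `TRUE`)
#' @return a [SubcomponentSequence-class]
#' @export
buildSubcomponentSequence <- function(smiles, tMax = NULL, radius = 2,
                                      width = 512, includeDummies = TRUE) {
  labelled <- bricsDecompose(smiles, stripLabels = FALSE)
  display <- stripDummyLabels(labelled)
  tMax <- as.integer(tMax %||% length(labelled))
  if (length(labelled) > tMax) {
    warning("drug has ", length(labelled), " fragments; truncating to tMax = ",
            tMax, call. = FALSE)
    labelled <- labelled[seq_len(tMax)]
    display <- display[seq_len(tMax)]
  }
  feats <- embedFragments(labelled, radius = radius, width = width,
                          includeDummies = includeDummies)
  m <- nrow(feats)
  features <- rbind(feats, matrix(0L, tMax - m, width))
  rownames(features) <- NULL
  methods::new("SubcomponentSequence", fragments = display,
               features = features,
               padMask = c(rep(1, m), rep(0, tMax - m)), tMax = tMax)
}

#' Corpus-wide maximum fragment count
#'
#' @param smilesVec character vector of drug SMILES
#' @return the largest BRICS fragment count over the corpus, the pad length
#'   `t_d`
#' @export
maxFragmentCount <- function(smilesVec) {
  max(vapply(smilesVec, function(s) length(bricsDecompose(s)), integer(1)))
}

#' Export the fragment decomposition of a drug set as delimited text
#'
#' One row per fragment: `drug_id,frag_index,fragment_smiles`, in scan
#' order, for inspection and as a test fixture format.
#'
#' @param drugs named character vector, drug id -> SMILES
#' @param path output CSV path
#' @return the cache data.frame, invisibly
#' @export
writeFragmentCache <- function(drugs, path) {
  rows <- lapply(names(drugs), function(d) {
    f <- bricsDecompose(drugs[[d]])
    data.frame(drug_id = d, frag_index = seq_along(f),
               fragment_smiles = f, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Initialise drug-encoder (stacked gated recurrent unit) parameters
#'
#' @param nin input feature width (fingerprint width)
#' @param hidden hidden width F
#' @param layers number of stacked layers (default 2)
#' @return nested parameter list for [encodeDrug()]
#' @export
drugEncoderInit <- function(nin, hidden, layers = 2) {
  lapply(seq_len(layers), function(l) {
    gruInit(if (l == 1) nin else hidden, hidden)
  })
}

# internal: full forward with caches for backprop
.drugForward <- function(features, params) {
  caches <- vector("list", length(params))
  X <- features
  for (l in seq_along(params)) {
    caches[[l]] <- gruForward(X, params[[l]])
    X <- caches[[l]]$H
  }
  caches
}

.drugBackward <- function(caches, params, dH) {
  grads <- vector("list", length(params))
  for (l in rev(seq_along(params))) {
    bk <- gruBackward(caches[[l]], params[[l]], dH)
    grads[[l]] <- bk$grads
    dH <- bk$dX
  }
  list(grads = grads, dX = dH)
}

#' Encode a drug subcomponent sequence
#'
#' Runs the stacked gated recurrent encoder over the padded fingerprint
#' sequence. States at padded positions are returned but must be ignored by
#' downstream consumers via the padding mask (they are produced from
#' all-zero inputs).
#'
#' @param sequence a [SubcomponentSequence-class]
#' @param params parameters from [drugEncoderInit()]
#' @return list with `H` (`tMax` x F hidden-state matrix) and `padMask`
#' @export
encodeDrug <- function(sequence, params) {
  if (ncol(sequence@features) != nrow(params[[1]]$Wr)) {
    stop("shape error: feature width ", ncol(sequence@features),
         " does not match encoder input width ", nrow(params[[1]]$Wr),
         call. = FALSE)
  }
  caches <- .drugForward(sequence@features, params)
  list(H = caches[[length(caches)]]$H, padMask = sequence@padMask)
}
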