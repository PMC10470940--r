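# Full model assembly, end-to-end training and evaluation.
#
# Forward path per instance:
#   drug fragments --GRU--> D_hat   cell subsets --CNN--> C_hat
#   Omega = sigmoid(D_hat omega C_hat^T)      (interaction map)
#   graph conv over the weighted complete bipartite graph, max||mean pooling
#   decoder MLP over [h || side_drug || side_cell]
# Ablation toggles remove or replace individual stages.

.ABLATIONS <- c("no_side_info", "no_sequence_encoders", "no_graph",
                "gated_graph", "no_subcomponents")

#' Model configuration
#'
#' @param hidden latent feature width F shared by both encoders (default 64)
#' @param fpRadius,fpWidth fragment fingerprint radius and width
#' @param gruLayers stacked recurrent layers in the drug encoder (default 2)
#' @param cnnLayers convolution layers in the cell encoder (default 2)
#' @param convKernel convolution kernel size (default 3)
#' @param gcnLayers graph-convolution layers K (default 2)
#' @param gcnNorm `"product"` (`q_v * q_u`, as stated) or `"sqrt"`
#' @param gcnSimplified drop intermediate graph nonlinearities
#' @param leakySlope negative slope of the leaky rectifier
#' @param decoderWidths hidden widths of the 3-layer decoder
#' @param dropout decoder dropout probability (default 0.2)
#' @param weightDecay L2 penalty on weight matrices (biases and
#'   normalisation parameters exempt; default 0)
#' @param huberDelta Huber scale parameter delta (default 1)
#' @param lr Adam learning rate (default 1e-4)
#' @param epochs training epochs (default 100)
#' @param batchSize minibatch size (default 128)
#' @param task `"regression"` or `"classification"`
#' @param ablation character subset of `no_side_info`,
#'   `no_sequence_encoders`, `no_graph`, `gated_graph`, `no_subcomponents`
#' @param rank side-information factorization rank (default 16)
#' @param mfIters,mfLr,mfMethod factorization settings
#' @param sideBatchnorm batch-normalise the side transform
#' @param includeDummies include dummy atoms in fragment fingerprints
#' @param unknownType tumour-mask behaviour for unknown types
#' @param seed master seed for initialisation, shuffling and dropout
#' @return validated configuration list
#' @export
cdrConfig <- function(hidden = 64, fpRadius = 2, fpWidth = 512,
                      gruLayers = 2, cnnLayers = 2, convKernel = 3,
                      gcnLayers = 2, gcnNorm = "product",
                      gcnSimplified = FALSE, leakySlope = 0.01,
                      decoderWidths = c(128, 32), dropout = 0.2,
                      weightDecay = 0,
                      huberDelta = 1, lr = 1e-4, epochs = 100,
                      batchSize = 128, task = c("regression",
                                                "classification"),
                      ablation = character(0), rank = 16, mfIters = 300,
                      mfLr = 1e-3, mfMethod = "gradient",
                      sideBatchnorm = TRUE, includeDummies = TRUE,
                      unknownType = "strict", seed = 1) {
  task <- match.arg(task)
  stopIfNot(huberDelta > 0, "huberDelta must be positive")
  stopIfNot(lr > 0, "learning rate must be positive")
  stopIfNot(gcnLayers >= 1, "gcnLayers must be at least 1")
  bad <- setdiff(ablation, .ABLATIONS)
  if (length(bad)) {
    stop("unknown ablation(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  list(hidden = hidden, fpRadius = fpRadius, fpWidth = fpWidth,
       gruLayers = gruLayers, cnnLayers = cnnLayers,
       convKernel = convKernel, gcnLayers = gcnLayers, gcnNorm = gcnNorm,
       gcnSimplified = gcnSimplified, leakySlope = leakySlope,
       decoderWidths = decoderWidths, dropout = dropout,
       weightDecay = weightDecay,
       huberDelta = huberDelta, lr = lr, epochs = epochs,
       batchSize = batchSize, task = task, ablation = ablation,
       rank = rank, mfIters = mfIters, mfLr = mfLr, mfMethod = mfMethod,
       sideBatchnorm = sideBatchnorm, includeDummies = includeDummies,
       unknownType = unknownType, seed = as.integer(seed))
}

#' Precompute the subcomponent corpus for a set of drugs and cell lines
#'
#' Decomposes and embeds every drug once, builds every cell's masked subset
#' profile, and fixes the corpus-wide pad widths (`t_d`, `t_c`) and the
#' one-hot attribute width shared by all interaction graphs.
#'
#' @param drugs named character vector: drug id -> SMILES
#' @param expression numeric matrix, cells x genes
#' @param geneAnnot gene annotation data.frame (see [buildGeneCatalog()])
#' @param cellTypes named character vector: cell id -> tumour type
#' @param config a [cdrConfig()] list
#' @return corpus list consumed by [trainCdrModel()]
#' @export
prepareCorpus <- function(drugs, expression, geneAnnot, cellTypes,
                          config = cdrConfig()) {
  catalog <- buildGeneCatalog(geneAnnot)
  drugIndex <- names(drugs)
  stopIfNot(!is.null(drugIndex) && !anyDuplicated(drugIndex),
            "drugs must be a uniquely named SMILES vector")
  cellIndex <- rownames(expression)
  cellIndex <- cellIndex[cellIndex %in% names(cellTypes)]
  tMax <- maxFragmentCount(drugs)
  sequences <- lapply(drugs, buildSubcomponentSequence, tMax = tMax,
                      radius = config$fpRadius, width = config$fpWidth,
                      includeDummies = config$includeDummies)
  tc <- as.integer(subsetPadWidth(catalog))
  profiles <- lapply(stats::setNames(nm = cellIndex), function(cid) {
    buildCellProfile(cid, expression[cid, ], cellTypes[[cid]], catalog,
                     tc = tc, unknownType = config$unknownType)
  })
  drugFp <- t(vapply(drugs, function(s) {
    morganFingerprint(parseSmiles(s), radius = config$fpRadius,
                      nBits = config$fpWidth)
  }, integer(config$fpWidth)))
  rownames(drugFp) <- drugIndex
  cellExpr <- t(vapply(cellIndex, function(cid) {
    v <- applyTumourMask(expression[cid, ], cellTypes[[cid]], catalog,
                         unknownType = config$unknownType)
    unname(v[catalog$genes])
  }, numeric(length(catalog$genes))))
  rownames(cellExpr) <- cellIndex
  n <- length(catalog$subsets)
  list(drugIndex = drugIndex, cellIndex = cellIndex, catalog = catalog,
       sequences = sequences, profiles = profiles, tMax = tMax, tc = tc,
       n = n, vMax = tMax + n, drugFp = drugFp, cellExpr = cellExpr,
       nGenes = length(catalog$genes))
}

# decoder input width for a configuration
.decoderInWidth <- function(cfg, corpus) {
  abl <- cfg$ablation
  side <- if ("no_side_info" %in% abl) 0 else 2 * cfg$hidden
  if ("no_subcomponents" %in% abl) {
    return(cfg$fpWidth + corpus$nGenes + side)
  }
  h <- if ("no_graph" %in% abl) corpus$tMax * corpus$n else 2 * cfg$hidden
  h + side
}

.initParams <- function(cfg, corpus) {
  p <- list()
  abl <- cfg$ablation
  useSub <- !("no_subcomponents" %in% abl)
  useSeq <- useSub && !("no_sequence_encoders" %in% abl)
  if (useSeq) {
    gru <- drugEncoderInit(cfg$fpWidth, cfg$hidden, cfg$gruLayers)
    for (l in seq_along(gru)) {
      for (nm in names(gru[[l]])) {
        p[[sprintf("gruL%d_%s", l, nm)]] <- gru[[l]][[nm]]
      }
    }
    cell <- cellEncoderInit(corpus$n, corpus$tc, cfg$hidden,
                            layers = cfg$cnnLayers,
                            kernel = cfg$convKernel)
    for (nm in setdiff(names(cell), "layers")) p[[nm]] <- cell[[nm]]
  }
  if (useSub) {
    dimD <- if (useSeq) cfg$hidden else cfg$fpWidth
    dimC <- if (useSeq) cfg$hidden else corpus$tc
    p$omega <- .glorot(dimD, dimC)
    if ("gated_graph" %in% abl) {
      p$ggIn <- .glorot(corpus$vMax, cfg$hidden)
      for (nm in c("ggWr", "ggUr", "ggWb", "ggUb", "ggWh", "ggUd")) {
        p[[nm]] <- .glorot(cfg$hidden, cfg$hidden)
      }
    } else if (!("no_graph" %in% abl)) {
      for (k in seq_len(cfg$gcnLayers)) {
        p[[paste0("gcnW", k)]] <-
          .glorot(if (k == 1) corpus$vMax else cfg$hidden, cfg$hidden)
      }
    }
  }
  if (!("no_side_info" %in% abl)) {
    st <- sideTransformInit(cfg$rank, cfg$hidden)
    for (nm in names(st)) p[[nm]] <- st[[nm]]
  }
  inW <- .decoderInWidth(cfg, corpus)
  w <- cfg$decoderWidths
  p$decW1 <- .glorot(inW, w[1]); p$decB1 <- matrix(0, 1, w[1])
  p$decW2 <- .glorot(w[1], w[2]); p$decB2 <- matrix(0, 1, w[2])
  p$decW3 <- .glorot(w[2], 1);    p$decB3 <- matrix(0, 1, 1)
  p
}

.gruParams <- function(p, layers) {
  lapply(seq_len(layers), function(l) {
    list(Wr = p[[sprintf("gruL%d_Wr", l)]],
         Wb = p[[sprintf("gruL%d_Wb", l)]],
         Wh = p[[sprintf("gruL%d_Wh", l)]],
         Ur = p[[sprintf("gruL%d_Ur", l)]],
         Ub = p[[sprintf("gruL%d_Ub", l)]],
         Ud = p[[sprintf("gruL%d_Ud", l)]])
  })
}

.cellParams <- function(p, layers) {
  out <- list(layers = layers, projW = p$projW, projB = p$projB)
  for (l in seq_len(layers)) {
    out[[paste0("convK", l)]] <- p[[paste0("convK", l)]]
    out[[paste0("convB", l)]] <- p[[paste0("convB", l)]]
  }
  out
}

.gcnParams <- function(p, layers) {
  lapply(seq_len(layers), function(k) p[[paste0("gcnW", k)]])
}

# ---- decoder -------------------------------------------------------------

.decoderForward <- function(u, p, cfg, training = FALSE) {
  slope <- cfg$leakySlope
  pre1 <- drop(u %*% p$decW1) + drop(p$decB1)
  a1 <- leakyRelu(pre1, slope)
  d1 <- if (training && cfg$dropout > 0) {
    (stats::runif(length(a1)) >= cfg$dropout) / (1 - cfg$dropout)
  } else rep(1, length(a1))
  a1d <- a1 * d1
  pre2 <- drop(a1d %*% p$decW2) + drop(p$decB2)
  a2 <- leakyRelu(pre2, slope)
  d2 <- if (training && cfg$dropout > 0) {
    (stats::runif(length(a2)) >= cfg$dropout) / (1 - cfg$dropout)
  } else rep(1, length(a2))
  a2d <- a2 * d2
  logit <- drop(a2d %*% p$decW3) + drop(p$decB3)
  out <- if (cfg$task == "classification") sigmoid(logit) else logit
  list(out = out, logit = logit, u = u, pre1 = pre1, a1d = a1d, d1 = d1,
       pre2 = pre2, a2d = a2d, d2 = d2)
}

# dLogit: scalar gradient w.r.t. the pre-activation output
.decoderBackward <- function(cache, p, cfg, dLogit) {
  slope <- cfg$leakySlope
  g <- list()
  g$decW3 <- matrix(cache$a2d * dLogit, ncol = 1)
  g$decB3 <- matrix(dLogit, 1, 1)
  dA2d <- drop(p$decW3) * dLogit
  dPre2 <- dA2d * cache$d2 * leakyReluGrad(cache$pre2, slope)
  g$decW2 <- outer(cache$a1d, dPre2)
  g$decB2 <- matrix(dPre2, 1)
  dA1d <- drop(p$decW2 %*% dPre2)
  dPre1 <- dA1d * cache$d1 * leakyReluGrad(cache$pre1, slope)
  g$decW1 <- outer(cache$u, dPre1)
  g$decB1 <- matrix(dPre1, 1)
  list(grads = g, dU = drop(p$decW1 %*% dPre1))
}

#' Decode a graph summary and side information into a response
#'
#' Standalone forward pass of the 3-layer decoder (no dropout); used for
#' prediction and for verifying the decoder arithmetic in isolation.
#'
#' @param h graph summary vector
#' @param drugSide,cellSide side-information vectors (may be zero-length)
#' @param params decoder parameters (`decW1` ... `decB3`)
#' @param task `"regression"` or `"classification"`
#' @param slope leaky-rectifier slope
#' @return predicted response (regression: unbounded; classification: in
#'   (0,1))
#' @export
decodeResponse <- function(h, drugSide = numeric(0), cellSide = numeric(0),
                           params, task = "regression", slope = 0.01) {
  u <- c(h, drugSide, cellSide)
  if (length(u) != nrow(params$decW1)) {
    stop("shape error: decoder expects input width ", nrow(params$decW1),
         ", got ", length(u), call. = FALSE)
  }
  cfg <- list(task = task, dropout = 0, leakySlope = slope)
  .decoderForward(u, params, cfg, training = FALSE)$out
}

# ---- per-instance forward / backward -------------------------------------

# drugEnc/cellEnc: caches produced once per unique entity in the batch.
.instanceForward <- function(di, cj, p, corpus, cfg, drugEnc, cellEnc,
                             sideD, sideC, training = FALSE) {
  abl <- cfg$ablation
  st <- list(di = di, cj = cj)
  if ("no_subcomponents" %in% abl) {
    u <- c(corpus$drugFp[di, ], corpus$cellExpr[cj, ], sideD, sideC)
    st$dec <- .decoderForward(u, p, cfg, training)
    st$out <- st$dec$out
    return(st)
  }
  useSeq <- !("no_sequence_encoders" %in% abl)
  seqD <- corpus$sequences[[di]]
  m <- sum(seqD@padMask)
  D <- if (useSeq) drugEnc[[di]]$H else seqD@features
  C <- if (useSeq) cellEnc[[cj]]$out else corpus$profiles[[cj]]@subsets
  Deff <- D[seq_len(m), , drop = FALSE]
  S <- Deff %*% p$omega %*% t(C)
  # clamp away from {0, 1} so the open-interval invariant survives extreme
  # logits in double precision
  Omega <- pmin(pmax(sigmoid(S), 1e-12), 1 - 1e-12)
  st$m <- m; st$Deff <- Deff; st$C <- C; st$S <- S; st$Omega <- Omega
  if ("no_graph" %in% abl) {
    flat <- matrix(0, corpus$tMax, corpus$n)
    flat[seq_len(m), ] <- Omega
    h <- as.vector(flat)
  } else {
    map <- methods::new("InteractionMap", scores = Omega,
                        rowLabels = seqD@fragments[seq_len(m)],
                        colLabels = corpus$catalog$subsets)
    graph <- buildInteractionGraph(map, attrWidth = corpus$vMax)
    if ("gated_graph" %in% abl) {
      st$gg <- .gatedGraphForward(graph, p, cfg$gcnLayers, cfg$gcnNorm)
      Z <- st$gg$Z
    } else {
      st$gcn <- gcnForward(graph, .gcnParams(p, cfg$gcnLayers),
                           slope = cfg$leakySlope, norm = cfg$gcnNorm,
                           simplified = cfg$gcnSimplified,
                           returnCache = TRUE)
      Z <- st$gcn$Z
    }
    st$Z <- Z
    h <- poolEmbeddings(Z)
  }
  st$h <- h
  u <- c(h, sideD, sideC)
  st$dec <- .decoderForward(u, p, cfg, training)
  st$out <- st$dec$out
  st
}

# Returns flat grads plus gradients routed to shared per-entity caches.
.instanceBackward <- function(st, p, corpus, cfg, dLogit) {
  abl <- cfg$ablation
  dec <- .decoderBackward(st$dec, p, cfg, dLogit)
  g <- dec$grads
  dU <- dec$dU
  sideW <- if ("no_side_info" %in% abl) 0 else cfg$hidden
  out <- list(grads = g)
  if ("no_subcomponents" %in% abl) {
    base <- cfg$fpWidth + corpus$nGenes
    if (sideW > 0) {
      out$dSideD <- dU[base + seq_len(sideW)]
      out$dSideC <- dU[base + sideW + seq_len(sideW)]
    }
    return(out)
  }
  hW <- length(st$h)
  dH <- dU[seq_len(hW)]
  if (sideW > 0) {
    out$dSideD <- dU[hW + seq_len(sideW)]
    out$dSideC <- dU[hW + sideW + seq_len(sideW)]
  }
  m <- st$m
  if ("no_graph" %in% abl) {
    dFlat <- matrix(dH, corpus$tMax, corpus$n)
    dOmega <- dFlat[seq_len(m), , drop = FALSE]
  } else {
    dZ <- .poolBackward(st$Z, dH)
    if ("gated_graph" %in% abl) {
      gb <- .gatedGraphBackward(st$gg, p, dZ)
      out$grads <- .addGrads(out$grads, gb$grads)
      dOmega <- gb$dOmega
    } else {
      gb <- .gcnBackward(st$gcn, .gcnParams(p, cfg$gcnLayers), dZ)
      for (k in seq_along(gb$grads)) {
        out$grads <- .addGrads(out$grads,
                               stats::setNames(gb$grads[k],
                                               paste0("gcnW", k)))
      }
      dOmega <- gb$dOmega
    }
  }
  dS <- dOmega * st$Omega * (1 - st$Omega)
  out$grads$omega <- (out$grads$omega %||% 0) +
    t(st$Deff) %*% dS %*% st$C
  out$dDeff <- dS %*% st$C %*% t(p$omega)
  out$dC <- t(dS) %*% st$Deff %*% p$omega
  out
}

# ---- training ------------------------------------------------------------

# One full forward/backward pass over a batch of instance indices.
# env carries the immutable training context (corpus, cfg, targets, entity
# indices and side factors). Returns the summed loss and accumulated grads.
.batchPass <- function(p, batch, env, training = TRUE) {
  corpus <- env$corpus; cfg <- env$cfg
  useSide <- env$useSide; useSeq <- env$useSeq; useSub <- env$useSub
  nb <- length(batch)
  gruP <- NULL; cellP <- NULL
  drugEnc <- list(); drugCache <- list()
  cellEnc <- list(); cellCache <- list()
  if (useSeq) {
    gruP <- .gruParams(p, cfg$gruLayers)
    cellP <- .cellParams(p, cfg$cnnLayers)
    for (d in unique(env$diId[batch])) {
      drugCache[[d]] <- .drugForward(corpus$sequences[[d]]@features, gruP)
      drugEnc[[d]] <- list(H = drugCache[[d]][[cfg$gruLayers]]$H)
    }
    for (cc in unique(env$cjId[batch])) {
      cellCache[[cc]] <- .cellForward(corpus$profiles[[cc]]@subsets, cellP,
                                      slope = cfg$leakySlope)
      cellEnc[[cc]] <- list(out = cellCache[[cc]]$out)
    }
  }
  if (useSide) {
    sfD <- .sideForward(env$Ifull, p, cfg$leakySlope, cfg$sideBatchnorm)
    sfC <- .sideForward(env$Jfull, p, cfg$leakySlope, cfg$sideBatchnorm)
  }
  grads <- list()
  dDrug <- list(); dCell <- list()
  dSideD <- if (useSide) matrix(0, nrow(env$Ifull), cfg$hidden)
  dSideC <- if (useSide) matrix(0, nrow(env$Jfull), cfg$hidden)
  batchLoss <- 0
  for (ii in batch) {
    di <- env$di[ii]; cj <- env$cj[ii]
    sdv <- if (useSide && env$obsD[di]) sfD$out[di, ] else
      if (useSide) numeric(cfg$hidden) else numeric(0)
    scv <- if (useSide && env$obsC[cj]) sfC$out[cj, ] else
      if (useSide) numeric(cfg$hidden) else numeric(0)
    st <- .instanceForward(env$diId[ii], env$cjId[ii], p, corpus, cfg,
                           drugEnc, cellEnc, sdv, scv,
                           training = training)
    y <- env$target[ii]
    if (cfg$task == "classification") {
      pr <- min(max(st$out, 1e-12), 1 - 1e-12)
      loss <- -(y * log(pr) + (1 - y) * log(1 - pr))
      dLogit <- (st$out - y) / nb
    } else {
      loss <- huberLoss(st$out, y, cfg$huberDelta)
      dLogit <- huberGrad(st$out, y, cfg$huberDelta) / nb
    }
    if (!is.finite(loss)) {
      stop("NaN/Inf loss at instance (", env$diId[ii], ", ", env$cjId[ii],
           ")", call. = FALSE)
    }
    batchLoss <- batchLoss + loss
    bk <- .instanceBackward(st, p, corpus, cfg, dLogit)
    grads <- .addGrads(grads, bk$grads)
    if (useSide) {
      if (env$obsD[di]) dSideD[di, ] <- dSideD[di, ] + bk$dSideD
      if (env$obsC[cj]) dSideC[cj, ] <- dSideC[cj, ] + bk$dSideC
    }
    if (useSub && useSeq && !is.null(bk$dDeff)) {
      d <- env$diId[ii]; cc <- env$cjId[ii]
      buf <- dDrug[[d]] %||% matrix(0, corpus$tMax, cfg$hidden)
      buf[seq_len(st$m), ] <- buf[seq_len(st$m), ] + bk$dDeff
      dDrug[[d]] <- buf
      dCell[[cc]] <- (dCell[[cc]] %||% 0) + bk$dC
    }
  }
  if (useSeq) {
    for (d in names(dDrug)) {
      db <- .drugBackward(drugCache[[d]], gruP, dDrug[[d]])
      for (l in seq_along(db$grads)) {
        nms <- sprintf("gruL%d_%s", l, names(db$grads[[l]]))
        grads <- .addGrads(grads, stats::setNames(db$grads[[l]], nms))
      }
    }
    for (cc in names(dCell)) {
      cb <- .cellBackward(cellCache[[cc]], cellP, dCell[[cc]],
                          slope = cfg$leakySlope)
      grads <- .addGrads(grads, cb$grads)
    }
  }
  if (useSide) {
    grads <- .addGrads(grads, .sideBackward(sfD, p, dSideD, cfg$leakySlope,
                                            cfg$sideBatchnorm))
    grads <- .addGrads(grads, .sideBackward(sfC, p, dSideC, cfg$leakySlope,
                                            cfg$sideBatchnorm))
  }
  list(loss = batchLoss, grads = grads)
}

# Assemble the immutable training context shared by all batches.
.trainEnv <- function(instances, corpus, cfg, factors) {
  useSide <- !("no_side_info" %in% cfg$ablation)
  env <- list(
    corpus = corpus, cfg = cfg,
    useSide = useSide,
    useSeq = !any(c("no_sequence_encoders", "no_subcomponents") %in%
                    cfg$ablation),
    useSub = !("no_subcomponents" %in% cfg$ablation),
    di = match(instances$drug_id, corpus$drugIndex),
    cj = match(instances$cell_id, corpus$cellIndex),
    target = if (cfg$task == "classification") instances$label else
      instances$response)
  if (anyNA(env$di) || anyNA(env$cj)) {
    stop("instance references an entity outside the corpus", call. = FALSE)
  }
  env$diId <- corpus$drugIndex[env$di]
  env$cjId <- corpus$cellIndex[env$cj]
  if (useSide) {
    env$obsD <- attr(factors, "observedDrugs")
    env$obsC <- attr(factors, "observedCells")
    env$Ifull <- t(factors@I)
    env$Jfull <- t(factors@J)
  }
  env
}

#' Train the subcomponent-interaction response model
#'
#' End-to-end seeded optimisation of all stages with Adam: the fragment
#' sequence encoder, subset convolution encoder, bilinear interaction
#' scorer, graph convolution, side-information transform and decoder.
#' Side factors are computed from the supplied (training) instances only.
#'
#' @param instances training data.frame with `drug_id`, `cell_id`,
#'   `response` and, for classification, `label`
#' @param corpus from [prepareCorpus()]
#' @param config a [cdrConfig()] list
#' @return a [CdrModel-class] with the per-epoch loss history
#' @export
trainCdrModel <- function(instances, corpus, config = cdrConfig()) {
  stopIfNot(nrow(instances) > 0, "empty training set")
  cfg <- config
  useSide <- !("no_side_info" %in% cfg$ablation)
  if (cfg$task == "classification") {
    stopIfNot(!is.null(instances$label), "classification needs labels")
  }

  factors <- NULL
  if (useSide) {
    R <- buildResponseMatrix(instances, corpus$drugIndex, corpus$cellIndex)
    factors <- factorizeResponses(R, rank = cfg$rank, iters = cfg$mfIters,
                                  lr = cfg$mfLr, seed = cfg$seed,
                                  method = cfg$mfMethod)
  }
  env <- .trainEnv(instances, corpus, cfg, factors)
  nInst <- nrow(instances)
  history <- numeric(0)

  params <- withSeed(cfg$seed, {
    p <- .initParams(cfg, corpus)
    state <- adamInit(p)
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample.int(nInst)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batchSize))
      epochLoss <- 0
      for (batch in batches) {
        bp <- .batchPass(p, batch, env, training = TRUE)
        if (cfg$weightDecay > 0) {
          for (nm in names(p)) {
            if (grepl("B[0-9]$|Gamma$|Beta$|convB", nm)) next
            bp$grads[[nm]] <- (bp$grads[[nm]] %||% 0) +
              cfg$weightDecay * p[[nm]]
          }
        }
        upd <- adamStep(p, bp$grads, state, cfg$lr)
        p <- upd$params
        state <- upd$state
        epochLoss <- epochLoss + bp$loss
      }
      history <- c(history, epochLoss / nInst)
    }
    p
  })

  sideInfo <- NULL
  if (useSide) {
    stP <- params[c("sdW1", "sdB1", "sdGamma", "sdBeta", "sdW2", "sdB2")]
    sideInfo <- transformFactors(factors, stP,
                                 batchnorm = cfg$sideBatchnorm,
                                 slope = cfg$leakySlope)
  }
  methods::new("CdrModel", params = params, config = cfg, corpus = corpus,
               sideFactors = factors, sideInfo = sideInfo,
               history = history)
}

# side vectors for prediction (cold entities get zeros)
.sideVectors <- function(model, drugId, cellId) {
  if (is.null(model@sideInfo)) {
    return(list(drug = numeric(0), cell = numeric(0)))
  }
  lookupSideInfo(model@sideInfo, drugId, cellId)
}

#' Predict responses for drug-cell pairs
#'
#' @param model a trained [CdrModel-class]
#' @param pairs data.frame with `drug_id` and `cell_id` columns; entities
#'   must exist in the model corpus (entities unseen by the training
#'   response matrix fall back to zero side information)
#' @return numeric vector of predicted responses
#' @export
predictResponses <- function(model, pairs) {
  p <- model@params
  cfg <- model@config
  corpus <- model@corpus
  useSeq <- !any(c("no_sequence_encoders", "no_subcomponents") %in%
                   cfg$ablation)
  drugEnc <- list(); cellEnc <- list()
  if (useSeq) {
    gruP <- .gruParams(p, cfg$gruLayers)
    cellP <- .cellParams(p, cfg$cnnLayers)
    for (d in unique(pairs$drug_id)) {
      if (!d %in% corpus$drugIndex) {
        stop("unknown drug id: ", d, call. = FALSE)
      }
      fw <- .drugForward(corpus$sequences[[d]]@features, gruP)
      drugEnc[[d]] <- list(H = fw[[cfg$gruLayers]]$H)
    }
    for (cc in unique(pairs$cell_id)) {
      if (!cc %in% corpus$cellIndex) {
        stop("unknown cell id: ", cc, call. = FALSE)
      }
      cellEnc[[cc]] <-
        list(out = .cellForward(corpus$profiles[[cc]]@subsets, cellP,
                                slope = cfg$leakySlope)$out)
    }
  }
  vapply(seq_len(nrow(pairs)), function(k) {
    sv <- .sideVectors(model, pairs$drug_id[k], pairs$cell_id[k])
    .instanceForward(pairs$drug_id[k], pairs$cell_id[k], p, corpus, cfg,
                     drugEnc, cellEnc, sv$drug, sv$cell,
                     training = FALSE)$out
  }, numeric(1))
}

#' Interaction map of one drug-cell instance under a trained model
#'
#' @param model a trained [CdrModel-class]
#' @param drugId,cellId entity identifiers present in the model corpus
#' @return an [InteractionMap-class] with fragment/subset labels
#' @export
interactionMapFor <- function(model, drugId, cellId) {
  p <- model@params
  cfg <- model@config
  corpus <- model@corpus
  if ("no_subcomponents" %in% cfg$ablation) {
    stop("the no_subcomponents ablation has no interaction map",
         call. = FALSE)
  }
  seqD <- corpus$sequences[[drugId]]
  if (is.null(seqD)) stop("unknown drug id: ", drugId, call. = FALSE)
  prof <- corpus$profiles[[cellId]]
  if (is.null(prof)) stop("unknown cell id: ", cellId, call. = FALSE)
  useSeq <- !("no_sequence_encoders" %in% cfg$ablation)
  if (useSeq) {
    D <- .drugForward(seqD@features,
                      .gruParams(p, cfg$gruLayers))[[cfg$gruLayers]]$H
    C <- .cellForward(prof@subsets, .cellParams(p, cfg$cnnLayers),
                      slope = cfg$leakySlope)$out
  } else {
    D <- seqD@features
    C <- prof@subsets
  }
  scoreInteractions(D, C, p$omega, padMask = seqD@padMask,
                    rowLabels = seqD@fragments,
                    colLabels = corpus$catalog$subsets)
}

#' Evaluate a trained model on a set of instances
#'
#' @param model a trained [CdrModel-class]
#' @param instances data.frame with `drug_id`, `cell_id`, `response` and
#'   (for classification) `label`
#' @param task `"regression"` or `"classification"`; defaults to the
#'   model's task
#' @param groupBy optional column of `instances` for per-group breakdowns
#' @return a metrics report list; regression reports `rmse`, `pcc`, `r2`,
#'   classification `auc` and `aupr` (flagged undefined for single-class
#'   groups)
#' @export
evaluateModel <- function(model, instances, task = NULL, groupBy = NULL) {
  task <- task %||% model@config$task
  preds <- predictResponses(model, instances)
  one <- function(pred, truth, labels) {
    if (task == "classification") {
      auc <- suppressWarnings(aucScore(pred, labels))
      list(auc = auc,
           aupr = suppressWarnings(auprScore(pred, labels)),
           undefined = is.na(auc), n = length(pred))
    } else {
      list(rmse = rmse(pred, truth), pcc = pcc(pred, truth),
           r2 = rsq(pred, truth), n = length(pred))
    }
  }
  report <- one(preds, instances$response, instances$label)
  report$predictions <- preds
  if (!is.null(groupBy)) {
    groups <- split(seq_len(nrow(instances)), instances[[groupBy]])
    report$byGroup <- lapply(groups, function(idx) {
      one(preds[idx], instances$response[idx], instances$label[idx])
    })
  }
  report
}

#' Write a metrics report as JSON
#'
#' @param report list from [evaluateModel()]
#' @param path output path
#' @return the path, invisibly
#' @export
writeMetricsJson <- function(report, path) {
  report$predictions <- NULL
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
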