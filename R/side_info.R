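# Side information: low-rank factorization of the masked training response
# matrix and its fully-connected transform.

#' Masked factorization objective
#'
#' `0.5 * || M * (R - t(I) %*% J) ||_F^2`, summed over observed entries
#' only.
#'
#' @param R response value matrix (drugs x cells)
#' @param M binary observation mask
#' @param I rank x drugs factor
#' @param J rank x cells factor
#' @return the objective value
#' @export
maskedObjective <- function(R, M, I, J) {
  E <- M * (R - t(I) %*% J)
  0.5 * sum(E^2)
}

#' Factorize the masked response matrix into low-rank side factors
#'
#' Minimises the masked least-squares objective by seeded gradient descent
#' with backtracking step acceptance (so the objective history is
#' non-increasing), or by alternating least squares. A zero-imputed
#' truncated singular-value decomposition is available as a third, closed
#' form variant.
#'
#' @param R a [ResponseMatrix-class]
#' @param rank factorization rank (default 16)
#' @param iters maximum iterations (default 500)
#' @param lr initial gradient step size (default 1e-3)
#' @param seed seed for the factor initialisation
#' @param method `"gradient"` (default), `"als"` or `"svd"`
#' @param tol stop when the relative objective decrease falls below this
#' @param init optional starting factors: a `list(I, J)` or `"svd"` to warm
#'   start from the zero-imputed truncated decomposition (default: seeded
#'   random)
#' @return a [SideFactors-class]; attribute `"history"` carries the
#'   objective trace
#' @export
factorizeResponses <- function(R, rank = 16, iters = 500, lr = 1e-3,
                               seed = 1, method = c("gradient", "als",
                                                    "svd"),
                               tol = 1e-10, init = NULL) {
  method <- match.arg(method)
  stopIfNot(rank >= 1, "rank must be at least 1")
  V <- R@values
  M <- R@mask
  if (sum(M) == 0) stop("no training responses (all-zero mask)",
                        call. = FALSE)
  nd <- nrow(V); nc <- ncol(V)
  if (identical(init, "svd")) {
    sv <- svd(V * M, nu = rank, nv = rank)
    d <- sqrt(sv$d[seq_len(rank)])
    init <- list(I = t(sv$u %*% diag(d, rank)),
                 J = diag(d, rank) %*% t(sv$v))
  }
  if (is.null(init)) {
    sdInit <- sqrt(stats::sd(V[M == 1]) / rank + 1e-8)
    init <- withSeed(seed, list(
      I = matrix(stats::rnorm(rank * nd, sd = sdInit), rank, nd),
      J = matrix(stats::rnorm(rank * nc, sd = sdInit), rank, nc)))
  }
  I <- init$I; J <- init$J

  if (method == "svd") {
    sv <- svd(V * M, nu = rank, nv = rank)
    d <- sqrt(sv$d[seq_len(rank)])
    I <- t(sv$u %*% diag(d, rank))
    J <- diag(d, rank) %*% t(sv$v)
    history <- maskedObjective(V, M, I, J)
  } else if (method == "als") {
    history <- maskedObjective(V, M, I, J)
    for (it in seq_len(iters)) {
      for (i in seq_len(nd)) {
        obs <- which(M[i, ] == 1)
        if (!length(obs)) next
        Jo <- J[, obs, drop = FALSE]
        I[, i] <- solve(Jo %*% t(Jo) + 1e-8 * diag(rank),
                        Jo %*% V[i, obs])
      }
      for (j in seq_len(nc)) {
        obs <- which(M[, j] == 1)
        if (!length(obs)) next
        Io <- I[, obs, drop = FALSE]
        J[, j] <- solve(Io %*% t(Io) + 1e-8 * diag(rank),
                        Io %*% V[obs, j])
      }
      history <- c(history, maskedObjective(V, M, I, J))
      n <- length(history)
      if (history[n - 1] - history[n] < tol * max(1, history[n - 1])) break
    }
  } else {
    obj <- maskedObjective(V, M, I, J)
    history <- obj
    step <- lr
    for (it in seq_len(iters)) {
      E <- M * (t(I) %*% J - V)
      gI <- J %*% t(E)
      gJ <- I %*% E
      accepted <- FALSE
      for (half in 1:30) {
        I2 <- I - step * gI
        J2 <- J - step * gJ
        obj2 <- maskedObjective(V, M, I2, J2)
        if (obj2 <= obj) { accepted <- TRUE; break }
        step <- step / 2
      }
      if (!accepted) break
      I <- I2; J <- J2; obj <- obj2
      history <- c(history, obj)
      step <- step * 1.2
      n <- length(history)
      if (history[n - 1] - history[n] < tol * max(1, history[n - 1])) break
    }
  }
  out <- methods::new("SideFactors", I = I, J = J, rank = as.integer(rank),
                      objective = maskedObjective(V, M, I, J),
                      drugIndex = R@drugIndex, cellIndex = R@cellIndex)
  attr(out, "history") <- history
  attr(out, "observedDrugs") <- rowSums(M) > 0
  attr(out, "observedCells") <- colSums(M) > 0
  out
}

#' Initialise the side-information transform
#'
#' A two-layer fully-connected network with column-wise batch
#' normalisation, shared between drug and cell factors.
#'
#' @param rank factor rank (input width)
#' @param width output width
#' @return parameter list for [transformFactors()]
#' @export
sideTransformInit <- function(rank, width) {
  list(sdW1 = .glorot(rank, width), sdB1 = matrix(0, 1, width),
       sdGamma = rep(1, width), sdBeta = rep(0, width),
       sdW2 = .glorot(width, width), sdB2 = matrix(0, 1, width))
}

# internal forward with caches; X = entities x rank
.sideForward <- function(X, p, slope = 0.01, batchnorm = TRUE) {
  pre1 <- sweep(X %*% p$sdW1, 2, drop(p$sdB1), `+`)
  if (batchnorm) {
    bn <- batchnormForward(pre1, p$sdGamma, p$sdBeta)
    a1 <- leakyRelu(bn$Y, slope)
  } else {
    bn <- NULL
    a1 <- leakyRelu(pre1, slope)
  }
  out <- sweep(a1 %*% p$sdW2, 2, drop(p$sdB2), `+`)
  list(out = out, X = X, pre1 = pre1, bn = bn, a1 = a1)
}

.sideBackward <- function(cache, p, dOut, slope = 0.01, batchnorm = TRUE) {
  g <- list()
  g$sdW2 <- t(cache$a1) %*% dOut
  g$sdB2 <- matrix(colSums(dOut), 1)
  dA1 <- dOut %*% t(p$sdW2)
  if (batchnorm) {
    dBnY <- dA1 * leakyReluGrad(cache$bn$Y, slope)
    bb <- batchnormBackward(cache$bn, p$sdGamma, dBnY)
    g$sdGamma <- bb$dGamma
    g$sdBeta <- bb$dBeta
    dPre1 <- bb$dX
  } else {
    dPre1 <- dA1 * leakyReluGrad(cache$pre1, slope)
  }
  g$sdW1 <- t(cache$X) %*% dPre1
  g$sdB1 <- matrix(colSums(dPre1), 1)
  g
}

#' Transform side factors into side-information vectors
#'
#' @param factors a [SideFactors-class]
#' @param params parameters from [sideTransformInit()]; pass `NULL` for the
#'   identity transform (then the output width equals the rank)
#' @param batchnorm apply column-wise batch normalisation per entity set
#' @param slope leaky-rectifier slope
#' @return a [SideInfo-class]
#' @export
transformFactors <- function(factors, params = NULL, batchnorm = TRUE,
                             slope = 0.01) {
  Id <- t(factors@I)
  Jc <- t(factors@J)
  if (is.null(params)) {
    drugInfo <- Id
    cellInfo <- Jc
  } else {
    drugInfo <- .sideForward(Id, params, slope, batchnorm)$out
    cellInfo <- .sideForward(Jc, params, slope, batchnorm)$out
  }
  obsD <- attr(factors, "observedDrugs") %||%
    rep(TRUE, length(factors@drugIndex))
  obsC <- attr(factors, "observedCells") %||%
    rep(TRUE, length(factors@cellIndex))
  methods::new("SideInfo", drugInfo = drugInfo, cellInfo = cellInfo,
               drugIndex = factors@drugIndex, cellIndex = factors@cellIndex,
               drugObserved = unname(obsD), cellObserved = unname(obsC))
}

#' Look up side information for one drug-cell pair
#'
#' Entities absent from the training response matrix (cold start) receive a
#' zero vector and a raised flag.
#'
#' @param side a [SideInfo-class]
#' @param drugId,cellId entity identifiers
#' @return list with `drug`, `cell` vectors and logical `coldDrug`,
#'   `coldCell` flags
#' @export
lookupSideInfo <- function(side, drugId, cellId) {
  w <- ncol(side@drugInfo)
  i <- match(drugId, side@drugIndex)
  j <- match(cellId, side@cellIndex)
  coldDrug <- is.na(i) || !side@drugObserved[i]
  coldCell <- is.na(j) || !side@cellObserved[j]
  list(drug = if (coldDrug) numeric(w) else side@drugInfo[i, ],
       cell = if (coldCell) numeric(w) else side@cellInfo[j, ],
       coldDrug = coldDrug, coldCell = coldCell)
}

#' Persist side factors as delimited matrices with entity headers
#'
#' @param factors a [SideFactors-class]
#' @param drugPath,cellPath output CSV paths
#' @return invisibly, the two file paths
#' @export
writeSideFactors <- function(factors, drugPath, cellPath) {
  di <- as.data.frame(t(factors@I))
  colnames(di) <- paste0("f", seq_len(factors@rank))
  utils::write.csv(cbind(drug_id = factors@drugIndex, di), drugPath,
                   row.names = FALSE, quote = FALSE)
  ci <- as.data.frame(t(factors@J))
  colnames(ci) <- paste0("f", seq_len(factors@rank))
  utils::write.csv(cbind(cell_id = factors@cellIndex, ci), cellPath,
                   row.names = FALSE, quote = FALSE)
  invisible(c(drugPath, cellPath))
}
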