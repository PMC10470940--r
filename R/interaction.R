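# Subcomponent interactions: bilinear scoring into the interaction map, the
# weighted complete bipartite graph, graph convolutions and global pooling.

#' Score all drug-by-cell subcomponent pairs
#'
#' Computes `Omega[i, j] = sigmoid(d_i %*% omega %*% c_j)` for every real
#' (unpadded) drug fragment i and cell subset j.
#'
#' @param drugH drug subcomponent features (`tMax` x Fd matrix or the list
#'   returned by [encodeDrug()])
#' @param cellH cell subcomponent features (n x Fc)
#' @param omega trainable bilinear matrix (Fd x Fc)
#' @param padMask binary vector marking real fragment rows of `drugH`;
#'   defaults to all ones
#' @param rowLabels,colLabels optional subcomponent labels
#' @return an [InteractionMap-class]
#' @export
scoreInteractions <- function(drugH, cellH, omega, padMask = NULL,
                              rowLabels = NULL, colLabels = NULL) {
  if (is.list(drugH)) {
    padMask <- padMask %||% drugH$padMask
    drugH <- drugH$H
  }
  padMask <- padMask %||% rep(1, nrow(drugH))
  if (ncol(drugH) != nrow(omega) || ncol(cellH) != ncol(omega)) {
    stop("shape error: omega must be ", ncol(drugH), " x ", ncol(cellH),
         call. = FALSE)
  }
  keep <- which(padMask > 0)
  scores <- sigmoid(drugH[keep, , drop = FALSE] %*% omega %*% t(cellH))
  scores <- pmin(pmax(scores, 1e-12), 1 - 1e-12)
  methods::new("InteractionMap", scores = scores,
               rowLabels = as.character(rowLabels %||%
                                          paste0("frag", keep)),
               colLabels = as.character(colLabels %||%
                                          rownames(cellH) %||%
                                          paste0("subset", seq_len(nrow(cellH)))))
}

#' Lift an interaction map to a weighted complete bipartite graph
#'
#' Drug-fragment nodes come first, then cell-subset nodes. Every
#' fragment-subset pair is connected; the edge weight is its interaction
#' score. Node attributes are one-hot identity vectors, zero-padded to
#' `attrWidth` so parameter shapes can be shared across instances.
#'
#' @param map an [InteractionMap-class]
#' @param attrWidth one-hot attribute width (default: number of nodes)
#' @return list with `nNodes`, `m`, `n`, `weights` (adjacency matrix),
#'   `X` (node attributes), `degree` and `q` (1 + degree)
#' @export
buildInteractionGraph <- function(map, attrWidth = NULL) {
  m <- nrow(map@scores)
  n <- ncol(map@scores)
  if (m == 0 || n == 0) stop("empty interaction map", call. = FALSE)
  V <- m + n
  attrWidth <- attrWidth %||% V
  stopIfNot(attrWidth >= V, "attrWidth smaller than node count")
  W <- matrix(0, V, V)
  W[seq_len(m), m + seq_len(n)] <- map@scores
  W[m + seq_len(n), seq_len(m)] <- t(map@scores)
  X <- diag(1, V, attrWidth)
  degree <- c(rep(n, m), rep(m, n))
  list(nNodes = V, m = m, n = n, weights = W, X = X,
       degree = degree, q = 1 + degree)
}

# Normalised propagation operator of the graph convolution:
# Ahat[v,u] = a_vu / (q_v q_u) for edges, 1 / q_v^2 on the diagonal
# (square-root reading optional).
.gcnOperator <- function(graph, norm = c("product", "sqrt")) {
  norm <- match.arg(norm)
  denom <- outer(graph$q, graph$q)
  if (norm == "sqrt") denom <- sqrt(denom)
  A <- graph$weights + diag(graph$nNodes)
  A / denom
}

#' Graph-convolution forward pass over an interaction graph
#'
#' Each layer propagates `z_v <- act(sum_u a_vu / (q_v q_u) * Theta z_u)`
#' over neighbours plus a unit self-loop, with `q_v = 1 + |N(v)|` and a
#' leaky-rectifier activation. The simplified variant drops the
#' intermediate nonlinearities and keeps only the final one.
#'
#' @param graph from [buildInteractionGraph()]
#' @param params list of layer weight matrices `W` (input-major: the first
#'   maps attribute width to F)
#' @param slope leaky-rectifier negative slope
#' @param norm `"product"` for `q_v * q_u` (as stated) or `"sqrt"`
#' @param simplified drop intermediate nonlinearities
#' @param returnCache keep intermediates for the backward pass
#' @return node embedding matrix `Z` (nodes x F), or a cache list when
#'   `returnCache = TRUE`
#' @export
gcnForward <- function(graph, params, slope = 0.01, norm = "product",
                       simplified = FALSE, returnCache = FALSE) {
  K <- length(params)
  stopIfNot(K >= 1, "at least one graph-convolution layer required")
  Ahat <- .gcnOperator(graph, norm)
  Z <- graph$X
  pre <- vector("list", K)
  zs <- vector("list", K + 1)
  zs[[1]] <- Z
  for (k in seq_len(K)) {
    P <- Ahat %*% Z %*% params[[k]]
    pre[[k]] <- P
    Z <- if (simplified && k < K) P else leakyRelu(P, slope)
    zs[[k + 1]] <- Z
  }
  if (returnCache) {
    list(Z = Z, pre = pre, zs = zs, Ahat = Ahat, graph = graph,
         slope = slope, norm = norm, simplified = simplified)
  } else {
    Z
  }
}

# Backward: returns layer-weight grads and the gradient w.r.t. the
# interaction map entries (through the propagation operator).
.gcnBackward <- function(cache, params, dZ) {
  K <- length(params)
  Ahat <- cache$Ahat
  dAhat <- matrix(0, nrow(Ahat), ncol(Ahat))
  grads <- vector("list", K)
  for (k in rev(seq_len(K))) {
    act <- !(cache$simplified && k < K)
    dP <- if (act) dZ * leakyReluGrad(cache$pre[[k]], cache$slope) else dZ
    B <- Ahat %*% cache$zs[[k]]
    grads[[k]] <- t(B) %*% dP
    dB <- dP %*% t(params[[k]])
    dAhat <- dAhat + dB %*% t(cache$zs[[k]])
    dZ <- t(Ahat) %*% dB
  }
  g <- cache$graph
  denom <- outer(g$q, g$q)
  if (cache$norm == "sqrt") denom <- sqrt(denom)
  dW <- dAhat / denom
  i <- seq_len(g$m)
  j <- g$m + seq_len(g$n)
  dOmega <- dW[i, j, drop = FALSE] + t(dW[j, i, drop = FALSE])
  list(grads = grads, dOmega = dOmega)
}

#' Pool node embeddings into a fixed-width graph summary
#'
#' Concatenates the column-wise maximum and mean over all nodes.
#'
#' @param Z node embedding matrix (nodes x F)
#' @return numeric vector of width 2F
#' @export
poolEmbeddings <- function(Z) {
  stopIfNot(nrow(Z) >= 1, "cannot pool an empty embedding matrix")
  c(apply(Z, 2, max), colMeans(Z))
}

.poolBackward <- function(Z, dh) {
  F <- ncol(Z)
  dZ <- matrix(0, nrow(Z), F)
  amax <- max.col(t(Z), ties.method = "first")
  dZ[cbind(amax, seq_len(F))] <- dh[seq_len(F)]
  dZ + matrix(dh[F + seq_len(F)] / nrow(Z), nrow(Z), F, byrow = TRUE)
}

# ---- gated graph layer (ablation variant) --------------------------------
# Message passing with the same normalised weighted sum, but the node update
# is a gated recurrent cell instead of a linear map + activation.

.gatedGraphForward <- function(graph, p, K, norm = "product") {
  Ahat <- .gcnOperator(graph, norm)
  Z <- graph$X %*% p$ggIn           # project one-hot attributes to F
  steps <- vector("list", K)
  for (k in seq_len(K)) {
    M <- Ahat %*% Z
    r <- sigmoid(M %*% p$ggWr + Z %*% p$ggUr)
    b <- sigmoid(M %*% p$ggWb + Z %*% p$ggUb)
    o <- tanh(M %*% p$ggWh + (r * Z) %*% p$ggUd)
    Znew <- b * Z + (1 - b) * o
    steps[[k]] <- list(Z = Z, M = M, r = r, b = b, o = o)
    Z <- Znew
  }
  list(Z = Z, steps = steps, Ahat = Ahat, graph = graph, norm = norm)
}

.gatedGraphBackward <- function(cache, p, dZ) {
  g <- list(ggIn = matrix(0, nrow(p$ggIn), ncol(p$ggIn)))
  for (nm in c("ggWr", "ggUr", "ggWb", "ggUb", "ggWh", "ggUd")) {
    g[[nm]] <- matrix(0, nrow(p[[nm]]), ncol(p[[nm]]))
  }
  Ahat <- cache$Ahat
  dAhat <- matrix(0, nrow(Ahat), ncol(Ahat))
  for (k in rev(seq_along(cache$steps))) {
    s <- cache$steps[[k]]
    do <- dZ * (1 - s$b)
    db <- dZ * (s$Z - s$o)
    dZprev <- dZ * s$b
    dao <- do * (1 - s$o^2)
    g$ggWh <- g$ggWh + t(s$M) %*% dao
    dRZ <- dao %*% t(p$ggUd)
    g$ggUd <- g$ggUd + t(s$r * s$Z) %*% dao
    dr <- dRZ * s$Z
    dZprev <- dZprev + dRZ * s$r
    dar <- dr * s$r * (1 - s$r)
    dab <- db * s$b * (1 - s$b)
    g$ggWr <- g$ggWr + t(s$M) %*% dar
    g$ggWb <- g$ggWb + t(s$M) %*% dab
    g$ggUr <- g$ggUr + t(s$Z) %*% dar
    g$ggUb <- g$ggUb + t(s$Z) %*% dab
    dZprev <- dZprev + dar %*% t(p$ggUr) + dab %*% t(p$ggUb)
    dM <- dar %*% t(p$ggWr) + dab %*% t(p$ggWb) + dao %*% t(p$ggWh)
    dAhat <- dAhat + dM %*% t(s$Z)
    dZprev <- dZprev + t(Ahat) %*% dM
    dZ <- dZprev
  }
  g$ggIn <- t(cache$graph$X) %*% dZ
  gr <- cache$graph
  denom <- outer(gr$q, gr$q)
  if (cache$norm == "sqrt") denom <- sqrt(denom)
  dW <- dAhat / denom
  i <- seq_len(gr$m)
  j <- gr$m + seq_len(gr$n)
  list(grads = g,
       dOmega = dW[i, j, drop = FALSE] + t(dW[j, i, drop = FALSE]))
}

#' Export the edge list of an interaction graph
#'
#' @param map an [InteractionMap-class]
#' @param path output path for a delimited edge list
#'   (`drug_frag_idx,cell_subset_idx,weight`)
#' @return the edge list data.frame, invisibly
#' @export
writeGraphEdges <- function(map, path) {
  s <- map@scores
  df <- data.frame(
    drug_frag_idx = rep(seq_len(nrow(s)), ncol(s)),
    cell_subset_idx = rep(seq_len(ncol(s)), each = nrow(s)),
    weight = as.vector(s))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
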