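# Circular (Morgan/ECFP-style) fingerprints for fragments.
#
# Each atom starts from an invariant built from its element, heavy-atom
# degree, hydrogen count, formal charge, ring membership and aromaticity.
# Identifiers are refined over `radius` rounds by hashing the atom's current
# identifier together with its (bond order, neighbour identifier) pairs in a
# canonical order; identifiers of all radii are folded into a fixed-width
# binary vector.

#' Circular fingerprint of a molecular graph
#'
#' @param mol molecular graph from [parseSmiles()]
#' @param radius neighbourhood radius (default 2, i.e. ECFP4-like)
#' @param nBits fingerprint width (default 512)
#' @param includeDummies if `FALSE`, dummy (attachment) atoms contribute no
#'   environments of their own, though they still appear as neighbours
#' @return binary integer vector of length `nBits`
#' @examples
#' sum(morganFingerprint(parseSmiles("c1ccccc1")))
#' @export
morganFingerprint <- function(mol, radius = 2, nBits = 512,
                              includeDummies = TRUE) {
  atoms <- mol$atoms
  bonds <- mol$bonds
  na <- nrow(atoms)
  nbr <- vector("list", na)
  if (nrow(bonds) > 0) {
    for (r in seq_len(nrow(bonds))) {
      a <- bonds$a[r]; b <- bonds$b[r]
      o <- bonds$order[r]
      if (atoms$aromatic[a] && atoms$aromatic[b] && bonds$inRing[r]) o <- 4L
      nbr[[a]] <- rbind(nbr[[a]], c(o, b))
      nbr[[b]] <- rbind(nbr[[b]], c(o, a))
    }
  }
  degree <- vapply(nbr, function(x) if (is.null(x)) 0L else nrow(x),
                   integer(1))
  ids <- vapply(seq_len(na), function(i) {
    hashIntVec(c(atoms$z[i], degree[i], atoms$nH[i], atoms$charge[i],
                 as.integer(atoms$inRing[i]), as.integer(atoms$aromatic[i])))
  }, integer(1))
  emit <- if (includeDummies) seq_len(na) else which(atoms$z != 0)
  allIds <- ids[emit]
  if (radius > 0) {
    for (k in seq_len(radius)) {
      newIds <- ids
      for (i in seq_len(na)) {
        if (is.null(nbr[[i]])) next
        env <- nbr[[i]]
        env[, 2] <- ids[env[, 2]]
        env <- env[order(env[, 1], env[, 2]), , drop = FALSE]
        newIds[i] <- hashIntVec(c(k, ids[i], t(env)))
      }
      ids <- newIds
      allIds <- c(allIds, ids[emit])
    }
  }
  fp <- integer(nBits)
  fp[(unique(allIds) %% nBits) + 1L] <- 1L
  fp
}

#' Embed fragment SMILES as fingerprint feature vectors
#'
#' One binary circular-fingerprint row per fragment. Identical fragment
#' strings always give identical rows; parsed fragments are cached within the
#' call.
#'
#' @param fragments character vector of fragment SMILES (dummy atoms allowed)
#' @param radius fingerprint radius (default 2)
#' @param width fingerprint width (default 512)
#' @param includeDummies passed to [morganFingerprint()]
#' @return integer matrix, `length(fragments)` x `width`, rows named by
#'   fragment
#' @examples
#' embedFragments(c("*C(C)=O", "*O*"))[, 1:8]
#' @export
embedFragments <- function(fragments, radius = 2, width = 512,
                           includeDummies = TRUE) {
  stopIfNot(length(fragments) > 0, "no fragments given")
  uniq <- unique(fragments)
  rows <- lapply(uniq, function(f) {
    mol <- tryCatch(parseSmiles(f), error = function(e) {
      stop("fragment failed sanitization: '", f, "'", call. = FALSE)
    })
    morganFingerprint(mol, radius = radius, nBits = width,
                      includeDummies = includeDummies)
  })
  names(rows) <- uniq
  out <- do.call(rbind, rows[fragments])
  rownames(out) <- fragments
  out
}
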