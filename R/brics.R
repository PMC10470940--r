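# BRICS molecular fragmentation: retrosynthetically interesting bonds are
# located by matching the 16 published chemical-environment classes around
# each bond, the matched bonds are broken simultaneously, and each fragment
# keeps a dummy atom ('*') at every cleavage site.

# Chemical environments; the first atom of each SMARTS is the attachment atom.
.BRICS_ENV <- c(
  L1  = "[C;D3]([#0,#6,#7,#8])(=O)",
  L3  = "[O;D2]-;!@[#0,#6,#1]",
  L4  = "[C;!D1;!$(C=*)]-;!@[#6]",
  L5  = "[N;!D1;!$(N=*);!$(N-[!#6;!#16;!#0;!#1]);!$([N;R]@[C;R]=O)]",
  L6  = "[C;D3;!R](=O)-;!@[#0,#6,#7,#8]",
  L7  = "[C;D2,D3]-[#6]",
  L8  = "[C;!R;!D1;!$(C!-*)]",
  L9  = "[n;+0;$(n(:[c,n,o,s]):[c,n,o,s])]",
  L10 = "[N;R;$(N(@C(=O))@[C,N,O,S])]",
  L11 = "[S;D2](-;!@[#0,#6])",
  L12 = "[S;D4]([#6,#0])(=O)(=O)",
  L13 = "[C;$(C(-;@[C,N,O,S])-;@[N,O,S])]",
  L14 = "[c;$(c(:[c,n,o,s]):[n,o,s])]",
  L15 = "[C;$(C(-;@C)-;@C)]",
  L16 = "[c;$(c(:c):c)]")

# Allowed environment pairs; bonds between L7 atoms are double, all others
# single and acyclic.
.BRICS_PAIRS <- matrix(c(
  1, 3,  1, 5,  1, 10,
  3, 4,  3, 13, 3, 14, 3, 15, 3, 16,
  4, 5,  4, 11,
  5, 12, 5, 14, 5, 16, 5, 13, 5, 15,
  6, 13, 6, 14, 6, 15, 6, 16,
  7, 7,
  8, 9,  8, 10, 8, 13, 8, 14, 8, 15, 8, 16,
  9, 13, 9, 14, 9, 15, 9, 16,
  10, 13, 10, 14, 10, 15, 10, 16,
  11, 13, 11, 14, 11, 15, 11, 16,
  13, 14, 13, 15, 13, 16,
  14, 14, 14, 15, 14, 16,
  15, 16,
  16, 16), ncol = 2, byrow = TRUE)

#' Locate BRICS-cleavable bonds in a molecule
#'
#' @param mol a molecular graph from [parseSmiles()]
#' @return data.frame with one row per cleavable bond: atom indices `a`, `b`
#'   and their environment labels `la`, `lb` (`a` matches environment `la`)
#' @examples
#' bricsBonds(parseSmiles("CC(=O)Oc1ccccc1C(=O)O"))
#' @export
bricsBonds <- function(mol) {
  bonds <- mol$bonds
  empty <- data.frame(a = integer(0), b = integer(0),
                      la = integer(0), lb = integer(0))
  if (nrow(bonds) == 0) return(empty)
  envAtoms <- .withObMol(mol$sdf, function(obmol) {
    lapply(.BRICS_ENV, function(s) .smartsAtoms(obmol, s))
  })
  hits <- list()
  for (k in seq_len(nrow(.BRICS_PAIRS))) {
    i <- .BRICS_PAIRS[k, 1]
    j <- .BRICS_PAIRS[k, 2]
    wantOrder <- if (i == 7 && j == 7) 2L else 1L
    Ai <- envAtoms[[paste0("L", i)]]
    Aj <- envAtoms[[paste0("L", j)]]
    if (length(Ai) == 0 || length(Aj) == 0) next
    for (r in seq_len(nrow(bonds))) {
      if (bonds$order[r] != wantOrder || bonds$inRing[r]) next
      a <- bonds$a[r]
      b <- bonds$b[r]
      key <- paste(min(a, b), max(a, b))
      if (!is.null(hits[[key]])) next
      if (a %in% Ai && b %in% Aj) hits[[key]] <- c(a, b, i, j)
      else if (b %in% Ai && a %in% Aj) hits[[key]] <- c(b, a, i, j)
    }
  }
  if (length(hits) == 0) return(empty)
  m <- do.call(rbind, unname(hits))
  data.frame(a = m[, 1], b = m[, 2], la = m[, 3], lb = m[, 4])
}

#' Decompose a drug SMILES into an ordered fragment sequence
#'
#' Breaks every BRICS-cleavable bond simultaneously and returns the resulting
#' fragments as SMILES strings. Cleavage sites carry dummy atoms; with
#' `stripLabels = TRUE` (the default) link labels such as `[1*]` are reduced
#' to a bare `*`. Fragments are ordered by the position of their first atom
#' in the input SMILES left-to-right scan. A molecule with no cleavable bond
#' is returned as a single fragment.
#'
#' @param smiles a single SMILES string
#' @param stripLabels drop BRICS link labels from the dummy atoms
#' @return character vector of fragment SMILES, in scan order
#' @examples
#' bricsDecompose("CC(=O)Oc1ccccc1C(=O)O")   # four fragments
#' bricsDecompose("c1ccccc1")                # nothing to cleave
#' @export
bricsDecompose <- function(smiles, stripLabels = TRUE) {
  mol <- parseSmiles(smiles)
  cuts <- bricsBonds(mol)
  if (nrow(cuts) == 0) {
    frag <- canonicalSmiles(mol)
    return(if (stripLabels) stripDummyLabels(frag) else frag)
  }
  bonds <- mol$bonds
  cutKey <- paste(pmin(cuts$a, cuts$b), pmax(cuts$a, cuts$b))
  bondKey <- paste(pmin(bonds$a, bonds$b), pmax(bonds$a, bonds$b))
  keep <- bonds[!(bondKey %in% cutKey), , drop = FALSE]

  # connected components of the cut molecule give the fragments
  g <- igraph::make_empty_graph(n = nrow(mol$atoms), directed = FALSE)
  if (nrow(keep) > 0) {
    g <- igraph::add_edges(g, t(as.matrix(keep[, c("a", "b")])))
  }
  comp <- igraph::components(g)$membership

  frags <- character(max(comp))
  ord <- integer(max(comp))
  for (ci in seq_len(max(comp))) {
    members <- which(comp == ci)
    ord[ci] <- min(members)
    atoms <- mol$atoms[members, , drop = FALSE]
    idx <- match(seq_len(nrow(mol$atoms)), members)  # old -> new index
    fb <- keep[keep$a %in% members & keep$b %in% members, , drop = FALSE]
    fb$a <- idx[fb$a]
    fb$b <- idx[fb$b]
    # add one labelled dummy per severed bond incident to this fragment
    for (r in seq_len(nrow(cuts))) {
      for (side in c("a", "b")) {
        at <- cuts[[side]][r]
        if (!(at %in% members)) next
        lab <- cuts[[if (side == "a") "la" else "lb"]][r]
        atoms <- rbind(atoms, data.frame(
          elem = "*", z = 0, aromatic = FALSE, inRing = FALSE, nH = 0L,
          charge = 0L, label = lab))
        cutOrder <- if (cuts$la[r] == 7 && cuts$lb[r] == 7) 2L else 1L
        fb <- rbind(fb, data.frame(a = idx[at], b = nrow(atoms),
                                   order = cutOrder, inRing = FALSE))
      }
    }
    frags[ci] <- canonicalSmiles(list(atoms = atoms, bonds = fb))
  }
  frags <- frags[order(ord)]
  if (stripLabels) stripDummyLabels(frags) else frags
}
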