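# Molecule handling on top of OpenBabel (via ChemmineOB): SMILES parsing into
# an internal molecular graph, SMARTS perception, and canonical SMILES output.
#
# The internal graph representation is a plain list:
#   atoms: data.frame(elem, z, aromatic, inRing, nH, charge, label)
#          `label` is the BRICS link label on dummy atoms (0 = unlabelled)
#   bonds: data.frame(a, b, order, inRing)   order 1/2/3; aromatic bonds keep
#          their Kekule order but both endpoints carry aromatic = TRUE
#   smiles: the input SMILES string

.obNamespace <- function() getNamespace("ChemmineOB")

# Element symbol -> atomic number for the organic subset plus halogens; dummy
# atoms ('*') are 0. Enough for drug-like molecules used here.
.ELEMENTS <- c("*" = 0, H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
               P = 15, S = 16, Cl = 17, Br = 35, I = 53)

#' @noRd
.smilesToSdf <- function(smiles, name = "mol") {
  out <- tryCatch(
    ChemmineOB::convertFormat("SMI", "SDF", paste0(smiles, "\t", name, "\n")),
    error = function(e) "")
  if (!nzchar(out) || !grepl("V2000", out, fixed = TRUE)) {
    stop("unparseable SMILES: '", smiles, "'", call. = FALSE)
  }
  out
}

# Minimal V2000 molblock reader. Kept in-package because fragment molblocks
# must round-trip dummy atoms with isotope labels (M ISO) and formal charges
# (M CHG), which the available SDF containers do not preserve.
#' @noRd
.parseMolblock <- function(sdf) {
  lines <- strsplit(sdf, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  atomLines <- lines[seq_len(na) + 4L]
  elem <- trimws(substr(atomLines, 32, 34))
  atoms <- data.frame(
    elem = elem,
    z = unname(.ELEMENTS[elem]),
    aromatic = FALSE, inRing = FALSE,
    nH = 0L, charge = 0L, label = 0L,
    stringsAsFactors = FALSE)
  if (anyNA(atoms$z)) {
    stop("unsupported element(s): ",
         paste(unique(elem[is.na(atoms$z)]), collapse = ", "), call. = FALSE)
  }
  if (nb > 0) {
    bondLines <- lines[seq_len(nb) + 4L + na]
    bonds <- data.frame(
      a = as.integer(substr(bondLines, 1, 3)),
      b = as.integer(substr(bondLines, 4, 6)),
      order = as.integer(substr(bondLines, 7, 9)),
      inRing = FALSE)
  } else {
    bonds <- data.frame(a = integer(0), b = integer(0), order = integer(0),
                        inRing = logical(0))
  }
  for (ln in grep("^M  (CHG|ISO)", lines, value = TRUE)) {
    n <- as.integer(substr(ln, 7, 9))
    for (k in seq_len(n)) {
      at <- as.integer(substr(ln, 10 + (k - 1) * 8, 13 + (k - 1) * 8))
      val <- as.integer(substr(ln, 14 + (k - 1) * 8, 17 + (k - 1) * 8))
      if (startsWith(ln, "M  CHG")) atoms$charge[at] <- val
      else atoms$label[at] <- val
    }
  }
  list(atoms = atoms, bonds = bonds)
}

# Run `f(obmol)` on the single molecule contained in an SDF string.
#' @noRd
.withObMol <- function(sdf, f) {
  res <- NULL
  ChemmineOB::forEachMol("SDF", sdf, function(mol) res <<- f(mol))
  res
}

# All SMARTS matches as a list of atom-index vectors (pattern order).
#' @noRd
.smartsMatches <- function(obmol, smarts) {
  ns <- .obNamespace()
  sp <- ns$OBSmartsPattern()
  if (!ns$OBSmartsPattern_Init(sp, smarts)) {
    stop("invalid SMARTS pattern: ", smarts, call. = FALSE)
  }
  ns$OBSmartsPattern_Match(sp, obmol)
  ns$OBSmartsPattern_GetMapList(sp)
}

# First-atom (attachment) indices of all matches of `smarts`.
#' @noRd
.smartsAtoms <- function(obmol, smarts) {
  m <- .smartsMatches(obmol, smarts)
  if (length(m) == 0) return(integer(0))
  unique(vapply(m, `[`, integer(1), 1L))
}

#' Parse a SMILES string into a molecular graph
#'
#' Converts a SMILES string through OpenBabel and annotates each atom with
#' aromaticity, ring membership and total hydrogen count (perceived via SMARTS
#' queries), plus formal charge and any isotope label carried by dummy atoms.
#'
#' @param smiles a single SMILES string
#' @return an internal molecular-graph list with elements `atoms`, `bonds`,
#'   and `smiles`; atom order follows the left-to-right SMILES scan
#' @examples
#' mol <- parseSmiles("CCO")
#' nrow(mol$atoms)
#' @export
parseSmiles <- function(smiles) {
  stopIfNot(is.character(smiles) && length(smiles) == 1,
            "'smiles' must be a single string")
  sdf <- .smilesToSdf(smiles)
  g <- .parseMolblock(sdf)
  percept <- .withObMol(sdf, function(mol) {
    list(aromatic = .smartsAtoms(mol, "[a]"),
         ring = .smartsAtoms(mol, "[R]"),
         h = lapply(0:4, function(k) {
           .smartsAtoms(mol, sprintf("[*;H%d]", k))
         }))
  })
  g$atoms$aromatic[percept$aromatic] <- TRUE
  g$atoms$inRing[percept$ring] <- TRUE
  for (k in 0:4) g$atoms$nH[percept$h[[k + 1L]]] <- k
  if (nrow(g$bonds) > 0) {
    g$bonds$inRing <- g$atoms$inRing[g$bonds$a] & g$atoms$inRing[g$bonds$b] &
      .bondInRing(g$atoms, g$bonds)
  }
  g$smiles <- smiles
  g$sdf <- sdf
  g
}

# A bond is in a ring iff its endpoints remain connected after removing it.
#' @noRd
.bondInRing <- function(atoms, bonds) {
  if (nrow(bonds) == 0) return(logical(0))
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a", "b")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < nrow(atoms)) {
    g <- igraph::add_vertices(g, nrow(atoms) - igraph::vcount(g))
  }
  vapply(seq_len(nrow(bonds)), function(i) {
    g2 <- igraph::delete_edges(g, i)
    is.finite(igraph::distances(g2, v = bonds$a[i], to = bonds$b[i])[1, 1])
  }, logical(1))
}

# Write a molecular graph (or an atom subset of one) as a V2000 molblock.
# `keepAtoms` selects atoms; dummies/labels/charges are taken from the graph.
#' @noRd
.writeMolblock <- function(atoms, bonds, name = "frag") {
  na <- nrow(atoms)
  nb <- nrow(bonds)
  atomLine <- function(i) {
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            (i - 1) %% 10, (i - 1) %/% 10, 0, atoms$elem[i])
  }
  lines <- c(name, " fragCDR 2D", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb),
             vapply(seq_len(na), atomLine, character(1)))
  if (nb > 0) {
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0",
                              bonds$a, bonds$b, bonds$order))
  }
  chg <- which(atoms$charge != 0)
  for (i in chg) {
    lines <- c(lines, sprintf("M  CHG%3d%4d%4d", 1L, i, atoms$charge[i]))
  }
  iso <- which(atoms$label != 0)
  for (i in iso) {
    lines <- c(lines, sprintf("M  ISO%3d%4d%4d", 1L, i, atoms$label[i]))
  }
  paste(c(lines, "M  END", "$$$$", ""), collapse = "\n")
}

#' Canonical SMILES of a molecular graph or SMILES string
#'
#' Canonicalisation is delegated to OpenBabel so that two different
#' spellings of the same structure compare equal.
#'
#' @param x a SMILES string or a graph returned by [parseSmiles()]
#' @return a canonical SMILES string
#' @examples
#' canonicalSmiles("OCC") == canonicalSmiles("CCO")
#' @export
canonicalSmiles <- function(x) {
  sdf <- if (is.character(x)) .smilesToSdf(x) else
    .writeMolblock(x$atoms, x$bonds)
  out <- ChemmineOB::convertFormat("SDF", "CAN", sdf)
  sub("\t.*$", "", strsplit(out, "\n", fixed = TRUE)[[1]][1])
}

#' Strip BRICS dummy-atom labels from a fragment SMILES
#'
#' Replaces labelled attachment points such as `[1*]` or `[16*]` with a bare
#' `*`, the form used when fragments are displayed or compared.
#'
#' @param smiles character vector of fragment SMILES
#' @return character vector with bare dummy atoms
#' @examples
#' stripDummyLabels("[1*]C(C)=O")
#' @export
stripDummyLabels <- function(smiles) {
  gsub("\\[[0-9]+\\*\\]", "*", smiles)
}
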