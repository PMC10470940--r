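# Fully synthetic study populations: drugs, gene catalog, expression,
# tumour annotations and response tables with a planted subcomponent-level
# signal, so every stage is testable offline.

# Curated, valid small molecules: mostly BRICS-cleavable drug-like
# structures plus a few non-cleavable controls. Randomly generated SMILES
# are avoided because they are frequently invalid.
.WORLD_SMILES <- c(
  "CC(=O)Oc1ccccc1C(=O)O",            # aspirin
  "CC(=O)Nc1ccc(O)cc1",               # paracetamol
  "CC(C)Cc1ccc(C(C)C(=O)O)cc1",       # ibuprofen
  "CCOC(=O)c1ccccc1",
  "CN1CCCC1c1cccnc1",                 # nicotine
  "CC(=O)OCC(=O)c1ccccc1",
  "COc1ccc(CCN)cc1",
  "CCN(CC)C(=O)c1ccccc1",
  "CC(C)NCC(O)c1ccccc1",
  "O=C(O)c1ccccc1O",                  # salicylic acid
  "CCOC(=O)CC(=O)OCC",
  "CCCCOC(=O)c1ccc(N)cc1",            # butamben
  "COc1ccccc1OC",
  "CC(=O)N1CCCCC1",
  "O=C(Nc1ccccc1)c1ccccc1",
  "CSc1ccccc1",
  "CCS(=O)(=O)c1ccccc1",
  "CC(C)(C)OC(=O)NC1CCNCC1",
  "O=C(OCc1ccccc1)c1ccccn1",
  "CCOc1ccc(NC(C)=O)cc1",             # phenacetin
  "CN(C)CCOC(c1ccccc1)c1ccccc1",      # diphenhydramine
  "CC(=O)c1ccc(OC)cc1",
  "OCCN1CCN(CCCN2c3ccccc3Sc3ccc(Cl)cc32)CC1",  # perphenazine-like
  "CC(N)Cc1ccccc1",                   # amphetamine
  "COC(=O)c1ccccc1N",
  "CCC(=O)OC",
  "NC(=O)c1ccccc1",                   # benzamide
  "CC(C)=CCCC(C)=CCO",                # geraniol
  "c1ccccc1",                         # control: no cleavable bond
  "Cn1cnc2c1c(=O)n(C)c(=O)n2C",       # caffeine (control)
  "CCCCCC",                           # control
  "Clc1ccccc1Cl",                     # control
  "CCOCC",
  "Oc1ccc(Cl)cc1")

# CGC-like role labels: four roles plus their overlaps, eight subsets.
.CGC_SUBSETS <- c("oncogene", "TSG", "fusion", "unknown",
                  "oncogene,TSG", "oncogene,fusion", "TSG,fusion",
                  "oncogene,TSG,fusion")

#' Generate a synthetic study population
#'
#' Expression values are i.i.d. standard normal per gene (emulating
#' z-scored log2-TPM); the catalog partitions genes into near-equal subsets
#' round-robin; tumour types are assigned round-robin over cells; each gene
#' is applicable to most tumour types on a deterministic rotation so the
#' masking stage has work to do.
#'
#' @param nDrugs number of drugs (at most the curated list length)
#' @param nCells number of cell lines
#' @param nGenes catalog size (default 656)
#' @param nSubsets number of gene subsets (default 8)
#' @param nTumourTypes number of tumour types (default 4)
#' @param planted data.frame (fragment, subset, effect) of planted signals;
#'   the default plants one sensitising effect of size -2 on the acetyl
#'   fragment against the first subset
#' @param noiseSd response noise standard deviation (default 0.3)
#' @param baseline baseline log-IC50 (default 2.5)
#' @param seed generator seed
#' @return a [SyntheticWorld-class]
#' @export
generateWorld <- function(nDrugs = 30, nCells = 40, nGenes = 656,
                          nSubsets = 8, nTumourTypes = 4, planted = NULL,
                          noiseSd = 0.3, baseline = 2.5, seed = 1) {
  stopIfNot(nDrugs >= 1 && nCells >= 1 && nGenes >= 1 && nSubsets >= 1,
            "sizes must be at least 1")
  stopIfNot(nDrugs <= length(.WORLD_SMILES),
            "at most ", length(.WORLD_SMILES), " drugs available")
  subsetNames <- if (nSubsets == 8) .CGC_SUBSETS else
    paste0("subset", seq_len(nSubsets))
  if (is.null(planted)) {
    planted <- data.frame(fragment = "*C(=O)C", subset = subsetNames[1],
                          effect = -2, stringsAsFactors = FALSE)
  }
  stopIfNot(all(planted$subset %in% subsetNames),
            "planted subset not in catalog")
  drugs <- stats::setNames(.WORLD_SMILES[seq_len(nDrugs)],
                           sprintf("D%03d", seq_len(nDrugs)))
  genes <- sprintf("G%04d", seq_len(nGenes))
  types <- paste0("T", seq_len(nTumourTypes))
  catalog <- list(
    genes = genes,
    subsetOf = stats::setNames(
      subsetNames[((seq_len(nGenes) - 1) %% nSubsets) + 1], genes),
    tumourTypes = stats::setNames(lapply(seq_len(nGenes), function(i) {
      types[(i + seq_len(nTumourTypes)) %% 5 != 0]
    }), genes),
    subsets = subsetNames,
    typeUniverse = types)
  cells <- sprintf("C%03d", seq_len(nCells))
  expression <- withSeed(seed, {
    matrix(stats::rnorm(nCells * nGenes), nCells, nGenes,
           dimnames = list(cells, genes))
  })
  cellTypes <- stats::setNames(types[((seq_len(nCells) - 1) %%
                                        nTumourTypes) + 1], cells)
  methods::new("SyntheticWorld", drugs = drugs, catalog = catalog,
               expression = expression, cellTypes = cellTypes,
               planted = planted, noiseSd = noiseSd, baseline = baseline,
               seed = as.integer(seed))
}

# BRICS fragment sets per drug (stripped canonical forms), cached per call
.worldFragments <- function(world) {
  lapply(world@drugs, bricsDecompose)
}

# mean masked expression of each subset for every cell (cells x subsets)
.subsetMeans <- function(world) {
  cat <- world@catalog
  cells <- rownames(world@expression)
  out <- matrix(0, length(cells), length(cat$subsets),
                dimnames = list(cells, cat$subsets))
  for (cid in cells) {
    masked <- applyTumourMask(world@expression[cid, ],
                              world@cellTypes[[cid]], cat)
    parts <- partitionGenes(cat, masked)
    out[cid, ] <- vapply(parts, mean, numeric(1))
  }
  out
}

#' Generate the response table of a synthetic world
#'
#' The generative model is
#' `response = baseline + sum over planted effects of
#'  present(drug, fragment) * meanMaskedExpr(cell, subset) * effect
#'  + N(0, noiseSd)`,
#' where `present` tests membership of the planted fragment in the drug's
#' BRICS fragment set and the subset mean is taken over the tumour-masked
#' expression values.
#'
#' @param world a [SyntheticWorld-class]
#' @param pairFraction fraction of the full drug-cell grid to keep
#'   (default 1, sampled without replacement)
#' @param seed seed for noise and pair sampling; defaults to the world's
#' @return instance data.frame (drug_id, cell_id, response)
#' @export
generateResponses <- function(world, pairFraction = 1, seed = NULL) {
  seed <- seed %||% world@seed
  frags <- .worldFragments(world)
  means <- .subsetMeans(world)
  drugIds <- names(world@drugs)
  cellIds <- rownames(world@expression)
  grid <- expand.grid(drug_id = drugIds, cell_id = cellIds,
                      stringsAsFactors = FALSE)
  withSeed(seed, {
    if (pairFraction < 1) {
      keep <- sort(sample.int(nrow(grid), round(pairFraction * nrow(grid))))
      grid <- grid[keep, , drop = FALSE]
    }
    signal <- numeric(nrow(grid))
    for (k in seq_len(nrow(world@planted))) {
      pl <- world@planted[k, ]
      present <- vapply(grid$drug_id,
                        function(d) pl$fragment %in% frags[[d]], logical(1))
      signal <- signal + as.numeric(present) *
        means[grid$cell_id, pl$subset] * pl$effect
    }
    grid$response <- world@baseline + signal +
      if (world@noiseSd > 0) stats::rnorm(nrow(grid), 0, world@noiseSd)
      else 0
    rownames(grid) <- NULL
    grid
  })
}

#' Write a synthetic world as the five standard input tables
#'
#' Files follow the exact schemas read by [loadTables()]: `response.csv`,
#' `smiles.csv`, `expression.csv`, `gene_annot.csv`, `cell_annot.csv`.
#'
#' @param world a [SyntheticWorld-class]
#' @param instances response instances from [generateResponses()]
#' @param dir output directory (created if needed)
#' @return named character vector of the five paths, invisibly
#' @export
writeWorldTables <- function(world, instances, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(response = file.path(dir, "response.csv"),
             smiles = file.path(dir, "smiles.csv"),
             expression = file.path(dir, "expression.csv"),
             gene_annot = file.path(dir, "gene_annot.csv"),
             cell_annot = file.path(dir, "cell_annot.csv"))
  utils::write.csv(data.frame(drug_id = instances$drug_id,
                              cell_id = instances$cell_id,
                              ln_ic50 = instances$response),
                   paths["response"], row.names = FALSE, quote = FALSE)
  utils::write.csv(data.frame(drug_id = names(world@drugs),
                              smiles = unname(world@drugs)),
                   paths["smiles"], row.names = FALSE, quote = FALSE)
  expr <- data.frame(cell_id = rownames(world@expression),
                     world@expression, check.names = FALSE)
  utils::write.csv(expr, paths["expression"], row.names = FALSE,
                   quote = FALSE)
  cat <- world@catalog
  utils::write.csv(data.frame(
    gene = cat$genes,
    category = unname(cat$subsetOf[cat$genes]),
    tumour_types = vapply(cat$tumourTypes[cat$genes], paste,
                          character(1), collapse = ";")),
    paths["gene_annot"], row.names = FALSE, quote = TRUE)
  utils::write.csv(data.frame(cell_id = names(world@cellTypes),
                              tumour_type = unname(world@cellTypes)),
                   paths["cell_annot"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Check recovery of the planted subcomponent signal by a trained model
#'
#' Averages the planted fragment's interaction-map row over corpus
#' instances whose drug carries the fragment, and reports whether the
#' highest column-averaged score lands on the planted subset. When the
#' training instances are supplied, the average is restricted to carrier
#' instances with a sensitive observed response (below the world baseline),
#' mirroring how interaction heatmaps are read for sensitive cases.
#'
#' @param model a trained [CdrModel-class]
#' @param world the [SyntheticWorld-class] the model was trained on
#' @param instances optional instance data.frame used for the
#'   sensitive-response restriction
#' @param cells optional subset of cell ids to average over
#' @return list with `columnMeans` (named vector over subsets),
#'   `topSubset`, `plantedSubset` and logical `recovered`
#' @export
plantedSignalRecovery <- function(model, world, instances = NULL,
                                  cells = NULL) {
  pl <- world@planted[1, ]
  frags <- .worldFragments(world)
  carriers <- names(frags)[vapply(frags, function(f) pl$fragment %in% f,
                                  logical(1))]
  carriers <- intersect(carriers, model@corpus$drugIndex)
  stopIfNot(length(carriers) > 0, "no corpus drug carries the planted ",
            "fragment")
  cells <- cells %||% model@corpus$cellIndex
  acc <- NULL
  for (d in carriers) {
    row <- which(model@corpus$sequences[[d]]@fragments == pl$fragment)[1]
    useCells <- cells
    if (!is.null(instances)) {
      sens <- instances$cell_id[instances$drug_id == d &
                                  instances$response < world@baseline]
      useCells <- intersect(cells, sens)
    }
    for (cid in useCells) {
      map <- interactionMapFor(model, d, cid)
      acc <- rbind(acc, map@scores[row, ])
    }
  }
  stopIfNot(!is.null(acc), "no instances available for the recovery check")
  cm <- colMeans(acc)
  names(cm) <- model@corpus$catalog$subsets
  top <- names(cm)[which.max(cm)]
  list(columnMeans = cm, topSubset = top, plantedSubset = pl$subset,
       recovered = identical(top, pl$subset))
}
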