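# Interpretation: softmax heatmaps of interaction maps, top-interaction
# extraction, and candidate ranking over unmeasured combinations.

#' Softmax-normalise an interaction map for heatmap display
#'
#' @param map an [InteractionMap-class]
#' @param axis `"map"` (whole-map softmax, the default), `"row"` or
#'   `"column"`
#' @param instanceId free-form identifier stored with the export
#' @return a [HeatmapExport-class]
#' @export
normalizeMap <- function(map, axis = c("map", "row", "column"),
                         instanceId = "") {
  axis <- match.arg(axis)
  s <- map@scores
  stopIfNot(length(s) > 0, "empty interaction map")
  soft <- function(x) {
    e <- exp(x - max(x))
    e / sum(e)
  }
  norm <- switch(axis,
    map = matrix(soft(as.vector(s)), nrow(s), ncol(s)),
    row = t(apply(s, 1, soft)),
    column = apply(s, 2, soft))
  if (axis == "row" && ncol(s) == 1) norm <- t(norm)  # apply() drops dims
  norm <- matrix(norm, nrow(s), ncol(s))
  methods::new("HeatmapExport", normalized = norm, axis = axis,
               rowLabels = map@rowLabels, colLabels = map@colLabels,
               instanceId = as.character(instanceId))
}

#' Extract the top-scoring subcomponent interactions
#'
#' @param map an [InteractionMap-class]
#' @param k number of interactions to return; when `k` exceeds the map
#'   size, all cells are returned and attribute `"truncated"` is set
#' @return data.frame (fragment, subset, row, col, score) in descending
#'   score order; ties break by (row index, column index)
#' @export
topInteractions <- function(map, k) {
  stopIfNot(k >= 1, "k must be at least 1")
  s <- map@scores
  cells <- expand.grid(row = seq_len(nrow(s)), col = seq_len(ncol(s)))
  cells$score <- s[as.matrix(cells)]
  ord <- order(-cells$score, cells$row, cells$col)
  truncated <- k > nrow(cells)
  out <- cells[ord[seq_len(min(k, nrow(cells)))], , drop = FALSE]
  out <- data.frame(fragment = map@rowLabels[out$row],
                    subset = map@colLabels[out$col],
                    row = out$row, col = out$col, score = out$score,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (truncated) attr(out, "truncated") <- TRUE
  out
}

#' Rank unmeasured drug-cell combinations by predicted sensitivity
#'
#' Predicts every supplied pair, keeps those with predicted log-IC50
#' strictly below the threshold, and returns the k most sensitive in
#' ascending order of predicted response.
#'
#' @param model a trained [CdrModel-class]
#' @param pairs data.frame with `drug_id`, `cell_id`
#' @param k maximum candidates to retain (default 10)
#' @param threshold sensitivity cutoff on the predicted log-IC50
#'   (default -2)
#' @return data.frame (drug_id, cell_id, predicted) sorted ascending; when
#'   no pair passes the threshold the frame is empty and attribute
#'   `"status"` explains why
#' @export
rankCandidates <- function(model, pairs, k = 10, threshold = -2) {
  preds <- predictResponses(model, pairs)
  ord <- order(preds, seq_along(preds))
  keep <- ord[preds[ord] < threshold]
  out <- data.frame(drug_id = pairs$drug_id[keep],
                    cell_id = pairs$cell_id[keep],
                    predicted = preds[keep], stringsAsFactors = FALSE)
  out <- out[seq_len(min(k, nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) {
    attr(out, "status") <- sprintf(
      "no prediction below threshold %g (minimum was %g)", threshold,
      if (length(preds)) min(preds) else NA_real_)
  }
  out
}

#' Write a heatmap export as delimited text
#'
#' The text form is the authoritative export; scores round-trip through
#' [readHeatmap()] at full double precision.
#'
#' @param export a [HeatmapExport-class]
#' @param path output TSV path
#' @return the path, invisibly
#' @export
writeHeatmap <- function(export, path) {
  df <- as.data.frame(export@normalized)
  colnames(df) <- export@colLabels
  df <- cbind(fragment = export@rowLabels, df)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# axis: %s", export@axis), con)
  writeLines(sprintf("# instance: %s", export@instanceId), con)
  utils::write.table(format(df, digits = 17, trim = TRUE), con, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a heatmap export written by [writeHeatmap()]
#'
#' @param path TSV path
#' @return a [HeatmapExport-class]
#' @export
readHeatmap <- function(path) {
  lines <- readLines(path)
  axis <- sub("^# axis: ", "", lines[1])
  inst <- sub("^# instance: ", "", lines[2])
  df <- utils::read.delim(text = lines[-(1:2)], check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  dimnames(m) <- NULL
  methods::new("HeatmapExport", normalized = m, axis = axis,
               rowLabels = as.character(df$fragment),
               colLabels = colnames(df)[-1], instanceId = inst)
}
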