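#' Write binding predictions to TSV
#'
#' One row per residue per protein with columns `protein_id`, `position`,
#' `residue`, per-class probabilities (`p_metal`, `p_nucleic`, `p_small`),
#' binary calls (`call_*`, 0/1), integer reliability indices (`ri_*`), and
#' `source` (`DL` or `HBI`). Probabilities are serialized with enough digits
#' to round trip through [read_predictions()] at the serialized precision.
#'
#' @param predictions List of [binding_prediction()] objects.
#' @param path Output TSV path.
#' @param sequences Optional named character vector supplying the `residue`
#'   column; `X` is written when unavailable.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, sequences = NULL) {
  rows <- lapply(predictions, function(pr) {
    L <- nrow(pr$prob)
    res <- if (!is.null(sequences) && pr$protein_id %in% names(sequences))
      strsplit(sequences[[pr$protein_id]], "")[[1]] else rep("X", L)
    data.table::data.table(
      protein_id = pr$protein_id, position = seq_len(L), residue = res,
      p_metal = pr$prob[, 1L], p_nucleic = pr$prob[, 2L], p_small = pr$prob[, 3L],
      call_metal = as.integer(pr$calls[, 1L]),
      call_nucleic = as.integer(pr$calls[, 2L]),
      call_small = as.integer(pr$calls[, 3L]),
      ri_metal = pr$ri[, 1L], ri_nucleic = pr$ri[, 2L], ri_small = pr$ri[, 3L],
      source = pr$source)
  })
  tab <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(protein_id = character(), position = integer(),
                           residue = character(), p_metal = numeric(),
                           p_nucleic = numeric(), p_small = numeric(),
                           call_metal = integer(), call_nucleic = integer(),
                           call_small = integer(), ri_metal = integer(),
                           ri_nucleic = integer(), ri_small = integer(),
                           source = character())
  for (cl in c("p_metal", "p_nucleic", "p_small"))
    data.table::set(tab, j = cl, value = sprintf("%.6f", tab[[cl]]))
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}

#' Read binding predictions from TSV
#'
#' @param path Prediction TSV written by [write_predictions()].
#' @return List of [binding_prediction()] objects (probabilities at the
#'   serialized precision; calls and RI re-derived from the file columns).
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop("prediction file not found: ", path)
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c("protein_id", "residue", "source")))
  if (nrow(tab) == 0L) return(list())
  out <- list()
  for (pid in unique(tab$protein_id)) {
    sub <- tab[tab$protein_id == pid, ][order(position)]
    prob <- cbind(sub$p_metal, sub$p_nucleic, sub$p_small)
    pr <- binding_prediction(pid, prob, source = sub$source[1L])
    # trust the serialized calls/RI over re-derivation only if they differ
    # by rounding of the probabilities; keep file values authoritative
    pr$calls <- cbind(METAL = sub$call_metal == 1L, NUCLEIC = sub$call_nucleic == 1L,
                      SMALL = sub$call_small == 1L)
    pr$any <- any_binding(pr$calls)
    pr$ri <- cbind(METAL = sub$ri_metal, NUCLEIC = sub$ri_nucleic, SMALL = sub$ri_small)
    out[[pid]] <- pr
  }
  out
}
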