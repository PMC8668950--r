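#' Cumulative precision/recall/coverage over probability cutoffs
#'
#' For each cutoff, residues with any-class probability at or above the
#' cutoff are called binding and the cumulative, residue-pooled precision
#' (fraction of called residues that are annotated) and recall (fraction of
#' all annotated binding residues recovered) are computed over the full
#' protein set, together with [cov_one_bind()]. This mirrors the
#' cumulative-curve construction used to study the reliability of strong
#' predictions: raising the cutoff trades recall and coverage for
#' precision. Recall and CovOneBind are non-increasing in the cutoff by
#' construction; precision usually rises with the cutoff but is not
#' guaranteed monotone.
#'
#' @param probabilities Named list of `L x 3` probability matrices.
#' @param annotations Named list of [residue_annotations()] for the same
#'   proteins (an error if the sets differ).
#' @param cutoffs Numeric vector of probability cutoffs in (0, 1).
#' @param scope Ligand class or `"ANY"` (default): which channel(s) to
#'   assess; `"ANY"` compares the row-wise OR on both sides.
#' @return `data.frame` with one row per cutoff: `cutoff`, `precision`,
#'   `recall`, `cov_one_bind`, `n_called` (residues above cutoff),
#'   `n_proteins_covered`.
#' @export
threshold_sweep <- function(probabilities, annotations, cutoffs, scope = "ANY") {
  scope <- match.arg(scope, c(ligand_classes(), "ANY"))
  ids <- names(probabilities)
  if (is.null(ids) || !setequal(ids, names(annotations)))
    stop("probabilities and annotations must cover the same proteins")
  if (any(cutoffs <= 0 | cutoffs >= 1))
    stop("cutoffs must lie in (0, 1)")
  for (pid in ids)
    check_length_match(probabilities[[pid]], nrow(annotations[[pid]]),
                       "probabilities", pid)

  rows <- lapply(cutoffs, function(ct) {
    total <- c(TP = 0, FP = 0, TN = 0, FN = 0)
    covered <- 0L
    annotated <- 0L
    for (pid in ids) {
      calls <- binarize(probabilities[[pid]], threshold = ct)$calls
      tr <- annotations[[pid]]
      total <- total + unclass(confusion_counts(calls, tr, scope))
      tr_m <- unclass(tr)
      has_ann <- if (scope == "ANY") any(tr_m) else any(tr_m[, scope])
      has_call <- if (scope == "ANY") any(calls) else any(calls[, scope])
      annotated <- annotated + has_ann
      covered <- covered + (has_ann && has_call)
    }
    if (annotated == 0L) stop("no protein carries annotations for scope ", scope)
    m <- binding_metrics(total, undefined = "exclude")
    data.frame(cutoff = ct,
               precision = m[["precision"]],
               recall = m[["recall"]],
               cov_one_bind = covered / annotated,
               n_called = unname(total[["TP"]] + total[["FP"]]),
               n_proteins_covered = covered)
  })
  do.call(rbind, rows)
}
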