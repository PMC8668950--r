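#' Combined predictor: homology transfer first, model otherwise
#'
#' Routes every query to homology-based inference when an experimentally
#' annotated sequence-similar protein is available (best local-alignment
#' hit under the E-value cutoff with binding annotations in the aligned
#' region), and to the learned model otherwise. HBI output carries hard
#' pseudo-probabilities (1 at transferred binding labels, 0 elsewhere), so
#' its reliability index is 9 everywhere; downstream probability-cutoff
#' analyses should therefore be run on model-sourced predictions only.
#'
#' @param queries Named character vector of query sequences.
#' @param embeddings Named list of `L x input_dim` embedding matrices; every
#'   query needs one so the model fallback is always possible (a query
#'   without an embedding that also gets no HBI result is an error naming
#'   the query).
#' @param model A trained `"plm_model"`.
#' @param lookup A [cluster_lookup()] result, or `NULL` for no lookup set
#'   (everything routed to the model).
#' @param evalue_cutoff Maximum E-value for homology transfer (default
#'   1e-3, the setting at which the combination performs best).
#' @param exclude_self Drop self-hits in the homology search.
#' @param threshold Decision threshold for the model path.
#' @param backend Alignment backend, see [search_lookup()].
#' @return Named list of [binding_prediction()] objects with `source`
#'   `"HBI"` or `"DL"`; HBI predictions carry hit provenance (target ID,
#'   E-value, PIDE).
#' @export
combine_predictions <- function(queries, embeddings, model, lookup = NULL,
                                evalue_cutoff = 1e-3, exclude_self = TRUE,
                                threshold = NULL, backend = "internal") {
  stopifnot(inherits(model, "plm_model"))
  if (is.null(threshold)) threshold <- model$config$decision_threshold
  qids <- names(queries)
  stopifnot(!is.null(qids), all(nzchar(qids)))

  hbi <- if (!is.null(lookup) && length(lookup$sequences) > 0L)
    run_hbi(queries, lookup, evalue_cutoff = evalue_cutoff,
            exclude_self = exclude_self, backend = backend)
  else NULL

  out <- vector("list", length(qids))
  names(out) <- qids
  for (qid in qids) {
    res <- if (!is.null(hbi)) hbi[[qid]] else NULL
    if (!is.null(res) && !is.null(res$annotations)) {
      prob <- matrix(as.numeric(unclass(res$annotations)),
                     nrow(res$annotations), 3L)
      out[[qid]] <- binding_prediction(
        qid, prob, threshold = threshold, source = "HBI",
        provenance = list(target_id = res$used_hit$target_id,
                          evalue = res$used_hit$evalue,
                          pide = res$used_hit$pide))
    } else {
      if (!qid %in% names(embeddings))
        stop("query ", qid, " has no embedding and no homology-based result")
      prob <- predict(model, embeddings[[qid]])
      out[[qid]] <- binding_prediction(qid, prob, threshold = threshold,
                                       source = "DL")
    }
  }
  out
}
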