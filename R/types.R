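#' Ligand classes
#'
#' The three ligand classes predicted by the package, in the fixed channel
#' order used everywhere (annotation matrices, model output channels,
#' report columns): metal ions, nucleic acids (DNA or RNA), small molecules.
#' Peptide ligands are outside the scope of the predictor.
#'
#' @return Character vector `c("METAL", "NUCLEIC", "SMALL")`.
#' @export
#' @examples
#' ligand_classes()
ligand_classes <- function() c("METAL", "NUCLEIC", "SMALL")

# canonical amino acids + X for non-canonical residues
AA_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' Residue-level binding annotations for one protein
#'
#' Builds the L x 3 logical annotation matrix used throughout the package:
#' one row per residue, one column per ligand class (see [ligand_classes()]).
#' The annotation is multi-label: a residue may bind several classes.
#'
#' @param protein_id Protein identifier (non-empty string).
#' @param length Sequence length L (>= 1).
#' @param positions Named list mapping ligand class to an integer vector of
#'   1-based binding positions. Classes absent from the list get no labels.
#' @return A logical `L x 3` matrix of class `"residue_annotations"` with
#'   column names `ligand_classes()` and attribute `protein_id`.
#' @export
#' @examples
#' residue_annotations("P1", 10, list(METAL = c(3, 4, 7)))
residue_annotations <- function(protein_id, length, positions = list()) {
  stopifnot(is.character(protein_id), nzchar(protein_id),
            is.numeric(length), length >= 1)
  length <- as.integer(length)
  labels <- matrix(FALSE, nrow = length, ncol = 3L,
                   dimnames = list(NULL, ligand_classes()))
  if (length(positions)) {
    bad <- setdiff(names(positions), ligand_classes())
    if (length(bad))
      stop("unknown ligand class: ", paste(bad, collapse = ", "))
    for (cl in names(positions)) {
      pos <- as.integer(positions[[cl]])
      if (any(pos < 1L | pos > length))
        stop("position out of range [1, ", length, "] for protein ",
             protein_id, " class ", cl)
      labels[pos, cl] <- TRUE
    }
  }
  structure(labels, protein_id = protein_id, class = c("residue_annotations", "matrix", "array"))
}

as_residue_annotations <- function(labels, protein_id) {
  stopifnot(is.logical(labels), ncol(labels) == 3L)
  dimnames(labels) <- list(NULL, ligand_classes())
  structure(labels, protein_id = protein_id,
            class = c("residue_annotations", "matrix", "array"))
}

#' Any-binding vector of an annotation or call matrix
#'
#' Row-wise OR over the three ligand-class columns: `TRUE` where the residue
#' binds (or is called for) at least one class.
#'
#' @param labels Logical `L x 3` matrix (annotations or binary calls).
#' @return Logical vector of length L.
#' @export
any_binding <- function(labels) {
  stopifnot(is.logical(labels), ncol(labels) == 3L)
  rowSums(labels) > 0L
}

# shape check shared by everything holding per-residue arrays
check_length_match <- function(x, n_expected, what, protein_id) {
  if (nrow(x) != n_expected)
    stop(what, " for protein ", protein_id, " has ", nrow(x),
         " rows, expected sequence length ", n_expected)
  invisible(x)
}

#' Per-residue binding prediction for one protein
#'
#' Container tying together the probability matrix, binary calls, reliability
#' indices and provenance for one protein. Constructed by
#' [predict_binding()] and [combine_predictions()]; users rarely call this
#' directly.
#'
#' @param protein_id Protein identifier.
#' @param prob Numeric `L x 3` matrix of per-class binding probabilities.
#' @param threshold Decision threshold applied to `prob` (default 0.5): a
#'   residue is non-binding for a class when its probability is below the
#'   threshold, non-binding overall when all three are.
#' @param source `"DL"` for model predictions, `"HBI"` for homology transfer.
#' @param provenance Optional list with transfer provenance (hit id, E-value).
#' @return An object of class `"binding_prediction"`: a list with elements
#'   `protein_id`, `prob`, `calls`, `any`, `ri`, `source`, `provenance`.
#' @export
binding_prediction <- function(protein_id, prob, threshold = 0.5,
                               source = c("DL", "HBI"), provenance = NULL) {
  source <- match.arg(source)
  stopifnot(is.matrix(prob), ncol(prob) == 3L, all(is.finite(prob)),
            all(prob >= 0), all(prob <= 1))
  colnames(prob) <- ligand_classes()
  b <- binarize(prob, threshold = threshold)
  structure(list(protein_id = protein_id,
                 prob = prob,
                 calls = b$calls,
                 any = b$any,
                 ri = reliability_index(prob),
                 source = source,
                 provenance = provenance),
            class = "binding_prediction")
}

#' @export
print.binding_prediction <- function(x, ...) {
  cat(sprintf("<binding_prediction> %s: %d residues, %d called binding, source=%s\n",
              x$protein_id, nrow(x$prob), sum(x$any), x$source))
  invisible(x)
}

#' @export
print.residue_annotations <- function(x, ...) {
  cat(sprintf("<residue_annotations> %s: %d residues, %d binding (%s)\n",
              attr(x, "protein_id"), nrow(x), sum(any_binding(unclass(x))),
              paste(sprintf("%s=%d", colnames(x), colSums(x)), collapse = ", ")))
  invisible(x)
}
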