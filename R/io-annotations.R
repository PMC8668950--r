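#' Read residue-level binding annotations
#'
#' Reads the flat annotation TSV dialect with columns
#' `protein_id`, `ligand_class` (`METAL`/`NUCLEIC`/`SMALL`),
#' `positions` (comma-separated 1-based residue indices),
#' `resolution_angstrom`, and `method`.
#'
#' Records from structures that fail the resolution or experiment-method
#' filter are dropped. Binding information surviving the filter is combined
#' per protein and ligand class as the position-wise union over all records,
#' mirroring how annotations from multiple chains and structures of the same
#' protein are merged; residues never annotated as binding are non-binding.
#' `PEPTIDE` records are ignored with a warning (peptide ligands are out of
#' scope); any other unknown class token is an error.
#'
#' @param path Path to the annotation TSV.
#' @param sequences Optional named character vector of sequences. When given,
#'   annotation lengths are taken from the sequences and out-of-range
#'   positions are an error; proteins without surviving annotation records
#'   get all-FALSE annotations only if listed in `sequences` and
#'   `fill_missing = TRUE`.
#' @param max_resolution Maximum structure resolution in Angstrom (default
#'   2.5); records with larger values are dropped.
#' @param methods_allowed Experiment types accepted (default X-ray
#'   crystallography).
#' @param fill_missing When `sequences` is given, also return all-FALSE
#'   annotations for sequences with no surviving record (default `FALSE`).
#' @return Named list of [residue_annotations()] matrices keyed by protein
#'   ID. Without `sequences`, each protein's length is inferred as the
#'   largest annotated position.
#' @export
read_annotations <- function(path, sequences = NULL, max_resolution = 2.5,
                             methods_allowed = "X-ray", fill_missing = FALSE) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- data.table::fread(path, sep = "\t", header = TRUE,
                           colClasses = list(character = c("protein_id", "ligand_class",
                                                           "positions", "method")))
  out <- list()
  if (nrow(tab) > 0L) {
    required <- c("protein_id", "ligand_class", "positions",
                  "resolution_angstrom", "method")
    missing <- setdiff(required, names(tab))
    if (length(missing))
      stop("annotation file lacks column(s): ", paste(missing, collapse = ", "))
    if (any(tab$ligand_class == "PEPTIDE")) {
      warning("ignoring ", sum(tab$ligand_class == "PEPTIDE"),
              " peptide-ligand annotation record(s); peptides are out of scope")
      tab <- tab[tab$ligand_class != "PEPTIDE", ]
    }
    unknown <- setdiff(unique(tab$ligand_class), ligand_classes())
    if (length(unknown))
      stop("unknown ligand class token(s): ", paste(unknown, collapse = ", "))
    if (any(!is.finite(tab$resolution_angstrom) | tab$resolution_angstrom <= 0))
      stop("resolution_angstrom must be a positive number")
    keep <- tab$resolution_angstrom <= max_resolution & tab$method %in% methods_allowed
    tab <- tab[keep, ]
    if (nrow(tab) > 0L) {
      pos_by <- split(seq_len(nrow(tab)), tab$protein_id)
      for (pid in names(pos_by)) {
        rows <- pos_by[[pid]]
        positions <- list()
        for (r in rows) {
          cl <- tab$ligand_class[r]
          pos <- as.integer(strsplit(tab$positions[r], ",", fixed = TRUE)[[1]])
          if (anyNA(pos)) stop("malformed positions field for protein ", pid)
          positions[[cl]] <- sort(unique(c(positions[[cl]], pos)))
        }
        L <- if (!is.null(sequences)) {
          if (!pid %in% names(sequences))
            stop("annotated protein ", pid, " not present in sequences")
          nchar(sequences[[pid]])
        } else {
          max(unlist(positions))
        }
        out[[pid]] <- residue_annotations(pid, L, positions)
      }
    }
  }
  if (!is.null(sequences) && fill_missing) {
    for (pid in setdiff(names(sequences), names(out)))
      out[[pid]] <- residue_annotations(pid, nchar(sequences[[pid]]))
    out <- out[names(sequences)]
  }
  out
}

#' Write residue-level binding annotations
#'
#' Inverse of [read_annotations()] for package-generated annotation sets:
#' one row per protein and ligand class with at least one binding position.
#'
#' @param annotations Named list of [residue_annotations()] matrices.
#' @param path Output TSV path.
#' @param resolution,method Values written to the provenance columns
#'   (synthetic annotations default to an in-range resolution).
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path, resolution = 1.5, method = "X-ray") {
  rows <- list()
  for (pid in names(annotations)) {
    ann <- annotations[[pid]]
    for (cl in ligand_classes()) {
      pos <- which(ann[, cl])
      if (length(pos))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          protein_id = pid, ligand_class = cl,
          positions = paste(pos, collapse = ","),
          resolution_angstrom = resolution, method = method)
    }
  }
  tab <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(protein_id = character(), ligand_class = character(),
                           positions = character(), resolution_angstrom = numeric(),
                           method = character())
  data.table::fwrite(tab, path, sep = "\t")
  invisible(path)
}
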