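#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased; record order is preserved. Identifiers are the
#' first whitespace-delimited token of each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of amino-acid sequences (names = IDs).
#' @export
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 some description", "MKV"), f)
#' read_fasta(f)
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L) stop("FASTA file is empty: ", path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence ID(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param sequences Named character vector (names = protein IDs).
#' @param path Output path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path, width = 60L) {
  stopifnot(is.character(sequences), !is.null(names(sequences)),
            all(nzchar(names(sequences))))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(sequences)) {
    writeLines(paste0(">", names(sequences)[i]), con)
    s <- sequences[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

# random amino-acid sequence (uniform over the 20 canonical residues)
random_sequence <- function(length) {
  paste(sample(AA_ALPHABET, length, replace = TRUE), collapse = "")
}
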