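#' Read a per-protein embedding store
#'
#' The embedding store is a directory holding one tab-separated matrix per
#' protein (`<protein_id>.tsv`, no header): L rows (one per residue) by
#' `dim` columns of floats written at full precision, so a write/read
#' round trip reproduces the values bitwise.
#'
#' @param path Directory containing `<id>.tsv` matrices.
#' @param dim Required embedding width (default 1024, the per-residue width
#'   of the language-model hidden states the predictor consumes).
#' @param ids Optional character vector restricting which proteins to load.
#' @return Named list of numeric `L x dim` matrices keyed by protein ID.
#' @export
read_embeddings <- function(path, dim = 1024L, ids = NULL) {
  if (!dir.exists(path)) stop("embedding store not found: ", path)
  files <- list.files(path, pattern = "\\.tsv$", full.names = TRUE)
  pids <- sub("\\.tsv$", "", basename(files))
  if (!is.null(ids)) {
    missing <- setdiff(ids, pids)
    if (length(missing))
      stop("embedding store lacks protein(s): ", paste(missing, collapse = ", "))
    files <- files[match(ids, pids)]
    pids <- ids
  }
  out <- vector("list", length(files))
  names(out) <- pids
  for (i in seq_along(files)) {
    # scan() parses through strtod, so full-precision text round-trips
    # bitwise (fast float parsers can be off by one ulp)
    first <- strsplit(readLines(files[i], n = 1L), "\t", fixed = TRUE)[[1]]
    vals <- scan(files[i], what = numeric(), sep = "\t", quiet = TRUE)
    m <- matrix(vals, ncol = length(first), byrow = TRUE)
    if (ncol(m) != dim)
      stop("embedding for protein ", pids[i], " has width ", ncol(m),
           ", expected ", dim)
    if (!all(is.finite(m)))
      stop("non-finite embedding values for protein ", pids[i])
    out[[i]] <- m
  }
  out
}

#' Write a per-protein embedding store
#'
#' @param embeddings Named list of numeric `L x dim` matrices.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @seealso [read_embeddings()] for the store layout.
#' @export
write_embeddings <- function(embeddings, path) {
  stopifnot(is.list(embeddings), !is.null(names(embeddings)),
            all(nzchar(names(embeddings))))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (pid in names(embeddings)) {
    m <- embeddings[[pid]]
    stopifnot(is.matrix(m), is.numeric(m))
    # %.17g guarantees a bitwise double round trip through text
    lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(lines, file.path(path, paste0(pid, ".tsv")))
  }
  invisible(path)
}
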