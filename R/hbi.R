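# Homology-based inference: transfer residue-level binding annotations from
# an annotated lookup set to queries via local alignment.
#
# The default ("internal") backend is Smith-Waterman local alignment
# (BLOSUM62, gap open 11 / extend 1) with a Karlin-Altschul E-value using
# the standard gapped parameters for that scoring system
# (lambda = 0.267, K = 0.041). An "mmseqs2" backend slot wraps the
# two-iteration profile-search protocol but requires the external binary
# and errors explicitly when it is absent.

KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Local pairwise alignment of two protein sequences
#'
#' Smith-Waterman local alignment via [Biostrings::pairwiseAlignment()]
#' with BLOSUM62 and affine gaps (open 11, extend 1). Returns the aligned
#' position pairs (gaps are simply absent pairs), the raw score, and the
#' percent sequence identity over the aligned pairs.
#'
#' @param query,target Amino-acid sequence strings.
#' @return List with `score`, `pide` (identical aligned pairs / aligned
#'   pairs), `pairs` (integer matrix with columns `q_pos`, `t_pos`, 1-based,
#'   strictly increasing), `q_start`, `t_start`. `NULL` if the optimal local
#'   alignment is empty.
#' @export
align_local <- function(query, target) {
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(target),
    type = "local", substitutionMatrix = "BLOSUM62",
    gapOpening = 11, gapExtension = 1)
  qa <- strsplit(as.character(Biostrings::pattern(al)), "")[[1]]
  ta <- strsplit(as.character(Biostrings::subject(al)), "")[[1]]
  if (length(qa) == 0L) return(NULL)
  qpos <- Biostrings::start(Biostrings::pattern(al)) - 1L
  tpos <- Biostrings::start(Biostrings::subject(al)) - 1L
  pairs <- matrix(0L, 0L, 2L)
  n_id <- 0L
  qs <- integer(length(qa)); ts <- integer(length(ta)); np <- 0L
  for (i in seq_along(qa)) {
    if (qa[i] != "-") qpos <- qpos + 1L
    if (ta[i] != "-") tpos <- tpos + 1L
    if (qa[i] != "-" && ta[i] != "-") {
      np <- np + 1L
      qs[np] <- qpos; ts[np] <- tpos
      if (qa[i] == ta[i]) n_id <- n_id + 1L
    }
  }
  pairs <- cbind(q_pos = qs[seq_len(np)], t_pos = ts[seq_len(np)])
  list(score = Biostrings::score(al),
       pide = n_id / np,
       pairs = pairs,
       q_start = pairs[1L, 1L], t_start = pairs[1L, 2L])
}

# Karlin-Altschul E-value of a local alignment score against a database of
# total length n_db, for a query of length m.
evalue_karlin_altschul <- function(score, m, n_db,
                                   lambda = KA_LAMBDA, K = KA_K) {
  K * m * n_db * exp(-lambda * score)
}

#' Build (and redundancy-reduce) an annotated lookup set
#'
#' Greedy clustering of the annotated proteins at a pairwise sequence
#' identity threshold: proteins are visited longest-first (ties broken by
#' ID) and join an existing representative when the local-alignment PIDE
#' reaches the threshold, otherwise they become a new representative. Only
#' representatives remain in the lookup set, so after clustering no pair of
#' retained proteins reaches the threshold.
#'
#' @param sequences Named character vector of annotated protein sequences.
#' @param annotations Named list of [residue_annotations()], same names.
#' @param pide_threshold Clustering threshold (default 0.95); values above
#'   1 disable clustering (every protein is kept).
#' @param cluster Set `FALSE` to keep all entries without clustering.
#' @return Object of class `"lookup_set"`: list with `sequences`,
#'   `annotations`, `clustered`, `pide_threshold`, `db_size` (total residue
#'   count, the database size used by E-value estimation).
#' @export
cluster_lookup <- function(sequences, annotations, pide_threshold = 0.95,
                           cluster = TRUE) {
  if (length(sequences) == 0L) stop("empty lookup set")
  ids <- names(sequences)
  stopifnot(!is.null(ids), all(ids %in% names(annotations)))
  keep <- ids
  if (cluster) {
    ord <- ids[order(-nchar(sequences[ids]), ids)]
    reps <- character(0)
    for (pid in ord) {
      joined <- FALSE
      for (r in reps) {
        al <- align_local(sequences[[pid]], sequences[[r]])
        if (!is.null(al) && al$pide >= pide_threshold) { joined <- TRUE; break }
      }
      if (!joined) reps <- c(reps, pid)
    }
    keep <- reps
  }
  structure(list(sequences = sequences[keep],
                 annotations = annotations[keep],
                 clustered = isTRUE(cluster),
                 pide_threshold = pide_threshold,
                 db_size = sum(nchar(sequences[keep]))),
            class = "lookup_set")
}

#' @export
print.lookup_set <- function(x, ...) {
  cat(sprintf("<lookup_set> %d annotated proteins (%s), %d residues\n",
              length(x$sequences),
              if (x$clustered) sprintf("clustered at PIDE %.2f", x$pide_threshold)
              else "unclustered", x$db_size))
  invisible(x)
}

#' Search a query against the annotated lookup set
#'
#' Aligns the query locally against every lookup entry and keeps hits whose
#' E-value passes the cutoff. Self-hits (target ID equal to the query ID)
#' can be excluded, as done when estimating performance on proteins that
#' are themselves part of the annotated set.
#'
#' @param query_id,query_seq Query identifier and sequence.
#' @param lookup A [cluster_lookup()] result.
#' @param evalue_cutoff Maximum E-value (default 1e-3).
#' @param exclude_self Drop hits with `target_id == query_id`.
#' @param backend `"internal"` (Smith-Waterman, default) or `"mmseqs2"`
#'   (external profile search; errors if the binary is unavailable).
#' @return List of hits, each a list with `query_id`, `target_id`,
#'   `evalue`, `pide`, `pairs`.
#' @export
search_lookup <- function(query_id, query_seq, lookup, evalue_cutoff = 1e-3,
                          exclude_self = TRUE,
                          backend = c("internal", "mmseqs2")) {
  backend <- match.arg(backend)
  stopifnot(inherits(lookup, "lookup_set"))
  if (backend == "mmseqs2") {
    if (Sys.which("mmseqs") == "")
      stop("mmseqs2 backend requested but the 'mmseqs' binary is not on PATH; ",
           "use backend = \"internal\" or install MMseqs2")
    return(search_lookup_mmseqs2(query_id, query_seq, lookup, evalue_cutoff,
                                 exclude_self))
  }
  hits <- list()
  m <- nchar(query_seq)
  for (tid in names(lookup$sequences)) {
    if (exclude_self && identical(tid, query_id)) next
    al <- align_local(query_seq, lookup$sequences[[tid]])
    if (is.null(al)) next
    ev <- evalue_karlin_altschul(al$score, m, lookup$db_size)
    if (ev <= evalue_cutoff)
      hits[[length(hits) + 1L]] <- list(query_id = query_id, target_id = tid,
                                        evalue = ev, pide = al$pide,
                                        pairs = al$pairs)
  }
  hits
}

# External profile-search protocol (two profile iterations, then
# profile-vs-lookup search). Only reachable when the binary exists; kept
# minimal because the internal backend is the tested default.
search_lookup_mmseqs2 <- function(query_id, query_seq, lookup, evalue_cutoff,
                                  exclude_self) {
  td <- tempfile("mmseqs_")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE))
  qf <- file.path(td, "query.fasta")
  lf <- file.path(td, "lookup.fasta")
  write_fasta(stats::setNames(query_seq, query_id), qf)
  write_fasta(lookup$sequences, lf)
  out <- file.path(td, "hits.tsv")
  run <- function(...) {
    status <- system2("mmseqs", c(...), stdout = FALSE, stderr = FALSE)
    if (status != 0L) stop("mmseqs2 failed (exit ", status, ")")
  }
  run("createdb", qf, file.path(td, "qdb"))
  run("createdb", lf, file.path(td, "ldb"))
  # two search iterations build the query profile before the final search
  run("search", file.path(td, "qdb"), file.path(td, "ldb"),
      file.path(td, "res"), file.path(td, "tmp"),
      "--num-iterations", "2", "-e", format(evalue_cutoff))
  run("convertalis", file.path(td, "qdb"), file.path(td, "ldb"),
      file.path(td, "res"), out,
      "--format-output", "query,target,evalue,pident,qstart,tstart,qaln,taln")
  tab <- data.table::fread(out, header = FALSE,
                           col.names = c("query", "target", "evalue", "pident",
                                         "qstart", "tstart", "qaln", "taln"))
  hits <- list()
  for (i in seq_len(nrow(tab))) {
    tid <- tab$target[i]
    if (exclude_self && identical(tid, query_id)) next
    if (tab$evalue[i] > evalue_cutoff) next
    qa <- strsplit(tab$qaln[i], "")[[1]]
    ta <- strsplit(tab$taln[i], "")[[1]]
    qpos <- tab$qstart[i] - 1L; tpos <- tab$tstart[i] - 1L
    qs <- integer(0); ts <- integer(0)
    for (j in seq_along(qa)) {
      if (qa[j] != "-") qpos <- qpos + 1L
      if (ta[j] != "-") tpos <- tpos + 1L
      if (qa[j] != "-" && ta[j] != "-") { qs <- c(qs, qpos); ts <- c(ts, tpos) }
    }
    hits[[length(hits) + 1L]] <- list(query_id = query_id, target_id = tid,
                                      evalue = tab$evalue[i],
                                      pide = tab$pident[i] / 100,
                                      pairs = cbind(q_pos = qs, t_pos = ts))
  }
  hits
}

#' Select the best hit from a hit list
#'
#' The local alignment with the lowest E-value is chosen; ties are broken
#' by the highest PIDE, remaining ties by lexicographic target ID (a
#' deterministic convention).
#'
#' @param hits List of hits from [search_lookup()].
#' @return The best hit, or `NULL` for an empty list.
#' @export
select_best_hit <- function(hits) {
  if (length(hits) == 0L) return(NULL)
  ev <- vapply(hits, `[[`, numeric(1), "evalue")
  pide <- vapply(hits, `[[`, numeric(1), "pide")
  tid <- vapply(hits, `[[`, character(1), "target_id")
  hits[[order(ev, -pide, tid)[1L]]]
}

#' Transfer annotations through an alignment hit
#'
#' If any binding annotation (any ligand class) of the target falls on an
#' aligned target position, every aligned query position inherits the
#' target's per-class labels at its aligned partner and all non-aligned
#' query positions are non-binding. If the aligned region of the target
#' carries no binding annotation at all, the hit is discarded and no
#' inference is made.
#'
#' @param hit A hit from [search_lookup()] / [select_best_hit()].
#' @param target_annotations [residue_annotations()] of the hit's target.
#' @param query_length Length of the query protein.
#' @return List with `query_id`, `annotations` ([residue_annotations()] or
#'   `NULL` when discarded), `used_hit` (the hit or `NULL`).
#' @export
transfer_annotations <- function(hit, target_annotations, query_length) {
  stopifnot(!is.null(hit$pairs))
  pairs <- hit$pairs
  tr <- unclass(target_annotations)
  if (any(pairs[, "t_pos"] < 1L) || any(pairs[, "t_pos"] > nrow(tr)))
    stop("aligned target position out of range for ", hit$target_id)
  if (any(pairs[, "q_pos"] < 1L) || any(pairs[, "q_pos"] > query_length))
    stop("aligned query position out of range for ", hit$query_id)
  aligned_labels <- tr[pairs[, "t_pos"], , drop = FALSE]
  if (!any(aligned_labels))
    return(list(query_id = hit$query_id, annotations = NULL, used_hit = NULL))
  labels <- matrix(FALSE, query_length, 3L,
                   dimnames = list(NULL, ligand_classes()))
  labels[pairs[, "q_pos"], ] <- aligned_labels
  list(query_id = hit$query_id,
       annotations = as_residue_annotations(labels, hit$query_id),
       used_hit = hit)
}

#' Homology-based inference for a set of queries
#'
#' Per query: search the lookup set, select the best hit, transfer
#' annotations. Queries without a surviving hit (no hit under the E-value
#' cutoff, or best hit discarded for lacking binding annotations in the
#' aligned region) get an absent result.
#'
#' @param queries Named character vector of query sequences.
#' @param lookup A [cluster_lookup()] result.
#' @param evalue_cutoff Maximum E-value (default 1e-3).
#' @param exclude_self Drop self-hits (default `TRUE`).
#' @param backend Alignment backend, see [search_lookup()].
#' @return Named list of transfer results (see [transfer_annotations()]);
#'   `annotations` is `NULL` where HBI made no inference.
#' @export
run_hbi <- function(queries, lookup, evalue_cutoff = 1e-3,
                    exclude_self = TRUE, backend = "internal") {
  out <- vector("list", length(queries))
  names(out) <- names(queries)
  for (qid in names(queries)) {
    if (length(lookup$sequences) == 0L) {
      out[[qid]] <- list(query_id = qid, annotations = NULL, used_hit = NULL)
      next
    }
    hits <- search_lookup(qid, queries[[qid]], lookup,
                          evalue_cutoff = evalue_cutoff,
                          exclude_self = exclude_self, backend = backend)
    best <- select_best_hit(hits)
    out[[qid]] <- if (is.null(best))
      list(query_id = qid, annotations = NULL, used_hit = NULL)
    else
      transfer_annotations(best, lookup$annotations[[best$target_id]],
                           nchar(queries[[qid]]))
  }
  out
}
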