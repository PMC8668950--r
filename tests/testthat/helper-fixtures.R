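# Shared fixtures, generated in code (nothing stored on disk).

# small planted-signal dataset for fast training tests
tiny_dataset <- function(n_proteins = 60, seed = 7, signal_strength = 3,
                         length_range = c(50, 100)) {
  generate_dataset(synthetic_spec(n_proteins = n_proteins,
                                  length_range = length_range,
                                  signal_strength = signal_strength,
                                  seed = seed))
}

# random probability matrices + annotations over the same proteins
random_probs_fixture <- function(n_proteins = 8, seed = 11) {
  set.seed(seed)
  probs <- list()
  ann <- list()
  for (i in seq_len(n_proteins)) {
    pid <- sprintf("R%02d", i)
    L <- sample(30:60, 1)
    probs[[pid]] <- matrix(runif(L * 3), L, 3)
    lab <- matrix(runif(L * 3) < 0.08, L, 3)
    ann[[pid]] <- plmbind:::as_residue_annotations(lab, pid)
  }
  list(probs = probs, annotations = ann)
}

# write a minimal annotation TSV
write_ann_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  header <- "protein_id\tligand_class\tpositions\tresolution_angstrom\tmethod"
  writeLines(c(header, rows), path)
  path
}
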