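test_that("dataset generation is deterministic and validated", {
  spec <- synthetic_spec(n_proteins = 10, length_range = c(50, 80), seed = 7)
  d1 <- generate_dataset(spec)
  d2 <- generate_dataset(spec)
  expect_identical(d1$sequences, d2$sequences)
  expect_identical(d1$embeddings, d2$embeddings)
  expect_identical(lapply(d1$annotations, unclass), lapply(d2$annotations, unclass))

  d3 <- generate_dataset(synthetic_spec(n_proteins = 10, seed = 8))
  expect_false(identical(d1$sequences, d3$sequences))

  expect_error(synthetic_spec(binding_prevalence = 0.08, length_range = c(5, 10)),
               "infeasible")
  expect_error(synthetic_spec(class_mix = c(0.5, 0.5, 0.5)), "class_mix")
  expect_error(synthetic_spec(n_proteins = 0), "n_proteins")
})

test_that("realized binding prevalence is close to its target", {
  ds <- generate_dataset(synthetic_spec(n_proteins = 200, seed = 7))
  n_bind <- sum(vapply(ds$annotations, function(a) sum(any_binding(unclass(a))),
                       numeric(1)))
  n_res <- sum(vapply(ds$embeddings, nrow, integer(1)))
  expect_lt(abs(n_bind / n_res - 0.08), 0.02)
})

test_that("planted signal shifts the class-specific embedding coordinates", {
  spec <- synthetic_spec(n_proteins = 20, length_range = c(60, 100),
                         signal_strength = 3, seed = 9)
  ds <- generate_dataset(spec)
  # mean of the METAL block over METAL-binding residues is near the shift
  vals_sig <- c(); vals_bg <- c()
  for (pid in names(ds$embeddings)) {
    lab <- unclass(ds$annotations[[pid]])
    dims <- plmbind:::signal_block(spec, 1L)
    if (any(lab[, 1])) vals_sig <- c(vals_sig, ds$embeddings[[pid]][lab[, 1], dims])
    far <- !any_binding(lab)
    vals_bg <- c(vals_bg, ds$embeddings[[pid]][far, dims])
  }
  expect_gt(mean(vals_sig), 2.5)
  expect_lt(abs(mean(vals_bg)), 0.5)

  # zero strength plants nothing
  ds0 <- generate_dataset(synthetic_spec(n_proteins = 5, signal_strength = 0,
                                         seed = 9))
  all_vals <- unlist(ds0$embeddings)
  expect_lt(abs(mean(all_vals)), 0.01)
})

test_that("family generation respects rates and maintains coordinate maps", {
  fam0 <- generate_family(ancestor_length = 80, n_members = 3,
                          mutation_rate = 0, indel_rate = 0, seed = 5)
  for (m in names(fam0$sequences)) {
    expect_identical(fam0$sequences[[m]], fam0$ancestor)
    expect_identical(fam0$maps[[m]], 1:80)
    expect_identical(unclass(fam0$annotations[[m]]),
                     unclass(fam0$ancestor_annotations), ignore_attr = TRUE)
  }

  # substitutions only: identity maps, labels at identical indices
  fam1 <- generate_family(ancestor_length = 200, n_members = 5,
                          mutation_rate = 0.1, indel_rate = 0, seed = 6)
  for (m in names(fam1$sequences)) {
    expect_identical(fam1$maps[[m]], 1:200)
    expect_identical(which(any_binding(unclass(fam1$annotations[[m]]))),
                     which(any_binding(unclass(fam1$ancestor_annotations))))
  }

  # mean pairwise identity matches the mutation process
  pides <- c()
  ids <- names(fam1$sequences)
  for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
    a <- strsplit(fam1$sequences[[ids[i]]], "")[[1]]
    b <- strsplit(fam1$sequences[[ids[j]]], "")[[1]]
    pides <- c(pides, mean(a == b))
  }
  expect_gte(mean(pides), 0.78)
  expect_lte(mean(pides), 0.95)

  # indels shift downstream coordinates but keep the map consistent
  fam2 <- generate_family(ancestor_length = 100, n_members = 3,
                          mutation_rate = 0.05, indel_rate = 0.05, seed = 8)
  for (m in names(fam2$sequences)) {
    map <- fam2$maps[[m]]
    mapped <- map[!is.na(map)]
    expect_true(all(diff(mapped) >= 1))
    expect_lte(max(mapped), nchar(fam2$sequences[[m]]))
  }

  expect_error(generate_family(mutation_rate = 0.6), "rate")
  expect_error(generate_family(indel_rate = -0.1), "rate")
})

test_that("generated artifacts round-trip through the package readers", {
  ds <- generate_dataset(synthetic_spec(n_proteins = 4, length_range = c(30, 40),
                                        embedding_dim = 64, seed = 13))
  td <- tempfile(); dir.create(td)
  write_fasta(ds$sequences, file.path(td, "seq.fasta"))
  write_embeddings(ds$embeddings, file.path(td, "emb"))
  write_annotations(ds$annotations, file.path(td, "ann.tsv"))

  expect_identical(read_fasta(file.path(td, "seq.fasta")), ds$sequences)
  back_emb <- read_embeddings(file.path(td, "emb"), dim = 64)
  expect_identical(back_emb[names(ds$embeddings)], ds$embeddings)
  back_ann <- read_annotations(file.path(td, "ann.tsv"), sequences = ds$sequences)
  for (pid in names(ds$annotations))
    expect_identical(unclass(back_ann[[pid]]), unclass(ds$annotations[[pid]]),
                     ignore_attr = TRUE)
})
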