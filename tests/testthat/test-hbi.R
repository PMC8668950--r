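make_lookup <- function(sequences, annotations = NULL, cluster = FALSE) {
  if (is.null(annotations))
    annotations <- lapply(names(sequences), function(pid)
      residue_annotations(pid, nchar(sequences[[pid]])))
  names(annotations) <- names(sequences)
  cluster_lookup(sequences, annotations, cluster = cluster)
}

test_that("local alignment of identical sequences has PIDE 1 and identity pairs", {
  set.seed(61)
  s <- plmbind:::random_sequence(80)
  al <- align_local(s, s)
  expect_equal(al$pide, 1)
  expect_identical(al$pairs[, "q_pos"], al$pairs[, "t_pos"])
  expect_identical(nrow(al$pairs), 80L)
})

test_that("greedy clustering keeps one representative per similar group", {
  set.seed(62)
  s <- plmbind:::random_sequence(100)
  ann <- list(A = residue_annotations("A", 100), B = residue_annotations("B", 100))
  lk <- cluster_lookup(c(A = s, B = s), ann)
  expect_length(lk$sequences, 1L)

  u <- plmbind:::random_sequence(100)
  ann2 <- list(A = residue_annotations("A", 100), B = residue_annotations("B", 100))
  lk2 <- cluster_lookup(c(A = s, B = u), ann2)
  expect_length(lk2$sequences, 2L)

  # unreachable threshold: nothing can join, all become representatives
  lk3 <- cluster_lookup(c(A = s, B = s), ann, pide_threshold = 1.01)
  expect_length(lk3$sequences, 2L)

  expect_error(cluster_lookup(character(0), list()), "empty")
})

test_that("search finds identical entries and honours self-hit exclusion", {
  set.seed(63)
  s <- plmbind:::random_sequence(90)
  lk <- make_lookup(c(T1 = s))
  hits <- search_lookup("Q1", s, lk, exclude_self = FALSE)
  expect_length(hits, 1L)
  expect_equal(hits[[1]]$pide, 1.0)
  expect_lt(hits[[1]]$evalue, 1e-10)

  # same sequence under the same ID: excluded as a self-hit
  hits_self <- search_lookup("T1", s, lk, exclude_self = TRUE)
  expect_length(hits_self, 0L)
  hits_kept <- search_lookup("T1", s, lk, exclude_self = FALSE)
  expect_length(hits_kept, 1L)

  # unrelated random queries stay far above the cutoff
  for (i in 1:5) {
    q <- plmbind:::random_sequence(90)
    expect_length(search_lookup("QR", q, lk, evalue_cutoff = 1e-3), 0L)
  }
})

test_that("the mmseqs2 backend refuses to run silently without the binary", {
  skip_if(Sys.which("mmseqs") != "", "mmseqs2 happens to be installed")
  lk <- make_lookup(c(T1 = plmbind:::random_sequence(50)))
  expect_error(search_lookup("Q", "MKVLA", lk, backend = "mmseqs2"), "mmseqs")
})

test_that("best-hit selection orders by E-value, then PIDE, then target ID", {
  h <- function(t, e, p) list(query_id = "Q", target_id = t, evalue = e,
                              pide = p, pairs = cbind(q_pos = 1L, t_pos = 1L))
  expect_identical(select_best_hit(list(h("A", 1e-10, 0.4),
                                        h("B", 1e-5, 0.9)))$target_id, "A")
  expect_identical(select_best_hit(list(h("A", 1e-5, 0.6),
                                        h("B", 1e-5, 0.8)))$target_id, "B")
  expect_identical(select_best_hit(list(h("B", 1e-5, 0.8),
                                        h("A", 1e-5, 0.8)))$target_id, "A")
  expect_null(select_best_hit(list()))
})

test_that("annotation transfer maps labels through aligned pairs only", {
  # identity alignment of an equal-length pair copies the annotations
  tann <- residue_annotations("T", 30, list(METAL = c(5, 6), SMALL = 20))
  hit <- list(query_id = "Q", target_id = "T", evalue = 1e-20, pide = 1,
              pairs = cbind(q_pos = 1:30, t_pos = 1:30))
  res <- transfer_annotations(hit, tann, 30)
  expect_identical(unclass(res$annotations), unclass(tann),
                   ignore_attr = TRUE)
  expect_equal(attr(res$annotations, "protein_id"), "Q")

  # binding outside the aligned region: hit discarded
  hit2 <- list(query_id = "Q", target_id = "T", evalue = 1e-20, pide = 1,
               pairs = cbind(q_pos = 1:10, t_pos = 11:20))
  tann2 <- residue_annotations("T", 30, list(METAL = 5))
  res2 <- transfer_annotations(hit2, tann2, 10)
  expect_null(res2$annotations)
  expect_null(res2$used_hit)

  # a single aligned pair carries exactly one label across
  hit3 <- list(query_id = "Q", target_id = "T", evalue = 1e-20, pide = 1,
               pairs = cbind(q_pos = 7L, t_pos = 12L))
  tann3 <- residue_annotations("T", 20, list(METAL = 12))
  res3 <- transfer_annotations(hit3, tann3, 15)
  expect_identical(which(res3$annotations[, "METAL"]), 7L)
  expect_identical(sum(res3$annotations), 1L)

  expect_error(transfer_annotations(hit3, residue_annotations("T", 5), 15),
               "range")
})

test_that("transfer never plants more labels than the aligned target carries", {
  set.seed(64)
  for (i in 1:20) {
    Lq <- sample(20:40, 1); Lt <- sample(20:40, 1)
    n_pairs <- sample(5:15, 1)
    qp <- sort(sample(Lq, n_pairs)); tp <- sort(sample(Lt, n_pairs))
    tann <- plmbind:::as_residue_annotations(
      matrix(runif(Lt * 3) < 0.15, Lt, 3), "T")
    hit <- list(query_id = "Q", target_id = "T", evalue = 1e-9, pide = 0.9,
                pairs = cbind(q_pos = qp, t_pos = tp))
    res <- transfer_annotations(hit, tann, Lq)
    n_aligned_labels <- sum(unclass(tann)[tp, ])
    if (is.null(res$annotations)) {
      expect_identical(n_aligned_labels, 0L)
    } else {
      expect_identical(sum(res$annotations), n_aligned_labels)
      expect_true(all(which(any_binding(unclass(res$annotations))) %in% qp))
    }
  }
})

test_that("homology transfer recovers planted family annotations", {
  fam <- generate_family(ancestor_length = 120, n_members = 5,
                         mutation_rate = 0.1, indel_rate = 0, seed = 17)
  ids <- names(fam$sequences)
  recovered <- 0L; total <- 0L
  for (qid in ids) {
    lk <- cluster_lookup(fam$sequences[setdiff(ids, qid)],
                         fam$annotations[setdiff(ids, qid)], cluster = FALSE)
    res <- run_hbi(fam$sequences[qid], lk)[[qid]]
    truth <- unclass(fam$annotations[[qid]])
    total <- total + sum(truth)
    if (!is.null(res$annotations))
      recovered <- recovered + sum(unclass(res$annotations) & truth)
  }
  expect_gte(recovered / total, 0.9)
})

test_that("run_hbi handles identical homologs, empty lookups and E-value monotonicity", {
  set.seed(65)
  s <- plmbind:::random_sequence(100)
  ann <- list(T1 = residue_annotations("T1", 100, list(NUCLEIC = c(10, 11, 50))))
  lk <- cluster_lookup(c(T1 = s), ann)
  res <- run_hbi(c(Q1 = s), lk)
  expect_identical(which(res$Q1$annotations[, "NUCLEIC"]), c(10L, 11L, 50L))

  empty_lk <- structure(list(sequences = character(0), annotations = list(),
                             clustered = FALSE, pide_threshold = 0.95,
                             db_size = 0L), class = "lookup_set")
  res0 <- run_hbi(c(Q1 = s), empty_lk)
  expect_null(res0$Q1$annotations)

  # raising the cutoff never loses queries with a result
  queries <- c(Q1 = s,
               Q2 = plmbind:::random_sequence(100),
               Q3 = paste0(substr(s, 1, 60), plmbind:::random_sequence(40)))
  n_results <- sapply(c(1e-10, 1e-3, 1, 100), function(ct) {
    r <- run_hbi(queries, lk, evalue_cutoff = ct)
    sum(!sapply(r, function(x) is.null(x$annotations)))
  })
  expect_true(all(diff(n_results) >= 0))
})
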