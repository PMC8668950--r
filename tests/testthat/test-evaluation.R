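naive_metrics <- function(tp, fp, tn, fn) {
  # independent re-derivation used as the oracle for binding_metrics()
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  r <- div(tp, tp + fn); p <- div(tp, tp + fp)
  f1 <- if (is.na(r) || is.na(p) || r + p == 0) NA_real_ else 2 * r * p / (r + p)
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (den == 0) NA_real_ else (tp * tn - fp * fn) / den
  nr <- div(tn, tn + fp); np <- div(tn, tn + fn)
  nf1 <- if (is.na(nr) || is.na(np) || nr + np == 0) NA_real_ else
    2 * nr * np / (nr + np)
  c(recall = r, precision = p, f1 = f1, mcc = mcc,
    neg_recall = nr, neg_precision = np, neg_f1 = nf1)
}

test_that("confusion counting matches a brute-force per-residue comparison", {
  truth <- residue_annotations("P1", 100, list(METAL = 1:9))
  calls <- matrix(FALSE, 100, 3, dimnames = list(NULL, ligand_classes()))
  calls[c(1, 2, 3, 10), "METAL"] <- TRUE
  cc <- confusion_counts(calls, truth, "METAL")
  expect_identical(unclass(cc), c(TP = 3L, FP = 1L, TN = 90L, FN = 6L))
  expect_identical(sum(cc), 100L)

  # perfect agreement and total miss
  cc2 <- confusion_counts(unclass(truth), truth, "ANY")
  expect_identical(unname(unclass(cc2)[c("FP", "FN")]), c(0L, 0L))
  cc3 <- confusion_counts(matrix(FALSE, 100, 3), truth, "ANY")
  expect_identical(unname(unclass(cc3)[c("TP", "FN")]), c(0L, 9L))

  # ANY compares the row-wise OR of both sides
  truth2 <- residue_annotations("P2", 10, list(METAL = 1, SMALL = 2))
  calls2 <- matrix(FALSE, 10, 3, dimnames = list(NULL, ligand_classes()))
  calls2[1, "SMALL"] <- TRUE  # wrong class, right residue
  expect_identical(unclass(confusion_counts(calls2, truth2, "ANY"))[["TP"]], 1L)
  expect_identical(unclass(confusion_counts(calls2, truth2, "SMALL"))[["TP"]], 0L)

  expect_error(confusion_counts(matrix(FALSE, 5, 3), truth, "ANY"), "length")
})

test_that("metric formulas reproduce frozen exact-arithmetic values", {
  m <- binding_metrics(c(TP = 3, FP = 1, TN = 90, FN = 6))
  expect_equal(m[["precision"]], 3 / 4)
  expect_equal(m[["recall"]], 1 / 3)
  expect_equal(m[["f1"]], 6 / 13)            # = 0.4615...
  expect_equal(m[["mcc"]], 264 / sqrt(314496), tolerance = 1e-12)  # ~0.4708
  expect_equal(m[["neg_precision"]], 90 / 96)
  expect_equal(m[["neg_recall"]], 90 / 91)
})

test_that("undefined denominators follow the exclude/zero policies", {
  # all residues truly binding and called: no negatives anywhere
  m <- binding_metrics(c(TP = 50, FP = 0, TN = 0, FN = 0))
  expect_equal(m[["precision"]], 1)
  expect_equal(m[["recall"]], 1)
  expect_equal(m[["f1"]], 1)
  expect_true(is.na(m[["mcc"]]))
  mz <- binding_metrics(c(TP = 50, FP = 0, TN = 0, FN = 0), undefined = "zero")
  expect_equal(mz[["mcc"]], 0)

  # annotated but nothing predicted: precision undefined, recall zero
  m2 <- binding_metrics(c(TP = 0, FP = 0, TN = 40, FN = 5))
  expect_true(is.na(m2[["precision"]]))
  expect_equal(m2[["recall"]], 0)

  expect_error(binding_metrics(c(TP = -1, FP = 0, TN = 0, FN = 0)), "negative")
})

test_that("metrics agree with an independent evaluation on random counts", {
  set.seed(42)
  for (i in 1:1000) {
    cts <- as.numeric(rmultinom(1, sample(1:500, 1), runif(4)))
    mine <- binding_metrics(c(TP = cts[1], FP = cts[2], TN = cts[3], FN = cts[4]))
    ref <- naive_metrics(cts[1], cts[2], cts[3], cts[4])
    expect_equal(mine, ref, tolerance = 1e-12)
    # F1 identity with the counts form
    if (!is.na(mine[["f1"]]))
      expect_equal(mine[["f1"]], 2 * cts[1] / (2 * cts[1] + cts[2] + cts[4]),
                   tolerance = 1e-12)
    if (!is.na(mine[["mcc"]]))
      expect_true(mine[["mcc"]] >= -1 && mine[["mcc"]] <= 1)
  }
})

test_that("MCC is 1 exactly for a perfect split with both classes present", {
  expect_equal(binding_metrics(c(TP = 8, FP = 0, TN = 92, FN = 0))[["mcc"]], 1)
  expect_true(binding_metrics(c(TP = 8, FP = 1, TN = 91, FN = 0))[["mcc"]] < 1)
})

test_that("coverage measures count proteins as defined", {
  mk_calls <- function(L, pos = integer(0), class = "METAL") {
    m <- matrix(FALSE, L, 3, dimnames = list(NULL, ligand_classes()))
    m[pos, class] <- TRUE
    m
  }
  ann <- list(A = residue_annotations("A", 10, list(METAL = 1)),
              B = residue_annotations("B", 10, list(METAL = 2)),
              C = residue_annotations("C", 10, list(NUCLEIC = 3)),
              D = residue_annotations("D", 10, list(SMALL = 4)))
  preds <- list(A = mk_calls(10, 5), B = mk_calls(10), C = mk_calls(10, 1),
                D = mk_calls(10))

  # 4 annotated (ANY), 2 with a call
  expect_equal(cov_one_bind(preds, ann, "ANY"), 0.5)
  # all or none predicted
  all_pred <- lapply(ann, function(a) unclass(a))
  expect_equal(cov_one_bind(all_pred, ann, "ANY"), 1.0)
  none <- lapply(ann, function(a) unclass(a) & FALSE)
  expect_equal(cov_one_bind(none, ann, "ANY"), 0.0)

  # 2 proteins lack METAL annotations (C, D); C got a METAL call -> 1/2
  expect_equal(cov_no_bind(preds, ann, "METAL"), 0.5)
  # 3 lack NUCLEIC annotations, none called NUCLEIC -> 1
  expect_equal(cov_no_bind(preds, ann, "NUCLEIC"), 1.0)
  # every protein annotated for ANY-class METAL? no: undefined case
  ann_all_metal <- list(A = residue_annotations("A", 5, list(METAL = 1)),
                        B = residue_annotations("B", 5, list(METAL = 2)))
  expect_true(is.na(cov_no_bind(preds[1:2], ann_all_metal, "METAL")))

  expect_error(cov_one_bind(list(), ann), "empty")
})

test_that("per-protein summaries match closed forms and ignore protein order", {
  vals <- rep(c(0, 1), each = 50)
  s <- summarize_metric(vals)
  expect_equal(s$mean, 0.5)
  expect_equal(s$ci95, 1.96 * sd(vals) / 10, tolerance = 1e-12)  # ~0.0985
  expect_equal(s$ci95, 0.09849, tolerance = 1e-3)

  expect_equal(summarize_metric(rep(0.3, 10))$ci95, 0)
  expect_error(summarize_metric(1), "at least 2")

  b1 <- summarize_metric(vals, method = "bootstrap", n_boot = 2000, seed = 1)
  b2 <- summarize_metric(vals, method = "bootstrap", n_boot = 2000, seed = 2)
  expect_lt(abs(b1$ci95 - b2$ci95) / b1$ci95, 0.10)
  # bootstrap and normal agree closely here
  expect_equal(b1$ci95, s$ci95, tolerance = 0.1)

  fx <- random_probs_fixture(6)
  calls <- lapply(fx$probs, function(p) binarize(p)$calls)
  e1 <- evaluate_predictions(calls, fx$annotations)
  perm <- sample(names(calls))
  e2 <- evaluate_predictions(calls[perm], fx$annotations)
  expect_equal(e1$summary, e2$summary)
  expect_equal(e1$cov_one_bind, e2$cov_one_bind)
})

test_that("pooled aggregation sums counts before computing metrics", {
  fx <- random_probs_fixture(5, seed = 21)
  calls <- lapply(fx$probs, function(p) binarize(p)$calls)
  pooled <- evaluate_predictions(calls, fx$annotations, aggregate = "pooled")
  total <- Reduce(`+`, lapply(names(calls), function(pid)
    unclass(confusion_counts(calls[[pid]], fx$annotations[[pid]], "ANY"))))
  expect_identical(unname(pooled$counts), unname(total))
  expect_equal(pooled$metrics, binding_metrics(total))
})
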