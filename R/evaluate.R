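# Per-protein evaluation framework: confusion counting, the derived
# statistics (recall, precision, F1, MCC and their negative-class
# analogues), coverage measures, and normal / bootstrap confidence
# intervals. Every statistic is computed per protein and then averaged;
# residue-pooled aggregation is available but is not the headline mode.

#' Per-protein confusion counts
#'
#' Counts true/false positives/negatives over the residues of one protein
#' for a selected ligand class, or for `"ANY"` where the row-wise OR of the
#' three classes is compared on both sides (binding vs. non-binding,
#' ignoring which ligand).
#'
#' @param calls Logical `L x 3` call matrix (or logical vector for ANY-style
#'   inputs).
#' @param truth [residue_annotations()] matrix of the same protein.
#' @param class One of `"METAL"`, `"NUCLEIC"`, `"SMALL"`, `"ANY"`.
#' @return Object of class `"confusion_counts"`: named integer vector with
#'   `TP`, `FP`, `TN`, `FN` (summing to L).
#' @export
confusion_counts <- function(calls, truth, class = "ANY") {
  class <- match.arg(class, c(ligand_classes(), "ANY"))
  truth_m <- unclass(truth)
  if (is.matrix(calls)) {
    if (nrow(calls) != nrow(truth_m))
      stop("calls and truth have different lengths (",
           nrow(calls), " vs ", nrow(truth_m), ")")
    pred <- if (class == "ANY") rowSums(calls) > 0L else calls[, class]
  } else {
    if (length(calls) != nrow(truth_m))
      stop("calls and truth have different lengths")
    pred <- as.logical(calls)
  }
  obs <- if (class == "ANY") rowSums(truth_m) > 0L else truth_m[, class]
  structure(c(TP = sum(pred & obs), FP = sum(pred & !obs),
              TN = sum(!pred & !obs), FN = sum(!pred & obs)),
            class = "confusion_counts")
}

#' Performance metrics from confusion counts
#'
#' Evaluates recall `TP/(TP+FN)`, precision `TP/(TP+FP)`,
#' F1 (harmonic mean of the two), MCC
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, and the
#' negative-class analogues: negative recall `TN/(TN+FP)` (specificity),
#' negative precision `TN/(TN+FN)` (NPV), and negative F1.
#'
#' A metric whose denominator is zero is undefined. With
#' `undefined = "exclude"` it is reported as `NA` (to be dropped at
#' aggregation, the convention when restricting to proteins with at least
#' one prediction); with `undefined = "zero"` it is set to 0 (the
#' convention under which a protein annotated but not predicted to bind
#' scores zero precision).
#'
#' @param counts A [confusion_counts()] (or named vector with TP/FP/TN/FN).
#' @param undefined `"exclude"` (NA) or `"zero"` for undefined metrics.
#' @return Named numeric vector: `recall`, `precision`, `f1`, `mcc`,
#'   `neg_recall`, `neg_precision`, `neg_f1`.
#' @export
#' @examples
#' binding_metrics(c(TP = 3, FP = 1, TN = 90, FN = 6))
binding_metrics <- function(counts, undefined = c("exclude", "zero")) {
  undefined <- match.arg(undefined)
  tp <- as.numeric(counts[["TP"]]); fp <- as.numeric(counts[["FP"]])
  tn <- as.numeric(counts[["TN"]]); fn <- as.numeric(counts[["FN"]])
  if (any(c(tp, fp, tn, fn) < 0)) stop("negative confusion counts")
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  recall <- frac(tp, tp + fn)
  precision <- frac(tp, tp + fp)
  f1 <- if (!is.na(recall) && !is.na(precision) && (recall + precision) > 0)
    2 * recall * precision / (recall + precision)
  else NA_real_
  mcc_den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (mcc_den > 0) (tp * tn - fp * fn) / sqrt(mcc_den) else NA_real_
  neg_recall <- frac(tn, tn + fp)
  neg_precision <- frac(tn, tn + fn)
  neg_f1 <- if (!is.na(neg_recall) && !is.na(neg_precision) &&
                (neg_recall + neg_precision) > 0)
    2 * neg_recall * neg_precision / (neg_recall + neg_precision)
  else NA_real_
  out <- c(recall = recall, precision = precision, f1 = f1, mcc = mcc,
           neg_recall = neg_recall, neg_precision = neg_precision,
           neg_f1 = neg_f1)
  if (undefined == "zero") out[is.na(out)] <- 0
  out
}

# extract the call matrix from a binding_prediction or pass a matrix through
calls_of <- function(x) {
  if (inherits(x, "binding_prediction")) x$calls else x
}

#' Fraction of proteins with at least one binding prediction
#'
#' Among the proteins carrying binding annotations for the assessed scope,
#' the fraction for which at least one residue is called binding
#' (`CovOneBind`). High values mean the method ventures a prediction for
#' almost every annotated protein.
#'
#' @param predictions Named list of [binding_prediction()] objects or call
#'   matrices.
#' @param annotations Named list of [residue_annotations()].
#' @param class Ligand class or `"ANY"`.
#' @return Fraction in `[0, 1]`.
#' @export
cov_one_bind <- function(predictions, annotations, class = "ANY") {
  class <- match.arg(class, c(ligand_classes(), "ANY"))
  if (length(predictions) == 0L) stop("empty prediction set")
  ids <- names(predictions)
  stopifnot(all(ids %in% names(annotations)))
  has_ann <- vapply(ids, function(pid) {
    tr <- unclass(annotations[[pid]])
    if (class == "ANY") any(tr) else any(tr[, class])
  }, logical(1))
  if (!any(has_ann)) stop("no protein carries annotations for scope ", class)
  has_pred <- vapply(ids, function(pid) {
    cl <- calls_of(predictions[[pid]])
    if (class == "ANY") any(cl) else any(cl[, class])
  }, logical(1))
  sum(has_pred & has_ann) / sum(has_ann)
}

#' Fraction of un-annotated proteins left without a prediction
#'
#' Among the proteins with no binding annotation for ligand class `class`,
#' the fraction for which the method also predicts no residue of that class
#' (`CovNoBind`). The complement of over-prediction for that class.
#'
#' @inheritParams cov_one_bind
#' @param class Ligand class (class-specific by construction).
#' @return Fraction in `[0, 1]`, or `NA` when every protein carries
#'   annotations for `class` (the measure is then undefined).
#' @export
cov_no_bind <- function(predictions, annotations, class) {
  class <- match.arg(class, ligand_classes())
  ids <- names(predictions)
  stopifnot(length(ids) > 0L, all(ids %in% names(annotations)))
  no_ann <- vapply(ids, function(pid)
    !any(unclass(annotations[[pid]])[, class]), logical(1))
  if (!any(no_ann)) return(NA_real_)
  no_pred <- vapply(ids, function(pid)
    !any(calls_of(predictions[[pid]])[, class]), logical(1))
  sum(no_pred & no_ann) / sum(no_ann)
}

#' Mean and 95% confidence interval of per-protein metric values
#'
#' Either a symmetric normal-approximation interval
#' (`mean +/- 1.96 * sd / sqrt(n)`) or a seeded bootstrap percentile
#' interval reported as the half-width of its wider side.
#'
#' @param values Numeric vector of per-protein metric values (`NA` allowed;
#'   dropped before summarizing).
#' @param method `"normal"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples.
#' @param seed Seed for the bootstrap resampling.
#' @return List with `mean`, `ci95` (half-width), `n`, `method`.
#' @export
#' @examples
#' summarize_metric(rep(c(0, 1), each = 50))
summarize_metric <- function(values, method = c("normal", "bootstrap"),
                             n_boot = 10000L, seed = 1L) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    stop("need at least 2 defined values to summarize")
  m <- mean(values)
  if (method == "normal") {
    half <- 1.96 * sd(values) / sqrt(length(values))
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    boots <- vapply(seq_len(n_boot), function(i)
      mean(values[sample.int(length(values), replace = TRUE)]), numeric(1))
    q <- quantile(boots, c(0.025, 0.975), names = FALSE, type = 7)
    half <- max(m - q[1L], q[2L] - m)
  }
  list(mean = m, ci95 = half, n = length(values), method = method)
}

#' Evaluate predictions against annotations
#'
#' The headline evaluation: every metric is computed per protein and then
#' averaged over proteins, with a 95% confidence interval. Coverage
#' measures ([cov_one_bind()], [cov_no_bind()]) are computed over the
#' protein set. Residue-pooled aggregation (summing confusion counts over
#' all proteins before computing metrics) is available via
#' `aggregate = "pooled"` for cumulative-curve style numbers; note the
#' per-protein average is the reference mode.
#'
#' @param predictions Named list of [binding_prediction()] objects or
#'   logical call matrices.
#' @param annotations Named list of [residue_annotations()] covering the
#'   same proteins.
#' @param scope Ligand class or `"ANY"`.
#' @param undefined Policy for undefined per-protein metrics, see
#'   [binding_metrics()].
#' @param aggregate `"per_protein"` (mean over proteins) or `"pooled"`.
#' @param ci `"normal"` or `"bootstrap"` confidence intervals.
#' @param n_boot,seed Bootstrap settings.
#' @return For `"per_protein"`: list with `summary` (data.frame of metric,
#'   mean, ci95, n), `per_protein` (matrix of per-protein values),
#'   `cov_one_bind`, `cov_no_bind` (per class, scope permitting),
#'   `n_proteins`. For `"pooled"`: list with pooled `metrics`, total
#'   `counts`, coverage measures and `n_proteins`.
#' @export
evaluate_predictions <- function(predictions, annotations, scope = "ANY",
                                 undefined = c("exclude", "zero"),
                                 aggregate = c("per_protein", "pooled"),
                                 ci = c("normal", "bootstrap"),
                                 n_boot = 10000L, seed = 1L) {
  undefined <- match.arg(undefined)
  aggregate <- match.arg(aggregate)
  ci <- match.arg(ci)
  scope <- match.arg(scope, c(ligand_classes(), "ANY"))
  ids <- names(predictions)
  if (length(ids) == 0L) stop("empty prediction set")
  if (!all(ids %in% names(annotations)))
    stop("annotations missing for: ",
         paste(setdiff(ids, names(annotations)), collapse = ", "))

  counts <- lapply(ids, function(pid)
    confusion_counts(calls_of(predictions[[pid]]), annotations[[pid]], scope))
  names(counts) <- ids

  cnb <- vapply(ligand_classes(), function(cl)
    cov_no_bind(predictions, annotations, cl), numeric(1))
  cob <- cov_one_bind(predictions, annotations, scope)

  if (aggregate == "pooled") {
    total <- Reduce(`+`, lapply(counts, unclass))
    return(list(metrics = binding_metrics(total, undefined = undefined),
                counts = total, cov_one_bind = cob, cov_no_bind = cnb,
                n_proteins = length(ids)))
  }

  per <- t(vapply(counts, binding_metrics, numeric(7), undefined = undefined))
  summ <- do.call(rbind, lapply(colnames(per), function(metric) {
    vals <- per[, metric]
    if (sum(!is.na(vals)) >= 2L) {
      s <- summarize_metric(vals, method = ci, n_boot = n_boot, seed = seed)
      data.frame(metric = metric, mean = s$mean, ci95 = s$ci95, n = s$n)
    } else {
      data.frame(metric = metric, mean = mean(vals, na.rm = TRUE),
                 ci95 = NA_real_, n = sum(!is.na(vals)))
    }
  }))
  list(summary = summ, per_protein = per, cov_one_bind = cob,
       cov_no_bind = cnb, n_proteins = length(ids))
}

#' Chance-level F1 by label permutation
#'
#' Estimates the F1 a predictor would reach by chance agreement alone:
#' the planted/observed labels are permuted within each protein and the
#' (any-class, residue-pooled) F1 of the unchanged calls against the
#' permuted truth is averaged over permutations. Used as the reference
#' a trained model must beat.
#'
#' @param predictions Named list of predictions or call matrices.
#' @param annotations Named list of [residue_annotations()].
#' @param n_perm Number of permutations.
#' @param seed Seed for the permutations.
#' @return Mean pooled any-class F1 over permutations.
#' @export
permutation_baseline <- function(predictions, annotations, n_perm = 20L,
                                 seed = 1L) {
  ids <- names(predictions)
  stopifnot(length(ids) > 0L, all(ids %in% names(annotations)))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  f1s <- vapply(seq_len(n_perm), function(i) {
    total <- c(TP = 0, FP = 0, TN = 0, FN = 0)
    for (pid in ids) {
      tr <- unclass(annotations[[pid]])
      perm <- tr[sample.int(nrow(tr)), , drop = FALSE]
      total <- total + unclass(confusion_counts(calls_of(predictions[[pid]]),
                                                as_residue_annotations(perm, pid),
                                                "ANY"))
    }
    m <- binding_metrics(total, undefined = "zero")
    m[["f1"]]
  }, numeric(1))
  mean(f1s)
}

#' Residue-pooled any-class F1 of predictions against annotations
#'
#' Convenience wrapper: sums confusion counts over all proteins (scope ANY)
#' and returns the pooled F1. Undefined (nothing predicted and nothing
#' annotated) returns 0.
#'
#' @inheritParams permutation_baseline
#' @return Pooled F1 in `[0, 1]`.
#' @export
pooled_f1 <- function(predictions, annotations) {
  ids <- names(predictions)
  total <- Reduce(`+`, lapply(ids, function(pid)
    unclass(confusion_counts(calls_of(predictions[[pid]]),
                             annotations[[pid]], "ANY"))))
  binding_metrics(total, undefined = "zero")[["f1"]]
}
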