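#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a uniformly chosen positive outranks a uniformly
#' chosen negative, with ties counted half:
#' `(#concordant + 0.5 #tied) / (P * N)`.
#'
#' @param scores Numeric vector of predicted scores.
#' @param labels Binary vector (0/1) of the same length.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  check_metric_input(scores, labels)
  P <- sum(labels == 1)
  N <- sum(labels == 0)
  if (P == 0 || N == 0) {
    stop("AUC undefined: need at least one positive and one negative",
         call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - P * (P + 1) / 2) / (P * N)
}

#' Area under the precision-recall step curve
#'
#' Descending-score sweep with tied scores processed as one block;
#' the area is the sum over thresholds of
#' `(recall_t - recall_{t-1}) * precision_t`.
#'
#' @inheritParams auc_score
#' @return AUPR in \[0, 1\].
#' @export
aupr_score <- function(scores, labels) {
  check_metric_input(scores, labels)
  P <- sum(labels == 1)
  if (P == 0) stop("AUPR undefined: no positive labels", call. = FALSE)
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  # block boundaries: last index of each run of equal scores
  last_of_block <- which(c(s[-length(s)] != s[-1L], TRUE))
  tp <- cumsum(y)[last_of_block]
  n_seen <- last_of_block
  recall <- tp / P
  precision <- tp / n_seen
  sum(diff(c(0, recall)) * precision)
}

#' R-precision
#'
#' Fraction of true positives among the top-P scored items, where P is the
#' number of positives; a threshold-free operating point. Ties are broken
#' by stable input order.
#'
#' @inheritParams auc_score
#' @return Precision in \[0, 1\].
#' @export
precision_at_r <- function(scores, labels) {
  check_metric_input(scores, labels)
  P <- sum(labels == 1)
  if (P == 0) stop("R-precision undefined: no positive labels", call. = FALSE)
  ord <- order(-scores, seq_along(scores))
  mean(labels[ord[seq_len(P)]])
}

check_metric_input <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) {
    stop("labels must be binary", call. = FALSE)
  }
}

#' Random partition of positive cells into cross-validation folds
#'
#' @param positives Vector of positive-cell indices.
#' @param n_folds Number of folds (default 10).
#' @param seed Integer seed.
#' @return List of `n_folds` disjoint index vectors covering `positives`,
#'   sizes differing by at most 1.
#' @export
make_cv_folds <- function(positives, n_folds = 10L, seed = 1L) {
  if (length(positives) < n_folds) {
    stop("fewer positives than folds", call. = FALSE)
  }
  local_rng(seed)
  shuffled <- positives[sample.int(length(positives))]
  split(shuffled, rep_len(seq_len(n_folds), length(shuffled)))
}

new_eval_report <- function(auc, aupr, precision, per_fold = NULL,
                            n_test_positives, n_candidates) {
  structure(
    list(auc = auc, aupr = aupr, precision = precision,
         per_fold = per_fold, n_test_positives = n_test_positives,
         n_candidates = n_candidates),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("eval_report: AUC %.4f | AUPR %.4f | precision %.4f\n",
              x$auc, x$aupr, x$precision))
  cat(sprintf("  %d test positives, %d scored candidates%s\n",
              x$n_test_positives, x$n_candidates,
              if (!is.null(x$per_fold)) {
                sprintf(", %d folds", nrow(x$per_fold))
              } else ""))
  invisible(x)
}

#' 10-fold cross-validation over known associations
#'
#' Positive cells are randomly partitioned into folds. For each fold the
#' fold's positives are zeroed in the training matrix, the pipeline is
#' rerun, and the fold is scored with label 1 on its held-out cells and 0
#' on every cell that is zero in the *original* matrix (training positives
#' of other folds are never scored). Aggregate metrics are the mean over
#' folds.
#'
#' @param bundle A `dda_bundle`.
#' @param params A [dnmf_params()].
#' @param n_folds Number of folds.
#' @param seed Seed controlling the fold assignment and the per-fold fits.
#' @inheritParams predict_ddas
#' @return An `eval_report` with a `per_fold` data frame.
#' @export
run_cv10 <- function(bundle, params = dnmf_params(), n_folds = 10L,
                     seed = 1L, use_knn = TRUE, use_pretrain = TRUE,
                     drug_sims = NULL, disease_sims = NULL) {
  A <- bundle$association
  positives <- which(A == 1)
  zeros <- which(A == 0)
  folds <- make_cv_folds(positives, n_folds, seed)
  per_fold <- lapply(seq_along(folds), function(f) {
    test_cells <- folds[[f]]
    train <- A
    train[test_cells] <- 0
    stopifnot(all(train[test_cells] == 0))  # leakage guard
    masked <- bundle
    masked$association <- train
    p <- params
    p$seed <- params$seed + 10L * f
    scores <- predict_ddas(masked, p, use_knn = use_knn,
                           use_pretrain = use_pretrain,
                           drug_sims = drug_sims,
                           disease_sims = disease_sims)
    cand <- c(test_cells, zeros)
    stopifnot(!any(train[cand] == 1))  # candidates never include training 1s
    y <- c(rep(1, length(test_cells)), rep(0, length(zeros)))
    s <- scores[cand]
    data.frame(fold = f, auc = auc_score(s, y), aupr = aupr_score(s, y),
               precision = precision_at_r(s, y))
  })
  per_fold <- do.call(rbind, per_fold)
  new_eval_report(
    auc = mean(per_fold$auc), aupr = mean(per_fold$aupr),
    precision = mean(per_fold$precision), per_fold = per_fold,
    n_test_positives = length(positives),
    n_candidates = length(zeros) + ceiling(length(positives) / n_folds)
  )
}

#' Cold-start evaluation on single-association drugs
#'
#' Every drug with exactly one known association is in turn treated as a
#' novel drug: its single positive is removed (leaving an all-zero row,
#' which exercises the KNN fill), the pipeline is rerun, and that drug's
#' score row is recorded with label 1 on the held-out disease and 0 on the
#' drug's original-zero cells. The per-drug rows are pooled into one list
#' and the metrics computed on the pool (a per-drug AUC is undefined with
#' a single positive). When the bundle contains drug similarities whose
#' names contain `ddi` or `se` (interaction- and side-effect-derived,
#' unavailable for truly novel drugs) they are excluded by default.
#'
#' @inheritParams run_cv10
#' @return An `eval_report` (no `per_fold`).
#' @export
run_coldstart <- function(bundle, params = dnmf_params(), seed = 1L,
                          use_knn = TRUE, use_pretrain = TRUE,
                          drug_sims = NULL, disease_sims = NULL) {
  A <- bundle$association
  targets <- which(rowSums(A) == 1)
  if (!length(targets)) {
    stop("no drug has exactly one known association", call. = FALSE)
  }
  if (is.null(drug_sims)) {
    legal <- !grepl("(^|_)(ddi|se)($|_)", names(bundle$drug_sims),
                    ignore.case = TRUE)
    if (any(legal) && !all(legal)) drug_sims <- names(bundle$drug_sims)[legal]
  }
  pooled_s <- numeric()
  pooled_y <- numeric()
  for (idx in seq_along(targets)) {
    d <- targets[[idx]]
    held_out <- which(A[d, ] == 1)
    train <- A
    train[d, held_out] <- 0
    stopifnot(all(train[d, ] == 0))  # leakage guard: row fully masked
    masked <- bundle
    masked$association <- train
    p <- params
    p$seed <- params$seed + 10L * idx
    scores <- predict_ddas(masked, p, use_knn = use_knn,
                           use_pretrain = use_pretrain,
                           drug_sims = drug_sims,
                           disease_sims = disease_sims)
    cand <- c(held_out, which(A[d, ] == 0))
    pooled_s <- c(pooled_s, scores[d, cand])
    pooled_y <- c(pooled_y, c(1, rep(0, length(cand) - 1L)))
  }
  new_eval_report(
    auc = auc_score(pooled_s, pooled_y),
    aupr = aupr_score(pooled_s, pooled_y),
    precision = precision_at_r(pooled_s, pooled_y),
    n_test_positives = length(targets),
    n_candidates = length(pooled_y)
  )
}
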