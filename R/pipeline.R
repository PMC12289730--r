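#' Extract the association block from a reconstructed integrated matrix
#'
#' The drug view keeps columns `sim_width+1 .. end` as-is (m x n); the
#' disease view transposes that block back to drug-rows orientation.
#'
#' @param X_star Reconstructed integrated matrix.
#' @param sim_width Width of the similarity block.
#' @param view `"drug"` or `"disease"`.
#' @return The m x n association score block.
#' @export
extract_association <- function(X_star, sim_width, view = c("drug", "disease")) {
  view <- match.arg(view)
  if (sim_width < 0L || sim_width >= ncol(X_star)) {
    stop("sim_width inconsistent with the reconstructed matrix", call. = FALSE)
  }
  block <- X_star[, (sim_width + 1L):ncol(X_star), drop = FALSE]
  if (view == "disease") t(block) else block
}

resolve_sims <- function(sims, subset, label) {
  if (is.null(subset)) return(sims)
  missing <- setdiff(subset, names(sims))
  if (length(missing)) {
    stop("unknown ", label, " similarity name(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  sims[subset]
}

#' Predict drug-disease association scores
#'
#' The full two-view pipeline: fuse the (optionally subset) similarity
#' matrices into comprehensive matrices `R` and `D`, fill empty
#' association profiles by weighted KNN on each side (unless
#' `use_knn = FALSE`), assemble the integrated matrices `[R | A]` and
#' `[D | t(A)]` and their Laplacians, fit the deep factorization on each
#' view (layer-wise pretraining unless `use_pretrain = FALSE`), extract
#' the two reconstructed association blocks and return their element-wise
#' mean. Internally entities are processed in sorted identifier order, so
#' the result is invariant to the input ordering; the returned matrix uses
#' the bundle's original order.
#'
#' @param bundle A `dda_bundle`.
#' @param params A [dnmf_params()].
#' @param use_knn Apply the weighted KNN fill to empty profiles.
#' @param use_pretrain Initialize by layer-wise NMF pretraining.
#' @param drug_sims,disease_sims Optional character vectors naming the
#'   similarity matrices to use (default: all in the bundle).
#' @return Nonnegative m x n score matrix with the bundle's identifiers.
#' @export
predict_ddas <- function(bundle, params = dnmf_params(),
                         use_knn = TRUE, use_pretrain = TRUE,
                         drug_sims = NULL, disease_sims = NULL) {
  stopifnot(inherits(bundle, "dda_bundle"))
  dsims <- resolve_sims(bundle$drug_sims, drug_sims, "drug")
  ssims <- resolve_sims(bundle$disease_sims, disease_sims, "disease")
  if (!length(dsims) || !length(ssims)) {
    stop("similarity subset left no matrices to fuse", call. = FALSE)
  }

  A <- bundle$association
  in_drugs <- rownames(A)
  in_diseases <- colnames(A)
  # canonical (sorted-id) order makes scores independent of input ordering
  dord <- order(in_drugs)
  sord <- order(in_diseases)
  A <- A[dord, sord, drop = FALSE]
  R <- fuse_similarities(lapply(dsims, function(s) s[dord, dord, drop = FALSE]))
  D <- fuse_similarities(lapply(ssims, function(s) s[sord, sord, drop = FALSE]))

  if (use_knn) {
    A1 <- knn_fill(A, R, k = params$k, decay = params$decay)
    A2t <- knn_fill(t(A), D, k = params$k, decay = params$decay)
  } else {
    A1 <- A
    A2t <- t(A)
  }

  X_R <- build_integrated(R, A1, "drug")
  X_D <- build_integrated(D, A2t, "disease")
  L_R <- build_laplacian(R)
  L_D <- build_laplacian(D)

  p_R <- params; p_R$seed <- params$seed + 1L
  p_D <- params; p_D$seed <- params$seed + 2L
  fit_R <- fit_dnmf(X_R, L_R, p_R, pretrain = use_pretrain)
  fit_D <- fit_dnmf(X_D, L_D, p_D, pretrain = use_pretrain)

  A1_star <- extract_association(reconstruct(fit_R), attr(X_R, "sim_width"),
                                 "drug")
  A2_star <- extract_association(reconstruct(fit_D), attr(X_D, "sim_width"),
                                 "disease")
  scores <- (A1_star + A2_star) / 2
  dimnames(scores) <- list(rownames(A), colnames(A))
  scores[in_drugs, in_diseases, drop = FALSE]
}

#' Compare ablated pipeline variants under a shared protocol
#'
#' Runs the chosen evaluation protocol once per variant with the same seed
#' (hence identical folds or cold-start targets) and tabulates the
#' aggregate metrics.
#'
#' @param bundle A `dda_bundle`.
#' @param params A [dnmf_params()].
#' @param variants Nonempty named list; each element a list of
#'   [predict_ddas()] flags (`use_knn`, `use_pretrain`, `drug_sims`,
#'   `disease_sims`).
#' @param protocol `"cv10"` or `"coldstart"`.
#' @param seed Seed shared across variants.
#' @return Data frame with one row per variant: `variant`, `auc`, `aupr`,
#'   `precision`.
#' @export
run_ablation <- function(bundle, params = dnmf_params(), variants,
                         protocol = c("cv10", "coldstart"), seed = 1L) {
  protocol <- match.arg(protocol)
  if (!length(variants)) stop("no ablation variants given", call. = FALSE)
  if (is.null(names(variants))) {
    names(variants) <- sprintf("variant%d", seq_along(variants))
  }
  runner <- if (protocol == "cv10") run_cv10 else run_coldstart
  rows <- lapply(names(variants), function(nm) {
    fl <- variants[[nm]]
    rep <- do.call(runner, c(list(bundle = bundle, params = params,
                                  seed = seed), fl))
    data.frame(variant = nm, auc = rep$auc, aupr = rep$aupr,
               precision = rep$precision, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
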