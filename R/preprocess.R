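#' Fuse several similarity matrices into one comprehensive matrix
#'
#' Element-wise arithmetic mean of the supplied matrices, symmetrized as
#' `(M + t(M)) / 2`. All matrices must share shape and identifier order.
#'
#' @param mats Nonempty list of square similarity matrices.
#' @return The fused similarity matrix.
#' @export
fuse_similarities <- function(mats) {
  if (!length(mats)) stop("no similarity matrices to fuse", call. = FALSE)
  d <- dim(mats[[1L]])
  for (s in mats) {
    if (!identical(dim(s), d)) {
      stop("similarity matrices differ in shape", call. = FALSE)
    }
  }
  fused <- Reduce(`+`, mats) / length(mats)
  fused <- (fused + t(fused)) / 2
  dimnames(fused) <- dimnames(mats[[1L]])
  fused
}

#' Weighted k-nearest-neighbour fill of empty association profiles
#'
#' Cold-start entities (rows of `A` with no known association) carry no
#' signal for matrix completion. For every all-zero row `p`, its `k` most
#' similar other rows (by `S[p, ]`, descending; ties broken by identifier
#' order; self excluded) are combined into a surrogate profile:
#'
#' \deqn{\tilde A(p,\cdot) = \frac{\sum_{i=1}^{k} \eta^{\,i-1}\, S(p, j_i)\,
#'   A(j_i, \cdot)}{\sum_{i=1}^{k} \eta^{\,i-1}\, S(p, j_i)}}
#'
#' where `j_i` is the i-th nearest neighbour and `eta = decay` down-weights
#' lower-ranked neighbours. When every neighbour weight is zero the row is
#' left as-is. Rows that already contain a positive are never modified, so
#' for a binary `A` the output lies in \[0,1\].
#'
#' @param A Binary association matrix (entities in rows).
#' @param S Fused similarity matrix indexed by `A`'s rows.
#' @param k Number of neighbours (clamped to `nrow(A) - 1` with a warning).
#' @param decay Rank decay `eta` in (0, 1]; `1` gives plain
#'   similarity-weighted averaging.
#' @return A real-valued matrix of the same shape as `A`.
#' @export
knn_fill <- function(A, S, k = 10L, decay = 0.9) {
  stopifnot(is.matrix(A), is.matrix(S), nrow(S) == nrow(A),
            ncol(S) == nrow(A))
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (decay <= 0 || decay > 1) stop("decay must be in (0, 1]", call. = FALSE)
  if (k >= nrow(A)) {
    warning("k clamped to nrow(A) - 1 = ", nrow(A) - 1L)
    k <- nrow(A) - 1L
  }
  out <- A
  ids <- rownames(A) %||% as.character(seq_len(nrow(A)))
  empty <- which(rowSums(A) == 0)
  for (p in empty) {
    others <- setdiff(seq_len(nrow(A)), p)
    ord <- others[order(-S[p, others], ids[others])]
    nb <- ord[seq_len(k)]
    w <- decay^(seq_len(k) - 1L) * S[p, nb]
    tot <- sum(w)
    if (tot > 0) {
      out[p, ] <- as.numeric(w %*% A[nb, , drop = FALSE]) / tot
    }
  }
  out
}

#' Build an integrated entity-view matrix
#'
#' Horizontal concatenation of an entity's fused similarity block and its
#' (possibly KNN-filled) association block: the drug view is
#' `[R | A]` of shape m x (m+n), the disease view `[D | t(A)]` of shape
#' n x (m+n). The similarity block width is recorded so the association
#' block can be recovered after factorization.
#'
#' @param S Fused similarity matrix for the view's entity.
#' @param A_block Association block: m x n for the drug view, n x m
#'   (already transposed) for the disease view.
#' @param view `"drug"` or `"disease"`.
#' @return An `integrated_matrix`: the concatenated matrix with attributes
#'   `sim_width` and `view`.
#' @export
build_integrated <- function(S, A_block, view = c("drug", "disease")) {
  view <- match.arg(view)
  if (nrow(S) != nrow(A_block)) {
    stop("similarity and association blocks disagree on row count",
         call. = FALSE)
  }
  X <- cbind(S, A_block)
  if (any(X < 0)) stop("integrated matrix must be nonnegative", call. = FALSE)
  structure(X, sim_width = ncol(S), view = view,
            class = c("integrated_matrix", class(X)))
}

#' Graph Laplacian of a similarity matrix
#'
#' `L = U - S` with `U = diag(rowSums(S))`; degrees include the diagonal
#' self-similarity. Rows of `L` sum to zero, and `L` is symmetric whenever
#' `S` is.
#'
#' @param S Square similarity matrix.
#' @return The Laplacian matrix.
#' @export
build_laplacian <- function(S) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  L <- diag(rowSums(S), nrow(S)) - S
  dimnames(L) <- dimnames(S)
  L
}
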