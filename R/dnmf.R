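#' Hyperparameters for the deep factorization model
#'
#' Collects every tunable of the model with the defaults found optimal on
#' the benchmark datasets: `k = 10` neighbours, Laplacian weight
#' `alpha = 0.01`, relaxation weight `beta = 1`, ridge weights
#' `lam = mu = 1` (kept equal by default to limit the search space, but
#' independently settable), layer fractions `taus = c(0.8, 0.6)` (layer i
#' has `round(tau_i * min(m, n))` dimensions), stopping tolerances
#' `xi1 = 5e-4`, `xi2 = 5e-7`.
#'
#' @param alpha Graph-Laplacian weight (>= 0).
#' @param beta Relaxation weight tying adjacent layers (>= 0).
#' @param lam Frobenius ridge on every basis matrix (>= 0).
#' @param mu Frobenius ridge on every coefficient matrix (>= 0).
#' @param taus Layer dimension fractions, each in (0, 1]; length = depth.
#' @param k Neighbour count for the KNN preprocessing.
#' @param decay Rank decay of the KNN weights, in (0, 1].
#' @param xi1,xi2 Stopping tolerances on the relative change of the
#'   reconstructed association block and on its trend.
#' @param max_iter Cap on update sweeps after pretraining.
#' @param pretrain_iters Multiplicative-update iterations per pretraining
#'   layer.
#' @param sweep Update schedule inside a sweep: `"layerwise"` (for each
#'   layer, `W_i` then `H_i`) or `"w_first"` (all bases, then all
#'   coefficients). The update rules fix only the formulas, not the
#'   order.
#' @param seed Master seed; all internal randomness derives from it.
#' @return A list of class `dnmf_params`.
#' @export
dnmf_params <- function(alpha = 0.01, beta = 1, lam = 1, mu = 1,
                        taus = c(0.8, 0.6), k = 10L, decay = 0.9,
                        xi1 = 5e-4, xi2 = 5e-7,
                        max_iter = 500L, pretrain_iters = 200L,
                        sweep = c("layerwise", "w_first"),
                        seed = 1L) {
  sweep <- match.arg(sweep)
  stopifnot(alpha >= 0, beta >= 0, lam >= 0, mu >= 0,
            length(taus) >= 1L, all(taus > 0), all(taus <= 1),
            xi1 > 0, xi2 > 0, max_iter >= 0L, pretrain_iters >= 1L)
  structure(
    list(alpha = alpha, beta = beta, lam = lam, mu = mu, taus = taus,
         k = as.integer(k), decay = decay, xi1 = xi1, xi2 = xi2,
         max_iter = as.integer(max_iter),
         pretrain_iters = as.integer(pretrain_iters),
         sweep = sweep, seed = as.integer(seed)),
    class = "dnmf_params"
  )
}

#' Split a matrix into its positive and negative parts
#'
#' `Mplus = (|M| + M)/2`, `Mminus = (|M| - M)/2`; both are element-wise
#' nonnegative, `Mplus - Mminus = M` exactly and their supports are
#' disjoint. The multiplicative update rules are written entirely in terms
#' of these parts so that numerators and denominators stay nonnegative.
#'
#' @param M A finite numeric matrix.
#' @return List with elements `pos` and `neg`.
#' @export
pos_neg_split <- function(M) {
  list(pos = (abs(M) + M) / 2, neg = (abs(M) - M) / 2)
}

mpos <- function(M) (abs(M) + M) / 2
mneg <- function(M) (abs(M) - M) / 2

#' Basic NMF by Frobenius multiplicative updates
#'
#' Factorizes a nonnegative matrix `M` as `W H` (rank `r`) with the
#' classical multiplicative updates, which never increase the squared
#' reconstruction error. Factors are initialized uniform(0,1) from `seed`;
#' denominators are guarded with a small epsilon.
#'
#' @param M Nonnegative matrix.
#' @param r Rank, `1 <= r <= min(dim(M))`.
#' @param iters Number of update iterations.
#' @param seed Integer seed for the initialization.
#' @param eps Denominator guard.
#' @return List with `W` (nrow x r) and `H` (r x ncol).
#' @export
basic_nmf <- function(M, r, iters = 200L, seed = 1L, eps = 1e-10) {
  if (any(M < 0)) stop("basic_nmf requires a nonnegative matrix", call. = FALSE)
  stopifnot(r >= 1L, r <= min(dim(M)))
  local_rng(seed)
  W <- matrix(stats::runif(nrow(M) * r), nrow(M), r)
  H <- matrix(stats::runif(r * ncol(M)), r, ncol(M))
  for (it in seq_len(iters)) {
    H <- H * (t(W) %*% M) / (t(W) %*% W %*% H + eps)
    W <- W * (M %*% t(H)) / (W %*% H %*% t(H) + eps)
  }
  list(W = W, H = H)
}

#' Layer dimensions from fractions of the association matrix size
#'
#' `l_i = round(tau_i * min(m, n))`, clamped below at 1. `m` and `n` are
#' the drug and disease counts; both entity views use the same dimensions.
#'
#' @param m,n Drug and disease counts.
#' @param taus Layer fractions in (0, 1].
#' @return Integer vector of layer dimensions.
#' @export
layer_dims <- function(m, n, taus) {
  stopifnot(length(taus) >= 1L)
  pmax(1L, as.integer(round(taus * min(m, n))))
}

#' Layer-wise pretraining of the factor stack
#'
#' Sequentially factorizes `X ~ W1 H1`, then `W1 ~ W2 H2`, and so on, each
#' step with [basic_nmf()]. Per-layer seeds derive deterministically from
#' the master seed.
#'
#' @param X Nonnegative matrix to decompose.
#' @param dims Integer vector of layer dimensions `l_1..l_l`.
#' @param params A [dnmf_params()] object (uses `pretrain_iters`, `seed`).
#' @return A `factor_stack`: list with `W` and `H` (lists of matrices) and
#'   `dims`.
#' @export
pretrain_stack <- function(X, dims, params = dnmf_params()) {
  W <- vector("list", length(dims))
  H <- vector("list", length(dims))
  target <- X
  for (i in seq_along(dims)) {
    fit <- basic_nmf(target, dims[[i]], iters = params$pretrain_iters,
                     seed = params$seed + 1000L * i)
    W[[i]] <- fit$W
    H[[i]] <- fit$H
    target <- fit$W
  }
  new_factor_stack(W, H, dims)
}

new_factor_stack <- function(W, H, dims) {
  structure(list(W = W, H = H, dims = as.integer(dims)),
            class = "factor_stack")
}

#' @export
print.factor_stack <- function(x, ...) {
  cat(sprintf("factor_stack: %d layer(s), dims [%s]\n",
              length(x$dims), paste(x$dims, collapse = ", ")))
  invisible(x)
}

#' Coefficient product for layer i
#'
#' `Phi_i = H_i H_{i-1} ... H_1` (just `H_1` when `i = 1`): the map from
#' layer-i basis space back to the data columns.
#'
#' @param stack A `factor_stack`.
#' @param i Layer index in `1..l`.
#' @return The product matrix, shaped `l_i x ncol(X)`.
#' @export
phi_product <- function(stack, i) {
  l <- length(stack$H)
  if (i < 1L || i > l) stop("layer index out of range", call. = FALSE)
  phi <- stack$H[[1L]]
  for (p in seq_len(i)[-1L]) phi <- stack$H[[p]] %*% phi
  phi
}

# Shared data-side terms of every W update: reconstruction pull,
# Laplacian smoothing, and ridge.
w_core_terms <- function(W, X, phi, L, alpha, ridge) {
  XPt <- X %*% t(phi)
  WPPt <- W %*% (phi %*% t(phi))
  LW <- L %*% W
  num <- mpos(XPt) + mneg(WPPt) + alpha * mneg(LW) + ridge * mneg(W)
  den <- mneg(XPt) + mpos(WPPt) + alpha * mpos(LW) + ridge * mpos(W)
  list(num = num, den = den)
}

#' Multiplicative update of one basis matrix
#'
#' Applies the KKT-derived rule for layer `i`:
#' `W_i <- W_i * sqrt(num / den)` element-wise, where numerator and
#' denominator collect the positive/negative parts of the gradient terms.
#' The ridge coefficient is `beta + lam` for layers with a deeper
#' neighbour and `lam` for the deepest layer (or a single-layer model,
#' where every `beta` neighbour term is absent).
#'
#' @param stack A `factor_stack`.
#' @param i Layer index.
#' @param X The integrated data matrix.
#' @param L Graph Laplacian of the view's fused similarity.
#' @param params A [dnmf_params()].
#' @param eps Denominator guard.
#' @return The updated `W_i`.
#' @export
update_W <- function(stack, i, X, L, params, eps = 1e-10) {
  l <- length(stack$W)
  W <- stack$W[[i]]
  phi <- phi_product(stack, i)
  beta <- params$beta
  if (l == 1L) {
    tt <- w_core_terms(W, X, phi, L, params$alpha, params$lam)
    num <- tt$num
    den <- tt$den
  } else if (i == 1L) {
    tt <- w_core_terms(W, X, phi, L, params$alpha, beta + params$lam)
    nxt <- stack$W[[2L]] %*% stack$H[[2L]]
    num <- tt$num + beta * mpos(nxt)
    den <- tt$den + beta * mneg(nxt)
  } else if (i < l) {
    tt <- w_core_terms(W, X, phi, L, params$alpha, beta + params$lam)
    prv <- stack$W[[i - 1L]] %*% t(stack$H[[i]])
    self <- W %*% (stack$H[[i]] %*% t(stack$H[[i]]))
    nxt <- stack$W[[i + 1L]] %*% stack$H[[i + 1L]]
    num <- tt$num + beta * (mpos(prv) + mneg(self) + mpos(nxt))
    den <- tt$den + beta * (mneg(prv) + mpos(self) + mneg(nxt))
  } else {
    tt <- w_core_terms(W, X, phi, L, params$alpha, params$lam)
    prv <- stack$W[[i - 1L]] %*% t(stack$H[[i]])
    self <- W %*% (stack$H[[i]] %*% t(stack$H[[i]]))
    num <- tt$num + beta * (mpos(prv) + mneg(self))
    den <- tt$den + beta * (mneg(prv) + mpos(self))
  }
  W_new <- W * sqrt(num / pmax(den, eps))
  if (anyNA(W_new)) {
    stop("numeric failure (NaN) while updating basis of layer ", i,
         call. = FALSE)
  }
  W_new
}

#' Multiplicative update of one coefficient matrix
#'
#' KKT-derived rule `H_i <- H_i * sqrt(num / den)`. The first layer sees
#' only its data term and ridge; deeper layers additionally carry the
#' relaxation terms coupling `H_i` to `W_{i-1}`.
#'
#' @inheritParams update_W
#' @return The updated `H_i`.
#' @export
update_H <- function(stack, i, X, params, eps = 1e-10) {
  l <- length(stack$H)
  W <- stack$W[[i]]
  H <- stack$H[[i]]
  WtW <- t(W) %*% W
  if (i == 1L) {
    WtWH <- WtW %*% H
    WtX <- t(W) %*% X
    num <- mneg(WtWH) + mpos(WtX) + params$mu * mneg(H)
    den <- mpos(WtWH) + mneg(WtX) + params$mu * mpos(H)
  } else {
    phi_prev <- phi_product(stack, i - 1L)
    PPt <- phi_prev %*% t(phi_prev)
    WtWHPPt <- WtW %*% H %*% PPt
    WtXPt <- t(W) %*% X %*% t(phi_prev)
    WtWprev <- t(W) %*% stack$W[[i - 1L]]
    WtWH <- WtW %*% H
    num <- mneg(WtWHPPt) + mpos(WtXPt) + params$mu * mneg(H) +
      params$beta * (mpos(WtWprev) + mneg(WtWH))
    den <- mpos(WtWHPPt) + mneg(WtXPt) + params$mu * mpos(H) +
      params$beta * (mneg(WtWprev) + mpos(WtWH))
  }
  H_new <- H * sqrt(num / pmax(den, eps))
  if (anyNA(H_new)) {
    stop("numeric failure (NaN) while updating coefficients of layer ", i,
         call. = FALSE)
  }
  H_new
}

#' Regularized objective of the deep factorization model
#'
#' \deqn{\|X - W_l H_l \cdots H_1\|_F^2
#'   + \alpha \sum_i \mathrm{Tr}(W_i^T L W_i)
#'   + \beta \sum_{i<l} \|W_i - W_{i+1} H_{i+1}\|_F^2
#'   + \lambda \sum_i \|W_i\|_F^2 + \mu \sum_i \|H_i\|_F^2}
#'
#' @inheritParams update_W
#' @return The scalar objective value.
#' @export
dnmf_objective <- function(stack, X, L, params) {
  l <- length(stack$W)
  recon <- stack$W[[l]] %*% phi_product(stack, l)
  val <- sum((X - recon)^2)
  for (i in seq_len(l)) {
    val <- val + params$alpha * sum(stack$W[[i]] * (L %*% stack$W[[i]]))
    val <- val + params$lam * sum(stack$W[[i]]^2)
    val <- val + params$mu * sum(stack$H[[i]]^2)
  }
  for (i in seq_len(l - 1L)) {
    val <- val +
      params$beta * sum((stack$W[[i]] -
                           stack$W[[i + 1L]] %*% stack$H[[i + 1L]])^2)
  }
  val
}

#' Stopping decision from the association-change history
#'
#' `h_k` is the relative Frobenius change of the reconstructed association
#' block between consecutive sweeps. Iteration stops once the latest
#' `h <= xi1` and the relative change of `h` itself,
#' `|h_k - h_{k-1}| / max(1, |h_{k-1}|)`, is `<= xi2`. With fewer than two
#' recorded values the answer is always "continue".
#'
#' @param history Numeric vector of successive `h` values.
#' @param params A [dnmf_params()] (uses `xi1`, `xi2`).
#' @return `TRUE` to stop, `FALSE` to continue.
#' @export
convergence_check <- function(history, params) {
  nh <- length(history)
  if (nh < 2L) return(FALSE)
  h_last <- history[[nh]]
  h_prev <- history[[nh - 1L]]
  h_last <= params$xi1 &&
    abs(h_last - h_prev) / max(1, abs(h_prev)) <= params$xi2
}

#' Fit the deep factorization model on one entity view
#'
#' Pretrains the stack layer-by-layer (unless `pretrain = FALSE`, in which
#' case factors are drawn uniform(0,1)), then refines it with sweeps of the
#' multiplicative updates (layer order `1..l`, `W_i` then `H_i`),
#' monitoring the relative change of the reconstructed association block
#' and stopping per [convergence_check()] or at `max_iter` sweeps.
#' Deterministic given `params$seed`.
#'
#' @param X An [build_integrated()] matrix (or any nonnegative matrix with
#'   a `sim_width` attribute).
#' @param L Graph Laplacian of the view's fused similarity.
#' @param params A [dnmf_params()].
#' @param pretrain Use layer-wise NMF pretraining (default) or random
#'   initialization.
#' @return A `dnmf_fit`: list with the final `stack`, the `h` `history`,
#'   `iterations` run and whether the stopping rule fired (`converged`).
#' @export
fit_dnmf <- function(X, L, params = dnmf_params(), pretrain = TRUE) {
  sim_width <- attr(X, "sim_width")
  if (is.null(sim_width)) sim_width <- 0L
  dims <- attr(X, "layer_dims") %||%
    layer_dims(nrow(X), ncol(X) - sim_width, params$taus)
  X <- unclass(X)

  if (pretrain) {
    stack <- pretrain_stack(X, dims, params)
  } else {
    local_rng(params$seed)
    cols_H <- c(ncol(X), dims[-length(dims)])
    W <- lapply(seq_along(dims), function(i) {
      matrix(stats::runif(nrow(X) * dims[[i]]), nrow(X), dims[[i]])
    })
    H <- lapply(seq_along(dims), function(i) {
      matrix(stats::runif(dims[[i]] * cols_H[[i]]), dims[[i]], cols_H[[i]])
    })
    stack <- new_factor_stack(W, H, dims)
  }

  l <- length(dims)
  assoc_cols <- if (sim_width < ncol(X)) (sim_width + 1L):ncol(X) else integer()
  recon_assoc <- function(st) {
    R <- st$W[[l]] %*% phi_product(st, l)
    if (length(assoc_cols)) R[, assoc_cols, drop = FALSE] else R
  }
  prev <- recon_assoc(stack)
  history <- numeric()
  iterations <- 0L
  converged <- FALSE
  w_first <- identical(params$sweep, "w_first")
  for (sweep in seq_len(params$max_iter)) {
    if (w_first) {
      for (i in seq_len(l)) stack$W[[i]] <- update_W(stack, i, X, L, params)
      for (i in seq_len(l)) stack$H[[i]] <- update_H(stack, i, X, params)
    } else {
      for (i in seq_len(l)) {
        stack$W[[i]] <- update_W(stack, i, X, L, params)
        stack$H[[i]] <- update_H(stack, i, X, params)
      }
    }
    cur <- recon_assoc(stack)
    denom <- sqrt(sum(prev^2))
    h <- if (denom == 0) 0 else sqrt(sum((cur - prev)^2)) / denom
    history <- c(history, h)
    prev <- cur
    iterations <- sweep
    if (convergence_check(history, params)) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(stack = stack, history = history, iterations = iterations,
         converged = converged, sim_width = sim_width),
    class = "dnmf_fit"
  )
}

#' @export
print.dnmf_fit <- function(x, ...) {
  cat(sprintf(
    "dnmf_fit: %d layer(s), %d sweep(s), %s (last h = %.3g)\n",
    length(x$stack$dims), x$iterations,
    if (x$converged) "converged" else "iteration cap reached",
    if (length(x$history)) x$history[[length(x$history)]] else NA_real_
  ))
  invisible(x)
}

#' Reconstruct the fitted integrated matrix
#'
#' `W_l H_l H_{l-1} ... H_1`; nonnegative by construction.
#'
#' @param stack A `factor_stack` or a `dnmf_fit`.
#' @return The reconstructed matrix.
#' @export
reconstruct <- function(stack) {
  if (inherits(stack, "dnmf_fit")) stack <- stack$stack
  l <- length(stack$W)
  stack$W[[l]] %*% phi_product(stack, l)
}
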