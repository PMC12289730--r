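# Small in-code fixtures shared across test files.

# A labeled matrix with given dims and deterministic contents.
lmat <- function(values, row_ids, col_ids) {
  matrix(values, length(row_ids), length(col_ids),
         dimnames = list(row_ids, col_ids))
}

# Random symmetric similarity matrix in [0,1] with unit diagonal.
rand_sim <- function(ids, seed) {
  set.seed(seed)
  n <- length(ids)
  S <- matrix(runif(n * n), n, n)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(ids, ids)
  S
}

# Tiny but complete bundle: m drugs x n diseases, binary associations.
tiny_bundle <- function(m = 6, n = 4, seed = 42, density = 0.25) {
  set.seed(seed)
  drugs <- sprintf("R%d", seq_len(m))
  diseases <- sprintf("D%d", seq_len(n))
  A <- matrix(as.numeric(runif(m * n) < density), m, n,
              dimnames = list(drugs, diseases))
  A[1, 1] <- 1  # guarantee at least one positive
  new_bundle(
    A,
    list(s1 = rand_sim(drugs, seed + 1), s2 = rand_sim(drugs, seed + 2)),
    list(t1 = rand_sim(diseases, seed + 3))
  )
}

# Brute-force metric oracles, independent of the package's implementations.
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

aupr_oracle <- function(scores, labels) {
  P <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  recall_prev <- 0
  for (t in thr) {
    tp <- sum(labels == 1 & scores >= t)
    called <- sum(scores >= t)
    recall <- tp / P
    area <- area + (recall - recall_prev) * (tp / called)
    recall_prev <- recall
  }
  area
}

# Random nonnegative factor stack with consistent layer shapes.
new_stack_for_test <- function(dims, ncols, rows = 8L, seed = 111) {
  set.seed(seed)
  l <- length(dims)
  W <- lapply(seq_len(l), function(i) {
    matrix(runif(rows * dims[[i]]), rows, dims[[i]])
  })
  H <- vector("list", l)
  H[[1]] <- matrix(runif(dims[[1]] * ncols), dims[[1]], ncols)
  if (l > 1) {
    for (i in 2:l) {
      H[[i]] <- matrix(runif(dims[[i]] * dims[[i - 1]]),
                       dims[[i]], dims[[i - 1]])
    }
  }
  dnmfdr:::new_factor_stack(W, H, dims)
}

# Independent term-by-term recomputation of the regularized objective,
# written with norm()/diag() rather than the package's sum() formulation.
objective_oracle <- function(st, X, L, p) {
  l <- length(st$W)
  prod <- st$H[[1]]
  if (l > 1) for (i in 2:l) prod <- st$H[[i]] %*% prod
  total <- norm(X - st$W[[l]] %*% prod, "F")^2
  for (i in seq_len(l)) {
    total <- total + p$alpha * sum(diag(t(st$W[[i]]) %*% L %*% st$W[[i]]))
    total <- total + p$lam * norm(st$W[[i]], "F")^2
    total <- total + p$mu * norm(st$H[[i]], "F")^2
  }
  if (l > 1) {
    for (i in seq_len(l - 1)) {
      total <- total +
        p$beta * norm(st$W[[i]] - st$W[[i + 1]] %*% st$H[[i + 1]], "F")^2
    }
  }
  total
}

# Strictly positive exactly factorable instance for fixed-point tests.
exact_instance <- function(nr = 8, nc = 6, r = 3, seed = 7) {
  set.seed(seed)
  W <- matrix(runif(nr * r, 0.5, 1.5), nr, r)
  H <- matrix(runif(r * nc, 0.5, 1.5), r, nc)
  list(W = W, H = H, X = W %*% H)
}
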