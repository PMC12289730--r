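#' Generate a synthetic drug-disease dataset with a planted low-rank signal
#'
#' Emulates the statistical structure the factorization model assumes:
#' nonnegative latent factors `U` (m x r) and `V` (n x r) drawn as |N(0,1)|,
#' a ground-truth score matrix `U V'`, a sparse binary association matrix
#' set to 1 at the `ceiling(density * m * n)` largest ground-truth entries,
#' and similarity matrices derived from `U U'` / `V V'` (rescaled to \[0,1\],
#' unit diagonal) with optional symmetric truncated noise. Because the
#' associations are thresholded from the planted product rather than sampled,
#' the true ranking of unknown pairs is unambiguous, which gives recovery
#' tests a clean oracle. Optionally, a number of drug rows are thinned to
#' exactly one positive (keeping the largest-scoring one) to create
#' cold-start targets.
#'
#' @param m,n Drug and disease counts.
#' @param r Latent rank of the planted signal.
#' @param density Target fraction of positive associations (0 < density < 1).
#' @param noise_sd Scale of the symmetric similarity noise (0 = none).
#' @param n_singleton_drugs Number of drug rows forced to exactly one
#'   positive association (cold-start targets).
#' @param n_drug_sims,n_disease_sims How many (independently noised)
#'   similarity matrices to emit per entity type.
#' @param seed Integer seed; the dataset is a deterministic function of it.
#' @return A list with `bundle` (a `dda_bundle`) and `ground_truth`
#'   (the real-valued m x n planted score matrix).
#' @export
generate_dataset <- function(m, n, r, density = 0.01, noise_sd = 0.1,
                             n_singleton_drugs = 0L,
                             n_drug_sims = 2L, n_disease_sims = 2L,
                             seed = 1L) {
  if (density <= 0 || density >= 1) {
    stop("density must lie strictly between 0 and 1", call. = FALSE)
  }
  if (r > min(m, n)) stop("rank r must not exceed min(m, n)", call. = FALSE)
  if (n_singleton_drugs > m) {
    stop("n_singleton_drugs must not exceed m", call. = FALSE)
  }
  local_rng(seed)

  drugs <- sprintf("DR%03d", seq_len(m))
  diseases <- sprintf("DI%03d", seq_len(n))
  U <- matrix(abs(stats::rnorm(m * r)), m, r)
  V <- matrix(abs(stats::rnorm(n * r)), n, r)
  truth <- U %*% t(V)
  dimnames(truth) <- list(drugs, diseases)

  n_pos <- ceiling(density * m * n)
  A <- matrix(0, m, n, dimnames = dimnames(truth))
  A[order(truth, decreasing = TRUE)[seq_len(n_pos)]] <- 1

  sim_from <- function(F, ids, n_mats, prefix) {
    S0 <- F %*% t(F)
    lo <- min(S0); hi <- max(S0)
    S0 <- (S0 - lo) / (hi - lo)
    stats::setNames(lapply(seq_len(n_mats), function(j) {
      S <- S0
      if (noise_sd > 0) {
        E <- matrix(stats::rnorm(length(S), sd = noise_sd), nrow(S))
        S <- S + (E + t(E)) / 2
      }
      S <- pmin(pmax((S + t(S)) / 2, 0), 1)
      diag(S) <- 1
      dimnames(S) <- list(ids, ids)
      S
    }), sprintf("%s%d", prefix, seq_len(n_mats)))
  }
  drug_sims <- sim_from(U, drugs, n_drug_sims, "Rsim")
  disease_sims <- sim_from(V, diseases, n_disease_sims, "Dsim")

  if (n_singleton_drugs > 0L) {
    # thin the densest rows so singleton targets actually lose information
    counts <- rowSums(A)
    cand <- order(counts, decreasing = TRUE)[seq_len(n_singleton_drugs)]
    for (i in cand) {
      pos <- which(A[i, ] == 1)
      if (length(pos) <= 1L) next
      keep <- pos[[which.max(truth[i, pos])]]
      A[i, ] <- 0
      A[i, keep] <- 1
    }
  }

  list(bundle = new_bundle(A, drug_sims, disease_sims), ground_truth = truth)
}

#' Hide a fraction of known associations
#'
#' Uniformly samples `ceiling(fraction_hidden * npos)` positive cells
#' without replacement, zeroes them in the returned training matrix and
#' reports them as a two-column (row, col) index matrix. The hidden pairs
#' and the training positives partition the original positives.
#'
#' @param A Binary association matrix.
#' @param fraction_hidden Fraction of positives to hide (0 < f < 1).
#' @param seed Integer seed.
#' @return List with `train` (matrix) and `hidden_pairs` (integer matrix
#'   with columns `row`, `col`).
#' @export
split_known_associations <- function(A, fraction_hidden, seed = 1L) {
  if (fraction_hidden <= 0 || fraction_hidden >= 1) {
    stop("fraction_hidden must lie strictly between 0 and 1", call. = FALSE)
  }
  pos <- which(A == 1)
  if (!length(pos)) stop("association matrix has no positives", call. = FALSE)
  local_rng(seed)
  n_hide <- ceiling(fraction_hidden * length(pos))
  hidden <- pos[sample.int(length(pos), n_hide)]
  train <- A
  train[hidden] <- 0
  list(
    train = train,
    hidden_pairs = cbind(row = (hidden - 1L) %% nrow(A) + 1L,
                         col = (hidden - 1L) %/% nrow(A) + 1L)
  )
}

# Scoped RNG: seeds R's generator for the calling function and restores the
# caller's RNG state on exit, so library code never perturbs user RNG flow.
local_rng <- function(seed, envir = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = envir)
  invisible(NULL)
}
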