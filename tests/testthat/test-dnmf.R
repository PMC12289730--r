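test_that("positive/negative split obeys its algebraic identities", {
  sp <- pos_neg_split(rbind(c(2, -3)))
  expect_equal(sp$pos, rbind(c(2, 0)))
  expect_equal(sp$neg, rbind(c(0, 3)))
  set.seed(17)
  for (case in 1:25) {
    M <- matrix(rnorm(20, sd = 10), 4, 5)
    sp <- pos_neg_split(M)
    expect_identical(sp$pos - sp$neg, M)        # exact reconstruction
    expect_true(all(sp$pos * sp$neg == 0))      # disjoint supports
    expect_true(all(sp$pos >= 0) && all(sp$neg >= 0))
  }
})

test_that("basic_nmf recovers an exact rank-1 factorization", {
  M <- rbind(c(1, 2), c(2, 4))
  fit <- basic_nmf(M, r = 1, iters = 500, seed = 1)
  expect_lt(norm(M - fit$W %*% fit$H, "F") / norm(M, "F"), 1e-3)
  expect_identical(fit, basic_nmf(M, r = 1, iters = 500, seed = 1))
  expect_error(basic_nmf(rbind(c(-1, 1)), 1), "nonnegative")
})

test_that("basic_nmf objective is nonincreasing across iterations", {
  set.seed(23)
  M <- matrix(runif(80), 10, 8)
  errs <- vapply(1:30, function(it) {
    fit <- basic_nmf(M, r = 4, iters = it, seed = 5)
    norm(M - fit$W %*% fit$H, "F")^2
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("layer dimensions are rounded fractions of min(m, n), clamped", {
  expect_identical(layer_dims(593, 313, c(0.8, 0.6)), c(250L, 188L))
  expect_identical(layer_dims(7, 9, 1.0), 7L)
  expect_identical(layer_dims(5, 4, 0.1), 1L)
})

test_that("pretraining stacks layer shapes and reduces to basic_nmf at l=1", {
  set.seed(41)
  X <- matrix(runif(12 * 9), 12, 9)
  p <- dnmf_params(taus = c(0.5), seed = 3, pretrain_iters = 50)
  st <- pretrain_stack(X, 4L, p)
  ref <- basic_nmf(X, 4L, iters = 50, seed = 3 + 1000)
  expect_identical(st$W[[1]], ref$W)
  expect_identical(st$H[[1]], ref$H)

  st2 <- pretrain_stack(X, c(6L, 4L), dnmf_params(seed = 3))
  expect_identical(dim(st2$W[[2]]), c(12L, 4L))
  expect_identical(dim(st2$H[[2]]), c(4L, 6L))   # H2 is l2 x l1
  expect_identical(dim(st2$H[[1]]), c(6L, 9L))
  expect_true(all(unlist(st2$W) >= 0) && all(unlist(st2$H) >= 0))
})

test_that("pretraining approximates a planted low-rank product", {
  set.seed(13)
  Wstar <- matrix(runif(30 * 4, 0.2, 1), 30, 4)
  Hstar <- matrix(runif(4 * 20, 0.2, 1), 4, 20)
  X <- Wstar %*% Hstar
  rel <- vapply(1:4, function(s) {
    st <- pretrain_stack(X, c(8L, 4L),
                         dnmf_params(seed = s, pretrain_iters = 500))
    norm(X - reconstruct(st), "F") / norm(X, "F")
  }, numeric(1))
  expect_true(all(rel < 0.1))   # every initialization lands near the product
  expect_lt(mean(rel), 0.05)    # and on average well inside it
})

test_that("phi products match a sequential-multiplication oracle", {
  set.seed(19)
  st <- new_stack_for_test(dims = c(5L, 4L, 3L), ncols = 11L)
  expect_identical(phi_product(st, 1), st$H[[1]])
  expect_equal(phi_product(st, 2), st$H[[2]] %*% st$H[[1]])
  oracle <- st$H[[3]] %*% (st$H[[2]] %*% st$H[[1]])
  expect_lt(max(abs(phi_product(st, 3) - oracle)), 1e-12)
  expect_identical(dim(phi_product(st, 2)), c(4L, 11L))
  expect_error(phi_product(st, 4), "out of range")
})

test_that("updates are exact fixed points at positive exact factorizations", {
  inst <- exact_instance()
  st <- dnmfdr:::new_factor_stack(list(inst$W), list(inst$H), 3L)
  L <- matrix(0, nrow(inst$X), nrow(inst$X))
  p0 <- dnmf_params(alpha = 0, beta = 0, lam = 0, mu = 0, taus = 1)
  expect_lt(max(abs(update_W(st, 1, inst$X, L, p0) - inst$W)), 1e-12)
  expect_lt(max(abs(update_H(st, 1, inst$X, p0) - inst$H)), 1e-12)
})

test_that("updates preserve non-negativity on arbitrary instances", {
  set.seed(29)
  for (case in 1:10) {
    X <- matrix(runif(10 * 14), 10, 14)
    L <- build_laplacian(rand_sim(sprintf("i%d", 1:10), 300 + case))
    p <- dnmf_params(alpha = 0.05, beta = 0.7, lam = 0.3, mu = 0.4,
                     taus = c(0.6, 0.4), seed = case)
    st <- pretrain_stack(X, layer_dims(10, 14, p$taus), p)
    for (i in seq_along(st$W)) {
      st$W[[i]] <- update_W(st, i, X, L, p)
      st$H[[i]] <- update_H(st, i, X, p)
      expect_true(all(st$W[[i]] >= 0))
      expect_true(all(st$H[[i]] >= 0))
    }
  }
})

test_that("a regularized W-sweep does not increase the full objective", {
  set.seed(37)
  X <- matrix(runif(12 * 9), 12, 9)
  L <- build_laplacian(rand_sim(sprintf("i%d", 1:12), 91))
  p <- dnmf_params(alpha = 0.01, beta = 1, lam = 1, mu = 1,
                   taus = c(0.5, 0.3), seed = 8, pretrain_iters = 100)
  st <- pretrain_stack(X, layer_dims(12, 9, p$taus), p)
  before <- objective_oracle(st, X, L, p)
  expect_equal(dnmf_objective(st, X, L, p), before, tolerance = 1e-9)
  for (i in seq_along(st$W)) st$W[[i]] <- update_W(st, i, X, L, p)
  after <- objective_oracle(st, X, L, p)
  expect_lte(after, before + 1e-9)
})

test_that("unregularized single-layer sweeps never increase the error", {
  set.seed(43)
  p0 <- dnmf_params(alpha = 0, beta = 0, lam = 0, mu = 0, taus = 1)
  L0 <- matrix(0, 10, 10)
  for (case in 1:20) {
    X <- matrix(runif(80), 10, 8)
    st <- pretrain_stack(X, 3L, dnmf_params(seed = case,
                                            pretrain_iters = 5))
    err0 <- norm(X - reconstruct(st), "F")^2
    for (sweep in 1:3) {
      st$W[[1]] <- update_W(st, 1, X, L0, p0)
      st$H[[1]] <- update_H(st, 1, X, p0)
      err1 <- norm(X - reconstruct(st), "F")^2
      expect_lte(err1, err0 + 1e-9)
      err0 <- err1
    }
  }
})

test_that("the objective matches an independent term-by-term oracle", {
  set.seed(47)
  for (case in 1:5) {
    X <- matrix(runif(9 * 13), 9, 13)
    L <- build_laplacian(rand_sim(sprintf("i%d", 1:9), 400 + case))
    p <- dnmf_params(alpha = runif(1), beta = runif(1), lam = runif(1),
                     mu = runif(1), taus = c(0.7, 0.5), seed = case)
    st <- pretrain_stack(X, layer_dims(9, 13, p$taus), p)
    expect_equal(dnmf_objective(st, X, L, p), objective_oracle(st, X, L, p),
                 tolerance = 1e-9)
  }
  # term isolation: all regularizers off leaves the reconstruction error
  inst <- exact_instance()
  st <- dnmfdr:::new_factor_stack(list(inst$W), list(inst$H), 3L)
  p0 <- dnmf_params(alpha = 0, beta = 0, lam = 0, mu = 0, taus = 1)
  expect_equal(dnmf_objective(st, inst$X, diag(nrow(inst$X)), p0), 0,
               tolerance = 1e-18)
})

test_that("the stopping rule follows the tolerance decision table", {
  p <- dnmf_params(xi1 = 5e-4, xi2 = 5e-7)
  expect_true(convergence_check(c(1e-5, 1e-5), p))
  expect_false(convergence_check(c(1e-3), p))
  expect_false(convergence_check(c(4e-4, 4e-4 + 1e-6), p))  # trend too large
  expect_false(convergence_check(numeric(), p))
  expect_false(convergence_check(c(1, 0), p))  # trend |0-1|/1 = 1 > xi2
  expect_true(convergence_check(c(0, 0), p))   # degenerate converged
})

test_that("fitting honours the iteration cap and refines the pretraining", {
  set.seed(53)
  inst <- exact_instance(nr = 10, nc = 8, r = 3)
  X <- structure(inst$X, sim_width = 0L)
  L <- matrix(0, 10, 10)
  p0 <- dnmf_params(alpha = 0, beta = 0, lam = 0, mu = 0, taus = 0.375,
                    seed = 2, max_iter = 0, pretrain_iters = 40)
  fit0 <- fit_dnmf(X, L, p0)
  expect_identical(fit0$iterations, 0L)
  expect_identical(fit0$stack,
                   pretrain_stack(unclass(X), 3L, p0))  # cap semantics

  p1 <- p0; p1$max_iter <- 60L
  fit1 <- fit_dnmf(X, L, p1)
  e_pre <- norm(inst$X - reconstruct(fit0), "F")
  e_fit <- norm(inst$X - reconstruct(fit1), "F")
  expect_lte(e_fit, e_pre)
  expect_identical(fit1, fit_dnmf(X, L, p1))  # bit-reproducible

  # alternative sweep schedule: same contracts, possibly different path
  p2 <- p1; p2$sweep <- "w_first"
  fit2 <- fit_dnmf(X, L, p2)
  expect_true(all(unlist(fit2$stack$W) >= 0))
  expect_lte(norm(inst$X - reconstruct(fit2), "F"), e_pre)
  expect_identical(fit2, fit_dnmf(X, L, p2))
})

test_that("reconstruction is the ordered product of the stack", {
  st <- new_stack_for_test(dims = c(6L, 4L, 2L), ncols = 9L)
  oracle <- st$W[[3]] %*% st$H[[3]] %*% st$H[[2]] %*% st$H[[1]]
  expect_lt(max(abs(reconstruct(st) - oracle)) / max(abs(oracle)), 1e-10)
  st$W[[3]][] <- 0
  expect_true(all(reconstruct(st) == 0))
  expect_true(all(reconstruct(new_stack_for_test(c(3L), 5L)) >= 0))
})
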