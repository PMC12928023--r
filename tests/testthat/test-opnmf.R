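# Nonnegativity transforms, NNDSVD, opNMF fitting, stability rank selection.

test_that("nonnegativity transforms preserve the intended structure", {
  set.seed(31)
  Z <- matrix(rnorm(82 * 187), 187, 82)   # subjects x regions, signed
  Z[1, 1] <- -3 - max(abs(Z))             # force a known minimum
  Xs <- to_nonnegative(Z, "shift")
  expect_equal(min(Xs), 0)
  expect_equal(dim(Xs), c(82L, 187L))     # transposed to regions x subjects
  # all pairwise differences preserved exactly by the affine shift
  i <- cbind(sample(82, 50, TRUE), sample(187, 50, TRUE))
  j <- cbind(sample(82, 50, TRUE), sample(187, 50, TRUE))
  Zt <- t(Z)
  expect_equal(Xs[i] - Xs[j], Zt[i] - Zt[j], tolerance = 1e-12)
  Xa <- to_nonnegative(Z, "abs")
  for (r in sample(82, 5)) for (s in sample(187, 5))
    expect_identical(Xa[r, s], abs(Zt[r, s]))     # elementwise oracle
  Xp <- to_nonnegative(Z, "split")
  expect_equal(dim(Xp), c(164L, 187L))
  expect_equal(Xp[1:82, ] - Xp[83:164, ], Zt, ignore_attr = TRUE)
  expect_true(all(Xp >= 0))
  expect_error(to_nonnegative(matrix(0, 3, 3)), "all-zero")
})

test_that("NNDSVD matches an independent reference implementation", {
  # independently coded dense/sparse NNDSVD from the SVD definition
  nndsvd_ref <- function(X, k) {
    sv <- svd(X)
    W <- matrix(0, nrow(X), k)
    u1 <- sv$u[, 1] * sign(sum(sv$u[, 1]))
    W[, 1] <- sqrt(sv$d[1]) * abs(u1)
    if (k > 1) for (j in 2:k) {
      u <- sv$u[, j]; v <- sv$v[, j]
      pu <- u; pu[pu < 0] <- 0; nu <- -u; nu[nu < 0] <- 0
      pv <- v; pv[pv < 0] <- 0; nv <- -v; nv[nv < 0] <- 0
      if (sqrt(sum(pu^2)) * sqrt(sum(pv^2)) >=
          sqrt(sum(nu^2)) * sqrt(sum(nv^2))) {
        if (sum(pu^2) > 0)
          W[, j] <- sqrt(sv$d[j] * sqrt(sum(pu^2)) * sqrt(sum(pv^2))) *
            pu / sqrt(sum(pu^2))
      } else {
        W[, j] <- sqrt(sv$d[j] * sqrt(sum(nu^2)) * sqrt(sum(nv^2))) *
          nu / sqrt(sum(nu^2))
      }
    }
    W
  }
  X <- matrix(c(5, 1, 0, 2, 8, 1, 3, 0, 7, 2, 4, 1, 9, 3, 2, 6, 0, 5,
                1, 4, 2, 7, 3, 8, 4, 0, 6, 2, 5, 1, 3, 9, 1, 4, 0, 2,
                6, 3, 7, 1, 2, 5, 0, 8, 4, 3, 1, 6), 6, 8)
  expect_equal(nndsvd_init(X, 4), nndsvd_ref(X, 4), tolerance = 1e-10)
  # rank-1 nonnegative matrix: first column proportional to the left factor
  a <- runif(6, 0.5, 2); b <- runif(9, 0.5, 2)
  W0 <- nndsvd_init(a %*% t(b), 2)
  expect_gt(sum(W0[, 1] * a) / sqrt(sum(W0[, 1]^2) * sum(a^2)), 1 - 1e-8)
  # nonnegative for random nonnegative inputs
  set.seed(32)
  for (s in 1:20) {
    Xr <- matrix(abs(rnorm(30)), 5, 6)
    expect_true(all(nndsvd_init(Xr, 3) >= 0))
  }
  expect_error(nndsvd_init(X, 7), "k exceeds")
})

test_that("opNMF recovers separable structure and keeps its invariants", {
  set.seed(33)
  W <- matrix(0, 10, 2)
  W[1:5, 1] <- runif(5, 0.5, 1); W[6:10, 2] <- runif(5, 0.5, 1)
  X <- W %*% matrix(abs(rnorm(60)), 2)
  fit <- opnmf_fit(X, 2)
  mt <- morphodev:::match_components(fit$W, W)
  expect_true(all(mt$similarity > 0.99))
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$H >= -1e-12))
  expect_equal(unname(colSums(fit$W^2)), c(1, 1), tolerance = 1e-8)
  expect_true(fit$converged)
  # deterministic given (X, W0): bit-identical refit
  fit2 <- opnmf_fit(X, 2)
  expect_identical(fit$W, fit2$W)
  expect_identical(fit$recon_error, fit2$recon_error)
  expect_error(opnmf_fit(X, 0), "positive")
  expect_error(opnmf_fit(X - 10, 2), "nonnegative")
})

test_that("opNMF recovers planted sparse components at high SNR", {
  pl <- planted_nmf(seed = 101, snr = 10)
  fit <- opnmf_fit(pl$X, 8)
  mt <- morphodev:::match_components(fit$W, pl$W)
  expect_gt(mean(mt$similarity), 0.95)
})

test_that("multiplicative updates descend and higher ranks fit better at scale", {
  set.seed(34)
  for (rep in 1:5) {
    X <- matrix(abs(rnorm(30 * 40)), 30)
    k <- sample(2:5, 1)
    W0 <- nndsvd_init(X, k); W0[W0 <= 0] <- 1e-12
    e0 <- norm(X - W0 %*% crossprod(W0, X), "F")
    fit <- opnmf_fit(X, k, W0 = W0)
    expect_lt(fit$recon_error, e0)
    # the fitted subspace is close to the optimal rank-k error (the
    # nonnegativity constraint costs a bounded premium)
    sv <- svd(X)
    expect_lt(fit$recon_error,
              1.3 * sqrt(sum(sv$d[-seq_len(k)]^2)) + 1)
  }
  X <- matrix(abs(rnorm(40 * 60)), 40)
  expect_lt(opnmf_fit(X, 10)$recon_error, opnmf_fit(X, 2)$recon_error)
})

test_that("Hungarian pairing equals brute-force best-permutation pairing", {
  set.seed(35)
  for (r in 1:30) {
    k <- sample(2:6, 1)
    A <- matrix(runif(20 * k), 20)
    B <- matrix(runif(20 * k), 20)
    sim <- morphodev:::cosine_cols(A, B)
    mt <- morphodev:::match_components(A, B)
    bf <- brute_assign(max(sim) - sim)
    expect_equal(sum(mt$similarity), sum(sim[cbind(1:k, bf$perm)]),
                 tolerance = 1e-10)
  }
})

test_that("split-half stability is 1 for replicated prototype subjects", {
  set.seed(36)
  proto <- matrix(0, 20, 3)
  proto[1:7, 1] <- runif(7, 0.5, 1)
  proto[8:14, 2] <- runif(7, 0.5, 1)
  proto[15:20, 3] <- runif(6, 0.5, 1)
  # every subject is a scaled copy of one prototype: both halves always
  # factorize to the same three patterns
  X <- proto[, rep(1:3, each = 20)] * rep(runif(60, 0.5, 2), each = 20)
  curve <- stability_analysis(X, k_range = 2:4, n_splits = 6, seed = 1,
                              tol = 1e-6)
  expect_gt(curve$stability[curve$k == 3], 1 - 1e-6)
  expect_equal(attr(curve, "n_splits"), 6)
  # gradient defined only once k-2 is inside the evaluated range
  expect_true(all(is.na(curve$error_gradient[1:2])))
  expect_false(is.na(curve$error_gradient[3]))
})

test_that("stability analysis validates inputs and handles odd cohorts", {
  X <- matrix(abs(rnorm(10 * 9)), 10)
  expect_error(stability_analysis(X, k_range = 1:3), "k_range")
  expect_error(stability_analysis(X[, 1:5], k_range = 2:3), "at least 8")
  curve <- stability_analysis(X, k_range = 2:3, n_splits = 2, seed = 1)
  expect_equal(nrow(curve), 2)           # odd n: larger half absorbs one
})

test_that("planted rank yields a stability peak and select_k finds it", {
  pl <- planted_nmf(seed = 102, m = 40, n = 80, k = 4, snr = 50,
                    supp = 8)
  curve <- stability_analysis(pl$X, k_range = 2:7, n_splits = 6,
                              seed = 2)
  expect_gt(curve$stability[curve$k == 4], 0.95)
  expect_true(all(curve$stability[curve$k > 4] <
                    curve$stability[curve$k == 4]))
  sel <- select_k(curve)
  expect_equal(sel$k, 4)
  expect_false(sel$no_elbow)
  # strictly increasing stability: boundary rank with the no-elbow flag
  fake <- data.frame(k = 2:6, stability = seq(0.5, 0.9, 0.1),
                     recon_error = 5:1,
                     error_gradient = c(NA, NA, -1, -1, -1))
  class(fake) <- c("stability_curve", "data.frame")
  sel <- select_k(fake)
  expect_true(sel$no_elbow)
  expect_equal(sel$k, 6)
})

test_that("factorization results serialize to CSV and JSON", {
  pl <- planted_nmf(seed = 103, m = 20, n = 30, k = 3, supp = 5)
  fit <- opnmf_fit(pl$X, 3)
  rownames(fit$W) <- paste0("r", 1:20)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_factorization(fit, csv, js)
  back <- read.csv(csv)
  expect_equal(dim(back), c(20L, 4L))
  expect_equal(back$component_1, unname(fit$W[, 1]), tolerance = 1e-12)
  pj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(pj$k, 3)
  expect_equal(pj$recon_error, fit$recon_error, tolerance = 1e-12)
})
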