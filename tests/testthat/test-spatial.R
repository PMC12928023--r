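# Multilinear spatial regression, dominance analysis, spatial nulls,
# distance-dependent CV, and term decoding.

test_that("multilinear fit handles exact, null and random cases", {
  set.seed(51)
  P <- matrix(rnorm(82 * 5), 82, dimnames = list(NULL, paste0("p", 1:5)))
  # map equal to one predictor: perfect fit
  fit <- multilinear_fit(P[, 2], P)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_equal(fit$adj_r2, 1, tolerance = 1e-12)
  # map orthogonal in sample to all predictors (and the intercept)
  y <- rnorm(82)
  y <- resid(lm(y ~ scale(P)))
  expect_lt(multilinear_fit(y, P)$r2, 1e-10)
  # random instance against an explicit normal-equations solver
  y <- rnorm(82)
  Zy <- drop(scale(y)); Zx <- scale(P)
  X <- cbind(1, Zx)
  beta <- solve(t(X) %*% X, t(X) %*% Zy)
  rss <- sum((Zy - X %*% beta)^2)
  r2 <- 1 - rss / sum((Zy - mean(Zy))^2)
  fit <- multilinear_fit(y, P)
  expect_equal(fit$r2, r2, tolerance = 1e-10)
  expect_equal(fit$adj_r2, 1 - (1 - r2) * 81 / (82 - 5 - 1),
               tolerance = 1e-10)
  # collinear predictors are rejected with the offending columns named
  P2 <- cbind(P, p6 = P[, 1] * (1 + 1e-13))
  expect_error(multilinear_fit(y, P2), "collinear")
})

test_that("dominance satisfies closed-form and brute-force oracles", {
  set.seed(52)
  y <- rnorm(82)
  P <- matrix(rnorm(82 * 3), 82)
  # single predictor: dominance is the whole R^2
  d1 <- dominance(y, P[, 1, drop = FALSE])
  expect_equal(unname(d1$dominance), d1$r2, tolerance = 1e-12)
  expect_equal(unname(d1$percent), 100, tolerance = 1e-9)
  # exactly orthogonal, centered predictors: dominance_i = squared
  # correlation with the map (orthogonal decomposition of R^2)
  M <- matrix(rnorm(82 * 4), 82)
  M <- sweep(M, 2, colMeans(M))           # centre, then orthogonalize
  Q <- qr.Q(qr(M))
  yq <- drop(Q %*% c(1, -0.5, 2, 0.3)) + rnorm(82, 0, 0.5)
  dq <- dominance(yq, Q)
  expect_equal(unname(dq$dominance), drop(cor(Q, yq))^2,
               tolerance = 1e-8)
  expect_equal(sum(dq$dominance), dq$r2, tolerance = 1e-10)
  # q = 3 against explicit subset enumeration with lm
  d3 <- dominance(y, P)
  r2of <- function(S) if (!length(S)) 0 else
    summary(lm(scale(y) ~ scale(P[, S])))$r.squared
  oracle <- vapply(1:3, function(j) {
    others <- setdiff(1:3, j)
    inc0 <- r2of(j) - 0
    inc1 <- mean(c(r2of(c(others[1], j)) - r2of(others[1]),
                   r2of(c(others[2], j)) - r2of(others[2])))
    inc2 <- r2of(1:3) - r2of(others)
    mean(c(inc0, inc1, inc2))
  }, 0)
  expect_equal(unname(d3$dominance), oracle, tolerance = 1e-10)
  expect_error(dominance(y, P[, integer(0)]), "no predictors")
})

test_that("the dominance identity holds on random instances and in sampling mode", {
  set.seed(53)
  for (q in c(2, 5, 8)) {
    y <- rnorm(60)
    P <- matrix(rnorm(60 * q), 60)
    d <- dominance(y, P)
    expect_equal(sum(d$dominance), d$r2, tolerance = 1e-8)
    expect_equal(sum(d$percent), 100, tolerance = 1e-6)
  }
  # stratified sampling approximates the exact decomposition
  y <- rnorm(82); P <- matrix(rnorm(82 * 6), 82)
  ex <- dominance(y, P)
  ap <- dominance(y, P, exact_max = 3, n_samples = 400, seed = 7)
  expect_equal(ap$method, "sampled")
  expect_lt(max(abs(ex$dominance - ap$dominance)), 0.02)
})

test_that("Benjamini-Hochberg adjustment matches the hand computation", {
  p <- c(0.001, 0.02, 0.03, 0.5, 0.9, 0.9, 0.9, 0.9)
  # hand computation: sort, multiply by m/i, enforce monotonicity
  o <- order(p); m <- length(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  hand <- numeric(m); hand[o] <- pmin(adj, 1)
  expect_equal(p.adjust(p, "BH"), hand, tolerance = 1e-12)
})

test_that("spatial nulls separate coupled from independent smooth maps", {
  atlas <- make_atlas(0)
  D <- region_distances(atlas)
  # coupled target: q-value significant
  mol <- simulate_molecular_maps(atlas, q = 6, length_scale = 30,
                                 seed = 61, target_subset = c(1, 4),
                                 target_weights = c(1, 0.8),
                                 target_noise = 0.3)
  res <- spatial_null_test(mol$target, mol$maps, D, n_surr = 100,
                           seed = 3)
  expect_lt(res$q_value[1], 0.05)
  expect_true(res$significant[1])
  # independent smooth maps: mostly non-significant across seeds
  ps <- vapply(1:20, function(s) {
    mm <- simulate_molecular_maps(atlas, q = 5, length_scale = 30,
                                  seed = 700 + s)
    spatial_null_test(mm$maps[, 1], mm$maps[, 2:5], D, n_surr = 200,
                      seed = s)$p_value
  }, 0)
  expect_gte(mean(ps > 0.05), 0.9)
  expect_error(spatial_null_test(rnorm(3), matrix(rnorm(9), 3),
                                 matrix(1, 3, 3) - diag(3), n_surr = 100),
               "distinct distances")
})

test_that("distance-dependent CV is exact for noiseless models and enumerable folds", {
  atlas <- make_atlas(0)
  D <- region_distances(atlas)
  set.seed(54)
  P <- matrix(rnorm(82 * 4), 82)
  y <- drop(P %*% c(1, -2, 0.5, 1))
  cv <- distance_dependent_cv(y, P, D)
  expect_equal(cv$n_train, 21)           # ceil(0.25 * 82)
  expect_equal(length(cv$fold_r), 82)
  expect_true(all(abs(cv$fold_r - 1) < 1e-8))
  # rigid rotation + translation of all centroids changes nothing
  th <- 0.7
  R <- diag(3); R[1:2, 1:2] <- matrix(c(cos(th), sin(th),
                                        -sin(th), cos(th)), 2)
  C2 <- as.matrix(atlas[, c("x", "y", "z")]) %*% R + 5
  cv2 <- distance_dependent_cv(y, P, as.matrix(dist(C2)))
  expect_equal(cv$fold_r, cv2$fold_r, tolerance = 1e-8)
  # 1-D toy atlas: nearest-2 training folds enumerable by hand
  D1 <- as.matrix(dist(1:8))
  P1 <- cbind(rnorm(8))
  y1 <- drop(P1) + rnorm(8)
  folds <- lapply(1:8, function(src) sort(order(D1[src, ])[1:2]))
  expected <- list(c(1, 2), c(1, 2), c(2, 3), c(3, 4), c(4, 5),
                   c(5, 6), c(6, 7), c(7, 8))
  expect_equal(folds, expected)
  # folds smaller than q + 2 are skipped with a warning
  expect_warning(distance_dependent_cv(y1, cbind(P1, rnorm(8)), D1,
                                       train_fraction = 0.25),
                 "skipped")
})

test_that("term decoding filters by association z and exclusion list", {
  atlas <- make_atlas(0)
  set.seed(55)
  x <- rnorm(82)
  # identity term: r = 1
  res <- decode_terms(x, cbind(self = x))
  expect_equal(res$correlations$r[1], 1)
  # elementary covariance-based oracle for the correlations
  tm <- matrix(rnorm(82 * 5), 82, dimnames = list(NULL, paste0("t", 1:5)))
  res <- decode_terms(x, tm, z_threshold = Inf)
  oracle <- vapply(1:5, function(j) {
    dx <- x - mean(x); dy <- tm[, j] - mean(tm[, j])
    sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
  }, 0)
  expect_equal(res$correlations$r, oracle, tolerance = 1e-12)
  # 50 candidate terms, 30 above threshold, 6 excluded as noise -> 24
  strong <- sapply(1:30, function(j) x + rnorm(82, 0, 0.6))
  weak <- matrix(rnorm(82 * 20), 82)
  maps50 <- cbind(strong, weak)
  colnames(maps50) <- paste0("term_", 1:50)
  res <- decode_terms(x, maps50, z_threshold = 3.1,
                      exclude = paste0("term_", 1:6))
  expect_equal(sum(res$correlations$z > 3.1), 30)
  expect_equal(res$n_retained, 24)
  expect_error(decode_terms(x[1:50], maps50), "aligned")
})
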