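# Shared fixture builders. Everything is generated in code at test time.

# small 8-region atlas (6 cortical, 2 subcortical) with fixed centroids
tiny_atlas <- function(seed = 11) {
  set.seed(seed)
  region_atlas(paste0("r", 1:8),
               rep(c("cortical_thickness", "subcortical_volume"), c(6, 2)),
               rep(c("left", "right"), 4),
               matrix(rnorm(24, 0, 30), 8))
}

# two-site reference table with linear age trends and a planted additive
# (+shift sd units) and multiplicative (x scale) site-B effect
two_site_fixture <- function(n = 400, shift = 0.3, scale = 1.4,
                             seed = 11) {
  set.seed(seed)
  atlas <- tiny_atlas(seed)
  demo <- data.frame(subject_id = paste0("s", seq_len(n)),
                     age = runif(n, 3, 18),
                     sex = sample(c("male", "female"), n, TRUE),
                     site = rep(c("A", "B"), each = n / 2),
                     group = "reference", stringsAsFactors = FALSE)
  slope <- runif(8, 0.8, 1.2)
  Y <- matrix(0, n, 8, dimnames = list(NULL, atlas$region_id))
  for (r in 1:8) {
    mu <- 2.5 + slope[r] * demo$age / 10 + 0.02 * (demo$sex == "male")
    e <- rnorm(n, 0, 0.1)
    y <- mu + e
    b <- demo$site == "B"
    y[b] <- mu[b] + shift * 0.1 + scale * e[b]
    Y[, r] <- y
  }
  df <- data.frame(subject_id = demo$subject_id, Y,
                   tiv = rnorm(n, 1.45e6, 1e5))
  list(atlas = atlas, morph = as_morphometry(df, atlas),
       demo = as_demographics(demo), slope = slope)
}

# planted sparse nonnegative factorization instance at a given SNR
planted_nmf <- function(seed, m = 82, n = 187, k = 8, snr = 10,
                        supp = 10) {
  set.seed(seed)
  W <- matrix(0, m, k)
  perm <- sample(m)
  for (c in seq_len(k))
    W[perm[((c - 1) * supp + 1):(c * supp)], c] <- runif(supp, 0.5, 1.5)
  W <- sweep(W, 2, sqrt(colSums(W^2)), "/")
  S <- W %*% matrix(abs(rnorm(k * n)), k)
  X <- S + abs(matrix(rnorm(m * n), m)) * sqrt(sum(S^2) / (m * n) / snr)
  list(X = X, W = W)
}

# brute-force minimum-cost assignment by permutation enumeration
brute_assign <- function(cost) {
  k <- nrow(cost)
  permute <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i)
      lapply(permute(v[-i]), function(p) c(v[i], p))))
  }
  best <- NULL; best_c <- Inf
  for (p in permute(seq_len(k))) {
    cc <- sum(cost[cbind(seq_len(k), p)])
    if (cc < best_c) { best_c <- cc; best <- p }
  }
  list(perm = best, cost = best_c)
}
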