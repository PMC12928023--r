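# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code with a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded package functions do not perturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Deterministic per-stage seed derived from a master seed
#'
#' Stable string hash (31-adic, mod a Mersenne prime) combined with the
#' master seed; always a positive 32-bit integer.
#' @noRd
spawn_seed <- function(master, stage) {
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 2147483647
  as.integer((as.numeric(master) * 7919 + h) %% 2147483629 + 1)
}

#' Column-wise z-scoring that errors on zero-variance columns
#' @noRd
zscore_cols <- function(m, what = "matrix") {
  m <- as.matrix(m)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0 | !is.finite(sds))) {
    bad <- colnames(m)[sds == 0 | !is.finite(sds)]
    if (is.null(bad)) bad <- which(sds == 0 | !is.finite(sds))
    stop("zero-variance column(s) in ", what, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  scale(m)
}

#' Cosine similarity between the columns of two matrices
#' @noRd
cosine_cols <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  na <- sqrt(colSums(a^2)); nb <- sqrt(colSums(b^2))
  na[na == 0] <- 1; nb[nb == 0] <- 1
  crossprod(a, b) / outer(na, nb)
}

#' Minimum-cost assignment (Hungarian algorithm, O(n^3))
#'
#' Solves the linear assignment problem for a square or wide (n <= m) cost
#' matrix using the shortest-augmenting-path formulation with potentials.
#'
#' @param cost numeric matrix, `nrow(cost) <= ncol(cost)`.
#' @return integer vector `a` with `a[i]` the column assigned to row `i`.
#' @noRd
hungarian_assign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n > m) stop("cost matrix must have nrow <= ncol")
  u <- numeric(n + 1L)          # row potentials (index i)
  v <- numeric(m + 1L)          # col potentials (index j+1, j = 0..m)
  p0 <- integer(m + 1L)         # p0[j+1]: row matched to column j (0 = none)
  way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p0[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1L)
    used <- logical(m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p0[j0 + 1L]
      delta <- Inf; j1 <- -1L
      for (j in seq_len(m)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1L]
          if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
          if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p0[j + 1L]] <- u[p0[j + 1L]] + delta
          if (j > 0L) v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p0[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p0[j0 + 1L] <- p0[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p0[j + 1L] > 0L) ans[p0[j + 1L]] <- j
  ans
}

#' Match columns of two matrices by maximum total cosine similarity
#' @return list(pairs = integer vector (col of b matched to each col of a),
#'   similarity = matched cosine values)
#' @noRd
match_components <- function(a, b) {
  sim <- cosine_cols(a, b)
  idx <- hungarian_assign(max(sim) - sim)
  list(pairs = idx, similarity = sim[cbind(seq_len(nrow(sim)), idx)])
}

#' Write an R object to JSON at full double precision
#' @noRd
write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}
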