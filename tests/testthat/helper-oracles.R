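# Independent oracles and small utilities shared across tests. These
# deliberately avoid the package's own code paths.

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# best matching of recovered components to truth by mean cosine similarity;
# returns the permutation p with recovered[p[i]] matched to truth i
match_components <- function(W_rec, W_true) {
  k <- ncol(W_true)
  best <- NULL; best_v <- -Inf
  for (p in all_perms(k)) {
    v <- mean(vapply(seq_len(k), function(i) cosine_sim(W_rec[, p[i]], W_true[, i]),
                     numeric(1)))
    if (v > best_v) { best_v <- v; best <- p }
  }
  best
}

# trapezoid weights, written independently of the package helper
trapz_w <- function(x) {
  n <- length(x)
  w <- numeric(n)
  d <- diff(x)
  w[1] <- d[1] / 2; w[n] <- d[n - 1] / 2
  if (n > 2) w[2:(n - 1)] <- (d[-(n - 1)] + d[-1]) / 2
  w
}

# brute-force SNIP clipping recurrence (plain loop over channels)
snip_oracle <- function(y, M) {
  n <- length(y)
  for (m in seq_len(M)) {
    ynew <- y
    for (i in seq_len(n)) {
      if (i - m >= 1 && i + m <= n) {
        ynew[i] <- min(y[i], (y[i - m] + y[i + m]) / 2)
      }
    }
    y <- ynew
  }
  y
}

# alternating non-negative least squares NMF oracle built on
# pracma::lsqnonneg (active set); independent of the package's
# multiplicative updates
anls_oracle <- function(A, k, n_iter = 100, n_restarts = 3, seed = 1) {
  best_obj <- Inf
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r)
    W <- matrix(runif(nrow(A) * k, 0, max(A)), nrow(A), k)
    S <- matrix(runif(k * ncol(A), 0, max(A)), k, ncol(A))
    for (it in seq_len(n_iter)) {
      for (j in seq_len(ncol(A))) S[, j] <- pracma::lsqnonneg(W, A[, j])$x
      for (i in seq_len(nrow(A))) W[i, ] <- pracma::lsqnonneg(t(S), A[i, ])$x
      if (all(W == 0) || all(S == 0)) break
    }
    obj <- sum((A - W %*% S)^2)
    if (obj < best_obj) best_obj <- obj
  }
  best_obj
}

# per-pixel non-negative least squares projection onto known pure spectra
nnls_abundance_oracle <- function(A, W_true) {
  vapply(seq_len(ncol(A)), function(j) pracma::lsqnonneg(W_true, A[, j])$x,
         numeric(ncol(W_true)))
}

# brute-force Venn region counts: per-element membership pattern
venn_oracle <- function(sets) {
  sets <- lapply(sets, function(v) unique(tolower(v)))
  u <- unique(unlist(sets))
  s <- length(sets)
  counts <- integer(2^s - 1L)
  for (el in u) {
    pat <- sum(2^(which(vapply(sets, function(v) el %in% v, logical(1))) - 1L))
    counts[pat] <- counts[pat] + 1L
  }
  counts
}

# brute-force DEG scan
deg_oracle <- function(tab, fc = 1, p = 0.05) {
  keep <- logical(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    keep[i] <- abs(tab$log2fc[i]) > fc && tab$p[i] < p
  }
  which(keep)
}

# a small preprocessed map for NMF tests: noiseless rank-k construction
rank_k_map <- function(k = 1, nx = 8, ny = 6, n = 120, seed = 1) {
  set.seed(seed)
  axis <- seq(400, 2000, length.out = n)
  W <- matrix(runif(n * k, 0, 1), n, k)
  S <- matrix(runif(k * nx * ny, 0, 2), k, nx * ny)
  hyperspectral_map(axis, W %*% S, nx, ny)
}
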