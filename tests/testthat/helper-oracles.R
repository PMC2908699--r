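# Independent oracles shared by the unit and acceptance suites.

# independent fixed-point oracle for pfcm: a direct transcription of the
# documented update scheme (k-means++-style seeding, constrained
# fuzzy-c-means centroid iteration, bandwidths from the converged
# partition, possibilistic read-out), written without reference to the
# package internals
pfcm_oracle <- function(X, c, m = 2, max_iter = 100, tol = 1e-6, seed = 1) {
  n <- nrow(X)
  uniq <- unique(X)
  set.seed(seed)
  DU <- as.matrix(dist(uniq))
  picked <- sample.int(nrow(uniq), 1)
  while (length(picked) < c) {
    d2min <- apply(DU[, picked, drop = FALSE], 1, min)^2
    d2min[picked] <- 0
    picked <- c(picked, if (sum(d2min) > 0)
      sample.int(nrow(uniq), 1, prob = d2min)
      else sample(setdiff(seq_len(nrow(uniq)), picked), 1))
  }
  v <- uniq[picked, , drop = FALSE]
  d2fun <- function(v) {
    out <- matrix(0, nrow(v), n)
    for (i in seq_len(nrow(v)))
      out[i, ] <- colSums((t(X) - v[i, ])^2)
    out
  }
  wfun <- function(d2) {
    if (c == 1) return(matrix(1, 1, n))
    d2 <- pmax(d2, 1e-12)
    inv <- d2^(-1 / (m - 1))
    sweep(inv, 2, colSums(inv), "/")
  }
  for (it in seq_len(max_iter)) {
    w <- wfun(d2fun(v))^m
    v_new <- (w %*% X) / rowSums(w)
    if (max(sqrt(rowSums((v_new - v)^2))) < tol) { v <- v_new; break }
    v <- v_new
  }
  d2 <- d2fun(v)
  w <- wfun(d2)
  wm <- w^m
  eta <- pmax(rowSums(wm * d2) / rowSums(wm), 1e-6)
  u <- 1 / (1 + (d2 / eta)^(1 / (m - 1)))
  u[d2 == 0] <- 1
  list(u = u, v = v, eta = eta)
}

# exact hypergeometric upper tail by direct enumeration of n-subsets
enum_hyper_pi <- function(p, h, n, g) {
  picks <- combn(g, n)
  mean(apply(picks, 2, function(s) sum(s <= h) >= p))
}
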