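# Rate of evolution of binding sites: Halpern-Bruno fixation-weighted
# rates built on an HKY85 background mutation matrix.  Distances
# (rate x time) rather than rates are reported throughout, under the
# assumption that all sites within one species share the same divergence
# time; differences in distance therefore reflect differences in rate.

#' Build an HKY85 substitution model
#'
#' Rate matrix `Q[a,b] = mu * kappa * pi_b` for transitions and
#' `mu * pi_b` for transversions, with `mu` chosen so the expected
#' substitution rate at equilibrium is 1; `scale` multiplies Q so that
#' `K_background = scale` substitutions.
#'
#' @param kappa transition/transversion rate ratio (> 0).
#' @param pi equilibrium base frequencies (A,C,G,T), summing to 1.
#' @param scale overall distance scale (expected substitutions at
#'   equilibrium; default 1).
#' @return a `subst_model`: list with `kind`, `kappa`, `pi`, `scale`,
#'   `Q` (4 x 4, rows sum to 0).
#' @export
hky85_model <- function(kappa, pi = rep(0.25, 4), scale = 1) {
  stopifnot(kappa > 0, length(pi) == 4, abs(sum(pi) - 1) < 1e-8,
            all(pi > 0))
  names(pi) <- DNA_BASES
  transitions <- matrix(FALSE, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  transitions["A", "G"] <- transitions["G", "A"] <- TRUE
  transitions["C", "T"] <- transitions["T", "C"] <- TRUE
  Q <- matrix(rep(pi, each = 4), 4, 4,
              dimnames = list(DNA_BASES, DNA_BASES))
  Q[transitions] <- Q[transitions] * kappa
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))  # expected rate before normalization
  Q <- Q / mu * scale
  structure(list(kind = "HKY85", kappa = kappa, pi = pi, scale = scale,
                 Q = Q), class = "subst_model")
}

#' Estimate an HKY85 background model from aligned sequences
#'
#' Equilibrium frequencies come from the observed base composition;
#' kappa and the pairwise distance are fit by maximizing the HKY85
#' likelihood of the pooled substitution pattern counts over
#' non-overlapping sequence pairs (1,2), (3,4), ...  Deterministic given
#' the input.
#'
#' @param sequences character vector of aligned, equal-length DNA
#'   sequences (>= 2); gaps are not supported.
#' @return a `subst_model` with `scale` set to the fitted pairwise
#'   distance and an extra `loglik` element.
#' @export
estimate_hky85 <- function(sequences) {
  sequences <- toupper(sequences)
  if (length(sequences) < 2L) stop("need >= 2 aligned sequences")
  if (length(unique(nchar(sequences))) != 1L)
    stop("sequences must be aligned to equal length")
  if (any(grepl("[^ACGT]", sequences)))
    stop("gaps/ambiguity codes are not supported")
  chars <- strsplit(sequences, "")
  tab <- table(factor(unlist(chars), levels = DNA_BASES))
  pi <- as.numeric(tab) / sum(tab)
  pi <- pmax(pi, 1e-6); pi <- pi / sum(pi)
  npair <- length(sequences) %/% 2L
  N <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  for (k in seq_len(npair)) {
    a <- match(chars[[2L * k - 1L]], DNA_BASES)
    b <- match(chars[[2L * k]], DNA_BASES)
    for (i in seq_along(a)) N[a[i], b[i]] <- N[a[i], b[i]] + 1
  }
  nll <- function(par) {
    kappa <- exp(par[1]); t <- exp(par[2])
    Q <- hky85_model(kappa, pi)$Q
    P <- mat_exp(Q * t)
    lp <- log(pmax(sweep(P, 1, pi, "*"), 1e-300))
    -sum(N * lp)
  }
  fit <- stats::optim(c(log(2), log(0.1)), nll, method = "Nelder-Mead",
                      control = list(maxit = 1000, reltol = 1e-10))
  kappa <- exp(fit$par[1]); t_hat <- exp(fit$par[2])
  m <- hky85_model(kappa, pi, scale = t_hat)
  m$loglik <- -fit$value
  m
}

# matrix exponential via eigendecomposition (the HKY85/HB generators used
# here are reversible, hence diagonalizable with real spectrum)
mat_exp <- function(M) {
  e <- eigen(M)
  P <- Re(e$vectors %*% diag(exp(e$values)) %*% solve(e$vectors))
  dimnames(P) <- dimnames(M)
  pmax(P, 0)
}

#' Halpern-Bruno substitution rate for one base pair at one position
#'
#' `R_ab = Q_ab * ln(lambda) / (1 - 1/lambda)` with selective ratio
#' `lambda = (f_b Q_ba) / (f_a Q_ab)`; reduces to the background `Q_ab`
#' when `lambda = 1` (no selection) and vanishes as `f_b -> 0`
#' (substitutions toward a forbidden base are suppressed).
#'
#' @param Q background rate matrix (from a `subst_model`).
#' @param f strictly positive length-4 PWM column (A,C,G,T).
#' @param a,b origin and target bases (`"A".."T"` or indices), `a != b`.
#' @return substitution rate (same scale as Q).
#' @export
hb_rate <- function(Q, f, a, b) {
  if (is.character(a)) a <- match(a, DNA_BASES)
  if (is.character(b)) b <- match(b, DNA_BASES)
  if (a == b) stop("a and b must differ")
  if (any(f <= 0)) stop("domain error: PWM column must be strictly ",
                        "positive (apply a pseudocount)")
  lam <- (f[b] * Q[b, a]) / (f[a] * Q[a, b])
  if (abs(lam - 1) < 1e-12) return(Q[a, b])
  Q[a, b] * log(lam) / (1 - 1 / lam)
}

# full 4x4 HB rate matrix for one PWM column; diagonal re-derived so rows
# sum to 0
hb_rate_matrix <- function(Q, f) {
  R <- matrix(0, 4, 4, dimnames = dimnames(Q))
  for (a in 1:4) for (b in 1:4) if (a != b) R[a, b] <- hb_rate(Q, f, a, b)
  diag(R) <- -rowSums(R)
  R
}

#' Per-position expected substitution distance profile
#'
#' For each PWM position, the expected distance under the Halpern-Bruno
#' model (`K_model = sum_a f_a sum_{b != a} R_ab`, the PWM column as the
#' initial/stationary distribution) and under the background alone
#' (`K_background = sum_a pi_a sum_{b != a} Q_ab`, constant across
#' positions).  Since Q already carries the distance scale, K is a
#' distance (substitutions), not a rate.  Positions of high information
#' content get small `K_model`: selection slows evolution.
#'
#' @param pwm a `pwm_model` (columns must be strictly positive; use a
#'   pseudocount).
#' @param model a `subst_model`.
#' @return a `rate_profile`: data.frame with `position`, `K_model`,
#'   `K_background`, `ic`.
#' @export
expected_distance_profile <- function(pwm, model) {
  Q <- model$Q
  L <- ncol(pwm$freqs)
  Kbg <- sum(model$pi * -diag(Q))
  ic <- information_content(pwm)$per_position
  Km <- vapply(seq_len(L), function(p) {
    f <- pwm$freqs[, p]
    R <- hb_rate_matrix(Q, f)
    sum(f * -diag(R))
  }, numeric(1))
  out <- data.frame(position = seq_len(L), K_model = Km,
                    K_background = Kbg, ic = ic)
  class(out) <- c("rate_profile", "data.frame")
  out
}

#' Mean square difference between two rate profiles
#'
#' @param profile1,profile2 `rate_profile`s of equal length.
#' @param field column compared (default `"K_model"`).
#' @return mean over positions of squared differences.
#' @export
msd <- function(profile1, profile2, field = "K_model") {
  if (nrow(profile1) != nrow(profile2))
    stop("profiles have different lengths")
  mean((profile1[[field]] - profile2[[field]])^2)
}

#' Simulate binding-site evolution under the Halpern-Bruno model
#'
#' Each site evolves independently: per position, the substitution
#' process with the HB rate matrix of that position's PWM column is
#' exponentiated over `time` and the new base sampled from the resulting
#' transition row.
#'
#' @param sites a [site_collection()].
#' @param pwm the `pwm_model` defining per-position selection.
#' @param model background `subst_model`.
#' @param time divergence time on the model's distance scale (>= 0).
#' @param seed RNG seed.
#' @return an evolved [site_collection()] with the same metadata.
#' @export
simulate_site_evolution <- function(sites, pwm, model, time, seed = 1L) {
  if (time < 0) stop("negative time")
  L <- sites$length
  stopifnot(L == ncol(pwm$freqs))
  n <- nrow(sites$sites)
  chars <- matrix(match(unlist(strsplit(sites$sites$sequence, "")),
                        DNA_BASES), nrow = n, byrow = TRUE)
  if (time > 0) {
    Ps <- lapply(seq_len(L), function(p) {
      R <- hb_rate_matrix(model$Q, pwm$freqs[, p])
      P <- mat_exp(R * time)
      P / rowSums(P)
    })
    with_seed(seed, {
      for (p in seq_len(L)) {
        P <- Ps[[p]]
        old <- chars[, p]
        for (a in 1:4) {
          idx <- which(old == a)
          if (length(idx))
            chars[idx, p] <- sample.int(4, length(idx), replace = TRUE,
                                        prob = P[a, ])
        }
      }
    })
  }
  out <- sites
  out$sites$sequence <- apply(chars, 1, function(r)
    paste(DNA_BASES[r], collapse = ""))
  out
}

#' Write a rate profile as TSV
#'
#' @param profile a `rate_profile`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
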