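test_that("hky85_model builds a valid normalized generator", {
  m <- hky85_model(4, pi = c(0.3, 0.2, 0.2, 0.3), scale = 2)
  expect_equal(rowSums(m$Q), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  off <- m$Q; diag(off) <- 0
  expect_true(all(off >= 0))
  # expected rate at equilibrium equals the scale
  expect_equal(-sum(m$pi * diag(m$Q)), 2)
  # transition entries carry the kappa factor
  expect_equal(m$Q["A", "G"] / m$Q["A", "C"], 4 * m$pi["G"] / m$pi["C"],
               ignore_attr = TRUE)
  expect_error(hky85_model(-1))
})

test_that("estimate_hky85 recovers kappa, pi and the AT-rich composition", {
  m0 <- hky85_model(4, scale = 0.5)
  anc <- site_collection(sample_background(1000, 19, 0.5, 0, seed = 7))
  upwm <- submotifr:::new_pwm(matrix(0.25, 4, 19))
  ev <- simulate_site_evolution(anc, upwm, m0, time = 1, seed = 8)
  fit <- estimate_hky85(as.vector(rbind(anc$sites$sequence,
                                        ev$sites$sequence)))
  expect_lte(abs(fit$kappa - 4) / 4, 0.2)
  expect_lte(max(abs(fit$pi - 0.25)), 0.02)
  expect_lte(abs(fit$scale - 0.5) / 0.5, 0.2)
  # AT-rich background: pi_A + pi_T within 0.05 of 0.7
  at <- estimate_hky85(sample_background(1000, 19, 0.3, 0, seed = 21))
  expect_lte(abs(sum(at$pi[c(1, 4)]) - 0.7), 0.05)
  expect_error(estimate_hky85(c("AC-T", "ACGT")), "gap")
  expect_error(estimate_hky85("ACGT"), ">= 2")
})

test_that("hb_rate hits the neutral limit, the suppression limit, and the formula oracle", {
  Q <- hky85_model(2)$Q
  # equal frequencies with reversible Q at uniform pi: rate = Q_ab
  expect_equal(hb_rate(Q, rep(0.25, 4), "A", "G"), Q["A", "G"])
  # substitutions toward a vanishing base are suppressed
  f <- c(0.25, 0.25, 0.25, 0.25)
  rates <- vapply(c(1e-4, 1e-6, 1e-8), function(eps) {
    fb <- c(1 - 3 * eps, eps, eps, eps)
    hb_rate(Q, fb, "A", "C")
  }, numeric(1))
  expect_true(all(diff(rates) < 0))
  expect_lt(rates[3], 1e-6)
  # independent transcription of the fixation-weighted form
  hb_oracle <- function(Q, f, a, b) {
    lam <- (f[b] * Q[b, a]) / (f[a] * Q[a, b])
    if (abs(lam - 1) < 1e-12) return(Q[a, b])
    Q[a, b] * log(lam) / (1 - 1 / lam)
  }
  f2 <- c(0.7, 0.1, 0.1, 0.1)
  Qr <- hky85_model(3, pi = c(0.2, 0.3, 0.3, 0.2))$Q
  for (a in 1:4) for (b in 1:4) if (a != b)
    expect_equal(hb_rate(Qr, f2, a, b), hb_oracle(Qr, f2, a, b),
                 tolerance = 1e-14)
  expect_error(hb_rate(Q, c(0.5, 0.5, 0, 0), 1, 2), "positive")
  expect_error(hb_rate(Q, f2, 2, 2), "differ")
})

test_that("HB generator rows sum to zero and respect stationarity", {
  Q <- hky85_model(4, pi = c(0.3, 0.2, 0.2, 0.3))$Q
  f <- c(0.6, 0.2, 0.1, 0.1)
  R <- submotifr:::hb_rate_matrix(Q, f)
  expect_equal(rowSums(R), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  # f is stationary: f %*% expm(R t) = f on a small time grid
  for (t in c(0.1, 1, 10)) {
    P <- submotifr:::mat_exp(R * t)
    expect_equal(as.vector(f %*% P), f, tolerance = 1e-8)
  }
})

test_that("expected distance profile: equilibrium equality, conservation slowdown, IC anticorrelation", {
  m <- hky85_model(4)
  # uniform column at uniform pi: K_model == K_background to 1e-9
  pu <- submotifr:::new_pwm(matrix(0.25, 4, 3))
  prof <- expected_distance_profile(pu, m)
  expect_lt(max(abs(prof$K_model - prof$K_background)), 1e-9)
  # near-deterministic column evolves slower than background
  f <- cbind(c(0.97, 0.01, 0.01, 0.01), rep(0.25, 4))
  pd <- submotifr:::new_pwm(sweep(f, 2, colSums(f), "/"))
  profd <- expected_distance_profile(pd, m)
  expect_lt(profd$K_model[1], profd$K_background[1])
  # Spearman(ic, K) <= -0.9 over a wide concentration range
  set.seed(9)
  alphas <- exp(runif(100, log(0.05), log(5)))
  cols <- sapply(alphas, function(a) { x <- rgamma(4, a) + 1e-4; x / sum(x) })
  pw <- submotifr:::new_pwm(sweep(cols, 2, colSums(cols), "/"))
  pr <- expected_distance_profile(pw, m)
  expect_lte(cor(pr$ic, pr$K_model, method = "spearman"), -0.9)
})

test_that("K is invariant under consistent base relabeling", {
  pi <- c(0.3, 0.2, 0.2, 0.3)
  f <- c(0.5, 0.3, 0.1, 0.1)
  perm <- c(2, 1, 4, 3)
  Q1 <- hky85_model(4, pi)$Q
  # relabel: permute pi and f consistently; HKY85 transition structure is
  # preserved by the A<->C, G<->T swap only in Q itself, so permute Q
  Q2 <- Q1[perm, perm]
  K1 <- sum(f * -diag(submotifr:::hb_rate_matrix(Q1, f)))
  K2 <- sum(f[perm] * -diag(submotifr:::hb_rate_matrix(Q2, f[perm])))
  expect_equal(K1, K2, tolerance = 1e-12)
})

test_that("msd computes mean squared profile differences with the published ordering", {
  m <- hky85_model(4)
  pu <- submotifr:::new_pwm(matrix(0.25, 4, 5))
  p1 <- expected_distance_profile(pu, m)
  expect_equal(msd(p1, p1), 0)
  p2 <- p1
  p2$K_model <- p1$K_model + 0.3
  expect_equal(msd(p1, p2), 0.09)
  expect_error(msd(p1, expected_distance_profile(
    submotifr:::new_pwm(matrix(0.25, 4, 3)), m)), "length")
  # a slow, high-information submotif deviates more from the background
  # than a mutable low-information one (cf. ancestral vs acquired boxes)
  m_at <- hky85_model(4, pi = c(0.35, 0.15, 0.15, 0.35))
  high <- submotifr:::new_pwm(submotifr:::pwm_from_consensus(
    rep("A", 19), rep(0.95, 19)))
  low <- submotifr:::new_pwm(submotifr:::pwm_from_consensus(
    rep("G", 19), rep(0.6, 19)))
  ph <- expected_distance_profile(high, m_at)
  pl <- expected_distance_profile(low, m_at)
  bg <- ph; bg$K_model <- bg$K_background
  bg_l <- pl; bg_l$K_model <- bg_l$K_background
  expect_gt(msd(ph, bg), msd(pl, bg_l))
})

test_that("simulate_site_evolution: identity at t=0, stationarity at large t, Monte Carlo matches K", {
  cfg <- synth_config(seed = 3)
  pwm <- make_submotif_pwms(cfg)$pwms[[1]]
  sites <- sample_sites(pwm, 50, seed = 4)
  m <- hky85_model(4, scale = 0.1)
  expect_identical(simulate_site_evolution(sites, pwm, m, 0, seed = 5)$sites,
                   sites$sites)
  expect_error(simulate_site_evolution(sites, pwm, m, -1), "negative")
  # t -> infinity: base frequencies converge to the column's stationary
  # distribution (matrix-exponential oracle)
  strong <- submotifr:::new_pwm(submotifr:::pwm_from_consensus(
    rep("A", 5), rep(0.7, 5)))
  start <- site_collection(rep(strrep("T", 5), 800),
                           site_id = paste0("s", 1:800))
  evolved <- simulate_site_evolution(start, strong, hky85_model(4), 50,
                                     seed = 6)
  freqA <- mean(vapply(strsplit(evolved$sites$sequence, ""),
                       function(x) mean(x == "A"), numeric(1)))
  expect_lt(abs(freqA - 0.7), 0.05)
  # observed substitution fraction matches predicted K within 10% at
  # short distance (multiple hits negligible), n = 1000 sites
  ss <- sample_sites(strong, 1000, seed = 11)
  sm <- hky85_model(4, scale = 0.1)
  ev <- simulate_site_evolution(ss, strong, sm, time = 1, seed = 12)
  obs <- mean(mapply(function(x, y)
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
    ss$sites$sequence, ev$sites$sequence)) / 5
  pred <- mean(expected_distance_profile(strong, sm)$K_model)
  expect_lte(abs(obs - pred) / pred, 0.1)
})

test_that("estimate -> simulate -> estimate closes the loop on kappa", {
  m0 <- hky85_model(3, scale = 0.4)
  anc <- site_collection(sample_background(600, 19, 0.5, 0, seed = 51))
  upwm <- submotifr:::new_pwm(matrix(0.25, 4, 19))
  ev <- simulate_site_evolution(anc, upwm, m0, 1, seed = 52)
  fit1 <- estimate_hky85(as.vector(rbind(anc$sites$sequence,
                                         ev$sites$sequence)))
  # re-simulate under the fitted model and re-estimate
  ev2 <- simulate_site_evolution(anc, upwm, hky85_model(fit1$kappa,
                                                        fit1$pi,
                                                        fit1$scale),
                                 1, seed = 53)
  fit2 <- estimate_hky85(as.vector(rbind(anc$sites$sequence,
                                         ev2$sites$sequence)))
  expect_lte(abs(fit2$kappa - fit1$kappa) / fit1$kappa, 0.2)
})
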