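# Shared fixtures and small oracles, all generated in code.

BASES <- c("A", "C", "G", "T")

# adjusted Rand index between two label vectors (closed-form oracle)
ari <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  n2 <- choose(sum(tab), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# labels of hard cluster assignments for a list of clusters
cluster_labels <- function(clusters, collection) {
  lab <- rep(NA_integer_, nrow(collection$sites))
  for (i in seq_along(clusters))
    lab[match(clusters[[i]]$member_ids, collection$sites$site_id)] <- i
  lab
}

# nested two-level fixture: 2 supergroups (consensus differing at k_c
# positions) each split into 2 subgroups (differing at k_f positions);
# per-site noise = one mutation at a neutral position, so the realized
# Xie-Beni values at c = 2 and c = 4 are nearly deterministic and tie
# within the 5% model-order tolerance by construction
make_nested_fixture <- function(seed, n_per = 15, k_c = 8, k_f = 4) {
  L <- 21
  set.seed(seed)
  base <- sample(BASES, L, replace = TRUE)
  coarse_pos <- 1:k_c
  fa <- (k_c + 1):(k_c + k_f)
  fb <- (k_c + k_f + 1):(k_c + 2 * k_f)
  rest <- (k_c + 2 * k_f + 1):L
  mk <- function(coarse_alt, fine_pos, fine_alt) {
    s <- base
    if (coarse_alt) for (p in coarse_pos) s[p] <- setdiff(BASES, s[p])[1]
    if (fine_alt) for (p in fine_pos) s[p] <- setdiff(BASES, s[p])[1]
    s
  }
  cons <- list(A1 = mk(FALSE, fa, FALSE), A2 = mk(FALSE, fa, TRUE),
               B1 = mk(TRUE, fb, FALSE), B2 = mk(TRUE, fb, TRUE))
  seqs <- character(0); lab <- character(0)
  for (g in names(cons)) for (i in seq_len(n_per)) {
    s <- cons[[g]]
    p <- sample(rest, 1)
    s[p] <- sample(setdiff(BASES, s[p]), 1)
    seqs <- c(seqs, paste(s, collapse = ""))
    lab <- c(lab, g)
  }
  list(coll = site_collection(seqs), lab = lab,
       coarse = substr(lab, 1, 1))
}

# flat k-group mixture without substructure: k dissimilar planted PWMs
make_flat_mixture <- function(seed, n_groups = 3, n_per = 20) {
  cfg <- synth_config(n_families = n_groups, submotifs_per_family = 1,
                      sites_per_submotif = n_per, seed = seed)
  ts <- make_training_set(cfg)
  list(coll = ts$positives, lab = ts$truth_labels$family, ts = ts)
}

# two strongly conserved dissimilar PWMs (sizes 25/15) plus intermediate
# decoy negatives (weaker consensus with 4 positions switched to the
# stronger consensus) -- the world in which subtractive clustering peels
# family by family
make_subtractive_world <- function(seed) {
  set.seed(seed)
  L <- 19
  cA <- sample(BASES, L, replace = TRUE)
  cB <- vapply(cA, function(x) sample(setdiff(BASES, x), 1), character(1),
               USE.NAMES = FALSE)
  lev <- rep(0.99, L)
  pA <- submotifr:::new_pwm(submotifr:::pwm_from_consensus(cA, lev), name = "A")
  pB <- submotifr:::new_pwm(submotifr:::pwm_from_consensus(cB, lev), name = "B")
  cD <- cB
  swp <- sample(L, 4)
  cD[swp] <- cA[swp]
  pD <- submotifr:::new_pwm(submotifr:::pwm_from_consensus(cD, lev), name = "D")
  a <- sample_sites(pA, 25, seed = seed + 1, prefix = "a")
  b <- sample_sites(pB, 15, seed = seed + 2, prefix = "b")
  coll <- site_collection(c(a$sites$sequence, b$sites$sequence),
                          site_id = c(a$sites$site_id, b$sites$site_id))
  negs <- site_collection(
    sample_sites(pD, 60, seed = seed + 3, prefix = "n")$sites$sequence)
  list(coll = coll, negatives = negs, lab = rep(c("A", "B"), c(25, 15)),
       pwms = list(A = pA, B = pB))
}

# truth-labelled submotif PWMs (children) built from a training set
truth_submotifs <- function(ts) {
  lapply(names(ts$family_of), function(sid)
    build_pwm(ts$positives[ts$truth_labels$site_id[
      ts$truth_labels$submotif == sid]], name = sid))
}

# best single-motif SCC: one PWM over all positives, threshold by
# exhaustive scan over observed scores (most favorable single classifier)
best_single_scc <- function(positives, negatives) {
  single <- build_pwm(positives, name = "single")
  sp <- score_sequence(single, positives$sites$sequence)
  sn <- score_sequence(single, negatives$sites$sequence)
  max(vapply(sort(unique(c(sp, sn))), function(t)
    scc(confusion_counts(TP = sum(sp >= t), FN = sum(sp < t),
                         FP = sum(sn >= t), TN = sum(sn < t))),
    numeric(1)))
}
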