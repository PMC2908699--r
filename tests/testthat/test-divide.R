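test_that("pfcm matches the independent fixed-point oracle to 1e-8", {
  set.seed(2)
  # 6 sites in two Hamming-separated 3-site groups, plus a 20-site case
  g1 <- c("AAAAAA", "AAAAAC", "AAAACA")
  g2 <- c("TTTGGG", "TTTGGC", "TTTGCG")
  X <- one_hot_encode(site_collection(c(g1, g2)))
  for (sd in c(1, 7)) {
    p <- pfcm(X, 2, seed = sd)
    o <- pfcm_oracle(X, 2, seed = sd)
    expect_lt(max(abs(p$memberships - o$u)), 1e-8)
    expect_lt(max(abs(p$centroids - o$v)), 1e-8)
    expect_lt(max(abs(p$eta - o$eta)), 1e-8)
  }
  flat <- make_flat_mixture(11, n_groups = 3, n_per = 6)  # n = 18 sites
  X2 <- one_hot_encode(flat$coll)
  p <- pfcm(X2, 3, seed = 4)
  o <- pfcm_oracle(X2, 3, seed = 4)
  expect_lt(max(abs(p$memberships - o$u)), 1e-8)
  expect_lt(max(abs(p$centroids - o$v)), 1e-8)
})

test_that("pfcm memberships satisfy the possibilistic contract", {
  flat <- make_flat_mixture(3)
  X <- one_hot_encode(flat$coll)
  p <- pfcm(X, 3, seed = 2)
  expect_true(all(p$memberships >= 0 & p$memberships <= 1))
  # a site placed exactly at a centroid has membership 1
  Xc <- rbind(X, p$centroids[1, ])
  p2 <- pfcm(Xc, 3, init = p$centroids, max_iter = 0)
  expect_equal(unname(p2$memberships[1, nrow(Xc)]), 1)
  # an outlier far from all centroids weakly belongs to everything:
  # per position, take the base least used by any centroid
  far <- numeric(ncol(X))
  for (pos in seq(1, ncol(X), by = 4)) {
    blk <- pos:(pos + 3)
    far[blk[which.min(colSums(p$centroids[, blk, drop = FALSE]))]] <- 1
  }
  d_out <- colSums((t(p$centroids) - far)^2)
  expect_gt(min(d_out), 25)  # fixture sanity: outlier really is far
  u_out <- 1 / (1 + d_out / p$eta)
  # no cluster claims the outlier (all memberships below the 0.5 hard
  # cut, well under a member site's own membership)
  expect_true(all(u_out < 0.4))
  member_u <- max(p$memberships[, 1])
  expect_gt(member_u, max(u_out))
})

test_that("pfcm degenerate and error cases", {
  X <- one_hot_encode(site_collection(c("AAAA", "CCCC")))
  expect_error(pfcm(X, 3, seed = 1), "more clusters")
  expect_error(pfcm(X, 2, m = 1), "fuzzifier")
  # one cluster: centroid is the arithmetic mean
  p1 <- pfcm(X, 1, seed = 1)
  expect_equal(as.vector(p1$centroids), unname(colMeans(X)))
  # all-identical features with c > 1 flag duplicate centroids
  Xd <- one_hot_encode(site_collection(rep("ACGT", 5),
                                       site_id = paste0("s", 1:5)))
  pd <- pfcm(Xd, 2, seed = 1)
  expect_true(pd$duplicate_centroids)
  expect_false(pd$converged)
})

test_that("xie_beni prefers the planted model order and rejects coincident centroids", {
  flat <- make_flat_mixture(5, n_groups = 2, n_per = 15)
  X <- one_hot_encode(flat$coll)
  xb <- sapply(2:4, function(cc) {
    best <- Inf
    for (r in 1:3) {
      p <- pfcm(X, cc, seed = 10 * cc + r)
      if (p$duplicate_centroids) next
      best <- min(best, xie_beni(X, p))
    }
    best
  })
  expect_lt(xb[1], xb[2])
  expect_lt(xb[1], xb[3])
  # coincident centroids are an error
  p <- pfcm(X, 2, seed = 1)
  p$centroids[2, ] <- p$centroids[1, ]
  expect_error(xie_beni(X, p), "separation-zero")
  # scaling features by a constant leaves the argmin over c unchanged
  xb_scaled <- sapply(2:4, function(cc) {
    best <- Inf
    for (r in 1:3) {
      p <- pfcm(X * 3, cc, seed = 10 * cc + r)
      if (p$duplicate_centroids) next
      best <- min(best, xie_beni(X * 3, p))
    }
    best
  })
  expect_equal(which.min(xb), which.min(xb_scaled))
})

test_that("select_cluster_numbers recovers planted and nested model orders", {
  flat <- make_flat_mixture(8)
  sel <- select_cluster_numbers(one_hot_encode(flat$coll), 2:5,
                                runs_per_c = 3, seed = 4)
  expect_equal(sel$optimal, 3L)
  # single-candidate range
  tiny <- one_hot_encode(site_collection(c("AAAAAA", "AAAAAC", "TTTGGG")))
  sel1 <- select_cluster_numbers(tiny, 2L, runs_per_c = 2, seed = 1)
  expect_equal(sel1$optimal, 2L)
  expect_error(select_cluster_numbers(tiny, integer(0)), "empty")
  # nested fixture: both coarse and fine level selected
  nf <- make_nested_fixture(7)
  sel2 <- select_cluster_numbers(one_hot_encode(nf$coll), 2:6,
                                 runs_per_c = 5, seed = 6)
  expect_true(all(c(2L, 4L) %in% sel2$optimal))
})

test_that("hypergeom_overlap matches exact enumeration and is monotone", {
  expect_equal(hypergeom_overlap(0, 3, 3, 6), 1)
  expect_equal(hypergeom_overlap(4, 4, 4, 4), 1)
  # PI(2; 3, 3, 6): P(X=2) = 9/20, P(X=3) = 1/20 by enumeration
  expect_equal(hypergeom_overlap(2, 3, 3, 6), 0.5)
  expect_error(hypergeom_overlap(4, 3, 5, 10), "domain")
  # enumeration oracle for g <= 12: count k-subsets directly
  enum_pi <- function(p, h, n, g) {
    picks <- combn(g, n)
    mean(apply(picks, 2, function(s) sum(s <= h) >= p))
  }
  set.seed(3)
  for (i in 1:20) {
    g <- sample(4:12, 1)
    h <- sample(1:g, 1)
    n <- sample(1:g, 1)
    p <- sample(0:min(h, n), 1)
    expect_equal(hypergeom_overlap(p, h, n, g), enum_pi(p, h, n, g),
                 tolerance = 1e-12)
  }
  # monotone: increasing p never increases PI
  pis <- sapply(0:5, hypergeom_overlap, h = 7, n = 5, g = 12)
  expect_true(all(diff(pis) <= 1e-15))
})

test_that("build_hierarchy reproduces containment chains and planted nesting", {
  coll <- site_collection(replicate(16, paste(sample(BASES, 4, TRUE),
                                              collapse = "")),
                          site_id = paste0("s", 1:16))
  ids <- coll$sites$site_id
  # disjoint clusters attach to root only
  tr <- build_hierarchy(list(list(member_ids = ids[1:4], size = 4),
                             list(member_ids = ids[5:8], size = 4)),
                        coll, alpha_hier = 0.01)
  expect_setequal(tr$nodes$root$children, c("S01", "S02"))
  # containment chain root -> A -> B:
  # PI(4; 8, 4, 16) = choose(8,4)/choose(16,4) = 0.038 < 0.05
  tr2 <- build_hierarchy(list(list(member_ids = ids[1:8], size = 8),
                              list(member_ids = ids[1:4], size = 4)),
                         coll, alpha_hier = 0.05)
  b <- setdiff(names(tr2$nodes), "root")
  sizes <- sapply(b, function(x) length(tr2$nodes[[x]]$member_ids))
  small <- b[which.min(sizes)]; big <- b[which.max(sizes)]
  expect_equal(tr2$nodes[[small]]$parent, big)
  expect_equal(tr2$nodes[[big]]$parent, "root")
  # planted nested fixture: pooled c=2 and c=4 clusters give the
  # two-level family structure
  nf <- make_nested_fixture(7)
  X <- one_hot_encode(nf$coll)
  sel <- select_cluster_numbers(X, 2:6, runs_per_c = 5, seed = 11)
  cl <- unlist(lapply(sel$partitions, partition_to_clusters,
                      collection = nf$coll), recursive = FALSE)
  tree <- build_hierarchy(cl, nf$coll)
  depth1 <- tree$nodes$root$children
  expect_equal(length(depth1), 2L)
  leaves <- unlist(lapply(depth1, function(x) tree$nodes[[x]]$children))
  expect_equal(length(leaves), 4L)
  for (leaf in leaves) {
    lab <- nf$lab[match(tree$nodes[[leaf]]$member_ids,
                        nf$coll$sites$site_id)]
    expect_equal(length(unique(lab)), 1L)  # each leaf is one subgroup
  }
})

test_that("build_hierarchy output is acyclic and root-complete on random pools", {
  coll <- site_collection(replicate(12, paste(sample(BASES, 4, TRUE),
                                              collapse = "")),
                          site_id = paste0("s", 1:12))
  set.seed(42)
  for (rep in 1:10) {
    pool <- lapply(seq_len(sample(2:6, 1)), function(i) {
      mem <- sample(coll$sites$site_id, sample(2:10, 1))
      list(member_ids = mem, size = length(mem))
    })
    tree <- build_hierarchy(pool, coll, alpha_hier = 0.05)
    # every non-root node reaches root by parent links, no cycles
    for (nid in setdiff(names(tree$nodes), "root")) {
      seen <- character(0)
      cur <- nid
      while (cur != "root") {
        expect_false(cur %in% seen)
        seen <- c(seen, cur)
        cur <- tree$nodes[[cur]]$parent
      }
    }
    expect_equal(length(tree$nodes$root$member_ids), 12L)
  }
})

test_that("agglomerative clustering recovers planted groups and handles edge cases", {
  flat <- make_flat_mixture(9, n_groups = 2, n_per = 20)
  X <- one_hot_encode(flat$coll)
  # depth-2 standardization caps inconsistency at 2/sqrt(3) ~ 1.155,
  # making the stock 1.15 cutoff marginal; depth 3 is the practical
  # setting for recovery (see vignette)
  cl <- agglomerative_divide(X, flat$coll, inconsistency_depth = 3,
                             inconsistency_cutoff = 1.5)
  expect_gte(ari(cluster_labels(cl, flat$coll), flat$lab), 0.9)
  # n = 2 distinct sites with a huge cutoff: one cluster
  two <- site_collection(c("AAAA", "TTTT"))
  cl2 <- agglomerative_divide(one_hot_encode(two), two,
                              inconsistency_cutoff = 100)
  expect_equal(length(cl2), 1L)
  # equally spaced chain: inconsistency ~ 0 everywhere, one cluster
  chain <- site_collection(c("AAAAAA", "AAAAAC", "AAAACC", "AAACCC",
                             "AACCCC", "ACCCCC"))
  cl3 <- agglomerative_divide(one_hot_encode(chain), chain)
  expect_equal(length(cl3), 1L)
  # all-identical data: one cluster, no error
  same <- site_collection(rep("ACGT", 4), site_id = paste0("s", 1:4))
  expect_equal(length(agglomerative_divide(one_hot_encode(same), same)), 1L)
})

test_that("subtractive clustering peels planted families by density", {
  # one strong planted PWM: a single cluster holding >= 90% of sites
  w <- make_subtractive_world(21)
  one <- sample_sites(w$pwms$A, 30, seed = 1, prefix = "p")
  sb1 <- subtractive_divide(one, w$negatives)
  expect_equal(length(sb1), 1L)
  expect_gte(sb1[[1]]$size, 27)
  # two dissimilar planted PWMs: >= 2 clusters matching planted labels
  sb2 <- subtractive_divide(w$coll, w$negatives)
  expect_gte(length(sb2), 2L)
  expect_gte(ari(cluster_labels(sb2, w$coll), w$lab), 0.9)
  # positives identical to negatives: no signal, empty result
  expect_warning(
    sb3 <- subtractive_divide(w$negatives, w$negatives),
    "empty")
  expect_equal(length(sb3), 0L)
})
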