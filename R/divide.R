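# "Divide" phase: decompose the binding-site collection into submotif
# clusters.  Three clustering routes are provided -- possibilistic fuzzy
# c-means (the main one), single-linkage agglomerative with the
# inconsistency cut, and subtractive (density/PWM-recovery) clustering --
# plus Xie-Beni model selection and the hypergeometric hierarchy builder.

#' Possibilistic fuzzy c-means clustering
#'
#' The reported memberships are possibilistic (Krishnapuram-Keller form):
#' `u_ij = 1 / (1 + (d_ij^2 / eta_i)^(1/(m-1)))`, where `d_ij` is the
#' Euclidean distance of observation j to centroid i.  They lie in
#' `[0,1]`, equal 1 at zero distance, and are NOT constrained to sum to 1
#' across clusters, so an outlier far from every centroid weakly belongs
#' to everything.
#'
#' Centroid estimation uses the constrained fuzzy c-means fixed point:
#' each iteration computes constrained memberships
#' `w_ij = 1 / sum_k (d_ij^2 / d_kj^2)^(1/(m-1))` and updates
#' `v_i = sum_j w_ij^m x_j / sum_j w_ij^m`, stopping at `max_iter` or
#' when the largest centroid movement falls below `tol`.  The constrained
#' update is what keeps centroids apart: iterating the possibilistic
#' memberships themselves (pure possibilistic c-means, or the
#' equal-weight possibilistic/probabilistic hybrid) makes every centroid
#' migrate to the global mean on one-hot sequence data -- the documented
#' coincident-cluster pathology -- and was verified to do so here.  The
#' possibilistic layer is the read-out: it supplies the unconstrained
#' memberships used for cluster extraction and outlier handling, while
#' the Xie-Beni index (which by construction scores fuzzy-c-means
#' partitions) consumes the constrained `w` stored alongside.  With
#' `c = 1` the constrained memberships are identically 1 and the
#' centroid is the plain mean.
#'
#' The default `eta = "auto"` sets each cluster's bandwidth to its
#' converged mean weighted squared distance
#' (`eta_i = sum_j w_ij^m d_ij^2 / sum_j w_ij^m`), so that a typical
#' within-cluster point gets possibilistic membership about 0.5.  With
#' `eta` fixed at 1 on one-hot features (squared distances of order
#' 10-20) memberships stay far below the 0.5 hard cut; the numeric
#' argument remains available for that literal variant.
#'
#' @param features numeric feature matrix (rows = observations), normally
#'   from [one_hot_encode()].
#' @param c number of clusters.
#' @param m fuzzifier, > 1 (default 2).
#' @param eta possibilistic bandwidth: `"auto"` (default, estimated per
#'   cluster from the FCM pre-pass) or a numeric scalar / length-c vector.
#' @param max_iter maximum number of iterations S (default 100).
#' @param tol convergence tolerance on maximum centroid movement
#'   (default 1e-6).
#' @param seed RNG seed for centroid initialization: centroids are seeded
#'   from c randomly chosen distinct data rows, the first uniformly, each
#'   subsequent one with probability proportional to its squared distance
#'   from the seeds already chosen (k-means++-style spreading, which keeps
#'   restarts from planting several centroids inside one tight group).
#' @param init optional c x ncol(features) matrix of initial centroids,
#'   overriding the seeded initialization.
#' @return a `fuzzy_partition`: list with `memberships` (c x n
#'   possibilistic matrix `u`), `fcm_memberships` (c x n constrained
#'   matrix `w`), `centroids` (c x d matrix `v`), `eta`, `fuzzifier`,
#'   `iterations_run`, `converged`, and `duplicate_centroids` flag.
#' @export
pfcm <- function(features, c, m = 2, eta = "auto", max_iter = 100L,
                 tol = 1e-6, seed = NULL, init = NULL) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n == 0L) stop("empty feature matrix")
  if (c < 1L) stop("configuration error: c must be >= 1")
  if (c > n) stop("configuration error: more clusters (", c,
                  ") than observations (", n, ")")
  if (m <= 1) stop("fuzzifier m must be > 1")
  auto_eta <- identical(eta, "auto")
  if (!auto_eta) eta <- rep_len(as.numeric(eta), c)
  if (is.null(init)) {
    uniq <- unique(X)
    if (nrow(uniq) < c) {
      # degenerate: fewer distinct points than clusters
      v <- uniq[rep_len(seq_len(nrow(uniq)), c), , drop = FALSE]
      dup_flag <- TRUE
    } else {
      idx <- with_seed(seed, {
        DU <- as.matrix(stats::dist(uniq))
        picked <- sample.int(nrow(uniq), 1L)
        while (length(picked) < c) {
          d2min <- apply(DU[, picked, drop = FALSE], 1, min)^2
          d2min[picked] <- 0
          picked <- c(picked,
                      if (sum(d2min) > 0)
                        sample.int(nrow(uniq), 1L, prob = d2min)
                      else sample(setdiff(seq_len(nrow(uniq)), picked), 1L))
        }
        picked
      })
      v <- uniq[idx, , drop = FALSE]
      dup_flag <- FALSE
    }
  } else {
    v <- as.matrix(init)
    stopifnot(nrow(v) == c, ncol(v) == ncol(X))
    dup_flag <- FALSE
  }
  sq_dist <- function(v) {
    # c x n matrix of squared Euclidean distances
    d2 <- outer(rowSums(v^2), rep(1, n)) +
      outer(rep(1, c), rowSums(X^2)) - 2 * v %*% t(X)
    pmax(d2, 0)
  }
  fcm_w <- function(d2) {
    if (c == 1L) return(matrix(1, 1L, n))
    d2 <- pmax(d2, 1e-12)
    inv <- d2^(-1 / (m - 1))
    sweep(inv, 2, colSums(inv), "/")
  }
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    wgt <- fcm_w(sq_dist(v))^m
    v_new <- (wgt %*% X) / rowSums(wgt)
    move <- max(sqrt(rowSums((v_new - v)^2)))
    v <- v_new
    if (move < tol) { converged <- TRUE; break }
  }
  d2 <- sq_dist(v)
  w <- fcm_w(d2)
  if (auto_eta) {
    wm <- w^m
    eta <- pmax(rowSums(wm * d2) / rowSums(wm), 1e-6)
  }
  u <- 1 / (1 + (d2 / eta)^(1 / (m - 1)))
  u[d2 == 0] <- 1
  # coincident centroids signal a degenerate solution (c above the
  # structure the data supports)
  if (c > 1L) {
    dv <- as.matrix(stats::dist(v))
    dup_flag <- dup_flag || any(dv[upper.tri(dv)] < 1e-4)
  }
  structure(list(memberships = u, fcm_memberships = w, centroids = v,
                 eta = eta, fuzzifier = m, iterations_run = it,
                 converged = converged && !dup_flag,
                 duplicate_centroids = dup_flag),
            class = "fuzzy_partition")
}

#' Xie-Beni cluster validity index
#'
#' Compactness over separation:
#' `XB = sum_ij w_ij^m d_ij^2 / (n * min_{i != k} ||v_i - v_k||^2)`,
#' computed on the constrained fuzzy-c-means memberships `w` of the
#' partition (the index is defined as a score of fuzzy-c-means
#' partitions).  Smaller is better; minimized over candidate cluster
#' counts to choose the model order.
#'
#' @param features the feature matrix the partition was fit on.
#' @param partition a `fuzzy_partition` from [pfcm()].
#' @return scalar index value.
#' @export
xie_beni <- function(features, partition) {
  X <- as.matrix(features)
  v <- partition$centroids
  u <- partition$fcm_memberships %||% partition$memberships
  m <- partition$fuzzifier
  if (nrow(v) < 2L) stop("Xie-Beni needs >= 2 centroids")
  dv <- as.matrix(stats::dist(v))^2
  sep <- min(dv[upper.tri(dv)])
  if (sep < 1e-12)
    stop("separation-zero error: coincident centroids, index undefined")
  n <- nrow(X)
  d2 <- outer(rowSums(v^2), rep(1, n)) + outer(rep(1, nrow(v)), rowSums(X^2)) -
    2 * v %*% t(X)
  d2 <- pmax(d2, 0)
  sum(u^m * d2) / (n * sep)
}

#' Select optimal cluster counts by Xie-Beni minimization
#'
#' For each candidate c the best (minimum) Xie-Beni index over
#' `runs_per_c` seeded restarts is retained; every c whose best index is
#' within `rel_tol` of the global minimum is returned — the data may admit
#' more than one optimal partition (e.g. nested coarse/fine structure),
#' and all optimal model orders are kept and clustered.
#'
#' @param features feature matrix.
#' @param c_range integer vector of candidate cluster counts (within
#'   `[2, n-1]`).
#' @param runs_per_c random restarts per candidate (default 5).
#' @param seed RNG seed.
#' @param rel_tol relative tolerance defining the optimal set
#'   (default 0.05).
#' @param ... passed to [pfcm()].
#' @return list with `optimal` (sorted integer vector of selected c),
#'   `index` (named vector of best Xie-Beni value per c), and
#'   `partitions` (best partition per selected c).
#' @export
select_cluster_numbers <- function(features, c_range, runs_per_c = 5L,
                                   seed = 1L, rel_tol = 0.05, ...) {
  X <- as.matrix(features)
  n <- nrow(X)
  c_range <- as.integer(c_range)
  if (!length(c_range)) stop("usage error: empty c_range")
  if (any(c_range < 2L | c_range > n - 1L))
    stop("c_range must lie within [2, n-1]")
  best <- setNames(rep(Inf, length(c_range)), c_range)
  parts <- vector("list", length(c_range))
  for (k in seq_along(c_range)) {
    for (r in seq_len(runs_per_c)) {
      p <- tryCatch(pfcm(X, c_range[k], seed = seed + 1000L * k + r, ...),
                    error = function(e) NULL)
      if (is.null(p) || p$duplicate_centroids) next
      xb <- tryCatch(xie_beni(X, p), error = function(e) Inf)
      if (xb < best[k]) { best[k] <- xb; parts[[k]] <- p }
    }
  }
  ok <- is.finite(best)
  if (!any(ok)) stop("no valid partition found in c_range")
  gmin <- min(best[ok])
  sel <- c_range[ok & best <= gmin * (1 + rel_tol)]
  list(optimal = sort(sel), index = best,
       partitions = setNames(parts[match(sel, c_range)], sel))
}

#' Hypergeometric cluster-overlap probability (PI)
#'
#' Upper-tail probability of observing at least `p` shared members
#' between a cluster of size `h` and a cluster of size `n` drawn from `g`
#' sites: the lower the PI the stronger the association.
#'
#' @param p observed overlap count.
#' @param h size of the first cluster.
#' @param n size of the second cluster.
#' @param g total number of sites.
#' @return probability in `[0,1]`.
#' @export
hypergeom_overlap <- function(p, h, n, g) {
  if (p < 0 || p > min(h, n) || h > g || n > g)
    stop("domain error: need 0 <= p <= min(h, n) <= g")
  if (p == 0) return(1)
  # P(X >= p), X ~ Hypergeometric(g; h successes; n draws)
  stats::phyper(p - 1, m = h, n = g - h, k = n, lower.tail = FALSE)
}

#' Extract hard clusters from a fuzzy partition
#'
#' @param partition a `fuzzy_partition`.
#' @param collection the clustered [site_collection()] (site order must
#'   match the feature rows).
#' @param cut membership cut for hard assignment (default 0.5).
#' @param min_size minimum cluster size (default 2; a PWM from one
#'   sequence is degenerate).
#' @param source label recorded on each cluster.
#' @return list of clusters, each `list(member_ids, size, source)`.
#' @export
partition_to_clusters <- function(partition, collection, cut = 0.5,
                                  min_size = 2L, source = "pfcm") {
  ids <- collection$sites$site_id
  out <- list()
  for (i in seq_len(nrow(partition$memberships))) {
    mem <- ids[partition$memberships[i, ] >= cut]
    if (length(mem) >= min_size)
      out[[length(out) + 1L]] <- list(member_ids = mem,
                                      size = length(mem), source = source)
  }
  out
}

#' Organize clusters into a submotif hierarchy
#'
#' Pools clusters (typically from several optimal model orders), roots
#' them under the all-sites single motif, and links cluster B under the
#' smaller-than-it cluster A with the most significant overlap
#' (`hypergeom_overlap` PI below `alpha_hier`).  Clusters with no
#' significant larger partner attach to the root.
#'
#' @param clusters list of clusters (`member_ids`, `size`, `source`), e.g.
#'   pooled [partition_to_clusters()] output across selected c values.
#' @param collection the full [site_collection()]; its size is `g`.
#' @param alpha_hier significance threshold on PI (default 0.01).
#' @return a `submotif_tree`: list with `nodes` (named list: `member_ids`,
#'   `parent`, `children`, `source`) where node `"root"` holds all sites.
#' @export
build_hierarchy <- function(clusters, collection, alpha_hier = 0.01) {
  if (!length(clusters)) stop("no clusters to organize")
  g <- nrow(collection$sites)
  ids <- paste0("S", sprintf("%02d", seq_along(clusters)))
  nodes <- list(root = list(member_ids = collection$sites$site_id,
                            parent = NA_character_, children = character(0),
                            source = "all"))
  ord <- order(-vapply(clusters, function(cl) cl$size, numeric(1)))
  for (k in ord) {
    cl <- clusters[[k]]
    nid <- ids[k]
    # candidate parents: strictly processed (larger or equal) clusters + root
    best_parent <- "root"; best_pi <- alpha_hier; best_size <- g
    for (pid in setdiff(names(nodes), "root")) {
      pn <- nodes[[pid]]
      if (length(pn$member_ids) < cl$size) next
      ov <- length(intersect(pn$member_ids, cl$member_ids))
      pi_val <- hypergeom_overlap(ov, length(pn$member_ids), cl$size, g)
      # prefer the smallest significant parent; break PI ties by size
      if (pi_val < alpha_hier &&
          (length(pn$member_ids) < best_size ||
           (length(pn$member_ids) == best_size && pi_val < best_pi))) {
        best_parent <- pid; best_pi <- pi_val
        best_size <- length(pn$member_ids)
      }
    }
    nodes[[nid]] <- list(member_ids = cl$member_ids, parent = best_parent,
                         children = character(0),
                         source = cl$source %||% "pfcm")
    nodes[[best_parent]]$children <- c(nodes[[best_parent]]$children, nid)
  }
  structure(list(nodes = nodes), class = "submotif_tree")
}

#' @export
print.submotif_tree <- function(x, ...) {
  cat(sprintf("submotif_tree: %d nodes (root + %d clusters)\n",
              length(x$nodes), length(x$nodes) - 1L))
  invisible(x)
}

# inconsistency coefficient of each link of an hclust tree, Matlab-style:
# link height standardized against mean/sd of link heights within `depth`
# levels below (including the link itself).
inconsistency <- function(hc, depth = 2L) {
  nlink <- nrow(hc$merge)
  below <- vector("list", nlink)  # link indices within depth, per link
  inc <- numeric(nlink)
  for (k in seq_len(nlink)) {
    hs <- hc$height[k]
    frontier <- hc$merge[k, ]
    d <- 1L
    while (d < depth) {
      kids <- frontier[frontier > 0]
      if (!length(kids)) break
      hs <- c(hs, hc$height[kids])
      frontier <- as.vector(hc$merge[kids, ])
      d <- d + 1L
    }
    inc[k] <- if (length(hs) > 1L && stats::sd(hs) > 0)
      (hc$height[k] - mean(hs)) / stats::sd(hs) else 0
  }
  inc
}

#' Agglomerative clustering with the inconsistency cut
#'
#' Single-linkage dendrogram on Euclidean distances of the one-hot
#' features; clusters are the maximal subtrees containing no link whose
#' inconsistency coefficient exceeds `inconsistency_cutoff`.
#'
#' @param features feature matrix from [one_hot_encode()].
#' @param collection the [site_collection()] (for member ids).
#' @param inconsistency_depth levels of links included in the
#'   standardization (default 2).
#' @param inconsistency_cutoff cut threshold (default 1.15).
#' @return list of clusters (`member_ids`, `size`, `source =
#'   "agglomerative"`).
#' @export
agglomerative_divide <- function(features, collection,
                                 inconsistency_depth = 2L,
                                 inconsistency_cutoff = 1.15) {
  X <- as.matrix(features)
  n <- nrow(X)
  ids <- collection$sites$site_id
  if (n < 2L) return(list(list(member_ids = ids, size = n,
                               source = "agglomerative")))
  hc <- stats::hclust(stats::dist(X), method = "single")
  inc <- inconsistency(hc, inconsistency_depth)
  # bottom-up: a merge node is "kept" if its link and its kept children
  # are all consistent; cluster labels via union-find over kept merges
  lab <- seq_len(n)
  members <- as.list(seq_len(n))  # per merge node, leaf indices
  keep <- logical(nrow(hc$merge))
  for (k in seq_len(nrow(hc$merge))) {
    kids <- hc$merge[k, ]
    leaf <- function(x) if (x < 0) -x else NULL
    mem <- integer(0)
    ok_children <- TRUE
    for (x in kids) {
      if (x < 0) mem <- c(mem, -x)
      else { mem <- c(mem, members[[n + x]]); ok_children <- ok_children && keep[x] }
    }
    members[[n + k]] <- mem
    keep[k] <- ok_children && inc[k] <= inconsistency_cutoff
    if (keep[k]) lab[mem] <- min(lab[mem])
  }
  split_idx <- split(seq_len(n), lab[seq_len(n)])
  lapply(unname(split_idx), function(ix)
    list(member_ids = ids[ix], size = length(ix), source = "agglomerative"))
}

#' Subtractive clustering by iterative PWM recovery
#'
#' Builds a PWM on the remaining positives, learns the score threshold
#' maximizing CC or SCC against the negatives, removes the recovered true
#' positives as one cluster, and repeats while the optimized measure stays
#' above `stop` (default 0.5).  Clusters come out in extraction order
#' (densest pattern first).
#'
#' @param collection positive [site_collection()].
#' @param negatives negative-example [site_collection()] of equal length.
#' @param measure `"scc"` or `"cc"`.
#' @param stop stopping value of the measure (default 0.5).
#' @param pseudocount,background passed to [build_pwm()].
#' @param min_size minimum cluster size (default 2).
#' @return list of clusters (`member_ids`, `size`, `source =
#'   "subtractive"`, `threshold`, `measure_value`).
#' @export
subtractive_divide <- function(collection, negatives,
                               measure = c("scc", "cc"), stop = 0.5,
                               pseudocount = 0.5,
                               background = rep(0.25, 4), min_size = 2L) {
  measure <- match.arg(measure)
  fun <- if (measure == "scc") scc else cc
  remaining <- collection
  neg_seqs <- negatives$sites$sequence
  out <- list()
  repeat {
    if (nrow(remaining$sites) < min_size) break
    pwm <- build_pwm(remaining, pseudocount = pseudocount,
                     background = background)
    pos_sc <- score_sequence(pwm, remaining$sites$sequence)
    neg_sc <- score_sequence(pwm, neg_seqs)
    cand <- sort(unique(c(pos_sc, neg_sc)))
    best_val <- -Inf; best_thr <- NA_real_
    for (t in cand) {
      counts <- confusion_counts(TP = sum(pos_sc >= t), FN = sum(pos_sc < t),
                                 FP = sum(neg_sc >= t), TN = sum(neg_sc < t))
      val <- fun(counts)
      if (val > best_val) { best_val <- val; best_thr <- t }
    }
    if (best_val <= stop) {
      if (!length(out))
        warning("subtractive clustering: measure never exceeded ", stop,
                "; empty result")
      break
    }
    rec <- pos_sc >= best_thr
    if (sum(rec) < min_size) break
    out[[length(out) + 1L]] <-
      list(member_ids = remaining$sites$site_id[rec], size = sum(rec),
           source = "subtractive", threshold = best_thr,
           measure_value = best_val)
    if (all(rec)) break
    remaining <- remaining[!rec]
  }
  out
}

#' Serialize a submotif tree (with optional PWMs) to JSON
#'
#' @param tree a `submotif_tree`.
#' @param path output path.
#' @export
write_tree <- function(tree, path) {
  nodes <- lapply(tree$nodes, function(nd)
    list(member_ids = nd$member_ids, parent = nd$parent,
         children = nd$children, source = nd$source))
  jsonlite::write_json(nodes, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
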