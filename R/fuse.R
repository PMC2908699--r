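# "Fuse" phase: fuzzy IF-THEN rules joining submotif membership (the
# normalized PWM score is read as a fuzzy membership, the PWM being the
# set's centroid) with TF-RNAP distance classes encoded as triangular
# fuzzy sets fitted to the distance histogram.  AND = product,
# combination of fired rules = maximum.

#' Triangular fuzzy set on the distance axis
#'
#' @param a,b,c left foot, apex, right foot (bp), `a <= b <= c`.
#' @param label set name (e.g. `"close"`).
#' @return a `fuzzy_set` of kind `"triangular"`.
#' @export
triangular_set <- function(a, b, c, label = "set") {
  if (!(a <= b && b <= c)) stop("need a <= b <= c")
  structure(list(kind = "triangular", a = a, b = b, c = c, label = label),
            class = "fuzzy_set")
}

#' Submotif score fuzzy set backed by a PWM
#'
#' @param pwm a `pwm_model`; membership of a sequence is its normalized
#'   score under this PWM.
#' @param label set name (defaults to the PWM name).
#' @return a `fuzzy_set` of kind `"score_set"`.
#' @export
score_set <- function(pwm, label = pwm$name) {
  structure(list(kind = "score_set", pwm = pwm, label = label),
            class = "fuzzy_set")
}

#' Membership degree in a fuzzy set
#'
#' Triangular sets interpolate linearly between the feet and the apex;
#' score sets delegate to [score_sequence()].
#'
#' @param set a `fuzzy_set`.
#' @param x bp distances (triangular) or DNA sequences (score set).
#' @return degrees in `[0,1]`.
#' @export
fuzzy_membership <- function(set, x) {
  if (set$kind == "score_set") return(score_sequence(set$pwm, x))
  with(set, {
    mu <- numeric(length(x))
    up <- x > a & x <= b
    if (b > a) mu[up] <- (x[up] - a) / (b - a)
    dn <- x > b & x < c
    if (c > b) mu[dn] <- (c - x[dn]) / (c - b)
    mu[x == b] <- 1
    mu
  })
}

#' Fit triangular distance fuzzy sets to observed TF-RNAP distances
#'
#' Histograms the signed distances (bin width `bin_bp`), splits them into
#' `k` modes by one-dimensional k-means (deterministically initialized at
#' the k quantile midpoints), and per mode fits triangle parameters
#' (a, b, c) by least squares between the triangular membership evaluated
#' at the bin centers and the peak-normalized bin counts.  Sets are
#' returned ordered by apex from least to most negative and labelled
#' close/medium/far when `k == 3`.
#'
#' @param distances signed bp offsets (upstream negative).
#' @param k number of sets (default 3).
#' @param bin_bp histogram bin width (default 2 bp).
#' @param window allowed distance range (default c(-90, 10): 90 bp
#'   upstream to 10 bp downstream of the TSS).
#' @return list of `k` triangular [triangular_set()]s.
#' @export
fit_distance_fuzzy_sets <- function(distances, k = 3L, bin_bp = 2,
                                    window = c(-90, 10)) {
  d <- distances[!is.na(distances)]
  if (any(d < window[1] | d > window[2]))
    stop("distances outside the promoter window [", window[1], ", ",
         window[2], "]")
  if (length(unique(d)) < k)
    stop("degenerate-fit error: fewer distinct distances (",
         length(unique(d)), ") than sets (", k, ")")
  if (k == 1L) {
    groups <- list(d)
  } else {
    centers <- stats::quantile(d, probs = (seq_len(k) - 0.5) / k,
                               names = FALSE)
    centers <- centers + seq(0, 1e-6, length.out = k)  # force distinct
    km <- stats::kmeans(d, centers = matrix(centers, ncol = 1))
    groups <- split(d, km$cluster)
  }
  fit_one <- function(x) {
    brk <- seq(floor(min(x) / bin_bp) * bin_bp - bin_bp,
               ceiling(max(x) / bin_bp) * bin_bp + bin_bp, by = bin_bp)
    h <- graphics::hist(x, breaks = brk, plot = FALSE)
    y <- h$counts / max(h$counts)
    ctr <- h$mids
    start <- c(a = min(x) - bin_bp, b = ctr[which.max(y)], c = max(x) + bin_bp)
    obj <- function(par) {
      par <- sort(par)
      s <- triangular_set(par[1], par[2], par[3])
      sum((fuzzy_membership(s, ctr) - y)^2)
    }
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 500))
    par <- sort(fit$par)
    triangular_set(par[1], par[2], par[3])
  }
  sets <- lapply(groups, fit_one)
  apexes <- vapply(sets, function(s) s$b, numeric(1))
  sets <- sets[order(-apexes)]  # closest to TSS (least negative) first
  labels <- if (k == 3L) c("close", "medium", "far")
  else paste0("d", seq_len(k))
  for (i in seq_len(k)) sets[[i]]$label <- labels[i]
  unname(sets)
}

#' Mine significant fuzzy IF-THEN rules
#'
#' Takes the Cartesian product of submotif score sets and distance sets;
#' for each pair, the site sets passing membership cut 0.5 on each
#' antecedent are intersected and the overlap's chance probability is
#' scored by [hypergeom_overlap()].  Pairs with PI below `alpha` become
#' rules.
#'
#' @param submotif_sets list of [score_set()]s.
#' @param distance_sets list of [triangular_set()]s.
#' @param training_sites [site_collection()] whose `tss_offset` carries
#'   the distances.
#' @param alpha significance cutoff on PI (default 1e-4).
#' @param cut_submotif membership cut defining the crisp submotif site
#'   sets; `NULL` (default) uses each score set's own PWM threshold.  A
#'   flat 0.5 cut on min-max-normalized scores is far too permissive
#'   (unrelated sites score 0.4-0.75) and drowns the enrichment signal.
#' @param cut_distance membership cut for the distance sets (default 0.5).
#' @param th default activation threshold given to new rules
#'   (default 0.4, the product of the two antecedent cuts).
#' @return a `rule_base`: list with `rules` (each: `submotif_set`,
#'   `distance_set`, `th`, `pi`), `and_operator = "product"`,
#'   `combine_operator = "maximum"`.  Empty with a warning if nothing is
#'   significant.
#' @export
generate_rules <- function(submotif_sets, distance_sets, training_sites,
                           alpha = 1e-4, cut_submotif = NULL,
                           cut_distance = 0.5, th = 0.4) {
  stopifnot(length(submotif_sets) > 0, length(distance_sets) > 0)
  d <- training_sites$sites$tss_offset
  if (all(is.na(d))) stop("training sites carry no tss_offset distances")
  seqs <- training_sites$sites$sequence
  g <- length(seqs)
  in_sub <- lapply(submotif_sets, function(s) {
    cut <- cut_submotif %||% s$pwm$threshold %||% 0.5
    fuzzy_membership(s, seqs) >= cut
  })
  in_dist <- lapply(distance_sets, function(s)
    fuzzy_membership(s, d) >= cut_distance)
  rules <- list()
  for (i in seq_along(submotif_sets)) {
    for (j in seq_along(distance_sets)) {
      h <- sum(in_sub[[i]]); n <- sum(in_dist[[j]])
      if (h == 0 || n == 0) next
      p <- sum(in_sub[[i]] & in_dist[[j]])
      pi_val <- hypergeom_overlap(p, h, n, g)
      if (pi_val < alpha)
        rules[[length(rules) + 1L]] <-
          list(submotif_set = submotif_sets[[i]],
               distance_set = distance_sets[[j]], th = th, pi = pi_val)
    }
  }
  if (!length(rules))
    warning("no (submotif, distance) pair significant at alpha = ", alpha)
  structure(list(rules = rules, and_operator = "product",
                 combine_operator = "maximum"),
            class = "rule_base")
}

#' @export
print.rule_base <- function(x, ...) {
  cat(sprintf("rule_base: %d rules (AND = %s, combine = %s)\n",
              length(x$rules), x$and_operator, x$combine_operator))
  invisible(x)
}

#' Fuzzy rule inference
#'
#' Each rule's activation is the product of its two antecedent
#' memberships; a rule fires if its activation reaches its threshold
#' `th`; the overall class degree is the maximum over fired rules
#' (defuzzify-then-combine).  A sequence is predicted to be a binding
#' site if at least one rule fires.
#'
#' @param rulebase a `rule_base`.
#' @param seq DNA sequence of the submotif length.
#' @param distance signed bp offset from the TSS.
#' @return list with `positive` (logical), `degree` (max fired
#'   activation, 0 if none), `activations` (per-rule), `fired` (logical
#'   per rule).
#' @export
infer_rules <- function(rulebase, seq, distance) {
  if (!length(rulebase$rules)) stop("empty rule base")
  act <- vapply(rulebase$rules, function(r)
    fuzzy_membership(r$submotif_set, seq) *
      fuzzy_membership(r$distance_set, distance), numeric(1))
  fired <- act >= vapply(rulebase$rules, function(r) r$th, numeric(1))
  list(positive = any(fired),
       degree = if (any(fired)) max(act[fired]) else 0,
       activations = act, fired = fired)
}

#' GA optimization of a rule base
#'
#' Reuses the GA engine over (presence, threshold) pairs, one pair per
#' rule: presence > 0.5 keeps the rule, the second allele replaces its
#' activation threshold.  Fitness is `w1 * measure - w2 * (rules used /
#' total rules)`.
#'
#' @param rulebase a `rule_base`.
#' @param positives,negatives [site_collection()]s carrying `tss_offset`.
#' @param config a [ga_config()].
#' @return list with `rulebase` (optimized), `best_fitness`, `history`,
#'   `pareto` as in [ga_optimize()].
#' @export
ga_optimize_rules <- function(rulebase, positives, negatives,
                              config = ga_config()) {
  rules <- rulebase$rules
  if (!length(rules)) stop("empty rule base")
  act_mat <- function(coll) {
    seqs <- coll$sites$sequence
    d <- coll$sites$tss_offset
    vapply(rules, function(r)
      fuzzy_membership(r$submotif_set, seqs) *
        fuzzy_membership(r$distance_set, d), numeric(length(seqs)))
  }
  A_pos <- act_mat(positives)
  A_neg <- act_mat(negatives)
  res <- ga_optimize_scores(A_pos, A_neg, config)
  keep <- chrom_presence(res$best)
  thr <- chrom_thresholds(res$best)
  new_rules <- rules[keep]
  for (i in seq_along(new_rules)) new_rules[[i]]$th <- thr[keep][i]
  out_rb <- structure(list(rules = new_rules,
                           and_operator = rulebase$and_operator,
                           combine_operator = rulebase$combine_operator),
                      class = "rule_base")
  list(rulebase = out_rb, best = res$best,
       best_fitness = res$best_fitness, history = res$history,
       pareto = res$pareto)
}

# Shared GA core operating directly on precomputed activation/score
# matrices (n_examples x n_voters); used by ga_optimize_rules.  The OR
# decision "any column with value >= its threshold" is the same for PWM
# voters and for rules.
ga_optimize_scores <- function(S_pos, S_neg, config) {
  k <- ncol(S_pos)
  fit_fn <- make_fitness_fn(S_pos, S_neg, config)
  measure_fun <- if (config$objective == "scc") scc else cc
  with_seed(config$seed, {
    pop <- lapply(seq_len(config$population), function(i)
      as.vector(rbind(stats::runif(k), stats::runif(k))))
    fits <- vapply(pop, fit_fn, numeric(1))
    history <- data.frame(generation = integer(0), best_fitness = numeric(0))
    archive <- list()
    note <- function(chrom, fit) {
      na <- sum(chrom_presence(chrom))
      if (na == 0 || !is.finite(fit)) return()
      key <- as.character(na)
      if (is.null(archive[[key]]) || fit > archive[[key]]$fitness)
        archive[[key]] <<- list(chrom = chrom, fitness = fit)
    }
    for (i in seq_along(pop)) note(pop[[i]], fits[i])
    for (gen in seq_len(config$generations)) {
      ord <- order(-fits)
      newpop <- pop[ord[seq_len(config$elitism)]]
      while (length(newpop) < config$population) {
        pick <- function() {
          ij <- sample.int(config$population, 2L)
          if (fits[ij[1]] >= fits[ij[2]]) pop[[ij[1]]] else pop[[ij[2]]]
        }
        p1 <- pick(); p2 <- pick()
        child <- if (stats::runif(1) < config$crossover_rate)
          crossover_maxmin(p1, p2, stats::runif(1), fit_fn)
        else p1
        newpop[[length(newpop) + 1L]] <- mutate_chromosome(child)
      }
      pop <- newpop
      fits <- vapply(pop, fit_fn, numeric(1))
      for (i in seq_along(pop)) note(pop[[i]], fits[i])
      history <- rbind(history, data.frame(generation = gen,
                                           best_fitness = max(fits)))
    }
  })
  b <- which.max(fits)
  tab <- do.call(rbind, lapply(names(archive), function(kk)
    data.frame(n_active = as.integer(kk),
               fitness = archive[[kk]]$fitness)))
  tab <- tab[order(tab$n_active), , drop = FALSE]
  list(best = pop[[b]], best_fitness = fits[b], history = history,
       pareto = tab)
}

#' Serialize a rule base to JSON
#'
#' @param rulebase a `rule_base`.
#' @param path output path.
#' @export
write_rules <- function(rulebase, path) {
  obj <- list(and_operator = rulebase$and_operator,
              combine_operator = rulebase$combine_operator,
              rules = lapply(rulebase$rules, function(r)
                list(submotif = r$submotif_set$label,
                     distance = r$distance_set$label,
                     triangle = c(r$distance_set$a, r$distance_set$b,
                                  r$distance_set$c),
                     th = r$th, pi = r$pi)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
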