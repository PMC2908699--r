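# "Optimize" phase: a generational genetic algorithm tunes which
# submotifs enter the multi-classifier and their score thresholds, under
# a multi-objective fitness trading accuracy (CC or SCC) against model
# complexity (fraction of submotifs used).
#
# A chromosome is a 2k numeric vector interleaving (presence, threshold)
# pairs, one pair per candidate submotif; presence > 0.5 means active.

chrom_presence <- function(chrom) chrom[seq(1, length(chrom), by = 2)] > 0.5
chrom_thresholds <- function(chrom) chrom[seq(2, length(chrom), by = 2)]

#' Default GA configuration
#'
#' @param objective `"scc"` or `"cc"`.
#' @param w1,w2 weights of the accuracy and complexity objectives
#'   (default 1 and 1: no preference among objectives).
#' @param population population size (default 50).
#' @param generations number of generations (default 100).
#' @param crossover_rate probability a selected pair is crossed
#'   (default 0.8).
#' @param elitism number of best chromosomes copied unchanged (default 1).
#' @param seed RNG seed (mandatory for reproducibility).
#' @return a list of class `ga_config`.
#' @export
ga_config <- function(objective = c("scc", "cc"), w1 = 1, w2 = 1,
                      population = 50L, generations = 100L,
                      crossover_rate = 0.8, elitism = 1L, seed = 1L) {
  objective <- match.arg(objective)
  if (population < 2L) stop("configuration error: population must be >= 2")
  if (w1 < 0 || w2 < 0) stop("weights must be >= 0")
  structure(list(objective = objective, w1 = w1, w2 = w2,
                 population = as.integer(population),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 elitism = as.integer(elitism), seed = as.integer(seed)),
            class = "ga_config")
}

# Precompute the n x k score matrix once; fitness evaluation then reduces
# to thresholding + OR, which keeps the GA fast.
make_fitness_fn <- function(pos_scores, neg_scores, config) {
  measure_fun <- if (config$objective == "scc") scc else cc
  k <- ncol(pos_scores)
  np <- nrow(pos_scores); nn <- nrow(neg_scores)
  function(chrom) {
    act <- chrom_presence(chrom)
    if (!any(act)) return(-Inf)
    thr <- chrom_thresholds(chrom)
    pp <- rowSums(pos_scores[, act, drop = FALSE] >=
                    rep(thr[act], each = np)) > 0
    pn <- rowSums(neg_scores[, act, drop = FALSE] >=
                    rep(thr[act], each = nn)) > 0
    counts <- confusion_counts(TP = sum(pp), FN = np - sum(pp),
                               FP = sum(pn), TN = nn - sum(pn))
    config$w1 * measure_fun(counts) - config$w2 * sum(act) / k
  }
}

#' GA fitness of a chromosome
#'
#' `fitness = w1 * measure - w2 * complexity`, where the measure is the
#' CC or SCC of the multi-classifier the chromosome encodes and
#' complexity is (number of used submotifs) / (total submotifs).  A
#' chromosome with no active submotif scores `-Inf`.
#'
#' @param chrom numeric vector of interleaved (presence, threshold) pairs.
#' @param submotifs list of candidate `pwm_model`s.
#' @param positives,negatives training [site_collection()]s.
#' @param config a [ga_config()].
#' @return scalar fitness.
#' @export
ga_fitness <- function(chrom, submotifs, positives, negatives, config) {
  mc <- multi_classifier(submotifs)
  S_pos <- score_matrix(mc, positives$sites$sequence)
  S_neg <- score_matrix(mc, negatives$sites$sequence)
  make_fitness_fn(S_pos, S_neg, config)(chrom)
}

#' Max-min arithmetical crossover
#'
#' From parents x and y, forms the four offspring
#' `a*x + (1-a)*y`, `a*y + (1-a)*x`, `pmin(x, y)`, `pmax(x, y)` and
#' returns the one with the best fitness under `scorer`.
#'
#' @param parent1,parent2 chromosomes of equal length.
#' @param a mixing parameter in `[0,1]` (drawn fresh from U(0,1) per
#'   crossover event inside the GA).
#' @param scorer function(chromosome) -> fitness.
#' @return the fittest offspring.
#' @export
crossover_maxmin <- function(parent1, parent2, a, scorer) {
  if (length(parent1) != length(parent2))
    stop("parents must have equal allele counts")
  if (a < 0 || a > 1) stop("a must lie in [0,1]")
  cands <- list(a * parent1 + (1 - a) * parent2,
                a * parent2 + (1 - a) * parent1,
                pmin(parent1, parent2),
                pmax(parent1, parent2))
  fits <- vapply(cands, scorer, numeric(1))
  cands[[which.max(fits)]]
}

#' Mutation operator
#'
#' Presence alleles flip on->off with probability 0.05 and off->on with
#' probability 0.005 (pressure toward sparser classifiers); each
#' threshold is perturbed by a uniform factor of up to +/-10% of its
#' value, clipped to `[0,1]`.  Uses the current RNG stream.
#'
#' @param chrom a chromosome.
#' @param p_on_off,p_off_on presence flip probabilities.
#' @param threshold_jitter relative perturbation bound (default 0.1).
#' @return mutated chromosome.
#' @export
mutate_chromosome <- function(chrom, p_on_off = 0.05, p_off_on = 0.005,
                              threshold_jitter = 0.1) {
  ip <- seq(1, length(chrom), by = 2)
  it <- ip + 1L
  pres <- chrom[ip]
  on <- pres > 0.5
  u <- stats::runif(length(pres))
  flip <- (on & u < p_on_off) | (!on & u < p_off_on)
  pres[flip] <- 1 - pres[flip]
  thr <- chrom[it]
  thr <- thr * (1 + stats::runif(length(thr), -threshold_jitter,
                                 threshold_jitter))
  chrom[ip] <- pres
  chrom[it] <- pmin(1, pmax(0, thr))
  chrom
}

#' Genetic-algorithm optimization of the multi-classifier
#'
#' Seeded generational GA with tournament selection (size 2), max-min
#' arithmetical crossover, asymmetric presence mutation and threshold
#' jitter, and elitism.  Alongside the single best chromosome it records,
#' per complexity level (number of active submotifs), the best-measure
#' configuration, and extracts the Pareto-optimal set over
#' (measure, -complexity) -- the table of optimal configurations.
#'
#' @param submotifs list of candidate `pwm_model`s.
#' @param positives,negatives training [site_collection()]s.
#' @param config a [ga_config()].
#' @return list with `best` (chromosome), `best_fitness`, `classifier`
#'   (the induced [multi_classifier()]), `history` (data.frame per
#'   generation), `pareto` (data.frame: n_active, measure, fitness, one
#'   `active_<name>` flag and `thr_<name>` per submotif).
#' @export
ga_optimize <- function(submotifs, positives, negatives,
                        config = ga_config()) {
  if (!length(submotifs)) stop("need at least one candidate submotif")
  k <- length(submotifs)
  mc0 <- multi_classifier(submotifs)
  S_pos <- score_matrix(mc0, positives$sites$sequence)
  S_neg <- score_matrix(mc0, negatives$sites$sequence)
  fit_fn <- make_fitness_fn(S_pos, S_neg, config)
  measure_fun <- if (config$objective == "scc") scc else cc
  measure_of <- function(chrom) {
    act <- chrom_presence(chrom)
    thr <- chrom_thresholds(chrom)
    pp <- rowSums(S_pos[, act, drop = FALSE] >=
                    rep(thr[act], each = nrow(S_pos))) > 0
    pn <- rowSums(S_neg[, act, drop = FALSE] >=
                    rep(thr[act], each = nrow(S_neg))) > 0
    measure_fun(confusion_counts(TP = sum(pp), FN = nrow(S_pos) - sum(pp),
                                 FP = sum(pn), TN = nrow(S_neg) - sum(pn)))
  }
  with_seed(config$seed, {
    pop <- lapply(seq_len(config$population), function(i)
      as.vector(rbind(stats::runif(k), stats::runif(k))))
    fits <- vapply(pop, fit_fn, numeric(1))
    # per-complexity-level archive of the best measure seen
    archive <- new.env(parent = emptyenv())
    note <- function(chrom, fit) {
      act <- chrom_presence(chrom)
      if (!any(act) || !is.finite(fit)) return()
      key <- as.character(sum(act))
      msr <- measure_of(chrom)
      old <- archive[[key]]
      if (is.null(old) || msr > old$measure)
        archive[[key]] <- list(chrom = chrom, measure = msr, fitness = fit)
    }
    for (i in seq_along(pop)) note(pop[[i]], fits[i])
    history <- data.frame(generation = integer(0), best_fitness = numeric(0),
                          best_complexity = numeric(0))
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
      b <- which.max(fits)
      history <- rbind(history, data.frame(
        generation = gen, best_fitness = fits[b],
        best_complexity = sum(chrom_presence(pop[[b]])) / k))
    }
  })
  b <- which.max(fits)
  best <- pop[[b]]
  # Pareto filter over (measure up, n_active down)
  keys <- ls(archive)
  rows <- lapply(keys, function(kk) {
    e <- archive[[kk]]
    data.frame(n_active = as.integer(kk), measure = e$measure,
               fitness = e$fitness)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$n_active), , drop = FALSE]
  dominated <- vapply(seq_len(nrow(tab)), function(i)
    any(tab$n_active <= tab$n_active[i] & tab$measure >= tab$measure[i] &
          (tab$n_active < tab$n_active[i] | tab$measure > tab$measure[i])),
    logical(1))
  tab <- tab[!dominated, , drop = FALSE]
  vn <- vapply(submotifs, function(p) p$name, character(1))
  detail <- do.call(rbind, lapply(tab$n_active, function(na) {
    ch <- archive[[as.character(na)]]$chrom
    act <- chrom_presence(ch); thr <- chrom_thresholds(ch)
    row <- c(as.list(setNames(act, paste0("active_", vn))),
             as.list(setNames(round(thr, 4), paste0("thr_", vn))))
    as.data.frame(row)
  }))
  pareto <- cbind(tab, detail)
  rownames(pareto) <- NULL
  act <- chrom_presence(best)
  classifier <- multi_classifier(submotifs,
                                 thresholds = chrom_thresholds(best),
                                 active = act)
  list(best = best, best_fitness = fits[b], classifier = classifier,
       history = history, pareto = pareto)
}

#' Leave-one-submotif-out recovery analysis
#'
#' For each submotif, deactivates it and reports how many of its member
#' sites are still recovered by the remaining voters -- the redundancy
#' analysis behind per-family robustness claims.
#'
#' @param mc a [multi_classifier()].
#' @param tree a `submotif_tree` whose node names match voter names.
#' @param collection the full [site_collection()].
#' @return data.frame with `submotif`, `n_members`, `n_recovered_by_rest`,
#'   `pi` (hypergeometric overlap probability of the recovery).
#' @export
leave_one_out <- function(mc, tree, collection) {
  vn <- vapply(mc$pwms, function(p) p$name, character(1))
  rows <- lapply(seq_along(vn), function(i) {
    nd <- tree$nodes[[vn[i]]]
    if (is.null(nd)) return(NULL)
    rest <- mc
    rest$active[i] <- FALSE
    if (!any(rest$active)) return(NULL)
    sub <- collection[match(nd$member_ids, collection$sites$site_id)]
    pred <- predict(rest, sub$sites$sequence)$prediction
    rec_all <- predict(rest, collection$sites$sequence)$prediction
    g <- nrow(collection$sites)
    data.frame(submotif = vn[i], n_members = length(nd$member_ids),
               n_recovered_by_rest = sum(pred == "positive"),
               pi = hypergeom_overlap(sum(pred == "positive"),
                                      sum(rec_all == "positive"),
                                      length(nd$member_ids), g))
  })
  do.call(rbind, rows)
}
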