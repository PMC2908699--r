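# "Combine" phase: OR-voting multi-classifier over submotif PWMs, plus
# the CC/SCC performance measures used throughout optimization.

#' Construct a voting multi-classifier
#'
#' Each voter is a submotif PWM with its own score threshold and an
#' active flag.  A sequence is classified positive if ANY active voter's
#' normalized score reaches its threshold (score >= threshold, inclusive)
#' -- a single positive vote is sufficient.
#'
#' @param pwms list of `pwm_model`s.
#' @param thresholds numeric vector in `[0,1]`, recycled; defaults to each
#'   PWM's own threshold.
#' @param active logical vector, recycled (default all active).
#' @return a `multi_classifier`.
#' @export
multi_classifier <- function(pwms, thresholds = NULL, active = TRUE) {
  if (inherits(pwms, "pwm_model")) pwms <- list(pwms)
  k <- length(pwms)
  if (is.null(thresholds))
    thresholds <- vapply(pwms, function(p) p$threshold, numeric(1))
  thresholds <- rep_len(thresholds, k)
  if (any(thresholds < 0 | thresholds > 1))
    stop("thresholds must lie in [0,1]")
  active <- rep_len(active, k)
  structure(list(pwms = pwms, thresholds = thresholds, active = active),
            class = "multi_classifier")
}

#' @export
print.multi_classifier <- function(x, ...) {
  cat(sprintf("multi_classifier: %d voters (%d active)\n",
              length(x$pwms), sum(x$active)))
  invisible(x)
}

# n x k matrix of normalized scores of each sequence under each voter PWM
score_matrix <- function(mc, seqs) {
  vapply(mc$pwms, function(p) score_sequence(p, seqs),
         numeric(length(seqs)))
}

#' Predict site/non-site for fixed-length sequences
#'
#' @param object a [multi_classifier()].
#' @param seqs character vector of sequences of the voters' length.
#' @param ... ignored.
#' @return data.frame with `prediction` (`"positive"`/`"negative"`) and a
#'   logical `vote_<name>` column per voter showing which submotif fired.
#' @export
predict.multi_classifier <- function(object, seqs, ...) {
  if (!any(object$active))
    stop("configuration error: no active voters")
  S <- score_matrix(object, seqs)
  if (is.null(dim(S))) S <- matrix(S, nrow = length(seqs))
  votes <- sweep(S, 2, object$thresholds, ">=")
  votes[, !object$active] <- FALSE
  pred <- ifelse(rowSums(votes) > 0, "positive", "negative")
  out <- data.frame(prediction = pred)
  vn <- vapply(object$pwms, function(p) p$name, character(1))
  colnames(votes) <- paste0("vote_", vn)
  cbind(out, as.data.frame(votes))
}

#' Confusion counts
#'
#' @param TP,FP,TN,FN non-negative integer counts.
#' @return a `confusion_counts` list with derived `P = TP + FN` and
#'   `N = TN + FP`.
#' @export
confusion_counts <- function(TP, FP, TN, FN) {
  if (any(c(TP, FP, TN, FN) < 0)) stop("counts must be non-negative")
  structure(list(TP = TP, FP = FP, TN = TN, FN = FN,
                 P = TP + FN, N = TN + FP),
            class = "confusion_counts")
}

#' Evaluate a classifier on labelled site collections
#'
#' @param mc a [multi_classifier()].
#' @param positives,negatives [site_collection()]s of true sites and
#'   non-sites (ids must not overlap).
#' @return a [confusion_counts()].
#' @export
evaluate_classifier <- function(mc, positives, negatives) {
  if (length(intersect(positives$sites$site_id, negatives$sites$site_id)))
    stop("validation error: positive and negative site_ids overlap")
  pp <- predict(mc, positives$sites$sequence)$prediction
  pn <- predict(mc, negatives$sites$sequence)$prediction
  confusion_counts(TP = sum(pp == "positive"), FN = sum(pp == "negative"),
                   FP = sum(pn == "positive"), TN = sum(pn == "negative"))
}

#' Correlation coefficient (Matthews/Pearson phi) of a confusion table
#'
#' `CC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, with the
#' zero-denominator convention CC = 0.  Suitable for balanced data.
#'
#' @param counts a [confusion_counts()].
#' @return value in `[-1, 1]`.
#' @export
cc <- function(counts) {
  with(counts, {
    if (P <= 0 || N <= 0) stop("CC needs P > 0 and N > 0")
    den <- sqrt(as.numeric(TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
    if (den == 0) return(0)
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / den
  })
}

#' Standardized correlation coefficient (SCC)
#'
#' Extends CC for unbalanced positive/negative magnitudes by rescaling the
#' negative-class counts to the positive-class magnitude before applying
#' the CC formula: `FP' = FP * P/N`, `TN' = TN * P/N`.  With `P == N` it
#' reduces to CC exactly; a perfect classifier scores 1 at any imbalance.
#' The standardization is isolated here so a revised algebraic form would
#' change nothing else.
#'
#' @param counts a [confusion_counts()].
#' @return standardized value.
#' @export
scc <- function(counts) {
  with(counts, {
    if (P <= 0 || N <= 0) stop("SCC needs P > 0 and N > 0")
    r <- P / N
    cc(confusion_counts(TP = TP, FN = FN, FP = FP * r, TN = TN * r))
  })
}

#' Empirical false-discovery fraction over null regions
#'
#' Scans regions known to contain no planted sites and reports the
#' fraction with at least one positive hit from any active voter.
#'
#' @param mc a [multi_classifier()].
#' @param null_regions character vector of DNA regions.
#' @param strands passed to [scan_window()].
#' @return fraction in `[0,1]`.
#' @export
empirical_fdr <- function(mc, null_regions, strands = "both") {
  if (!length(null_regions)) stop("no null regions supplied")
  act <- which(mc$active)
  hit <- vapply(null_regions, function(rg) {
    for (i in act) {
      h <- scan_window(mc$pwms[[i]], rg, strands = strands,
                       threshold = mc$thresholds[i])
      if (nrow(h) > 0) return(TRUE)
    }
    FALSE
  }, logical(1), USE.NAMES = FALSE)
  mean(hit)
}

#' Calibrate voter thresholds for genome-wide scanning
#'
#' Thresholds learned on fixed-length training examples admit too many
#' hits when sliding over kilobases of genomic background (thousands of
#' placements per region).  This raises each active voter's threshold to
#' at least the maximum score its PWM attains anywhere on a set of null
#' regions, plus a safety margin.
#'
#' @param mc a [multi_classifier()].
#' @param null_regions character vector of background DNA regions
#'   containing no sites.
#' @param margin added to the observed null maximum (default 0.03).
#' @param floor per-voter lower bound kept on the thresholds (default 0:
#'   the calibration replaces the training thresholds, which answer a
#'   different question -- discriminating decoy sites, not background).
#' @param strands passed to [scan_window()].
#' @return the classifier with updated thresholds.
#' @export
calibrate_thresholds <- function(mc, null_regions, margin = 0.03,
                                 floor = 0, strands = "both") {
  floor <- rep_len(floor, length(mc$pwms))
  for (i in which(mc$active)) {
    null_max <- 0
    for (rg in null_regions) {
      h <- scan_window(mc$pwms[[i]], rg, strands = strands, threshold = 0)
      if (nrow(h)) null_max <- max(null_max, h$score[1])
    }
    mc$thresholds[i] <- min(1, max(floor[i], null_max + margin))
  }
  mc
}

#' Serialize a multi-classifier to JSON
#'
#' @param mc a [multi_classifier()].
#' @param path output path.
#' @export
write_classifier <- function(mc, path) {
  obj <- list(voters = lapply(seq_along(mc$pwms), function(i)
    list(name = mc$pwms[[i]]$name,
         freqs = mc$pwms[[i]]$freqs,
         background = mc$pwms[[i]]$background,
         threshold = mc$thresholds[i],
         active = mc$active[i])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a multi-classifier written by [write_classifier()]
#'
#' @param path JSON path.
#' @return a [multi_classifier()].
#' @export
read_classifier <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  v <- obj$voters
  pwms <- lapply(seq_len(nrow(v)), function(i) {
    f <- matrix(unlist(v$freqs[[i]]), nrow = 4, byrow = FALSE)
    f <- f / rep(colSums(f), each = 4)
    new_pwm(f, background = as.numeric(v$background[[i]]),
            threshold = v$threshold[i], name = v$name[i])
  })
  multi_classifier(pwms, thresholds = v$threshold, active = v$active)
}
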