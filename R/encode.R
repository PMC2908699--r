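# PWM encoding and scoring.  This is the in-repo submotif encoder: any
# external motif tool producing a 4xL probability matrix can be plugged in
# through new_pwm(), which is all the classifier layer depends on.

new_pwm <- function(freqs, pseudocount = 0, background = rep(0.25, 4),
                    threshold = 0.8, name = "pwm", nsites = NULL) {
  stopifnot(is.matrix(freqs), nrow(freqs) == 4L)
  rownames(freqs) <- DNA_BASES
  cs <- colSums(freqs)
  if (any(abs(cs - 1) > 1e-9)) stop("PWM columns must sum to 1")
  structure(list(freqs = freqs, pseudocount = pseudocount,
                 background = background, threshold = threshold,
                 name = name, nsites = nsites),
            class = "pwm_model")
}

#' Build a position weight matrix from cluster member sites
#'
#' Column frequencies are smoothed counts:
#' `f[b,p] = (count[b,p] + pseudocount * background[b]) / (n + pseudocount)`.
#'
#' @param members a [site_collection()] of cluster members.
#' @param pseudocount total pseudocount weight distributed according to the
#'   background (default 0.5).
#' @param background length-4 genomic base composition (A,C,G,T); default
#'   uniform.
#' @param threshold initial score cutoff in `[0,1]` attached to the model
#'   (later tuned by the optimizer).
#' @param name submotif label.
#' @return a `pwm_model` with elements `freqs` (4 x L), `pseudocount`,
#'   `background`, `threshold`, `name`.
#' @export
build_pwm <- function(members, pseudocount = 0.5,
                      background = rep(0.25, 4), threshold = 0.8,
                      name = "pwm") {
  stopifnot(inherits(members, "site_collection"))
  n <- nrow(members$sites)
  if (n == 0L) stop("cannot build a PWM from an empty member set")
  L <- members$length
  chars <- matrix(unlist(strsplit(members$sites$sequence, "")),
                  nrow = n, byrow = TRUE)
  counts <- vapply(seq_len(L), function(p)
    tabulate(match(chars[, p], DNA_BASES), nbins = 4L), numeric(4))
  f <- (counts + pseudocount * background) / (n + pseudocount)
  new_pwm(f, pseudocount = pseudocount, background = background,
          threshold = threshold, name = name, nsites = n)
}

#' @export
print.pwm_model <- function(x, ...) {
  cat(sprintf("pwm_model '%s': %d positions, IC %.2f bits, threshold %.2f\n",
              x$name, ncol(x$freqs), information_content(x)$total,
              x$threshold))
  invisible(x)
}

#' Information content of a PWM
#'
#' Uses the uniform-background convention: per position
#' `2 + sum_b f log2 f` bits.
#'
#' @param pwm a `pwm_model`.
#' @return list with `per_position` (numeric vector) and `total`.
#' @export
information_content <- function(pwm) {
  f <- pwm$freqs
  pl <- ifelse(f > 0, f * log2(f), 0)
  per <- 2 + colSums(pl)
  list(per_position = as.numeric(per), total = sum(per))
}

#' Consensus sequence of a PWM
#'
#' @param pwm a `pwm_model`.
#' @return the highest-probability base at each position (ties to the
#'   first base in A,C,G,T order).
#' @export
consensus_sequence <- function(pwm) {
  paste(DNA_BASES[apply(pwm$freqs, 2, which.max)], collapse = "")
}

# 4 x L log-odds score matrix vs background
logodds_matrix <- function(pwm) {
  log2(pwm$freqs / pwm$background)
}

#' Score a sequence against a PWM, normalized to [0,1]
#'
#' Log-odds sum against the background, min-max normalized by the best and
#' worst achievable scores of the PWM, so the consensus scores exactly 1
#' and the anti-consensus exactly 0.
#'
#' @param pwm a `pwm_model`.
#' @param seq a DNA string of the PWM's length (or character vector of
#'   them, scored vectorized).
#' @return numeric score(s) in `[0,1]`.
#' @export
score_sequence <- function(pwm, seq) {
  lo <- logodds_matrix(pwm)
  L <- ncol(lo)
  if (any(nchar(seq) != L))
    stop("sequence length must equal PWM length ", L)
  best <- sum(apply(lo, 2, max))
  worst <- sum(apply(lo, 2, min))
  chars <- matrix(match(unlist(strsplit(toupper(seq), "")), DNA_BASES),
                  nrow = length(seq), byrow = TRUE)
  if (anyNA(chars)) stop("non-ACGT character in sequence")
  raw <- vapply(seq_along(seq), function(i)
    sum(lo[cbind(chars[i, ], seq_len(L))]), numeric(1))
  if (best - worst < 1e-12) return(rep(1, length(seq)))
  pmin(1, pmax(0, (raw - worst) / (best - worst)))
}

#' Scan a region with a PWM on both strands
#'
#' Every placement on the forward and (optionally) reverse strand is
#' scored; reverse-strand hits are reported in forward coordinates
#' (0-based start of the matched window).
#'
#' @param pwm a `pwm_model`.
#' @param region DNA string, length >= PWM length.
#' @param strands `"both"` or `"+"`.
#' @param threshold score cutoff; defaults to `pwm$threshold`.
#' @return data.frame `ScoredHit`: columns `position` (0-based forward
#'   start), `strand`, `score`, `submotif`, sorted by decreasing score.
#' @export
scan_window <- function(pwm, region, strands = c("both", "+"),
                        threshold = NULL) {
  strands <- match.arg(strands)
  if (is.null(threshold)) threshold <- pwm$threshold
  L <- ncol(pwm$freqs)
  region <- toupper(region)
  n <- nchar(region)
  empty <- data.frame(position = integer(0), strand = character(0),
                      score = numeric(0), submotif = character(0))
  if (n < L) {
    warning("region shorter than PWM length; no placements")
    return(empty)
  }
  starts <- seq_len(n - L + 1L)
  wins <- substring(region, starts, starts + L - 1L)
  if (any(grepl("[^ACGT]", wins))) {
    ok <- !grepl("[^ACGT]", wins)
    starts <- starts[ok]; wins <- wins[ok]
    if (!length(starts)) return(empty)
  }
  sc_f <- score_sequence(pwm, wins)
  hits <- data.frame(position = starts - 1L, strand = "+", score = sc_f,
                     submotif = pwm$name)
  if (strands == "both") {
    sc_r <- score_sequence(pwm, revcomp(wins))
    hits <- rbind(hits,
                  data.frame(position = starts - 1L, strand = "-",
                             score = sc_r, submotif = pwm$name))
  }
  hits <- hits[hits$score >= threshold, , drop = FALSE]
  hits <- hits[order(-hits$score, hits$position), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
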