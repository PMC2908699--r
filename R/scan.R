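# Genome-wide application: ChIP-chip peak calling, region scanning with
# the multi-classifier, the five-category gene table with its empirical
# FDR, and cross-species submotif presence/absence.

#' Call ChIP-chip peaks from tiling signal
#'
#' The cutoff is `cutoff_fraction` of a hypothetical maximum defined as
#' mean + 6 standard deviations of all tile signals.  A 500-bp window
#' slides tile-wise; runs of at least `min_tiles` above-cutoff tiles
#' whose span fits inside a window merge into one peak.  Each peak gets
#' an FDR score: the fraction of `n_randomizations` within-chromosome
#' signal shuffles producing any peak with at least as many tiles.
#'
#' @param signal data.frame with `chrom, start, end, log2_ratio`, tiles
#'   sorted and non-overlapping per chromosome.
#' @param window_bp sliding window size (default 500).
#' @param min_tiles minimum above-cutoff tiles per peak (default 4).
#' @param cutoff_fraction fraction of the hypothetical maximum in (0,1]
#'   (default 0.5; the exploration range is 0.15-0.9).
#' @param n_randomizations shuffles for the FDR score (default 20).
#' @param seed RNG seed for the shuffles.
#' @return data.frame of peaks: `chrom, start, end, n_tiles, max_signal,
#'   fdr_score`.
#' @export
call_chip_peaks <- function(signal, window_bp = 500L, min_tiles = 4L,
                            cutoff_fraction = 0.5, n_randomizations = 20L,
                            seed = 1L) {
  if (!nrow(signal)) stop("empty signal")
  stopifnot(cutoff_fraction > 0, cutoff_fraction <= 1)
  if (any(!is.finite(signal$log2_ratio))) stop("non-finite tile signals")
  cutoff <- cutoff_fraction *
    (mean(signal$log2_ratio) + 6 * stats::sd(signal$log2_ratio))
  find_peaks <- function(sig) {
    out <- list()
    for (ch in unique(sig$chrom)) {
      s <- sig[sig$chrom == ch, , drop = FALSE]
      s <- s[order(s$start), , drop = FALSE]
      above <- s$log2_ratio > cutoff
      if (sum(above) < min_tiles) next
      # slide a window_bp window tile-wise; a window "fires" when it
      # holds >= min_tiles above-cutoff tiles; above-tiles inside firing
      # windows merge into peaks
      nt <- nrow(s)
      marked <- logical(nt)
      wincount <- integer(nt)
      j <- 1L
      for (i in seq_len(nt)) {
        if (j < i) j <- i
        while (j < nt && s$start[j + 1L] < s$start[i] + window_bp) j <- j + 1L
        cnt <- sum(above[i:j])
        wincount[i] <- cnt
        if (cnt >= min_tiles) marked[i:j] <- marked[i:j] | above[i:j]
      }
      if (!any(marked)) next
      idx <- which(marked)
      grp <- cumsum(c(1, diff(idx) > 1L))
      for (g in split(idx, grp)) {
        # peak strength = densest single window it contains
        dens <- max(wincount[g])
        if (dens < min_tiles) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, start = min(s$start[g]), end = max(s$end[g]),
          n_tiles = dens, max_signal = max(s$log2_ratio[g]))
      }
    }
    if (!length(out))
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), n_tiles = integer(0),
                        max_signal = numeric(0)))
    do.call(rbind, out)
  }
  peaks <- find_peaks(signal)
  if (!nrow(peaks)) {
    peaks$fdr_score <- numeric(0)
    return(peaks)
  }
  null_max <- with_seed(seed, vapply(seq_len(n_randomizations), function(r) {
    sh <- signal
    for (ch in unique(sh$chrom)) {
      i <- sh$chrom == ch
      sh$log2_ratio[i] <- sample(sh$log2_ratio[i])
    }
    np <- find_peaks(sh)
    if (nrow(np)) max(np$n_tiles) else 0L
  }, numeric(1)))
  peaks$fdr_score <- vapply(peaks$n_tiles, function(nt)
    mean(null_max >= nt), numeric(1))
  peaks[order(peaks$chrom, peaks$start), , drop = FALSE]
}

#' Scan annotated regions for binding sites
#'
#' Applies every active voter of the classifier to each eligible region
#' (by default the non-excluded intergenic regions: intergenic stretches
#' longer than 20 bp) on both strands, and annotates hits with the
#' attributed gene (the head of its operon), the submotif that fired,
#' and -- when the region's TSS is known -- the signed offset of the
#' site's TSS-proximal edge from the TSS.
#'
#' @param mc a [multi_classifier()].
#' @param genome named character vector (or `DNAStringSet`) of chromosome
#'   sequences.
#' @param annotation a `genome_annotation` from [read_annotation()] or
#'   [make_dataset()].
#' @param kinds region kinds to scan (default `"intergenic"`).
#' @return data.frame of hits: `region_id, chrom, start, end, strand,
#'   score, submotif, gene, operon_head, tss_offset`.
#' @export
scan_regions <- function(mc, genome, annotation,
                         kinds = "intergenic") {
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  act <- which(mc$active)
  L <- ncol(mc$pwms[[act[1]]]$freqs)
  regions <- annotation[annotation$kind %in% kinds & !annotation$excluded, ,
                        drop = FALSE]
  rows <- list()
  for (r in seq_len(nrow(regions))) {
    reg <- regions[r, ]
    chrom_seq <- unname(genome[reg$chrom])
    if (length(chrom_seq) != 1L || is.na(chrom_seq))
      stop("coordinate error: chromosome ", reg$chrom, " not in genome")
    if (reg$end > nchar(chrom_seq))
      stop("coordinate error: region ", reg$region_id,
           " beyond chromosome end")
    seq <- substr(chrom_seq, reg$start + 1L, reg$end)
    if (nchar(seq) < L) next
    for (i in act) {
      h <- scan_window(mc$pwms[[i]], seq, threshold = mc$thresholds[i])
      if (!nrow(h)) next
      abs_start <- reg$start + h$position
      tssoff <- rep(NA_integer_, nrow(h))
      if (!is.na(reg$tss)) {
        # signed offset of the site's TSS-proximal edge, on the gene strand
        edge <- ifelse(rep(reg$strand == "-", nrow(h)), abs_start,
                       abs_start + L)
        tssoff <- if (reg$strand == "-") as.integer(reg$tss - edge)
        else as.integer(edge - reg$tss)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        region_id = reg$region_id, chrom = reg$chrom,
        start = abs_start, end = abs_start + L, strand = h$strand,
        score = h$score, submotif = h$submotif, gene = reg$gene,
        operon_head = reg$operon_head, tss_offset = tssoff)
    }
  }
  if (!length(rows))
    return(data.frame(region_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0),
                      submotif = character(0), gene = character(0),
                      operon_head = logical(0), tss_offset = integer(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

#' Categorize genes by expression, promoter occupancy and predicted sites
#'
#' Each gene (operon head) is assigned exactly one of five categories
#' from its expression call, ChIP peak overlap and predicted-site status:
#' `expr+peak`, `expr-only`, `peak-only`, `neither`, and `coding-peak`
#' (non-expressed gene whose only peak lies in its coding region).  The
#' empirical method FDR is the fraction of `neither` genes that
#' nevertheless carry a predicted site.
#'
#' @param hits [scan_regions()] output.
#' @param expression_calls data.frame with `gene` and `expressed`
#'   (logical or `"yes"/"no"`).
#' @param peaks [call_chip_peaks()] output.
#' @param annotation the `genome_annotation`.
#' @return list with `table` (per-gene data.frame: `gene, expressed,
#'   chip_peak, bs_found, category`), `counts` (per category),
#'   `bs_fraction` (per category), `method_fdr`.
#' @export
categorize_genes <- function(hits, expression_calls, peaks, annotation) {
  genes <- unique(annotation$gene[annotation$operon_head &
                                    !is.na(annotation$gene)])
  expr <- expression_calls
  if (!is.logical(expr$expressed)) expr$expressed <- expr$expressed %in% c("yes", "TRUE", "1")
  unknown <- setdiff(expr$gene, genes)
  if (length(unknown))
    stop("validation error: unknown gene ids in expression calls: ",
         paste(unknown, collapse = ", "))
  tab <- data.frame(gene = genes, stringsAsFactors = FALSE)
  tab$expressed <- tab$gene %in% expr$gene[expr$expressed]
  inter <- annotation[annotation$kind == "intergenic", , drop = FALSE]
  coding <- annotation[annotation$kind == "coding", , drop = FALSE]
  peak_over <- function(regions) {
    vapply(tab$gene, function(g) {
      rg <- regions[!is.na(regions$gene) & regions$gene == g, , drop = FALSE]
      if (!nrow(rg) || !nrow(peaks)) return(FALSE)
      any(vapply(seq_len(nrow(rg)), function(i)
        any(peaks$chrom == rg$chrom[i] &
              overlaps(peaks$start, peaks$end, rg$start[i], rg$end[i])),
        logical(1)))
    }, logical(1), USE.NAMES = FALSE)
  }
  tab$chip_peak <- peak_over(inter)
  coding_peak <- peak_over(coding)
  tab$bs_found <- tab$gene %in% hits$gene
  tab$category <- ifelse(tab$expressed & tab$chip_peak, "expr+peak",
                  ifelse(tab$expressed, "expr-only",
                  ifelse(tab$chip_peak, "peak-only",
                  ifelse(coding_peak, "coding-peak", "neither"))))
  counts <- table(factor(tab$category,
                         levels = c("expr+peak", "expr-only", "peak-only",
                                    "neither", "coding-peak")))
  bs_frac <- tapply(tab$bs_found, factor(tab$category,
                                         levels = names(counts)), mean)
  neither <- tab$category == "neither"
  method_fdr <- if (any(neither)) mean(tab$bs_found[neither]) else 0
  list(table = tab, counts = counts, bs_fraction = bs_frac,
       method_fdr = method_fdr)
}

#' Cross-species submotif presence/count matrix
#'
#' Counts, per species, how many orthologous promoters carry each
#' submotif.  Optionally compresses submotifs to their most general
#' ancestor family in a `submotif_tree`.
#'
#' @param hits_by_species named list of [scan_regions()] outputs (or
#'   site-level data.frames with `gene` and `submotif` columns), one per
#'   species.
#' @param ortholog_table data.frame with one column per species holding
#'   orthologous gene ids (rows = ortholog groups).
#' @param tree optional `submotif_tree` for family compression.
#' @param compress compress submotifs to the child-of-root family they
#'   descend from (default FALSE).
#' @return integer matrix species x submotif.
#' @export
submotif_presence_matrix <- function(hits_by_species, ortholog_table,
                                     tree = NULL, compress = FALSE) {
  species <- names(hits_by_species)
  if (!nrow(ortholog_table))
    return(matrix(0L, nrow = length(species), ncol = 0,
                  dimnames = list(species, NULL)))
  missing_sp <- setdiff(species, names(ortholog_table))
  if (length(missing_sp)) {
    warning("species absent from ortholog table: ",
            paste(missing_sp, collapse = ", "))
    species <- setdiff(species, missing_sp)
  }
  family_of <- identity
  if (compress && !is.null(tree)) {
    anc <- function(nid) {
      while (!is.na(tree$nodes[[nid]]$parent) &&
             tree$nodes[[nid]]$parent != "root")
        nid <- tree$nodes[[nid]]$parent
      nid
    }
    family_of <- function(x) vapply(x, function(s)
      if (s %in% names(tree$nodes)) anc(s) else s, character(1),
      USE.NAMES = FALSE)
  }
  subs <- sort(unique(unlist(lapply(species, function(sp)
    family_of(hits_by_species[[sp]]$submotif)))))
  M <- matrix(0L, nrow = length(species), ncol = length(subs),
              dimnames = list(species, subs))
  for (sp in species) {
    h <- hits_by_species[[sp]]
    h <- h[h$gene %in% ortholog_table[[sp]], , drop = FALSE]
    if (!nrow(h)) next
    fam <- family_of(h$submotif)
    cnt <- table(unique(data.frame(gene = h$gene, fam = fam))$fam)
    M[sp, names(cnt)] <- as.integer(cnt)
  }
  M
}
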