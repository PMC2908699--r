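flat_signal <- function(n_tiles = 200, tile = 50, value = 0) {
  data.frame(chrom = "chr1", start = (seq_len(n_tiles) - 1L) * tile,
             end = seq_len(n_tiles) * tile, log2_ratio = value)
}

test_that("call_chip_peaks recovers planted boxcars and rejects short runs", {
  empty_sig <- data.frame(chrom = character(0), start = integer(0),
                          end = integer(0), log2_ratio = numeric(0))
  expect_error(call_chip_peaks(empty_sig), "empty")
  # all-zero signal: no peaks
  expect_equal(nrow(call_chip_peaks(flat_signal())), 0L)
  # one boxcar of 6 high tiles in noisy-flat background: exactly 1 peak
  set.seed(1)
  sig <- flat_signal()
  sig$log2_ratio <- rnorm(200, 0, 0.2)
  sig$log2_ratio[90:95] <- 3
  pk <- call_chip_peaks(sig, seed = 2)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, sig$start[90])
  expect_equal(pk$end, sig$end[95])
  expect_equal(pk$n_tiles, 6L)
  expect_lte(pk$fdr_score, 0.1)
  # a 3-tile run never qualifies (the >= 4 tiles rule)
  sig3 <- flat_signal()
  sig3$log2_ratio <- rnorm(200, 0, 0.2)
  sig3$log2_ratio[50:52] <- 3
  expect_equal(nrow(call_chip_peaks(sig3, seed = 2)), 0L)
})

test_that("peak calling is translation invariant", {
  set.seed(4)
  sig <- flat_signal()
  sig$log2_ratio <- rnorm(200, 0, 0.2)
  sig$log2_ratio[40:44] <- 3
  pk1 <- call_chip_peaks(sig, seed = 5)
  shifted <- sig
  shifted$start <- sig$start + 10000L
  shifted$end <- sig$end + 10000L
  pk2 <- call_chip_peaks(shifted, seed = 5)
  expect_equal(pk2$start, pk1$start + 10000L)
  expect_equal(pk2$end, pk1$end + 10000L)
  expect_equal(pk2$n_tiles, pk1$n_tiles)
})

# one genome fixture shared by the scanning tests
scan_world <- local({
  ds <- NULL
  function() {
    if (is.null(ds))
      ds <<- make_dataset(synth_config(seed = 8, n_planted_genes = 30))
    ds
  }
})

test_that("scan_regions recovers planted sites and respects region filters", {
  ds <- scan_world()
  subs <- c(lapply(unique(ds$family_of), function(f) build_pwm(
    ds$positives[ds$truth_labels$site_id[ds$truth_labels$family == f]],
    name = f)), truth_submotifs(ds))
  mc <- calibrate_thresholds(multi_classifier(subs),
                             sample_background(120, 300, 0.5, 0, seed = 9))
  hits <- scan_regions(mc, ds$genome, ds$annotation)
  found <- mapply(function(g, st)
    any(hits$gene == g & abs(hits$start - st) < 3),
    ds$planted$gene, ds$planted$start)
  expect_gte(mean(found), 0.95)
  # excluded (short) intergenic regions are never scanned
  short_ann <- ds$annotation
  short_ann$excluded[short_ann$kind == "intergenic"] <- TRUE
  expect_equal(nrow(scan_regions(mc, ds$genome, short_ann)), 0L)
  # distance annotation: planted hits carry the planted offset
  m <- merge(hits, ds$planted, by = "gene", suffixes = c("", "_p"))
  m <- m[abs(m$start - m$start_p) < 3 & m$submotif == m$submotif_p, ]
  expect_gt(nrow(m), 0)
  expect_true(all(abs(m$tss_offset - m$tss_offset_p) <= 1))
})

test_that("scan_regions reports reverse-orientation sites in forward coordinates", {
  ds <- scan_world()
  pwm <- ds$pwms[[names(ds$family_of)[1]]]
  cons <- consensus_sequence(pwm)
  rc <- submotifr:::revcomp(cons)
  genome <- c(chr1 = paste0(sample_background(1, 100, 0.5, 0, seed = 11),
                            rc,
                            sample_background(1, 100, 0.5, 0, seed = 12)))
  ann <- data.frame(region_id = "intergenic_1", chrom = "chr1",
                    start = 80L, end = 150L, strand = "+",
                    kind = "intergenic", gene = "g1", operon_head = TRUE,
                    tss = 150L, excluded = FALSE)
  mc <- multi_classifier(list(pwm), thresholds = 0.95)
  hits <- scan_regions(mc, genome, ann)
  expect_gte(nrow(hits), 1L)
  expect_equal(hits$strand[1], "-")
  expect_equal(hits$start[1], 100L)
  expect_equal(hits$end[1], 100L + nchar(cons))
})

test_that("categorize_genes matches the per-gene oracle and bounds the method FDR", {
  ds <- scan_world()
  subs <- c(lapply(unique(ds$family_of), function(f) build_pwm(
    ds$positives[ds$truth_labels$site_id[ds$truth_labels$family == f]],
    name = f)), truth_submotifs(ds))
  mc <- calibrate_thresholds(multi_classifier(subs),
                             sample_background(120, 300, 0.5, 0, seed = 9))
  hits <- scan_regions(mc, ds$genome, ds$annotation)
  peaks <- call_chip_peaks(ds$signal, seed = 10)
  cats <- categorize_genes(hits, ds$expression, peaks, ds$annotation)
  tab <- cats$table
  # category counts partition the gene universe
  expect_equal(sum(cats$counts),
               length(unique(ds$annotation$gene[ds$annotation$operon_head])))
  # per-gene brute-force oracle over the three flags
  inter <- ds$annotation[ds$annotation$kind == "intergenic", ]
  for (i in sample(nrow(tab), 12)) {
    g <- tab$gene[i]
    expr <- g %in% ds$expression$gene[ds$expression$expressed]
    rg <- inter[inter$gene == g, ]
    pk <- nrow(rg) > 0 && nrow(peaks) > 0 &&
      any(peaks$start < rg$end[1] & rg$start[1] < peaks$end)
    bs <- g %in% hits$gene
    expect_equal(tab$expressed[i], expr)
    expect_equal(tab$chip_peak[i], pk)
    expect_equal(tab$bs_found[i], bs)
    want <- if (expr && pk) "expr+peak" else if (expr) "expr-only"
    else if (pk) "peak-only" else tab$category[i]
    expect_equal(tab$category[i], want)
  }
  # the designated unexpressed ChIP-positive genes land in peak-only
  expect_gte(cats$counts[["peak-only"]], 1)
  # no planted sites among neither genes: method FDR below the 1% bound
  expect_lte(cats$method_fdr, 0.01)
  # unknown gene ids are a validation error
  bad_expr <- rbind(ds$expression,
                    data.frame(gene = "no_such_gene", expressed = TRUE))
  expect_error(categorize_genes(hits, bad_expr, peaks, ds$annotation),
               "unknown gene")
})

test_that("raising thresholds never increases bs_found in any category", {
  ds <- scan_world()
  subs <- truth_submotifs(ds)
  peaks <- call_chip_peaks(ds$signal, seed = 10)
  prev <- Inf
  for (t in c(0.8, 0.9, 0.97)) {
    mc <- multi_classifier(subs, thresholds = t)
    hits <- scan_regions(mc, ds$genome, ds$annotation)
    cats <- categorize_genes(hits, ds$expression, peaks, ds$annotation)
    expect_lte(sum(cats$table$bs_found), prev)
    prev <- sum(cats$table$bs_found)
  }
})

test_that("submotif_presence_matrix reflects planted cross-species turnover", {
  ds <- scan_world()
  subs <- truth_submotifs(ds)
  mc <- calibrate_thresholds(multi_classifier(subs),
                             sample_background(120, 300, 0.5, 0, seed = 9))
  hits_a <- scan_regions(mc, ds$genome, ds$annotation)
  hits_b <- scan_regions(mc, ds$genome_b, ds$annotation_b)
  M <- submotif_presence_matrix(list(speciesA = hits_a, speciesB = hits_b),
                                ds$ortholog_table)
  fams <- ds$family_of[colnames(M)]
  # species B lacks the last family by construction
  dropped <- setdiff(unique(ds$family_of), unique(ds$planted_b$family))
  expect_gt(sum(M["speciesA", fams == dropped]), 0)
  expect_equal(sum(M["speciesB", fams == dropped]), 0)
  # family compression collapses columns onto child-of-root ancestors
  Mc <- submotif_presence_matrix(list(speciesA = hits_a,
                                      speciesB = hits_b),
                                 ds$ortholog_table, tree = ds$tree,
                                 compress = TRUE)
  expect_true(all(colnames(Mc) %in% unique(ds$family_of)))
  # duplicate species give identical rows; empty table gives empty matrix
  M2 <- submotif_presence_matrix(list(s1 = hits_a, s2 = hits_a),
                                 data.frame(s1 = ds$ortholog_table$speciesA,
                                            s2 = ds$ortholog_table$speciesA))
  expect_equal(unname(M2[1, ]), unname(M2[2, ]))
  expect_equal(ncol(submotif_presence_matrix(list(speciesA = hits_a),
                                             data.frame(speciesA = character(0))[0, , drop = FALSE])),
               0L)
})
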