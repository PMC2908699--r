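# Seeded synthetic-data generators.  They emulate the statistical
# structure the method assumes -- family-organized submotif PWMs over a
# two-hexamer direct-repeat box, Markov background of configurable
# composition, decoy-PWM negatives, TF-RNAP distance classes, a genome
# with planted promoter sites, tiling signal with planted peaks -- so the
# whole pipeline is testable offline.  Statistical stand-ins only; no
# attempt to imitate real PhoP sequence content.

#' Synthetic-world configuration
#'
#' Defaults state the world the generators produce: a 19-bp box (two
#' direct-repeat hexamers at positions 3-8 and 12-17 separated by a 3-bp
#' spacer), 3 submotif families of 2 submotifs with 10 sites each
#' (a training set on the order of the classical two-genome PhoP
#' collection), 150 decoy/background negatives, distance classes peaking
#' at -34/-44/-68 bp, and a 50-kb genome of ~40 operons with 20 planted
#' promoters.
#'
#' @param n_families number of submotif families.
#' @param submotifs_per_family children per family.
#' @param site_length box length L in bp.
#' @param sites_per_submotif training sites sampled per submotif.
#' @param conservation probability mass on the consensus base in the
#'   conserved hexamer positions of a parent PWM.
#' @param sharp_conservation same, in the sharpened hexamer of a child.
#' @param weak_conservation consensus mass at spacer/flank positions.
#' @param child_divergence number of consensus positions (inside the
#'   sharpened tandem, disjoint per sibling) at which each child submotif
#'   departs from its family consensus.
#' @param background_order Markov order of the background (0, 1 or 2).
#' @param gc_content background GC fraction in (0,1).
#' @param n_negatives number of negative examples.
#' @param distance_apexes per-family distance-class triangle apexes (bp
#'   upstream of the TSS); recycled over families.
#' @param genome_length,n_genes,gene_length genome geometry (bp).
#' @param n_planted_genes promoters receiving a planted site.
#' @param planted_site_min_score minimum normalized score of a planted
#'   genomic site under its generating submotif PWM (functional sites
#'   are under selection to bind; default 0.88).
#' @param tile_bp tiling-array tile size.
#' @param seed mandatory RNG seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_families = 3L, submotifs_per_family = 2L,
                         site_length = 19L, sites_per_submotif = 10L,
                         conservation = 0.92, sharp_conservation = 0.98,
                         weak_conservation = 0.75, child_divergence = 4L,
                         background_order = 0L, gc_content = 0.5,
                         n_negatives = 150L,
                         distance_apexes = c(-34, -44, -68),
                         genome_length = 50000L, n_genes = 40L,
                         gene_length = 800L, n_planted_genes = 20L,
                         planted_site_min_score = 0.88,
                         tile_bp = 50L, seed = 1L) {
  stopifnot(n_families >= 1, submotifs_per_family >= 1,
            site_length >= 15, gc_content > 0, gc_content < 1,
            background_order %in% 0:2, !is.null(seed))
  structure(as.list(environment()), class = "synth_config")
}

# box geometry helpers for a site of length L >= 15:
# hexamer1 at 3..8, spacer 9..11, hexamer2 at 12..17 (19-bp default)
box_blocks <- function(L) {
  list(tandem1 = 3:8, spacer = 9:11, tandem2 = 12:17,
       flank = setdiff(seq_len(L), 3:17))
}

pwm_from_consensus <- function(consensus, cons_level) {
  L <- length(consensus)
  f <- matrix((1 - rep(cons_level, each = 4)) / 3, nrow = 4,
              dimnames = list(DNA_BASES, NULL))
  f[cbind(match(consensus, DNA_BASES), seq_len(L))] <- cons_level
  f
}

#' Generate family-structured submotif PWMs with a planted hierarchy
#'
#' Each family gets a random consensus; the parent PWM conserves both
#' hexamer tandems at `conservation` while spacer/flank positions stay
#' weak; each child sharpens one tandem (alternating, echoing the
#' strong-first-repeat vs strong-second-repeat contrast between sibling
#' submotifs) to `sharp_conservation`.
#'
#' @param config a [synth_config()].
#' @return list with `pwms` (named list, `F<f>` parents and `F<f>S<j>`
#'   children), `family_of` (named vector child -> family), `tree`
#'   (planted `submotif_tree` skeleton without member sites).
#' @export
make_submotif_pwms <- function(config) {
  L <- config$site_length
  blk <- box_blocks(L)
  with_seed(config$seed, {
    pwms <- list()
    family_of <- character(0)
    nodes <- list(root = list(member_ids = character(0),
                              parent = NA_character_,
                              children = character(0), source = "planted"))
    for (f in seq_len(config$n_families)) {
      consensus <- sample(DNA_BASES, L, replace = TRUE)
      cons <- rep(config$weak_conservation, L)
      cons[c(blk$tandem1, blk$tandem2)] <- config$conservation
      fam_id <- sprintf("F%d", f)
      pwms[[fam_id]] <- new_pwm(pwm_from_consensus(consensus, cons),
                                name = fam_id)
      nodes[[fam_id]] <- list(member_ids = character(0), parent = "root",
                              children = character(0), source = "planted")
      nodes$root$children <- c(nodes$root$children, fam_id)
      for (j in seq_len(config$submotifs_per_family)) {
        cons_j <- cons
        sharp <- if (j %% 2L == 1L) blk$tandem1 else blk$tandem2
        cons_j[sharp] <- config$sharp_conservation
        # siblings diverge at child_divergence consensus positions inside
        # their sharpened tandem (disjoint positions per child), so fine
        # structure is visible in sequence space, not just in conservation
        cons_child <- consensus
        nd <- min(config$child_divergence, length(sharp))
        div_pos <- sharp[((j - 1L) * nd + seq_len(nd) - 1L) %%
                           length(sharp) + 1L]
        for (p in div_pos)
          cons_child[p] <- sample(setdiff(DNA_BASES, cons_child[p]), 1)
        sid <- sprintf("%sS%d", fam_id, j)
        pwms[[sid]] <- new_pwm(pwm_from_consensus(cons_child, cons_j),
                               name = sid)
        family_of[sid] <- fam_id
        nodes[[sid]] <- list(member_ids = character(0), parent = fam_id,
                             children = character(0), source = "planted")
        nodes[[fam_id]]$children <- c(nodes[[fam_id]]$children, sid)
      }
    }
    list(pwms = pwms, family_of = family_of,
         tree = structure(list(nodes = nodes), class = "submotif_tree"))
  })
}

#' Sample sites i.i.d. from a PWM
#'
#' @param pwm a `pwm_model`.
#' @param n number of sites (>= 1).
#' @param seed RNG seed.
#' @param prefix site_id prefix.
#' @return a [site_collection()].
#' @export
sample_sites <- function(pwm, n, seed = 1L, prefix = pwm$name) {
  stopifnot(n >= 1)
  f <- pwm$freqs
  L <- ncol(f)
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(vapply(seq_len(L), function(p)
        sample(DNA_BASES, 1, prob = f[, p]), character(1)), collapse = ""),
      character(1))
    site_collection(seqs, site_id = sprintf("%s_%03d", prefix, seq_len(n)))
  })
}

#' Sample Markov background sequences
#'
#' Order-0 draws i.i.d. bases from the composition; orders 1-2 use a
#' Markov chain whose transition rows mix the target composition with a
#' small self-transition excess (autocorrelation 0.1), keeping the
#' marginal composition on target.
#'
#' @param n number of sequences.
#' @param length sequence length (>= 1).
#' @param gc_content GC fraction; the AT-rich preset of the acquired-
#'   region analyses is `gc_content = 0.3` (A+T = 0.7).
#' @param order Markov order in 0:2.
#' @param seed RNG seed.
#' @return character vector of sequences.
#' @export
sample_background <- function(n, length, gc_content = 0.5, order = 0L,
                              seed = 1L) {
  if (length < 1) stop("length must be >= 1")
  comp <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
            G = gc_content / 2, T = (1 - gc_content) / 2)
  with_seed(seed, {
    if (order == 0L) {
      m <- matrix(sample(DNA_BASES, n * length, replace = TRUE,
                         prob = comp), nrow = n)
      return(apply(m, 1, paste, collapse = ""))
    }
    rho <- 0.1
    trans <- (1 - rho) * matrix(comp, 4, 4, byrow = TRUE) + rho * diag(4)
    vapply(seq_len(n), function(i) {
      s <- integer(length)
      s[1] <- sample.int(4, 1, prob = comp)
      for (p in seq_len(length - 1L))
        s[p + 1L] <- sample.int(4, 1, prob = trans[s[p], ])
      paste(DNA_BASES[s], collapse = "")
    }, character(1))
  })
}

# integer sample from a triangular density with feet a,c and apex b
sample_triangular <- function(n, a, b, c) {
  u <- stats::runif(n)
  fc <- (b - a) / (c - a)
  x <- ifelse(u < fc, a + sqrt(u * (c - a) * (b - a)),
              c - sqrt((1 - u) * (c - a) * (c - b)))
  as.integer(round(x))
}

default_distance_sets <- function(apexes = c(-34, -44, -68),
                                  half_width = 6) {
  labs <- if (length(apexes) == 3L) c("close", "medium", "far")
  else paste0("d", seq_along(apexes))
  lapply(seq_along(apexes), function(i)
    triangular_set(apexes[i] - half_width, apexes[i], apexes[i] + half_width,
                   label = labs[i]))
}

#' Generate the full synthetic fixture
#'
#' Produces every input the pipeline needs, mutually consistent and fully
#' determined by `(config, seed)`: training positives with TF-RNAP
#' distances, decoy + background negatives, a genome with planted
#' promoter sites and its annotation, tiling signal with peaks at the
#' ChIP-positive promoters, expression calls, an ortholog table for two
#' synthetic species (the second species lacking the last family --
#' planted submotif turnover), and a ground-truth manifest.
#'
#' @param config a [synth_config()].
#' @return list with elements `pwms`, `family_of`, `tree`, `positives`,
#'   `negatives`, `distance_sets`, `genome`, `annotation`, `planted`,
#'   `signal`, `expression`, `ortholog_table`, `genome_b`,
#'   `annotation_b`, `planted_b`, `truth`.
#' @export
make_dataset <- function(config = synth_config()) {
  ts <- make_training_set(config)
  c(ts, make_genome_fixture(config, ts))
}

#' Generate only the training part of the synthetic fixture
#'
#' The positives/negatives/labels subset of [make_dataset()], without the
#' genome, tiling signal, or expression fixtures -- much faster, for
#' tests that loop over many seeds.
#'
#' @param config a [synth_config()].
#' @return list with `pwms`, `family_of`, `tree`, `positives`,
#'   `negatives`, `distance_sets`, `truth_labels`, `config`.
#' @export
make_training_set <- function(config = synth_config()) {
  L <- config$site_length
  mot <- make_submotif_pwms(config)
  child_ids <- names(mot$family_of)
  fam_ids <- unique(mot$family_of)
  apexes <- rep_len(config$distance_apexes, length(fam_ids))
  dsets <- default_distance_sets(config$distance_apexes)
  fam_apex <- setNames(apexes, fam_ids)

  # training positives: sites per child submotif, with distances drawn
  # from the family's triangle
  pos_list <- list()
  labels <- list()
  for (i in seq_along(child_ids)) {
    sid <- child_ids[i]
    coll <- sample_sites(mot$pwms[[sid]], config$sites_per_submotif,
                         seed = config$seed + 17L * i, prefix = sid)
    fam <- mot$family_of[[sid]]
    apx <- fam_apex[[fam]]
    d <- with_seed(config$seed + 31L * i,
                   sample_triangular(length(coll), apx - 6, apx, apx + 6))
    coll$sites$tss_offset <- pmin(10L, pmax(-90L, d))
    coll$sites$gene <- paste0("train_", coll$sites$site_id)
    coll$sites$genome <- "speciesA"
    coll$sites$strand <- "+"
    pos_list[[sid]] <- coll
    labels[[sid]] <- data.frame(site_id = coll$sites$site_id,
                                submotif = sid, family = fam)
  }
  positives <- do.call(rbind, lapply(pos_list, function(x) x$sites))
  positives <- structure(list(sites = positives, length = L),
                         class = "site_collection")
  rownames(positives$sites) <- NULL
  truth_labels <- do.call(rbind, labels)
  rownames(truth_labels) <- NULL

  # negatives: half decoy-PWM samples emulating binding sites of "other
  # TFs" that share the direct-repeat grammar -- chimeras pairing the
  # first tandem of one family's consensus with the second tandem of
  # another's.  A blended single motif scores a chimera like a true site
  # (each half matches one family), while a family-specific submotif sees
  # only a half-match; this is the structure that makes submotif voting
  # outperform the single motif.  The other half are background windows.
  n_dec <- config$n_negatives %/% 2L
  n_bg <- config$n_negatives - n_dec
  blk <- box_blocks(L)
  decoys <- with_seed(config$seed + 101L, {
    nf <- length(fam_ids)
    lapply(seq_len(max(nf, 2L)), function(k) {
      lev <- rep(config$weak_conservation, L)
      lev[c(blk$tandem1, blk$tandem2)] <- config$conservation
      cons <- sample(DNA_BASES, L, replace = TRUE)
      if (nf >= 2L) {
        c1 <- strsplit(consensus_sequence(mot$pwms[[fam_ids[(k - 1L) %% nf + 1L]]]), "")[[1]]
        c2 <- strsplit(consensus_sequence(mot$pwms[[fam_ids[k %% nf + 1L]]]), "")[[1]]
        cons[blk$tandem1] <- c1[blk$tandem1]
        cons[blk$tandem2] <- c2[blk$tandem2]
      }
      new_pwm(pwm_from_consensus(cons, lev), name = paste0("decoy", k))
    })
  })
  per_decoy <- diff(round(seq(0, n_dec, length.out = length(decoys) + 1L)))
  neg_seqs <- c(
    unlist(lapply(seq_along(decoys), function(k) {
      if (per_decoy[k] < 1L) return(character(0))
      sample_sites(decoys[[k]], per_decoy[k],
                   seed = config$seed + 101L + k,
                   prefix = paste0("neg_d", k))$sites$sequence
    })),
    sample_background(n_bg, L, config$gc_content, config$background_order,
                      seed = config$seed + 104L))
  negatives <- site_collection(neg_seqs,
                               site_id = sprintf("neg_%03d",
                                                 seq_along(neg_seqs)),
                               genome = "speciesA")
  # distances of negatives: uniform over the window (no architecture)
  negatives$sites$tss_offset <-
    with_seed(config$seed + 105L,
              as.integer(round(stats::runif(length(neg_seqs), -90, 10))))

  list(pwms = mot$pwms, family_of = mot$family_of, tree = mot$tree,
       positives = positives, negatives = negatives,
       distance_sets = dsets, truth_labels = truth_labels,
       config = config)
}

# genome, tiling, expression and ortholog fixtures around a training set
make_genome_fixture <- function(config, ts) {
  mot <- list(pwms = ts$pwms, family_of = ts$family_of)
  fam_ids <- unique(ts$family_of)
  gA <- plant_genome(config, mot, fam_ids, seed = config$seed + 200L)
  gB <- plant_genome(config, mot, fam_ids[-length(fam_ids)],
                     seed = config$seed + 300L, gene_prefix = "b")

  # tiling signal: baseline noise + boxcar peaks at ChIP-positive promoters
  n_tiles <- config$genome_length %/% config$tile_bp
  signal <- data.frame(chrom = "chr1",
                       start = (seq_len(n_tiles) - 1L) * config$tile_bp,
                       end = seq_len(n_tiles) * config$tile_bp)
  chip_genes <- gA$planted$gene[gA$planted$chip_positive]
  signal$log2_ratio <- with_seed(config$seed + 400L,
                                 stats::rnorm(n_tiles, 0, 0.25))
  # peak tiles must stay a small fraction of the array: the calling
  # cutoff is tied to mean + 6 sd of ALL tiles, which the peaks
  # themselves inflate when they cover more than ~5% of tiles
  for (g in chip_genes) {
    p <- gA$planted[gA$planted$gene == g, ]
    centre <- (p$start + p$end) %/% 2L
    i0 <- centre %/% config$tile_bp
    idx <- pmax(1L, pmin(n_tiles, (i0 - 2L):(i0 + 2L)))
    signal$log2_ratio[idx] <- with_seed(
      config$seed + 401L + p$start,
      stats::rnorm(length(idx), 3, 0.2))
  }

  # expression calls: planted genes are expressed except two designated
  # ChIP-positive ones (the binding-without-expression, peak-only class);
  # background genes are expressed rarely.  Keeping unexpressed+unpeaked
  # ("neither") genes free of planted sites makes the neither-category
  # site fraction a genuine false-discovery estimate.
  genes <- unique(gA$annotation$gene[gA$annotation$operon_head &
                                       !is.na(gA$annotation$gene)])
  chip_pl <- gA$planted$gene[gA$planted$chip_positive]
  peak_only <- utils::head(chip_pl, 2L)
  expressed <- with_seed(config$seed + 500L, {
    pl <- genes %in% gA$planted$gene
    ifelse(pl, !(genes %in% peak_only),
           stats::runif(length(genes)) < 0.05)
  })
  expression <- data.frame(gene = genes, expressed = expressed)

  ortho <- data.frame(speciesA = gA$genes, speciesB = gB$genes)

  list(genome = gA$genome, annotation = gA$annotation,
       planted = gA$planted, signal = signal, expression = expression,
       ortholog_table = ortho, genome_b = gB$genome,
       annotation_b = gB$annotation, planted_b = gB$planted)
}

# lay out n_genes genes separated by background intergenic gaps on one
# chromosome and plant one site (from a randomly chosen child submotif of
# the allowed families) into the first n_planted_genes promoters, at an
# offset drawn from the family's distance class; ~half the planted
# promoters are additionally flagged ChIP-positive
plant_genome <- function(config, mot, families, seed, gene_prefix = "a") {
  L <- config$site_length
  child_ids <- names(mot$family_of)
  allowed <- child_ids[mot$family_of %in% families]
  gap <- 180L
  n_genes <- min(config$n_genes,
                 config$genome_length %/% (config$gene_length + gap) - 1L)
  if (config$n_planted_genes > n_genes - 1L)
    stop("inconsistent config: more planted genes than genome capacity")
  with_seed(seed, {
    genome <- strsplit(sample_background(1, config$genome_length,
                                         config$gc_content,
                                         config$background_order,
                                         seed = seed + 1L), "")[[1]]
    genes <- sprintf("%s_gene_%02d", gene_prefix, seq_len(n_genes))
    starts <- gap + (seq_len(n_genes) - 1L) * (config$gene_length + gap)
    ann <- data.frame(region_id = paste0("coding_", seq_len(n_genes)),
                      chrom = "chr1", start = starts,
                      end = starts + config$gene_length, strand = "+",
                      kind = "coding", gene = genes, operon_head = TRUE,
                      tss = starts, excluded = FALSE)
    inter <- data.frame(region_id = paste0("intergenic_", seq_len(n_genes - 1L)),
                        chrom = "chr1",
                        start = ann$end[-n_genes], end = ann$start[-1L],
                        strand = "+", kind = "intergenic",
                        gene = genes[-1L], operon_head = TRUE,
                        tss = ann$tss[-1L], excluded = FALSE)
    inter$excluded <- (inter$end - inter$start) < 21L
    # plant into promoters of genes 2..(n_planted+1)
    planted <- NULL
    fam_apex <- setNames(rep_len(config$distance_apexes,
                                 length(unique(mot$family_of))),
                         unique(mot$family_of))
    for (k in seq_len(config$n_planted_genes)) {
      gi <- 1L + k  # downstream gene index
      sid <- sample(allowed, 1)
      fam <- mot$family_of[[sid]]
      apx <- fam_apex[[fam]]
      off <- max(-gap + L + 1L,
                 min(-L - 1L, sample_triangular(1, apx - 6, apx, apx + 6)))
      tss <- ann$tss[gi]
      s0 <- tss + off - L  # 0-based start: proximal edge at tss + off
      # planted sites are functional binders: resample until the site
      # scores at least planted_site_min_score under its own submotif
      # (genomic sites are under selection to bind; the sampling tail of
      # a PWM is not a site)
      site <- NULL
      for (try in 1:100) {
        cand <- sample_sites(mot$pwms[[sid]], 1,
                             seed = seed + 7L * k + 100000L * try)
        if (score_sequence(mot$pwms[[sid]], cand$sites$sequence) >=
            config$planted_site_min_score) { site <- cand; break }
      }
      if (is.null(site)) site <- cand
      genome[(s0 + 1L):(s0 + L)] <- strsplit(site$sites$sequence, "")[[1]]
      planted <- rbind(planted, data.frame(
        gene = genes[gi], submotif = sid, family = fam, start = s0,
        end = s0 + L, tss_offset = off,
        chip_positive = k %% 3L == 1L))
    }
    annotation <- rbind(ann, inter)
    class(annotation) <- c("genome_annotation", "data.frame")
    list(genome = c(chr1 = paste(genome, collapse = "")),
         annotation = annotation, planted = planted, genes = genes)
  })
}

#' Write the synthetic fixture to a directory of standard-format files
#'
#' FASTA for genome and sites, TSV for site tables / signal / expression /
#' orthologs, GFF3 for annotation, JSON manifest of ground truth.
#'
#' @param ds a [make_dataset()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_sites(ds$positives, file.path(dir, "positives.tsv"))
  write_sites(ds$negatives, file.path(dir, "negatives.tsv"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(ds$genome),
                              file.path(dir, "genome.fa"))
  ann <- ds$annotation[ds$annotation$kind == "coding", ]
  gr <- GenomicRanges::GRanges(ann$chrom,
                               IRanges::IRanges(ann$start + 1L, ann$end),
                               strand = ann$strand, type = "gene",
                               gene = ann$gene,
                               operon_head = ann$operon_head)
  rtracklayer::export(gr, file.path(dir, "genes.gff3"), format = "gff3")
  utils::write.table(ds$signal, file.path(dir, "signal.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ds$expression, file.path(dir, "expression.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ds$ortholog_table, file.path(dir, "orthologs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(planted = ds$planted,
                            truth_labels = ds$truth_labels,
                            seed = ds$config$seed),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(dir)
}
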