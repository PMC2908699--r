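#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  All stochastic entry points funnel through this
# so that same seed => identical output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Construct a collection of equal-length binding sites
#'
#' A `site_collection` is the unit of clustering and training: an ordered
#' table of aligned, equal-length DNA binding sites with optional promoter
#' metadata (gene, genome/species label, signed offset of the site relative
#' to the transcription start site, and strand).
#'
#' @param sequence character vector of DNA sequences over A/C/G/T, all of
#'   the same length.
#' @param site_id unique identifiers (default `site_1..n`).
#' @param gene,genome optional per-site labels.
#' @param tss_offset optional signed integer offsets (bp) of each site
#'   relative to the transcription start site of its gene.
#' @param strand optional `"+"`/`"-"` orientation relative to the gene.
#' @param tss_window allowed range for `tss_offset` (bp); offsets outside
#'   it are rejected.
#' @param ambiguity `"reject"` (default) errors on non-ACGT characters;
#'   `"skip"` silently drops offending sites.
#' @return An object of class `site_collection` with elements `sites`
#'   (data.frame) and `length` (common site length L).
#' @export
site_collection <- function(sequence, site_id = NULL, gene = NA_character_,
                            genome = NA_character_, tss_offset = NA_integer_,
                            strand = NA_character_,
                            tss_window = c(-500L, 500L),
                            ambiguity = c("reject", "skip")) {
  ambiguity <- match.arg(ambiguity)
  sequence <- toupper(as.character(sequence))
  n <- length(sequence)
  if (n == 0L) stop("empty site collection")
  if (is.null(site_id)) site_id <- paste0("site_", seq_len(n))
  bad <- grepl("[^ACGT]", sequence)
  df <- data.frame(site_id = as.character(site_id),
                   gene = rep_len(as.character(gene), n),
                   genome = rep_len(as.character(genome), n),
                   sequence = sequence,
                   tss_offset = rep_len(as.integer(tss_offset), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  if (any(bad)) {
    if (ambiguity == "reject")
      stop("alphabet error: non-ACGT characters in site(s) ",
           paste(df$site_id[bad], collapse = ", "))
    df <- df[!bad, , drop = FALSE]
    if (nrow(df) == 0L) stop("all sites dropped by ambiguity policy")
  }
  L <- unique(nchar(df$sequence))
  if (length(L) != 1L)
    stop("length-mismatch error: sites have lengths ",
         paste(sort(L), collapse = ", "))
  if (anyDuplicated(df$site_id))
    stop("duplicate site_id: ",
         paste(unique(df$site_id[duplicated(df$site_id)]), collapse = ", "))
  off <- df$tss_offset
  out_of_win <- !is.na(off) & (off < tss_window[1] | off > tss_window[2])
  if (any(out_of_win))
    stop("tss_offset outside window for site(s) ",
         paste(df$site_id[out_of_win], collapse = ", "))
  rownames(df) <- NULL
  structure(list(sites = df, length = as.integer(L)),
            class = "site_collection")
}

#' @export
print.site_collection <- function(x, ...) {
  cat(sprintf("site_collection: %d sites of length %d bp\n",
              nrow(x$sites), x$length))
  invisible(x)
}

#' @export
length.site_collection <- function(x) nrow(x$sites)

#' Subset a site collection
#'
#' @param x a `site_collection`.
#' @param i index vector (logical, integer, or site_id character).
#' @param ... ignored.
#' @export
`[.site_collection` <- function(x, i, ...) {
  if (is.character(i)) i <- match(i, x$sites$site_id)
  df <- x$sites[i, , drop = FALSE]
  rownames(df) <- NULL
  structure(list(sites = df, length = x$length), class = "site_collection")
}

#' Read binding sites from FASTA or a TSV site table
#'
#' TSV dialect: tab-separated columns `site_id, gene, genome, sequence,
#' tss_offset, strand` (header required, `#` comments allowed); FASTA
#' records use the header as `site_id`.
#'
#' @param path file path; format inferred from extension unless `format`
#'   is given.
#' @param format `"auto"`, `"fasta"` or `"tsv"`.
#' @param length_policy `"strict"` (error on ragged lengths) or `"trim"`
#'   (trim all sites to the shortest length).
#' @param ... passed to [site_collection()] (e.g. `ambiguity`).
#' @return a [site_collection()].
#' @export
read_sites <- function(path, format = c("auto", "fasta", "tsv"),
                       length_policy = c("strict", "trim"), ...) {
  format <- match.arg(format)
  length_policy <- match.arg(length_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    seqs <- as.character(ss)
    ids <- sub("\\s.*$", "", names(ss))
    gene <- NA_character_; genome <- NA_character_
    tss <- NA_integer_; strand <- NA_character_
  } else {
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (!"sequence" %in% names(df)) stop("TSV site table needs a 'sequence' column")
    seqs <- df$sequence
    ids <- if ("site_id" %in% names(df)) df$site_id else NULL
    gene <- if ("gene" %in% names(df)) df$gene else NA_character_
    genome <- if ("genome" %in% names(df)) df$genome else NA_character_
    tss <- if ("tss_offset" %in% names(df)) df$tss_offset else NA_integer_
    strand <- if ("strand" %in% names(df)) df$strand else NA_character_
  }
  if (length_policy == "trim") {
    L <- min(nchar(seqs))
    seqs <- substr(seqs, 1L, L)
  }
  site_collection(seqs, site_id = ids, gene = gene, genome = genome,
                  tss_offset = tss, strand = strand, ...)
}

#' Write a site collection as a TSV site table
#'
#' @param collection a [site_collection()].
#' @param path output path.
#' @export
write_sites <- function(collection, path) {
  utils::write.table(collection$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' One-hot (dummy-variable) encoding of a site collection
#'
#' Each site of length L becomes a binary row of 4L indicator features,
#' one block of four per position.  Euclidean distance between two rows is
#' `sqrt(2 * Hamming distance)` of the underlying sequences, which is the
#' metric all clustering in this package operates on.
#'
#' @param collection a [site_collection()].
#' @return numeric matrix with `length(collection)` rows and `4 * L`
#'   columns named `p<position>_<base>`; rownames are site_ids.
#' @export
one_hot_encode <- function(collection) {
  stopifnot(inherits(collection, "site_collection"))
  n <- nrow(collection$sites)
  if (n == 0L) stop("empty-input error: no sites to encode")
  L <- collection$length
  chars <- matrix(unlist(strsplit(collection$sites$sequence, "")),
                  nrow = n, byrow = TRUE)
  X <- matrix(0, nrow = n, ncol = 4L * L)
  for (p in seq_len(L)) {
    idx <- match(chars[, p], DNA_BASES)
    X[cbind(seq_len(n), (p - 1L) * 4L + idx)] <- 1
  }
  colnames(X) <- paste0("p", rep(seq_len(L), each = 4L), "_",
                        rep(DNA_BASES, L))
  rownames(X) <- collection$sites$site_id
  X
}

#' Read gene annotation and derive intergenic regions
#'
#' Accepts GFF3 or BED.  Coordinates are converted to 0-based half-open
#' internally.  When only gene features are present, intergenic regions are
#' computed as the gaps between consecutive genes on each chromosome; gaps
#' shorter than `min_intergenic` are kept but flagged `excluded` (too short
#' to harbor a site per the >20 bp intergenic filter).
#'
#' @param path GFF3 (`.gff`, `.gff3`) or BED file.
#' @param min_intergenic minimum intergenic length in bp (default 21, i.e.
#'   regions of more than 20 bp are eligible).
#' @return a `genome_annotation`: data.frame with columns `region_id,
#'   chrom, start, end, strand, kind, gene, operon_head, tss, excluded`.
#' @export
read_annotation <- function(path, min_intergenic = 21L) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path)
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,  # to 0-based
                   end = GenomicRanges::end(gr),
                   strand = as.character(GenomicRanges::strand(gr)),
                   stringsAsFactors = FALSE)
  md <- as.data.frame(S4Vectors::mcols(gr))
  getcol <- function(nm, default) if (nm %in% names(md)) as.character(md[[nm]]) else default
  gene <- getcol("gene", getcol("Name", getcol("ID", getcol("name", NA_character_))))
  kind <- getcol("type", "gene")
  kind <- ifelse(kind %in% c("gene", "CDS", "coding"), "coding", kind)
  oh <- if ("operon_head" %in% names(md)) as.logical(md$operon_head) else TRUE
  df$kind <- kind
  df$gene <- gene
  df$operon_head <- oh
  df$strand[!df$strand %in% c("+", "-")] <- "+"
  df$tss <- ifelse(df$strand == "-", df$end, df$start)
  bad <- df$start >= df$end
  if (any(bad))
    stop("validation error: malformed records (start >= end): ",
         paste(which(bad), collapse = ", "))
  ann <- df[df$kind == "coding", , drop = FALSE]
  ann <- ann[order(ann$chrom, ann$start), ]
  inter <- do.call(rbind, lapply(split(ann, ann$chrom), function(g) {
    if (nrow(g) < 2L) return(NULL)
    s <- g$end[-nrow(g)]
    e <- g$start[-1L]
    keep <- e > s
    if (!any(keep)) return(NULL)
    data.frame(chrom = g$chrom[1L], start = s[keep], end = e[keep],
               strand = "+", kind = "intergenic",
               gene = g$gene[-1L][keep],  # attribute to downstream gene
               operon_head = g$operon_head[-1L][keep],
               tss = g$tss[-1L][keep],
               stringsAsFactors = FALSE)
  }))
  out <- rbind(ann, inter)
  out$excluded <- out$kind == "intergenic" & (out$end - out$start) < min_intergenic
  out$region_id <- paste0(out$kind, "_", seq_len(nrow(out)))
  rownames(out) <- NULL
  out <- out[, c("region_id", "chrom", "start", "end", "strand", "kind",
                 "gene", "operon_head", "tss", "excluded")]
  class(out) <- c("genome_annotation", "data.frame")
  out
}

#' Write a position weight matrix to file
#'
#' @param pwm a [build_pwm()] result.
#' @param path output path.
#' @param format `"meme-minimal"` (MEME minimal motif format) or `"tsv"`
#'   (positions in rows, bases in columns).
#' @export
write_pwm <- function(pwm, path, format = c("meme-minimal", "tsv")) {
  format <- match.arg(format)
  stopifnot(inherits(pwm, "pwm_model"))
  f <- pwm$freqs
  if (format == "tsv") {
    df <- as.data.frame(t(f))
    df <- cbind(position = seq_len(ncol(f)), df)
    utils::write.table(format(df, digits = 10), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
                 "strands: + -", "",
                 sprintf("Background letter frequencies"),
                 paste(sprintf("%s %.6f", DNA_BASES, pwm$background),
                       collapse = " "), "",
                 sprintf("MOTIF %s", pwm$name),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                         ncol(f), pwm$nsites %||% 20L)), con)
    writeLines(apply(f, 2, function(col)
      paste(sprintf("%.6f", col), collapse = "  ")), con)
  }
  invisible(path)
}

#' Read a position weight matrix written by [write_pwm()]
#'
#' @param path input path.
#' @param format `"meme-minimal"` or `"tsv"`.
#' @return a `pwm_model`.
#' @export
read_pwm <- function(path, format = c("meme-minimal", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path)
    f <- t(as.matrix(df[, DNA_BASES]))
    rownames(f) <- DNA_BASES
    return(new_pwm(f / rep(colSums(f), each = 4L), name = "pwm"))
  }
  lines <- readLines(path)
  bg <- rep(0.25, 4)
  bgi <- grep("^A [0-9.]+ C", lines)
  if (length(bgi)) {
    tok <- strsplit(lines[bgi[1]], "\\s+")[[1]]
    bg <- as.numeric(tok[c(2, 4, 6, 8)])
  }
  mi <- grep("^MOTIF ", lines)[1]
  name <- strsplit(lines[mi], "\\s+")[[1]][2]
  hi <- grep("^letter-probability matrix", lines)[1]
  w <- as.integer(sub(".*w= *(\\d+).*", "\\1", lines[hi]))
  rows <- lines[(hi + 1L):(hi + w)]
  f <- t(vapply(strsplit(trimws(rows), "\\s+"),
                function(x) as.numeric(x), numeric(4)))
  f <- t(f)  # 4 x L
  rownames(f) <- DNA_BASES
  f <- sweep(f, 2, colSums(f), "/")  # absorb 1e-6 print rounding
  new_pwm(f, background = bg, name = name)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

revcomp <- function(seq) {
  chartr("ACGT", "TGCA",
         vapply(seq, function(s) paste(rev(strsplit(s, "")[[1]]), collapse = ""),
                character(1), USE.NAMES = FALSE))
}
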