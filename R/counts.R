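NC_BIOTYPES <- c("ncRNA", "lincRNA", "snoRNA")

# Exon GRanges (one range per exon, gene_id in mcols) for interval queries.
annotation_exon_granges <- function(annotation) {
  exons <- attr(annotation, "exons")
  strand <- annotation$strand[match(exons$gene_id, annotation$gene_id)]
  chrom <- annotation$chromosome[match(exons$gene_id, annotation$gene_id)]
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(exons$start, exons$end),
                               strand = strand)
  S4Vectors::mcols(gr)$gene_id <- exons$gene_id
  gr
}

reads_granges <- function(reads) {
  GenomicRanges::GRanges(reads$chromosome,
                         IRanges::IRanges(reads$start, reads$end),
                         strand = reads$strand)
}

#' Assign reads to genes by exon overlap
#'
#' A read is assigned to a gene if and only if it overlaps an exon of that
#' gene on the same strand (>= 1 shared base). In `counting` mode a read
#' overlapping exons of two or more genes is `ambiguous` (discarded from
#' per-gene counts) and a read with no exon overlap is `unassigned`. In
#' `peak_assignment` mode, if the overlapped genes include exactly one
#' gene of non-coding biotype, the read/peak goes to that ncRNA (ncRNA
#' priority); otherwise the counting rule applies.
#'
#' @param reads data frame with `chromosome`, `strand`, `start`, `end`.
#' @param annotation a `gene_annotation`.
#' @param mode `"counting"` or `"peak_assignment"`.
#' @return character vector (per read): a gene_id, `"ambiguous"`, or
#'   `"unassigned"`.
#' @export
assign_read_to_gene <- function(reads, annotation,
                                mode = c("counting", "peak_assignment")) {
  mode <- match.arg(mode)
  if (nrow(reads) == 0) return(character(0))
  ex <- annotation_exon_granges(annotation)
  hits <- GenomicRanges::findOverlaps(reads_granges(reads), ex,
                                      ignore.strand = FALSE)
  gene <- S4Vectors::mcols(ex)$gene_id[S4Vectors::subjectHits(hits)]
  per_read <- split(gene, factor(S4Vectors::queryHits(hits),
                                 levels = seq_len(nrow(reads))))
  biotype <- setNames(annotation$biotype, annotation$gene_id)
  vapply(per_read, function(gs) {
    gs <- unique(gs)
    if (length(gs) == 0) return("unassigned")
    if (length(gs) == 1) return(gs)
    if (mode == "peak_assignment") {
      nc <- gs[biotype[gs] %in% NC_BIOTYPES]
      if (length(nc) == 1) return(nc)
    }
    "ambiguous"
  }, character(1), USE.NAMES = FALSE)
}

#' Build a genes-by-samples counts matrix
#'
#' Counts, per sample, the deduplicated reads assigned to each gene in
#' counting mode. The library size of a sample is its total number of
#' assigned reads.
#'
#' @param read_sets named list of read data frames (one per sample).
#' @param annotation a `gene_annotation`.
#' @return list of class `counts_matrix`: `counts` (integer matrix, genes x
#'   samples), `library_size` (named numeric), and an `assignment` table of
#'   per-sample assigned/ambiguous/unassigned totals.
#' @export
build_counts_matrix <- function(read_sets, annotation) {
  if (nrow(annotation) == 0) stopf("empty annotation")
  genes <- annotation$gene_id
  counts <- matrix(0L, length(genes), length(read_sets),
                   dimnames = list(genes, names(read_sets)))
  assignment <- matrix(0L, 3, length(read_sets),
                       dimnames = list(c("assigned", "ambiguous", "unassigned"),
                                       names(read_sets)))
  for (s in seq_along(read_sets)) {
    a <- assign_read_to_gene(read_sets[[s]], annotation, mode = "counting")
    tab <- table(factor(a, levels = c(genes, "ambiguous", "unassigned")))
    counts[, s] <- as.integer(tab[genes])
    assignment[, s] <- c(sum(tab[genes]), tab[["ambiguous"]], tab[["unassigned"]])
  }
  structure(list(counts = counts,
                 library_size = setNames(as.numeric(assignment["assigned", ]),
                                         colnames(counts)),
                 assignment = assignment),
            class = "counts_matrix")
}

#' Construct a counts_matrix from a plain matrix
#'
#' @param counts integer matrix (genes x samples) with dimnames.
#' @param library_size per-sample totals; defaults to column sums.
#' @return a `counts_matrix`.
#' @export
as_counts_matrix <- function(counts, library_size = colSums(counts)) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (any(counts < 0)) stopf("counts must be non-negative")
  structure(list(counts = counts,
                 library_size = setNames(as.numeric(library_size),
                                         colnames(counts))),
            class = "counts_matrix")
}

#' Reads-per-million normalization
#'
#' @param x a `counts_matrix`.
#' @return numeric matrix: `count * 1e6 / library_size` per column.
#' @export
normalize_rpm <- function(x) {
  zero <- x$library_size == 0
  if (any(zero))
    stopf("zero library size for sample(s): %s",
          paste(names(x$library_size)[zero], collapse = ", "))
  sweep(x$counts, 2, x$library_size, function(k, n) k * 1e6 / n)
}

#' Combine paired replicates of two counts matrices
#'
#' Sums paired columns (and their library sizes), mirroring how FBF-1 and
#' FBF-2 iCLIP replicates are concatenated into combined "FBF" replicates.
#' The canonical pairings for the 25-degree oogenic and spermatogenic
#' replicate sets are available as `pairing = "oogenic"` ((1,3),(2,2),(3,1))
#' and `pairing = "spermatogenic"` ((2,1),(1,2),(3,3)).
#'
#' @param a,b `counts_matrix` objects over the same gene universe.
#' @param pairing either a two-column matrix/list of (replicate_a,
#'   replicate_b) index pairs, or one of `"oogenic"`, `"spermatogenic"`.
#' @param prefix column-name prefix for the combined replicates.
#' @return a `counts_matrix` with one column per pair.
#' @export
combine_replicates <- function(a, b, pairing, prefix = "FBF_rep") {
  if (is.character(pairing))
    pairing <- switch(match.arg(pairing, c("oogenic", "spermatogenic")),
                      oogenic = cbind(1:3, c(3, 2, 1)),
                      spermatogenic = cbind(c(2, 1, 3), c(1, 2, 3)))
  if (is.list(pairing)) pairing <- do.call(rbind, pairing)
  if (!identical(rownames(a$counts), rownames(b$counts)))
    stopf("mismatched gene sets")
  if (anyDuplicated(pairing[, 1]) || anyDuplicated(pairing[, 2]))
    stopf("pairing must be a bijection between replicate indices")
  counts <- vapply(seq_len(nrow(pairing)), function(i)
    a$counts[, pairing[i, 1]] + b$counts[, pairing[i, 2]],
    numeric(nrow(a$counts)))
  counts <- matrix(counts, nrow = nrow(a$counts))
  colnames(counts) <- paste0(prefix, seq_len(nrow(pairing)))
  rownames(counts) <- rownames(a$counts)
  lib <- a$library_size[pairing[, 1]] + b$library_size[pairing[, 2]]
  as_counts_matrix(counts, setNames(lib, colnames(counts)))
}

#' Replicate correlation report
#'
#' Spearman rank correlations of reads-per-gene between every pair of
#' samples, pooled into within-gender and between-gender sets and compared
#' by a classic two-sample two-tailed t-test (pooled variance). Pairs
#' involving a constant (zero-variance) sample are reported as missing.
#'
#' @param x a `counts_matrix`.
#' @param gender character vector per sample (e.g. `"sperm"`/`"oocyte"`).
#' @return list of class `correlation_report`: `rho` (symmetric matrix with
#'   unit diagonal), group means, the pooled within/between rho vectors and
#'   the t-test (`statistic`, `p_value`).
#' @export
correlation_report <- function(x, gender) {
  stopifnot(length(gender) == ncol(x$counts))
  if (min(table(gender)) < 2) stopf("need >= 2 samples per gender")
  sds <- apply(x$counts, 2, stats::sd)
  rho <- suppressWarnings(stats::cor(x$counts, method = "spearman"))
  rho[sds == 0, ] <- NA; rho[, sds == 0] <- NA
  diag(rho) <- 1
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  vals <- rho[ut]
  within <- gender[ut[, 1]] == gender[ut[, 2]]
  wv <- vals[within & !is.na(vals)]
  bv <- vals[!within & !is.na(vals)]
  tt <- tryCatch(stats::t.test(wv, bv, var.equal = TRUE),
                 error = function(e)
                   list(statistic = NA_real_, p.value = NA_real_))
  genders <- unique(gender)
  within_means <- vapply(genders, function(g) {
    sel <- within & gender[ut[, 1]] == g
    mean(vals[sel], na.rm = TRUE)
  }, numeric(1))
  structure(list(rho = rho,
                 mean_within = setNames(within_means, genders),
                 mean_between = mean(bv),
                 within_values = wv, between_values = bv,
                 statistic = unname(tt$statistic),
                 p_value = tt$p.value),
            class = "correlation_report")
}
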