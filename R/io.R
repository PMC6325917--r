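# File-format boundaries. Sequence and annotation I/O go through
# Biostrings / rtracklayer; alignments are written as plain SAM text (UMI
# carried in the read name after the final underscore) and tables as TSV.

#' Write the synthetic genome as FASTA
#' @param genome named list of chromosome sequences (character strings).
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  x <- Biostrings::DNAStringSet(unlist(genome))
  names(x) <- names(genome)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a genome FASTA into the internal representation
#' @param path FASTA file.
#' @return named list of chromosome sequence strings.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.list(as.character(x)), names(x))
}

#' Write a gene annotation as GFF3
#'
#' Emits gene / mRNA (or the non-coding biotype) / exon /
#' three_prime_UTR features with `biotype=` attributes.
#' @param annotation a `gene_annotation`.
#' @param path output file.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stopf("rtracklayer is required for GFF3 export")
  exons <- attr(annotation, "exons")
  feats <- list()
  for (i in seq_len(nrow(annotation))) {
    g <- annotation[i, ]
    feats[[length(feats) + 1L]] <- data.frame(
      chromosome = g$chromosome, start = g$start, end = g$end,
      strand = g$strand, type = "gene", ID = g$gene_id, Parent = NA,
      biotype = g$biotype, stringsAsFactors = FALSE)
    ex <- exons[exons$gene_id == g$gene_id, , drop = FALSE]
    feats[[length(feats) + 1L]] <- data.frame(
      chromosome = g$chromosome, start = ex$start, end = ex$end,
      strand = g$strand, type = "exon",
      ID = sprintf("%s.e%d", g$gene_id, seq_len(nrow(ex))),
      Parent = g$gene_id, biotype = g$biotype, stringsAsFactors = FALSE)
    if (!is.na(g$utr3_start))
      feats[[length(feats) + 1L]] <- data.frame(
        chromosome = g$chromosome, start = g$utr3_start, end = g$utr3_end,
        strand = g$strand, type = "three_prime_UTR",
        ID = paste0(g$gene_id, ".utr3"), Parent = g$gene_id,
        biotype = g$biotype, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(df$chromosome,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- df$Parent
  S4Vectors::mcols(gr)$biotype <- df$biotype
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write aligned reads as SAM
#'
#' Single-end alignments; FLAG 0/16 encodes strand, CIGAR is full-length
#' match, SEQ/QUAL are `*` unless `genome` is supplied. The UMI stays in
#' the read name after the final underscore.
#' @param reads read data frame (`name`, `chromosome`, `strand`, `start`,
#'   `end`, `umi`).
#' @param seqlengths named chromosome lengths for the header.
#' @param path output file.
#' @param genome optional genome list to emit real SEQ fields.
#' @export
write_sam <- function(reads, seqlengths, path, genome = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                     as.integer(seqlengths)), con)
  if (nrow(reads)) {
    seqf <- if (is.null(genome)) "*" else
      vapply(seq_len(nrow(reads)), function(i)
        fetch_seq(genome, reads$chromosome[i], "+", reads$start[i],
                  reads$end[i]), character(1))
    name <- if (grepl("_[ACGTN]+$", reads$name[1])) reads$name else
      paste0(reads$name, "_", reads$umi)
    writeLines(sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*",
                       name, ifelse(reads$strand == "-", 16L, 0L),
                       reads$chromosome, reads$start,
                       reads$end - reads$start + 1L, seqf), con)
  }
  invisible(path)
}

#' Read a SAM file of single-end alignments
#' @param path SAM file.
#' @return read data frame with the UMI parsed from the read name.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(name = character(), chromosome = character(),
                      strand = character(), start = integer(),
                      end = integer(), umi = character(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  name <- vapply(f, `[[`, character(1), 1)
  flag <- as.integer(vapply(f, `[[`, character(1), 2))
  cigar <- vapply(f, `[[`, character(1), 6)
  len <- as.integer(sub("M$", "", cigar))
  start <- as.integer(vapply(f, `[[`, character(1), 4))
  data.frame(name = name,
             chromosome = vapply(f, `[[`, character(1), 3),
             strand = ifelse(bitwAnd(flag, 16L) > 0, "-", "+"),
             start = start, end = start + len - 1L,
             umi = sub(".*_", "", name), stringsAsFactors = FALSE)
}

#' Write raw reads as FASTQ
#' @param fastq data frame with `name`, `seq` (e.g. [reads_to_fastq()]).
#' @param path output file.
#' @export
write_fastq <- function(fastq, path) {
  x <- Biostrings::DNAStringSet(fastq$seq)
  names(x) <- fastq$name
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(strrep("I", nchar(fastq$seq))))
  invisible(path)
}

#' Read a FASTQ file
#' @param path FASTQ file.
#' @return data frame with `name`, `seq`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(name = names(x), seq = as.character(x),
             stringsAsFactors = FALSE)
}

#' Write a counts matrix (genes x samples) as TSV
#' @param x a `counts_matrix` or plain matrix.
#' @param path output file.
#' @export
write_counts_tsv <- function(x, path) {
  m <- if (inherits(x, "counts_matrix")) x$counts else x
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write any data frame as TSV
#' @param df data frame.
#' @param path output file.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called peaks as BED6+ plus statistics columns
#'
#' chrom, window start/end (0-based half-open, as BED requires), gene id
#' as name, per-million height as score, strand, then raw/control/p
#' columns and the FBE annotations.
#' @param peaks an `fbf_peaks` table.
#' @param path output file.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(chrom = peaks$chromosome,
                   start = peaks$window_start - 1L,
                   end = peaks$window_end,
                   name = peaks$gene_id,
                   score = peaks$height_rpm,
                   strand = peaks$strand,
                   summit = peaks$summit,
                   height_raw = peaks$height_raw,
                   control_raw = peaks$control_raw,
                   control_rpm = peaks$control_rpm,
                   p_value = peaks$p_value,
                   p_adjusted = peaks$p_adjusted,
                   n_fbe = peaks$n_fbe,
                   n_fbe_summit = peaks$n_fbe_summit,
                   rank = peaks$rank, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a dendrogram in Newick format
#' @param hc an `hclust` object.
#' @param path output file.
#' @export
write_dendrogram_newick <- function(hc, path) {
  nwk <- hclust_to_newick(hc)
  writeLines(nwk, path)
  invisible(path)
}

hclust_to_newick <- function(hc) {
  lab <- hc$labels %||% as.character(seq_len(nrow(hc$merge) + 1L))
  rec <- function(i) {
    m <- hc$merge[i, ]
    part <- vapply(m, function(j)
      if (j < 0) lab[-j] else rec(j), character(1))
    sprintf("(%s,%s):%g", part[1], part[2], hc$height[i])
  }
  paste0(rec(nrow(hc$merge)), ";")
}
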