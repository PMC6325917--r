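# Shared fixtures built in code. The mini experiment is generated once per
# test run and reused across files.

.fixture_cache <- new.env(parent = emptyenv())

mini_config <- function(...) {
  synthetic_config(n_genes = 120, library_size = 24000, seed = 42, ...)
}

mini_experiment <- function() {
  if (is.null(.fixture_cache$mini))
    .fixture_cache$mini <- simulate_experiment(mini_config())
  .fixture_cache$mini
}

# Hand-built annotation object matching the package's internal structure.
make_annotation <- function(genes, exons, seqlengths) {
  genes$utr3_start <- genes$utr3_start %||% NA_integer_
  genes$utr3_end <- genes$utr3_end %||% NA_integer_
  genes$program <- genes$program %||% "both"
  structure(genes, exons = exons, seqlengths = seqlengths,
            class = c("gene_annotation", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_reads <- function(chromosome, strand, start, end = start + 34L,
                       umi = NULL, name = NULL) {
  n <- max(length(chromosome), length(strand), length(start), length(end))
  data.frame(name = name %||% sprintf("r%03d_%s", seq_len(n),
                                      umi %||% strrep("A", 5)),
             chromosome = rep_len(chromosome, n),
             strand = rep_len(strand, n),
             start = rep_len(as.integer(start), n),
             end = rep_len(as.integer(end), n),
             umi = rep_len(umi %||% strrep("A", 5), n),
             stringsAsFactors = FALSE)
}

# Two-gene annotation (one mRNA with an intron, one ncRNA overlapping the
# mRNA's second exon) used across assignment tests.
two_gene_annotation <- function() {
  genes <- data.frame(
    gene_id = c("mrna1", "nc1"),
    biotype = c("mRNA", "ncRNA"),
    chromosome = "chr1", strand = "+",
    start = c(1000L, 2100L), end = c(2500L, 2600L),
    utr3_start = c(2300L, NA), utr3_end = c(2500L, NA),
    program = c("both", "none"), stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = c("mrna1", "mrna1", "nc1"),
    start = c(1000L, 2000L, 2100L),
    end = c(1500L, 2500L, 2600L))
  make_annotation(genes, exons, c(chr1 = 5000L))
}
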