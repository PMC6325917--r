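test_that("config validation enforces the documented invariants", {
  expect_error(synthetic_config(block_proportions = c(0.5, 0.4, 0.2, 0.1)),
               "sum")
  expect_error(synthetic_config(umi_length = 2), "umi_length")
  expect_error(synthetic_config(n_genes = 100, library_size = 500),
               "library_size")
  expect_error(synthetic_config(frac_ncRNA = 1.5), "fractions")
  expect_error(synthetic_config(sperm_oocyte_fold = 0.5), "fold")
  expect_error(synthetic_config(utr_length_range = c(10, 20)), "UTR")
})

test_that("an empty configuration yields empty annotation and sequence", {
  cfg <- synthetic_config(n_genes = 0, library_size = 0)
  tx <- generate_transcriptome(cfg)
  expect_equal(nrow(tx$annotation), 0)
  expect_length(tx$genome, 0)
  expect_equal(nrow(tx$truth), 0)
})

test_that("seeded transcriptome generation is bit-reproducible", {
  cfg <- synthetic_config(n_genes = 100, library_size = 2000, seed = 7)
  a <- generate_transcriptome(cfg)
  b <- generate_transcriptome(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$annotation, b$annotation)
  expect_identical(a$truth, b$truth)
  rd1 <- simulate_iclip_reads(cfg, a, "sperm", "FBF", 1)
  rd2 <- simulate_iclip_reads(cfg, b, "sperm", "FBF", 1)
  expect_identical(as.data.frame(rd1), as.data.frame(rd2))
})

test_that("every planted site carries a canonical FBE and none-gene 3'UTRs carry none", {
  tx <- generate_transcriptome(mini_config())
  tgt <- tx$truth[tx$truth$block != "none", ]
  expect_true(nrow(tgt) > 10)
  found <- vapply(seq_len(nrow(tgt)), function(i) {
    g <- tgt[i, ]
    lo <- g$peak_genome_start - 4L
    s <- substr(tx$genome[[g$peak_chrom]], lo, lo + 15L)
    if (g$peak_strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    nrow(scan_fbe(s)) >= 1
  }, logical(1))
  expect_true(all(found))

  ann <- tx$annotation
  none_genes <- tx$truth$gene_id[tx$truth$block == "none"]
  nn <- ann[ann$gene_id %in% none_genes & !is.na(ann$utr3_start), ]
  n_fbe <- vapply(seq_len(nrow(nn)), function(i) {
    s <- substr(tx$genome[[nn$chromosome[i]]], nn$utr3_start[i], nn$utr3_end[i])
    if (nn$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    nrow(scan_fbe(s))
  }, numeric(1))
  expect_equal(sum(n_fbe), 0)
})

test_that("planted upstream cytosines land at -1 or -2 of the element", {
  tx <- generate_transcriptome(mini_config())
  tgt <- tx$truth[tx$truth$block != "none" &
                  (tx$truth$minus1C | tx$truth$minus2C), ]
  expect_true(nrow(tgt) > 0)
  ok <- vapply(seq_len(nrow(tgt)), function(i) {
    g <- tgt[i, ]
    lo <- g$peak_genome_start - 4L
    s <- substr(tx$genome[[g$peak_chrom]], lo, lo + 15L)
    if (g$peak_strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    m <- scan_fbe(s)
    # a planted upstream cytosine must be seen; the other position may
    # carry a C by chance, so test the implication only
    (!g$minus1C || any(m$minus1C)) && (!g$minus2C || any(m$minus2C))
  }, logical(1))
  expect_true(all(ok))
})

test_that("zero duplication rate means reads equal unique molecules", {
  cfg <- synthetic_config(n_genes = 50, library_size = 5000,
                          duplicate_rate = 0, seed = 11)
  tx <- generate_transcriptome(cfg)
  rd <- simulate_iclip_reads(cfg, tx, "oocyte", "FBF", 1)
  expect_equal(nrow(rd), sum(attr(rd, "molecule_counts")))
  expect_equal(nrow(rd), length(unique(rd$molecule)))
})

test_that("the planted gender fold is recovered by simulated molecule counts", {
  # one planted block-I gene bound 4x more in sperm; 200 replicate pairs
  cfg <- synthetic_config(n_genes = 10, frac_ncRNA = 0, library_size = 2000,
                          block_proportions = c(I = 0.1, II = 0, III = 0, IV = 0),
                          binding_rpm_range = c(20000, 80000),
                          binding_spread = 0, sperm_oocyte_fold = 4,
                          duplicate_rate = 0, seed = 13)
  tx <- generate_transcriptome(cfg)
  g <- tx$truth$gene_id[tx$truth$block == "I"]
  expect_length(g, 1)
  expect_equal(tx$truth$rpm_sperm[tx$truth$gene_id == g] /
               tx$truth$rpm_oocyte[tx$truth$gene_id == g], 4)
  tot <- c(sperm = 0, oocyte = 0)
  for (r in 1:200) {
    for (cond in c("sperm", "oocyte")) {
      rd <- simulate_iclip_reads(cfg, tx, cond, "FBF", r)
      tot[cond] <- tot[cond] + sum(rd$gene_true == g)
    }
  }
  expect_gt(tot["oocyte"], 500)  # enough events for a stable ratio
  expect_lt(abs(tot[["sperm"]] / tot[["oocyte"]] - 4), 0.4)
})

test_that("control coverage tracks abundance and ignores planted binding", {
  cfg <- synthetic_config(n_genes = 40, library_size = 4000,
                          duplicate_rate = 0, seed = 17)
  tx <- generate_transcriptome(cfg)
  blk <- tx$truth$gene_id[tx$truth$block != "none"][1]
  none <- tx$truth$gene_id[tx$truth$block == "none"][1]
  tx$truth$abundance_rpm[tx$truth$gene_id %in% c(blk, none)] <- 5e4
  tot <- c(0, 0)
  for (r in 1:100) {
    rd <- simulate_iclip_reads(cfg, tx, "sperm", "control", r)
    tot <- tot + c(sum(rd$gene_true == blk), sum(rd$gene_true == none))
  }
  # both genes share lambda = 50000 rpm * 4000 * 0.25 / 1e6 = 50 per rep
  expect_gt(min(tot), 3500)
  expect_lt(abs(tot[1] / tot[2] - 1), 0.15)
})

test_that("unique molecules per gene recover the planted RPM within sampling error", {
  cfg <- synthetic_config(n_genes = 100, library_size = 1e5,
                          duplicate_rate = 0, seed = 19)
  tx <- generate_transcriptome(cfg)
  rd <- simulate_iclip_reads(cfg, tx, "sperm", "FBF", 1)
  mc <- attr(rd, "molecule_counts")
  lambda <- tx$truth$rpm_sperm * cfg$library_size / 1e6
  names(lambda) <- tx$truth$gene_id
  obs <- as.numeric(mc[tx$truth$gene_id])
  obs[is.na(obs)] <- 0
  expect_lt(abs(sum(obs) / cfg$library_size - 1), 0.02)
  z <- (obs - lambda) / sqrt(pmax(lambda, 1))
  expect_true(all(abs(z) < 5.5))
})

test_that("raw-read rendering round-trips through demultiplexing", {
  cfg <- synthetic_config(n_genes = 30, library_size = 1000, seed = 23,
                          umi_length = 6)
  tx <- generate_transcriptome(cfg)
  rd <- simulate_iclip_reads(cfg, tx, "oocyte", "FBF", 1)
  layout <- read_layout(sample_barcode_length = 4, umi_length = 6,
                        three_prime_linker = "AGATCGGAAGAGC")
  fq <- reads_to_fastq(rd, tx$genome, layout, barcode = "ACGT")
  dm <- demultiplex_and_extract(fq, layout, c(ACGT = "s1"))
  expect_equal(nrow(dm$samples$s1), nrow(rd))
  expect_equal(nrow(dm$undetermined), 0)
  # UMI moved into the read name; insert equals the aligned read sequence
  expect_equal(sub(".*_", "", dm$samples$s1$name), rd$umi)
  expect_equal(unique(nchar(dm$samples$s1$seq)), cfg$read_length)
})
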