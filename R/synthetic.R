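#' Configuration for the synthetic iCLIP generator
#'
#' Bundles every knob of the ground-truth simulator. The defaults describe a
#' desk-scale germline iCLIP experiment: two germline genders (spermatogenic
#' and oogenic adults), three FBF replicates and three no-antibody control
#' replicates per gender, a long-tailed RNA abundance distribution, and a
#' planted four-block binding structure (block I spermatogenic-enriched,
#' blocks II/III gender-neutral with III bound at high frequency, block IV
#' oogenic-enriched) whose relative sizes mirror the 75:510:21:24 regime of
#' the real target network.
#'
#' @param n_genes number of genes to simulate.
#' @param frac_ncRNA fraction of genes given a non-coding biotype.
#' @param n_replicates_per_condition replicates per (gender, assay).
#' @param library_size expected reads per FBF replicate; must be at least
#'   `10 * n_genes`.
#' @param control_library_fraction expected size of a no-antibody control
#'   library relative to an FBF library (no-antibody iCLIP is low-yield;
#'   per-million normalization removes the scale downstream).
#' @param block_proportions named fractions of genes planted as blocks
#'   I--IV; the remainder are non-target ("none") genes. Must sum to <= 1.
#' @param binding_rpm_range low/high bounds (reads per million) for planted
#'   binding frequencies.
#' @param binding_spread within-block log-normal spread of binding
#'   frequencies, in log2 units (sd of the factor; default 0.75).
#' @param sperm_oocyte_fold planted fold-difference (>= 1) in binding
#'   frequency for the gender-specific blocks I and IV.
#' @param abundance_shape sdlog of the log-normal per-gene abundance
#'   distribution (long-tailed, as in real transcriptomes).
#' @param duplicate_rate PCR duplication intensity in `[0, 1)`: each
#'   molecule is re-emitted `Geom(1 - duplicate_rate)` extra times, so 0
#'   means reads equal unique molecules.
#' @param umi_length length (nt) of the random molecular tag; >= 3.
#' @param umi_error_rate per-nucleotide substitution rate applied when a
#'   duplicate re-emits its molecule's UMI.
#' @param read_length simulated read length (nt), single-end, sense strand.
#' @param frac_upstream_c fraction of planted FBEs that also receive an
#'   affinity-enhancing cytosine one or two positions upstream.
#' @param utr_length_range range (nt) of simulated 3'UTR lengths; must be
#'   long enough to host a planted binding element.
#' @param seed root seed; every stage derives its own sub-seed from it, so
#'   seeded runs are bit-reproducible.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 900L,
                             frac_ncRNA = 0.05,
                             n_replicates_per_condition = 3L,
                             library_size = 3e5,
                             control_library_fraction = 0.25,
                             block_proportions = c(I = 0.035, II = 0.24,
                                                   III = 0.010, IV = 0.012),
                             binding_rpm_range = c(25, 2000),
                             binding_spread = 0.75,
                             sperm_oocyte_fold = 4,
                             abundance_shape = 1.5,
                             duplicate_rate = 0.35,
                             umi_length = 9L,
                             umi_error_rate = 0.01,
                             read_length = 35L,
                             frac_upstream_c = 0.7,
                             utr_length_range = c(150L, 250L),
                             seed = 1L) {
  block_proportions <- unlist(block_proportions)
  binding_rpm_range <- unlist(binding_rpm_range)
  utr_length_range <- unlist(utr_length_range)
  cfg <- list(n_genes = as.integer(n_genes), frac_ncRNA = frac_ncRNA,
              n_replicates_per_condition = as.integer(n_replicates_per_condition),
              library_size = library_size,
              control_library_fraction = control_library_fraction,
              block_proportions = block_proportions,
              binding_rpm_range = binding_rpm_range,
              binding_spread = binding_spread,
              sperm_oocyte_fold = sperm_oocyte_fold,
              abundance_shape = abundance_shape,
              duplicate_rate = duplicate_rate,
              umi_length = as.integer(umi_length),
              umi_error_rate = umi_error_rate,
              read_length = as.integer(read_length),
              frac_upstream_c = frac_upstream_c,
              utr_length_range = as.integer(utr_length_range),
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_synthetic_config <- function(cfg) {
  frac <- c(cfg$frac_ncRNA, cfg$block_proportions, cfg$duplicate_rate,
            cfg$umi_error_rate, cfg$frac_upstream_c)
  if (any(frac < 0 | frac > 1)) stopf("all fractions must lie in [0, 1]")
  if (sum(cfg$block_proportions) > 1)
    stopf("block_proportions must sum to <= 1")
  if (length(cfg$block_proportions) != 4L)
    stopf("block_proportions must have four entries (blocks I-IV)")
  if (cfg$umi_length < 3L) stopf("umi_length must be >= 3")
  if (cfg$n_genes > 0 && cfg$library_size < 10 * cfg$n_genes)
    stopf("library_size must be >= 10 * n_genes")
  if (cfg$binding_rpm_range[1] <= 0 ||
      cfg$binding_rpm_range[2] < cfg$binding_rpm_range[1])
    stopf("binding_rpm_range must be positive and increasing")
  if (cfg$sperm_oocyte_fold < 1) stopf("sperm_oocyte_fold must be >= 1")
  if (cfg$duplicate_rate >= 1) stopf("duplicate_rate must be < 1")
  if (cfg$control_library_fraction <= 0 || cfg$control_library_fraction > 1)
    stopf("control_library_fraction must be in (0, 1]")
  if (cfg$utr_length_range[1] < 40L)
    stopf("3'UTRs of < 40 nt cannot host a planted binding element")
  invisible(cfg)
}

# DNA-alphabet canonical FBE (UGUNNNAU read on the RNA sense strand) and its
# reverse complement, used for planting and scrubbing genome sequence.
FBE_DNA_PLUS <- c("T", "G", "T", NA, NA, NA, "A", "T")
FBE_DNA_MINUS <- c("A", "T", NA, NA, NA, "A", "C", "A")

#' Generate a ground-truth annotated synthetic transcriptome
#'
#' Lays out single- or two-exon genes (with a 3'UTR inside the terminal
#' exon for mRNAs) on one or more chromosomes, draws per-gene abundances and
#' planted binding frequencies, plants exactly one canonical FBE octamer in
#' the 3'UTR of every block I--IV gene (optionally with a -1C/-2C upstream
#' cytosine), and scrubs every other canonical FBE occurrence from both
#' strands so that non-target 3'UTRs are provably element-free.
#'
#' @param config a [synthetic_config()].
#' @return A list of class `synthetic_transcriptome` with elements
#'   `annotation` (a `gene_annotation` data frame with an `exons`
#'   attribute), `genome` (named list of chromosome sequences as character
#'   strings), and `truth` (per-gene block label, program, abundance RPM,
#'   expected binding RPM per gender, and planted peak coordinates).
#' @export
generate_transcriptome <- function(config) {
  validate_synthetic_config(config)
  if (config$n_genes == 0L) {
    ann <- empty_annotation()
    return(structure(list(annotation = ann, genome = list(),
                          truth = empty_truth()),
                     class = "synthetic_transcriptome"))
  }
  set.seed(stage_seed(config$seed, "transcriptome"))
  n <- config$n_genes

  ## --- gene structure layout ----------------------------------------------
  biotype <- rep("mRNA", n)
  n_nc <- round(config$frac_ncRNA * n)
  if (n_nc > 0) {
    nc_idx <- sample.int(n, n_nc)
    biotype[nc_idx] <- sample(c("ncRNA", "lincRNA", "snoRNA"), n_nc,
                              replace = TRUE)
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)
  two_exon <- biotype == "mRNA" & stats::runif(n) < 0.3
  utr_len <- sample(seq(config$utr_length_range[1], config$utr_length_range[2]),
                    n, replace = TRUE)
  exonic_len <- ifelse(biotype == "mRNA",
                       sample(600:1200, n, replace = TRUE),
                       sample(300:800, n, replace = TRUE))
  exonic_len <- pmax(exonic_len, utr_len + 200L)
  intron_len <- ifelse(two_exon, sample(100:300, n, replace = TRUE), 0L)
  gap <- sample(200:400, n, replace = TRUE)
  gene_len <- exonic_len + intron_len

  genes_per_chrom <- 250L
  chrom_idx <- (seq_len(n) - 1L) %/% genes_per_chrom + 1L
  chrom <- sprintf("chr%d", chrom_idx)

  start <- integer(n)
  pos <- setNames(rep(1L, max(chrom_idx)), sprintf("chr%d", seq_len(max(chrom_idx))))
  for (i in seq_len(n)) {
    start[i] <- pos[[chrom[i]]] + gap[i]
    pos[[chrom[i]]] <- start[i] + gene_len[i]
  }
  end <- start + gene_len - 1L
  chrom_len <- vapply(names(pos), function(cc) pos[[cc]] + 300L, integer(1))

  ## exons: for two-exon genes the first (genomic) exon is followed by the
  ## intron; the terminal exon carries the 3'UTR.
  exon_rows <- vector("list", n)
  utr3 <- matrix(NA_integer_, n, 2)
  for (i in seq_len(n)) {
    if (two_exon[i]) {
      # split exonic length so the transcript-terminal exon holds UTR + 100nt
      last_len <- utr_len[i] + sample(100:200, 1L)
      last_len <- min(last_len, exonic_len[i] - 100L)
      first_len <- exonic_len[i] - last_len
      if (strand[i] == "+") {
        e1 <- c(start[i], start[i] + first_len - 1L)
        e2 <- c(e1[2] + intron_len[i] + 1L, end[i])
      } else {
        # transcript-terminal exon is the genomically-first one
        e1 <- c(start[i], start[i] + last_len - 1L)
        e2 <- c(e1[2] + intron_len[i] + 1L, end[i])
      }
      exon_rows[[i]] <- data.frame(gene_id = i, start = c(e1[1], e2[1]),
                                   end = c(e1[2], e2[2]))
    } else {
      exon_rows[[i]] <- data.frame(gene_id = i, start = start[i], end = end[i])
    }
    if (biotype[i] == "mRNA") {
      utr3[i, ] <- if (strand[i] == "+") c(end[i] - utr_len[i] + 1L, end[i])
                   else c(start[i], start[i] + utr_len[i] - 1L)
    }
  }
  exons <- do.call(rbind, exon_rows)

  gene_id <- sprintf("gene%04d", seq_len(n))
  exons$gene_id <- gene_id[exons$gene_id]

  ## --- block labels, programs ---------------------------------------------
  block <- rep("none", n)
  n_blk <- round(config$block_proportions * n)
  mRNA_pool <- sample(which(biotype == "mRNA"))
  if (sum(n_blk) > length(mRNA_pool))
    stopf("not enough mRNA genes to host the requested block proportions")
  off <- 0L
  for (b in c("I", "II", "III", "IV")) {
    k <- n_blk[[match(b, c("I", "II", "III", "IV"))]]
    if (k > 0) block[mRNA_pool[(off + 1L):(off + k)]] <- b
    off <- off + k
  }
  program <- ifelse(block == "I", "spermatogenic",
             ifelse(block == "IV", "oogenic",
             ifelse(block %in% c("II", "III"), "both", NA)))
  free <- is.na(program)
  program[free] <- sample(c("spermatogenic", "oogenic", "both", "none"),
                          sum(free), replace = TRUE,
                          prob = c(0.25, 0.3, 0.25, 0.2))

  ## --- abundances and planted binding frequencies -------------------------
  abundance <- stats::rlnorm(n, meanlog = 0, sdlog = config$abundance_shape)
  abundance[block == "III"] <- abundance[block == "III"] * 8  # block III RNAs are abundant
  abundance <- abundance / sum(abundance)
  abundance_rpm <- abundance * 1e6

  ## binding frequencies cluster around a per-block level (log-normal
  ## spread of binding_spread log2 units), clipped to binding_rpm_range:
  ## blocks I/IV sit above the geometric mid-point of the range in their
  ## "on" gender, block II at the mid-point, block III near the top
  ## (exceptionally frequent interactors).
  lo <- config$binding_rpm_range[1]; hi <- config$binding_rpm_range[2]
  geomid <- sqrt(lo * hi)
  center <- c(I = 2 * geomid, II = geomid, III = 0.75 * hi, IV = 2 * geomid)
  r_on <- rep(NA_real_, n)
  tgt <- block != "none"
  r_on[tgt] <- pmin(pmax(
    center[block[tgt]] *
      exp(stats::rnorm(sum(tgt), 0, log(2) * config$binding_spread)),
    lo), hi)

  fold <- config$sperm_oocyte_fold
  rpm_sperm <- ifelse(block == "I", r_on,
               ifelse(block == "IV", r_on / fold,
               ifelse(tgt, r_on, NA)))
  rpm_oocyte <- ifelse(block == "IV", r_on,
                ifelse(block == "I", r_on / fold,
                ifelse(tgt, r_on, NA)))
  for (cond in c("sperm", "oocyte")) {
    rr <- if (cond == "sperm") rpm_sperm else rpm_oocyte
    mass <- sum(rr[tgt])
    if (mass >= 0.95e6)
      stopf("planted binding mass (%.0f RPM) exceeds the library", mass)
    a_bg <- abundance[!tgt] / sum(abundance[!tgt])
    rr[!tgt] <- a_bg * (1e6 - mass)
    if (cond == "sperm") rpm_sperm <- rr else rpm_oocyte <- rr
  }

  ## --- genome sequence, planting, scrubbing -------------------------------
  genome <- lapply(chrom_len, function(L)
    sample(c("A", "C", "G", "T"), L, replace = TRUE))

  peak_genome_start <- rep(NA_integer_, n)
  peak_tx_pos <- rep(NA_integer_, n)
  minus1C <- rep(FALSE, n); minus2C <- rep(FALSE, n)
  for (i in which(tgt)) {
    u1 <- utr3[i, 1]; u2 <- utr3[i, 2]
    if (u2 - u1 + 1L < 40L) stopf("3'UTR of %s too short for planting", gene_id[i])
    s <- sample(seq(u1 + 12L, u2 - 17L), 1L)
    peak_genome_start[i] <- s
    nnn <- sample(c("A", "C", "G", "T"), 3, replace = TRUE)
    if (strand[i] == "+") {
      oct <- FBE_DNA_PLUS; oct[4:6] <- nnn
      genome[[chrom[i]]][s:(s + 7L)] <- oct
      if (stats::runif(1) < config$frac_upstream_c) {
        at <- sample(1:2, 1L)
        genome[[chrom[i]]][s - at] <- "C"
        if (at == 1L) minus1C[i] <- TRUE else minus2C[i] <- TRUE
      }
    } else {
      oct <- FBE_DNA_MINUS
      oct[3:5] <- rev(chartr("ACGT", "TGCA", nnn))
      genome[[chrom[i]]][s:(s + 7L)] <- oct
      if (stats::runif(1) < config$frac_upstream_c) {
        at <- sample(1:2, 1L)
        genome[[chrom[i]]][s + 7L + at] <- "G"  # complement of upstream C
        if (at == 1L) minus1C[i] <- TRUE else minus2C[i] <- TRUE
      }
    }
    ex <- exons[exons$gene_id == gene_id[i], ]
    peak_tx_pos[i] <- genome_to_tx(ex, strand[i],
                                   if (strand[i] == "+") s else s + 7L)
  }

  for (cc in names(genome)) {
    prot <- data.frame(strand = strand[tgt & chrom == cc],
                       left = peak_genome_start[tgt & chrom == cc])
    genome[[cc]] <- scrub_fbe(genome[[cc]], prot)
  }
  genome <- lapply(genome, paste, collapse = "")

  annotation <- structure(
    data.frame(gene_id = gene_id, biotype = biotype, chromosome = chrom,
               strand = strand, start = start, end = end,
               utr3_start = utr3[, 1], utr3_end = utr3[, 2],
               program = program, stringsAsFactors = FALSE),
    exons = exons,
    seqlengths = chrom_len,
    class = c("gene_annotation", "data.frame"))

  truth <- structure(
    data.frame(gene_id = gene_id, block = block, program = program,
               abundance_rpm = abundance_rpm,
               rpm_sperm = rpm_sperm, rpm_oocyte = rpm_oocyte,
               peak_chrom = ifelse(tgt, chrom, NA),
               peak_strand = ifelse(tgt, strand, NA),
               peak_genome_start = peak_genome_start,
               peak_tx_pos = peak_tx_pos,
               minus1C = minus1C, minus2C = minus2C,
               stringsAsFactors = FALSE),
    class = c("synthetic_truth", "data.frame"))

  structure(list(annotation = annotation, genome = genome, truth = truth),
            class = "synthetic_transcriptome")
}

empty_annotation <- function() {
  structure(data.frame(gene_id = character(), biotype = character(),
                       chromosome = character(), strand = character(),
                       start = integer(), end = integer(),
                       utr3_start = integer(), utr3_end = integer(),
                       program = character(), stringsAsFactors = FALSE),
            exons = data.frame(gene_id = character(), start = integer(),
                               end = integer()),
            seqlengths = integer(),
            class = c("gene_annotation", "data.frame"))
}

empty_truth <- function() {
  structure(data.frame(gene_id = character(), block = character(),
                       program = character(), abundance_rpm = numeric(),
                       rpm_sperm = numeric(), rpm_oocyte = numeric(),
                       peak_chrom = character(), peak_strand = character(),
                       peak_genome_start = integer(), peak_tx_pos = integer(),
                       minus1C = logical(), minus2C = logical(),
                       stringsAsFactors = FALSE),
            class = c("synthetic_truth", "data.frame"))
}

# Transcript coordinate (1-based from the transcript 5' end) of a genomic
# position, given a gene's exons (genomic order) and strand.
genome_to_tx <- function(exons, strand, gpos) {
  exons <- exons[order(exons$start), , drop = FALSE]
  w <- exons$end - exons$start + 1L
  hit <- which(gpos >= exons$start & gpos <= exons$end)
  if (length(hit) != 1L) stopf("position %d not exonic", gpos)
  if (strand == "+") {
    sum(w[seq_len(hit - 1L)]) + (gpos - exons$start[hit] + 1L)
  } else {
    k <- nrow(exons)
    after <- if (hit < k) sum(w[(hit + 1L):k]) else 0L
    after + (exons$end[hit] - gpos + 1L)
  }
}

# Remove every canonical-FBE occurrence (both strands) from a chromosome,
# except the planted octamers listed in `protected` (strand, left-most
# genomic start). A single fixed-position base of each stray match is
# mutated to G (which breaks every non-G fixed position of the pattern),
# choosing a position outside any protected octamer or its 2-nt upstream
# flank; rescanning repeats until clean.
scrub_fbe <- function(seqvec, protected) {
  dna <- Biostrings::DNAString(paste(seqvec, collapse = ""))
  prot_plus <- protected$left[protected$strand == "+"]
  prot_minus <- protected$left[protected$strand == "-"]
  keepout <- c(unlist(lapply(prot_plus, function(s) (s - 2L):(s + 7L))),
               unlist(lapply(prot_minus, function(s) s:(s + 9L))))
  for (iter in 1:25) {
    hit_p <- Biostrings::start(Biostrings::matchPattern("TGTNNNAT", dna, fixed = FALSE))
    hit_m <- Biostrings::start(Biostrings::matchPattern("ATNNNACA", dna, fixed = FALSE))
    hit_p <- setdiff(hit_p, prot_plus)
    hit_m <- setdiff(hit_m, prot_minus)
    if (length(hit_p) + length(hit_m) == 0L) break
    seqvec <- strsplit(as.character(dna), "", fixed = TRUE)[[1]]
    for (s in hit_p) {
      for (ofs in c(1L, 0L, 2L, 6L, 7L)) {   # fixed chars T,G,T,A,T; pick non-G target
        p <- s + ofs
        if (ofs != 1L && !(p %in% keepout)) { seqvec[p] <- "G"; break }
        if (ofs == 1L && !(p %in% keepout)) { seqvec[p] <- "C"; break }
      }
    }
    for (s in hit_m) {
      for (ofs in c(0L, 1L, 5L, 6L, 7L)) {   # fixed chars A,T,A,C,A
        p <- s + ofs
        if (!(p %in% keepout)) {
          seqvec[p] <- if (seqvec[p] == "G") "T" else "G"
          break
        }
      }
    }
    dna <- Biostrings::DNAString(paste(seqvec, collapse = ""))
  }
  strsplit(as.character(dna), "", fixed = TRUE)[[1]]
}

#' Simulate aligned iCLIP reads for one sample
#'
#' Draws unique molecules per gene from a Poisson whose mean realises the
#' planted expected RPM (binding frequency for FBF assays; abundance only
#' for the no-antibody control), places FBF reads on target genes as a
#' discretised Gaussian (sd 10 nt) around the planted binding element and
#' all other reads uniformly over exons, tags each molecule with a random
#' UMI, and re-emits PCR duplicates whose UMIs acquire sequencing errors at
#' `umi_error_rate` per nucleotide.
#'
#' @param config a [synthetic_config()].
#' @param transcriptome output of [generate_transcriptome()] from the same
#'   config.
#' @param condition `"sperm"` or `"oocyte"` (germline gender).
#' @param assay `"FBF"` (immunoprecipitation) or `"control"` (no antibody).
#' @param replicate replicate index (determines the sub-seed).
#' @param seed optional explicit seed overriding the derived one.
#' @return A data frame of class `iclip_reads` with columns `name`,
#'   `chromosome`, `strand`, `start`, `end`, `umi`, `gene_true`, `molecule`;
#'   attributes carry the sample label and the per-gene unique-molecule
#'   bookkeeping (`molecule_counts`) used as a test oracle.
#' @export
simulate_iclip_reads <- function(config, transcriptome,
                                 condition = c("sperm", "oocyte"),
                                 assay = c("FBF", "control"),
                                 replicate = 1L, seed = NULL) {
  condition <- match.arg(condition)
  assay <- match.arg(assay)
  validate_synthetic_config(config)
  ann <- transcriptome$annotation
  truth <- transcriptome$truth
  exons <- attr(ann, "exons")
  set.seed(seed %||% stage_seed(config$seed, "reads", condition, assay, replicate))

  rpm <- switch(assay,
                control = truth$abundance_rpm,
                FBF = if (condition == "sperm") truth$rpm_sperm else truth$rpm_oocyte)
  lib <- config$library_size *
    if (assay == "control") config$control_library_fraction else 1
  lambda <- lib * rpm / 1e6
  n_mol <- stats::rpois(length(lambda), lambda)
  rl <- config$read_length

  out <- vector("list", sum(n_mol > 0))
  j <- 0L
  for (i in which(n_mol > 0)) {
    m <- n_mol[i]
    ex <- exons[exons$gene_id == ann$gene_id[i], , drop = FALSE]
    is_target <- assay == "FBF" && !is.na(truth$peak_genome_start[i])
    if (is_target) {
      s0 <- truth$peak_genome_start[i]
      center <- s0 + 3L
      hit_ex <- ex[s0 >= ex$start & s0 <= ex$end, , drop = FALSE]
      starts <- as.integer(round(stats::rnorm(m, center - (rl %/% 2), 10)))
      starts <- pmin(pmax(starts, hit_ex$start[1]), hit_ex$end[1] - rl + 1L)
    } else {
      w <- ex$end - ex$start + 1L
      pick <- sample.int(nrow(ex), m, replace = TRUE, prob = w)
      room <- pmax(w[pick] - rl + 1L, 1L)
      starts <- ex$start[pick] + floor(stats::runif(m) * room)
    }
    out[[j <- j + 1L]] <- data.frame(
      gene_true = ann$gene_id[i], chromosome = ann$chromosome[i],
      strand = ann$strand[i], start = as.integer(starts),
      end = as.integer(starts) + rl - 1L, stringsAsFactors = FALSE)
  }
  reads <- if (j > 0) do.call(rbind, out) else
    data.frame(gene_true = character(), chromosome = character(),
               strand = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)

  n_total <- nrow(reads)
  sample_id <- paste(assay, condition, paste0("rep", replicate), sep = "_")
  mol_counts <- if (n_total > 0) table(reads$gene_true) else table(character())

  # molecular tags and PCR duplication
  if (n_total > 0) {
    umi_mat <- matrix(sample(c("A", "C", "G", "T"),
                             n_total * config$umi_length, replace = TRUE),
                      nrow = n_total)
    umi <- do.call(paste0, as.data.frame(umi_mat, stringsAsFactors = FALSE))
    reads$umi <- umi
    reads$molecule <- seq_len(n_total)
    extra <- stats::rgeom(n_total, prob = 1 - config$duplicate_rate)
    idx <- rep(seq_len(n_total), 1L + extra)
    reads <- reads[idx, , drop = FALSE]
    dup <- duplicated(idx)
    if (any(dup) && config$umi_error_rate > 0) {
      dmat <- matrix(unlist(strsplit(reads$umi[dup], "", fixed = TRUE)),
                     ncol = config$umi_length, byrow = TRUE)
      err <- matrix(stats::runif(length(dmat)) < config$umi_error_rate,
                    nrow = nrow(dmat))
      if (any(err)) {
        repl <- vapply(dmat[err],
                       function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                       character(1))
        dmat[err] <- repl
        reads$umi[dup] <- do.call(paste0, as.data.frame(dmat, stringsAsFactors = FALSE))
      }
    }
    copy <- stats::ave(seq_along(idx), idx, FUN = seq_along)
    reads$name <- sprintf("%s:m%06d:c%d_%s", sample_id, reads$molecule, copy,
                          reads$umi)
    rownames(reads) <- NULL
  } else {
    reads$umi <- character(); reads$molecule <- integer(); reads$name <- character()
  }

  reads <- reads[, c("name", "chromosome", "strand", "start", "end", "umi",
                     "gene_true", "molecule")]
  structure(reads, sample = sample_id, condition = condition, assay = assay,
            replicate = replicate, molecule_counts = mol_counts,
            class = c("iclip_reads", "data.frame"))
}

#' Simulate a complete two-gender iCLIP experiment
#'
#' Convenience wrapper generating the transcriptome plus FBF and control
#' replicates for both germline genders.
#'
#' @param config a [synthetic_config()].
#' @return list with `annotation`, `genome`, `truth` and `reads` (a named
#'   list, e.g. `FBF_sperm_rep1`, `control_oocyte_rep2`, ...).
#' @export
simulate_experiment <- function(config) {
  tx <- generate_transcriptome(config)
  reads <- list()
  for (assay in c("FBF", "control"))
    for (cond in c("sperm", "oocyte"))
      for (r in seq_len(config$n_replicates_per_condition)) {
        rd <- simulate_iclip_reads(config, tx, cond, assay, r)
        reads[[attr(rd, "sample")]] <- rd
      }
  c(tx[c("annotation", "genome", "truth")], list(reads = reads, config = config))
}

#' Simulate a planted four-block binding matrix
#'
#' Generates, directly in log2 binding-frequency space, the matrix the block
#' clustering operates on: four planted blocks (I spermatogenic-enriched,
#' II gender-neutral, III gender-neutral at high frequency, IV
#' oogenic-enriched) over a background of unbound RNAs, with Gaussian
#' within-block noise. Used to score parameter recovery of the clustering
#' and PCA stages at desk scale.
#'
#' @param n_rnas number of rows (RNAs).
#' @param n_samples number of columns; the first half are spermatogenic,
#'   the second half oogenic samples.
#' @param proportions fractions of RNAs per block I--IV (rest: none).
#' @param level baseline log2 binding level of a bound block.
#' @param high_level log2 level of the high-frequency block III.
#' @param gender_delta log2 drop of the off-gender samples in blocks I/IV.
#' @param noise_sd within-block Gaussian noise sd (log2 units).
#' @param seed RNG seed.
#' @return list with `matrix` (rows named rna0001...), `blocks` (true
#'   labels), `sperm_cols`, `oocyte_cols`.
#' @export
simulate_block_matrix <- function(n_rnas = 2000L, n_samples = 12L,
                                  proportions = c(I = 0.05, II = 0.30,
                                                  III = 0.02, IV = 0.03),
                                  level = 8, high_level = 12,
                                  gender_delta = 4, noise_sd = 0.5,
                                  seed = 1L) {
  stopifnot(n_samples %% 2 == 0, sum(proportions) <= 1)
  set.seed(seed)
  half <- n_samples %/% 2
  sperm_cols <- seq_len(half); oocyte_cols <- half + seq_len(half)
  n_blk <- round(proportions * n_rnas)
  blocks <- rep("none", n_rnas)
  idx <- sample.int(n_rnas)
  off <- 0L
  for (b in c("I", "II", "III", "IV")) {
    k <- n_blk[[match(b, c("I", "II", "III", "IV"))]]
    if (k > 0) blocks[idx[(off + 1L):(off + k)]] <- b
    off <- off + k
  }
  mu <- matrix(0, n_rnas, n_samples)
  mu[blocks == "I", sperm_cols] <- level
  mu[blocks == "I", oocyte_cols] <- level - gender_delta
  mu[blocks == "II", ] <- level
  mu[blocks == "III", ] <- high_level
  mu[blocks == "IV", sperm_cols] <- level - gender_delta
  mu[blocks == "IV", oocyte_cols] <- level
  m <- pmax(mu + matrix(stats::rnorm(length(mu), 0, noise_sd), n_rnas), 0)
  dimnames(m) <- list(sprintf("rna%04d", seq_len(n_rnas)),
                      c(sprintf("FBF_sperm_rep%d", seq_len(half)),
                        sprintf("FBF_oocyte_rep%d", seq_len(half))))
  list(matrix = m, blocks = setNames(blocks, rownames(m)),
       sperm_cols = sperm_cols, oocyte_cols = oocyte_cols)
}

#' Render aligned synthetic reads as raw iCLIP FASTQ records
#'
#' Reconstructs the pre-demultiplexing read layout: sample barcode, then the
#' (possibly error-bearing) UMI, then the insert sequence taken from the
#' genome (reverse-complemented for minus-strand alignments so the record is
#' in sequencing orientation), then the 3' linker.
#'
#' @param reads an `iclip_reads` data frame.
#' @param genome named list of chromosome sequences (character).
#' @param layout a [read_layout()] whose `umi_length` matches the generator.
#' @param barcode the sample barcode to prepend.
#' @return data frame with `name` and `seq` columns (one record per read).
#' @export
reads_to_fastq <- function(reads, genome, layout, barcode) {
  if (nchar(barcode) != layout$sample_barcode_length)
    stopf("barcode length does not match layout")
  insert <- vapply(seq_len(nrow(reads)), function(i) {
    s <- substr(genome[[reads$chromosome[i]]], reads$start[i], reads$end[i])
    if (reads$strand[i] == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    s
  }, character(1))
  data.frame(name = sub("_[ACGTN]+$", "", reads$name),
             seq = paste0(barcode, reads$umi, insert, layout$three_prime_linker),
             stringsAsFactors = FALSE)
}
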