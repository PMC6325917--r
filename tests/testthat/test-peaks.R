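fake_track <- function(cov, chrom = "chr1", strand = "+", lib = sum(cov)) {
  structure(setNames(list(as.integer(cov)), paste(chrom, strand, sep = "|")),
            library_size = lib,
            seqlengths = setNames(length(cov), chrom),
            class = "coverage_track")
}

test_that("coverage tracks conserve read mass", {
  r <- make_reads("chr1", "+", 101, end = 135)
  tr <- build_coverage(r, c(chr1 = 300L))
  cov <- tr[["chr1|+"]]
  expect_equal(sum(cov), 35)
  expect_equal(unname(cov[101]), 1)
  expect_equal(unname(cov[135]), 1)
  expect_equal(unname(cov[136]), 0)

  r2 <- rbind(r, r)
  tr2 <- build_coverage(r2, c(chr1 = 300L))
  expect_equal(max(tr2[["chr1|+"]]), 2)
  expect_equal(sum(tr2[["chr1|+"]]), sum(r2$end - r2$start + 1))
})

test_that("candidate detection takes the run argmax and merges nearby summits", {
  expect_equal(nrow(find_candidate_peaks(fake_track(rep(0, 200)), 5)), 0)

  tri <- c(rep(0, 99), 1:12, 11:1, rep(0, 100))
  cand <- find_candidate_peaks(fake_track(tri), 5)
  expect_equal(nrow(cand), 1)
  expect_equal(cand$summit, 111)
  expect_equal(cand$summit_height, 12L)

  # two equal maxima 30 bp apart collapse onto the left one
  cov <- rep(0, 400)
  cov[100:110] <- 8
  cov[130:140] <- 8
  cand2 <- find_candidate_peaks(fake_track(cov), 5)
  expect_equal(nrow(cand2), 1)
  expect_equal(cand2$summit, 100)

  # beyond the merge radius both survive
  cov2 <- rep(0, 400)
  cov2[100] <- 8; cov2[200] <- 9
  cand3 <- find_candidate_peaks(fake_track(cov2), 5)
  expect_equal(cand3$summit, c(100, 200))
})

test_that("the Gaussian null reproduces hand-computed sample moments", {
  # one control replicate, library 1e6, bin heights 0,1,2,1,0,1,2,1,0,2
  heights <- c(0, 1, 2, 1, 0, 1, 2, 1, 0, 2)
  starts <- unlist(lapply(seq_along(heights), function(b)
    rep(1000 + (b - 1) * 50, heights[b])))
  ctrl <- make_reads("chr1", "+", starts)
  null <- fit_control_null(ctrl, "chr1", "+", 1000, 1499,
                           library_sizes = 1e6)
  expect_equal(null$n_bins, 10)
  expect_equal(null$mu, 1.0)
  expect_equal(null$sigma, 0.8165, tolerance = 1e-4)

  # constant bins give sigma zero
  flat <- make_reads("chr1", "+", rep(1000 + 0:9 * 50, each = 5))
  n2 <- fit_control_null(flat, "chr1", "+", 1000, 1499, library_sizes = 1e6)
  expect_equal(n2$mu, 5)
  expect_equal(n2$sigma, 0)

  # per-million scale invariance: doubled counts with doubled library
  ctrl2 <- rbind(ctrl, ctrl)
  n3 <- fit_control_null(ctrl2, "chr1", "+", 1000, 1499,
                         library_sizes = 2e6)
  expect_equal(n3$mu, null$mu)
  expect_equal(n3$sigma, null$sigma)
})

test_that("peak p-values equal the Gaussian upper tail", {
  null <- list(mu = 1.0, sigma = 0.8165)
  expect_equal(peak_pvalue(1.0, null, sigma_floor = 1e-6), 0.5)
  # z = (5 - 1)/0.8165 = 4.899 -> p ~ 4.8e-7
  p <- peak_pvalue(5, null, sigma_floor = 1e-6)
  expect_equal(p, stats::pnorm(5, 1, 0.8165, lower.tail = FALSE))
  expect_lt(abs(p - 4.8e-7), 0.05e-7)
  # monotone decreasing in height, vanishing tail
  hs <- seq(0, 30, by = 0.5)
  ps <- vapply(hs, peak_pvalue, numeric(1), null = null, sigma_floor = 1e-6)
  expect_true(all(diff(ps) < 0))
  expect_lt(ps[length(ps)], 1e-200)
  # the sigma floor takes over degenerate nulls
  expect_equal(peak_pvalue(2, list(mu = 0, sigma = 0), sigma_floor = 1),
               stats::pnorm(2, lower.tail = FALSE))
})

test_that("BH adjustment matches the step-up definition and the ratio cutoffs apply", {
  df <- data.frame(p_value = c(0.001, 0.008, 0.039, 0.041),
                   height_rpm = 100, height_raw = 100,
                   control_rpm = 0, control_raw = 0)
  out <- adjust_and_filter(df, fdr = 1, rpm_ratio_min = 0, raw_ratio_min = 0)
  expect_equal(out$p_adjusted, c(0.004, 0.016, 0.041, 0.041))

  same <- data.frame(p_value = rep(0.03, 5), height_rpm = 100,
                     height_raw = 100, control_rpm = 0, control_raw = 0)
  expect_equal(adjust_and_filter(same, fdr = 1, rpm_ratio_min = 0,
                                 raw_ratio_min = 0)$p_adjusted, rep(0.03, 5))

  # significant but under twofold over control: rejected
  weak <- data.frame(p_value = 1e-5, height_rpm = 30, height_raw = 300,
                     control_rpm = 20, control_raw = 2)
  expect_equal(nrow(adjust_and_filter(weak)), 0)
  strong <- data.frame(p_value = 1e-5, height_rpm = 45, height_raw = 300,
                       control_rpm = 20, control_raw = 2)
  expect_equal(nrow(adjust_and_filter(strong)), 1)
  # raw tenfold cutoff against the one-read pseudocount
  zero_ctrl <- data.frame(p_value = 1e-5, height_rpm = 45, height_raw = 9,
                          control_rpm = 0, control_raw = 0)
  expect_equal(nrow(adjust_and_filter(zero_ctrl)), 0)
  zero_ctrl$height_raw <- 10
  expect_equal(nrow(adjust_and_filter(zero_ctrl)), 1)

  empty <- adjust_and_filter(df[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("BH equals the brute-force oracle on random vectors", {
  set.seed(77)
  for (trial in 1:60) {
    p <- runif(sample(1:60, 1))^sample(1:3, 1)
    df <- data.frame(p_value = p, height_rpm = 1, height_raw = 1,
                     control_rpm = 0, control_raw = 0)
    out <- adjust_and_filter(df, fdr = 1, rpm_ratio_min = 0,
                             raw_ratio_min = 0)
    expect_equal(out$p_adjusted, bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("called peaks recover planted sites with correct gene assignment", {
  cfg <- synthetic_config(n_genes = 300, library_size = 6e4,
                          abundance_shape = 0.25,
                          block_proportions = c(I = 0.1, II = 0.2, III = 0,
                                                IV = 0.1),
                          binding_rpm_range = c(1000, 2000),
                          sperm_oocyte_fold = 1, duplicate_rate = 0.2,
                          seed = 55)
  tx <- generate_transcriptome(cfg)
  fbf <- lapply(1:3, function(r)
    collapse_duplicates(simulate_iclip_reads(cfg, tx, "sperm", "FBF", r)))
  ctl <- lapply(1:3, function(r)
    collapse_duplicates(simulate_iclip_reads(cfg, tx, "sperm", "control", r)))
  peaks <- call_peaks(fbf, ctl, tx$annotation, tx$genome)
  tgt <- tx$truth[tx$truth$block != "none", ]
  recall <- mean(tgt$gene_id %in% peaks$gene_id)
  expect_gt(recall, 0.85)
  expect_true(all(peaks$gene_id %in% tgt$gene_id))
  # called summits sit near the planted elements
  d <- abs(peaks$summit -
           tgt$peak_genome_start[match(peaks$gene_id, tgt$gene_id)])
  expect_lt(stats::median(d), 30)
  # ranking is by per-million height, ties by coordinate
  expect_equal(peaks$rank, seq_len(nrow(peaks)))
  expect_true(all(diff(peaks$height_rpm) <= 0))
})

test_that("peak ranking breaks exact ties by leftmost coordinate", {
  cfg <- synthetic_config(n_genes = 20, library_size = 2000, seed = 1)
  tx <- generate_transcriptome(cfg)
  # two identical synthetic piles on two genes
  g <- tx$annotation[tx$annotation$biotype == "mRNA", ][1:2, ]
  mk_pile <- function(gene, n) make_reads(gene$chromosome, gene$strand,
                                          rep(gene$start + 50, n))
  fbf <- rbind(mk_pile(g[1, ], 40), mk_pile(g[2, ], 40))
  # scattered control reads well away from the piles
  ctl <- make_reads(g$chromosome[1], g$strand[1],
                    seq(2, 3000, length.out = 200))
  peaks <- call_peaks(fbf, ctl, tx$annotation, genome = NULL)
  expect_equal(nrow(peaks), 2)
  expect_equal(peaks$height_rpm[1], peaks$height_rpm[2])
  ord <- order(peaks$chromosome, peaks$window_start)
  expect_equal(peaks$rank[ord], sort(peaks$rank[ord]))
  expect_true(peaks$window_start[peaks$rank == 1] <=
              peaks$window_start[peaks$rank == 2] ||
              peaks$chromosome[peaks$rank == 1] <
              peaks$chromosome[peaks$rank == 2])
})
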