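test_that("exon-overlap assignment follows the iff-exon rule with ncRNA priority", {
  ann <- two_gene_annotation()
  # fully intronic read -> unassigned
  expect_equal(assign_read_to_gene(make_reads("chr1", "+", 1600), ann,
                                   "counting"), "unassigned")
  # read in the mRNA/ncRNA shared region: ambiguous when counting,
  # the ncRNA for peak assignment
  shared <- make_reads("chr1", "+", 2150)
  expect_equal(assign_read_to_gene(shared, ann, "counting"), "ambiguous")
  expect_equal(assign_read_to_gene(shared, ann, "peak_assignment"), "nc1")
  # unique exon overlap -> that gene, even by a single base
  expect_equal(assign_read_to_gene(make_reads("chr1", "+", 1490), ann,
                                   "counting"), "mrna1")
  expect_equal(assign_read_to_gene(make_reads("chr1", "+", 966, end = 1000),
                                   ann, "counting"), "mrna1")
  # iCLIP is stranded: antisense reads do not count
  expect_equal(assign_read_to_gene(make_reads("chr1", "-", 1200), ann,
                                   "counting"), "unassigned")
})

test_that("counts matrices conserve reads and are order-independent", {
  ann <- two_gene_annotation()
  reads <- rbind(make_reads("chr1", "+", c(1100, 1200, 1300, 2150, 1600)),
                 make_reads("chr1", "+", c(2550, 2560)))
  m <- build_counts_matrix(list(s1 = reads), ann)
  expect_equal(unname(m$counts[, "s1"]), c(3L, 2L))
  expect_equal(unname(m$library_size["s1"]), 5)
  expect_equal(sum(m$assignment[, "s1"]), nrow(reads))

  perm <- reads[sample(nrow(reads)), ]
  m2 <- build_counts_matrix(list(s1 = perm), ann)
  expect_identical(m$counts, m2$counts)

  empty <- build_counts_matrix(list(s1 = reads[0, ]), ann)
  expect_true(all(empty$counts == 0))
  expect_equal(dim(empty$counts), c(2L, 1L))
  expect_error(build_counts_matrix(list(s1 = reads),
                                   two_gene_annotation()[0, ]), "empty")
})

test_that("per-gene counts on the synthetic fixture match generator truth", {
  cfg <- synthetic_config(n_genes = 60, library_size = 6000,
                          duplicate_rate = 0, seed = 3)
  tx <- generate_transcriptome(cfg)
  rd <- simulate_iclip_reads(cfg, tx, "sperm", "FBF", 1)
  m <- build_counts_matrix(list(s = rd), tx$annotation)
  mc <- attr(rd, "molecule_counts")
  expect_equal(m$counts[names(mc), "s"], setNames(as.integer(mc), names(mc)))
  expect_equal(unname(m$assignment["ambiguous", "s"]), 0)
})

test_that("RPM normalization is exact arithmetic and errors on empty libraries", {
  m <- as_counts_matrix(matrix(c(50L, 0L), 2, 1,
                               dimnames = list(c("g1", "g2"), "s1")),
                        library_size = c(s1 = 2e6))
  rpm <- normalize_rpm(m)
  expect_equal(rpm["g1", "s1"], 25)
  expect_equal(rpm["g2", "s1"], 0)

  full <- as_counts_matrix(matrix(c(3L, 7L), 2, 1,
                                  dimnames = list(c("g1", "g2"), "s1")))
  expect_equal(sum(normalize_rpm(full)), 1e6)

  bad <- as_counts_matrix(matrix(0L, 1, 1, dimnames = list("g", "empty")),
                          library_size = c(empty = 0))
  expect_error(normalize_rpm(bad), "empty")
})

test_that("replicate combination sums paired columns with the canonical pairings", {
  mk <- function(vals, prefix) {
    as_counts_matrix(matrix(vals, nrow = 2,
                            dimnames = list(c("g1", "g2"),
                                            paste0(prefix, 1:3))))
  }
  a <- mk(c(1, 2, 3, 4, 5, 6), "a")   # columns a1=(1,2) a2=(3,4) a3=(5,6)
  b <- mk(c(10, 20, 30, 40, 50, 60), "b")
  comb <- combine_replicates(a, b, "oogenic")
  # oogenic pairing (1,3),(2,2),(3,1)
  expect_equal(unname(comb$counts[, 1]), c(1 + 50, 2 + 60))
  expect_equal(unname(comb$counts[, 2]), c(3 + 30, 4 + 40))
  expect_equal(unname(comb$counts[, 3]), c(5 + 10, 6 + 20))
  sp <- combine_replicates(a, b, "spermatogenic")
  expect_equal(unname(sp$counts[, 1]), c(3 + 10, 4 + 20))

  one <- as_counts_matrix(matrix(c(2L, 3L), 2, 1,
                                 dimnames = list(c("g1", "g2"), "r1")))
  doubled <- combine_replicates(one, one, cbind(1, 1))
  expect_equal(unname(doubled$counts[, 1]), c(4, 6))
  expect_equal(unname(doubled$library_size), 10)

  # combining then normalizing equals the count-weighted average of RPMs
  comb_rpm <- normalize_rpm(comb)
  ra <- normalize_rpm(a); rb <- normalize_rpm(b)
  la <- a$library_size; lb <- b$library_size
  pair <- cbind(1:3, c(3, 2, 1))
  for (i in 1:3) {
    w <- c(la[pair[i, 1]], lb[pair[i, 2]])
    expected <- (ra[, pair[i, 1]] * w[1] + rb[, pair[i, 2]] * w[2]) / sum(w)
    expect_equal(unname(comb_rpm[, i]), unname(expected))
  }

  expect_error(combine_replicates(a, b, cbind(c(1, 1), c(2, 3))),
               "bijection")
})

test_that("correlation report pools rho by gender and applies a pooled t-test", {
  set.seed(9)
  base <- rpois(200, 50)
  mk_col <- function(noise) pmax(base + rpois(200, noise) - noise %/% 2, 0)
  counts <- cbind(s1 = mk_col(4), s2 = mk_col(4),
                  o1 = mk_col(40), o2 = mk_col(40))
  rownames(counts) <- paste0("g", 1:200)
  x <- as_counts_matrix(counts)
  rep <- correlation_report(x, c("sperm", "sperm", "oocyte", "oocyte"))
  expect_equal(diag(rep$rho), rep(1, 4), ignore_attr = TRUE)
  expect_equal(rep$rho, t(rep$rho))
  expect_length(rep$within_values, 2)   # one within-sperm + one within-oocyte
  expect_length(rep$between_values, 4)

  # closed-form pooled two-sample t oracle on the pooled rho sets
  w <- rep$within_values; b <- rep$between_values
  sp2 <- ((length(w) - 1) * var(w) + (length(b) - 1) * var(b)) /
    (length(w) + length(b) - 2)
  tstat <- (mean(w) - mean(b)) / sqrt(sp2 * (1 / length(w) + 1 / length(b)))
  p_oracle <- 2 * pt(-abs(tstat), df = length(w) + length(b) - 2)
  expect_equal(rep$statistic, tstat, tolerance = 1e-12)
  expect_equal(rep$p_value, p_oracle, tolerance = 1e-12)

  # rank reversal gives rho = -1
  rev2 <- as_counts_matrix(cbind(a1 = 1:10, a2 = 2:11, b1 = 10:1, b2 = 11:2) |>
                           (\(m) { rownames(m) <- paste0("g", 1:10); m })())
  rr <- correlation_report(rev2, c("x", "x", "y", "y"))
  expect_equal(rr$rho["a1", "b1"], -1)
  # perfectly separated rho sets are degenerate for the t-test
  expect_true(is.na(rr$p_value))
})

test_that("within-gender correlation exceeds between-gender on gendered fixtures", {
  exp <- mini_experiment()
  dedup <- lapply(exp$reads[grep("^FBF_", names(exp$reads))],
                  collapse_duplicates)
  m <- build_counts_matrix(dedup, exp$annotation)
  gender <- ifelse(grepl("sperm", colnames(m$counts)), "sperm", "oocyte")
  rep <- correlation_report(m, gender)
  expect_gt(mean(rep$within_values), mean(rep$between_values))
})
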