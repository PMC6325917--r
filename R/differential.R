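#' Restrict to testable genes
#'
#' Keeps genes that belong to the spermatogenic and/or oogenic gamete
#' program and whose mean raw count across the designated samples is at
#' least `min_mean_reads` (default 20), mirroring the read-depth filter
#' applied before differential-binding testing.
#'
#' @param x a `counts_matrix`.
#' @param programs named character vector gene -> program
#'   (`"spermatogenic"`, `"oogenic"`, `"both"`, `"none"`).
#' @param min_mean_reads inclusive mean-count threshold (default 20).
#' @param samples columns over which the mean is taken (default all).
#' @return character vector of retained gene ids.
#' @export
filter_testable_genes <- function(x, programs, min_mean_reads = 20,
                                  samples = colnames(x$counts)) {
  genes <- rownames(x$counts)
  prog <- programs[genes]
  in_program <- !is.na(prog) & prog %in% c("spermatogenic", "oogenic", "both")
  mu <- rowMeans(x$counts[, samples, drop = FALSE])
  genes[in_program & mu >= min_mean_reads]
}

#' Median-of-ratios size factors
#'
#' For each sample, the median over genes of the ratio of its count to the
#' gene's geometric mean across samples, computed over genes with nonzero
#' counts in every sample, then rescaled so the factors have geometric
#' mean 1.
#'
#' @param x a `counts_matrix` or plain counts matrix.
#' @return named numeric vector of positive per-sample factors.
#' @export
estimate_size_factors <- function(x) {
  counts <- if (inherits(x, "counts_matrix")) x$counts else x
  all_nonzero <- rowSums(counts == 0) == 0
  if (!any(all_nonzero))
    stopf("no gene has nonzero counts in all samples; consider a pseudocount")
  k <- counts[all_nonzero, , drop = FALSE]
  gm <- exp(rowMeans(log(k)))
  sf <- apply(k / gm, 2, stats::median)
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(counts))
}

#' Negative-binomial test for gender-differential binding
#'
#' A documented stand-in for a full GLM-based differential analysis:
#' counts are normalized by size factors, a per-gene NB dispersion is
#' estimated by the method of moments on normalized counts pooled within
#' gender (floored at 1e-8) and shrunk in log space toward a `a0 + a1 /
#' mean` trend fitted across genes, the log2 fold change (sperm over
#' oocyte) uses a pseudo-normalized-count of `delta = 0.5`, and a Wald
#' statistic (delta-method standard error under the NB variance
#' `mu + alpha * mu^2`) is referred to the normal distribution, two-sided.
#' P-values are Benjamini-Hochberg adjusted across tested genes.
#'
#' @param x a `counts_matrix` (genes already filtered to the testable set).
#' @param size_factors per-sample factors from [estimate_size_factors()].
#' @param design character/factor per sample: `"sperm"` or `"oocyte"`
#'   (>= 2 replicates each).
#' @param delta pseudo-normalized-count for fold changes (default 0.5).
#' @param shrink_weight weight of the trend in the log-space dispersion
#'   shrinkage (0 = none, 1 = trend only; default 0.5).
#' @return data frame of class `differential_result`: `gene_id`,
#'   `base_mean`, `log2_fold_change`, `dispersion`, `p_value`,
#'   `p_adjusted`. Genes with all-zero counts in both genders are excluded
#'   (reported in the `excluded` attribute).
#' @export
test_differential_binding <- function(x, size_factors, design, delta = 0.5,
                                      shrink_weight = 0.5) {
  counts <- x$counts
  stopifnot(length(design) == ncol(counts))
  design <- as.character(design)
  if (!all(design %in% c("sperm", "oocyte")))
    stopf("design labels must be 'sperm' or 'oocyte'")
  if (min(table(design)) < 2) stopf("need >= 2 replicates per gender")
  sf <- size_factors[colnames(counts)]
  q <- sweep(counts, 2, sf, "/")

  zero <- rowSums(counts) == 0
  excluded <- rownames(counts)[zero]
  q <- q[!zero, , drop = FALSE]

  sp <- design == "sperm"; oo <- design == "oocyte"
  m_sp <- rowMeans(q[, sp, drop = FALSE])
  m_oo <- rowMeans(q[, oo, drop = FALSE])
  base_mean <- rowMeans(q)

  # method-of-moments dispersion, pooled within gender
  v_sp <- apply(q[, sp, drop = FALSE], 1, stats::var)
  v_oo <- apply(q[, oo, drop = FALSE], 1, stats::var)
  n_sp <- sum(sp); n_oo <- sum(oo)
  pooled_var <- ((n_sp - 1) * v_sp + (n_oo - 1) * v_oo) / (n_sp + n_oo - 2)
  pooled_mean <- (m_sp + m_oo) / 2
  alpha_mom <- pmax((pooled_var - pooled_mean) / pooled_mean^2, 1e-8)

  # trend alpha(mu) = a0 + a1/mu over genes with informative estimates
  use <- alpha_mom > 1e-8 & pooled_mean > 0
  if (sum(use) >= 10) {
    fit <- stats::lm(alpha_mom[use] ~ I(1 / pooled_mean[use]))
    a0 <- max(stats::coef(fit)[1], 1e-4); a1 <- max(stats::coef(fit)[2], 0)
  } else {
    a0 <- max(mean(alpha_mom), 1e-4); a1 <- 0
  }
  alpha_trend <- a0 + a1 / pmax(pooled_mean, 1e-8)
  alpha <- exp((1 - shrink_weight) * log(alpha_mom) +
               shrink_weight * log(alpha_trend))

  lfc <- log2((m_sp + delta) / (m_oo + delta))

  # delta-method SE of the log2 ratio of gender means; normalized counts
  # are treated as NB with variance mu + alpha * mu^2 (size factors enter
  # only through the normalization, keeping results invariant under joint
  # count/factor rescaling)
  var_mean_sp <- (m_sp + alpha * m_sp^2) / n_sp
  var_mean_oo <- (m_oo + alpha * m_oo^2) / n_oo
  ln2sq <- log(2)^2
  se <- sqrt(var_mean_sp / (ln2sq * (m_sp + delta)^2) +
             var_mean_oo / (ln2sq * (m_oo + delta)^2))
  z <- lfc / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(gene_id = rownames(q), base_mean = base_mean,
                    log2_fold_change = lfc, dispersion = alpha,
                    p_value = p,
                    p_adjusted = stats::p.adjust(p, method = "BH"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, excluded = excluded,
            class = c("differential_result", "data.frame"))
}

#' Call gender-enriched genes
#'
#' `sperm_enriched` if `log2_fold_change >= log2(min_fold)` and
#' `p_adjusted < padj_max`; `oocyte_enriched` symmetrically; otherwise
#' `ns`. The fold comparison is inclusive (`>=`, "twofold or higher") by
#' default; `strict = TRUE` uses `>` (">2 fold").
#'
#' @param results a `differential_result`.
#' @param padj_max adjusted-p cutoff (default 0.01).
#' @param min_fold fold-change cutoff (default 2).
#' @param strict use strict inequality for the fold cutoff.
#' @return `results` with a `call` column added.
#' @export
call_gender_enriched <- function(results, padj_max = 0.01, min_fold = 2,
                                 strict = FALSE) {
  lf <- log2(min_fold)
  cmp <- if (strict) `>` else `>=`
  sig <- results$p_adjusted < padj_max
  results$call <- ifelse(sig & cmp(results$log2_fold_change, lf),
                         "sperm_enriched",
                  ifelse(sig & cmp(-results$log2_fold_change, lf),
                         "oocyte_enriched", "ns"))
  results
}
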