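#' Build the binding-frequency matrix for clustering
#'
#' For each target RNA and FBF sample: reads-per-million, minus the mean
#' of the no-antibody controls for that gene, clamped at zero, then
#' `log2(x + 1)`. Rows whose underlying RPM is zero in every FBF sample
#' are dropped and reported (ncRNAs can acquire peaks yet have no
#' reads-per-gene, because peak assignment gives ncRNAs priority while
#' ambiguous reads are discarded from counting).
#'
#' @param rpm numeric RPM matrix (genes x FBF samples).
#' @param control_rpm_mean per-gene mean control RPM (named).
#' @param targets gene ids to include (rows).
#' @return matrix of class `binding_matrix` with attribute `dropped`
#'   (gene ids removed for having no reads-per-gene).
#' @export
build_binding_matrix <- function(rpm, control_rpm_mean, targets) {
  missing <- setdiff(targets, rownames(rpm))
  targets2 <- intersect(targets, rownames(rpm))
  m <- rpm[targets2, , drop = FALSE]
  allzero <- rowSums(m) == 0
  dropped <- c(missing, targets2[allzero])
  m <- m[!allzero, , drop = FALSE]
  ctrl <- control_rpm_mean[rownames(m)]
  ctrl[is.na(ctrl)] <- 0
  v <- log2(pmax(m - ctrl, 0) + 1)
  structure(v, dropped = dropped, class = c("binding_matrix", class(v)))
}

#' Cluster RNAs into binding blocks
#'
#' Agglomerative clustering with unweighted average linkage on Euclidean
#' distances between the rows of the binding matrix, cut into `k` flat
#' clusters. The cluster with the lowest overall binding is the residual
#' (`none`); the remaining clusters are labelled I--IV (then V, ... if
#' `k > 5`) in descending order of their mean spermatogenic-minus-oogenic
#' value, so block I is the most spermatogenic-enriched and block IV the
#' most oogenic-enriched.
#'
#' @param matrix a `binding_matrix` (or plain matrix with rownames).
#' @param k number of flat clusters (default 5: four blocks + residual).
#' @param sperm_cols,oocyte_cols column indices (or names) of the
#'   spermatogenic and oogenic samples.
#' @param linkage linkage method passed to [stats::hclust()] (default
#'   `"average"`; `"single"`/`"complete"` available).
#' @return list of class `block_assignment`: `blocks` (named per-RNA
#'   labels), `dendrogram` (the hclust tree), `block_ratio` (per-block
#'   mean sperm-oocyte difference, sorted), `provenance` (per-RNA,
#'   `"clustered"` or `"manual"`).
#' @export
cluster_rnas <- function(matrix, k = 5, sperm_cols, oocyte_cols,
                         linkage = "average") {
  if (k > nrow(matrix)) stopf("k = %d exceeds %d rows", k, nrow(matrix))
  hc <- stats::hclust(stats::dist(matrix, method = "euclidean"),
                      method = linkage)
  cl <- stats::cutree(hc, k = k)
  ratio <- vapply(seq_len(k), function(j) {
    rows <- matrix[cl == j, , drop = FALSE]
    mean(rows[, sperm_cols]) - mean(rows[, oocyte_cols])
  }, numeric(1))
  level <- vapply(seq_len(k), function(j)
    mean(matrix[cl == j, , drop = FALSE]), numeric(1))
  residual <- which.min(level)
  ord <- order(-ratio[-residual])
  blocked <- setdiff(seq_len(k), residual)[ord]
  labels <- rep("none", k)
  labels[blocked] <- c("I", "II", "III", "IV", paste0("V", seq_len(max(k - 5, 0))))[seq_along(blocked)]
  blocks <- setNames(labels[cl], rownames(matrix))
  structure(list(blocks = blocks, dendrogram = hc,
                 block_ratio = setNames(ratio, labels),
                 provenance = setNames(rep("clustered", length(blocks)),
                                       names(blocks))),
            class = "block_assignment")
}

#' Manually reassign an RNA to a block
#'
#' Mirrors the analyst workflow in which an outlier RNA evident in the PCA
#' projection is moved into the block it plainly belongs to; the
#' reassignment is recorded with `"manual"` provenance.
#'
#' @param assignment a `block_assignment`.
#' @param gene_id RNA to move (must be present).
#' @param block target label (`"I"`..`"IV"` or `"none"`).
#' @return the updated assignment.
#' @export
override_block <- function(assignment, gene_id, block) {
  if (!gene_id %in% names(assignment$blocks))
    stopf("unknown gene: %s", gene_id)
  assignment$blocks[gene_id] <- block
  assignment$provenance[gene_id] <- "manual"
  assignment
}

#' PCA projection of the binding matrix
#'
#' Column-centred principal component analysis over RNAs (rows). For a
#' deterministic orientation, each component's loading vector is flipped
#' so that its coefficients sum to a non-negative value. On FBF binding
#' matrices the first component tracks the overall binding frequency of
#' an RNA and the second the spermatogenic/oogenic ratio.
#'
#' @param matrix a `binding_matrix` (>= 3 rows, non-constant).
#' @return list of class `binding_pca`: `scores` (rows x PC1/PC2),
#'   `explained` (variance fractions), `rotation`.
#' @export
pca_projection <- function(matrix) {
  if (nrow(matrix) < 3) stopf("need >= 3 rows for PCA")
  if (stats::sd(as.vector(matrix)) == 0)
    stopf("constant matrix: principal components undefined")
  pc <- stats::prcomp(matrix, center = TRUE, scale. = FALSE)
  flip <- ifelse(colSums(pc$rotation) < 0, -1, 1)
  rot <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  explained <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = scores[, 1:2, drop = FALSE],
                 explained = explained[1:2], rotation = rot),
            class = "binding_pca")
}

#' Pare down a block to its strongest candidates
#'
#' Keeps RNAs whose highest peak is at least modestly high (25 reads per
#' million by default) and contains a canonical FBE. RNAs without any
#' called peak are excluded.
#'
#' @param block_rnas gene ids in the block.
#' @param peaks an `fbf_peaks` table (with `gene_id`, `height_rpm` and the
#'   summit-window FBE count `n_fbe_summit`).
#' @param min_rpm inclusive per-million height threshold (default 25).
#' @return character vector of retained gene ids.
#' @export
filter_block_candidates <- function(block_rnas, peaks, min_rpm = 25) {
  keep <- character(0)
  for (g in block_rnas) {
    pk <- peaks[peaks$gene_id == g, , drop = FALSE]
    if (nrow(pk) == 0) next
    top <- pk[which.max(pk$height_rpm), ]
    if (top$height_rpm >= min_rpm && !is.na(top$n_fbe_summit) &&
        top$n_fbe_summit >= 1)
      keep <- c(keep, g)
  }
  keep
}
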