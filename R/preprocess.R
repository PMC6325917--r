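#' Raw iCLIP read layout
#'
#' Describes how a raw read is put together: a sample barcode, then a random
#' molecular tag (UMI), then the insert, then the 3' linker (and possibly
#' the reverse-transcription primer). Demultiplexing strips all of these and
#' moves the UMI into the read name.
#'
#' @param sample_barcode_length barcode length in nt.
#' @param umi_length UMI length in nt.
#' @param three_prime_linker linker sequence to clip from the 3' end.
#' @param rt_primer reverse-transcription primer sequence to clip.
#' @return list of class `read_layout`.
#' @export
read_layout <- function(sample_barcode_length = 4L, umi_length = 9L,
                        three_prime_linker = "AGATCGGAAGAGC",
                        rt_primer = "") {
  if (sample_barcode_length < 0 || umi_length < 0)
    stopf("lengths must be >= 0")
  for (s in c(three_prime_linker, rt_primer))
    if (nchar(s) > 0 && grepl("[^ACGTN]", s))
      stopf("linker/primer may contain only ACGTN")
  structure(list(sample_barcode_length = as.integer(sample_barcode_length),
                 umi_length = as.integer(umi_length),
                 three_prime_linker = three_prime_linker,
                 rt_primer = rt_primer),
            class = "read_layout")
}

#' Demultiplex raw reads and move the UMI into the read name
#'
#' Splits a raw read stream by exact sample barcode match, strips barcode
#' and UMI from the sequence, clips the 3' linker and RT primer, and appends
#' the UMI to the read name after an underscore. Reads whose leading bases
#' match no barcode are routed to an `undetermined` stream; counts are
#' conserved (assigned + undetermined = input).
#'
#' @param reads data frame with columns `name` and `seq` (or a named
#'   character vector of sequences).
#' @param layout a [read_layout()].
#' @param barcode_table named character vector `barcode -> sample` (names
#'   are barcodes) or a character vector of barcodes (samples named after
#'   them). Barcodes must be mutually distinct at Hamming distance >= 2.
#' @param allow_mismatch if `TRUE`, rescue reads whose barcode is within
#'   Hamming distance 1 of exactly one table entry (default off: exact
#'   match only).
#' @return list with `samples` (named list of data frames `name`, `seq`)
#'   and `undetermined` (data frame).
#' @export
demultiplex_and_extract <- function(reads, layout, barcode_table,
                                    allow_mismatch = FALSE) {
  if (!is.data.frame(reads))
    reads <- data.frame(name = names(reads) %||% paste0("read", seq_along(reads)),
                        seq = unname(as.character(reads)), stringsAsFactors = FALSE)
  if (is.null(names(barcode_table)))
    barcode_table <- setNames(barcode_table, barcode_table)
  bcs <- names(barcode_table)
  if (anyDuplicated(bcs)) stopf("ambiguous barcode table: duplicate barcodes")
  if (any(nchar(bcs) != layout$sample_barcode_length))
    stopf("barcodes must have length %d", layout$sample_barcode_length)
  if (length(bcs) > 1) {
    for (i in seq_along(bcs)[-1])
      if (any(hamming(bcs[i], bcs[seq_len(i - 1)]) < 2))
        stopf("barcodes must be mutually distinct at Hamming distance >= 2")
  }

  bl <- layout$sample_barcode_length
  ul <- layout$umi_length
  obs <- substr(reads$seq, 1L, bl)
  hit <- match(obs, bcs)
  if (allow_mismatch && anyNA(hit)) {
    for (i in which(is.na(hit))) {
      d <- hamming(obs[i], bcs)
      if (sum(d <= 1) == 1) hit[i] <- which(d <= 1)
    }
  }

  umi <- substr(reads$seq, bl + 1L, bl + ul)
  insert <- substr(reads$seq, bl + ul + 1L, nchar(reads$seq))
  insert <- clip_adapter(insert, layout$three_prime_linker)
  insert <- clip_adapter(insert, layout$rt_primer)

  samples <- lapply(seq_along(bcs), function(k) {
    sel <- which(!is.na(hit) & hit == k)
    nm <- if (length(sel)) paste0(reads$name[sel], "_", umi[sel])
          else character(0)
    data.frame(name = nm, seq = insert[sel], stringsAsFactors = FALSE)
  })
  names(samples) <- unname(barcode_table)
  undet <- reads[is.na(hit), , drop = FALSE]
  rownames(undet) <- NULL
  list(samples = samples, undetermined = undet)
}

# Truncate each sequence at the first occurrence of `adapter` (exact match).
clip_adapter <- function(seqs, adapter) {
  if (is.null(adapter) || nchar(adapter) == 0) return(seqs)
  pos <- regexpr(adapter, seqs, fixed = TRUE)
  found <- pos > 0
  seqs[found] <- substr(seqs[found], 1L, pos[found] - 1L)
  seqs
}

#' Collapse PCR duplicates with error-tolerant (directional) UMI clustering
#'
#' Groups aligned reads by (chromosome, strand, start) -- the 5' alignment
#' end is the molecular signature in iCLIP -- and clusters the UMIs within
#' each group by the directional rule: a UMI `u` absorbs `v` when their
#' Hamming distance is 1 and `count(u) >= 2 * count(v) - 1`, expanding
#' transitively from the highest-count seed (ties broken by lexicographic
#' UMI order). One representative read per cluster survives.
#'
#' The representative row's `n_reads` is the number of reads that carried
#' the representative UMI itself; the full cluster total is reported in
#' `cluster_reads`. Under this bookkeeping collapsing is idempotent. If the
#' input already has an `n_reads` column it is honoured as multiplicity.
#'
#' @param reads data frame with columns `chromosome`, `strand`, `start`,
#'   `umi` (additional columns are carried through on the representative
#'   row); rows with a missing/empty UMI are dropped with a warning.
#' @param count_threshold multiplier in the directional condition
#'   (`count(u) >= count_threshold * count(v) - 1`); default 2.
#' @return data frame (one row per inferred molecule) with `n_reads` and
#'   `cluster_reads` columns, sorted by chromosome, strand, start, UMI.
#' @export
collapse_duplicates <- function(reads, count_threshold = 2) {
  stopifnot(all(c("chromosome", "strand", "start", "umi") %in% names(reads)))
  bad <- is.na(reads$umi) | reads$umi == ""
  if (any(bad)) {
    warning(sprintf("dropping %d reads with missing UMIs", sum(bad)))
    reads <- reads[!bad, , drop = FALSE]
  }
  if (nrow(reads) == 0) {
    out <- reads
    out$n_reads <- integer(0); out$cluster_reads <- integer(0)
    return(out)
  }
  mult <- if ("n_reads" %in% names(reads)) reads$n_reads else rep(1L, nrow(reads))

  dt <- data.table::data.table(row = seq_len(nrow(reads)),
                               chromosome = reads$chromosome,
                               strand = reads$strand, start = reads$start,
                               umi = reads$umi, mult = mult)
  # aggregate identical (position, UMI) first; positions with a single
  # distinct UMI need no clustering
  agg <- dt[, list(mult = sum(mult), row = row[1]),
            by = list(chromosome, strand, start, umi)]
  agg[, n_umis := .N, by = list(chromosome, strand, start)]
  simple <- agg[agg$n_umis == 1L]
  res1 <- data.table::data.table(row = simple$row,
                                 n_reads = as.integer(simple$mult),
                                 cluster_reads = as.integer(simple$mult))
  multi <- agg[agg$n_umis > 1L]
  res2 <- NULL
  if (nrow(multi)) {
    cm_all <- matrix(unlist(strsplit(multi$umi, "", fixed = TRUE)),
                     nrow = nrow(multi), byrow = TRUE)
    key <- paste(multi$chromosome, multi$strand, multi$start)
    groups <- split(seq_len(nrow(multi)), key)
    parts <- lapply(groups, function(ix)
      collapse_group_codes(cm_all[ix, , drop = FALSE],
                           as.integer(multi$mult[ix]), multi$umi[ix],
                           multi$row[ix], count_threshold))
    res2 <- data.table::data.table(
      row = unlist(lapply(parts, `[[`, "row"), use.names = FALSE),
      n_reads = unlist(lapply(parts, `[[`, "n_reads"), use.names = FALSE),
      cluster_reads = unlist(lapply(parts, `[[`, "cluster_reads"),
                             use.names = FALSE))
  }
  res <- rbind(res1, res2)
  out <- reads[res$row, setdiff(names(reads), c("n_reads", "cluster_reads")),
               drop = FALSE]
  out$n_reads <- res$n_reads
  out$cluster_reads <- res$cluster_reads
  ord <- order(out$chromosome, out$strand, out$start, out$umi)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Directional clustering of one position group (string interface; used
# for standalone calls and small inputs).
collapse_group <- function(umis, mult, rows, count_threshold = 2) {
  counts <- tapply(mult, umis, sum)
  uu <- names(counts)
  cm <- matrix(unlist(strsplit(uu, "", fixed = TRUE)), nrow = length(uu),
               byrow = TRUE)
  collapse_group_codes(cm, as.integer(counts), uu, rows[match(uu, umis)],
                       count_threshold)
}

# Core directional clustering over one position group's distinct UMIs,
# given their character matrix, counts, strings and source row indices.
collapse_group_codes <- function(cm, counts, uu, rows, count_threshold = 2) {
  n <- length(uu)
  if (n == 1L)
    return(list(row = rows, n_reads = counts, cluster_reads = counts))
  ord <- order(-counts, uu)
  uu <- uu[ord]; counts <- counts[ord]; rows <- rows[ord]
  cm <- cm[ord, , drop = FALSE]
  cluster <- rep(NA_integer_, n)
  n_clust <- 0L
  for (s in seq_len(n)) {
    if (!is.na(cluster[s])) next
    n_clust <- n_clust + 1L
    cluster[s] <- n_clust
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (u in frontier) {
        cand <- which(is.na(cluster))
        if (!length(cand)) break
        d <- rowSums(cm[cand, , drop = FALSE] !=
                     matrix(cm[u, ], length(cand), ncol(cm), byrow = TRUE))
        ok <- cand[d == 1 & counts[u] >= count_threshold * counts[cand] - 1]
        if (length(ok)) { cluster[ok] <- n_clust; nxt <- c(nxt, ok) }
      }
      frontier <- nxt
    }
  }
  rep_idx <- vapply(seq_len(n_clust), function(k) min(which(cluster == k)),
                    integer(1))
  list(row = rows[rep_idx],
       n_reads = counts[rep_idx],
       cluster_reads = as.integer(
         tapply(counts, cluster, sum)[as.character(seq_len(n_clust))]))
}
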