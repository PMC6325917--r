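#' Strand-aware read coverage track
#'
#' @param reads data frame with `chromosome`, `strand`, `start`, `end`.
#' @param seqlengths named integer vector of chromosome lengths.
#' @return list of class `coverage_track`: integer coverage vectors keyed
#'   `"chrom|strand"`, with attribute `library_size` (number of reads).
#' @export
build_coverage <- function(reads, seqlengths) {
  keys <- unique(paste(reads$chromosome, reads$strand, sep = "|"))
  cov <- lapply(keys, function(k) {
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    sel <- reads$chromosome == p[1] & reads$strand == p[2]
    as.integer(IRanges::coverage(
      IRanges::IRanges(reads$start[sel], reads$end[sel]),
      width = seqlengths[[p[1]]]))
  })
  names(cov) <- keys
  structure(cov, library_size = nrow(reads), seqlengths = seqlengths,
            class = "coverage_track")
}

#' Candidate peak detection
#'
#' Finds maximal runs of coverage at or above `min_height_raw`; each run
#' contributes one summit at its coverage argmax (leftmost position on
#' ties). Summits closer than `merge_distance` bp on the same strand are
#' merged, keeping the higher summit (leftmost on ties).
#'
#' @param track a [build_coverage()] track.
#' @param min_height_raw minimum raw coverage for a candidate (>= 1).
#' @param merge_distance merge radius in bp (default 50).
#' @return data frame: `chromosome`, `strand`, `summit`, `summit_height`.
#' @export
find_candidate_peaks <- function(track, min_height_raw = 5,
                                 merge_distance = 50L) {
  stopifnot(min_height_raw >= 1)
  out <- list()
  for (k in names(track)) {
    cov <- track[[k]]
    p <- strsplit(k, "|", fixed = TRUE)[[1]]
    r <- rle(cov >= min_height_raw)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    if (!length(runs)) next
    summits <- vapply(runs, function(j) {
      a <- starts[j]; b <- ends[j]
      a + which.max(cov[a:b]) - 1L
    }, integer(1))
    heights <- cov[summits]
    # merge close summits, keeping the higher (leftmost on ties)
    keep <- merge_summits(summits, heights, merge_distance)
    out[[k]] <- data.frame(chromosome = p[1], strand = p[2],
                           summit = summits[keep],
                           summit_height = heights[keep],
                           stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(chromosome = character(), strand = character(),
                      summit = integer(), summit_height = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chromosome, res$strand, res$summit), , drop = FALSE]
}

# Greedy left-to-right grouping: summits whose neighbour gap is below
# merge_distance join a group; the group's winner is the maximum height,
# leftmost on ties. Summits assumed sorted ascending.
merge_summits <- function(summits, heights, merge_distance) {
  if (length(summits) <= 1) return(seq_along(summits))
  grp <- cumsum(c(1L, as.integer(diff(summits) >= merge_distance)))
  keep <- tapply(seq_along(summits), grp, function(ix)
    ix[which.max(heights[ix])])
  sort(as.integer(keep))
}

#' Fit the Gaussian control null for one peak window
#'
#' Tiles the 500-bp window around a candidate peak into disjoint 50-bp
#' bins; a bin's height is the number of control reads whose start lies in
#' the bin, scaled to per-million by that replicate's library size. Bin
#' heights are pooled over all control replicates and summarised by their
#' sample mean and (n-1) standard deviation.
#'
#' @param controls list of control read data frames (one per replicate).
#' @param chromosome,strand window location.
#' @param window_start,window_end window interval (clipped windows give
#'   proportionally truncated bins; `n_bins` records how many were used).
#' @param library_sizes per-replicate control library sizes; defaults to
#'   `nrow` of each replicate.
#' @param bin_width bin width in bp (default 50).
#' @return list of class `gaussian_null`: `mu`, `sigma`, `n_bins`,
#'   `heights` (the pooled per-million bin heights).
#' @export
fit_control_null <- function(controls, chromosome, strand,
                             window_start, window_end,
                             library_sizes = NULL, bin_width = 50L) {
  if (is.data.frame(controls)) controls <- list(controls)
  if (is.null(library_sizes))
    library_sizes <- vapply(controls, nrow, integer(1))
  edges <- bin_edges(window_start, window_end, bin_width)
  nb <- length(edges) - 1L
  heights <- numeric(0)
  for (r in seq_along(controls)) {
    rd <- controls[[r]]
    sel <- rd$chromosome == chromosome & rd$strand == strand &
           rd$start >= window_start & rd$start <= window_end
    cnt <- tabulate(findInterval(rd$start[sel], edges), nbins = nb)
    heights <- c(heights, cnt * 1e6 / library_sizes[r])
  }
  structure(list(mu = mean(heights),
                 sigma = if (length(heights) > 1) stats::sd(heights) else 0,
                 n_bins = nb, heights = heights),
            class = "gaussian_null")
}

#' Peak p-value under the Gaussian control null
#'
#' The chance of observing a bin height at least this large from the
#' no-antibody control: the upper-tail probability of
#' `Normal(mu, max(sigma, sigma_floor))` at `height_rpm`.
#'
#' @param height_rpm per-million peak-bin height.
#' @param null a [fit_control_null()] object (or list with `mu`, `sigma`).
#' @param sigma_floor positive lower bound on sigma (per-million units),
#'   guarding against degenerate all-zero controls.
#' @return upper-tail p-value.
#' @export
peak_pvalue <- function(height_rpm, null, sigma_floor) {
  stopifnot(sigma_floor > 0)
  stats::pnorm(height_rpm, mean = null$mu,
               sd = max(null$sigma, sigma_floor), lower.tail = FALSE)
}

#' Benjamini-Hochberg correction and the two reads-in-peak cutoffs
#'
#' Adjusts all candidate p-values of the dataset by the BH step-up
#' procedure, then keeps peaks that pass the FDR cutoff AND both ratio
#' cutoffs: per-million height at least `rpm_ratio_min` times the matched
#' control per-million height, and raw height at least `raw_ratio_min`
#' times the matched raw control count. A one-read pseudocount (`eps_raw`,
#' `eps_rpm`) keeps zero-control peaks testable.
#'
#' @param peaks data frame with `p_value`, `height_rpm`, `height_raw`,
#'   `control_rpm`, `control_raw`.
#' @param fdr FDR cutoff (default 0.01).
#' @param rpm_ratio_min per-million ratio cutoff (default 2, "twofold").
#' @param raw_ratio_min raw ratio cutoff (default 10, "tenfold").
#' @param eps_raw,eps_rpm pseudocounts: the one-read equivalent on each
#'   scale.
#' @return the surviving peaks, with a `p_adjusted` column (computed over
#'   ALL input candidates before filtering).
#' @export
adjust_and_filter <- function(peaks, fdr = 0.01, rpm_ratio_min = 2,
                              raw_ratio_min = 10, eps_raw = 1,
                              eps_rpm = 1) {
  if (nrow(peaks) == 0) {
    peaks$p_adjusted <- numeric(0)
    return(peaks)
  }
  peaks$p_adjusted <- stats::p.adjust(peaks$p_value, method = "BH")
  keep <- peaks$p_adjusted <= fdr &
    peaks$height_rpm >= rpm_ratio_min * pmax(peaks$control_rpm, eps_rpm) &
    peaks$height_raw >= raw_ratio_min * pmax(peaks$control_raw, eps_raw)
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Call FBF binding peaks against the no-antibody control
#'
#' The full peak-calling route: candidate detection on pooled FBF
#' coverage, 50-bp binning of the 500-bp window around each candidate, a
#' per-window Gaussian null fit to the pooled control replicates,
#' Benjamini-Hochberg control at `fdr`, the two reads-in-peak ratio
#' cutoffs, gene assignment with ncRNA priority, FBE annotation of the
#' window sequence, and ranking by per-million height (ties broken by
#' leftmost coordinate).
#'
#' @param fbf_reads deduplicated FBF reads: a data frame or list of
#'   replicate data frames (pooled for calling).
#' @param control_reads deduplicated no-antibody reads: data frame or list
#'   of replicates (kept separate for the per-million null).
#' @param annotation a `gene_annotation` (supplies chromosome lengths).
#' @param genome named list of chromosome sequences, for FBE annotation
#'   (optional: `NULL` skips sequence annotation).
#' @param min_height_raw candidate threshold in raw reads (default 5).
#' @param fdr,rpm_ratio_min,raw_ratio_min see [adjust_and_filter()].
#' @param sigma_floor Gaussian sigma floor; default one read per million
#'   of the smallest control library.
#' @param window_size,bin_width window and bin geometry (defaults 500/50).
#' @param summit_flank half-width of the summit sub-window used for the
#'   per-peak FBE statistic (default 25 nt).
#' @return data frame of class `fbf_peaks`, one row per significant peak.
#' @export
call_peaks <- function(fbf_reads, control_reads, annotation, genome = NULL,
                       min_height_raw = 5, fdr = 0.01, rpm_ratio_min = 2,
                       raw_ratio_min = 10, sigma_floor = NULL,
                       window_size = 500L, bin_width = 50L,
                       summit_flank = 25L) {
  if (is.data.frame(fbf_reads)) fbf_reads <- list(fbf_reads)
  if (is.data.frame(control_reads)) control_reads <- list(control_reads)
  fbf <- do.call(rbind, lapply(fbf_reads, function(d)
    d[, c("chromosome", "strand", "start", "end")]))
  ctrl_libs <- vapply(control_reads, nrow, integer(1))
  fbf_lib <- nrow(fbf)
  seqlengths <- attr(annotation, "seqlengths")
  if (is.null(sigma_floor)) sigma_floor <- 1e6 / max(min(ctrl_libs), 1)

  track <- build_coverage(fbf, seqlengths)
  cand <- find_candidate_peaks(track, min_height_raw = min_height_raw,
                               merge_distance = bin_width)
  if (nrow(cand) == 0) return(empty_peaks())

  n <- nrow(cand)
  # the 50-bp test bin is centred on the summit; the 500-bp window tiles
  # five bins either side of it (bins truncated at chromosome edges)
  n_flank <- (window_size %/% bin_width - 1L) %/% 2L
  cand$bin_start <- pmax(cand$summit - bin_width %/% 2L, 1L)
  cand$bin_end <- pmin(cand$bin_start + bin_width - 1L,
                       seqlengths[cand$chromosome])
  cand$window_start <- pmax(cand$bin_start - n_flank * bin_width, 1L)
  cand$window_end <- pmin(cand$bin_start + (n_flank + 1L) * bin_width +
                          (window_size - (2L * n_flank + 1L) * bin_width) - 1L,
                          seqlengths[cand$chromosome])

  fbf_idx <- start_index(fbf)
  ctrl_idx <- lapply(control_reads, start_index)
  keys <- paste(cand$chromosome, cand$strand, sep = "|")
  cand$height_raw <- vapply(seq_len(n), function(i)
    count_in(fbf_idx[[keys[i]]], cand$bin_start[i], cand$bin_end[i]),
    numeric(1))
  cand$height_rpm <- cand$height_raw * 1e6 / fbf_lib
  cand$control_raw <- vapply(seq_len(n), function(i)
    sum(vapply(ctrl_idx, function(ix)
      count_in(ix[[keys[i]]], cand$bin_start[i], cand$bin_end[i]),
      numeric(1))), numeric(1))
  cand$control_rpm <- cand$control_raw * 1e6 / sum(ctrl_libs)

  nulls <- lapply(seq_len(n), function(i) {
    edges <- bin_edges(cand$window_start[i], cand$window_end[i], bin_width)
    heights <- unlist(lapply(seq_along(ctrl_idx), function(r) {
      cnt <- diff(vapply(edges, function(e)
        count_below(ctrl_idx[[r]][[keys[i]]], e), numeric(1)))
      cnt * 1e6 / ctrl_libs[r]
    }))
    list(mu = mean(heights),
         sigma = if (length(heights) > 1) stats::sd(heights) else 0,
         n_bins = length(edges) - 1L)
  })
  cand$mu <- vapply(nulls, `[[`, numeric(1), "mu")
  cand$sigma <- vapply(nulls, `[[`, numeric(1), "sigma")
  cand$n_bins <- vapply(nulls, `[[`, numeric(1), "n_bins")
  cand$p_value <- vapply(seq_len(n), function(i)
    peak_pvalue(cand$height_rpm[i], nulls[[i]], sigma_floor), numeric(1))

  peaks <- adjust_and_filter(cand, fdr = fdr, rpm_ratio_min = rpm_ratio_min,
                             raw_ratio_min = raw_ratio_min,
                             eps_raw = 1, eps_rpm = 1e6 / sum(ctrl_libs))
  if (nrow(peaks) == 0) return(empty_peaks())

  # gene assignment (ncRNA priority) on the summit bin
  peaks$gene_id <- assign_read_to_gene(
    data.frame(chromosome = peaks$chromosome, strand = peaks$strand,
               start = peaks$bin_start, end = peaks$bin_end),
    annotation, mode = "peak_assignment")

  # FBE annotation of the window and of the summit sub-window
  if (!is.null(genome)) {
    window_seq <- vapply(seq_len(nrow(peaks)), function(i)
      fetch_seq(genome, peaks$chromosome[i], peaks$strand[i],
                peaks$window_start[i], peaks$window_end[i]), character(1))
    ss <- pmax(peaks$summit - summit_flank, 1L)
    se <- pmin(peaks$summit + summit_flank, seqlengths[peaks$chromosome])
    summit_seq <- vapply(seq_len(nrow(peaks)), function(i)
      fetch_seq(genome, peaks$chromosome[i], peaks$strand[i], ss[i], se[i]),
      character(1))
    peaks$n_fbe <- vapply(window_seq, function(s) nrow(scan_fbe(s)),
                          numeric(1), USE.NAMES = FALSE)
    peaks$n_fbe_summit <- vapply(summit_seq, function(s) nrow(scan_fbe(s)),
                                 numeric(1), USE.NAMES = FALSE)
  } else {
    peaks$n_fbe <- NA_real_
    peaks$n_fbe_summit <- NA_real_
  }

  ord <- order(-peaks$height_rpm, peaks$chromosome, peaks$window_start)
  peaks$rank <- NA_integer_
  peaks$rank[ord] <- seq_len(nrow(peaks))
  peaks <- peaks[order(peaks$rank), , drop = FALSE]
  rownames(peaks) <- NULL
  class(peaks) <- c("fbf_peaks", "data.frame")
  peaks
}

# Sorted read-start positions split by "chrom|strand", for O(log n)
# interval counting via binary search.
start_index <- function(reads) {
  lapply(split(reads$start, paste(reads$chromosome, reads$strand, sep = "|")),
         sort)
}

# number of sorted positions x with a <= x <= b
count_in <- function(x, a, b) {
  if (is.null(x)) return(0)
  findInterval(b, x) - findInterval(a - 1L, x)
}

# number of sorted positions strictly below e
count_below <- function(x, e) {
  if (is.null(x)) return(0)
  findInterval(e - 1L, x)
}

bin_edges <- function(window_start, window_end, bin_width) {
  edges <- seq(window_start, window_end + 1L, by = bin_width)
  if (edges[length(edges)] != window_end + 1L)
    edges <- c(edges, window_end + 1L)
  edges
}

# Sequence of [start, end] on the sense strand: reverse-complemented for
# minus-strand features.
fetch_seq <- function(genome, chromosome, strand, start, end) {
  s <- substr(genome[[chromosome]], start, end)
  if (strand == "-")
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  s
}

empty_peaks <- function() {
  structure(data.frame(chromosome = character(), strand = character(),
                       summit = integer(), summit_height = integer(),
                       window_start = integer(), window_end = integer(),
                       bin_start = integer(), bin_end = integer(),
                       height_raw = numeric(), height_rpm = numeric(),
                       control_raw = numeric(), control_rpm = numeric(),
                       mu = numeric(), sigma = numeric(), n_bins = numeric(),
                       p_value = numeric(), p_adjusted = numeric(),
                       gene_id = character(), n_fbe = numeric(),
                       n_fbe_summit = numeric(), rank = integer(),
                       stringsAsFactors = FALSE),
            class = c("fbf_peaks", "data.frame"))
}
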