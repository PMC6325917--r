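# FBF binding element (FBE) definitions, on the RNA sense strand:
#   canonical          UGUNNNAU  (octamer)
#   relaxed "optimal"  UGUDHHAU  (D = A/U/G, H = A/U/C)
#   strict  "optimal"  an upstream C followed by UGURCCAUR (R = A/G)
# Cytosines one or two positions upstream (-1C / -2C) enhance affinity.

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

#' Scan a sequence for FBF binding elements
#'
#' Reports every canonical FBE octamer (UGUNNNAU) on the given sequence
#' (sense strand only; T and U are equivalent), with classification flags
#' for the relaxed optimal form (UGUDHHAU), the strict optimal form (the
#' nonamer UGURCCAUR preceded by a cytosine), and affinity-enhancing
#' upstream cytosines at -1 / -2. Overlapping matches are all reported.
#'
#' @param sequence a single nucleotide string (case-insensitive, DNA or
#'   RNA alphabet; IUPAC ambiguity letters are tolerated but never match).
#' @return data frame of class `fbe_matches`, sorted by `start` (1-based
#'   offset in the scanned sequence): `start`, `octamer` (RNA alphabet),
#'   `is_canonical`, `is_relaxed_optimal`, `is_strict_optimal`, `minus1C`,
#'   `minus2C`.
#' @export
scan_fbe <- function(sequence) {
  stopifnot(length(sequence) == 1)
  s <- chartr("T", "U", toupper(sequence))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  if (length(chars) && any(!chars %in% IUPAC_CHARS))
    stopf("sequence contains non-IUPAC characters: %s",
          paste(unique(chars[!chars %in% IUPAC_CHARS]), collapse = ""))
  n <- length(chars)
  empty <- data.frame(start = integer(), octamer = character(),
                      is_canonical = logical(), is_relaxed_optimal = logical(),
                      is_strict_optimal = logical(), minus1C = logical(),
                      minus2C = logical(), stringsAsFactors = FALSE)
  class(empty) <- c("fbe_matches", "data.frame")
  if (n < 8) return(empty)

  i <- seq_len(n - 7L)
  hit <- chars[i] == "U" & chars[i + 1] == "G" & chars[i + 2] == "U" &
         chars[i + 6] == "A" & chars[i + 7] == "U" &
         chars[i + 3] %in% c("A", "C", "G", "U") &
         chars[i + 4] %in% c("A", "C", "G", "U") &
         chars[i + 5] %in% c("A", "C", "G", "U")
  i <- i[hit]
  if (!length(i)) return(empty)

  D <- c("A", "U", "G"); H <- c("A", "U", "C"); R <- c("A", "G")
  relaxed <- chars[i + 3] %in% D & chars[i + 4] %in% H & chars[i + 5] %in% H
  minus1C <- i > 1 & chars[pmax(i - 1, 1)] == "C"
  minus2C <- i > 2 & chars[pmax(i - 2, 1)] == "C"
  nonamer <- chars[i + 3] %in% R & chars[i + 4] == "C" & chars[i + 5] == "C" &
             i + 8 <= n & chars[pmin(i + 8, n)] %in% R
  strict <- nonamer & minus1C

  out <- data.frame(start = i,
                    octamer = substring(s, i, i + 7L),
                    is_canonical = TRUE,
                    is_relaxed_optimal = relaxed,
                    is_strict_optimal = strict,
                    minus1C = minus1C, minus2C = minus2C,
                    stringsAsFactors = FALSE)
  class(out) <- c("fbe_matches", "data.frame")
  out
}

#' Fraction of peaks containing a canonical FBE
#'
#' @param peaks a peak table carrying per-peak canonical-FBE counts
#'   (column `n_fbe`, as produced by [call_peaks()]) and a `rank` column.
#' @param top_n restrict to the `top_n` highest-ranked peaks (e.g. 500), or
#'   `NULL` for all peaks. If `top_n` exceeds the number of peaks, all are
#'   used (with a message).
#' @return fraction in `[0, 1]` (NA for an empty peak set).
#' @export
peak_fbe_fraction <- function(peaks, top_n = NULL) {
  if (nrow(peaks) == 0) return(NA_real_)
  sel <- peaks
  if (!is.null(top_n)) {
    if (top_n > nrow(peaks)) {
      message(sprintf("top_n = %d exceeds %d peaks; using all", top_n,
                      nrow(peaks)))
      top_n <- nrow(peaks)
    }
    sel <- peaks[order(peaks$rank), , drop = FALSE][seq_len(top_n), , drop = FALSE]
  }
  mean(sel$n_fbe >= 1)
}
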