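# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.datatable.aware <- TRUE

#' @importFrom stats setNames
NULL

# Deterministic sub-seed for a named stage, derived from a root seed.
# Kept well below .Machine$integer.max.
stage_seed <- function(root_seed, ...) {
  parts <- paste(c(...), collapse = "/")
  h <- 0L
  for (ch in utf8ToInt(parts)) h <- (h * 31L + ch) %% 1000003L
  (as.integer(root_seed) %% 1000000L) * 1009L + h
}

# Hamming distance between equal-length strings (vectorised over y).
hamming <- function(x, y) {
  xs <- strsplit(x, "", fixed = TRUE)[[1]]
  vapply(strsplit(y, "", fixed = TRUE),
         function(ys) sum(xs != ys), integer(1))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
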