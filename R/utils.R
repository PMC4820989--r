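#' @importFrom rlang abort warn .data %||%
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join anti_join bind_rows bind_cols distinct n count
#'   slice_max rename relocate across if_else row_number pull
#' @importFrom tibble tibble as_tibble
#' @importFrom stats pnorm sd median rbinom rmultinom runif setNames
NULL

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over character DNA sequences (A/C/G/T/N).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "GGA"))
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Derive reproducible child seeds from a master seed
#'
#' Stage- and replicate-level random streams are all derived from one master
#' seed so a whole run is reproducible from a single integer.
#'
#' @param master_seed Integer master seed.
#' @param n Number of child seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master_seed, n) {
  withr::with_seed(as.integer(master_seed),
                   sample.int(.Machine$integer.max - 1L, n))
}

# Row-wise multinomial draws: sizes[i] trials over probs[i, ] (columns = bins).
# Implemented as a chain of conditional binomials so it vectorises over rows.
rmultinom_rows <- function(sizes, probs) {
  stopifnot(length(sizes) == nrow(probs))
  k <- ncol(probs)
  out <- matrix(0L, nrow = length(sizes), ncol = k,
                dimnames = list(NULL, colnames(probs)))
  remaining <- as.integer(sizes)
  ptail <- rowSums(probs)
  for (j in seq_len(k - 1)) {
    pj <- ifelse(ptail > 0, pmin(1, pmax(0, probs[, j] / ptail)), 0)
    draw <- rbinom(length(remaining), remaining, pj)
    out[, j] <- draw
    remaining <- remaining - draw
    ptail <- ptail - probs[, j]
  }
  out[, k] <- remaining
  out
}

# substring() that tolerates zero-length index vectors.
substr_vec <- function(text, start, stop) {
  if (length(start) == 0 || length(text) == 0) return(character(0))
  substring(text, start, stop)
}

# Hamming distance between equal-length strings (vectorised over x).
hamming <- function(x, y) {
  stopifnot(length(y) == 1)
  xs <- strsplit(x, "", fixed = TRUE)
  yt <- strsplit(y, "", fixed = TRUE)[[1]]
  vapply(xs, function(ch) sum(ch != yt), integer(1))
}
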