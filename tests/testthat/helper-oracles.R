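# Independent brute-force oracles and fixture builders used across tests.
# These deliberately avoid the package's own vectorised code paths.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

oracle_classify <- function(pam) {
  b2 <- substr(pam, 2, 2)
  b3 <- substr(pam, 3, 3)
  if (b2 == "G" && b3 == "G") "NGG" else if (b2 == "G" && b3 == "A") "NGA"
  else "OTHER"
}

# Naive per-window scan over every position on both strands.
oracle_enumerate <- function(region_id, seq, spacer_len = 19,
                             pam_filter = c("NGG", "NGA", "OTHER")) {
  n <- nchar(seq)
  rows <- list()
  for (s in 0:max(n - 1, 0)) {
    if (s + spacer_len + 3 <= n) {
      pam <- substr(seq, s + spacer_len + 1, s + spacer_len + 3)
      cls <- oracle_classify(pam)
      if (cls %in% pam_filter) {
        rows[[length(rows) + 1]] <- data.frame(
          region_id = region_id, strand = "+", spacer_start = s,
          spacer_seq = substr(seq, s + 1, s + spacer_len), pam_seq = pam,
          pam_class = cls, last_base_pos = s + spacer_len - 1,
          third_last_pos = s + spacer_len - 3, stringsAsFactors = FALSE)
      }
    }
    if (s >= 3 && s + spacer_len <= n) {
      pam <- oracle_revcomp(substr(seq, s - 2, s))
      cls <- oracle_classify(pam)
      if (cls %in% pam_filter) {
        rows[[length(rows) + 1]] <- data.frame(
          region_id = region_id, strand = "-", spacer_start = s,
          spacer_seq = oracle_revcomp(substr(seq, s + 1, s + spacer_len)),
          pam_seq = pam, pam_class = cls, last_base_pos = s,
          third_last_pos = s + 2, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(region_id = character(0), strand = character(0),
                      spacer_start = integer(0), spacer_seq = character(0),
                      pam_seq = character(0), pam_class = character(0),
                      last_base_pos = integer(0),
                      third_last_pos = integer(0))
  }
  out[order(out$strand, out$spacer_start), , drop = FALSE]
}

# Direct per-center product of upper-tail probabilities.
oracle_scan <- function(last_base_pos, scores, region_length, mu, sigma,
                        window_size = 21) {
  hw <- (window_size - 1) / 2
  vapply(0:(region_length - 1), function(c) {
    in_win <- last_base_pos >= c - hw & last_base_pos <= c + hw
    if (!any(in_win)) return(0)
    p <- pmax(pnorm(scores[in_win], mu, sigma, lower.tail = FALSE), 1e-300)
    -log10(prod(p))
  }, numeric(1))
}

# Hamming distance between two equal-length strings.
oracle_hamming <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

write_fasta_lines <- function(records, path) {
  writeLines(unlist(lapply(names(records), function(id) {
    c(paste0(">", id), records[[id]])
  })), path)
  path
}

# Standard three-element truth used by the simulation-based properties:
# a central hairpin-like element (med/high on disruption) flanked by a
# 5' and a 3' processing element (low on disruption).
standard_truth <- function(region_len) {
  mid <- floor(region_len / 2)
  truth_elements(
    region_id = rep("locus", 3),
    start = c(mid - 45, mid - 260, mid + 180),
    end = c(mid + 45, mid - 200, mid + 240),
    element_class = c("mature_or_pre", "five_prime_hit", "three_prime_hit"),
    p_neg = c(0.05, 0.30, 0.30),
    p_low = c(0.10, 0.60, 0.60),
    p_med = c(0.35, 0.07, 0.07),
    p_high = c(0.50, 0.03, 0.03))
}

# One compact library -> screen -> mapping -> enrichment -> scan run.
sim_screen_run <- function(seed, region_len = 1500, truth = NULL,
                           replicates = 3, n_cells = 1e5, read_depth = 5e4,
                           n_fragments = 3000, clone_count = 5e4) {
  seeds <- chipperscan::derive_seeds(seed, 3)
  region <- chipperscan::random_region(region_len, seed = seeds[1],
                                       region_id = "locus")
  lib <- chipperscan::build_library(
    region,
    chipperscan::chipper_params(n_fragments = n_fragments,
                                clone_count = clone_count),
    seed = seeds[2])
  cfg <- chipperscan::screen_config(
    n_cells = n_cells, replicates = replicates, read_depth = read_depth,
    sequencing_error_rate = 0, seed = seeds[3])
  eff <- chipperscan::assign_effects(lib, truth, cfg)
  counts <- suppressWarnings(chipperscan::simulate_screen_counts(eff, cfg))
  ann <- chipperscan::map_spacers(unique(counts$spacer), region)
  ct <- dplyr::left_join(tibble::as_tibble(counts), ann, by = "spacer")
  enr <- chipperscan::enrichment_table(ct)
  scan <- chipperscan::scan_profile(enr, region)
  list(region = region, library = lib, truth = truth, counts = ct,
       enrichment = enr, scan = scan)
}
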