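#' Load input DNA regions from a FASTA file
#'
#' Reads a multi-record FASTA of input DNA regions (the pieces an sgRNA
#' library is built from). Sequences are uppercased; records containing
#' anything other than A/C/G/T are rejected with an error naming the record,
#' because the input regions are short curated sequences for which ambiguity
#' codes indicate a preparation problem rather than data to tolerate.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A tibble with columns `region_id` (first whitespace-delimited token
#'   of the header, unique), `name` (full header), `sequence` (uppercase
#'   A/C/G/T) and `length`.
#' @export
load_regions <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    abort(paste0("FASTA file not found: ", fasta_path))
  }
  dss <- Biostrings::readDNAStringSet(fasta_path)
  if (length(dss) == 0) {
    abort(paste0("No FASTA records in ", fasta_path))
  }
  headers <- names(dss)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    abort(paste0("Duplicate region id(s): ",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(dss))
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad)) {
    abort(paste0("Non-ACGT characters in region(s): ",
                 paste(ids[bad], collapse = ", ")))
  }
  tibble(region_id = ids, name = headers, sequence = unname(seqs),
         length = unname(nchar(seqs)))
}

#' Build a region table from bare sequences
#'
#' Convenience constructor used throughout the simulators and tests: turns a
#' named (or unnamed) character vector of sequences into the same tibble
#' [load_regions()] returns.
#'
#' @param sequences Character vector of A/C/G/T sequences; names become
#'   region ids (defaults to `region_1`, `region_2`, ...).
#' @return Region tibble (see [load_regions()]).
#' @export
region_table <- function(sequences) {
  seqs <- toupper(sequences)
  if (any(grepl("[^ACGT]", seqs))) abort("Sequences must contain only A/C/G/T.")
  ids <- names(sequences) %||% paste0("region_", seq_along(sequences))
  if (is.null(names(sequences))) names(ids) <- NULL
  tibble(region_id = ids, name = ids, sequence = unname(seqs),
         length = nchar(seqs))
}

#' Classify a 3-nt PAM sequence
#'
#' Only PAM bases 2 and 3 are inspected (the leading N is free):
#' `NGG` if both are G, `NGA` if G then A, otherwise `OTHER`. Classification
#' is exclusive and exhaustive; `NA` input yields `NA`.
#'
#' @param pam_seq Character vector of 3-nt PAM sequences.
#' @return Character vector over `{"NGG","NGA","OTHER"}` (or `NA`).
#' @export
#' @examples
#' classify_pam(c("AGG", "TGA", "GTG"))
classify_pam <- function(pam_seq) {
  b2 <- substr(pam_seq, 2, 2)
  b3 <- substr(pam_seq, 3, 3)
  dplyr::case_when(
    is.na(pam_seq) ~ NA_character_,
    b2 == "G" & b3 == "G" ~ "NGG",
    b2 == "G" & b3 == "A" ~ "NGA",
    TRUE ~ "OTHER"
  )
}

#' Enumerate all sgRNA target sites on input regions
#'
#' Scans both strands of every region for protospacers of `spacer_len` bases
#' followed immediately (3' on the protospacer strand) by a 3-nt PAM, both
#' contained entirely within the region. Coordinates are 0-based, half-open,
#' in the plus-strand frame: `spacer_start` is always the leftmost protospacer
#' base. `last_base_pos` / `third_last_pos` are the plus-frame coordinates of
#' the final / third-last base of the targeting domain, i.e. for plus-strand
#' sites `spacer_start + spacer_len - 1` / `- 3` and for minus-strand sites
#' `spacer_start` / `spacer_start + 2`.
#'
#' The expressed targeting domain is a leading G plus the protospacer
#' (`spacer_seq`); the leading G is implicit and not part of any coordinate.
#'
#' @param regions Region tibble (see [load_regions()]).
#' @param spacer_len Protospacer length in bases (default 19).
#' @param pam_filter Subset of `c("NGG","NGA","OTHER")` to keep.
#' @return A tibble of sites sorted by region (input order), strand (`+`
#'   before `-`) and `spacer_start`, with columns `region_id`, `strand`,
#'   `spacer_start`, `spacer_len`, `spacer_seq`, `pam_seq`, `pam_class`,
#'   `last_base_pos`, `third_last_pos`.
#' @export
enumerate_sites <- function(regions, spacer_len = 19,
                            pam_filter = c("NGG", "NGA", "OTHER")) {
  stopifnot(spacer_len >= 1)
  pam_filter <- match.arg(pam_filter, several.ok = TRUE)
  out <- purrr::map2(regions$region_id, regions$sequence,
                     enumerate_sites_one,
                     spacer_len = spacer_len, pam_filter = pam_filter)
  bind_rows(out)
}

enumerate_sites_one <- function(region_id, sequence, spacer_len, pam_filter) {
  n <- nchar(sequence)
  empty <- tibble(region_id = character(0), strand = character(0),
                  spacer_start = integer(0), spacer_len = integer(0),
                  spacer_seq = character(0), pam_seq = character(0),
                  pam_class = character(0), last_base_pos = integer(0),
                  third_last_pos = integer(0))
  if (n < spacer_len + 3) return(empty)
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]

  # plus strand: protospacer [s, s+L), PAM [s+L, s+L+3), 0-based s
  s_plus <- 0:(n - spacer_len - 3)
  p2 <- ch[s_plus + spacer_len + 2]   # PAM base 2 (0-based s+L+1)
  p3 <- ch[s_plus + spacer_len + 3]   # PAM base 3
  cls_plus <- ifelse(p2 == "G" & p3 == "G", "NGG",
                     ifelse(p2 == "G" & p3 == "A", "NGA", "OTHER"))
  keep <- cls_plus %in% pam_filter
  s_p <- s_plus[keep]
  plus <- tibble(
    region_id = region_id, strand = "+",
    spacer_start = s_p, spacer_len = spacer_len,
    spacer_seq = substr_vec(sequence, s_p + 1, s_p + spacer_len),
    pam_seq = substr_vec(sequence, s_p + spacer_len + 1, s_p + spacer_len + 3),
    pam_class = cls_plus[keep],
    last_base_pos = s_p + spacer_len - 1L,
    third_last_pos = s_p + spacer_len - 3L
  )

  # minus strand: protospacer plus-frame [s, s+L), PAM plus-frame [s-3, s);
  # pam_seq = revcomp(region[s-3, s)) so base 2 is complement of region[s-2].
  s_minus <- 3:(n - spacer_len)
  m2 <- ch[s_minus - 1]               # region base at 0-based s-2
  m3 <- ch[s_minus - 2]               # region base at 0-based s-3
  cls_minus <- ifelse(m2 == "C" & m3 == "C", "NGG",
                      ifelse(m2 == "C" & m3 == "T", "NGA", "OTHER"))
  keep <- cls_minus %in% pam_filter
  s_m <- s_minus[keep]
  minus <- tibble(
    region_id = region_id, strand = "-",
    spacer_start = s_m, spacer_len = spacer_len,
    spacer_seq = revcomp(substr_vec(sequence, s_m + 1, s_m + spacer_len)),
    pam_seq = revcomp(substr_vec(sequence, s_m - 2, s_m)),
    pam_class = cls_minus[keep],
    last_base_pos = s_m,
    third_last_pos = s_m + 2L
  )

  bind_rows(plus, minus) |>
    arrange(.data$strand, .data$spacer_start)
}

#' Site density and PAM-class composition
#'
#' @param sites Site tibble from [enumerate_sites()].
#' @param total_length Total length in bp of the region set scanned.
#' @return One-row tibble: `n_sites`, `total_bp`, `density` (sites per bp,
#'   both strands pooled), and `frac_NGG`/`frac_NGA`/`frac_OTHER` (fractions
#'   of sites, `NA` and flagged via the `undefined_fractions` column when no
#'   sites are present).
#' @export
site_density <- function(sites, total_length) {
  stopifnot(total_length > 0)
  n <- nrow(sites)
  if (n == 0) {
    return(tibble(n_sites = 0L, total_bp = total_length, density = 0,
                  frac_NGG = NA_real_, frac_NGA = NA_real_,
                  frac_OTHER = NA_real_, undefined_fractions = TRUE))
  }
  tibble(
    n_sites = n, total_bp = total_length, density = n / total_length,
    frac_NGG = mean(sites$pam_class == "NGG"),
    frac_NGA = mean(sites$pam_class == "NGA"),
    frac_OTHER = mean(sites$pam_class == "OTHER"),
    undefined_fractions = FALSE
  )
}

#' Export sites as BED6
#'
#' BED uses 0-based half-open intervals over the protospacer; `name` is the
#' strand-oriented spacer sequence, `score` 0.
#'
#' @param sites Site tibble from [enumerate_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sites_bed <- function(sites, path) {
  bed <- tibble(
    chrom = sites$region_id,
    start = sites$spacer_start,
    end = sites$spacer_start + sites$spacer_len,
    name = sites$spacer_seq,
    score = 0L,
    strand = sites$strand
  )
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}

#' Export sites as an annotated TSV
#'
#' Written coordinates are 1-based inclusive (human-readable convention);
#' in-memory tibbles stay 0-based half-open.
#'
#' @inheritParams write_sites_bed
#' @return `path`, invisibly.
#' @export
write_sites_tsv <- function(sites, path) {
  out <- sites |>
    mutate(
      start_1based = .data$spacer_start + 1L,
      end_1based = .data$spacer_start + .data$spacer_len,
      last_base_1based = .data$last_base_pos + 1L,
      third_last_1based = .data$third_last_pos + 1L
    ) |>
    select("region_id", "strand", "start_1based", "end_1based",
           "spacer_seq", "pam_seq", "pam_class",
           "last_base_1based", "third_last_1based")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Generate a uniform-random DNA region
#'
#' i.i.d. uniform A/C/G/T; used for density/self-calibration analyses and in
#' the synthetic-data generators.
#'
#' @param length_bp Sequence length.
#' @param seed Optional integer seed.
#' @param region_id Region id for the returned table.
#' @return One-row region tibble.
#' @export
random_region <- function(length_bp, seed = NULL, region_id = "random") {
  draw <- function() paste(sample(c("A", "C", "G", "T"), length_bp,
                                  replace = TRUE), collapse = "")
  seq <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  region_table(setNames(seq, region_id))
}
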