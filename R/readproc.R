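#' Read screen reads from FASTQ
#'
#' @param path FASTQ path (gzipped accepted).
#' @return Tibble with a single `read` column (uppercase).
#' @export
read_screen_fastq <- function(path) {
  dss <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read = toupper(as.character(unname(dss))))
}

#' Clip the sgRNA scaffold and extract spacer + barcode
#'
#' Locates the leftmost match of the 20-nt wildcard scaffold pattern
#' `GNNNNNNAGCTAGAAATAGC` (N matches any base) in each read. The spacer is
#' everything before the match (the targeting domain without its leading G,
#' which sits in the sequencing primer); the 6-nt sample barcode immediately
#' follows the matched pattern. Reads with no match, or with fewer than 6
#' bases after it, are rejected (counted, not errored).
#'
#' @param reads Character vector of reads, or a tibble with a `read` column.
#' @return Tibble (`read`, `clipped`, `spacer`, `barcode`); `spacer`/
#'   `barcode` are `NA` for rejected reads. Attribute `n_rejected`.
#' @export
clip_reads <- function(reads) {
  if (is.data.frame(reads)) reads <- reads$read
  reads <- toupper(reads)
  pattern <- "G[ACGTN]{6}AGCTAGAAATAGC"
  m <- regexpr(pattern, reads)
  pos <- as.integer(m)
  ok <- pos > 0 & nchar(reads) >= pos + 20 + 5
  out <- tibble(
    read = reads,
    clipped = ok,
    spacer = if_else(ok, substr(reads, 1, pos - 1), NA_character_),
    barcode = if_else(ok, substr(reads, pos + 20, pos + 25), NA_character_)
  )
  attr(out, "n_rejected") <- sum(!ok)
  out
}

#' Demultiplex clipped reads by sample barcode
#'
#' Exact barcode matching by default; with `max_mismatch = 1` a read is
#' assigned when exactly one table barcode lies within one substitution.
#' Table barcodes whose pairwise Hamming distance is within the allowed
#' radius (ambiguity possible) are a configuration error.
#'
#' @param clipped Output of [clip_reads()].
#' @param barcodes Barcode tibble (`sample_id`, `replicate`, `bin`,
#'   `barcode`), barcodes unique and exactly 6 nt.
#' @param max_mismatch 0 (default) or 1.
#' @return `clipped` with `sample_id`, `replicate`, `bin` joined (`NA` =
#'   unassigned). Attributes `n_rejected`, `n_unassigned`, `n_assigned`.
#' @export
demultiplex_reads <- function(clipped, barcodes, max_mismatch = 0) {
  stopifnot(max_mismatch %in% c(0, 1))
  bc <- toupper(barcodes$barcode)
  if (any(nchar(bc) != 6)) abort("Barcodes must be exactly 6 nt")
  if (anyDuplicated(bc)) abort("Barcodes must be unique")
  if (max_mismatch > 0) {
    for (i in seq_along(bc)) {
      d <- hamming(bc[-i], bc[i])
      if (any(d <= 2 * max_mismatch)) {
        abort("Two barcodes lie within the allowed mismatch radius")
      }
    }
  }
  tab <- barcodes |>
    mutate(barcode = toupper(.data$barcode)) |>
    select("barcode", "sample_id", "replicate", "bin")
  out <- clipped |>
    left_join(tab, by = "barcode")
  if (max_mismatch == 1) {
    todo <- which(out$clipped & is.na(out$sample_id))
    if (length(todo) > 0) {
      uniq <- unique(out$barcode[todo])
      dmat <- vapply(bc, function(b) hamming(uniq, b), integer(length(uniq)))
      dmat <- matrix(dmat, nrow = length(uniq))
      best <- apply(dmat, 1, function(d) {
        w <- which(d <= 1)
        if (length(w) == 1) w else NA_integer_
      })
      assign_idx <- best[match(out$barcode[todo], uniq)]
      ok <- !is.na(assign_idx)
      out$sample_id[todo[ok]] <- tab$sample_id[assign_idx[ok]]
      out$replicate[todo[ok]] <- tab$replicate[assign_idx[ok]]
      out$bin[todo[ok]] <- tab$bin[assign_idx[ok]]
    }
  }
  attr(out, "n_rejected") <- sum(!out$clipped)
  attr(out, "n_unassigned") <- sum(out$clipped & is.na(out$sample_id))
  attr(out, "n_assigned") <- sum(!is.na(out$sample_id))
  out
}

# Dictionary of every protospacer-sized substring of the regions, both
# strands, for a set of spacer lengths: the exact-match index behind mapping.
spacer_dictionary <- function(regions, lengths) {
  res <- list()
  for (len in sort(unique(lengths))) {
    for (i in seq_len(nrow(regions))) {
      n <- regions$length[i]
      if (n < len) next
      s <- 0:(n - len)
      seqs <- substring(regions$sequence[i], s + 1, s + len)
      res[[length(res) + 1]] <- tibble(
        seq = c(seqs, revcomp(seqs)),
        region_id = regions$region_id[i],
        strand = rep(c("+", "-"), each = length(s)),
        spacer_start = c(s, s), spacer_len = len)
    }
  }
  bind_rows(res)
}

#' Map observed spacers back to the input regions
#'
#' Exhaustive search over both strands of every region, with 0 (default) or 1
#' mismatch allowed. A unique locus gives a `mapped` annotation with full
#' site coordinates and the PAM read from the reference; more than one locus
#' gives `multi` (excluded from positional analyses downstream); none gives
#' `unmapped`. Spacers shorter than `min_len` are `too_short`.
#'
#' @param spacers Character vector of spacer sequences (duplicates fine), or
#'   a tibble with a `spacer` column.
#' @param regions Region tibble.
#' @param max_mismatch 0 or 1.
#' @param min_len Minimum spacer length retained (default 10).
#' @return Annotation tibble keyed by unique `spacer`: `status`
#'   (`mapped`/`multi`/`unmapped`/`too_short`), `n_loci`, `region_id`,
#'   `strand`, `spacer_start`, `spacer_len`, `pam_seq`, `pam_class`,
#'   `last_base_pos`, `third_last_pos` (locus columns `NA` unless mapped).
#' @export
map_spacers <- function(spacers, regions, max_mismatch = 0, min_len = 10) {
  stopifnot(max_mismatch %in% c(0, 1))
  if (is.data.frame(spacers)) spacers <- spacers$spacer
  uniq <- unique(spacers[!is.na(spacers)])
  len <- nchar(uniq)
  short <- len < min_len
  queries <- uniq[!short]
  qlen <- len[!short]

  hits <- tibble(spacer = character(0), region_id = character(0),
                 strand = character(0), spacer_start = integer(0),
                 spacer_len = integer(0))
  if (length(queries) > 0) {
    dict <- spacer_dictionary(regions, unique(qlen))
    exact <- tibble(spacer = queries, seq = queries) |>
      inner_join(dict, by = "seq", relationship = "many-to-many") |>
      select(-"seq")
    hits <- exact
    if (max_mismatch == 1) {
      vars <- one_mismatch_variants(queries)
      mm <- vars |>
        inner_join(dict, by = c(variant = "seq"),
                   relationship = "many-to-many") |>
        select(-"variant")
      hits <- bind_rows(exact, mm) |>
        distinct(.data$spacer, .data$region_id, .data$strand,
                 .data$spacer_start, .data$spacer_len)
    }
  }
  locus_counts <- hits |> count(.data$spacer, name = "n_loci")
  unique_hits <- hits |>
    inner_join(filter(locus_counts, .data$n_loci == 1), by = "spacer")
  ann <- tibble(spacer = uniq) |>
    left_join(locus_counts, by = "spacer") |>
    mutate(n_loci = dplyr::coalesce(.data$n_loci, 0L),
           status = dplyr::case_when(
             nchar(.data$spacer) < min_len ~ "too_short",
             .data$n_loci == 1 ~ "mapped",
             .data$n_loci > 1 ~ "multi",
             TRUE ~ "unmapped")) |>
    left_join(unique_hits |> select(-"n_loci"), by = "spacer") |>
    mutate(
      pam_seq = pam_at_site(regions, .data$region_id, .data$strand,
                            .data$spacer_start, .data$spacer_len),
      pam_class = classify_pam(.data$pam_seq),
      last_base_pos = dplyr::case_when(
        .data$strand == "+" ~ .data$spacer_start + .data$spacer_len - 1L,
        .data$strand == "-" ~ .data$spacer_start,
        TRUE ~ NA_integer_),
      third_last_pos = dplyr::case_when(
        .data$strand == "+" ~ .data$spacer_start + .data$spacer_len - 3L,
        .data$strand == "-" ~ .data$spacer_start + 2L,
        TRUE ~ NA_integer_)
    )
  ann
}

# All single-substitution variants of each query (plus the query itself is
# handled separately as the exact pass).
one_mismatch_variants <- function(queries) {
  bases <- c("A", "C", "G", "T")
  out <- vector("list", length(queries))
  for (i in seq_along(queries)) {
    q <- queries[i]
    n <- nchar(q)
    ch <- strsplit(q, "", fixed = TRUE)[[1]]
    vs <- character(3 * n)
    k <- 0
    for (p in seq_len(n)) {
      for (b in setdiff(bases, ch[p])) {
        k <- k + 1
        v <- ch; v[p] <- b
        vs[k] <- paste(v, collapse = "")
      }
    }
    out[[i]] <- tibble(spacer = q, variant = vs[seq_len(k)])
  }
  bind_rows(out) |> distinct()
}

#' Build a per-sample sgRNA count table
#'
#' Aggregates identical spacer strings within each sample (counting is by
#' exact spacer sequence, matching unique-sgRNA accounting) and joins the
#' mapping annotation.
#'
#' @param assigned Output of [demultiplex_reads()] (one row per read), or any
#'   tibble with `sample_id`, `replicate`, `bin`, `spacer` columns.
#' @param annotations Optional [map_spacers()] output to join.
#' @return Count tibble (`sample_id`, `replicate`, `bin`, `spacer`, `count`,
#'   + annotation columns) of class `screen_counts`; unassigned/rejected
#'   reads are dropped (their totals live on the demultiplex attributes).
#' @export
build_count_table <- function(assigned, annotations = NULL) {
  counts <- assigned |>
    filter(!is.na(.data$sample_id), !is.na(.data$spacer)) |>
    count(.data$sample_id, .data$replicate, .data$bin, .data$spacer,
          name = "count")
  if (!is.null(annotations)) {
    counts <- counts |> left_join(annotations, by = "spacer")
  }
  class(counts) <- c("screen_counts", class(counts))
  counts
}

#' Targeting-domain length distribution
#'
#' Domain length = spacer length + 1 (the leading G sits in the sequencing
#' primer and is not part of the read). Counts are normalised to the
#' length-20 bin within each replicate; if a replicate has no length-20
#' domains the raw histogram is returned with a warning.
#'
#' @param counts Count tibble with `replicate`, `spacer`, `count`.
#' @return Tibble (`replicate`, `domain_length`, `count`, `normalized`).
#' @export
length_histogram <- function(counts) {
  h <- counts |>
    mutate(domain_length = nchar(.data$spacer) + 1L) |>
    group_by(.data$replicate, .data$domain_length) |>
    summarise(count = sum(.data$count), .groups = "drop_last") |>
    mutate(ref = sum(.data$count[.data$domain_length == 20L])) |>
    ungroup()
  if (any(h$ref == 0)) {
    warn("No length-20 targeting domains in some replicate(s); returning unnormalized counts")
    h <- h |> mutate(normalized = if_else(.data$ref > 0,
                                          .data$count / .data$ref,
                                          as.numeric(.data$count)))
  } else {
    h <- h |> mutate(normalized = .data$count / .data$ref)
  }
  h |> select(-"ref") |> arrange(.data$replicate, .data$domain_length)
}

#' Processing QC summary
#'
#' @param demux Output of [demultiplex_reads()].
#' @param annotations Output of [map_spacers()].
#' @return A list (`n_input`, `n_rejected`, `n_unassigned`, `n_assigned`,
#'   `n_spacers_mapped`, `n_spacers_multi`, `n_spacers_unmapped`,
#'   `n_spacers_too_short`) ready for JSON export.
#' @export
readproc_qc <- function(demux, annotations) {
  list(
    n_input = nrow(demux),
    n_rejected = attr(demux, "n_rejected"),
    n_unassigned = attr(demux, "n_unassigned"),
    n_assigned = attr(demux, "n_assigned"),
    n_spacers_mapped = sum(annotations$status == "mapped"),
    n_spacers_multi = sum(annotations$status == "multi"),
    n_spacers_unmapped = sum(annotations$status == "unmapped"),
    n_spacers_too_short = sum(annotations$status == "too_short")
  )
}
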