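#' Frequency floors used in enrichment scoring
#'
#' To avoid division by zero and log2 of zero, sgRNA read frequencies are
#' floored before the ratio: negative-bin (reference) frequencies at
#' 6.25e-7 and GFP-positive-bin frequencies at 1e-8. Floors apply to
#' frequencies, never to counts, and only raise values.
#'
#' @return Named list with `neg` and `pos` floors.
#' @export
frequency_floors <- function() list(neg = 6.25e-7, pos = 1e-8)

#' Per-sample sgRNA read frequencies
#'
#' Counts are normalised by the total mapped read count of each sample. Rows
#' without a `status` column are all treated as mapped.
#'
#' @param counts Count tibble (`sample_id`, `replicate`, `bin`, `spacer`,
#'   `count`, optionally `status`).
#' @return The mapped rows with added `mapped_total` and `freq` columns;
#'   frequencies sum to 1 within each sample (before any flooring).
#' @export
sample_frequencies <- function(counts) {
  x <- as_tibble(counts)
  if ("status" %in% names(x)) {
    x <- x |> filter(.data$status == "mapped")
  }
  x <- x |>
    group_by(.data$sample_id) |>
    mutate(mapped_total = sum(.data$count)) |>
    ungroup()
  if (any(x$mapped_total == 0)) abort("Sample with zero mapped reads")
  x |> mutate(freq = .data$count / .data$mapped_total)
}

#' Floored log2 enrichment score
#'
#' `log2(max(freq_pos, pos floor) / max(freq_neg, neg floor))`. The maximum
#' attainable score at fixed `freq_pos` occurs when the reference sits at its
#' floor; an sgRNA absent from the positive sample scores at most
#' `log2(1e-8 / 6.25e-7)`, which is negative.
#'
#' @param freq_pos,freq_neg Frequencies in `[0, 1]` (vectorised).
#' @param floors Floor list from [frequency_floors()].
#' @return Numeric vector of log2 enrichment values.
#' @export
#' @examples
#' enrichment_score(6.25e-4, 6.25e-7) # log2(1000)
enrichment_score <- function(freq_pos, freq_neg, floors = frequency_floors()) {
  log2(pmax(freq_pos, floors$pos) / pmax(freq_neg, floors$neg))
}

#' Floored log2 enrichment per sgRNA, bin and replicate
#'
#' Within each replicate, every GFP-positive bin (`low`, `med`, `high`) is
#' compared against the negative bin of the same replicate. The sgRNA
#' universe is the union over the replicate's samples; an sgRNA absent from a
#' sample has frequency 0 there (then floored).
#'
#' @param counts Count tibble including the `neg` bin; annotation columns
#'   (`status`, `region_id`, `strand`, `spacer_start`, `pam_class`,
#'   `last_base_pos`, `third_last_pos`, `n_loci`) are carried through when
#'   present.
#' @param floors Floor list from [frequency_floors()].
#' @return Enrichment tibble: `spacer`, `replicate`, `bin`, `freq_pos`,
#'   `freq_neg`, `log2_enrichment`, plus any annotation columns.
#' @export
enrichment_table <- function(counts, floors = frequency_floors()) {
  freqs <- sample_frequencies(counts)
  ann_cols <- intersect(c("status", "n_loci", "region_id", "strand",
                          "spacer_start", "spacer_len", "pam_seq",
                          "pam_class", "last_base_pos", "third_last_pos"),
                        names(freqs))
  ann <- freqs |> distinct(dplyr::across(dplyr::all_of(c("spacer", ann_cols))))
  core <- freqs |> select("replicate", "bin", "spacer", "freq")
  neg <- core |>
    filter(.data$bin == "neg") |>
    select("replicate", "spacer", freq_neg = "freq")
  pos_bins <- setdiff(unique(core$bin), "neg")
  universe <- core |>
    distinct(.data$replicate, .data$spacer) |>
    tidyr::expand_grid(bin = pos_bins)
  enr <- universe |>
    left_join(filter(core, .data$bin != "neg"),
              by = c("replicate", "spacer", "bin")) |>
    left_join(neg, by = c("replicate", "spacer")) |>
    mutate(
      freq_pos = pmax(dplyr::coalesce(.data$freq, 0), floors$pos),
      freq_neg = pmax(dplyr::coalesce(.data$freq_neg, 0), floors$neg),
      log2_enrichment = log2(.data$freq_pos / .data$freq_neg)
    ) |>
    select(-"freq")
  enr |>
    left_join(ann, by = "spacer") |>
    arrange(.data$replicate, .data$bin, .data$spacer)
}

#' Per-position best-enrichment track
#'
#' Plotting convention for raw enrichment: each sgRNA is placed at the
#' plus-frame coordinate of the last base of its targeting section; where
#' several sgRNAs share a position, the best score is shown; by default only
#' NGG-PAM sgRNAs with positive log2 enrichment appear. Strand is retained
#' for colouring. Unmapped and multi-mapping records are skipped (counted in
#' attribute `n_skipped`).
#'
#' @param enr Enrichment tibble from [enrichment_table()] (with mapping
#'   annotation).
#' @param pam_filter PAM classes kept (default `"NGG"`).
#' @param positive_only Drop scores `<= 0` (default `TRUE`).
#' @return Track tibble: `replicate`, `bin`, `region_id`, `last_base_pos`,
#'   `strand`, `score`.
#' @export
positional_track <- function(enr, pam_filter = "NGG", positive_only = TRUE) {
  usable <- enr |> filter(.data$status == "mapped")
  n_skipped <- nrow(enr) - nrow(usable)
  track <- usable |>
    filter(.data$pam_class %in% pam_filter) |>
    group_by(.data$replicate, .data$bin, .data$region_id,
             .data$last_base_pos) |>
    slice_max(.data$log2_enrichment, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("replicate", "bin", "region_id", "last_base_pos", "strand",
           score = "log2_enrichment")
  if (positive_only) track <- track |> filter(.data$score > 0)
  track <- track |> arrange(.data$replicate, .data$bin, .data$region_id,
                            .data$last_base_pos)
  attr(track, "n_skipped") <- n_skipped
  track
}

#' Call candidate hit sgRNAs across replicates
#'
#' An sgRNA is a hit when all of the following hold: (1) its log2 enrichment
#' exceeds `threshold` (strictly) in the high- or med-GFP bin in at least
#' `min_replicates` replicates (a replicate qualifies if either bin
#' exceeds the threshold), or (2) the same in the low-GFP bin; (3) it lies
#' before an NGG PAM; and (4) it maps within the target locus.
#'
#' @param enr Enrichment tibble from [enrichment_table()], with >= 2
#'   replicates.
#' @param locus Target locus as a one-row tibble/list with `region_id`,
#'   `start`, `end` (0-based half-open; membership by `last_base_pos`).
#' @param threshold Strict log2 enrichment threshold (default 2).
#' @param min_replicates Minimum qualifying replicates (default 2).
#' @return Hit tibble: `spacer`, mapping columns, criteria flags
#'   (`highmed_2reps`, `low_2reps`, `is_NGG`, `in_target_locus`) and derived
#'   `is_hit`.
#' @export
call_hits <- function(enr, locus, threshold = 2, min_replicates = 2) {
  if (dplyr::n_distinct(enr$replicate) < 2) {
    abort("Hit criteria need at least two biological replicates")
  }
  wide <- enr |>
    tidyr::pivot_wider(id_cols = c("spacer", "replicate"),
                       names_from = "bin",
                       values_from = "log2_enrichment")
  for (b in c("low", "med", "high")) {
    if (!b %in% names(wide)) wide[[b]] <- NA_real_
  }
  reps <- wide |>
    group_by(.data$spacer) |>
    summarise(
      n_highmed = sum(pmax(dplyr::coalesce(.data$high, -Inf),
                           dplyr::coalesce(.data$med, -Inf)) > threshold),
      n_low = sum(dplyr::coalesce(.data$low, -Inf) > threshold),
      .groups = "drop")
  ann <- enr |>
    distinct(.data$spacer, .data$status, .data$region_id, .data$strand,
             .data$spacer_start, .data$pam_class, .data$last_base_pos)
  reps |>
    left_join(ann, by = "spacer") |>
    mutate(
      highmed_2reps = .data$n_highmed >= min_replicates,
      low_2reps = .data$n_low >= min_replicates,
      is_NGG = .data$status == "mapped" &
        dplyr::coalesce(.data$pam_class == "NGG", FALSE),
      in_target_locus = .data$status == "mapped" &
        dplyr::coalesce(.data$region_id == locus$region_id &
                          .data$last_base_pos >= locus$start &
                          .data$last_base_pos < locus$end, FALSE),
      is_hit = (.data$highmed_2reps | .data$low_2reps) &
        .data$is_NGG & .data$in_target_locus
    ) |>
    arrange(dplyr::desc(.data$is_hit), .data$region_id, .data$last_base_pos)
}

#' Write a positional track as bedGraph (one file per replicate and bin)
#'
#' bedGraph intervals are 0-based half-open single bases at the sgRNA
#' last-base positions.
#'
#' @param track Output of [positional_track()].
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Character vector of written paths, invisibly.
#' @export
write_track_bedgraph <- function(track, dir, prefix = "enrichment") {
  groups <- track |> distinct(.data$replicate, .data$bin)
  paths <- character(0)
  for (i in seq_len(nrow(groups))) {
    g <- track |>
      filter(.data$replicate == groups$replicate[i],
             .data$bin == groups$bin[i])
    path <- file.path(dir, paste0(prefix, "_r", groups$replicate[i], "_",
                                  groups$bin[i], ".bedGraph"))
    readr::write_tsv(
      tibble(chrom = g$region_id, start = g$last_base_pos,
             end = g$last_base_pos + 1L, value = g$score),
      path, col_names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
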