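#' Planted truth elements for the synthetic screen
#'
#' A truth element is an interval of an input region whose disruption by a
#' Cas9 cut shifts a cell's reporter read-out: `mature_or_pre` elements
#' emulate the hairpin/mature-miRNA region (near-complete loss, med/high
#' GFP), `five_prime_hit`/`three_prime_hit` emulate flanking processing
#' elements (partial loss, low GFP). The bin profile is the probability
#' distribution over FACS bins for a cell whose sgRNA cut site falls inside
#' the element (given the cut happened).
#'
#' @param region_id,start,end Element interval (0-based half-open).
#' @param element_class One of `mature_or_pre`, `five_prime_hit`,
#'   `three_prime_hit`.
#' @param p_neg,p_low,p_med,p_high Bin profile; each row must sum to 1.
#' @param priority Optional integer resolving overlaps (lower wins).
#' @return Tibble of class `truth_elements`.
#' @export
truth_elements <- function(region_id, start, end, element_class,
                           p_neg, p_low, p_med, p_high, priority = NULL) {
  el <- tibble(
    region_id = region_id, start = as.integer(start), end = as.integer(end),
    element_class = element_class,
    p_neg = p_neg, p_low = p_low, p_med = p_med, p_high = p_high,
    priority = priority %||% NA_integer_
  )
  if (any(el$end <= el$start)) abort("Element end must exceed start")
  tot <- el$p_neg + el$p_low + el$p_med + el$p_high
  if (any(abs(tot - 1) > 1e-9)) abort("Each bin profile must sum to 1")
  bad <- !(el$element_class %in%
             c("mature_or_pre", "five_prime_hit", "three_prime_hit"))
  if (any(bad)) abort("Unknown element_class")
  class(el) <- c("truth_elements", class(el))
  el
}

#' Screen configuration
#'
#' Holds the cell-level experiment parameters: cells infected at ~30% titre
#' (one integration per infected cell), three biological replicates, and a
#' PAM-class activity model per Cas9 variant. Wild-type Cas9 requires NGG;
#' the VQR mutant recognises NGA. The default activity magnitudes are model
#' knobs, not measured constants.
#'
#' @param n_cells Cells exposed to the library per replicate.
#' @param infection_rate Fraction of cells infected (default 0.30).
#' @param replicates Number of biological replicates (default 3).
#' @param cas9_variants Character subset of `c("WT","VQR")` present.
#' @param pam_activity Tibble (`variant`, `pam_class`, `activity`): cutting
#'   probability for that variant at that PAM class.
#' @param gtgg_activity Optional activity for OTHER-class PAMs whose 4-nt
#'   context (last protospacer base + PAM) reads `GTGG` under WT Cas9;
#'   `NULL` (default) disables the exception.
#' @param read_depth Sequencing reads per sample.
#' @param sequencing_error_rate Per-base substitution rate in emitted reads.
#' @param seed Integer seed for the screen streams.
#' @return List of class `screen_config`.
#' @export
screen_config <- function(n_cells = 1e7, infection_rate = 0.30,
                          replicates = 3, cas9_variants = "WT",
                          pam_activity = default_pam_activity(),
                          gtgg_activity = NULL,
                          read_depth = 750000,
                          sequencing_error_rate = 0.001, seed = 1) {
  stopifnot(replicates >= 1, infection_rate >= 0, infection_rate <= 1)
  stopifnot(all(cas9_variants %in% c("WT", "VQR")))
  stopifnot(all(pam_activity$activity >= 0 & pam_activity$activity <= 1))
  structure(list(
    n_cells = as.integer(n_cells), infection_rate = infection_rate,
    replicates = as.integer(replicates), cas9_variants = cas9_variants,
    pam_activity = pam_activity, gtgg_activity = gtgg_activity,
    read_depth = as.integer(read_depth),
    sequencing_error_rate = sequencing_error_rate, seed = as.integer(seed)
  ), class = "screen_config")
}

#' Default PAM-class activity model
#'
#' @return Tibble (`variant`, `pam_class`, `activity`).
#' @export
default_pam_activity <- function() {
  tibble(
    variant = c("WT", "WT", "WT", "VQR", "VQR", "VQR"),
    pam_class = c("NGG", "NGA", "OTHER", "NGA", "NGG", "OTHER"),
    activity = c(0.8, 0.05, 0.0, 0.4, 0.05, 0.0)
  )
}

#' Screen FACS bins, in sort order
#' @export
screen_bins <- function() c("neg", "low", "med", "high")

# Plus-frame coordinate of the cut site: spCas9 cuts bluntly 3 bp 5' of the
# PAM, i.e. at the third protospacer base counting from the PAM-proximal end.
cut_site <- function(strand, spacer_start, spacer_len) {
  ifelse(strand == "+", spacer_start + spacer_len - 3L, spacer_start + 2L)
}

#' Assign per-sgRNA FACS-bin distributions
#'
#' For every library sgRNA: the cut probability is the PAM-class activity of
#' the Cas9 variant(s) present (variants combine independently); if the cut
#' site falls inside a truth element, a cut moves the cell to that element's
#' bin profile, otherwise (and for uncut cells, junction sgRNAs and sgRNAs
#' outside all elements) the cell stays GFP-negative.
#'
#' @param library A `chipper_library` tibble.
#' @param truth A [truth_elements()] tibble (or `NULL` for an effect-free
#'   screen).
#' @param config A [screen_config()].
#' @return The library with added columns `cut_pos`, `cut_prob`,
#'   `element_class`, and bin probabilities `p_neg`, `p_low`, `p_med`,
#'   `p_high`.
#' @export
assign_effects <- function(library, truth = NULL, config = screen_config()) {
  act <- config$pam_activity |>
    filter(.data$variant %in% config$cas9_variants)
  lib <- as_tibble(library) |>
    mutate(
      cut_pos = cut_site(.data$strand, .data$spacer_start, .data$insert_len),
      .row = row_number()
    )
  # combine variants independently: P(cut) = 1 - prod(1 - activity_v)
  probs <- lib |>
    select(".row", "pam_class") |>
    left_join(act, by = "pam_class", relationship = "many-to-many") |>
    group_by(.data$.row) |>
    summarise(cut_prob = 1 - prod(1 - dplyr::coalesce(.data$activity, 0)),
              .groups = "drop")
  lib <- lib |>
    left_join(probs, by = ".row") |>
    mutate(cut_prob = if_else(.data$junction | is.na(.data$pam_class),
                              0, dplyr::coalesce(.data$cut_prob, 0)))
  if (!is.null(config$gtgg_activity) && "WT" %in% config$cas9_variants) {
    ctx <- paste0(substr(lib$insert_seq, lib$insert_len, lib$insert_len),
                  lib$pam_seq)
    bump <- !lib$junction & !is.na(lib$pam_class) &
      lib$pam_class == "OTHER" & !is.na(ctx) & ctx == "GTGG"
    lib$cut_prob[bump] <- 1 - (1 - lib$cut_prob[bump]) *
      (1 - config$gtgg_activity)
  }

  if (is.null(truth) || nrow(truth) == 0) {
    hits <- lib[0, c(".row"), drop = FALSE] |>
      mutate(element_class = character(0), q_neg = numeric(0),
             q_low = numeric(0), q_med = numeric(0), q_high = numeric(0))
  } else {
    hits <- lib |>
      filter(!.data$junction) |>
      select(".row", "region_id", "cut_pos") |>
      inner_join(as_tibble(truth), by = "region_id",
                 relationship = "many-to-many") |>
      filter(.data$cut_pos >= .data$start, .data$cut_pos < .data$end)
    multi <- hits |> count(.data$.row) |> filter(.data$n > 1)
    if (nrow(multi) > 0) {
      if (all(!is.na(truth$priority))) {
        hits <- hits |>
          group_by(.data$.row) |>
          arrange(.data$priority, .by_group = TRUE) |>
          dplyr::slice(1) |>
          ungroup()
      } else {
        abort("Overlapping truth elements cover the same cut site; supply a priority order")
      }
    }
    hits <- hits |>
      select(".row", "element_class",
             q_neg = "p_neg", q_low = "p_low", q_med = "p_med",
             q_high = "p_high")
  }
  lib |>
    left_join(hits, by = ".row") |>
    mutate(
      in_element = !is.na(.data$element_class),
      eff = if_else(.data$in_element, .data$cut_prob, 0),
      p_neg = .data$eff * dplyr::coalesce(.data$q_neg, 0) + (1 - .data$eff),
      p_low = .data$eff * dplyr::coalesce(.data$q_low, 0),
      p_med = .data$eff * dplyr::coalesce(.data$q_med, 0),
      p_high = .data$eff * dplyr::coalesce(.data$q_high, 0)
    ) |>
    select(-".row", -"eff", -"q_neg", -"q_low", -"q_med", -"q_high")
}

#' Simulate per-bin, per-replicate sgRNA read counts
#'
#' Cell model per replicate: `round(n_cells * infection_rate)` infected cells
#' drawn multinomially over library clone frequencies (single integration per
#' cell); each cell falls into a FACS bin by its sgRNA's bin distribution;
#' per-bin read counts are multinomial over within-bin sgRNA cell
#' frequencies at `read_depth`. Replicates use derived RNG streams.
#'
#' @param effects Output of [assign_effects()].
#' @param config A [screen_config()].
#' @return Tidy count tibble (`sample_id`, `replicate`, `bin`, `spacer`,
#'   `count`) of class `screen_counts`; bins with zero cells are flagged in
#'   attribute `empty_samples`. Attribute `cells` holds the per-locus,
#'   per-bin cell counts (ground truth).
#' @export
simulate_screen_counts <- function(effects, config = screen_config()) {
  stopifnot(config$read_depth > 0)
  bins <- screen_bins()
  seeds <- derive_seeds(config$seed, config$replicates)
  n_inf <- as.integer(round(config$n_cells * config$infection_rate))
  pm <- as.matrix(effects[, c("p_neg", "p_low", "p_med", "p_high")])
  colnames(pm) <- bins
  out <- vector("list", config$replicates)
  cells_out <- vector("list", config$replicates)
  empty <- character(0)
  for (r in seq_len(config$replicates)) {
    res <- withr::with_seed(seeds[r], {
      ncell <- as.integer(rmultinom(1, n_inf, effects$clones)[, 1])
      cellbins <- rmultinom_rows(ncell, pm)
      counts <- matrix(0L, nrow = nrow(effects), ncol = length(bins),
                       dimnames = list(NULL, bins))
      for (b in bins) {
        tot <- sum(cellbins[, b])
        if (tot == 0) next
        counts[, b] <- as.integer(rmultinom(1, config$read_depth,
                                            cellbins[, b])[, 1])
      }
      list(cellbins = cellbins, counts = counts)
    })
    for (b in bins) {
      if (sum(res$cellbins[, b]) == 0) empty <- c(empty, paste0("r", r, "_", b))
    }
    cnt <- as_tibble(res$counts) |>
      mutate(spacer = effects$insert_seq, replicate = r) |>
      tidyr::pivot_longer(dplyr::all_of(bins), names_to = "bin",
                          values_to = "count") |>
      group_by(.data$replicate, .data$bin, .data$spacer) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      filter(.data$count > 0)
    out[[r]] <- cnt
    cellb <- res$cellbins
    colnames(cellb) <- paste0("cells_", bins)
    cells_out[[r]] <- bind_cols(
      tibble(replicate = r),
      as_tibble(effects[, c("insert_seq", "region_id", "strand",
                            "spacer_start", "pam_class", "junction",
                            "in_element", "element_class")]),
      as_tibble(cellb))
  }
  counts <- bind_rows(out) |>
    mutate(sample_id = paste0("r", .data$replicate, "_", .data$bin)) |>
    relocate("sample_id") |>
    arrange(.data$replicate, factor(.data$bin, levels = bins), .data$spacer)
  if (length(empty) > 0) {
    warn(paste0("Samples with zero cells: ", paste(empty, collapse = ", ")))
  }
  attr(counts, "empty_samples") <- empty
  attr(counts, "cells") <- bind_rows(cells_out)
  attr(counts, "config") <- config
  class(counts) <- c("screen_counts", class(counts))
  counts
}

#' Default barcode table for a simulated screen
#'
#' One 6-nt barcode per (replicate, bin) sample; the first is the classic
#' `CGTGAT` index.
#'
#' @param replicates Number of replicates.
#' @param bins Bin names.
#' @return Tibble (`sample_id`, `replicate`, `bin`, `barcode`).
#' @export
default_barcodes <- function(replicates = 3, bins = screen_bins()) {
  pool <- c("CGTGAT", "ACATCG", "GCCTAA", "TGGTCA", "CACTGT", "ATTGGC",
            "GATCTG", "TCAAGT", "CTGATC", "AAGCTA", "GTAGCC", "TACAAG",
            "TTGACT", "GGAACT", "TGACAT", "GGACGG", "CTCTAC", "GCGGAC",
            "TTTCAC", "GGCCAC", "CGAAAC", "CGTACG", "CCACTC", "GCTACC")
  n <- replicates * length(bins)
  if (n > length(pool)) abort("Not enough built-in barcodes; supply your own table")
  grid <- tidyr::expand_grid(replicate = seq_len(replicates), bin = bins)
  grid |>
    mutate(sample_id = paste0("r", .data$replicate, "_", .data$bin),
           barcode = pool[seq_len(n)]) |>
    relocate("sample_id")
}

#' sgRNA scaffold prefix present in every read after the spacer
#' @export
scaffold_prefix <- function() "GTTTTAGAGCTAGAAATAGC"

#' Emit barcoded amplicon reads as FASTQ
#'
#' Each read is `spacer + scaffold prefix + 6-nt sample barcode + constant
#' tail`, mirroring the sequenced amplicon (the sequencing primer ends at the
#' transcription-start G, so the leading G of the targeting domain is not
#' read). i.i.d. substitution errors are applied at
#' `config$sequencing_error_rate`; Phred qualities are constant `I`.
#'
#' @param counts A `screen_counts` tibble.
#' @param barcodes Barcode tibble from [default_barcodes()] (or same shape).
#' @param config A [screen_config()] (error rate and seed).
#' @param path Output FASTQ path (`.gz` honoured by downstream readers; plain
#'   text written here).
#' @param tail Constant 3' tail after the barcode.
#' @return `path`, invisibly. Attribute-free; an empty count table yields an
#'   empty FASTQ.
#' @export
emit_reads <- function(counts, barcodes, config = screen_config(),
                       path, tail = "ATCTCGTATGCCGTCTTCTGCTTG") {
  missing_bc <- setdiff(unique(counts$sample_id), barcodes$sample_id)
  if (length(missing_bc) > 0) {
    abort(paste0("No barcode for sample(s): ",
                 paste(missing_bc, collapse = ", ")))
  }
  joined <- as_tibble(counts) |>
    inner_join(select(barcodes, "sample_id", "barcode"), by = "sample_id")
  reads <- if (nrow(joined) == 0) character(0) else
    rep(paste0(joined$spacer, scaffold_prefix(), toupper(joined$barcode),
               tail),
        times = joined$count)
  if (length(reads) > 0 && config$sequencing_error_rate > 0) {
    reads <- withr::with_seed(derive_seeds(config$seed, 5)[5],
                              add_sequencing_errors(
                                reads, config$sequencing_error_rate))
  }
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(reads) > 0) {
    lines <- character(4 * length(reads))
    lines[seq(1, length(lines), by = 4)] <- paste0("@read_", seq_along(reads))
    lines[seq(2, length(lines), by = 4)] <- reads
    lines[seq(3, length(lines), by = 4)] <- "+"
    lines[seq(4, length(lines), by = 4)] <- strrep("I", nchar(reads))
    writeLines(lines, con)
  }
  invisible(path)
}

# i.i.d. substitutions at rate per base; only reads with >=1 error touched.
add_sequencing_errors <- function(reads, rate) {
  nc <- nchar(reads)
  nerr <- rbinom(length(reads), nc, rate)
  idx <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    pos <- sample.int(nc[i], nerr[i])
    ch <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1)
    reads[i] <- paste(ch, collapse = "")
  }
  reads
}

#' Write planted truth elements as BED and JSON
#'
#' @param truth A [truth_elements()] tibble.
#' @param bed_path,json_path Output paths (either may be `NULL`).
#' @return Invisibly, a list of the written paths.
#' @export
write_truth <- function(truth, bed_path = NULL, json_path = NULL) {
  if (!is.null(bed_path)) {
    readr::write_tsv(
      tibble(chrom = truth$region_id, start = truth$start, end = truth$end,
             name = truth$element_class, score = 0L, strand = "."),
      bed_path, col_names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(as_tibble(truth), json_path, digits = NA)
  }
  invisible(list(bed = bed_path, json = json_path))
}
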