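#' Configuration for a full simulate-and-analyse run
#'
#' Bundles the inputs and parameters of the whole pipeline: library digest,
#' synthetic screen, read processing, enrichment/hit calling, window scan
#' and library QC. All stage seeds are derived deterministically from
#' `seed`, so a run is reproducible from the config alone.
#'
#' @param regions Region tibble (see [load_regions()]).
#' @param out_dir Output directory (created if missing).
#' @param truth Optional [truth_elements()] tibble (`NULL` = effect-free).
#' @param chipper A [chipper_params()] object.
#' @param screen A [screen_config()] object.
#' @param barcodes Barcode tibble (`NULL` = [default_barcodes()]).
#' @param locus Target-locus list/tibble (`region_id`, `start`, `end`) for
#'   hit calling; defaults to the full extent of the first region carrying a
#'   truth element, or the first region.
#' @param window_size Scan window (odd, default 21).
#' @param threshold Hit-calling log2 threshold (default 2).
#' @param max_mismatch Mapping mismatches for the main analyses (default 0;
#'   distance QC always additionally uses 1).
#' @param saturation_sizes Subsample sizes as fractions of the mapped-read
#'   total (default `c(0.1, 0.25, 0.5, 1)`).
#' @param seed Master seed.
#' @return List of class `run_config`.
#' @export
run_config <- function(regions, out_dir, truth = NULL,
                       chipper = chipper_params(), screen = screen_config(),
                       barcodes = NULL, locus = NULL, window_size = 21,
                       threshold = 2, max_mismatch = 0,
                       saturation_sizes = c(0.1, 0.25, 0.5, 1), seed = 1) {
  stopifnot(nrow(regions) > 0)
  if (window_size %% 2 == 0) abort("window_size must be odd")
  if (is.null(locus)) {
    rid <- if (!is.null(truth) && nrow(truth) > 0) truth$region_id[1] else
      regions$region_id[1]
    locus <- list(region_id = rid, start = 0L,
                  end = regions$length[match(rid, regions$region_id)])
  }
  structure(list(
    regions = regions, out_dir = out_dir, truth = truth, chipper = chipper,
    screen = screen, barcodes = barcodes, locus = locus,
    window_size = window_size, threshold = threshold,
    max_mismatch = max_mismatch, saturation_sizes = saturation_sizes,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Run the full pipeline
#'
#' Stages, in dependency order: (1) in-silico chipper library; (2) synthetic
#' screen counts and barcoded FASTQ; (3) read processing (clip, demultiplex,
#' map, count); (4) enrichment scoring, positional tracks, hit calling;
#' (5) window-cluster scan; (6) library QC (length histogram, neighbour
#' distances observed vs theoretical, saturation curve, capacity estimate).
#' All artifacts are written under `config$out_dir` and a manifest with
#' derived seeds and file checksums is saved; rerunning the same config
#' reproduces identical checksums.
#'
#' @param config A [run_config()].
#' @return Invisible list with the main in-memory results (`library`,
#'   `counts`, `enrichment`, `track`, `hits`, `scan`, `qc`, `manifest`).
#' @export
run_chipper_screen <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- derive_seeds(config$seed, 6)
  regions <- config$regions

  # 1. library
  lib <- build_library(regions, config$chipper, seed = seeds[1])
  write_library_tsv(lib, file.path(config$out_dir, "library.tsv"))
  write_library_fasta(lib, file.path(config$out_dir, "library.fasta"))

  # 2. screen
  screen <- config$screen
  screen$seed <- seeds[2]
  effects <- assign_effects(lib, config$truth, screen)
  sim_counts <- simulate_screen_counts(effects, screen)
  barcodes <- config$barcodes %||%
    default_barcodes(screen$replicates)
  fastq_path <- file.path(config$out_dir, "reads.fastq")
  emit_reads(sim_counts, barcodes, screen, fastq_path)
  if (!is.null(config$truth)) {
    write_truth(config$truth,
                bed_path = file.path(config$out_dir, "truth.bed"),
                json_path = file.path(config$out_dir, "truth.json"))
  }

  # 3. read processing
  reads <- read_screen_fastq(fastq_path)
  clipped <- clip_reads(reads)
  demux <- demultiplex_reads(clipped, barcodes)
  ann <- map_spacers(demux$spacer[!is.na(demux$sample_id)], regions,
                     max_mismatch = config$max_mismatch)
  counts <- build_count_table(demux, ann)
  readr::write_tsv(as_tibble(counts),
                   file.path(config$out_dir, "counts.tsv"))
  lh <- length_histogram(counts)
  qc_json <- readproc_qc(demux, ann)
  qc_json$length_histogram <- lh
  jsonlite::write_json(qc_json, file.path(config$out_dir, "readproc_qc.json"),
                       digits = NA, auto_unbox = TRUE)

  # 4. enrichment
  enr <- enrichment_table(counts)
  readr::write_tsv(enr, file.path(config$out_dir, "enrichment.tsv"))
  track <- positional_track(enr)
  write_track_bedgraph(track, config$out_dir)
  hits <- call_hits(enr, config$locus, threshold = config$threshold)
  readr::write_tsv(hits, file.path(config$out_dir, "hits.tsv"))

  # 5. scan
  scan <- scan_profile(enr, regions, window_size = config$window_size)
  readr::write_tsv(as_tibble(scan), file.path(config$out_dir, "scan.tsv"))
  write_scan_bedgraph(scan, config$out_dir)

  # 6. library QC: distances (1-mismatch remap), saturation, capacity
  ann1 <- map_spacers(unique(counts$spacer), regions, max_mismatch = 1)
  obs_sites <- ann1 |>
    filter(.data$status == "mapped") |>
    distinct(.data$region_id, .data$third_last_pos, .data$pam_class)
  obs_dist <- neighbor_distances(obs_sites)
  theo_dist <- theoretical_distances(regions)
  mapped_reads <- demux |>
    filter(!is.na(.data$sample_id)) |>
    inner_join(filter(ann, .data$status == "mapped"), by = "spacer")
  sizes <- unique(pmax(1L, as.integer(
    round(config$saturation_sizes * nrow(mapped_reads)))))
  sat <- saturation_curve(mapped_reads, sizes, seed = seeds[5])
  readr::write_tsv(as_tibble(sat), file.path(config$out_dir, "saturation.tsv"))
  cap <- capacity_estimate(sum(regions$length), config$chipper$clone_count,
                           max(sizes))
  qc <- list(
    observed_median_ngg_distance = obs_dist$median,
    theoretical_median_ngg_distance = theo_dist$median,
    n_unique_spacers = dplyr::n_distinct(counts$spacer),
    n_unique_mapped = sum(ann$status == "mapped"),
    capacity = as.list(cap)
  )
  jsonlite::write_json(qc, file.path(config$out_dir, "library_qc.json"),
                       digits = NA, auto_unbox = TRUE)
  readr::write_tsv(obs_dist$histogram,
                   file.path(config$out_dir, "distances_observed.tsv"))
  readr::write_tsv(theo_dist$histogram,
                   file.path(config$out_dir, "distances_theoretical.tsv"))

  # manifest
  files <- sort(setdiff(list.files(config$out_dir),
                        c("manifest.json", "regions.fasta", "report.md")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("chipperscan")),
    master_seed = config$seed,
    derived_seeds = seeds,
    input_checksum = unname(tools::md5sum(
      write_regions_fasta(regions, file.path(config$out_dir, "regions.fasta")))),
    files = as.list(setNames(
      unname(tools::md5sum(file.path(config$out_dir, files))), files))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(library = lib, counts = counts, enrichment = enr,
                 track = track, hits = hits, scan = scan, qc = qc,
                 manifest = manifest))
}

#' Read a run configuration from YAML
#'
#' The YAML file references the regions FASTA by path and carries the
#' simulation and analysis parameters inline, e.g.:
#'
#' ```yaml
#' regions_fasta: regions.fasta
#' out_dir: run1
#' seed: 1
#' chipper: {n_fragments: 10000, clone_count: 1500000}
#' screen: {n_cells: 1.0e7, replicates: 3, read_depth: 750000}
#' locus: {region_id: mir_locus, start: 0, end: 2000}
#' truth:
#'   - {region_id: mir_locus, start: 700, end: 760,
#'      element_class: five_prime_hit,
#'      p_neg: 0.3, p_low: 0.6, p_med: 0.07, p_high: 0.03}
#' ```
#'
#' Unlisted parameters take their defaults. Relative paths resolve against
#' the YAML file's directory.
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
run_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y$regions_fasta)) abort("YAML must name a regions_fasta")
  fasta <- y$regions_fasta
  if (!file.exists(fasta)) fasta <- file.path(dirname(path), y$regions_fasta)
  regions <- load_regions(fasta)
  truth <- NULL
  if (!is.null(y$truth)) {
    tt <- bind_rows(lapply(y$truth, as_tibble))
    truth <- truth_elements(tt$region_id, tt$start, tt$end,
                            tt$element_class, tt$p_neg, tt$p_low,
                            tt$p_med, tt$p_high,
                            priority = tt[["priority"]])
  }
  chip <- do.call(chipper_params, y$chipper %||% list())
  scr <- do.call(screen_config, y$screen %||% list())
  run_config(
    regions = regions,
    out_dir = y$out_dir %||% "chipperscan_run",
    truth = truth, chipper = chip, screen = scr,
    locus = y$locus,
    window_size = y$window_size %||% 21,
    threshold = y$threshold %||% 2,
    max_mismatch = y$max_mismatch %||% 0,
    saturation_sizes = unlist(y$saturation_sizes) %||% c(0.1, 0.25, 0.5, 1),
    seed = y$seed %||% 1
  )
}

#' Write a region table as FASTA
#'
#' @param regions Region tibble.
#' @param path Output path.
#' @return `path`, invisibly... returned visibly for checksum chaining.
#' @export
write_regions_fasta <- function(regions, path) {
  dss <- Biostrings::DNAStringSet(regions$sequence)
  names(dss) <- regions$region_id
  Biostrings::writeXStringSet(dss, path)
  path
}

#' Summarise a completed run directory
#'
#' Reads the artifacts of [run_chipper_screen()] (no recomputation) and
#' writes a self-contained markdown report: processing QC, length
#' distribution, hit list, scan peaks and their overlap with planted truth
#' elements when present. Regeneration is idempotent. Missing artifacts are
#' listed rather than fatal.
#'
#' @param run_dir A run directory.
#' @param path Report path (default `report.md` inside `run_dir`).
#' @return The report path, invisibly; the parsed summary as attribute
#'   `summary`.
#' @export
report_run <- function(run_dir, path = file.path(run_dir, "report.md")) {
  need <- c("counts.tsv", "enrichment.tsv", "hits.tsv", "scan.tsv",
            "readproc_qc.json", "library_qc.json", "manifest.json")
  present <- file.exists(file.path(run_dir, need))
  lines <- c("# Screen run report", "")
  if (any(!present)) {
    lines <- c(lines, "Missing artifacts:",
               paste0("- ", need[!present]), "")
  }
  summary <- list(missing = need[!present])
  if (file.exists(file.path(run_dir, "readproc_qc.json"))) {
    qc <- jsonlite::read_json(file.path(run_dir, "readproc_qc.json"))
    lines <- c(lines, "## Read processing",
               sprintf("- input reads: %s", qc$n_input),
               sprintf("- rejected (no scaffold/barcode): %s", qc$n_rejected),
               sprintf("- unassigned barcodes: %s", qc$n_unassigned),
               sprintf("- assigned: %s", qc$n_assigned), "")
    summary$readproc <- qc
  }
  if (file.exists(file.path(run_dir, "library_qc.json"))) {
    lqc <- jsonlite::read_json(file.path(run_dir, "library_qc.json"))
    lines <- c(lines, "## Library QC",
               sprintf("- unique spacers: %s", lqc$n_unique_spacers),
               sprintf("- observed median NGG neighbour distance: %s bp",
                       lqc$observed_median_ngg_distance),
               sprintf("- theoretical median NGG neighbour distance: %s bp",
                       lqc$theoretical_median_ngg_distance),
               sprintf("- capacity: %s-fold, up to %s bp input",
                       lqc$capacity$fold, lqc$capacity$max_input_bp), "")
    summary$library_qc <- lqc
  }
  if (file.exists(file.path(run_dir, "hits.tsv"))) {
    hits <- readr::read_tsv(file.path(run_dir, "hits.tsv"),
                            show_col_types = FALSE)
    nh <- sum(hits$is_hit)
    lines <- c(lines, "## Hits", sprintf("- hit sgRNAs: %d", nh))
    if (nh > 0) {
      top <- hits |> filter(.data$is_hit) |>
        dplyr::slice_head(n = 10)
      lines <- c(lines, "", "| spacer | region | last base (1-based) |",
                 "|---|---|---|",
                 sprintf("| %s | %s | %d |", top$spacer, top$region_id,
                         top$last_base_pos + 1L))
    } else {
      lines <- c(lines, "- (empty hit list)")
    }
    lines <- c(lines, "")
    summary$n_hits <- nh
  }
  if (file.exists(file.path(run_dir, "scan.tsv"))) {
    scan <- readr::read_tsv(file.path(run_dir, "scan.tsv"),
                            show_col_types = FALSE)
    peaks <- scan_peaks(scan)
    truth_path <- file.path(run_dir, "truth.json")
    if (file.exists(truth_path)) {
      truth <- jsonlite::read_json(truth_path, simplifyVector = TRUE)
      peaks <- peaks |>
        left_join(as_tibble(truth) |>
                    select("region_id", "start", "end", "element_class"),
                  by = "region_id", relationship = "many-to-many") |>
        mutate(in_element = !is.na(.data$start) &
                 .data$peak_pos >= .data$start & .data$peak_pos < .data$end) |>
        group_by(.data$replicate, .data$bin, .data$region_id,
                 .data$peak_pos, .data$peak_value) |>
        summarise(in_truth_element = any(.data$in_element),
                  .groups = "drop")
    }
    lines <- c(lines, "## Scan peaks",
               utils::capture.output(print(as.data.frame(peaks))), "")
    summary$peaks <- peaks
  }
  writeLines(lines, path)
  structure(invisible(path), summary = summary)
}
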