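#' Neighbour-distance statistics between sgRNA sites
#'
#' Distances are measured between the third-last bases of the sgRNA target
#' recognition domains, pooled across strands within each region, sorted and
#' differenced; distances never cross region boundaries. By default only
#' NGG-PAM sites enter the calculation.
#'
#' @param sites Tibble with `region_id`, `third_last_pos`, `pam_class`
#'   columns (theoretical sites from [enumerate_sites()] or observed mapped
#'   sgRNAs from [map_spacers()]).
#' @param pam_scope PAM classes included (default `"NGG"`; `NULL` = all).
#' @return List of class `distance_stats`: `distances` (tibble `region_id`,
#'   `distance`), `median`, `mean`, `n`, `histogram` (tibble `distance`,
#'   `count`), `pam_scope`, `empty` flag.
#' @export
#' @examples
#' s <- tibble::tibble(region_id = "r", third_last_pos = c(10, 18, 19, 40),
#'                     pam_class = "NGG")
#' neighbor_distances(s)$median # 8
neighbor_distances <- function(sites, pam_scope = "NGG") {
  x <- as_tibble(sites)
  if (!is.null(pam_scope)) x <- x |> filter(.data$pam_class %in% pam_scope)
  x <- x |> filter(!is.na(.data$third_last_pos))
  dists <- x |>
    group_by(.data$region_id) |>
    summarise(distance = list(diff(sort(.data$third_last_pos))),
              .groups = "drop") |>
    tidyr::unnest("distance")
  empty <- nrow(dists) == 0
  hist <- dists |> count(.data$distance, name = "count")
  structure(list(
    distances = dists,
    median = if (empty) NA_real_ else median(dists$distance),
    mean = if (empty) NA_real_ else mean(dists$distance),
    n = nrow(dists),
    histogram = hist,
    pam_scope = pam_scope %||% "all",
    empty = empty
  ), class = "distance_stats")
}

#' @export
print.distance_stats <- function(x, ...) {
  cat(sprintf("<distance_stats> %s sites: %d gaps, median %.4g bp, mean %.4g bp\n",
              paste(x$pam_scope, collapse = "/"), x$n, x$median, x$mean))
  invisible(x)
}

#' Median recomputed from the distance histogram
#'
#' Independent of the sorted-array median; used as an internal consistency
#' check.
#'
#' @param stats A `distance_stats` object.
#' @return The median distance.
#' @export
histogram_median <- function(stats) {
  h <- stats$histogram |> arrange(.data$distance)
  if (nrow(h) == 0) return(NA_real_)
  rep_d <- rep(h$distance, h$count)
  median(rep_d)
}

#' Theoretical neighbour distances assuming every site is present
#'
#' Enumerates all possible sites on the regions, then computes neighbour
#' distances.
#'
#' @param regions Region tibble.
#' @param spacer_len Protospacer length (default 19).
#' @param pam_scope PAM classes (default `"NGG"`).
#' @return A `distance_stats` object.
#' @export
theoretical_distances <- function(regions, spacer_len = 19,
                                  pam_scope = "NGG") {
  sites <- enumerate_sites(regions, spacer_len = spacer_len)
  neighbor_distances(sites, pam_scope = pam_scope)
}

#' Saturation subsampling curve
#'
#' Randomly subsamples mapped reads (without replacement) at increasing
#' sizes and reports unique sgRNAs detected and the median NGG neighbour
#' distance at each size. Subsamples are nested -- each larger subsample
#' contains every smaller one -- so unique counts are exactly nondecreasing
#' in size within a draw.
#'
#' @param reads Tibble of mapped reads, one row per read: columns `spacer`,
#'   and (for the distance statistic) `region_id`, `third_last_pos`,
#'   `pam_class`.
#' @param sizes Integer subsample sizes (all `<=` number of reads).
#' @param seed Integer seed.
#' @param n_draws Independent draws (default 5); results are reported per
#'   draw.
#' @return Tibble of class `saturation_curve`: `draw`, `size`, `n_unique`,
#'   `median_ngg_distance`.
#' @export
saturation_curve <- function(reads, sizes, seed = 1, n_draws = 5) {
  n <- nrow(reads)
  if (any(sizes > n)) abort("Subsample size exceeds the number of reads")
  sizes <- sort(unique(as.integer(sizes)))
  seeds <- derive_seeds(seed, n_draws)
  out <- list()
  for (d in seq_len(n_draws)) {
    perm <- withr::with_seed(seeds[d], sample.int(n))
    for (s in sizes) {
      sub <- reads[perm[seq_len(s)], , drop = FALSE]
      med <- NA_real_
      if (all(c("region_id", "third_last_pos", "pam_class") %in% names(sub))) {
        uniq_sites <- sub |>
          filter(.data$pam_class %in% "NGG") |>
          distinct(.data$region_id, .data$third_last_pos)
        if (nrow(uniq_sites) >= 2) {
          med <- neighbor_distances(
            mutate(uniq_sites, pam_class = "NGG"))$median
        }
      }
      out[[length(out) + 1]] <- tibble(
        draw = d, size = s,
        n_unique = dplyr::n_distinct(sub$spacer),
        median_ngg_distance = med)
    }
  }
  res <- bind_rows(out)
  class(res) <- c("saturation_curve", class(res))
  res
}

#' Input-capacity extrapolation
#'
#' If `reference_reads` subsampled reads already recover most of the library
#' at acceptable density, then a clone count `fold = clone_count /
#' reference_reads` times larger supports proportionally longer input DNA:
#' `max_input_bp = floor(fold) * input_length_bp` (the conservative integer
#' fold).
#'
#' @param input_length_bp Total input DNA length (bp).
#' @param clone_count Library clone count.
#' @param reference_reads Reference subsample size (> 0).
#' @return One-row tibble: `fold`, `fold_integer`, `max_input_bp`.
#' @export
#' @examples
#' capacity_estimate(9000, 1.5e6, 160000) # fold 9.375, 81 kb
capacity_estimate <- function(input_length_bp, clone_count, reference_reads) {
  if (reference_reads <= 0) abort("reference_reads must be > 0")
  fold <- clone_count / reference_reads
  tibble(fold = fold, fold_integer = floor(fold),
         max_input_bp = floor(fold) * input_length_bp)
}

#' Subsample recovery percentage
#'
#' Percentage of the library's unique sgRNAs already detected in a
#' subsample.
#'
#' @param n_unique_subsample Unique sgRNAs in the subsample.
#' @param n_unique_total Unique sgRNAs in the full data.
#' @return Percentage (0-100).
#' @export
subsample_recovery <- function(n_unique_subsample, n_unique_total) {
  stopifnot(n_unique_total > 0)
  100 * n_unique_subsample / n_unique_total
}
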