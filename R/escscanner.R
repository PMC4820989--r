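#' Fit the normal null model for sgRNA enrichment scores
#'
#' The bulk of NGG-PAM sgRNA enrichment scores in a sample is approximately
#' normal; the window-cluster statistic converts each score to an upper-tail
#' probability under this null. The fit is the sample mean and standard
#' deviation (n-1 denominator) of all finite scores; an optional symmetric
#' trim (e.g. `trim = 0.05` drops 2.5% from each tail) restricts the fit to
#' the central bulk, and is off by default.
#'
#' @param scores Numeric vector of log2 enrichment scores (>= 3 finite).
#' @param trim Total fraction trimmed (0 = none).
#' @param scope Optional label (e.g. "r1/low") carried on the object.
#' @return An object of class `sgrna_null` with fields `mu`, `sigma`,
#'   `n_fit`, `scope`.
#' @export
#' @examples
#' fit_null(c(0, 2, 4)) # mu 2, sigma 2
fit_null <- function(scores, trim = 0, scope = NULL) {
  x <- scores[is.finite(scores)]
  if (trim > 0) {
    q <- stats::quantile(x, c(trim / 2, 1 - trim / 2), names = FALSE)
    x <- x[x >= q[1] & x <= q[2]]
  }
  if (length(x) < 3) abort("Need at least 3 finite scores to fit the null")
  sigma <- sd(x)
  if (sigma == 0) abort("Degenerate null: all scores equal")
  structure(list(mu = mean(x), sigma = sigma, n_fit = length(x),
                 scope = scope),
            class = "sgrna_null")
}

#' @export
print.sgrna_null <- function(x, ...) {
  cat(sprintf("<sgrna_null>%s mu = %.4f, sigma = %.4f (n = %d)\n",
              if (is.null(x$scope)) "" else paste0(" [", x$scope, "]"),
              x$mu, x$sigma, x$n_fit))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the fitted null model
#'
#' @param x An `sgrna_null` object.
#' @param ... Unused.
#' @return One-row tibble with `term`-free parameter columns `mu`, `sigma`.
#' @export
tidy.sgrna_null <- function(x, ...) {
  tibble(parameter = c("mu", "sigma"), estimate = c(x$mu, x$sigma))
}

#' @rdname tidy.sgrna_null
#' @return `glance()`: one-row tibble `mu`, `sigma`, `n_fit`, `scope`.
#' @export
glance.sgrna_null <- function(x, ...) {
  tibble(mu = x$mu, sigma = x$sigma, n_fit = x$n_fit,
         scope = x$scope %||% NA_character_)
}

#' Upper-tail probability of a score under the null
#'
#' `P(X > score)` for `X ~ Normal(mu, sigma)`, floored at 1e-300 so that
#' `-log10` stays finite.
#'
#' @param score Numeric vector of scores.
#' @param null An `sgrna_null` model.
#' @return Probabilities in `(0, 1]`.
#' @export
#' @examples
#' m <- fit_null(c(-1, 0, 1))
#' tail_probability(m$mu, m) # 0.5
tail_probability <- function(score, null) {
  pmax(pnorm(score, mean = null$mu, sd = null$sigma, lower.tail = FALSE),
       1e-300)
}

#' Window-cluster scan of one region
#'
#' For every nucleotide position c of the region, the window
#' `[c - hw, c + hw]` (hw = (window_size - 1)/2; clipped at the region ends,
#' so edge windows are effectively smaller) collects the unique sgRNAs whose
#' last targeting-domain base lies inside it; the window probability is the
#' product of their upper-tail probabilities under the null, and the profile
#' value is `-log10` of that product (0 for an empty window). Both strands
#' pool into the same window. By default only NGG-PAM sgRNAs are scanned.
#'
#' @param records Tibble of scored, mapped sgRNAs for one (replicate, bin):
#'   columns `spacer`, `last_base_pos`, `log2_enrichment`, `pam_class`,
#'   `status` (optional; non-`mapped` rows are dropped).
#' @param region_length Length of the region in bp.
#' @param null An `sgrna_null` model.
#' @param window_size Odd window width in bp (default 21).
#' @param pam_filter PAM classes scanned (default `"NGG"`).
#' @return Tibble of class `scan_profile`: `pos` (0-based center), `value`
#'   (`-log10` window probability, >= 0), `n_sgrnas` (members in window).
#' @export
scan_region <- function(records, region_length, null, window_size = 21,
                        pam_filter = "NGG") {
  if (window_size %% 2 == 0) abort("window_size must be odd")
  hw <- (window_size - 1) / 2
  x <- as_tibble(records)
  if ("status" %in% names(x)) x <- x |> filter(.data$status == "mapped")
  x <- x |>
    filter(.data$pam_class %in% pam_filter,
           .data$last_base_pos >= 0,
           .data$last_base_pos < region_length) |>
    distinct(.data$spacer, .keep_all = TRUE)
  nll <- numeric(region_length)   # per-position sum of -log10 p
  cnt <- numeric(region_length)
  if (nrow(x) > 0) {
    p <- tail_probability(x$log2_enrichment, null)
    contrib <- -log10(p)
    pos1 <- x$last_base_pos + 1L
    nll <- as.numeric(tapply(contrib, factor(pos1, levels = seq_len(region_length)),
                             sum, default = 0))
    cnt <- as.numeric(tapply(rep(1, nrow(x)),
                             factor(pos1, levels = seq_len(region_length)),
                             sum, default = 0))
  }
  csum <- c(0, cumsum(nll))
  ccnt <- c(0, cumsum(cnt))
  centers <- seq_len(region_length)          # 1-based index
  lo <- pmax(centers - hw, 1)
  hi <- pmin(centers + hw, region_length)
  value <- csum[hi + 1] - csum[lo]
  nmem <- ccnt[hi + 1] - ccnt[lo]
  out <- tibble(pos = centers - 1L, value = value,
                n_sgrnas = as.integer(nmem))
  class(out) <- c("scan_profile", class(out))
  out
}

#' Window-cluster profiles for a whole screen
#'
#' Fits one null per (replicate, bin) on all NGG-PAM scores of that sample
#' (across regions, floored scores included), then scans every region.
#'
#' @param enr Enrichment tibble from [enrichment_table()] with mapping
#'   annotation.
#' @param regions Region tibble.
#' @param window_size,pam_filter See [scan_region()].
#' @param trim Null-fit trim fraction (see [fit_null()]).
#' @return Tibble of class `scan_profile`: `replicate`, `bin`, `region_id`,
#'   `pos`, `value`, `n_sgrnas`; attribute `nulls` holds the per-sample
#'   fitted models.
#' @export
scan_profile <- function(enr, regions, window_size = 21, pam_filter = "NGG",
                         trim = 0) {
  samples <- enr |> distinct(.data$replicate, .data$bin)
  nulls <- list()
  out <- list()
  for (i in seq_len(nrow(samples))) {
    r <- samples$replicate[i]; b <- samples$bin[i]
    sub <- enr |>
      filter(.data$replicate == r, .data$bin == b,
             .data$status == "mapped", .data$pam_class %in% pam_filter)
    null <- fit_null(sub$log2_enrichment, trim = trim,
                     scope = paste0("r", r, "/", b))
    nulls[[paste0("r", r, "_", b)]] <- null
    for (j in seq_len(nrow(regions))) {
      prof <- scan_region(
        sub |> filter(.data$region_id == regions$region_id[j]),
        regions$length[j], null, window_size = window_size,
        pam_filter = pam_filter)
      out[[length(out) + 1]] <- prof |>
        mutate(replicate = r, bin = b, region_id = regions$region_id[j]) |>
        relocate("replicate", "bin", "region_id")
    }
  }
  res <- bind_rows(out)
  attr(res, "nulls") <- nulls
  class(res) <- c("scan_profile", class(res))
  res
}

#' Peak windows of a scan profile
#'
#' @param profile A `scan_profile` tibble.
#' @return One row per (replicate, bin): the global-argmax center position
#'   and value.
#' @export
scan_peaks <- function(profile) {
  profile |>
    group_by(.data$replicate, .data$bin) |>
    slice_max(.data$value, n = 1, with_ties = FALSE) |>
    ungroup() |>
    select("replicate", "bin", "region_id", peak_pos = "pos",
           peak_value = "value", "n_sgrnas")
}

#' Write scan profiles as bedGraph (one file per replicate and bin)
#'
#' @param profile A `scan_profile` tibble (multi-sample form).
#' @param dir Output directory.
#' @param prefix File name prefix.
#' @return Written paths, invisibly.
#' @export
write_scan_bedgraph <- function(profile, dir, prefix = "scan") {
  groups <- profile |> distinct(.data$replicate, .data$bin)
  paths <- character(0)
  for (i in seq_len(nrow(groups))) {
    g <- profile |>
      filter(.data$replicate == groups$replicate[i],
             .data$bin == groups$bin[i])
    path <- file.path(dir, paste0(prefix, "_r", groups$replicate[i], "_",
                                  groups$bin[i], ".bedGraph"))
    readr::write_tsv(
      tibble(chrom = g$region_id, start = g$pos, end = g$pos + 1L,
             value = g$value),
      path, col_names = FALSE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
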