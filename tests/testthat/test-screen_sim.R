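make_tiny_library <- function() {
  # hand-built pool: one NGG sgRNA inside the element, one NGG outside,
  # one NGA inside, one junction read
  lib <- tibble::tibble(
    targeting_domain = paste0("G", c(strrep("A", 19), strrep("C", 19),
                                     strrep("T", 19), strrep("G", 19))),
    insert_seq = c(strrep("A", 19), strrep("C", 19), strrep("T", 19),
                   strrep("G", 19)),
    insert_len = 19L,
    junction = c(FALSE, FALSE, FALSE, TRUE),
    region_id = c("locus", "locus", "locus", NA),
    strand = c("+", "+", "+", NA),
    spacer_start = c(10L, 200L, 12L, NA),
    pam_seq = c("TGG", "AGG", "TGA", NA),
    pam_class = c("NGG", "NGG", "NGA", NA),
    clones = c(100L, 100L, 100L, 100L)
  )
  class(lib) <- c("chipper_library", class(lib))
  lib
}

element_truth <- function() {
  truth_elements(region_id = "locus", start = 20L, end = 40L,
                 element_class = "five_prime_hit",
                 p_neg = 0, p_low = 0, p_med = 0, p_high = 1)
}

test_that("bin profiles mix element effect with cutting probability", {
  lib <- make_tiny_library()
  truth <- element_truth()
  eff <- assign_effects(lib, truth, screen_config())
  # plus-strand cut site = spacer_start + 16: in-element NGG sgRNA (26)
  in_el <- eff[eff$spacer_start %in% 10L & eff$pam_class %in% "NGG", ]
  expect_equal(in_el$cut_pos, 26L)
  expect_equal(c(in_el$p_neg, in_el$p_low, in_el$p_med, in_el$p_high),
               c(0.2, 0, 0, 0.8))
  # outside all elements -> neg point mass regardless of PAM
  out_el <- eff[eff$spacer_start %in% 200L, ]
  expect_equal(out_el$p_neg, 1)
  # NGA under WT Cas9: activity 0.05, in element
  nga <- eff[eff$pam_class %in% "NGA", ]
  expect_equal(c(nga$p_neg, nga$p_high), c(0.95, 0.05))
  # junction sgRNAs are inert
  jn <- eff[eff$junction, ]
  expect_equal(jn$cut_prob, 0)
  expect_equal(jn$p_neg, 1)
})

test_that("zero activity gives a neg point mass", {
  lib <- make_tiny_library()
  cfg <- screen_config(pam_activity = tibble::tibble(
    variant = "WT", pam_class = c("NGG", "NGA", "OTHER"), activity = 0))
  eff <- assign_effects(lib, element_truth(), cfg)
  expect_true(all(eff$p_neg == 1))
})

test_that("Cas9 variants combine independently on cut probability", {
  lib <- make_tiny_library()
  cfg <- screen_config(cas9_variants = c("WT", "VQR"))
  eff <- assign_effects(lib, element_truth(), cfg)
  ngg <- eff[eff$pam_class %in% "NGG" & eff$spacer_start %in% 10L, ]
  expect_equal(ngg$cut_prob, 1 - (1 - 0.8) * (1 - 0.05))
  nga <- eff[eff$pam_class %in% "NGA", ]
  expect_equal(nga$cut_prob, 1 - (1 - 0.05) * (1 - 0.4))
})

test_that("overlapping truth elements require a priority order", {
  lib <- make_tiny_library()
  overlap <- truth_elements(
    region_id = c("locus", "locus"), start = c(20L, 25L), end = c(40L, 45L),
    element_class = c("five_prime_hit", "three_prime_hit"),
    p_neg = c(0, 0), p_low = c(1, 0), p_med = c(0, 0), p_high = c(0, 1))
  expect_error(assign_effects(lib, overlap, screen_config()), "priority")
  overlap$priority <- c(1L, 2L)
  eff <- assign_effects(lib, overlap, screen_config())
  in_el <- eff[eff$spacer_start %in% 10L & eff$pam_class %in% "NGG", ]
  expect_equal(in_el$p_low, 0.8)   # element 1 wins
})

test_that("a one-sgRNA pure-high library puts all high-bin reads on it", {
  lib <- make_tiny_library()[1, ]
  truth <- element_truth()
  cfg <- screen_config(n_cells = 1000, replicates = 1, read_depth = 500,
                       pam_activity = tibble::tibble(
                         variant = "WT", pam_class = "NGG", activity = 1),
                       seed = 3)
  eff <- assign_effects(lib, truth, cfg)
  cnt <- suppressWarnings(simulate_screen_counts(eff, cfg))
  high <- cnt[cnt$bin == "high", ]
  expect_equal(nrow(high), 1L)
  expect_equal(high$spacer, strrep("A", 19))
  expect_equal(high$count, 500L)
})

test_that("screen counts are seed-deterministic", {
  lib <- make_tiny_library()
  cfg <- screen_config(n_cells = 5000, replicates = 2, read_depth = 2000,
                       seed = 12)
  eff <- assign_effects(lib, element_truth(), cfg)
  c1 <- suppressWarnings(simulate_screen_counts(eff, cfg))
  c2 <- suppressWarnings(simulate_screen_counts(eff, cfg))
  expect_equal(as.data.frame(c1), as.data.frame(c2), ignore_attr = TRUE)
})

test_that("neutral screens reproduce library frequencies in the neg bin", {
  reg <- random_region(2000, seed = 71, region_id = "locus")
  lib <- build_library(reg, chipper_params(n_fragments = 1000,
                                           clone_count = 50000), seed = 9)
  cfg <- screen_config(n_cells = 2e6, replicates = 1, read_depth = 1e6,
                       seed = 13)
  eff <- assign_effects(lib, NULL, cfg)
  cnt <- suppressWarnings(simulate_screen_counts(eff, cfg))
  neg <- cnt[cnt$bin == "neg", ]
  joined <- dplyr::inner_join(
    dplyr::slice_max(tibble::as_tibble(lib), clones, n = 20,
                     with_ties = FALSE),
    neg, by = c(insert_seq = "spacer"))
  expect_equal(nrow(joined), 20L)
  lib_freq <- joined$clones / sum(lib$clones)
  obs_freq <- joined$count / sum(neg$count)
  se <- sqrt(lib_freq * (1 - lib_freq) / sum(neg$count)) +
    sqrt(lib_freq * (1 - lib_freq) / cfg$n_cells)
  expect_true(all(abs(obs_freq - lib_freq) < 4 * se + 1e-6))
})

test_that("emitted reads have the amplicon structure spacer+scaffold+barcode", {
  counts <- tibble::tibble(sample_id = "r1_low", replicate = 1L, bin = "low",
                           spacer = strrep("A", 19), count = 2L)
  bc <- tibble::tibble(sample_id = "r1_low", replicate = 1L, bin = "low",
                       barcode = "cgtgat")
  cfg <- screen_config(sequencing_error_rate = 0)
  path <- withr::local_tempfile(fileext = ".fastq")
  emit_reads(counts, bc, cfg, path)
  lines <- readLines(path)
  expect_equal(length(lines), 8L)
  expect_true(startsWith(lines[2],
                         paste0(strrep("A", 19), "GTTTTAGAGCTAGAAATAGC",
                                "CGTGAT")))
  expect_equal(nchar(lines[4]), nchar(lines[2]))

  # empty count table -> empty FASTQ; missing barcode -> error
  emit_reads(counts[0, ], bc, cfg, path)
  expect_equal(length(readLines(path)), 0L)
  expect_error(emit_reads(dplyr::mutate(counts, sample_id = "r9_x"), bc,
                          cfg, path), "barcode")
})

test_that("bin proportions converge to the assigned mixture", {
  lib <- make_tiny_library()[1, ]
  truth <- element_truth()
  cfg <- screen_config(n_cells = 1e6, replicates = 1, read_depth = 1000,
                       seed = 19)
  eff <- assign_effects(lib, truth, cfg)
  cnt <- suppressWarnings(simulate_screen_counts(eff, cfg))
  cells <- attr(cnt, "cells")
  tot <- cells$cells_neg + cells$cells_low + cells$cells_med +
    cells$cells_high
  expect_lt(abs(cells$cells_high / tot - 0.8), 0.01)
  expect_lt(abs(cells$cells_neg / tot - 0.2), 0.01)
})
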