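test_that("digest geometry derives 19/17 released bases from the enzyme cuts", {
  p <- chipper_params()
  expect_equal(p$released_long, 19L)
  expect_equal(p$released_short, 17L)
  expect_equal(p$released_long, p$ecop15i_cut_bottom - p$adaptor_spacer_len)
  expect_equal(p$released_short, p$ecop15i_cut_top - p$adaptor_spacer_len)
  expect_error(chipper_params(fragment_min = 500, fragment_max = 400),
               "fragment_min")
  expect_error(chipper_params(length_jitter = c(`19` = 0.5)), "sum to 1")
})

test_that("a single-region concatemer at region length is the region itself", {
  r <- region_table(c(r1 = rand_seq(200)))
  cc <- simulate_concatemer(r, 200, seed = 4)
  expect_equal(nrow(cc$pieces), 1L)
  ori <- cc$pieces$orientation
  want <- if (ori == "+") r$sequence else oracle_revcomp(r$sequence)
  expect_equal(cc$sequence, want)
})

test_that("concatemers are seed-deterministic and piece intervals round-trip", {
  set.seed(8)
  r <- region_table(c(a = rand_seq(120), b = rand_seq(250), c = rand_seq(90)))
  c1 <- simulate_concatemer(r, 2000, seed = 11)
  c2 <- simulate_concatemer(r, 2000, seed = 11)
  expect_identical(c1$sequence, c2$sequence)
  expect_identical(c1$pieces, c2$pieces)
  expect_error(simulate_concatemer(r[0, ], 100), "Empty")
  # every piece interval maps back to its region (or its reverse complement)
  for (i in seq_len(nrow(c1$pieces))) {
    pc <- c1$pieces[i, ]
    sub <- substr(c1$sequence, pc$concat_start + 1, pc$concat_end)
    reg <- r$sequence[r$region_id == pc$region_id]
    expect_equal(sub, if (pc$orientation == "+") reg else oracle_revcomp(reg))
  }
})

test_that("fragmentation draws respect bounds and uniform start positions", {
  r <- region_table(c(a = rand_seq(500)))
  cc <- simulate_concatemer(r, 20000, seed = 2)
  p <- chipper_params(n_fragments = 0)
  expect_equal(nrow(fragment_dna(cc, p, seed = 1)), 0L)

  p <- chipper_params(n_fragments = 10000)
  fr <- fragment_dna(cc, p, seed = 3)
  expect_true(all(fr$length >= 400 & fr$length <= 450))
  expect_true(all(fr$start >= 0))
  expect_true(all(fr$start + fr$length <= nchar(cc$sequence)))
  expect_equal(fr$seq[1],
               substr(cc$sequence, fr$start[1] + 1, fr$start[1] + fr$length[1]))

  # starts in the unconstrained range are uniform (chi-square, alpha 0.01)
  p2 <- chipper_params(n_fragments = 100000)
  fr2 <- fragment_dna(cc, p2, seed = 5)
  L <- nchar(cc$sequence)
  inside <- fr2$start[fr2$start < L - 450]
  h <- table(cut(inside, breaks = seq(0, L - 450, length.out = 21),
                 include.lowest = TRUE))
  expect_gt(suppressWarnings(chisq.test(h)$p.value), 0.01)
})

test_that("end release builds G+k domains from both fragment ends", {
  r <- region_table(c(a = rand_seq(5000)))
  cc <- simulate_concatemer(r, 5000, seed = 21)
  # fixed-length release (jitter disabled)
  p <- chipper_params(n_fragments = 50, length_jitter = c(`19` = 1))
  fr <- fragment_dna(cc, p, seed = 1)
  ends <- release_end_sgrnas(fr, cc, r, p, seed = 2)
  expect_equal(nrow(ends), 100L)
  expect_true(all(nchar(ends$targeting_domain) == 20L))
  expect_true(all(substr(ends$targeting_domain, 1, 1) == "G"))

  f1 <- fr[1, ]
  left <- ends[ends$fragment_id == 1 & ends$end == "left", ]
  right <- ends[ends$fragment_id == 1 & ends$end == "right", ]
  expect_equal(left$targeting_domain, paste0("G", substr(f1$seq, 1, 19)))
  expect_equal(right$targeting_domain,
               paste0("G", oracle_revcomp(substr(f1$seq, f1$length - 18,
                                                 f1$length))))
})

test_that("released inserts map back exactly to their recorded region loci", {
  set.seed(31)
  r <- region_table(c(a = rand_seq(300), b = rand_seq(400)))
  cc <- simulate_concatemer(r, 4000, seed = 31)
  p <- chipper_params(n_fragments = 400, fragment_min = 60, fragment_max = 90)
  fr <- fragment_dna(cc, p, seed = 32)
  ends <- release_end_sgrnas(fr, cc, r, p, seed = 33)
  nj <- ends[!ends$junction, ]
  expect_gt(nrow(nj), 0)
  for (i in sample(nrow(nj), min(200, nrow(nj)))) {
    e <- nj[i, ]
    reg <- r$sequence[r$region_id == e$region_id]
    sub <- substr(reg, e$spacer_start + 1, e$spacer_start + e$insert_len)
    expect_equal(e$insert_seq,
                 if (e$strand == "+") sub else oracle_revcomp(sub))
  }
  # junction-free inserts are substrings of a region on either strand
  on_region <- vapply(seq_len(nrow(nj)), function(i) {
    any(grepl(nj$insert_seq[i], r$sequence, fixed = TRUE)) ||
      any(grepl(oracle_revcomp(nj$insert_seq[i]), r$sequence, fixed = TRUE))
  }, logical(1))
  expect_true(all(on_region))
})

test_that("a palindromic fragment releases identical inserts from both ends", {
  half <- rand_seq(20)
  pal <- paste0(half, oracle_revcomp(half))   # 40-bp reverse palindrome
  r <- region_table(c(a = pal))
  cc <- list(sequence = pal,
             pieces = tibble::tibble(piece = 1L, region_id = "a",
                                     region_length = 40L, orientation = "+",
                                     concat_start = 0L, concat_end = 40L))
  class(cc) <- "concatemer"
  fr <- tibble::tibble(fragment_id = 1L, start = 0L, length = 40L, seq = pal)
  p <- chipper_params(length_jitter = c(`19` = 1))
  ends <- release_end_sgrnas(fr, cc, r, p, seed = 1)
  expect_equal(ends$insert_seq[1], ends$insert_seq[2])
})

test_that("build_library samples clones over released ends with provenance", {
  reg <- random_region(2500, seed = 41, region_id = "locus")
  p <- chipper_params(n_fragments = 2000, clone_count = 1)
  lib1 <- build_library(reg, p, seed = 6)
  expect_equal(sum(lib1$clones), 1L)

  p <- chipper_params(n_fragments = 2000, clone_count = 30000)
  lib <- build_library(reg, p, seed = 6)
  lib2 <- build_library(reg, p, seed = 6)
  expect_equal(as.data.frame(lib), as.data.frame(lib2), ignore_attr = TRUE)
  expect_equal(sum(lib$clones), 30000L)

  # non-junction NGG inventory is a subset of the theoretical enumeration,
  # matching coordinates exactly (19-base inserts only)
  sites <- enumerate_sites(reg, spacer_len = 19)
  key <- function(d) paste(d$strand, d$spacer_start, d$pam_class)
  nj <- lib[!lib$junction & lib$insert_len == 19 & !is.na(lib$pam_class), ]
  expect_true(all(key(nj) %in% key(sites)))
  expect_true(all(nj$insert_seq %in% sites$spacer_seq))
})

test_that("targeting-domain length histogram mode follows the jitter mode", {
  reg <- random_region(3000, seed = 51, region_id = "locus")
  lib <- build_library(reg, chipper_params(n_fragments = 3000,
                                           clone_count = 20000), seed = 7)
  lens <- rep(nchar(lib$targeting_domain), lib$clones)
  tab <- table(lens)
  expect_equal(names(tab)[which.max(tab)], "20")
})

test_that("dense fragmentation recovers nearly all enumerable sgRNA ends", {
  reg <- random_region(800, seed = 61, region_id = "locus")
  p <- chipper_params(n_fragments = 40000, clone_count = 200000,
                      length_jitter = c(`19` = 1), fragment_min = 100,
                      fragment_max = 120, concatemer_fold = 50)
  lib <- build_library(reg, p, seed = 8)
  sites <- enumerate_sites(reg, spacer_len = 19, pam_filter = "NGG")
  key <- function(d) paste(d$strand, d$spacer_start)
  nj <- lib[!lib$junction & !is.na(lib$pam_class) & lib$pam_class == "NGG", ]
  coverage <- mean(key(sites) %in% key(nj))
  expect_gte(coverage, 0.99)
})
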