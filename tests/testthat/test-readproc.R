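scaffold <- "GTTTTAGAGCTAGAAATAGC"

test_that("clip_reads finds the wildcard scaffold and splits spacer/barcode", {
  reads <- c(
    paste0(strrep("A", 19), scaffold, "cgtgat", "ATCTCG"),  # normal
    paste0(scaffold, "ACATCG"),                              # empty spacer
    paste0(strrep("A", 19), scaffold),                       # no barcode room
    paste0(strrep("T", 30)),                                 # no match
    paste0("CC", "GACGTACAGCTAGAAATAGC", "GCCTAA", "T")      # any-N wildcard
  )
  cl <- clip_reads(reads)
  expect_equal(cl$spacer[1], strrep("A", 19))
  expect_equal(cl$barcode[1], "CGTGAT")
  expect_equal(cl$spacer[2], "")
  expect_equal(cl$barcode[2], "ACATCG")
  expect_false(cl$clipped[3])
  expect_false(cl$clipped[4])
  expect_true(cl$clipped[5])
  expect_equal(cl$spacer[5], "CC")
  expect_equal(attr(cl, "n_rejected"), 2L)
})

test_that("wildcard positions accept any base (matching a direct oracle)", {
  set.seed(301)
  for (i in 1:25) {
    fill <- rand_seq(6)
    read <- paste0(rand_seq(19), "G", fill, "AGCTAGAAATAGC", "CGTGAT", "AA")
    cl <- clip_reads(read)
    expect_true(cl$clipped)
    expect_equal(nchar(cl$spacer), 19)
    expect_equal(cl$barcode, "CGTGAT")
  }
})

test_that("demultiplexing assigns exactly and conserves reads", {
  bc <- default_barcodes(1, bins = c("neg", "low"))
  reads <- c(
    paste0(strrep("A", 19), scaffold, bc$barcode[1], "AA"),
    paste0(strrep("C", 19), scaffold, bc$barcode[2], "AA"),
    paste0(strrep("C", 19), scaffold, "NNNNNN", "AA"),   # unassignable
    strrep("T", 40)                                      # rejected
  )
  dm <- demultiplex_reads(clip_reads(reads), bc)
  expect_equal(dm$sample_id[1], bc$sample_id[1])
  expect_equal(dm$sample_id[2], bc$sample_id[2])
  expect_true(is.na(dm$sample_id[3]))
  expect_equal(attr(dm, "n_assigned") + attr(dm, "n_unassigned") +
                 attr(dm, "n_rejected"), length(reads))
})

test_that("one-mismatch demultiplexing assigns unambiguous near-misses", {
  bc <- tibble::tibble(sample_id = c("s1", "s2"), replicate = 1L,
                       bin = c("neg", "low"),
                       barcode = c("CGTGAT", "ACATCG"))
  near <- paste0(strrep("A", 19), scaffold, "CGTGAA", "TT")
  dm0 <- demultiplex_reads(clip_reads(near), bc, max_mismatch = 0)
  expect_true(is.na(dm0$sample_id))
  dm1 <- demultiplex_reads(clip_reads(near), bc, max_mismatch = 1)
  expect_equal(dm1$sample_id, "s1")
  # colliding barcodes within the radius are a configuration error
  bad <- tibble::tibble(sample_id = c("s1", "s2"), replicate = 1L,
                        bin = c("neg", "low"),
                        barcode = c("CGTGAT", "CGTGAA"))
  expect_error(demultiplex_reads(clip_reads(near), bad, max_mismatch = 1),
               "radius")
  expect_error(demultiplex_reads(clip_reads(near),
                                 dplyr::mutate(bad, barcode = "CGTGAT")),
               "unique")
})

test_that("mapping agrees with a brute-force Hamming scan", {
  set.seed(302)
  regions <- region_table(c(ra = rand_seq(300), rb = rand_seq(200)))
  for (i in 1:60) {
    mm <- i %% 2
    # half constructed from a region (with 0-2 planted mismatches), half random
    if (i %% 3 == 0) {
      spacer <- rand_seq(19)
    } else {
      ridx <- sample(2, 1)
      s <- sample(0:(regions$length[ridx] - 19), 1)
      spacer <- substr(regions$sequence[ridx], s + 1, s + 19)
      nmut <- sample(0:2, 1)
      if (nmut > 0) {
        ch <- strsplit(spacer, "")[[1]]
        for (p in sample(19, nmut)) ch[p] <- sample(setdiff(c("A","C","G","T"), ch[p]), 1)
        spacer <- paste(ch, collapse = "")
      }
      if (sample(c(TRUE, FALSE), 1)) spacer <- oracle_revcomp(spacer)
    }
    got <- map_spacers(spacer, regions, max_mismatch = mm)
    # oracle: scan every locus on both strands
    n_loci <- 0; oracle_hit <- NULL
    for (ridx in 1:2) {
      seqr <- regions$sequence[ridx]
      for (s in 0:(regions$length[ridx] - 19)) {
        sub <- substr(seqr, s + 1, s + 19)
        if (oracle_hamming(spacer, sub) <= mm) {
          n_loci <- n_loci + 1
          oracle_hit <- c(regions$region_id[ridx], "+", s)
        }
        if (oracle_hamming(spacer, oracle_revcomp(sub)) <= mm) {
          n_loci <- n_loci + 1
          oracle_hit <- c(regions$region_id[ridx], "-", s)
        }
      }
    }
    expect_equal(got$n_loci, n_loci)
    want_status <- if (n_loci == 0) "unmapped" else if (n_loci == 1) "mapped"
      else "multi"
    expect_equal(got$status, want_status)
    if (n_loci == 1) {
      expect_equal(c(got$region_id, got$strand, as.character(got$spacer_start)),
                   oracle_hit)
    }
  }
})

test_that("mapped loci carry reference PAM and coordinate annotation", {
  regions <- region_table(c(ra = paste0(strrep("A", 21), "GGA")))
  got <- map_spacers(strrep("A", 19), regions)
  # two A-run loci exist (starts 0 and 1) -> multi
  expect_equal(got$status, "multi")
  spa <- substr(regions$sequence[1], 2, 20)
  got2 <- map_spacers(substr(regions$sequence[1], 1, 19), regions)
  expect_equal(got2$status, "multi")
  # an unambiguous spacer: use a random region
  set.seed(9)
  regions <- region_table(c(ra = rand_seq(100)))
  s <- 5
  spacer <- substr(regions$sequence[1], s + 1, s + 19)
  got3 <- map_spacers(spacer, regions)
  if (got3$status == "mapped") {
    expect_equal(got3$spacer_start, s)
    expect_equal(got3$strand, "+")
    expect_equal(got3$pam_seq, substr(regions$sequence[1], s + 20, s + 22))
    expect_equal(got3$last_base_pos, s + 18)
    expect_equal(got3$third_last_pos, s + 16)
    # its reverse complement maps to the same interval, minus strand
    got4 <- map_spacers(oracle_revcomp(spacer), regions)
    expect_equal(got4$strand, "-")
    expect_equal(got4$spacer_start, s)
  }
  # too-short spacers are dropped
  expect_equal(map_spacers("ACGTACGT", regions)$status, "too_short")
})

test_that("count tables aggregate identical spacers and conserve totals", {
  assigned <- tibble::tibble(
    sample_id = c("s1", "s1", "s1", "s2", NA),
    replicate = 1L,
    bin = c("neg", "neg", "neg", "low", NA),
    spacer = c("AAA", "AAA", "CCC", "AAA", "TTT"))
  ct <- build_count_table(assigned)
  expect_equal(ct$count[ct$sample_id == "s1" & ct$spacer == "AAA"], 2L)
  expect_equal(ct$count[ct$sample_id == "s1" & ct$spacer == "CCC"], 1L)
  expect_equal(sum(ct$count), sum(!is.na(assigned$sample_id)))
})

test_that("length histogram normalises to the 20-base domain bin", {
  counts <- tibble::tibble(
    replicate = 1L,
    spacer = c(strrep("A", 19), strrep("C", 19), strrep("G", 18)),
    count = c(60L, 30L, 9L))
  h <- length_histogram(counts)
  expect_equal(h$normalized[h$domain_length == 20], 1.0)
  expect_equal(h$normalized[h$domain_length == 19], 0.1)
  h19 <- tibble::tibble(replicate = 1L, spacer = strrep("A", 19), count = 5L)
  expect_equal(length_histogram(h19)$normalized, 1.0)
  no20 <- tibble::tibble(replicate = 1L, spacer = strrep("A", 17), count = 5L)
  expect_warning(length_histogram(no20), "length-20")
})
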