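#' Parameters of the in-silico molecular chipper digest
#'
#' Captures the geometry of the library construction: random fragmentation to
#' 400-450 bp, ligation of an EcoP15I-bearing adaptor whose recognition site
#' sits 8 bp (the adaptor spacer) away from the fragment end, and EcoP15I
#' cleavage 25/27 nt downstream of its site, releasing 17/19 fragment-end
#' bases. The expressed sgRNA targeting domain is a leading G plus the
#' released insert, so with a 19-base insert the domain is 20 bases.
#'
#' `released_long`/`released_short` are derived, not free:
#' `cut_bottom - adaptor_spacer_len = 19` and `cut_top - adaptor_spacer_len =
#' 17`. `length_jitter` is the distribution of the insert length actually
#' cloned (the enzyme's reach varies by a base or two); its default places
#' 0.90 on 19 so that domain lengths are predominantly 20.
#'
#' @param fragment_min,fragment_max Sonication fragment length bounds (bp).
#' @param n_fragments Number of random fragments to draw.
#' @param clone_count Number of transformed clones sampled from the released
#'   ends (default 1.5e6).
#' @param ecop15i_cut_top,ecop15i_cut_bottom Cut distances of EcoP15I from its
#'   recognition site, top/bottom strand (25/27 nt, fixed by the enzyme).
#' @param adaptor_spacer_len Bases between the EcoP15I site and the fragment
#'   end within the adaptor (8, fixed by the adaptor design).
#' @param leading_base Non-genomic base prepended to every insert ("G").
#' @param length_jitter Named numeric vector: insert length -> probability.
#' @param concatemer_fold Ligation concatemer length as a multiple of the
#'   total input length (ligation products average >10 kb).
#' @return A validated list of class `chipper_params`.
#' @export
chipper_params <- function(fragment_min = 400, fragment_max = 450,
                           n_fragments = 10000, clone_count = 1.5e6,
                           ecop15i_cut_top = 25, ecop15i_cut_bottom = 27,
                           adaptor_spacer_len = 8, leading_base = "G",
                           length_jitter = c(`19` = 0.90, `18` = 0.05,
                                             `20` = 0.04, `17` = 0.01),
                           concatemer_fold = 10) {
  if (fragment_min > fragment_max) abort("fragment_min must be <= fragment_max")
  if (abs(sum(length_jitter) - 1) > 1e-9) {
    abort("length_jitter probabilities must sum to 1")
  }
  if (is.null(names(length_jitter))) abort("length_jitter must be named by insert length")
  p <- list(
    fragment_min = as.integer(fragment_min),
    fragment_max = as.integer(fragment_max),
    n_fragments = as.integer(n_fragments),
    clone_count = as.integer(clone_count),
    ecop15i_cut_top = as.integer(ecop15i_cut_top),
    ecop15i_cut_bottom = as.integer(ecop15i_cut_bottom),
    adaptor_spacer_len = as.integer(adaptor_spacer_len),
    released_long = as.integer(ecop15i_cut_bottom - adaptor_spacer_len),
    released_short = as.integer(ecop15i_cut_top - adaptor_spacer_len),
    leading_base = leading_base,
    length_jitter = length_jitter,
    concatemer_fold = concatemer_fold
  )
  structure(p, class = "chipper_params")
}

#' Simulate the random-ligation concatemer
#'
#' Before fragmentation the input pieces are randomly ligated into long linear
#' products (so sequence near piece ends is not under-represented after size
#' selection). Pieces are sampled with replacement, each in a random
#' orientation, until the concatemer reaches `target_length`.
#'
#' @param regions Region tibble (see [load_regions()]).
#' @param target_length Minimum concatemer length in bp.
#' @param seed Optional integer seed.
#' @return List of class `concatemer`: `sequence` (one string) and `pieces`,
#'   a tibble with `piece`, `region_id`, `orientation` (`+`/`-`),
#'   `concat_start`, `concat_end` (0-based half-open concatemer coordinates).
#' @export
simulate_concatemer <- function(regions, target_length, seed = NULL) {
  if (nrow(regions) == 0) abort("Empty region set")
  if (target_length < max(regions$length)) {
    abort("target_length must be >= the longest region")
  }
  build <- function() {
    ids <- integer(0); ori <- character(0); len_total <- 0
    while (len_total < target_length) {
      i <- sample.int(nrow(regions), 1)
      ids <- c(ids, i)
      ori <- c(ori, sample(c("+", "-"), 1))
      len_total <- len_total + regions$length[i]
    }
    list(ids = ids, ori = ori)
  }
  picked <- if (is.null(seed)) build() else withr::with_seed(seed, build())
  seqs <- regions$sequence[picked$ids]
  seqs[picked$ori == "-"] <- revcomp(seqs[picked$ori == "-"])
  lens <- nchar(seqs)
  ends <- cumsum(lens)
  pieces <- tibble(
    piece = seq_along(picked$ids),
    region_id = regions$region_id[picked$ids],
    region_length = regions$length[picked$ids],
    orientation = picked$ori,
    concat_start = ends - lens,
    concat_end = ends
  )
  structure(list(sequence = paste(seqs, collapse = ""), pieces = pieces),
            class = "concatemer")
}

#' Random fragmentation of a concatemer
#'
#' Models sonication as independent interval draws: each fragment has a
#' length uniform on `[fragment_min, fragment_max]` and a start uniform over
#' all positions where it fits. Only fragment ends matter downstream, so a
#' sampling model (rather than a physical partition of molecules) is used.
#'
#' @param concatemer A `concatemer` from [simulate_concatemer()].
#' @param params A [chipper_params()] object.
#' @param seed Optional integer seed.
#' @return Tibble: `fragment_id`, `start` (0-based concatemer coordinate),
#'   `length`, `seq` (top strand).
#' @export
fragment_dna <- function(concatemer, params, seed = NULL) {
  L <- nchar(concatemer$sequence)
  if (L < params$fragment_min) abort("Concatemer shorter than fragment_min")
  if (L <= params$fragment_max) abort("Concatemer must exceed fragment_max")
  n <- params$n_fragments
  if (n == 0) {
    return(tibble(fragment_id = integer(0), start = integer(0),
                  length = integer(0), seq = character(0)))
  }
  draw <- function() {
    len <- sample(params$fragment_min:params$fragment_max, n, replace = TRUE)
    start <- floor(runif(n) * (L - len + 1))
    list(len = as.integer(len), start = as.integer(start))
  }
  d <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble(
    fragment_id = seq_len(n),
    start = d$start,
    length = d$len,
    seq = substring(concatemer$sequence, d$start + 1, d$start + d$len)
  )
}

# Map a concatemer plus-frame interval [start, end) with concatemer-frame
# strand back to region coordinates; junction when it spans piece boundaries.
map_concat_interval <- function(start, end, concat_strand, pieces) {
  idx <- findInterval(start, pieces$concat_start)
  ok <- idx >= 1 & end <= pieces$concat_end[pmax(idx, 1)]
  offset <- start - pieces$concat_start[idx]
  k <- end - start
  ori <- pieces$orientation[idx]
  rlen <- pieces$region_length[idx]
  region_start <- ifelse(ori == "+", offset, rlen - offset - k)
  strand <- ifelse((concat_strand == "+") == (ori == "+"), "+", "-")
  tibble(
    junction = !ok,
    region_id = ifelse(ok, pieces$region_id[idx], NA_character_),
    strand = ifelse(ok, strand, NA_character_),
    spacer_start = ifelse(ok, as.integer(region_start), NA_integer_)
  )
}

# PAM sequence read from the reference at a mapped protospacer locus;
# NA when the PAM would extend beyond the region boundary.
pam_at_site <- function(regions, region_id, strand, spacer_start, spacer_len) {
  seqs <- regions$sequence[match(region_id, regions$region_id)]
  rlen <- nchar(seqs)
  plus <- strand == "+"
  pam <- rep(NA_character_, length(region_id))
  fits_plus <- which(plus & !is.na(spacer_start) &
                       (spacer_start + spacer_len + 3) <= rlen)
  pam[fits_plus] <- substr_vec(
    seqs[fits_plus],
    spacer_start[fits_plus] + spacer_len[fits_plus] + 1,
    spacer_start[fits_plus] + spacer_len[fits_plus] + 3)
  fits_minus <- which(!plus & !is.na(spacer_start) & spacer_start >= 3)
  if (length(fits_minus) > 0) {
    pam[fits_minus] <- revcomp(substr_vec(
      seqs[fits_minus], spacer_start[fits_minus] - 2,
      spacer_start[fits_minus]))
  }
  pam
}

#' Release both fragment-end sgRNA inserts
#'
#' Each fragment yields two EcoP15I-released ends: the left end reads the top
#' strand 5'->3' (insert = first k top-strand bases), the right end reads the
#' bottom strand (insert = reverse complement of the last k top-strand
#' bases), with k drawn from `length_jitter`. The targeting domain is the
#' leading G plus the insert. Provenance coordinates are mapped back through
#' the concatemer piece map; ends spanning a ligation junction are flagged.
#'
#' @param fragments Fragment tibble from [fragment_dna()].
#' @param concatemer The `concatemer` the fragments came from.
#' @param regions Region tibble (for PAM lookup at the mapped locus).
#' @param params A [chipper_params()] object.
#' @param seed Optional integer seed.
#' @return Tibble with one row per released end: `fragment_id`, `end`
#'   (`left`/`right`), `insert_len`, `insert_seq`, `targeting_domain`,
#'   `junction`, `region_id`, `strand`, `spacer_start`, `pam_seq`,
#'   `pam_class`, plus attribute `n_skipped` counting fragments too short to
#'   release.
#' @export
release_end_sgrnas <- function(fragments, concatemer, regions, params,
                               seed = NULL) {
  n <- nrow(fragments)
  klen <- as.integer(names(params$length_jitter))
  draw <- function() klen[sample.int(length(klen), 2 * n, replace = TRUE,
                                     prob = params$length_jitter)]
  ks <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  k_left <- ks[seq_len(n)]
  k_right <- ks[n + seq_len(n)]

  too_short <- fragments$length < pmax(k_left, k_right)
  n_skipped <- sum(too_short)
  frag <- fragments[!too_short, , drop = FALSE]
  k_left <- k_left[!too_short]; k_right <- k_right[!too_short]

  left_insert <- substr_vec(frag$seq, rep(1L, nrow(frag)), k_left)
  right_insert <- revcomp(substr_vec(frag$seq, frag$length - k_right + 1,
                                     frag$length))
  left_map <- map_concat_interval(frag$start, frag$start + k_left, "+",
                                  concatemer$pieces)
  right_map <- map_concat_interval(frag$start + frag$length - k_right,
                                   frag$start + frag$length, "-",
                                   concatemer$pieces)
  ends <- bind_rows(
    bind_cols(tibble(fragment_id = frag$fragment_id, end = "left",
                     insert_len = k_left, insert_seq = left_insert),
              left_map),
    bind_cols(tibble(fragment_id = frag$fragment_id, end = "right",
                     insert_len = k_right, insert_seq = right_insert),
              right_map)
  ) |>
    mutate(
      targeting_domain = paste0(params$leading_base, .data$insert_seq),
      pam_seq = pam_at_site(regions, .data$region_id, .data$strand,
                            .data$spacer_start, .data$insert_len),
      pam_class = classify_pam(.data$pam_seq)
    )
  attr(ends, "n_skipped") <- n_skipped
  ends
}

#' Build an in-silico molecular chipper sgRNA library
#'
#' Runs the whole digest: random ligation into a concatemer, random
#' fragmentation, EcoP15I end release, then samples `clone_count` transformed
#' clones uniformly over all released ends. The result is the clone pool with
#' known provenance -- the synthetic stand-in for the wet-lab library.
#'
#' @param regions Region tibble.
#' @param params A [chipper_params()] object.
#' @param seed Integer master seed for the digest (concatemer, fragmentation,
#'   jitter and cloning streams are derived from it).
#' @return A tibble of class `chipper_library`, one row per distinct
#'   (targeting domain, provenance) with column `clones` (number of clones
#'   carrying it) plus provenance columns as in [release_end_sgrnas()].
#'   Attributes: `params`, `n_ends`, `n_skipped`, `input_bp`, `seed`.
#' @export
build_library <- function(regions, params = chipper_params(), seed = 1) {
  seeds <- derive_seeds(seed, 4)
  target <- max(params$concatemer_fold * sum(regions$length),
                2 * params$fragment_max + 1)
  concat <- simulate_concatemer(regions, target, seed = seeds[1])
  frags <- fragment_dna(concat, params, seed = seeds[2])
  ends <- release_end_sgrnas(frags, concat, regions, params, seed = seeds[3])
  n_ends <- nrow(ends)
  clones <- withr::with_seed(seeds[4], {
    tabulate(sample.int(n_ends, params$clone_count, replace = TRUE), n_ends)
  })
  lib <- ends |>
    mutate(clones = clones) |>
    filter(.data$clones > 0) |>
    group_by(.data$targeting_domain, .data$insert_seq, .data$insert_len,
             .data$junction, .data$region_id, .data$strand,
             .data$spacer_start, .data$pam_seq, .data$pam_class) |>
    summarise(clones = sum(.data$clones), .groups = "drop") |>
    arrange(dplyr::desc(.data$clones), .data$targeting_domain)
  attr(lib, "params") <- params
  attr(lib, "n_ends") <- n_ends
  attr(lib, "n_skipped") <- attr(ends, "n_skipped")
  attr(lib, "input_bp") <- sum(regions$length)
  attr(lib, "seed") <- seed
  class(lib) <- c("chipper_library", class(lib))
  lib
}

#' Export a library pool as TSV
#'
#' @param library A `chipper_library` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library_tsv <- function(library, path) {
  readr::write_tsv(
    select(as_tibble(library), "targeting_domain", "clones", "region_id",
           "strand", "spacer_start", "pam_class", "junction"),
    path)
  invisible(path)
}

#' Export unique targeting domains as FASTA
#'
#' @inheritParams write_library_tsv
#' @return `path`, invisibly.
#' @export
write_library_fasta <- function(library, path) {
  domains <- unique(library$targeting_domain)
  dss <- Biostrings::DNAStringSet(domains)
  names(dss) <- paste0("sgRNA_", seq_along(domains))
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}
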