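# chipperscan

Simulation and analysis of dense CRISPR tiling screens built from type III
restriction-digest (EcoP15I) sgRNA libraries.

## The problem

Mapping functional elements in noncoding DNA with CRISPR requires sgRNA
libraries that tile a region at near-base resolution. One way to build such
a library without microarray synthesis is a "molecular chipper" digest:
randomly ligate the input pieces, sonicate, ligate an adaptor carrying an
EcoP15I site 8 bp from the fragment end, and let EcoP15I — which cuts 25/27
nt downstream of its recognition site — release 17/19 bases of each fragment
end. Each released insert, expressed as `G` + insert, is a 20-base sgRNA
targeting domain. Because NGG PAMs occur every ~8 bp on random DNA (each
strand carries `GG` at the two fixed PAM positions with probability 1/16, so
pooled density is 1/8 per bp), the library densely tiles both strands.

`chipperscan` gives researchers working with such screens a tested, seeded
implementation of the full computational arc:

1. **refmodel** — exhaustive protospacer/PAM enumeration on input regions
   (`load_regions()`, `enumerate_sites()`, `site_density()`);
2. **digest simulator** — the in-silico chipper with provenance tracking
   (`chipper_params()`, `build_library()`);
3. **screen simulator** — a generative FACS-bin reporter screen with planted
   truth elements, emitting barcoded amplicon FASTQ
   (`truth_elements()`, `assign_effects()`, `simulate_screen_counts()`,
   `emit_reads()`);
4. **read processing** — scaffold clipping with the wildcard pattern
   `GNNNNNNAGCTAGAAATAGC`, demultiplexing, exhaustive 0/1-mismatch mapping
   (`clip_reads()`, `demultiplex_reads()`, `map_spacers()`);
5. **enrichment** — floored log2 scores
   `log2(max(f_pos, 1e-8) / max(f_neg, 6.25e-7))`, positional tracks, and
   four-criterion hit calling (score > 2 in high/med or in low GFP bins in
   ≥ 2 replicates, NGG PAM, inside the target locus) (`enrichment_table()`,
   `call_hits()`);
6. **window-cluster scan** — fit a normal null to a sample's NGG scores,
   convert scores to upper-tail probabilities `p_i = 1 - Φ((x_i - μ)/σ)`,
   and report `-log10 Π p_i` over 21-bp windows (`fit_null()`,
   `scan_profile()`);
7. **library QC** — third-last-base neighbour distances (observed vs
   theoretical), nested saturation subsampling, capacity extrapolation
   (`neighbor_distances()`, `saturation_curve()`, `capacity_estimate()`);
8. **workflow** — one-call orchestration with a checksummed manifest
   (`run_config()`, `run_chipper_screen()`, `report_run()`).

All functions are tibble-in/tibble-out and chain with the pipe; fitted null
models support `tidy()`/`glance()`; `plot_*()`/`autoplot()` give ggplot2
figures for each result type.

## Worked example

Simulate a library on a 2-kb synthetic locus, plant a hairpin element and
two flanking regulatory elements, run a 3-replicate screen, and scan:

```r
library(chipperscan)
library(dplyr)

region <- random_region(2000, seed = 11, region_id = "mir_locus")
truth <- truth_elements(
  region_id = rep("mir_locus", 3),
  start = c(950, 700, 1250), end = c(1040, 760, 1310),
  element_class = c("mature_or_pre", "five_prime_hit", "three_prime_hit"),
  p_neg = c(0.05, 0.3, 0.3), p_low = c(0.10, 0.60, 0.60),
  p_med = c(0.35, 0.07, 0.07), p_high = c(0.50, 0.03, 0.03))

lib <- build_library(region,
                     chipper_params(n_fragments = 4000, clone_count = 1e5),
                     seed = 5)
n_distinct(lib$targeting_domain)
#> [1] 4106
theoretical_distances(region)
#> <distance_stats> NGG sites: 238 gaps, median 5 bp, mean 8.345 bp

cfg <- screen_config(n_cells = 2e5, read_depth = 1e5, replicates = 3,
                     sequencing_error_rate = 0, seed = 9)
cnt <- simulate_screen_counts(assign_effects(lib, truth, cfg), cfg)
ann <- map_spacers(unique(cnt$spacer), region)
ct  <- left_join(tibble::as_tibble(cnt), ann, by = "spacer")
enr <- enrichment_table(ct)

hits <- call_hits(enr, list(region_id = "mir_locus", start = 0, end = 2000))
sum(hits$is_hit)
#> [1] 32

scan <- scan_profile(enr, region)
scan_peaks(scan) |> filter(bin == "low")
#> # A tibble: 3 × 6
#>   replicate bin   region_id peak_pos peak_value n_sgrnas
#>       <int> <chr> <chr>        <int>      <dbl>    <int>
#> 1         1 low   mir_locus      744       20.7        7
#> 2         2 low   mir_locus      744       19.1        7
#> 3         3 low   mir_locus      744       20.3        7
```

The digest released 4,106 distinct targeting domains (the theoretical NGG
sites on this locus sit a median 5 bp and mean 8.3 bp apart). Hit calling
flags 32 sgRNAs, all inside the planted elements, and the low-GFP scan peaks
at position 744 in every replicate — inside the planted 5' element
(700–760) — with window values near 20, i.e. the seven clustered sgRNAs'
joint enrichment has probability ~1e-20 under the per-sample null. Flanking
elements surface in the **low** bin (partial loss of reporter repression)
while the hairpin element dominates med/high, so the bin identity of a peak
also reports the kind of element found.

`vignettes/chipperscan-methods.Rmd` documents the models, parameter
defaults, numerical choices and limitations in detail.

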