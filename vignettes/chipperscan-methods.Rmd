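---
title: "Models and methods behind chipperscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chipperscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chipperscan)
library(dplyr)
```

# The problem

Dense CRISPR tiling screens interrogate noncoding DNA by targeting Cas9 at
(nearly) every possible protospacer of a region and reading out which cuts
change a phenotype. One inexpensive way to build such a library is a
restriction-digest scheme: input DNA pieces are randomly ligated, randomly
fragmented, an adaptor carrying an EcoP15I recognition site is ligated onto
the fragment ends, and EcoP15I — a type III enzyme that cuts 25/27 nt away
from its site — releases a defined-length bite of each fragment end. The
released 19-base insert plus a leading non-genomic G becomes the 20-base
targeting domain of an sgRNA. Because sonication breakpoints are essentially
random, the library tiles the input at near-base resolution on both strands.

`chipperscan` implements that whole arc as testable software: exhaustive
protospacer/PAM enumeration, an in-silico digest with full provenance
tracking, a generative model of a FACS-binned reporter screen (the synthetic
stand-in for a wet-lab experiment), read processing back to count tables,
floored log2 enrichment scoring with multi-replicate hit calling, a
window-cluster scan statistic, and library complexity QC.

# Coordinate conventions

All in-memory coordinates are 0-based, half-open, in the plus-strand frame
of a region; written TSV outputs are 1-based inclusive and BED/bedGraph
files follow their native 0-based half-open convention. For a protospacer
occupying plus-frame interval $[s, s+L)$:

* plus strand: `last_base_pos` $= s + L - 1$, `third_last_pos` $= s + L - 3$;
* minus strand: `last_base_pos` $= s$, `third_last_pos` $= s + 2$.

The minus-strand "last base" is the leftmost plus-frame coordinate because
the targeting domain is read 5'→3' on its own strand; the convention is a
package choice (no external standard exists for it) and is applied
consistently to plotting, distances and the scan.

A PAM is classified from its bases 2–3 only (`NGG` if `GG`, `NGA` if `GA`,
else `OTHER`); classification is exclusive and exhaustive. On i.i.d. uniform
DNA each strand carries an NGG PAM at a given position with probability
$1/16$, so pooled over strands the expected site density is $1/8$ per bp —
one sgRNA every ~8 bp, the property that makes the library useful for
noncoding tiling. The package's tests verify this analytic limit on 1 Mb of
seeded random sequence.

# The digest simulator

`chipper_params()` fixes the geometry: 25/27-nt EcoP15I cuts, an 8-bp
adaptor spacer, hence 17/19 released bases (`released_short/long` are
derived, not free), fragments uniform on 400–450 bp, and a default clone
count of 1.5 million. Three modelling decisions deserve explanation:

* **Fragmentation is a sampling model, not a partition.** Fragments are
  independent (start, length) draws. Only fragment *ends* matter downstream,
  and independent draws keep the model seedable and analytically simple.
  Sequence-dependent sonication bias is out of scope.
* **One sgRNA per fragment end.** The adaptor's printed oligos ligate
  productively only at the blunt G-carrying end, so the left end of a
  fragment releases the first $k$ top-strand bases and the right end the
  first $k$ bottom-strand bases, each expressed as `G` + insert.
* **The ligation concatemer is linear.** Piece boundaries are recorded, and
  inserts spanning a junction are emitted but flagged; they are excluded
  from provenance-based analyses (they have no single genomic locus).

The insert-length distribution `length_jitter` (default 0.90 on 19, 0.05 on
18, 0.04 on 20, 0.01 on 17) is a free parameter of the generator chosen so
that targeting domains are predominantly 20 bases with a small spread, the
qualitative shape observed for real EcoP15I libraries. It is documented as a
knob, not a measured constant, and the only acceptance-level claim tied to
it is the *mode* (20), which is insensitive to the exact tail masses.

`build_library()` samples `clone_count` clones uniformly over all released
ends and aggregates by (targeting domain, provenance), so the clone pool
carries exact ground truth for every downstream check: every non-junction
insert round-trips to its recorded region coordinates, and the NGG inventory
is a subset of the theoretical enumeration.

# The synthetic screen

The screen generator emulates a GFP-reporter enrichment screen sorted into
`neg/low/med/high` bins, with defaults mirroring the experimental design it
stands in for: ~30% infection (chosen low to give single integrations, which
the model therefore assumes outright), three biological replicates, and
per-sample sequencing depth of 750,000 reads.

* **Cut probability** is a per-(Cas9 variant, PAM class) activity:
  wild-type Cas9 0.8 at NGG and 0.05 at NGA, the VQR mutant 0.4 at NGA and
  0.05 at NGG, 0 elsewhere. These magnitudes are model knobs (documented as
  such, excluded from acceptance claims); variants present in the same cell
  combine independently. An optional exception can give OTHER-class PAMs
  whose 4-nt context reads `GTGG` a small wild-type activity, reflecting
  reports of residual activity at such sites; it is off by default.
* **Cut site** is placed 3 bp 5' of the PAM (the standard blunt spCas9 cut,
  between targeting-domain bases 17 and 18 of a 20-base domain). The choice
  is testable and localised in one function.
* **Phenotype** is binary per cell: if the cut site falls inside a planted
  truth element, the cell adopts that element's bin profile with the cut
  probability, otherwise it stays GFP-negative. Indel-size modelling (large
  deletions) is deliberately abstracted away — element membership of the cut
  site is the entire phenotype model.
* **Counts** are multinomial: infected cells over clone frequencies, cells
  over bins, then reads over within-bin cell frequencies at fixed depth.
  FACS sort impurity, PCR jackpots and proliferation selection are not
  modelled.

Reads are emitted with the sequenced amplicon structure: spacer (the domain
minus its leading G, which sits in the sequencing primer), the 20-nt
scaffold prefix `GTTTTAGAGCTAGAAATAGC`, a 6-nt sample barcode, and a
constant tail, with i.i.d. substitution errors at a configurable rate and
constant Phred qualities. With the error rate at zero the full
emit → clip → demultiplex → count path reproduces the simulated count tables
exactly; this inverse property is asserted in the test suite.

# Read processing

Clipping searches each read for the leftmost match of the 20-nt wildcard
pattern `GNNNNNNAGCTAGAAATAGC` (N = any base); the spacer is the prefix
before the match and the barcode the 6 nt after it. The pattern's six
wildcard positions are reproduced literally from the established protocol.
Demultiplexing is exact by default (a 1-mismatch mode exists and refuses
barcode tables whose codes collide within the radius). Mapping is an
exhaustive dictionary search over both strands of all regions at 0 or 1
mismatch; a unique locus yields full site annotation with the PAM read from
the reference, multi-locus spacers are kept in count tables but barred from
positional analyses (a conservative choice that avoids phantom positional
hits), and counting is by exact spacer string, matching unique-sgRNA
accounting. One mismatch is used only for the neighbour-distance QC; all
other analyses use exact matching.

# Enrichment scoring and hit calling

Within each sample, counts are normalised by the total mapped reads to give
frequencies. For each GFP-positive bin and replicate, each sgRNA's score is

$$\log_2 \frac{\max(f_{pos},\,10^{-8})}{\max(f_{neg},\,6.25\times10^{-7})}$$

with the floors applied to frequencies (never counts) and only upward. The
floor constants are the published ones for this assay family; under them an
sgRNA absent from the positive sample scores at most
$\log_2(10^{-8}/6.25\times10^{-7}) \approx -5.97$, and the best attainable
score at fixed $f_{pos}$ occurs when the reference sits at its floor.

A candidate hit must satisfy, with strict inequalities: (1) score > 2 in the
high- **or** med-GFP bin in ≥ 2 replicates, or (2) score > 2 in the low-GFP
bin in ≥ 2 replicates; (3) an NGG PAM; (4) location inside the target locus.
The "high or med" clause is interpreted per replicate — a replicate
qualifies if *either* bin exceeds the threshold, and qualifying replicates
are then counted — which is the weakest reading consistent with the
criterion's wording; both the threshold and the replicate minimum are
function arguments. The target locus is a parameter (a region/interval
triple), not a hard-coded gene.

# The window-cluster scan

True regulatory elements produce *clusters* of enriched sgRNAs of different
sequences, while off-target artifacts rarely do. The scan statistic
formalises this: fit a normal null $(\mu, \sigma)$ to the NGG-PAM scores of
a sample, convert each sgRNA's score to an upper-tail probability
$p_i = 1 - \Phi\left(\frac{x_i - \mu}{\sigma}\right)$, and for every window
of 21 bp (10 bp each side of a centre nucleotide, clipped at region ends so
edge windows are effectively smaller) report

$$-\log_{10} \prod_{i \in \text{window}} p_i
  \;=\; \sum_{i \in \text{window}} -\log_{10} p_i .$$

Numerical and design choices:

* The null is fitted per (replicate, bin) on **all** NGG scores of that
  sample, floored values included; a trimmed fit (central bulk) is available
  via `trim` but off by default. With many sgRNAs absent from a small sorted
  bin, the null mean can be strongly negative and its SD wide; that is the
  correct reference for "how surprising is this score in this sample", and
  the cluster peaks separate cleanly from background in the recovery tests.
* Window membership is by last-base position, with both strands pooled, and
  *every* unique sgRNA in the window contributes — the best-per-position
  collapse used for plotting raw enrichment is a display rule, not a scan
  rule.
* $p$ is floored at $10^{-300}$ so $-\log_{10}$ stays finite; the empty
  product is 1, so empty windows score exactly 0.
* The sliding sum is computed by cumulative sums, and an independent
  per-window product oracle in the tests agrees to $10^{-9}$ absolute.

No multiple-testing calibration is applied to window probabilities: profiles
are reported as raw $-\log_{10}$ values, to be compared across positions and
replicates, matching how such scans are read in practice.

# Library QC

Neighbour distances are differences of sorted third-last-base coordinates,
pooled across strands within each region and never crossing region
boundaries; observed-library distances use 1-mismatch mapping. The
theoretical distribution assumes every NGG site is present, with
minus-strand sites entering at their third-last-base coordinates pooled with
plus-strand ones, mirroring the observed-distance definition (the package's
resolution of an ambiguity the original description leaves open). Since the
observed sites are a subset of the theoretical ones, observed gaps can never
be smaller — an invariant the tests assert.

Saturation curves subsample mapped reads without replacement; subsamples are
**nested** (each larger subsample contains every smaller one) so unique-count
monotonicity is exact rather than merely expected, and 5 independent draws
are reported rather than one (the per-draw spread is the uncertainty
estimate). The capacity extrapolation is deliberately conservative
arithmetic: `fold = clone_count / reference_reads`, and the supported input
length multiplies by `floor(fold)`. With 1.5 million clones against a
160,000-read reference on 9 kb of input this gives a 9-fold, >80 kb
capacity.

# What the generator does and does not emulate

The synthetic screen reproduces: the amplicon read structure and barcoding,
the clone-frequency skew of a transformed pool, multinomial sampling noise
at realistic depths, replicate-to-replicate sampling variation, PAM-class
dependent activity, and positionally clustered effects with distinct
low-GFP (partial loss) versus med/high-GFP (complete loss) signatures.

It does **not** emulate: FACS sort impurity, PCR chimeras/jackpots,
sequence-dependent fragmentation or cutting biases, off-target cutting,
multi-integration cells, indel-size distributions, or proliferation
selection. Passing tests therefore demonstrate the correctness of the
*computational* pipeline under a faithful sampling model, not robustness to
every artifact of real screens. The "positionally structureless" control
used in the separation tests (a whole-region element with a small uniform
GFP-positive leak) is the package's null for cluster detection: effects
exist but carry no positional information, so scan peaks stay low.

# Problem sizes and determinism

Everything stochastic flows from one master seed through
`derive_seeds()` (named child streams per stage and replicate), so library,
screen and analysis runs are reproducible bit-for-bit, and the workflow
manifest records derived seeds plus output checksums.

The test suite exercises the self-calibrating limits at sizes chosen to make
the statistics decisive while keeping a laptop-scale run: 1 Mb of random
sequence for the 8-bp density law, a 10-kb input with 10,000 fragments for
the digest length mode, 1.5-kb regions with ~3,000 fragments, 50,000–100,000
cells and 30,000–50,000 reads per sample for the 20-seed end-to-end recovery
property (the scan's global low-bin peak must fall inside a planted flanking
element in at least 90% of runs). These sizes are the package's chosen study
conditions for its synthetic experiments.

# Known limitations

* Mapping supports substitutions only (0 or 1); indel-containing spacers go
  unmapped. Real pipelines using short-read aligners share this behaviour at
  these read lengths.
* The enrichment model is a pure ratio statistic with fixed floors; no
  variance model (e.g. negative binomial) is fitted, by design.
* Genome-scale references and off-target search are out of scope; regions
  are curated input pieces, and ambiguity codes in them are rejected rather
  than skipped.
* The VQR/NGA activity model treats PAM classes uniformly; real PAM
  preferences are finer-grained than three classes.
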