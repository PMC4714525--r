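---
title: "Models and methods behind m6aquant"
author: "m6aquant authors"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Models and methods behind m6aquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m6aquant)
```

# The analysis problem

m6aquant analyzes transcriptome-wide N6-methyladenosine (m⁶A) sequencing
experiments of the MeRIP-seq family: fragmented RNA (~100 nt) is
immunoprecipitated with an anti-m⁶A antibody and sequenced alongside an
mRNA-seq control (and optionally the un-captured fragmented "input" pool).
When the antibody's non-specific precipitation rate is very low (< 1 %),
essentially every deduplicated m⁶A-seq fragment derives from a
site-bearing RNA fragment, so the m⁶A-seq fragment counts themselves — not
peak calls against the input — carry the methylation signal. The package
implements the post-alignment computations such a design needs: covered-
length-normalized quantification, methylation-extent categorization,
between-organ differential methylation, metagene topology, consensus-motif
analysis, and qRT-PCR validation arithmetic.

# Quantification model

**FPKM** normalizes mRNA-seq counts by spliced transcript length and library
size:

$$\mathrm{FPKM} = \frac{c \times 10^9}{L \times N}$$

with $c$ the transcript's fragment count, $L$ its spliced length (exon
union; the genomic span is never used) and $N$ the library's mapped total.

**MFPKM** is the m⁶A-seq analogue. Because the captured library derives
only from site-bearing fragments, transcript length is replaced by the
*covered length* $L_c$ — the union length of the transcript's projected
m⁶A fragments:

$$\mathrm{MFPKM} = \frac{c_{m6A} \times 10^9}{L_c \times N_{m6A}}$$

A zero count yields 0 by convention; a positive count with zero covered
length is an internal inconsistency and raises an error.

**Peak (site) count** is estimated as $\mathrm{round}(L_c / 150)$ with a
floor of 1 for any positive coverage: the average m⁶A peak spans roughly
150 nt, and a methylated transcript must report at least one site. The
estimator presumes that coverage regime; at saturating depth with a wide
fragment-length spread a single site's cluster widens toward twice the
longest fragment and the estimator counts ~2 per site. This is a property
of the estimator, visible in the synthetic tests, not a defect of the
implementation.

**Coordinates.** Genomic intervals live in GenomicRanges containers with
rtracklayer converting GFF3 (1-based inclusive) and BED (0-based half-open)
at the boundary. All transcript-coordinate quantities — projections, site
positions, peak spans, the stop-codon landmark — are 0-based half-open with
0 at the 5' end; reverse-strand transcripts are flipped during projection.
A fragment overlapping several transcripts is counted for each (no rescue
model; the simplest reproducible rule), unknown-strand fragments are
projected with the transcript's strand (RIP libraries are effectively
unstranded), and fragments without exon overlap are dropped from
per-transcript work while still counting toward library totals, because the
per-million terms are library-wide.

# Methylation-extent categorization

Each methylated transcript's MFPKM is compared with its FPKM by a two-cell
goodness-of-fit statistic on the percentage split of the two values against
50:50:

$$\chi^2 = \frac{(100a/(a+b) - 50)^2}{50} + \frac{(100b/(a+b) - 50)^2}{50}$$

The statistic depends only on the ratio $a:b$. p-values use the upper tail
of $\chi^2_1$ — two cells with one free proportion give one degree of
freedom. Categories: **High** ($p < \alpha$, MFPKM > FPKM), **Low**
($p < \alpha$, MFPKM < FPKM), **Equivalent** ($p \ge \alpha$), with
$\alpha = 0.05$. Treating "the ratio fits 1:1" as a significance *rejection*
would be self-contradictory, so Equivalent is implemented as the
non-rejection region. Unmethylated transcripts are excluded, not
categorized.

For the expression-tertile summary, methylated transcripts are ranked by
FPKM (descending; ties broken by transcript id for determinism) and split
into thirds, remainders going to the earlier groups. Each grouping reports
mean MFPKM, mean FPKM and their ratio. The between-grouping test is a Welch
t-test on the *per-transcript* MFPKM/FPKM ratios — a t-test on the two
grouping means alone would be undefined, so per-transcript ratios are the
only defensible unit.

**Extensively methylated transcripts** pass, per organ and in every
replicate: MFPKM:FPKM fold ≥ 10, Benjamini–Hochberg FDR < 10⁻¹² (BH within
organ/replicate over the extent p-values), and m⁶A fragment count ≥ 30. The
"read number" filter is taken on the m⁶A-seq count — the methylation
evidence being filtered — as the assay is not otherwise specified.

# Differential methylation between organs

High m⁶A depth may simply reflect high expression, so the between-organ
statistic damps the transcript level:

$$\mathrm{NFPKM} = \frac{\mathrm{MFPKM}}{\log_2(\mathrm{FPKM})}$$

Transcripts with FPKM ≤ 1 are excluded (the denominator would be zero or
negative) and reported with an exclusion reason rather than silently
dropped; non-methylated transcripts are likewise excluded from the NFPKM
metric. The same percentage χ² is applied to the two organs' values —
consistency with the one statistic the extent analysis defines — followed
by BH FDR across the tested transcripts of the pair. Default calls require
fold > 2 or < 0.5 and FDR < 0.05; the extreme organ-specific preset is
fold ≥ 10 or < 0.1, FDR < 10⁻¹⁰, m⁶A count ≥ 20 in both organs. Alternative
FDR presets (0.02 for expression, 0.005 for methylation) exist for
pathway-level filtering. Organ-specific sets require the focal organ to be
higher than *both* other organs in *every* replicate (common-elements
rule). No between-library scaling beyond the per-million terms inside
MFPKM/FPKM is applied, since the method defines none.

A calibration caveat: the percentage χ² treats normalized values as if they
were a two-cell count table, so its null distribution is only approximately
$\chi^2_1$; the statistic is conservative for deeply covered transcripts
and anti-conservative in the low-count tail. At the package's default
simulated depth (~400 fragments per transcript) the realized null
false-positive fraction at FDR < 0.05 stays at or below 5 %, which the
acceptance suite checks; at much shallower coverage a fragment-count filter
is advisable.

# Metagene topology

Each transcript with spliced length ≥ 60 nt is divided into 60 equal bins
from 5' (bin 0, the TSS end) to 3' (bin 59); per-bin depth is normalized
"per 1 kb per 1 Mb" — mean depth in the bin × 10³ × 10⁶ / library total,
mirroring the FPKM convention — and averaged across transcripts. Binning is
over spliced transcript coordinates, which places stop codons of typical
gene architecture in bins ~49–59; genomic-span binning would smear the
landmark and is rejected. Organ profiles are compared by one-way ANOVA with
bins as observations (the statistic behind "the overall patterns do not
differ" statements); identical profiles return p = 1 with a degenerate
flag.

Peaks are maximal runs of per-base depth ≥ 1 in transcript coordinates;
the summit is the leftmost maximum. At that threshold the peak spans
partition the covered bases, so their total equals the covered length used
by MFPKM — an internal consistency link the tests assert exactly. A
transcript is **Type 1** when the stop-codon region (stop codon − 100 nt to
the 3' end) holds a peak at least 2× the highest coding-region peak (the
lower bound of the "two- to tens-of-fold" dominance regime; configurable),
**Type 2** otherwise; transcripts without a CDS or without peaks are
flagged not-applicable.

# Motif analysis

The top 1,000 peaks (configurable) contribute one window of ~100 nt of
sense-strand transcript sequence centered on the summit. Windows are
extracted with a 2-nt margin so a 5-mer whose central A sits exactly at
the window edge is not clipped. The m⁶A consensus RRACH (R = A/G,
H = A/C/U; DNA-space T for U, with an RNA-rendered column in the output) is
matched via IUPAC-aware string matching; frequencies are tallied one
instance per peak — the match nearest the summit — so they are peak-
weighted; counting all instances is available behind a flag. Truncated
windows at transcript ends are used as-is.

# The synthetic-data generator

The generator is first-class, tested code. It emulates the study
conditions:

- **Architecture**: 500 transcripts across 5 chromosomes (ids in the
  AT\<chr\>G\<number\> style so alphabetic order walks the chromosomes),
  5'UTR 50–200 nt, CDS 450–1,350 nt, 3'UTR 150–300 nt; 20 % of transcripts
  get two exons (150-nt intron); 3 % are TE transcripts whose sampling is
  restricted to 2–4 sub-intervals, reproducing the "fragmented" TE form;
  TEs carry no CDS.
- **Sites**: 75 % of transcripts methylated; 1–4 sites each (mean ≈ 2,
  matching the ~2.0–2.6 sites per methylated transcript regime); every
  site is written into the genome as an RRACH 5-mer (the generator plants
  the motif rather than searching for it, so motif-recovery tests have
  known truth), with AAACU/AAACA enriched by default. A transcript is
  Type 1 with probability 0.75 (sites in the stop-codon − 100 nt … 3' end
  window) and Type 2 otherwise (sites in CDS/5' regions), so the site-level
  placement mass and the transcript-level topology fraction coincide.
- **Libraries**: fragments ~N(100, 20) nt truncated at 30; start positions
  use a clip model (uniform over [−(len−1), L−1], clipped), giving uniform
  steady-state coverage along the transcript — the well-defined uniform
  null the metagene tests need, and standard in read simulators. mRNA-seq
  and input draw transcripts proportional to log-normal expression weights
  (a weight is the transcript's expected share of the fragmented pool).
  m⁶A-seq retains a fragment with probability 0.9 × (methylation level) if
  it covers a site and 5 × 10⁻⁴ otherwise; the background rate is set so
  ~1 % of a captured library is non-specific, matching the < 1 %
  non-specific immunoprecipitation regime. 2 × 10⁵ fragments per library;
  all randomness is seeded, with one sub-seed per {organ, replicate,
  assay} grid cell so a library's stream does not depend on which subset
  was simulated.
- **Methylation design**: methylated transcripts sit at capture level
  0.35; a 6 % "extensively methylated" subset sits at 1.0. Under the
  capture model the realized MFPKM:FPKM ratio is ≈ 0.5·m/E[P·m] (m the
  level, P the chance a fragment covers a site), giving ~2–5 for typical
  and ~6–12 for extreme transcripts — the same order as the published
  tertile ratios (1.2–26). Ratios much above that bound are unreachable by
  a capture probability, so recovery tests for the extensive filter use a
  low-baseline contrast preset rather than pretending a ratio dial exists.
- **Differential design**: 10 % of methylated transcripts carry a 4-fold
  methylation difference, focal organs alternating so library totals stay
  balanced (an unbalanced design would compositionally shrink the realized
  fold).

What the generator does **not** emulate: sequencing errors and quality
scores, isoform complexity, positional coverage biases of real libraries,
antibody batch effects, and genome-scale transcriptome size. Passing
recovery tests therefore demonstrates the pipeline's correctness and
calibration under the stated model, not performance on any real dataset.
In particular, at desk scale the ~1 % background touches every transcript,
so the simulated "proportion methylated" saturates near 100 % rather than
the ~70 % seen at genome scale.

# qRT-PCR validation

Relative abundance uses the standard ΔCt convention against the
housekeeping amplicon: RA = 100 × 2^−(Ct_target − Ct_reference). Expected
abundance from sequencing is 100 × (m⁶A-seq fragments of the test gene in
the amplicon region / mRNA-seq fragments of the reference gene in its
region), with region-restricted counts computed on projected fragments.
Validation is the Pearson correlation of paired (RA, EA) values pooled over
genes × organs (the published design pools 11 genes × 3 organs, n = 33),
with a Fisher-z 95 % CI; raw values are the default and a log10 option is
provided, since the original transform is unstated.

# Numerical and degenerate-input choices

- `round()` follows R's IEEE convention (half-to-even) in the peak
  estimator; the floor of 1 dominates the only contentious band.
- Tertile ties: FPKM rank ties broken lexicographically by transcript id.
- Degenerate t-tests (zero variance in both groups) and correlations (zero
  variance in either vector) return NA with a degenerate flag rather than
  erroring.
- Identical metagene profiles compare at p = 1 (F = 0/positive within-group
  variance); the all-constant case is flagged.
- Self-comparison in the differential test yields χ² ≈ 0 (to floating-point
  rounding) and zero significant calls, exactly.
- Empty libraries quantify to all-zero records rather than erroring;
  the formula-level functions (`compute_fpkm`, `compute_mfpkm`) still
  reject zero library totals as domain errors.

# Problem sizes used by the test and acceptance suites

Simulation-backed checks run at 300–800 transcripts and 10⁵–2 × 10⁵
fragments per library — the package's desk-scale study conditions — which
keeps every stage verifiable in minutes while preserving per-transcript
coverage comparable to the full-scale design. The published tables'
arithmetic (category percentages, tertile ratios) is reproduced exactly
from the printed counts and means shipped under `inst/extdata/`; two
tertile ratios and one percentage cell in those tables disagree with their
own printed inputs in the last digit (the originals evidently divided
unrounded means), and the suite asserts printed-precision agreement there.

# Known limitations

- The percentage χ² is the method's own statistic, reproduced faithfully;
  it is not a calibrated count test (see the caveat above).
- The peak-count estimator is a coverage heuristic, not base-resolution
  site calling; the m⁶A/A ratio inherits it.
- Multi-isoform assignment is unspecified by the method; each overlapping
  transcript counts the fragment.
- The ANOVA behind the profile comparison treats bins as independent
  observations, which overstates degrees of freedom; it is used as the
  method defines it, for a summary p-value, not for inference.
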