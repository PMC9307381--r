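---
title: "Methods: MeRIP-Seq m6A peak analysis with meripr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MeRIP-Seq m6A peak analysis with meripr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meripr)
```

## The experimental design meripr models

MeRIP-Seq fragments RNA to roughly 100 nt, immunoprecipitates
m6A-containing fragments with an anti-m6A antibody (the IP sample), and
sequences the IP alongside an unenriched input control.  Genomic intervals
where IP coverage is enriched over input ("peaks") are candidate m6A
sites.  meripr analyses a two-condition design — a case group and a
control group, each with IP and input samples — through peak calling,
merging, differential scoring, metagene profiling, functional annotation,
motif enrichment and gene-set enrichment.

All coordinates inside the package are 0-based half-open (the BED
convention); GTF input, which is 1-based closed, is shifted on read.
Transcript offsets always run 5'→3' of the transcript, so minus-strand
arithmetic is confined to `genomic_to_transcript()` and its inverse.
Biotype is inferred from CDS presence (a transcript with at least one CDS
feature is mRNA, otherwise lncRNA), which is robust across annotation
dialects; transcripts with overlapping exons are rejected rather than
repaired, so malformed annotations surface early.

## Peak calling and merging

`call_peaks()` tiles the genome into non-overlapping windows (default
25 bp) and flags a window as enriched when

$$\frac{w_{IP}/N_{IP}}{(w_{input}+c)/N_{input}} \;\ge\; f_{min},$$

with $w$ the window coverage sums, $N$ the library sizes (total summed
coverage, asserted on load), $c$ a pseudocount (default 1 coverage unit,
which avoids division by zero on empty input windows) and $f_{min}$ the
minimum enrichment (default 2).  Maximal runs of adjacent enriched
windows at least 50 bp long become peaks; the score is the run's mean
enrichment and the summit the center of its best window.  This is a
deliberately simple enrichment caller: the surrounding analysis only
needs intervals with a ranking score, and every property of the caller is
oracle-testable.

Replicate peak sets within a group are combined base-wise: a base
survives `intersect_within_group()` only if every replicate covers it —
the strictest reading of a "common region".  The two groups' merged sets
are then combined by `union_between_groups()` (base-wise OR), with
provenance (`A`, `B`, `AB`) recorded in the peak name.
`count_signal()` sums each sample's coverage over each union peak with no
normalization; "signal" is summed coverage rather than read counts, so
simulated tracks need no read model and counting is exactly additive
under peak splits.

## E-score differential methylation

Within a group, replicate signals are pooled by summing and the per-peak
enrichment score is the library-normalized linear ratio

$$E = \frac{(s_{IP}+c)/N_{IP}}{(s_{input}+c)/N_{input}}.$$

The linear scale (rather than a log score) is the natural reading of a
mean-score gate of 6: on a log2 scale a threshold of 6 would demand a
64-fold enrichment, which no MeRIP experiment approaches peak-wide.  With
group A the control and group B the case, a peak is called

* `up` when $\bar E = (E_A+E_B)/2 > t_{mean}$ and
  $\log_2(E_B/E_A) > t_{diff}$,
* `down` when $\bar E > t_{mean}$ and $\log_2(E_B/E_A) < -t_{diff}$,
* `ns` otherwise,

with defaults $t_{mean} = 6$ and $t_{diff} = 1$ (a two-fold E-score
difference).  The "difference" is the log of the ratio of E-scores —
the only reading under which a symmetric "less than −1" branch exists.
This is a threshold rule, not a hypothesis test, so no multiple-testing
correction applies; swapping the group labels negates every `log2_diff`
and exchanges `up` and `down` exactly, which the tests assert.

## Metagene profiles

Each peak is reduced to one representative point — the summit when the
caller provides one, else the interval midpoint.  A point mapping is
oracle-testable by enumerating exonic bases, whereas smearing an interval
across region boundaries is not; the cost is ignoring peak width, which
at the ~100–200 bp fragment scale shifts densities by at most a bin or
two.  The point is mapped into every overlapping transcript; a peak
mapping into $k$ transcripts contributes weight $1/k$, avoiding any
dependence on annotation order.  For mRNA the offset is classified by the
CDS bounds into 5'UTR, CDS or 3'UTR and expressed as a fraction of that
region's length; regions get 20/40/40 bins (the conventional layout with
UTRs narrower than the CDS — the bin counts, not transcript lengths, fix
the x-axis widths).  lncRNA positions are fractions of the spliced body
over 100 bins.  Densities are normalized to sum to 1 whenever at least
one peak maps.

## Functional annotation

The same representative point is tested against every overlapping
transcript and the best of seven disjoint categories wins:
5'UTR > 3'UTR > 1st exon > other exon > 1st intron > other intron >
distal intergenic.  UTRs must outrank exons because a UTR base is also
exonic and the categories are reported as disjoint; UTR-first matches the
ChIPseeker convention.  Exon and intron ordinals are counted 5'→3' of the
transcript.  When several transcripts tie at the winning category, the
one with the nearest TSS supplies the gene id, a deterministic
tie-break.  Intergenic peaks record the nearest gene and the signed
distance to its TSS (positive downstream in gene orientation); genic
peaks have distance 0.  Promoter/downstream classes are intentionally
absent: the seven categories above are the reported classification.

## Motif enrichment with erasure

Sequences are extracted around the top-scoring peaks (default top 5000,
±100 bp flanks, clipped at chromosome ends, minus-strand
reverse-complemented).  Candidates are a fixed universe of IUPAC
patterns — by default all 256 DNA 4-mers plus the degenerate m6A
consensus patterns RRAC, DRAC, RRACH and DRACH — rather than an EM over
position weight matrices: the reported surface is a motif name with an
E-value, and a fixed candidate set makes every step exactly checkable.

Each round scores every remaining candidate by a one-sided Fisher's exact
test on the 2×2 table of sequences containing at least one unerased match
(positives vs background), sequence-level counting being the standard
ZOOPS-like convention.  The E-value is the Fisher P multiplied by the
number of candidate motifs tested.  The minimum-E candidate is emitted,
all bases it matched are erased (lowercase-masked, and masked bases never
match again) in both sequence sets, and the loop repeats until `max_motifs`
motifs are found or no candidate has E < 1.  Each emitted motif also
carries its "unerased" E-value computed on the pristine sequences; for
the first motif the two are identical by construction.  When no
background is supplied, a seeded Altschul–Erikson dinucleotide shuffle of
the positives is used, preserving exact mono- and dinucleotide
composition.

One identifiability limit is worth stating: when the planted signal is a
fixed 5-mer such as GGACT, its two 4-mer frames (GGAC and GACT) are
present in exactly the same positive sequences, so which frame is emitted
first depends only on background fluctuations.  Recovery checks therefore
ask whether the top motif matches *within* the planted GGACT context, not
for one specific frame.

## Gene-set enrichment

Term maps are flat GMT-style sets; no GO DAG propagation is performed
(annotations are tested as given).  The universe defaults to all genes
carrying at least one term annotation, the standard Fisher-enrichment
convention.  Per term, $P = P[X \ge k]$ for the hypergeometric tail of
the in-study × in-term table; BH-FDR is applied within each namespace
(BP/MF/CC/pathway), the field's default FDR procedure; the rich factor is
$k/K$.  Report tables select the top-N terms per namespace by P with
lexicographic term-id tie-breaks, so output is deterministic.

## The simulator and what passing tests mean

`simulation_config()` defaults define the package's reference scenario:

* 200 mRNAs and 50 lncRNAs packed on a 2 Mb chromosome, both strands,
  2–4 exons per mRNA (5'UTR 100–200 nt, CDS 600–1200 nt, 3'UTR
  400–700 nt), 1–3 exons per lncRNA (500–2000 nt spliced);
* one planted peak per transcript (~250 peaks), width 100–200 bp (the
  ~100 nt fragment scale), kept within a single exon;
* mRNA peak centers drawn Normal(CDS/3'UTR junction, sd = 50 nt) — the
  stop-codon hotspot — and lncRNA centers uniform over the spliced body;
* the motif GGACT written into the genome at every peak center, the rest
  of the genome uniform ACGT;
* input coverage Poisson around a flat 20× per exonic base; IP coverage
  multiplied by 8 inside peaks;
* 20% of peaks differential at 4-fold, and — a deliberate design choice —
  the fold applied to *one* group per peak (half in the case group,
  planting `up` calls; half in the control group, planting `down`
  calls).  Scaling only the case group could never plant a recoverable
  `down` call: a peak at baseline 8 reduced 4-fold has mean E-score
  (8+2)/2 = 5, below the mean gate of 6 by construction;
* one replicate per group × kind, matching the minimal IP/input design;
* term maps with 50 terms, one planted term of 40 genes over-sampled
  10-fold from the differential genes.

The simulator emits coverage directly (no reads, no aligner, Poisson
rather than negative-binomial noise) and a uniform-composition genome.
Passing tests on it therefore demonstrate that the procedures recover
exactly the structure they model — planted enrichment, planted folds,
placement bias, a planted motif and a planted term — under library-size
asymmetries and Poisson noise.  They do not demonstrate robustness to
overdispersion, mappability artefacts, transcript-abundance dynamics,
isoform ambiguity or annotation error in real data.

Everything is seeded through integer RNG streams with no hash-order
dependence, so reruns are byte-identical; the test suite asserts identical
checksums across full pipeline reruns.

## Numerical choices and edge cases

* Pseudocounts default to 1 coverage unit in both the caller and the
  E-score; degenerate zero-input windows therefore score finitely.
* Ties in motif selection (equal E) and term selection (equal P) break
  lexicographically; differential records order up, down, ns with
  |log2_diff| descending inside each class.
* Written tables use fixed column orders and 6-decimal floats (P-values
  in 6-significant-digit scientific form), so regression comparisons are
  bit-exact.
* Empty inputs: unions of empty peak sets are empty; an empty replicate
  list, an empty study set or an empty universe are errors; a profile
  with no mapped peak is all-zero rather than NaN.
* `phyper` supplies the hypergeometric tails; tests verify it against
  explicit `lchoose` summation over all tables with margins up to 50.

## Problem sizes used by the test suite

Unit tests run on constructed transcripts and 20–25-transcript
simulations; the end-to-end checks use the 250-transcript reference
scenario above, which completes in seconds.  These sizes were chosen as
the smallest at which every rate being asserted (sensitivity, precision,
recovery, flatness) is measured on at least ~50 events.

## Known limitations

* The caller is window-quantized; peak boundaries are resolved only to
  the window size, and strand-specific calling is not attempted.
* Interval-level (rather than point-level) metagene weighting is not
  implemented.
* Replicate-reproducibility statistics (IDR) and dispersion-aware
  differential tests are out of scope; the E-score rule is a threshold,
  not a test, and reports no per-peak P-value.
* GO structure is ignored: term sets are tested flat, as supplied.
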