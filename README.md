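# meripr

Downstream analysis of MeRIP-Seq (m6A) experiments in R.

MeRIP-Seq maps N6-methyladenosine — the most common internal mRNA
modification — by immunoprecipitating methylated RNA fragments (IP) and
sequencing them alongside an unenriched input control.  `meripr` takes the
coverage-level data of a two-condition IP/input design (e.g. a tumor cell
line vs a control line) through the full downstream analysis:

* **Peak calling** — windows where library-normalized IP/input enrichment
  `(w_IP/N_IP) / ((w_input + c)/N_input)` clears a threshold, merged into
  peaks;
* **Merging** — base-wise intersection of replicates within a group, then
  base-wise union between groups, with per-sample signal counting over
  the union peaks;
* **Differential methylation** — the per-peak enrichment score
  `E = ((s_IP + c)/N_IP) / ((s_input + c)/N_input)` per group; a peak is
  `up`/`down` when the group-mean E exceeds 6 and `log2(E_B/E_A)` exceeds
  1 in magnitude (the volcano-plot axes);
* **Metagene profiles** — peak-frequency densities over scaled
  5'UTR/CDS/3'UTR bins of mRNAs (the stop-codon hotspot) and over lncRNA
  bodies;
* **Functional annotation** — each peak assigned to one of seven disjoint
  categories (5'UTR, 3'UTR, 1st/other exon, 1st/other intron, distal
  intergenic) with category proportions;
* **Motif enrichment** — iterative IUPAC motif discovery over sequences
  around the top peaks: one-sided Fisher's exact test per candidate,
  E-value = P × number of candidates, erasure of matched sites between
  rounds (recovering the canonical GGAC/DRACH m6A consensus);
* **Gene-set enrichment** — one-sided hypergeometric tests over GMT term
  maps with Benjamini–Hochberg FDR and rich factor `k/K`.

A seeded simulator (`simulate_annotation()`, `simulate_experiment()`,
`simulate_term_map()`) generates genomes, annotations, coverage tracks and
term maps with planted ground truth for every stage, and
`run_pipeline()` orchestrates the whole analysis with a checksummed output
manifest.  See `vignettes/meripr-methods.Rmd` for the model details and
design rationale.

## Worked example

```r
library(meripr)
cfg <- pipeline_config(seed = 42)   # reference scenario: ~250 peaks
res <- run_pipeline(cfg, "m6a_run")
```

The run logs each stage:

```
... [simulate] 250 transcripts, 250 planted peaks (50 differential)
... [callpeaks] group A: 250 peaks; group B: 250 peaks
... [merge] 250 union peaks
... [diff] 25 up, 25 down, 200 ns
... [motif] 1 motifs discovered (top: GGAC)
... [enrich] 50 terms tested, 1 with FDR < 0.05 (planted T017)
... [done] 16 output files
```

All 50 planted differential peaks (25 per direction) are recovered with no
false calls.  The motif table shows the planted m6A consensus at rank 1:
GGAC is present in 250/250 peak sequences against 194/250
dinucleotide-shuffled backgrounds (Fisher P = 4.3e-19, E = 1.1e-16), and
the enrichment table ranks the planted term first (k = 28 of K = 40 term
genes among the n = 50 differential genes, FDR = 2.0e-13, rich factor
0.70).  The mRNA metagene density peaks at global bin 59 of 100 — the last
CDS bin, directly at the CDS/3'UTR junction where m6A concentrates — while
the lncRNA profile is flat.

Individual stages are exported (`call_peaks()`, `call_differential()`,
`build_profile()`, `annotate_peaks()`, `discover_motifs()`,
`fisher_enrichment()`, ...) and operate on plain data frames, bedGraph/BED/
GTF/FASTA/GMT files and coverage tracks, so each step can also be run on
real data independently of the simulator.

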