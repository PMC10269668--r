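---
title: "Classifying plasmid and chromosome contigs from shared k-mers and genomic markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying plasmid and chromosome contigs from shared k-mers and genomic markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the model

Distinguishing plasmid from chromosome contigs in bacterial genome
assemblies is hard precisely where it matters most: short-read assemblies
produce many fragments below 10 kb, where composition-only and
marker-only predictors both degrade. plasmidr combines the two signal
families in a single random forest over 26 features per sequence:

* **Shared-k-mer fractions** against four reference databases:
  `r_k18` (chromosome set, k = 18), `p_k25` (plasmid set, k = 25),
  `rmp_k18` (chromosome minus plasmid) and `pmr_k25` (plasmid minus
  chromosome), plus the bias ratio `rp = r_k18 / (r_k18 + p_k25)`.
  A fraction is the proportion of a query's distinct canonical k-mers
  found in the database, so it is length-normalised and strand-invariant.
* **Genomic-marker summaries**: for conjugation, mobilization,
  replication and AMR genes, the maximum alignment score and maximum
  −log10(E) over hits on the sequence, plus a presence flag that is 1
  exactly when max −log10(E) ≥ 50 (E ≤ 1e−50); the replicon distribution
  score (RDS) summaries `RDSAvgScore`, `RDSMaxScore` and `rdsBias`
  (1 if the average per-gene RDS ≥ 5, −1 if ≤ −10, else 0); oriT and
  rRNA motif features; and `maxEvalue`, the maximum of the
  plasmid-related E-value features (rRNA excluded, since rRNA marks
  chromosomes).

Plasmid is the positive class throughout. The forest (500 trees by
default) returns a plasmid probability; a sequence is called plasmid
when the probability is at least 0.5 (inclusive; `strict = TRUE` breaks
exact ties toward chromosome, and the cutoff is exposed because
comparable tools ship different defaults).

## Canonical k-mers, sketching, and set subtraction

K-mers are counted canonically (the lexicographic minimum of a window
and its reverse complement), so every downstream quantity is invariant
to the arbitrary strand of an assembled contig. Internally a k-mer is
2-bit encoded into at most 52 bits (k ≤ 26), which an IEEE double holds
exactly; set operations are therefore exact integer arithmetic.

Min-hash sketching keeps a k-mer iff `H(kmer) < f · 2^64`, where `H` is
splitmix64 with a fixed seed of 42. The hash and seed are pinned so
databases are bit-identical across runs and platforms. Queries are
filtered by the *database's own* criterion before counting, which has
the important consequence that a query drawn verbatim from a database's
source still scores 1.0 under sketching — the sketch thins both sides
consistently rather than biasing the denominator.

For the difference databases the minuend keeps its sketch fraction, but
the subtrahend is built unsketched. Subtracting a 10% sketch of the
plasmid set from the chromosome set would leave ~90% of the shared
k-mers in place and defeat the purpose of a "chromosome-unique"
database; building the subtrahend at f = 1 removes every overlapping
k-mer. The reference configuration (`build_reference_dbs()`) sketches
chromosome-side databases at f = 0.1 and leaves plasmid-side databases
unsketched.

Windows containing any non-ACGT symbol contribute no k-mers; lowercase
(soft-masked) bases are uppercased, not skipped. A query with no
informative k-mers reports a shared fraction of 0 and a flag.

## The built-in search backend

Marker search is a pluggable contract: any object with a
`backend_search()` method returning the unified hit schema can stand
behind `search_markers()`. The built-in backend is deliberately naive
and fully self-contained: ORFs are predicted by a six-frame maximal
ATG→stop scan (default ≥ 30 codons; ORFs without an in-frame stop are
not emitted), proteins and nucleotide motifs are scored by best
*ungapped* local alignment (match +5, mismatch −4), and a raw score S
becomes a pseudo E-value `e = m · n · 2^(−S)`. This statistic is
documented as such: it is *not* comparable to HMMER/DIAMOND/BLAST
E-values, but it is monotone in alignment quality, deterministic, and
calibrated so that an exactly recovered marker cassette (e.g. a planted
60-bp oriT, S = 300) lands far below the 1e−50 presence threshold while
chance similarities in random sequence stay far above it.

−log E-values are taken base 10 — the natural reading under which the
printed presence threshold of 50 means E ≤ 1e−50 — floored at 0 (E ≥ 1)
and capped at 300 (E underflowing to 0). Absent categories contribute 0
to every max-score and max-−log-E feature. RDS averaging first reduces
multiple marker-protein hits on one gene to the best hit (lowest
E-value, ties by higher score then marker id), so one gene contributes
one RDS value; a sequence with no marker-protein hits scores (0, 0, 0).
All threshold comparisons (≥ 50, ≥ 5, ≤ −10) are inclusive, exactly as
printed. `rp(0, 0)` returns the neutral 0.5, since a sequence sharing
nothing with either database is evidence for neither class.

## Training-set construction and fitting

Replicons are slid into overlapping fixed-size windows at ten
window/overlap pairs from 500 kb/50 kb down to 500 bp/50 bp. Window
starts form an arithmetic progression with step = window − overlap;
trailing fragments shorter than the window are dropped so every example
in a stratum has exactly the stratum's length. Chromosomal replicons
shorter than 500 kb are excluded from training — sequences that short
labelled "chromosome" in public assemblies are frequently mislabelled
plasmids, and the filter keeps the chromosome class clean. Within each
window-size stratum, 80% of windows are drawn uniformly without
replacement and the draw is truncated to a 100,000-window ceiling
("sample, then cap"). No class rebalancing is applied at training time;
the per-class counts are recorded in the model's training summary, and
the evaluation module provides balanced down-sampling where
balance-sensitive metrics are wanted.

`train_plasmid_model()` fits a probability forest (ranger, impurity
importance, single-threaded, explicitly seeded) on a seeded 2/3 sample
and evaluates on the held-out 1/3. `repeated_training()` re-runs the
resample-and-fit cycle (100 times by default) to report metric
dispersion. Feature importance is the forest's normalised impurity
decrease — a ranking diagnostic, not a selection step.

## Prediction workflow

`classify_contigs()` checks lengths first: contigs above 500 kb are
labelled chromosome outright (`bypass = TRUE`) without feature
extraction, since sequences that long essentially never assemble from
plasmids; contigs below the 500-bp minimum (configurable down to 1 bp)
are reported as `"filtered"` rather than dropped, so output rows always
reconcile with input records. Everything in between gets the full
feature vector and a forest vote. The feature order is fixed and stored
in the model; prediction refuses a model whose order disagrees with the
package's canonical order. All-N contigs are predicted (with all-zero
k-mer features) and flagged.

## Evaluation harness

`compute_metrics()` implements the ten confusion-matrix formulas with
plasmid as positive. Any metric with a zero denominator is reported as
`NA` — never coerced to 0 or 1 — and prevalence is always reported
alongside, because precision, accuracy, FDR and F1 are functions of
class balance. AUC is the Mann–Whitney rank-sum estimator (ties count
0.5). `balanced_downsample()` equalises class counts (optionally per
length stratum) by seeded sampling without replacement.

Benchmark truth for simulated assemblies comes from
`label_contigs_by_kmer_bias()`: a contig sharing < 95% of its k-mers
with the whole reference genome is discarded as mis-assembled; the rest
are labelled by the larger of their shared fractions against the
chromosome and plasmid sets, compared jointly, with an exact tie
discarded as ambiguous. The comparison k defaults to 21 — between the
two feature ks, long enough that chance sharing is negligible — and is
configurable.

## The synthetic study system

`generate_genome()` produces a fully deterministic genome set: one
chromosome and several plasmids drawn from two order-2 Markov chains
with distinct GC targets (0.42 vs 0.58), with exact copies of toy
markers planted at recorded coordinates — conjugation, mobilization,
replication, AMR and positive-RDS marker-protein cassettes plus a 60-bp
oriT on every plasmid; rRNA motifs and negative-RDS marker-protein
genes on the chromosome. Defaults: a 600-kb chromosome (clearing the
500-kb training filter) and six plasmids of 20–80 kb. Cassettes are
planted as exact copies so the naive backend recovers them below the
1e−50 threshold by construction. `fragment_assembly()` emulates a
fragmented assembly with log-normal contig lengths (median 2 kb,
minimum 200 bp) and records each contig's true source.

What the generator emulates — and what it does not: it reproduces the
*structure* of the problem (two compositionally distinct sequence
classes, marker genes concentrated on plasmids, fragmented contigs of
mixed length) but not the biology of real corpora. Real chromosomes and
plasmids share mobile elements and horizontally transferred genes, have
taxon-specific composition rather than a clean GC offset, and real
reference databases are not built from the very genomes being
classified. Passing the parameter-recovery tests therefore demonstrates
that the pipeline is wired correctly end to end — features carry the
planted signal, training recovers it, prediction applies it — not that
the reported holdout metrics transfer to real data. On this synthetic
system the classes separate almost perfectly (holdout sensitivity,
specificity and AUC near 1.0 in the test suite), which is expected: the
databases contain the source genomes, so shared-k-mer features are
nearly decisive.

## Numerical choices and problem sizes

* Hash: splitmix64, seed 42; sketch threshold computed in 64-bit
  integer space; f = 1 bypasses hashing entirely.
* k is limited to 26 so codes stay exact in doubles; the shipped
  configuration uses 18, 21 and 25.
* Pseudo E-values may underflow to 0 for long exact matches; −log10 is
  capped at 300 before they reach any feature.
* The test suite exercises a 40-kb/2-plasmid genome for unit tests and
  the 600-kb/6-plasmid default set for the end-to-end checks, with
  training windows at the 500 bp–10 kb strata (~3,000 windows): sizes
  chosen to exercise every code path at desk scale.
* Every random draw (sequence generation, sampling, splits, forest)
  flows from one explicit integer seed per entry point.

## Known limitations

The built-in backend's statistics are pseudo-E-values; for real data an
adapter to HMMER/DIAMOND/BLAST should stand behind the backend contract
and real marker databases (with curated RDS values) must be supplied.
The classifier is binary: sequences that legitimately occur on both
replicon types (transposable AMR cassettes, integrated plasmids) get a
probability, not an "ambiguous" call. Databases are held in memory as
numeric vectors; genome-scale reference corpora (10^9 k-mers) would
need a disk-backed representation.
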