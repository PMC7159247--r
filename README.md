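# repliclass

Alignment-free classification of bacterial sequences as **plasmid** or
**chromosomal** in origin, from k-mer composition alone. The intended users
are microbiome and metagenomics researchers who need to separate
plasmid-derived contigs from chromosomal ones in an assembly — for tracking
mobile resistance genes, binning, or plasmidome analysis — without BLASTing
every contig against reference databases.

## Method

Each sequence is represented by its **canonical k-mer frequency vector**
for k = 3..7. A k-mer and its reverse complement are collapsed onto the
lexicographically smaller of the pair, so the representation is
strand-independent; over k = 3..7 there are

&nbsp;&nbsp;&nbsp;&nbsp;D = Σₖ Cₖ,&nbsp;&nbsp; Cₖ = 4ᵏ/2 (odd k),&nbsp;
(4ᵏ + 4^{k/2})/2 (even k)&nbsp;&nbsp;⇒&nbsp;&nbsp;D = 10952

features, with each k-block normalized to sum to one. The feature vector x
is scored by an L2-regularized logistic regression,
p(plasmid | x) = 1 / (1 + e^{−(w·x + b)}), and a sequence is called plasmid
when p > 0.5.

Composition estimates sharpen with sequence length, so **four** such models
are trained, on reference fragments of 1 kb, 10 kb, 100 kb and 500 kb, and
a query of length L is routed to the model of nearest training length —
equivalently the ranges (0, 5.5 kb], (5.5 kb, 55 kb], (55 kb, 300 kb],
(300 kb, ∞). Training fragments are drawn uniformly over all windows of the
reference sets, with replacement (a fixed count per class for the short
bins; enough to cover the long plasmids to depth 5 for the long bins, with
the chromosome class sampled to match).

Evaluation is **count-based**: precision, recall and F1 over the number of
sequences (optionally length-stratified, e.g. All / >500 / >1 kb / >5 kb),
plus step-wise (average-precision) PR curves. A synthetic-data module
generates compositionally distinct reference sets from Markov sources and
simulated communities with log-normal genome abundance and geometric
plasmid copy number, p = min(1, log₁₀(L)/7) — so the whole pipeline runs
with no external downloads.

## Worked example

```r
library(repliclass)

# synthetic benchmark: 20 "plasmids" (1-30 kb), 5 "chromosomes" (100 kb-1 Mb),
# GC pulled apart by the divergence parameter
refs <- make_benchmark_refs(divergence = 0.8, seed = 1)
sp <- split_references(refs$plasmids,    0.25, seed = 12)
sc <- split_references(refs$chromosomes, 0.25, seed = 14)

model <- train_length_binned(sp$train, sc$train,
                             training_config(n_short = 500, seed = 1))
#> Warning: no plasmid reference of length >= 100000; skipping the 100000 bp bin
#> Warning: no plasmid or chromosome reference of length >= 500000; skipping the 500000 bp bin

frags <- c(sample_fragments(sp$heldout, 1000, 300, seed = 2),
           sample_fragments(sc$heldout, 1000, 300, seed = 3))
names(frags) <- paste0("f", 1:600)
res <- classify(frags, model)
head(res, 3)
#>   id length  bin probability   label
#> 1 f1   1000 1000   0.8332451 plasmid
#> 2 f2   1000 1000   0.8177265 plasmid
#> 3 f3   1000 1000   0.8573112 plasmid

truth <- setNames(rep(c("plasmid", "chromosome"), each = 300), res$id)
score_classification(res, truth)
#>   min_length   n  tp fp fn  tn precision recall f1
#> 1          0 600 300  0  0 300         1      1  1
```

Held-out fragments from the two Markov sources are fully separated at this
divergence: all 300 plasmid fragments score above 0.5, all 300
chromosomal ones below, giving precision = recall = F1 = 1. The two long
bins are skipped (with a warning) because no synthetic plasmid reaches
100 kb; queries in those ranges fall back to the nearest trained bin.

A command-line wrapper with `classify`, `train`, `evaluate` and `simulate`
subcommands is installed at `inst/scripts/repliclass`.

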