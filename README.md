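# mircascade

Completely ab initio prediction of microRNA precursor (pre-miRNA)
hairpins from genomic sequence, for anyone hunting species-specific
miRNA loci without homology, expression data, or a trained model from
someone else's genome.

Genomic sequence is full of incidental stem-loops, so the practical
failure mode of ab initio predictors is a flood of false positives.
`mircascade` attacks selectivity with a three-stage search-and-classify
cascade:

1. each 150-nt sliding window (10-nt step) is folded through a
   triangular base-pairing matrix in which cell *(i, j)* counts the
   contiguous run of pairs ending at *(s[j], s[n-1-i])* — diagonal runs
   are **exact stems** (uninterrupted helices, min 4 bp);
2. stems that survive a random-forest gate are extended along their
   diagonal into **non-exact stems** (helices separated by symmetric
   internal loops strictly smaller than both flanking stems), gated
   again;
3. survivors are grown into **complete hairpins** (bulges and
   asymmetric loops allowed via a best-first search over nearby
   diagonals), gated a third time and size-filtered to 50–150 nt.

Each stage has its own SMOTE-rebalanced random-forest model (29, 35 and
80 features respectively: composition, pairing, loop/bulge geometry,
energy indices, structure triplets). Class probabilities are gated
inclusively at thresholds (0.3, 0.3, 0.7) by default. Predictions from
overlapping windows are merged by greedy non-maximum suppression at 50%
reciprocal overlap, and evaluation uses the center-distance criterion
(a prediction is true if its center is within 10% of the known
hairpin's length from the known center), with

SN = 100·TP/(TP+FN), SL = 100·TP/(TP+FP), GM = √(SN·SL).

A synthetic-data module (hairpin generator, dinucleotide-preserving
shuffles, background, genomes with implanted hairpins plus truth BED)
makes the whole pipeline trainable and testable offline. See the
methods vignette (`vignettes/mircascade-methods.Rmd`) for the model,
parameter meanings and design decisions.

## Worked example

```r
library(mircascade)

# train a cascade on synthetic hairpins vs. shuffled/background negatives
corpus <- synthetic_training_corpus(n_pos = 40, n_neg = 40, seed = 1)
model  <- train_cascade(corpus$positives, corpus$negatives, seed = 1)
model
#> <cascade_model> thresholds (0.30, 0.30, 0.70); 100 trees/stage

# a 2-kb genome with three implanted hairpins and known truth intervals
genome <- implant(2000,
                  list(list(stem_len = 30, loop_len = 8),
                       list(stem_len = 26, loop_len = 10),
                       list(stem_len = 34, loop_len = 6)),
                  seed = 2)

preds <- scan_sequence(genome$seq, model)
preds[, c("seqid", "start", "end", "prob")]
#>   seqid            start end  prob
#> 1 synthetic_genome  111   183 0.99
#> 2 synthetic_genome 1320  1392 0.99
#> 3 synthetic_genome 1790  1885 1.00

match_predictions(preds, genome$truth)
#> <evaluation_result> TP=3 FP=0 FN=0 | SN=100.00 SL=100.00 GM=100.00
```

The three predictions are the three implants: `start`/`end` are 0-based
half-open genomic coordinates, `prob` is the stage-3 forest's
P(positive), and each prediction also carries its dot-bracket
structure. `write_gff3()` / `write_bed()` export them (1-based, type
`pre_miRNA`, probability as score); `write_arff()` round-trips training
sets in the Weka ARFF layout.

The tiny matrix that starts it all:

```r
pm <- build_pairing_matrix(rna_seq("GGGGAAACCCC"))
diag(pm$run)[1:4]
#> [1] 1 2 3 4        # the 4-bp stem accumulating along its diagonal
```

## Command line

```sh
exec/mircascade train --positives pos.fa --negatives neg.fa --model-dir M
exec/mircascade scan  --input genome.fa --model-dir M --out pred.gff3 \
                      --thresholds 0.3,0.3,0.7 --structures pred.fa
exec/mircascade evaluate --pred pred.gff3 --truth known.bed
exec/mircascade cv --trainset ts.arff --folds 10
```

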