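# spliceRNN

Splice-site identification and exon prediction for eukaryotic genomic DNA
with a bidirectional LSTM sequence classifier.

## The problem

Eukaryotic coding sequences are split into exons separated by introns.
Introns almost always begin with the dinucleotide `GT` (the splice **donor**)
and end with `AG` (the splice **acceptor**), but only a small fraction of the
`GT`/`AG` occurrences in genomic DNA are real splice sites. `spliceRNN`
frames the problem as three-class sequence classification: a fixed 60-nt
window centred on a candidate dinucleotide is labelled *donor* (0),
*acceptor* (1) or *no-site* (2), encoded ordinally per position
(`A→1, G→2, T→3, C→4`), and classified by a four-layer network

```
embedding (4 tokens → 8) → dropout (0.2) → bidirectional LSTM (60/direction) → dense (3, softmax)
```

trained with categorical cross-entropy and Adam for up to 50 epochs
(5 rounds × 10 epochs). On new sequence, every flanked `GT`/`AG` is
classified; surviving donors and acceptors are paired greedily under an
intron length constraint (70–100 nt by default, measured inclusively from
the first base of `GT` to the last base of `AG`), and exons are emitted as
the complement of the introns within gene spans. The package is aimed at
people studying compact intron-poor genomes (the motivating data are the
eight chromosomes of an apicomplexan parasite) and at anyone who wants a
fully self-contained, testable re-implementation of this class of
splice-site pipeline.

The pipeline stages are ordinary R functions: `read_fasta()` /
`scan_orfs()` (ORF extraction, replacing an external ORF finder),
`build_dataset()` (the GT/AG/no-site catalogue and window cutter),
`split_dataset()` (seeded stratified 80/20 split), `splice_rnn()` (the
classifier, an S3 model with `print`/`summary`/`predict`/`plot`/`coef`
methods; the LSTM and its backpropagation are implemented in
C++ via RcppArmadillo), `call_splice_structure()` (candidate scan →
classification → intron pairing → exon assembly), and `simulate_genome()` /
`truth_windows()` (a seeded synthetic-genome testbed with ground-truth
GFF3). `run_pipeline()` wires everything together from a YAML config and
writes a JSON run manifest.

## Worked example

```r
library(spliceRNN)

sim   <- simulate_genome(n_genes = 50, seed = 7)   # ~57 kb, 175 introns
wins  <- truth_windows(sim, seed = 7)              # 175 windows per class
split <- split_dataset(wins, train_fraction = 0.8, seed = 17)
fit   <- splice_rnn(split, splice_config(seed = 1))
print(fit)
```

```
Bidirectional LSTM splice-site classifier
  embedding(4 tokens + pad -> 8) -> dropout(0.20) -> BiLSTM(60 x 2) -> dense(3, softmax)
  parameters: 33523   window: 60 nt
  trained 10 epochs on 420 windows (105 held out)
  final held-out accuracy: 0.8762  loss: 0.3210
```

On a dataset this small the model learns the flanking-composition signal
(held-out accuracy ~0.88) but not yet the centre dinucleotide; with a few
thousand windows per class it converges to ~1.0 (see the acceptance script
below). Structure calling and comparison against the simulator's ground
truth:

```r
st <- call_splice_structure(fit, sim$genome,
                            spans = sim$truth$genes[, c("start", "end")])
st$summary
evaluate_against_truth(st$calls, sim, exons = st$exons)
```

```
$n_exons
[1] 210
$n_introns
[1] 200
$mean_exon_length
[1] 187
$mean_intron_length
[1] 83

  category n_pred n_truth  tp precision    recall        f1 precision_undefined
1    donor    785     175 150 0.1910828 0.8571429 0.3125000               FALSE
2 acceptor   1134     175 154 0.1358025 0.8800000 0.2352941               FALSE
3     exon    210     225  42 0.2000000 0.1866667 0.1931034               FALSE
```

Every called intron lies in [70, 100] nt and the exons/introns tile each
gene span exactly; site-level *recall* is high while site-level *precision*
is low — with no `GT`/`AG`-centred negatives in the training labels the
classifier cannot reject background dinucleotides, a structural property of
this method discussed in the methods vignette
(`vignettes/splice-site-calling.Rmd`).

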