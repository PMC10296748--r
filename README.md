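# bfdna

DNA numerical encoding schemes and a BiLSTM classifier stack for enhancer
sequence classification, with a nine-metric evaluation suite and a
synthetic labeled-sequence generator.

## What this is for

Classifiers cannot consume DNA strings directly; sequences must first be
mapped to numbers, and the mapping matters. This package implements four
per-position encoding schemes —

* **integer**: A→1, C→3, G→2, T→4 (arbitrary labels),
* **atomic**: A→70, C→58, G→78, T→66 (atomic numbers),
* **EIIP**: A→0.1260, C→0.1340, G→0.0806, T→0.1335 (electron–ion
  interaction pseudo-potentials),
* **BFDNA** (base-frequency DNA): position *i* takes the relative frequency
  of its own base within the sequence,
  `BFDNA_X = count(X) / length(s)` —

together with the infrastructure to compare them on enhancer classification
tasks: two stacked bidirectional-LSTM architectures (binary human-vs-mouse
enhancer, and 3-class human/mouse/no enhancer), min–max normalization and
fixed-length padding, stratified train/validation/test splitting, and a
metric suite computing accuracy, precision, recall, specificity, F1, CSI
(precision + recall − 1), G-mean (√(recall·specificity)), MCC, Cohen's
kappa, and micro/macro-averaged ROC-AUC, plus the standard AUC and kappa
interpretation bins.

The first three schemes are *static* — a base always gets the same value.
BFDNA is *dynamic*: the same base encodes differently in different
sequences (C is 0.4 in `CATCG` but 0.2 in `CGAAT`), so the encoding carries
whole-sequence compositional information at every position.

The recurrent stack (BPTT, SELU activations, dropout, batch normalization,
RMSProp/Adam) is implemented natively in vectorized R and verified against
numerical gradients in the test suite. A synthetic generator produces
labeled enhancer-like datasets with class-specific base composition so the
whole pipeline is testable without any external download.

## Worked example

```r
library(bfdna)

# the reference 10-mer: A/C/G/T occur 3/4/2/1 times in 10 positions
encode_bfdna("ACACCCAGGT")
#> <encoded_sequence> scheme=bfdna source=seq1 length=10
#>  [1] 0.3 0.4 0.3 0.4 0.4 0.4 0.3 0.2 0.2 0.1

# a desk-scale end-to-end run: simulate strongly separated 2-class data,
# encode with BFDNA, split 70/15/15, train the scaled-down scenario-1
# stack (BiLSTM 32/16/8, dense 64/32/16, input length 200), evaluate
ds  <- generate_dataset(preset_separable("strong", 2, n_per_class = 300,
                                         seed = 42))
res <- run_scenario(ds, "bfdna", 1,
                    spec = model_spec(1, scaled_down = TRUE),
                    config = train_config(1, epochs = 15, seed = 42))
res$evaluation$row
#>   accuracy precision recall f1 csi gmean mcc kappa auc
#> 1        1         1      1  1   1     1   1     1   1
```

Every metric is 1 because the strong preset separates the two classes by
composition vectors differing by ≥ 0.15 in several bases — a signal the
BFDNA encoding exposes almost noiselessly, so the held-out test split (90
sequences) is classified perfectly; `kappa = 1` is "Perfect agreement" and
`auc = 1` is "Outstanding classification" in the interpretation tables
(`interpret_kappa()`, `interpret_auc()`). On the `"none"` preset (identical
compositions) the same pipeline stays at chance, `kappa = 0`.

A command-line interface wraps the same stages:

```sh
bfdna simulate --preset strong --classes 2 --n 300 --seed 42 --out run/
bfdna encode --in run/synthetic.fasta --scheme bfdna --out run/
bfdna train-eval --config run.yaml --out run/
bfdna metrics --predictions predictions.csv --out run/
```

(the `bfdna` script installs to `<library>/bfdna/exec/bfdna`; every run
writes a JSON manifest sufficient to re-execute it).

See `vignettes/bfdna-methods.Rmd` for the model, its numerical choices,
what the synthetic generator does and does not emulate, and known
limitations — including BFDNA's permutation degeneracy (sequences whose
compositions are permutations of one another are indistinguishable to it).

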