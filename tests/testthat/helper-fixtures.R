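# Shared fixtures: random sequences, tiny datasets, and brute-force oracles.

random_sequence <- function(len, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, len, replace = TRUE), collapse = "")
}

tiny_dataset <- function(n = 6, len = 30, labels = c("a", "b"), seed = 1) {
  set.seed(seed)
  dna_dataset(sprintf("s%02d", seq_len(n)),
              replicate(n, random_sequence(len)),
              rep(labels, length.out = n))
}

# Two-pass BFDNA oracle: count each base by scanning, then substitute.
bfdna_oracle <- function(s) {
  chars <- strsplit(toupper(s), "")[[1]]
  counts <- c(A = 0, C = 0, G = 0, T = 0)
  for (ch in chars) counts[ch] <- counts[ch] + 1
  freqs <- counts / length(chars)
  unname(freqs[chars])
}

# One-pass tally oracle for confusion counts.
confusion_oracle <- function(true, pred, positive) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(true)) {
    if (true[i] == positive && pred[i] == positive) tp <- tp + 1
    else if (true[i] != positive && pred[i] == positive) fp <- fp + 1
    else if (true[i] != positive && pred[i] != positive) tn <- tn + 1
    else fn <- fn + 1
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# Concordant-pair AUC oracle: concordant + half ties over all pos x neg pairs.
auc_pair_oracle <- function(labels, scores, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
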