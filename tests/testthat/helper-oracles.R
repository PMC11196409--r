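# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package implementations they check.

# Double-loop evaluation of the sharpening recurrence on one channel,
# replicate borders.
nimble_oracle <- function(x, alpha) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(NA_real_, h, w)
  at <- function(i, j) x[min(max(i, 1), h), min(max(j, 1), w)]
  for (i in seq_len(h)) {
    for (j in seq_len(w)) {
      avg <- (at(i, j + 1) + at(i, j - 1) + at(i + 1, j) + at(i - 1, j)) / 4
      out[i, j] <- alpha * x[i, j] + (1 - alpha) * avg
    }
  }
  out
}

# Pairwise Mann-Whitney AUC: wins + half-ties over all positive-negative pairs.
auc_bruteforce <- function(truth, score, positive) {
  pos <- score[truth == positive]
  neg <- score[truth != positive]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + if (p > n) 1 else if (p == n) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Naive same-padding convolution (channels-last), TF-style asymmetric padding.
conv_oracle <- function(x, w, b, stride) {
  H <- dim(x)[1]; W <- dim(x)[2]; cin <- dim(x)[3]
  kh <- dim(w)[1]; kw <- dim(w)[2]; cout <- dim(w)[4]
  Ho <- ceiling(H / stride); Wo <- ceiling(W / stride)
  pad_h <- max((Ho - 1) * stride + kh - H, 0) %/% 2
  pad_w <- max((Wo - 1) * stride + kw - W, 0) %/% 2
  out <- array(0, c(Ho, Wo, cout))
  for (o in seq_len(cout)) {
    for (ho in seq_len(Ho)) {
      for (wo in seq_len(Wo)) {
        acc <- b[o]
        for (ci in seq_len(cin)) {
          for (ki in seq_len(kh)) {
            for (kj in seq_len(kw)) {
              hi <- (ho - 1) * stride - pad_h + ki
              wi <- (wo - 1) * stride - pad_w + kj
              if (hi >= 1 && hi <= H && wi >= 1 && wi <= W) {
                acc <- acc + x[hi, wi, ci] * w[ki, kj, ci, o]
              }
            }
          }
        }
        out[ho, wo, o] <- acc
      }
    }
  }
  out
}

# Small phantom spec used by pipeline-level tests (shrunken input so the
# network trains in seconds; the architecture audit always runs at 224).
small_phantom_spec <- function(n_per_class, n_classes = 2, seed = 1) {
  phantom_spec(n_per_class = n_per_class, n_classes = n_classes,
               image_side = 32, seed = seed)
}
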