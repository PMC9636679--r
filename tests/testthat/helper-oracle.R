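# Independent brute-force oracle: literal re-evaluation of the entropy
# and PKV definitions from one column's letters, kept free of any package
# internals so it can arbitrate the implementation.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Entropy and PKV for a character vector of column letters; n_sp is the
# global sequence count used for kappa normalization. Returns NULL for an
# all-gap column.
oracle_column <- function(chars, n_sp) {
  res <- chars[chars != "-"]
  if (length(res) == 0L) return(NULL)
  tab <- table(res)
  cnt <- as.integer(tab)
  nm <- names(tab)
  o <- order(-cnt, nm)        # count descending, then alphabetical
  cnt <- cnt[o]
  nm <- nm[o]
  p <- cnt / length(res)
  S <- sum(p * log(p))
  d <- seq_along(cnt) - 1L
  phi_val <- 1 + sum(d^2 * cnt)
  Phi_val <- phi_val / n_sp^2
  list(residues = nm, counts = cnt,
       S = S, H = -S, display = if (S == 0) Inf else -1 / S,
       phi = phi_val, Phi = Phi_val, kappa = -log(Phi_val))
}

# A random gapped alignment as a character matrix (rows = sequences).
# A small alphabet keeps count ties frequent, which stresses the
# rank-ordering tie-break.
random_alignment_matrix <- function(n_sp, len, gap_rate = 0,
                                    alphabet = AA20) {
  cells <- matrix(sample(alphabet, n_sp * len, replace = TRUE),
                  nrow = n_sp, ncol = len)
  if (gap_rate > 0) {
    gaps <- matrix(runif(n_sp * len) < gap_rate, nrow = n_sp)
    cells[gaps] <- "-"
  }
  cells
}

matrix_to_aligned_set <- function(cells) {
  aligned_set(sprintf("s%03d", seq_len(nrow(cells))),
              apply(cells, 1L, paste, collapse = ""))
}

# Column letters from an aligned_set, for feeding the oracle.
column_letters <- function(msa, i) substr(msa$rows, i, i)
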