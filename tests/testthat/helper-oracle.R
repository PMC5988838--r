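# Independent brute-force alignment oracle: enumerates every global
# alignment of two short sequences, scoring match +1 / mismatch -1 and a
# gap of length g at gap_open + (g-1) * gap_extend. Returns the maximal
# score and the identity values attained by maximal-score alignments.
brute_align <- function(a, b, match = 1, mismatch = -1,
                        gap_open = -2, gap_extend = -1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  best <- new.env()
  best$score <- -Inf
  best$identities <- numeric(0)
  rec <- function(i, j, state, score, matches, cols) {
    if (i > length(A) && j > length(B)) {
      if (score > best$score + 1e-9) {
        best$score <- score
        best$identities <- 100 * matches / cols
      } else if (abs(score - best$score) <= 1e-9) {
        best$identities <- unique(c(best$identities, 100 * matches / cols))
      }
      return(invisible(NULL))
    }
    if (i <= length(A) && j <= length(B)) {
      m <- iupac_match(A[i], B[j])
      rec(i + 1L, j + 1L, "M", score + if (m) match else mismatch,
          matches + m, cols + 1L)
    }
    if (i <= length(A))
      rec(i + 1L, j, "X", score + if (state == "X") gap_extend else gap_open,
          matches, cols + 1L)
    if (j <= length(B))
      rec(i, j + 1L, "Y", score + if (state == "Y") gap_extend else gap_open,
          matches, cols + 1L)
  }
  rec(1L, 1L, "start", 0, 0L, 0L)
  list(score = best$score, identities = best$identities)
}

# random plain-ACGT string
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
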