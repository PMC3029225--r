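# independent Needleman-Wunsch oracle: plain double-loop dynamic program,
# linear gap cost (= the package's affine cost for single-base gaps)
nw_score <- function(a, b, match = 1, mismatch = -1, gap = 5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  prev <- -(0:m) * gap
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- -i * gap
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      cur[j + 1] <- max(prev[j] + s, prev[j + 1] - gap, cur[j] - gap)
    }
    prev <- cur
  }
  prev[m + 1]
}
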