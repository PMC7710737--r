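# Independent oracles used across tests. These deliberately avoid the code
# paths (and the libraries) they are checking.

# IUPAC code sets for the brute-force motif oracle.
iupacSets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Brute-force sliding-window IUPAC scan over a character vector of bases.
bruteScanMotif <- function(sequence, motif) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  m <- strsplit(toupper(motif), "")[[1]]
  k <- length(m)
  n <- length(chars) - k + 1L
  if (n < 1L) return(integer())
  ok <- rep(TRUE, n)
  for (j in seq_len(k))
    ok <- ok & chars[seq_len(n) + j - 1L] %in% iupacSets[[m[j]]]
  which(ok)
}

# Reverse-complement oracle on a plain character string.
revcompOracle <- function(x) {
  paste(rev(strsplit(chartr("ACGTacgt", "TGCAtgca", x), "")[[1]]),
        collapse = "")
}

# Per-base genome -> transcript lift oracle: map every base individually
# through plus-strand exons given as a 2-column matrix (start, end).
perBaseLiftOracle <- function(gstart, gend, exons) {
  off <- cumsum(c(0L, exons[-nrow(exons), 2] - exons[-nrow(exons), 1] + 1L))
  tpos <- integer()
  for (g in gstart:gend) {
    for (i in seq_len(nrow(exons))) {
      if (g >= exons[i, 1] && g <= exons[i, 2])
        tpos <- c(tpos, off[i] + g - exons[i, 1] + 1L)
    }
  }
  tpos
}

# A random small DG table (valid arm geometry) for property tests.
randomDgTable <- function(n, L, seed) {
  set.seed(seed)
  lw <- sample(20:40, n, TRUE); rw <- sample(20:40, n, TRUE)
  gap <- sample(100:3000, n, TRUE)
  span <- lw + gap + rw
  s <- sample.int(L - max(span), n, TRUE)
  data.frame(id = sprintf("dg%02d", seq_len(n)),
             l_start = s, l_end = s + lw - 1L,
             r_start = s + lw + gap, r_end = s + span - 1L,
             support = 5L)
}

# Expected log2 enrichment ratio of a domain under the multinomial
# generative model: enrichment = (fold * w_d / W) / (w_d / L) with
# W = L + sum((fold - 1) * width); ratios are allele vs reference.
expectedLog2Ratio <- function(foldsAllele, foldsRef, widths, L) {
  W_a <- L + sum((foldsAllele - 1) * widths)
  W_r <- L + sum((foldsRef - 1) * widths)
  log2(foldsAllele / foldsRef) - log2(W_a / W_r)
}
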