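# Independent brute-force oracles. These deliberately use naive loops and a
# different code path (Biostrings string ops, explicit neighbor generation)
# from the package internals they check.

STOPS <- c("TAA", "TAG", "TGA")
NT <- c("A", "C", "G", "T")

oracle_revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# all single-nucleotide neighbors of a k-mer
oracle_neighbors <- function(s) {
  ch <- strsplit(s, "")[[1]]
  out <- character(0)
  pos <- integer(0)
  for (i in seq_along(ch)) {
    for (b in setdiff(NT, ch[i])) {
      ch2 <- ch
      ch2[i] <- b
      out <- c(out, paste(ch2, collapse = ""))
      pos <- c(pos, i)
    }
  }
  list(seqs = out, pos = pos)
}

oracle_kmers <- function(width) {
  g <- expand.grid(rep(list(NT), width), stringsAsFactors = FALSE)
  apply(g, 1, paste, collapse = "")
}

# product-measure mass at GC content g
oracle_mass <- function(g, seqs) {
  pb <- c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
  vapply(seqs, function(s) prod(pb[strsplit(s, "")[[1]]]), 0, USE.NAMES = FALSE)
}

# hypergeometric right-tail (alternative "greater") for a 2x2 table
# (a, A-a; b, B-b): P(X >= a) with X ~ Hypergeom drawing (a+b) from A+B
oracle_fisher_greater <- function(a, A, b, B) {
  k <- a + b
  xs <- max(0, k - B):min(A, k)
  probs <- stats::dhyper(xs, A, B, k)
  sum(probs[xs >= a])
}

# step-up Benjamini-Hochberg, naive
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# exact one-sided ("greater") permutation p-value of the rank-sum statistic
oracle_mwu_greater <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  idx <- utils::combn(length(pooled), n)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n)])
  stat <- apply(idx, 2, function(i) sum(r[i]))
  mean(stat >= obs)
}

# naive enumeration of frame-specific event probabilities on the trimer space
oracle_intergenic_stop_gain <- function(g, spec) {
  tri <- oracle_kmers(3)
  total <- 0
  for (s in setdiff(tri, STOPS)) {
    nb <- oracle_neighbors(s)
    for (j in seq_along(nb$seqs)) {
      if (nb$seqs[j] %in% STOPS) {
        i <- which(strsplit(s, "")[[1]] != strsplit(nb$seqs[j], "")[[1]])
        from <- substr(s, i, i)
        to <- substr(nb$seqs[j], i, i)
        total <- total + oracle_mass(g, s) *
          substitution_probability(spec, from, to)
      }
    }
  }
  total
}
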