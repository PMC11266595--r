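# Vectorized machinery for the Monte-Carlo oracle tests: batch draws from
# conditional state measures, one-generation mutation of many loci at once,
# and the sense-selection filter applied the way the analytic model defines
# it (an intolerable mutation does not happen; tolerable ones do).

mc_bias_dests <- function() {
  b <- yeast_mutation_bias()
  list(
    A = c(T = unname(b[["A:T>T:A"]]), G = unname(b[["A:T>G:C"]]),
          C = unname(b[["A:T>C:G"]])),
    T = c(A = unname(b[["A:T>T:A"]]), C = unname(b[["A:T>G:C"]]),
          G = unname(b[["A:T>C:G"]])),
    G = c(A = unname(b[["G:C>A:T"]]), T = unname(b[["G:C>T:A"]]),
          C = unname(b[["G:C>C:G"]])),
    C = c(T = unname(b[["G:C>A:T"]]), A = unname(b[["G:C>T:A"]]),
          G = unname(b[["G:C>C:G"]]))
  )
}

# one generation of mutation applied to a character vector of equal-width
# units; returns the mutated vector
mc_mutate <- function(units, u_eff) {
  w <- nchar(units[1])
  bases <- unlist(strsplit(units, ""), use.names = FALSE)
  dests <- mc_bias_dests()
  wt <- vapply(dests, sum, 0)
  p <- u_eff * wt[bases]
  hit <- which(stats::runif(length(bases)) < p)
  if (length(hit) > 0) {
    orig <- bases[hit]
    for (b in NT) {
      hb <- hit[orig == b]
      if (length(hb) == 0) next
      d <- dests[[b]]
      bases[hb] <- sample(names(d), length(hb), replace = TRUE, prob = d)
    }
  }
  m <- matrix(bases, ncol = w, byrow = TRUE)
  do.call(paste0, lapply(seq_len(w), function(j) m[, j]))
}

# revert mutated sense-codon halves that violate the selection level
# (level "none": a codon that became a stop reverts)
mc_filter_none <- function(orig, mut) {
  c1o <- substr(orig, 1, 3); c1m <- substr(mut, 1, 3)
  c2o <- substr(orig, 4, 6); c2m <- substr(mut, 4, 6)
  bad1 <- c1m != c1o & c1m %in% STOPS
  bad2 <- c2m != c2o & c2m %in% STOPS
  c1m[bad1] <- c1o[bad1]
  c2m[bad2] <- c2o[bad2]
  paste0(c1m, c2m)
}

# draw n states from a subset of a state space, with product-measure weights
mc_draw <- function(states, mass, keep, n) {
  sample(states[keep], n, replace = TRUE, prob = mass[keep])
}

# oligomer model matching the true composition of generator output at GC g:
# sense CDS interiors are stop-free, so codon and dicodon tables are the
# product measure conditioned on stop-freeness; intergenic background is the
# plain product measure.
mc_conditional_model <- function(g) {
  tri <- oracle_kmers(3)
  m3 <- oracle_mass(g, tri)
  names(m3) <- tri
  nonstop <- !(tri %in% STOPS)
  codon <- m3[nonstop] / sum(m3[nonstop])
  dic <- as.vector(outer(tri[nonstop], tri[nonstop], paste0))
  dmass <- as.vector(outer(m3[nonstop], m3[nonstop]))
  dicodon <- setNames(dmass / sum(dmass), dic)
  oligomer_model(trimer_freqs = setNames(m3 / sum(m3), tri),
                 codon_freqs = codon, dicodon_freqs = dicodon)
}
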