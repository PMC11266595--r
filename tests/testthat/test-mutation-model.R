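sp <- mutation_spec()

test_that("substitution probabilities follow the six strand-symmetric classes", {
  u <- 1.7e-10
  expect_equal(substitution_probability(sp, "A", "G"), u * 0.144)
  expect_equal(substitution_probability(sp, "T", "C"), u * 0.144)
  expect_equal(substitution_probability(sp, "G", "A"), u * 0.349)
  expect_equal(substitution_probability(sp, "C", "T"), u * 0.349)
  expect_equal(substitution_probability(sp, "A", "T"),
               substitution_probability(sp, "T", "A"))
  expect_error(substitution_probability(sp, "A", "A"), "must differ")
  expect_equal(sum(yeast_mutation_bias()), 1)
})

test_that("selection tolerance implements the three levels", {
  expect_true(sense_mutation_tolerated("GAT", "GAA", "weak"))   # D -> E similar
  expect_false(sense_mutation_tolerated("GAT", "GAA", "strong"))
  expect_false(sense_mutation_tolerated("TAT", "TAA", "none"))  # nonsense
  expect_true(sense_mutation_tolerated("TTA", "TTG", "strong")) # Leu synonymous
  expect_false(sense_mutation_tolerated("TGT", "TGG", "weak"))  # C has no partner
  expect_error(sense_mutation_tolerated("TAA", "TCA", "none"), "stop")
  expect_error(sense_mutation_tolerated("AAA", "TTT", "none"), "exactly one")
  # similarity sets are symmetric
  sim <- amino_acid_similarity()
  for (a in names(sim)) for (b in sim[[a]]) expect_true(a %in% sim[[b]])
})

test_that("zero mutation rate gives zero gain/loss and stay = existence", {
  sp0 <- mutation_spec(rate = 0)
  for (f in c("intergenic", "as0", "as1")) {
    ev <- event_probabilities(gc_model(0.5), sp0, f)
    expect_equal(ev$p_stop_gain, 0)
    expect_equal(ev$p_stop_loss, 0)
    expect_equal(ev$p_atg_gain, 0)
    expect_equal(ev$p_atg_loss, 0)
    expect_equal(ev$p_stop_stay, stop_probability(gc_model(0.5), f))
    expect_equal(ev$p_atg_stay, start_probability(gc_model(0.5)))
    expect_equal(orf_gain_probability(ev, 10), 0)
    expect_equal(orf_loss_probability(ev, 10), 0)
  }
})

test_that("intergenic stop gain equals the naive 61 x 9 enumeration", {
  for (g in c(0.4, 0.5)) {
    ev <- event_probabilities(gc_model(g), sp, "intergenic")
    expect_gt(ev$p_stop_gain, 0)
    expect_equal(ev$p_stop_gain, oracle_intergenic_stop_gain(g, sp),
                 tolerance = 1e-12)
  }
})

test_that("frame-1 events match a naive dicodon-space oracle", {
  # independent loop-based enumeration at g = 0.5, no selection
  g <- 0.5
  allowed <- enumerate_stop_dicodons("as1")$overlapping_allowed
  all192 <- enumerate_stop_dicodons("as1")$overlapping_all
  dic <- oracle_kmers(6)
  gain <- 0
  loss <- 0
  p_allowed <- sum(oracle_mass(g, allowed))
  for (s in dic) {
    nb <- oracle_neighbors(s)
    for (j in seq_along(nb$seqs)) {
      to <- nb$seqs[j]
      mutated_codon_to <- if (nb$pos[j] <= 3) substr(to, 1, 3) else substr(to, 4, 6)
      tol <- !(mutated_codon_to %in% STOPS) # level "none"
      if (!tol) next
      i <- nb$pos[j]
      m <- substitution_probability(sp, substr(s, i, i), substr(to, i, i))
      if (!(s %in% all192) && to %in% allowed) {
        gain <- gain + oracle_mass(g, s) * m
      }
      if (s %in% allowed && !(to %in% allowed)) {
        loss <- loss + oracle_mass(g, s) / p_allowed * m
      }
    }
  }
  ev <- event_probabilities(gc_model(g), sp, "as1", "none")
  expect_equal(ev$p_stop_gain, gain, tolerance = 1e-12)
  expect_equal(ev$p_stop_loss, loss, tolerance = 1e-12)
})

test_that("frame-0 stop existence and gain equal intergenic when unselected", {
  # reverse-complement bijection maps the two enumerations onto each other;
  # loss is not compared because even the lowest selection level forbids
  # nonsense mutations in the sense reading, which intergenic loci allow.
  for (g in c(0.4, 0.6)) {
    ev0 <- event_probabilities(gc_model(g), sp, "as0", "none")
    evi <- event_probabilities(gc_model(g), sp, "intergenic")
    expect_equal(ev0$p_stop, evi$p_stop, tolerance = 1e-14)
    expect_equal(ev0$p_stop_gain, evi$p_stop_gain, tolerance = 1e-14)
  }
})

test_that("selection monotonically suppresses frame-1 emergence", {
  for (g in c(0.4, 0.6)) {
    m <- gc_model(g)
    ev_n <- event_probabilities(m, sp, "as1", "none")
    ev_w <- event_probabilities(m, sp, "as1", "weak")
    ev_s <- event_probabilities(m, sp, "as1", "strong")
    expect_lt(ev_s$p_stop_gain, ev_n$p_stop_gain)
    ks <- seq(10, 300, by = 10)
    g_n <- orf_gain_probability(ev_n, ks)
    g_w <- orf_gain_probability(ev_w, ks)
    g_s <- orf_gain_probability(ev_s, ks)
    expect_true(all(g_s <= g_w & g_w <= g_n))
  }
})

test_that("gain and loss scale linearly with the mutation rate", {
  ev1 <- event_probabilities(gc_model(0.5), sp, "as1", "weak")
  ev2 <- event_probabilities(gc_model(0.5),
                             mutation_spec(rate = 2 * sp$rate), "as1", "weak")
  for (q in c("p_stop_gain", "p_stop_loss", "p_atg_gain", "p_atg_loss")) {
    expect_equal(ev2[[q]] / ev1[[q]], 2, tolerance = 1e-10)
  }
  # hence crossover lengths are invariant to the rate scale
  expect_identical(
    gain_crossover_length(gc_model(0.4), sp, "as1", "none"),
    gain_crossover_length(gc_model(0.4), mutation_spec(rate = 1e-8),
                          "as1", "none")
  )
})

test_that("loss grows linearly in k and gain eventually decays", {
  ev <- event_probabilities(gc_model(0.5), sp, "as1", "none")
  ks <- 3:300
  loss <- orf_loss_probability(ev, ks)
  expect_true(all(diff(loss) > 0))
  gain <- orf_gain_probability(ev, ks)
  expect_true(all(diff(gain[ks > 20]) < 0))
  # protection from loss: frame 1 under strong selection loses less than
  # intergenic at the same length
  ev_s <- event_probabilities(gc_model(0.5), sp, "as1", "strong")
  ev_i <- event_probabilities(gc_model(0.5), sp, "intergenic")
  expect_lt(orf_loss_probability(ev_s, 100), orf_loss_probability(ev_i, 100))
})

test_that("the two third-term readings differ as documented", {
  ev <- event_probabilities(gc_model(0.5), sp, "as1", "none")
  k <- 50
  joint <- orf_gain_probability(ev, k, third_term = "joint")
  printed <- orf_gain_probability(ev, k, third_term = "printed")
  # printed omits the P_stop factor in the internal-stop-loss term
  diff_expected <- ev$p_atg_stay * ev$p_stop_stay * ev$p_stop_loss *
    (1 - ev$p_stop) * (k - 2) *
    (1 - ev$p_stop - ev$p_stop_gain)^(k - 3)
  expect_equal(printed - joint, diff_expected, tolerance = 1e-10)
  expect_gt(printed, joint)
})

test_that("gain-crossover sensitivity near the documented edge cases", {
  # the 40% GC, no-selection crossover is nearly degenerate: the gain ratio
  # one codon below the threshold is within 0.6% of unity
  ev_a <- event_probabilities(gc_model(0.4), sp, "as1", "none")
  ev_i <- event_probabilities(gc_model(0.4), sp, "intergenic")
  r26 <- orf_gain_probability(ev_a, 26) / orf_gain_probability(ev_i, 26)
  expect_gt(r26, 0.99)
  expect_lt(r26, 1)
  expect_identical(gain_crossover_length(gc_model(0.4), sp, "as1", "none"),
                   27L)
  # relaxing strong (synonymous-only) to the chemically-similar tolerance
  # moves the 60% GC crossover from 125 to 109
  expect_identical(gain_crossover_length(gc_model(0.6), sp, "as1", "strong"),
                   125L)
  expect_identical(gain_crossover_length(gc_model(0.6), sp, "as1", "weak"),
                   109L)
})

test_that("event probabilities work under an empirical oligomer model", {
  set.seed(51)
  m <- gc_model(0.45)
  cds <- vapply(1:300, function(i) draw_stop_free_cds(m, 30), "")
  tabs <- codon_dicodon_frequencies(cds)
  ig <- paste(sample(NT, 5000, replace = TRUE), collapse = "")
  om <- oligomer_model(trimer_freqs = trimer_frequencies(ig),
                       codon_freqs = tabs$codon_freqs,
                       dicodon_freqs = tabs$dicodon_freqs)
  ev <- event_probabilities(om, sp, "as1", "none")
  expect_gt(ev$p_stop, 0)
  expect_gt(ev$p_stop_gain, 0)
  expect_true(ev$p_stop_loss >= 0 && ev$p_stop_loss <= 1)
})
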