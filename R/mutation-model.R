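#' Six-class mutation bias of budding yeast
#'
#' Relative probabilities of the six base-pair substitution classes measured in
#' *Saccharomyces cerevisiae* mutation-accumulation experiments. The classes
#' are strand-symmetric: an `A -> G` mutation on one strand is a `T -> C`
#' mutation on the other, and both belong to the `A:T>G:C` class.
#'
#' @return Named numeric vector over the six classes, summing to 1.
#' @export
yeast_mutation_bias <- function() {
  c("A:T>T:A" = 0.063, "A:T>G:C" = 0.144, "A:T>C:G" = 0.110,
    "G:C>A:T" = 0.349, "G:C>T:A" = 0.182, "G:C>C:G" = 0.152)
}

#' Mutation specification: rate and bias spectrum
#'
#' Bundles the per-nucleotide per-generation mutation rate `u` with the
#' six-class substitution bias. The per-substitution probability is
#' `m(a -> b) = u x bias[class(a -> b)]` with no per-source renormalization;
#' all gain/loss quantities are linear in `u`, so ratios and crossover lengths
#' do not depend on the overall rate scale.
#'
#' @param rate per-nucleotide per-generation mutation rate (default: the yeast
#'   estimate 1.7e-10).
#' @param bias named numeric vector over the six substitution classes,
#'   summing to 1.
#' @return An object of class `"mutation_spec"`.
#' @export
mutation_spec <- function(rate = 1.7e-10, bias = yeast_mutation_bias()) {
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0) {
    abort("`rate` must be a single nonnegative number")
  }
  classes <- names(yeast_mutation_bias())
  if (!setequal(names(bias), classes)) {
    abort(paste0("`bias` must be named with the six classes: ",
                 paste(classes, collapse = ", ")))
  }
  bias <- bias[classes]
  if (any(bias < 0) || abs(sum(bias) - 1) > 1e-6) {
    abort("`bias` weights must be nonnegative and sum to 1")
  }
  structure(list(rate = rate, bias = bias), class = "mutation_spec")
}

#' @export
print.mutation_spec <- function(x, ...) {
  cat("<mutation_spec> rate =", format(x$rate), "per nt per generation\n")
  print(x$bias)
  invisible(x)
}

# strand-symmetric class of a single-base substitution
.subst_class <- function(from, to) {
  cls <- c(
    "A>T" = "A:T>T:A", "A>G" = "A:T>G:C", "A>C" = "A:T>C:G",
    "T>A" = "A:T>T:A", "T>C" = "A:T>G:C", "T>G" = "A:T>C:G",
    "G>A" = "G:C>A:T", "G>T" = "G:C>T:A", "G>C" = "G:C>C:G",
    "C>T" = "G:C>A:T", "C>A" = "G:C>T:A", "C>G" = "G:C>C:G"
  )
  unname(cls[paste0(from, ">", to)])
}

#' Per-generation probability of a single-base substitution
#'
#' `u x bias[class(from -> to)]`, strand-symmetric (A->G and T->C share the
#' `A:T>G:C` weight).
#'
#' @param spec a [mutation_spec()].
#' @param from,to single bases (vectorized); `from != to` elementwise.
#' @return Vector of per-generation probabilities.
#' @examples
#' substitution_probability(mutation_spec(), "A", "G") # 1.7e-10 * 0.144
#' @export
substitution_probability <- function(spec, from, to) {
  stopifnot(inherits(spec, "mutation_spec"))
  if (any(from == to)) abort("`from` and `to` must differ")
  cls <- .subst_class(from, to)
  if (anyNA(cls)) abort("bases must be A, C, G or T")
  spec$rate * unname(spec$bias[cls])
}

#' Chemically similar amino acids
#'
#' Symmetric similarity sets used to define weak purifying selection: an amino
#' acid may be replaced by any member of its set (derived from peptide-MHC
#' binding covariance, pairs with covariance above 0.05). Cysteine, glycine,
#' asparagine and glutamine have no similar partner.
#'
#' @return Named list mapping each one-letter amino acid code to a character
#'   vector of similar amino acids.
#' @export
amino_acid_similarity <- function() {
  list(
    A = c("P", "T", "V"), C = character(0), D = "E", E = "D",
    F = c("I", "W", "Y"), G = character(0), H = c("K", "R"),
    I = c("F", "L", "M", "V"), K = c("H", "R"), L = c("I", "M"),
    M = c("I", "L"), N = character(0), P = "A", Q = character(0),
    R = c("H", "K"), S = "T", T = c("A", "S"), V = c("A", "I"),
    W = c("F", "Y"), Y = c("F", "W")
  )
}

# vectorized tolerance of a single-nucleotide sense-codon change.
# none:   any mutation except one creating a sense stop;
# weak:   synonymous, or replacement by a chemically similar amino acid;
# strong: synonymous only.
# Sources that are themselves stops are only traversable under `none`
# (they carry product-measure mass in the unnormalized convention but admit
# no amino-acid comparison).
.tolerated <- function(codon_from, codon_to, level) {
  to_ok <- !(codon_to %in% STOP_CODONS)
  if (level == "none") return(to_ok)
  from_ok <- !(codon_from %in% STOP_CODONS)
  gc <- Biostrings::GENETIC_CODE
  aa_f <- gc[codon_from]
  aa_t <- gc[codon_to]
  syn <- aa_f == aa_t
  if (level == "strong") return(to_ok & from_ok & syn)
  sim <- amino_acid_similarity()
  similar <- mapply(function(a, b) b %in% sim[[a]], aa_f, aa_t, USE.NAMES = FALSE)
  to_ok & from_ok & (syn | similar)
}

#' Is a sense-codon mutation tolerated under a selection level?
#'
#' Single-nucleotide change of a (non-stop) sense codon: under `"none"` any
#' mutation is tolerated except a nonsense mutation (creation of a sense
#' stop); `"weak"` additionally requires the amino acid to be conserved or
#' replaced by a chemically similar one ([amino_acid_similarity()]);
#' `"strong"` tolerates synonymous changes only.
#'
#' @param codon_from,codon_to codons differing at exactly one position;
#'   `codon_from` must not be a stop codon.
#' @param level `"none"`, `"weak"` or `"strong"`.
#' @return Logical.
#' @examples
#' sense_mutation_tolerated("GAT", "GAA", "weak")   # TRUE (Asp -> Glu)
#' sense_mutation_tolerated("GAT", "GAA", "strong") # FALSE
#' @export
sense_mutation_tolerated <- function(codon_from, codon_to, level) {
  level <- match.arg(level, c("none", "weak", "strong"))
  if (any(codon_from %in% STOP_CODONS)) {
    abort("`codon_from` must not be a stop codon")
  }
  diffs <- mapply(function(a, b) {
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  }, codon_from, codon_to, USE.NAMES = FALSE)
  if (any(diffs != 1L)) abort("codons must differ at exactly one position")
  .tolerated(codon_from, codon_to, level)
}

# --- event probability machinery ------------------------------------------

# state measure over the full k-mer space for a given model and frame
.state_measure <- function(model, frame, states) {
  if (inherits(model, "gc_model")) return(.gc_mass(model$g, states))
  tab <- switch(frame,
    intergenic = model$trimer_freqs,
    as0 = model$codon_freqs,
    as1 = , as2 = model$dicodon_freqs
  )
  if (is.null(tab)) {
    abort(paste0("oligomer model lacks the table required for frame '", frame, "'"))
  }
  p <- tab[states]
  p[is.na(p)] <- 0
  unname(p)
}

#' Stop and start event probabilities for a frame
#'
#' Computes, by exhaustive enumeration of the codon (intergenic, frame 0) or
#' dicodon (frames 1, 2) state space and its single-nucleotide mutation
#' neighborhood, the per-generation probabilities of stop-codon gain, loss and
#' stay in a given frame, together with the analogous `ATG` quantities:
#'
#' \describe{
#'   \item{`p_stop_gain`}{joint probability that a state carries no
#'     antisense-frame stop and one tolerated mutation creates one:
#'     `sum_state P(state) x sum(substitution probabilities into the allowed
#'     stop set)`.}
#'   \item{`p_stop_loss`}{conditional probability, given a stop exists, that a
#'     tolerated mutation removes it: states weighted `P(state)/P(stop set)`.}
#'   \item{`p_stop_stay`}{`p_stop x (1 - p_stop_loss)`.}
#' }
#'
#' For antisense frames the tolerance filter acts on whichever sense codon the
#' mutated position falls in (see [sense_mutation_tolerated()]); for
#' intergenic loci there is no sense reading and `level` is ignored. `ATG`
#' events are computed on the plain trimer measure with no sense constraint in
#' every frame (the overlap's effect on the start codon is not modelled).
#'
#' @param model a composition model.
#' @param spec a [mutation_spec()].
#' @param frame `"intergenic"`, `"as0"`, `"as1"` or `"as2"`.
#' @param level purifying-selection level on the sense ORF: `"none"`,
#'   `"weak"` or `"strong"`.
#' @return An object of class `"frame_events"`: a list with elements `frame`,
#'   `level`, `p_stop`, `p_stop_gain`, `p_stop_loss`, `p_stop_stay`, `p_atg`,
#'   `p_atg_gain`, `p_atg_loss`, `p_atg_stay` and `rate`.
#' @export
event_probabilities <- function(model, spec, frame,
                                level = c("none", "weak", "strong")) {
  .check_frame(frame)
  level <- match.arg(level)
  stopifnot(inherits(spec, "mutation_spec"))

  width <- if (frame %in% c("as1", "as2")) 6L else 3L
  states <- if (width == 3L) .trimers() else .dicodons()
  edges <- .edge_list(width)
  P <- .state_measure(model, frame, states)

  # allowed stop set and "carries an antisense-frame stop" indicator
  if (frame == "intergenic") {
    in_stop <- states %in% STOP_CODONS
    has_stop <- in_stop
  } else if (frame == "as0") {
    in_stop <- states %in% AS0_SENSE_CODONS
    has_stop <- in_stop
  } else {
    sets <- enumerate_stop_dicodons(frame)
    in_stop <- states %in% sets$overlapping_allowed
    has_stop <- states %in% sets$overlapping_all
  }

  rate <- substitution_probability(spec, edges$fb, edges$tb)

  tol <- if (frame == "intergenic") {
    rep(TRUE, nrow(edges))
  } else if (width == 3L) {
    .edge_tolerance_key(level, "tri", function() {
      .tolerated(states[edges$from], states[edges$to], level)
    })
  } else {
    .edge_tolerance_key(level, "dic", function() {
      cf <- ifelse(edges$pos <= 3L,
                   substr(states[edges$from], 1, 3),
                   substr(states[edges$from], 4, 6))
      ct <- ifelse(edges$pos <= 3L,
                   substr(states[edges$to], 1, 3),
                   substr(states[edges$to], 4, 6))
      .tolerated(cf, ct, level)
    })
  }

  # gain: sources are states without an antisense-frame stop
  ge <- !has_stop[edges$from] & in_stop[edges$to] & tol
  p_stop_gain <- sum(P[edges$from[ge]] * rate[ge])

  p_stop <- sum(P[in_stop])
  le <- in_stop[edges$from] & !in_stop[edges$to] & tol
  if (p_stop == 0) {
    if (any(le)) abort("stop set has zero mass under the model; loss undefined")
    p_stop_loss <- 0
  } else {
    p_stop_loss <- sum(P[edges$from[le]] / p_stop * rate[le])
  }

  # ATG events on the trimer measure, no sense constraint
  tri <- .trimers()
  tedges <- .edge_list(3L)
  Pt <- if (inherits(model, "gc_model")) {
    .gc_mass(model$g, tri)
  } else {
    tab <- model$trimer_freqs %||% model$codon_freqs
    if (is.null(tab)) abort("oligomer model has no trimer or codon table")
    pt <- tab[tri]; pt[is.na(pt)] <- 0; unname(pt)
  }
  trate <- substitution_probability(spec, tedges$fb, tedges$tb)
  i_atg <- which(tri == "ATG")
  ag <- tedges$to == i_atg
  p_atg_gain <- sum(Pt[tedges$from[ag]] * trate[ag])
  p_atg_loss <- sum(trate[tedges$from == i_atg]) # every change destroys ATG
  p_atg <- start_probability(model)

  structure(list(
    frame = frame, level = if (frame == "intergenic") "none" else level,
    p_stop = p_stop, p_stop_gain = p_stop_gain, p_stop_loss = p_stop_loss,
    p_stop_stay = p_stop * (1 - p_stop_loss),
    p_atg = p_atg, p_atg_gain = p_atg_gain, p_atg_loss = p_atg_loss,
    p_atg_stay = p_atg * (1 - p_atg_loss),
    rate = spec$rate
  ), class = "frame_events")
}

# cache edge tolerance masks per (level, space); they are model-independent
.edge_tolerance_key <- function(level, space, build) {
  .cache_get(paste0("tol_", space, "_", level), build)
}

#' @export
print.frame_events <- function(x, ...) {
  cat("<frame_events>", x$frame, "/ selection:", x$level, "\n")
  v <- unlist(x[c("p_stop", "p_stop_gain", "p_stop_loss", "p_stop_stay",
                  "p_atg", "p_atg_gain", "p_atg_loss", "p_atg_stay")])
  print(v)
  invisible(x)
}

#' Tidy a frame_events object
#' @param x a `"frame_events"` object.
#' @param ... unused.
#' @return One-row tibble of the event probabilities.
#' @export
tidy.frame_events <- function(x, ...) {
  as_tibble(x[c("frame", "level", "p_stop", "p_stop_gain", "p_stop_loss",
                "p_stop_stay", "p_atg", "p_atg_gain", "p_atg_loss",
                "p_atg_stay", "rate")])
}

#' Per-generation ORF gain probability
#'
#' Probability that a locus of `k` codons that is not an ORF becomes one in a
#' single generation. An ORF emerges when two of its three required features
#' (start codon, terminal stop, stop-free interior) are present and retained
#' while the missing one arises by mutation, giving a three-term sum over the
#' missing-start, missing-terminal-stop and one-internal-stop-lost
#' configurations.
#'
#' The third (internal-stop-lost) term is ambiguous between two readings, kept
#' behind `third_term`:
#' \describe{
#'   \item{`"joint"` (default)}{the term carries an extra factor `p_stop`, so
#'     it is the joint probability that one interior position holds a stop
#'     *and* that stop is lost. This is the probabilistically coherent reading
#'     and the one reproduced by forward mutation simulation.}
#'   \item{`"printed"`}{the term uses the conditional loss probability alone,
#'     `P_ATG-stay x P_stop-stay x P_stop-loss x (k-2) x
#'     (1 - P_stop - P_stop-gain)^(k-3)`.}
#' }
#'
#' @param events a `"frame_events"` object from [event_probabilities()].
#' @param k ORF length in codons (vectorized), >= 3.
#' @param third_term `"joint"` or `"printed"` (see Details).
#' @return Vector of per-generation gain probabilities.
#' @export
orf_gain_probability <- function(events, k, third_term = c("joint", "printed")) {
  stopifnot(inherits(events, "frame_events"))
  third_term <- match.arg(third_term)
  if (any(k < 3)) abort("ORF length `k` must be at least 3 codons")
  ps <- events$p_stop
  base <- 1 - ps - events$p_stop_gain
  t3_scale <- if (third_term == "joint") ps else 1
  events$p_atg_gain * events$p_stop_stay * base^(k - 2) +
    events$p_atg_stay * events$p_stop_gain * base^(k - 2) +
    events$p_atg_stay * events$p_stop_stay * events$p_stop_loss * t3_scale *
      (k - 2) * base^(k - 3)
}

#' Per-generation ORF loss probability
#'
#' Probability that an existing ORF of `k` codons loses one of its required
#' features in a single generation:
#' `P_ATG-loss + P_stop-loss + (k - 2) x P_stop-gain / (1 - P_stop)`
#' (loss of the start, loss of the terminal stop, or gain of a premature stop
#' at any of the `k - 2` interior positions, conditioned on those positions
#' being currently stop-free).
#'
#' @inheritParams orf_gain_probability
#' @return Vector of per-generation loss probabilities.
#' @export
orf_loss_probability <- function(events, k) {
  stopifnot(inherits(events, "frame_events"))
  if (any(k < 3)) abort("ORF length `k` must be at least 3 codons")
  events$p_atg_loss + events$p_stop_loss +
    (k - 2) * events$p_stop_gain / (1 - events$p_stop)
}

#' Length above which antisense ORF gain out-probabilizes intergenic gain
#'
#' Scans `k = 3 .. k_max` and returns the smallest length at which the
#' per-generation gain probability of an asORF in `frame` under selection
#' `level` strictly exceeds the intergenic gain probability, or `NA`.
#'
#' @inheritParams event_probabilities
#' @param k_max upper end of the scan.
#' @inheritParams orf_gain_probability
#' @return Integer length in codons, or `NA_integer_`.
#' @export
gain_crossover_length <- function(model, spec, frame,
                                  level = c("none", "weak", "strong"),
                                  k_max = 500,
                                  third_term = c("joint", "printed")) {
  level <- match.arg(level)
  third_term <- match.arg(third_term)
  ev_f <- event_probabilities(model, spec, frame, level)
  ev_i <- event_probabilities(model, spec, "intergenic")
  ks <- 3:k_max
  hit <- orf_gain_probability(ev_f, ks, third_term) >
    orf_gain_probability(ev_i, ks, third_term)
  if (!any(hit)) return(NA_integer_)
  ks[which(hit)[1]]
}

#' Gain and loss probability curves across frames and selection levels
#'
#' Evaluates [orf_gain_probability()] and [orf_loss_probability()] over a
#' length grid for each requested frame and selection level, with log2 ratios
#' against the intergenic values.
#'
#' @inheritParams event_probabilities
#' @param k_min,k_max inclusive codon-length range.
#' @param frames antisense frames to evaluate.
#' @param levels selection levels to evaluate.
#' @inheritParams orf_gain_probability
#' @return Tibble with columns `k`, `frame`, `level`, `p_gain`, `p_loss`,
#'   `log2_gain_ratio`, `log2_loss_ratio`.
#' @export
gain_loss_curve <- function(model, spec, k_min = 10, k_max = 300,
                            frames = c("as0", "as1", "as2"),
                            levels = c("none", "weak", "strong"),
                            third_term = c("joint", "printed")) {
  third_term <- match.arg(third_term)
  ks <- seq.int(k_min, k_max)
  ev_i <- event_probabilities(model, spec, "intergenic")
  g_i <- orf_gain_probability(ev_i, ks, third_term)
  l_i <- orf_loss_probability(ev_i, ks)
  rows <- list(tibble(k = ks, frame = "intergenic", level = "none",
                      p_gain = g_i, p_loss = l_i,
                      log2_gain_ratio = 0, log2_loss_ratio = 0))
  for (f in frames) for (lv in levels) {
    ev <- event_probabilities(model, spec, f, lv)
    g <- orf_gain_probability(ev, ks, third_term)
    l <- orf_loss_probability(ev, ks)
    rows[[length(rows) + 1L]] <- tibble(
      k = ks, frame = f, level = lv, p_gain = g, p_loss = l,
      log2_gain_ratio = log2(g / g_i), log2_loss_ratio = log2(l / l_i)
    )
  }
  bind_rows(rows)
}
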