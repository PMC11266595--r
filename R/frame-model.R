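#' Frame-specific stop codon probability
#'
#' Probability of finding a stop codon at one codon position, for an intergenic
#' locus or an antisense locus in frame 0, 1 or 2.
#'
#' \describe{
#'   \item{intergenic}{mass of `TAA`, `TAG`, `TGA` under the trimer measure.}
#'   \item{as0}{an antisense stop exactly overlaps one sense codon, which must
#'     read `TTA`, `CTA` or `TCA`; mass of those codons under the sense codon
#'     measure.}
#'   \item{as1, as2}{an antisense stop overlaps a sense dicodon; mass of the
#'     allowed (sense-stop-free) dicodon set from [enumerate_stop_dicodons()].}
#' }
#'
#' Under a [gc_model()] the mass is the plain (unnormalized) product measure:
#' no renormalization by the probability that the sense reading is stop-free is
#' applied. This convention makes frames 0 and 2 exactly equal to intergenic
#' for every GC content, which is the behaviour the model asserts (frame 2
#' antisense stops are compatible with all 192 overlapping dicodons, so the
#' overlap imposes no constraint). Under an [oligomer_model()] the codon and
#' dicodon tables are estimated from stop-free ORF interiors and are therefore
#' intrinsically conditioned; the two model variants deliberately differ.
#'
#' @param model a composition model.
#' @param frame one of `"intergenic"`, `"as0"`, `"as1"`, `"as2"`.
#' @return A probability.
#' @examples
#' stop_probability(gc_model(0.5), "intergenic") # 3/64
#' stop_probability(gc_model(0.5), "as1")        # 128/4096
#' @export
stop_probability <- function(model, frame) {
  .check_frame(frame)
  if (inherits(model, "gc_model")) {
    g <- model$g
    switch(frame,
      intergenic = sum(.gc_mass(g, STOP_CODONS)),
      as0        = sum(.gc_mass(g, AS0_SENSE_CODONS)),
      as1        = sum(.gc_mass(g, enumerate_stop_dicodons("as1")$overlapping_allowed)),
      as2        = sum(.gc_mass(g, enumerate_stop_dicodons("as2")$overlapping_allowed))
    )
  } else if (inherits(model, "oligomer_model")) {
    need <- function(tab, what) {
      if (is.null(tab)) abort(paste0("oligomer model lacks the ", what,
                                     " table required for frame '", frame, "'"))
      tab
    }
    lookup <- function(tab, keys) sum(tab[keys], na.rm = TRUE)
    switch(frame,
      intergenic = lookup(need(model$trimer_freqs, "trimer"), STOP_CODONS),
      as0        = lookup(need(model$codon_freqs, "codon"), AS0_SENSE_CODONS),
      as1        = lookup(need(model$dicodon_freqs, "dicodon"),
                          enumerate_stop_dicodons("as1")$overlapping_allowed),
      as2        = lookup(need(model$dicodon_freqs, "dicodon"),
                          enumerate_stop_dicodons("as2")$overlapping_allowed)
    )
  } else {
    abort("`model` must be a composition model")
  }
}

#' Start codon probability
#'
#' Probability of an `ATG` at the first codon position. The effect of the
#' antisense overlap on the start codon is not modelled, so the value is
#' identical for all frames. Under an [oligomer_model()] the trimer table is
#' used when present (the background measure), the codon table otherwise.
#'
#' @inheritParams stop_probability
#' @return A probability.
#' @export
start_probability <- function(model) {
  if (inherits(model, "gc_model")) {
    .gc_mass(model$g, "ATG")
  } else if (inherits(model, "oligomer_model")) {
    tab <- model$trimer_freqs %||% model$codon_freqs
    if (is.null(tab)) abort("oligomer model has no trimer or codon table")
    p <- tab["ATG"]
    if (is.na(p)) 0 else unname(p)
  } else {
    abort("`model` must be a composition model")
  }
}

#' Stationary ORF probability
#'
#' Probability that a locus of `k` codons is an ORF: a start codon at the
#' first position, a stop codon at the last, and no stop at any of the `k - 2`
#' interior positions,
#' `P_ORF(k) = P_ATG x P_stop x (1 - P_stop)^(k-2)`,
#' with the frame-appropriate stop probability. `k` counts codons including
#' the start and the terminal stop (length in nt = 3k).
#'
#' @inheritParams stop_probability
#' @param k ORF length in codons (vectorized); all values must be >= 3.
#' @return Vector of probabilities, same length as `k`.
#' @export
orf_probability <- function(model, frame, k) {
  if (any(k < 3)) abort("ORF length `k` must be at least 3 codons")
  p_atg <- start_probability(model)
  p_stop <- stop_probability(model, frame)
  p_atg * p_stop * (1 - p_stop)^(k - 2)
}

#' Stationary ORF probability curves across frames
#'
#' Evaluates [orf_probability()] on a grid of lengths for a set of frames and
#' reports each frame's log2 probability ratio against the intergenic frame.
#'
#' @inheritParams stop_probability
#' @param k_min,k_max inclusive codon-length range.
#' @param frames frames to evaluate.
#' @return A tibble with columns `k`, `frame`, `p_orf`, `log2_ratio`.
#' @export
orf_probability_curve <- function(model, k_min = 10, k_max = 300,
                                  frames = c("as0", "as1", "as2")) {
  ks <- seq.int(k_min, k_max)
  p_ig <- orf_probability(model, "intergenic", ks)
  rows <- lapply(unique(c(frames, "intergenic")), function(f) {
    p <- orf_probability(model, f, ks)
    tibble(k = ks, frame = f, p_orf = p, log2_ratio = log2(p / p_ig))
  })
  bind_rows(rows)
}

#' Length above which an antisense frame out-probabilizes intergenic
#'
#' Scans `k = 3 .. k_max` and returns the smallest length (in codons) at which
#' the stationary asORF probability strictly exceeds the intergenic ORF
#' probability of the same length, or `NA` if it never does in range.
#'
#' @inheritParams stop_probability
#' @param k_max upper end of the scan.
#' @return Integer length in codons, or `NA_integer_`.
#' @examples
#' crossover_length(gc_model(0.5), "as1") # 27
#' @export
crossover_length <- function(model, frame, k_max = 500) {
  .check_frame(frame)
  ks <- 3:k_max
  hit <- orf_probability(model, frame, ks) > orf_probability(model, "intergenic", ks)
  if (!any(hit)) return(NA_integer_)
  ks[which(hit)[1]]
}
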