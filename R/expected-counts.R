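#' Number of antisense ORF loci of a given length in a region
#'
#' In an antisense overlap region of length `l_A` nucleotides, the number of
#' loci (codon-register start positions) where an ORF of `k` codons could sit
#' is `(l_A - 3k + 1) / 3`, kept as a real number (no flooring). Lengths
#' outside the summation bounds (`k >= k_min`, `3k < l_A`) yield `NA` and are
#' excluded from sums.
#'
#' @param l_A region length in nucleotides (vectorized).
#' @param k ORF length in codons (vectorized).
#' @param k_min minimum ORF length counted (default 10 codons = 30 nt).
#' @return Real-valued locus counts; `NA` where the bounds fail.
#' @examples
#' n_loci_antisense(301, 10) # 272/3
#' @export
n_loci_antisense <- function(l_A, k, k_min = 10) {
  out <- (l_A - 3 * k + 1) / 3
  out[k < k_min | 3 * k >= l_A] <- NA_real_
  out
}

#' Number of intergenic ORF loci of a given length in a region
#'
#' In an intergenic region of length `l_I` the count is `l_I - 3k + 1`: any
#' nucleotide offset starts a reading frame, so there is no division by 3.
#'
#' @param l_I region length in nucleotides (vectorized).
#' @inheritParams n_loci_antisense
#' @return Real-valued locus counts; `NA` where the bounds fail.
#' @export
n_loci_intergenic <- function(l_I, k, k_min = 10) {
  out <- l_I - 3 * k + 1
  out[k < k_min | 3 * k >= l_I] <- NA_real_
  out
}

#' Expected ORF counts over a region set
#'
#' For each requested frame, sums `P_ORF(frame, k) x nLoci(region, k)` over
#' all regions and all lengths within bounds, giving the expected number of
#' ORFs and the expected frequency (expected number / total loci).
#'
#' Two model modes mirror the two ways composition can be assigned:
#' a single global `model` used for every region, or per-locus GC mode
#' (`model = NULL` and a `gc` column in `regions`), where each region gets its
#' own [gc_model()] built from its GC content.
#'
#' @param regions a data frame with columns `region_id`, `length` (nt) and,
#'   for per-locus GC mode, `gc`.
#' @param frames frames to evaluate (intergenic regions should be summarised
#'   with `frames = "intergenic"`, which uses the intergenic locus formula).
#' @param model a composition model, or `NULL` for per-locus GC mode.
#' @param k_min minimum ORF length in codons.
#' @return Tibble with columns `frame`, `n_loci_total`, `expected_n`,
#'   `expected_frequency`.
#' @export
expected_orf_count <- function(regions, frames = c("as0", "as1", "as2"),
                               model = NULL, k_min = 10) {
  regions <- as_tibble(regions)
  if (nrow(regions) == 0L) {
    warn("empty region set: expected counts are zero")
    return(tibble(frame = frames, n_loci_total = 0,
                  expected_n = 0, expected_frequency = NA_real_))
  }
  if (!all(c("region_id", "length") %in% names(regions))) {
    abort("`regions` needs columns region_id and length")
  }
  if (anyDuplicated(regions$region_id)) abort("region identifiers must be unique")
  if (any(regions$length < 1)) abort("region lengths must be >= 1")
  per_locus <- is.null(model)
  if (per_locus && !"gc" %in% names(regions)) {
    abort("per-locus GC mode needs a `gc` column in `regions`")
  }
  rows <- lapply(frames, function(f) {
    loci_fun <- if (f == "intergenic") n_loci_intergenic else n_loci_antisense
    tot_loci <- 0
    expected <- 0
    for (i in seq_len(nrow(regions))) {
      l <- regions$length[i]
      k_top <- floor((l - 1) / 3)
      if (k_top < k_min) next
      ks <- k_min:k_top
      nl <- loci_fun(l, ks, k_min = k_min)
      keep <- !is.na(nl)
      if (!any(keep)) next
      m <- if (per_locus) gc_model(regions$gc[i]) else model
      p <- orf_probability(m, f, ks[keep])
      tot_loci <- tot_loci + sum(nl[keep])
      expected <- expected + sum(p * nl[keep])
    }
    tibble(frame = f, n_loci_total = tot_loci, expected_n = expected,
           expected_frequency = if (tot_loci > 0) expected / tot_loci else NA_real_)
  })
  bind_rows(rows)
}

#' Observed-versus-expected ORF count report
#'
#' Joins a scan summary (observed ORF counts per frame, optionally with
#' sub-ORFs included) with expected counts into a single report with one row
#' per frame: total loci, expected number and frequency, observed number (and
#' observed + sub-ORFs when available) and observed frequency.
#'
#' @param observed tibble with columns `frame`, `n_observed` and optionally
#'   `n_observed_with_sub`.
#' @param expected output of [expected_orf_count()].
#' @return Tibble in report column order.
#' @export
observed_vs_expected <- function(observed, expected) {
  observed <- as_tibble(observed)
  expected <- as_tibble(expected)
  if (!all(observed$frame %in% expected$frame)) {
    abort("frames in `observed` are missing from `expected`")
  }
  out <- left_join(expected, observed, by = "frame")
  out$n_observed[is.na(out$n_observed)] <- 0
  out$observed_frequency <- ifelse(out$n_loci_total > 0,
                                   out$n_observed / out$n_loci_total, NA_real_)
  if ("n_observed_with_sub" %in% names(out)) {
    out$observed_frequency_with_sub <- ifelse(
      out$n_loci_total > 0, out$n_observed_with_sub / out$n_loci_total, NA_real_)
  }
  out
}
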