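#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false-discovery-rate adjustment (monotone, capped at 1).
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Per-frame ORF enrichment tests
#'
#' One-tailed Fisher exact tests on 2x2 tables of ORF counts against locus
#' counts, for each requested pair of frames, with Benjamini-Hochberg
#' correction across the family. The default pairs test whether frame 1 holds
#' more ORFs per locus than frames 0 and 2.
#'
#' @param counts named integer vector of ORF counts per frame.
#' @param loci named numeric vector of locus totals per frame (same names).
#' @param pairs list of length-2 character vectors naming the frames to
#'   compare (first vs second).
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"` for
#'   the first frame of each pair.
#' @return Tibble with one row per pair: the four table cells, `odds_ratio`,
#'   one-tailed `p` and BH-adjusted `q`.
#' @export
frame_enrichment_test <- function(counts, loci,
                                  pairs = list(c("as1", "as0"), c("as1", "as2")),
                                  alternative = "greater") {
  if (is.null(names(counts)) || is.null(names(loci))) {
    abort("`counts` and `loci` must be named by frame")
  }
  if (any(loci[names(counts)] <= 0)) abort("locus totals must be positive")
  if (any(counts > loci[names(counts)])) abort("counts cannot exceed loci")
  rows <- lapply(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    tab <- matrix(c(round(counts[[a]]), round(loci[[a]] - counts[[a]]),
                    round(counts[[b]]), round(loci[[b]] - counts[[b]])),
                  nrow = 2, byrow = TRUE)
    ft <- fisher.test(tab, alternative = alternative)
    tibble(frame_a = a, frame_b = b,
           count_a = counts[[a]], loci_a = loci[[a]],
           count_b = counts[[b]], loci_b = loci[[b]],
           odds_ratio = unname(ft$estimate), p = ft$p.value,
           alternative = alternative)
  })
  out <- bind_rows(rows)
  out$q <- bh_adjust(out$p)
  out
}

#' One-tailed Mann-Whitney comparison of two samples
#'
#' Wilcoxon rank-sum test (normal approximation with tie correction for large
#' samples, exact otherwise) plus both sample medians.
#'
#' @param lengths_a,lengths_b numeric samples (e.g. ORF lengths or exon GC
#'   contents); both nonempty.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`, referring to
#'   `lengths_a` relative to `lengths_b`.
#' @return One-row tibble: `U`, `p`, `median_a`, `median_b`, `n_a`, `n_b`,
#'   `alternative`.
#' @export
length_comparison_test <- function(lengths_a, lengths_b,
                                   alternative = "greater") {
  if (length(lengths_a) == 0L || length(lengths_b) == 0L) {
    abort("both samples must be nonempty")
  }
  wt <- suppressWarnings(
    wilcox.test(lengths_a, lengths_b, alternative = alternative)
  )
  tibble(U = unname(wt$statistic), p = wt$p.value,
         median_a = median(lengths_a), median_b = median(lengths_b),
         n_a = length(lengths_a), n_b = length(lengths_b),
         alternative = alternative)
}
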