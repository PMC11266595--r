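#' Uniform-composition model from GC content
#'
#' A composition model in which every nucleotide position is independent with
#' `P(G) = P(C) = g/2` and `P(A) = P(T) = (1 - g)/2`. All codon, dicodon and
#' trimer probabilities derive from this product measure.
#'
#' @param g GC fraction, strictly between 0 and 1.
#' @return An object of class `c("gc_model", "composition_model")`.
#' @examples
#' m <- gc_model(0.5)
#' oligomer_probability(m, "TAA") # 1/64
#' @export
gc_model <- function(g) {
  if (!is.numeric(g) || length(g) != 1L || is.na(g) || g <= 0 || g >= 1) {
    abort("`g` must be a single number strictly between 0 and 1")
  }
  structure(list(g = g), class = c("gc_model", "composition_model"))
}

#' Empirical composition model from oligomer frequency tables
#'
#' A composition model backed by observed frequency tables: trimers (counted in
#' sliding windows over intergenic DNA), codons and dicodons (counted at fixed
#' offsets in annotated ORFs). Codon and dicodon tables must place zero mass on
#' stop codons because they are estimated from stop-free ORF interiors.
#'
#' @param trimer_freqs named numeric vector over 3-mers, or `NULL`.
#' @param codon_freqs named numeric vector over codons, or `NULL`.
#' @param dicodon_freqs named numeric vector over 6-mers, or `NULL`.
#' @return An object of class `c("oligomer_model", "composition_model")`.
#' @seealso [trimer_frequencies()], [codon_dicodon_frequencies()]
#' @export
oligomer_model <- function(trimer_freqs = NULL, codon_freqs = NULL,
                           dicodon_freqs = NULL) {
  check_table <- function(x, width, what, stop_free = FALSE) {
    if (is.null(x)) return(NULL)
    if (is.null(names(x)) || any(nchar(names(x)) != width)) {
      abort(paste0(what, " must be a named numeric vector of ", width, "-mers"))
    }
    if (any(x < 0)) abort(paste0(what, " contains negative frequencies"))
    if (abs(sum(x) - 1) > 1e-9) {
      abort(paste0(what, " must sum to 1 (got ", format(sum(x)), ")"))
    }
    if (stop_free) {
      bad <- if (width == 3L) {
        names(x) %in% STOP_CODONS & x > 0
      } else {
        (substr(names(x), 1, 3) %in% STOP_CODONS |
           substr(names(x), 4, 6) %in% STOP_CODONS) & x > 0
      }
      if (any(bad)) {
        abort(paste0(what, " must have zero mass on stop-containing entries (",
                     paste(head(names(x)[bad], 3), collapse = ", "), " ...)"))
      }
    }
    x
  }
  if (is.null(trimer_freqs) && is.null(codon_freqs) && is.null(dicodon_freqs)) {
    abort("supply at least one frequency table")
  }
  structure(
    list(
      trimer_freqs  = check_table(trimer_freqs, 3L, "trimer_freqs"),
      codon_freqs   = check_table(codon_freqs, 3L, "codon_freqs", stop_free = TRUE),
      dicodon_freqs = check_table(dicodon_freqs, 6L, "dicodon_freqs", stop_free = TRUE)
    ),
    class = c("oligomer_model", "composition_model")
  )
}

#' @export
print.gc_model <- function(x, ...) {
  cat("<gc_model> uniform composition, GC =", x$g, "\n")
  invisible(x)
}

#' @export
print.oligomer_model <- function(x, ...) {
  tabs <- names(Filter(Negate(is.null), unclass(x)))
  cat("<oligomer_model> tables:", paste(tabs, collapse = ", "), "\n")
  invisible(x)
}

.base_probs <- function(g) {
  c(A = (1 - g) / 2, C = g / 2, G = g / 2, T = (1 - g) / 2)
}

# unnormalized product-measure mass of oligomers under a gc_model (vectorized)
.gc_mass <- function(g, oligomers) {
  pb <- .base_probs(g)
  w <- nchar(oligomers[1])
  p <- rep(1, length(oligomers))
  for (i in seq_len(w)) p <- p * pb[substr(oligomers, i, i)]
  unname(p)
}

#' Sliding-window trimer frequencies
#'
#' Counts every length-3 window at every offset (0, 1, 2, ...) of each input
#' sequence and normalizes over the total number of countable windows. Windows
#' do not cross sequence boundaries. Windows containing a non-ACGT character
#' are skipped; the number skipped is reported and attached as an attribute.
#'
#' @param sequences character vector or `DNAStringSet` of (intergenic) DNA.
#' @return Named numeric vector of frequencies summing to 1, with attribute
#'   `skipped_windows`.
#' @examples
#' trimer_frequencies("ACGT") # ACG 0.5, CGT 0.5
#' @export
trimer_frequencies <- function(sequences) {
  seqs <- .as_character_seqs(sequences)
  if (length(seqs) == 0L) abort("no sequences supplied")
  counts <- integer(0)
  skipped <- 0L
  for (s in seqs) {
    n <- nchar(s)
    if (n < 3L) next
    starts <- seq_len(n - 2L)
    tri <- substring(s, starts, starts + 2L)
    ok <- !grepl("[^ACGT]", tri)
    skipped <- skipped + sum(!ok)
    tab <- table(tri[ok])
    counts <- c(counts, setNames(as.integer(tab), names(tab)))
  }
  if (length(counts) == 0L) abort("no countable trimers in input")
  agg <- tapply(counts, names(counts), sum)
  if (skipped > 0L) {
    inform(paste0("trimer_frequencies: skipped ", skipped,
                  " windows containing ambiguous bases"))
  }
  out <- agg / sum(agg)
  structure(setNames(as.numeric(out), names(out)), skipped_windows = skipped)
}

#' Codon and dicodon frequencies from ORF sequences
#'
#' Counts non-overlapping codons (every third position) and dicodons (every
#' sixth position), both starting at the first position of each ORF. The
#' terminal stop codon is excluded from both tables, so the resulting tables
#' place zero mass on stop-containing entries. Sequences that are not valid
#' ORFs (length not a multiple of 3, no ATG start, no terminal stop, or an
#' internal stop) are rejected with a warning and do not contribute.
#'
#' @param orf_sequences character vector or `DNAStringSet` of ORF sequences,
#'   each `ATG ... stop`.
#' @return A list with named numeric vectors `codon_freqs` and `dicodon_freqs`.
#' @examples
#' codon_dicodon_frequencies("ATGAAATTTTAA")
#' @export
codon_dicodon_frequencies <- function(orf_sequences) {
  seqs <- .as_character_seqs(orf_sequences)
  codon_counts <- integer(0)
  dicodon_counts <- integer(0)
  rejected <- character(0)
  for (i in seq_along(seqs)) {
    s <- seqs[i]
    n <- nchar(s)
    reason <- NULL
    if (n < 9L || n %% 3L != 0L) {
      reason <- "length not a multiple of 3 (or < 9 nt)"
    } else {
      cods <- substring(s, seq(1L, n - 2L, by = 3L), seq(3L, n, by = 3L))
      if (any(grepl("[^ACGT]", cods))) reason <- "ambiguous bases"
      else if (cods[1] != "ATG") reason <- "does not start with ATG"
      else if (!tail(cods, 1) %in% STOP_CODONS) reason <- "does not end with a stop codon"
      else if (any(head(cods, -1) %in% STOP_CODONS)) reason <- "internal stop codon"
    }
    if (!is.null(reason)) {
      rejected <- c(rejected, paste0("sequence ", i, ": ", reason))
      next
    }
    interior <- head(cods, -1) # terminal stop excluded
    tab <- table(interior)
    codon_counts <- c(codon_counts, setNames(as.integer(tab), names(tab)))
    # dicodons at offsets 0, 6, 12, ... nt; exclude any touching the stop
    n_int <- length(interior)
    di_first <- seq(1L, n_int, by = 2L)
    di_first <- di_first[di_first + 1L <= n_int]
    if (length(di_first) > 0L) {
      di <- paste0(interior[di_first], interior[di_first + 1L])
      tabd <- table(di)
      dicodon_counts <- c(dicodon_counts, setNames(as.integer(tabd), names(tabd)))
    }
  }
  if (length(rejected) > 0L) {
    warn(paste0("codon_dicodon_frequencies: rejected ", length(rejected),
                " sequence(s):\n  ", paste(head(rejected, 5), collapse = "\n  ")))
  }
  if (length(codon_counts) == 0L) abort("no valid ORF sequences")
  norm <- function(x) {
    agg <- tapply(x, names(x), sum)
    setNames(as.numeric(agg) / sum(agg), names(agg))
  }
  list(
    codon_freqs = norm(codon_counts),
    dicodon_freqs = if (length(dicodon_counts)) norm(dicodon_counts) else
      setNames(numeric(0), character(0))
  )
}

#' GC content of sequences
#'
#' `(G + C) / (A + C + G + T)` over all input sequences pooled; ambiguous
#' bases are excluded from numerator and denominator.
#'
#' @param sequences character vector or `DNAStringSet`.
#' @return GC fraction in `[0, 1]`.
#' @export
gc_content <- function(sequences) {
  seqs <- .as_character_seqs(sequences)
  s <- paste(seqs, collapse = "")
  ch <- strsplit(s, "")[[1]]
  gc <- sum(ch %in% c("G", "C"))
  at <- sum(ch %in% c("A", "T"))
  if (gc + at == 0L) abort("no countable (ACGT) bases in input")
  gc / (gc + at)
}

#' Probability of an oligomer under a composition model
#'
#' For a [gc_model()] this is the product of per-base probabilities; for an
#' [oligomer_model()] it is a table lookup (trimer table preferred for 3-mers
#' when present, codon table otherwise; dicodon table for 6-mers). Oligomers
#' absent from a table have probability 0.
#'
#' @param model a composition model.
#' @param oligomer a single DNA string of length 3 or 6.
#' @return A probability.
#' @export
oligomer_probability <- function(model, oligomer) {
  UseMethod("oligomer_probability")
}

#' @export
oligomer_probability.gc_model <- function(model, oligomer) {
  if (!nchar(oligomer) %in% c(3L, 6L)) abort("oligomer must have length 3 or 6")
  .gc_mass(model$g, oligomer)
}

#' @export
oligomer_probability.oligomer_model <- function(model, oligomer) {
  w <- nchar(oligomer)
  tab <- if (w == 3L) {
    model$trimer_freqs %||% model$codon_freqs
  } else if (w == 6L) {
    model$dicodon_freqs
  } else {
    abort("oligomer must have length 3 or 6")
  }
  if (is.null(tab)) abort(paste0("model has no table for ", w, "-mers"))
  p <- unname(tab[oligomer])
  p[is.na(p)] <- 0
  p
}
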