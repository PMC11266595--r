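# Synthetic genomes with known ground truth. The generator emulates the kind
# of input the scanner consumes in real analyses: a contig of intergenic
# background, stop-free sense CDSs on the plus strand, antisense transcripts
# covering them on the minus strand, and optionally asORFs planted at known
# frames. Sequence composition follows a composition model; all randomness
# uses R's global RNG, seeded from the spec for reproducibility.

# sample n codons from the model's codon measure, conditioned as requested
.sample_codons <- function(model, n, condition = c("nonstop", "stop", "any")) {
  condition <- match.arg(condition)
  tri <- .trimers()
  p <- if (inherits(model, "gc_model")) {
    .gc_mass(model$g, tri)
  } else {
    tab <- model$codon_freqs %||% model$trimer_freqs
    if (is.null(tab)) abort("oligomer model has no codon or trimer table")
    pt <- tab[tri]; pt[is.na(pt)] <- 0; unname(pt)
  }
  keep <- switch(condition,
    nonstop = !(tri %in% STOP_CODONS),
    stop = tri %in% STOP_CODONS,
    any = rep(TRUE, length(tri))
  )
  if (sum(p[keep]) == 0) abort("requested codon class has zero mass")
  sample(tri[keep], n, replace = TRUE, prob = p[keep])
}

.sample_bases <- function(model, n) {
  g <- if (inherits(model, "gc_model")) model$g else {
    abort("intergenic background requires a gc_model")
  }
  sample(BASES, n, replace = TRUE, prob = .base_probs(g)[BASES])
}

#' Draw a stop-free coding sequence
#'
#' `ATG`, then `k - 2` interior codons drawn i.i.d. from the model's codon
#' measure conditioned on being non-stop, then a stop codon drawn
#' proportionally to the stop-codon masses.
#'
#' @param model a composition model.
#' @param k length in codons, `>= 3` (sequence length `3k` nt).
#' @return A DNA string.
#' @export
draw_stop_free_cds <- function(model, k) {
  if (k < 3) abort("`k` must be at least 3")
  paste0("ATG",
         paste(.sample_codons(model, k - 2L, "nonstop"), collapse = ""),
         .sample_codons(model, 1L, "stop"))
}

#' Specification of a synthetic genome
#'
#' @param seed RNG seed; the generator is deterministic given the spec.
#' @param g GC content of the composition model for all sequence classes.
#' @param n_cds number of sense CDSs (plus strand).
#' @param cds_codons inclusive range of CDS lengths in codons.
#' @param intergenic_nt inclusive range of intergenic spacer lengths.
#' @param antisense_fraction fraction of CDSs covered by an antisense
#'   transcript (hosts of planted asORFs are always covered).
#' @param planted integer vector named `as0`, `as1`, `as2`: number of asORFs
#'   to plant per frame; or `NULL` for none.
#' @param planted_k length of planted asORFs in codons.
#' @param contig name of the single output contig.
#' @return A list of class `"synthetic_genome_spec"`.
#' @export
synthetic_genome_spec <- function(seed = 1L, g = 0.4, n_cds = 10L,
                                  cds_codons = c(100L, 200L),
                                  intergenic_nt = c(200L, 400L),
                                  antisense_fraction = 1.0,
                                  planted = NULL, planted_k = 15L,
                                  contig = "chrS1") {
  if (!is.null(planted)) {
    if (is.null(names(planted)) || !all(names(planted) %in% c("as0", "as1", "as2"))) {
      abort("`planted` must be named with frames as0/as1/as2")
    }
    if (sum(planted) > n_cds) {
      abort("cannot plant more asORFs than CDSs (one per CDS)")
    }
    if (planted_k + 5L > cds_codons[1]) {
      abort("planted asORF too long for the shortest CDS: need cds_codons >= planted_k + 5")
    }
  }
  structure(list(seed = seed, g = g, n_cds = n_cds, cds_codons = cds_codons,
                 intergenic_nt = intergenic_nt,
                 antisense_fraction = antisense_fraction,
                 planted = planted, planted_k = planted_k, contig = contig),
            class = "synthetic_genome_spec")
}

# embed an asORF of k codons at antisense frame d into a CDS of K codons.
# Returns list(cds = nucleotide string, off = 0-based offset of the asORF
# segment within the CDS) or NULL if no valid draw was found.
.embed_asorf <- function(model, K, k, d, max_tries = 1000L) {
  # plus-strand offset of the asORF segment must satisfy off == -d (mod 3)
  phase <- (3L - d) %% 3L
  lo <- 3L
  hi <- 3L * (K - 1L) - 3L - 3L * k - 3L # segment + guard stop end before the terminal codon
  if (hi < lo) {
    abort(paste0("cannot plant a ", k, "-codon asORF at frame ", d,
                 " in a ", K, "-codon CDS: no room inside the interior"))
  }
  offs <- seq(lo, hi)
  offs <- offs[offs %% 3L == phase]
  if (length(offs) == 0L) {
    abort("no offset with the required codon phase fits inside the CDS")
  }
  for (try in seq_len(max_tries)) {
    off <- if (length(offs) == 1L) offs else sample(offs, 1L)
    cds <- strsplit(draw_stop_free_cds(model, K), "")[[1]]
    as_seq <- draw_stop_free_cds(model, k)
    segment <- strsplit(.revcomp(as_seq), "")[[1]]
    # guard: an antisense stop codon immediately 5' (antisense sense) of the
    # planted ATG, so the planted ORF is the longest ORF for its stop codon
    guard <- strsplit(.revcomp(.sample_codons(model, 1L, "stop")), "")[[1]]
    cds[(off + 1L):(off + 3L * k)] <- segment
    cds[(off + 3L * k + 1L):(off + 3L * k + 3L)] <- guard
    # sense reading must stay stop-free over the interior
    n_cod <- K
    cods <- vapply(seq_len(n_cod), function(i) {
      paste(cds[(3L * i - 2L):(3L * i)], collapse = "")
    }, "")
    if (any(cods[2:(n_cod - 1L)] %in% STOP_CODONS)) next
    return(list(cds = paste(cds, collapse = ""), off = off))
  }
  abort(paste0("failed to embed a frame-", d, " asORF after ", max_tries,
               " attempts (sense stop-freeness unsatisfiable at this composition)"))
}

#' Generate a synthetic genome with ground truth
#'
#' Builds one contig alternating intergenic background and stop-free sense
#' CDSs, annotates antisense transcripts over (a fraction of) the CDSs, and
#' optionally plants asORFs of known frame and length inside chosen CDSs. A
#' planted asORF is constructed so that it is exactly recoverable by
#' [scan_antisense_transcripts()]: its interior is antisense-stop-free and an
#' antisense stop codon is placed immediately upstream of its start codon.
#'
#' @param spec a [synthetic_genome_spec()].
#' @return A list of class `"synthetic_genome"`: `genome` (`DNAStringSet`),
#'   `cds` and `transcripts` (`GRanges`), `truth` (tibble of planted asORFs
#'   with genomic coordinates and frames), `overlap_regions` (tibble of
#'   antisense overlap region lengths for [expected_orf_count()]), and the
#'   spec.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  set.seed(spec$seed)
  model <- gc_model(spec$g)
  plant_jobs <- integer(0)
  if (!is.null(spec$planted)) {
    plant_jobs <- rep(c(as0 = 0L, as1 = 1L, as2 = 2L)[names(spec$planted)],
                      times = spec$planted)
  }
  n_planted <- length(plant_jobs)
  # hosts: first n_planted CDSs carry one planted asORF each
  pieces <- character(0)
  pos <- 0L
  cds_rows <- list()
  truth_rows <- list()
  ig_len <- function() {
    if (spec$intergenic_nt[1] == spec$intergenic_nt[2]) spec$intergenic_nt[1]
    else sample(spec$intergenic_nt[1]:spec$intergenic_nt[2], 1L)
  }
  ig_rows <- list()
  add_spacer <- function() {
    spacer <- paste(.sample_bases(model, ig_len()), collapse = "")
    ig_rows[[length(ig_rows) + 1L]] <<- tibble(
      id = paste0("ig_", length(ig_rows) + 1L),
      start = pos, end = pos + nchar(spacer)
    )
    spacer
  }
  for (i in seq_len(spec$n_cds)) {
    spacer <- add_spacer()
    pieces <- c(pieces, spacer)
    pos <- pos + nchar(spacer)
    K <- if (spec$cds_codons[1] == spec$cds_codons[2]) spec$cds_codons[1]
         else sample(spec$cds_codons[1]:spec$cds_codons[2], 1L)
    if (i <= n_planted) {
      d <- plant_jobs[i]
      emb <- .embed_asorf(model, K, spec$planted_k, d)
      cds_seq <- emb$cds
      # asORF genomic coordinates: segment occupies [pos+off, pos+off+3k)
      truth_rows[[length(truth_rows) + 1L]] <- tibble(
        cds_id = paste0("cds_", i),
        frame = paste0("as", d), frame_d = d,
        k = spec$planted_k,
        gstart = pos + emb$off,
        gend = pos + emb$off + 3L * spec$planted_k,
        strand = "-"
      )
    } else {
      cds_seq <- draw_stop_free_cds(model, K)
    }
    cds_rows[[length(cds_rows) + 1L]] <- tibble(
      id = paste0("cds_", i), start = pos, end = pos + nchar(cds_seq)
    )
    pieces <- c(pieces, cds_seq)
    pos <- pos + nchar(cds_seq)
  }
  final_spacer <- add_spacer()
  pieces <- c(pieces, final_spacer)
  pos <- pos + nchar(final_spacer)
  contig_seq <- paste(pieces, collapse = "")
  cds_tbl <- bind_rows(cds_rows)
  ig_tbl <- bind_rows(ig_rows)

  # antisense transcripts on the minus strand over hosts + sampled others
  covered <- seq_len(n_planted)
  others <- setdiff(seq_len(spec$n_cds), covered)
  n_extra <- round(spec$antisense_fraction * spec$n_cds) - n_planted
  if (n_extra > 0 && length(others) > 0) {
    covered <- c(covered, head(others, n_extra))
  }
  covered <- sort(unique(covered))
  tx_tbl <- cds_tbl[covered, , drop = FALSE]
  tx_tbl$id <- sub("^cds_", "tx_", tx_tbl$id)

  genome <- Biostrings::DNAStringSet(setNames(contig_seq, spec$contig))
  to_gr <- function(tbl, strand) {
    GenomicRanges::GRanges(
      seqnames = spec$contig,
      ranges = IRanges::IRanges(start = tbl$start + 1L, end = tbl$end),
      strand = strand, ID = tbl$id
    )
  }
  truth <- if (length(truth_rows)) bind_rows(truth_rows) else
    tibble(cds_id = character(), frame = character(), frame_d = integer(),
           k = integer(), gstart = integer(), gend = integer(),
           strand = character())
  overlap_regions <- tibble(
    region_id = tx_tbl$id,
    length = tx_tbl$end - tx_tbl$start
  )
  intergenic_regions <- tibble(
    region_id = ig_tbl$id,
    start = ig_tbl$start, end = ig_tbl$end,
    length = ig_tbl$end - ig_tbl$start
  )
  structure(list(
    genome = genome,
    cds = to_gr(cds_tbl, "+"),
    transcripts = to_gr(tx_tbl, "-"),
    intergenic = to_gr(ig_tbl, "*"),
    truth = truth,
    overlap_regions = overlap_regions,
    intergenic_regions = intergenic_regions,
    spec = spec
  ), class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("<synthetic_genome>", names(x$genome), "-",
      Biostrings::width(x$genome), "nt,", length(x$cds), "CDS,",
      length(x$transcripts), "antisense transcripts,",
      nrow(x$truth), "planted asORFs\n")
  invisible(x)
}

#' Write a synthetic genome to standard files
#'
#' FASTA for the contig, GFF3 for CDSs and antisense transcripts, TSV for the
#' ground truth. Output is deterministic given the spec.
#'
#' @param x a `"synthetic_genome"`.
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of file paths.
#' @export
write_genome_files <- function(x, dir) {
  stopifnot(inherits(x, "synthetic_genome"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    genome = file.path(dir, "genome.fa"),
    cds = file.path(dir, "cds.gff3"),
    transcripts = file.path(dir, "antisense_transcripts.gff3"),
    truth = file.path(dir, "planted_asorfs.tsv")
  )
  Biostrings::writeXStringSet(x$genome, paths$genome)
  rtracklayer::export(x$cds, paths$cds, format = "gff3")
  rtracklayer::export(x$transcripts, paths$transcripts, format = "gff3")
  write.table(x$truth, paths$truth, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(paths)
}

#' One generation of forward mutation
#'
#' Each site mutates independently with probability
#' `u x rate_scale x sum(bias weights from that base)`; the destination base
#' is drawn proportionally to the bias weights. `rate_scale` inflates the
#' rate for simulation studies where per-generation events would otherwise be
#' unobservably rare; it should be kept small enough that double hits within
#' a codon stay negligible.
#'
#' @param sequence a DNA string.
#' @param spec a [mutation_spec()].
#' @param rate_scale multiplicative rate inflation (default 1).
#' @return A list: `sequence` (mutated string) and `events` (tibble with
#'   `pos`, `from`, `to`; 1-based positions).
#' @export
mutate_one_generation <- function(sequence, spec, rate_scale = 1) {
  stopifnot(inherits(spec, "mutation_spec"))
  if (rate_scale < 0) abort("`rate_scale` must be nonnegative")
  s <- strsplit(.as_character_seqs(sequence), "")[[1]]
  n <- length(s)
  # total outgoing weight and per-destination weights for each base
  dests <- list(
    A = c(T = unname(spec$bias[["A:T>T:A"]]), G = unname(spec$bias[["A:T>G:C"]]),
          C = unname(spec$bias[["A:T>C:G"]])),
    T = c(A = unname(spec$bias[["A:T>T:A"]]), C = unname(spec$bias[["A:T>G:C"]]),
          G = unname(spec$bias[["A:T>C:G"]])),
    G = c(A = unname(spec$bias[["G:C>A:T"]]), T = unname(spec$bias[["G:C>T:A"]]),
          C = unname(spec$bias[["G:C>C:G"]])),
    C = c(T = unname(spec$bias[["G:C>A:T"]]), A = unname(spec$bias[["G:C>T:A"]]),
          G = unname(spec$bias[["G:C>C:G"]]))
  )
  w_tot <- vapply(dests, sum, 0)
  p_site <- spec$rate * rate_scale * w_tot[s]
  hit <- which(runif(n) < p_site)
  if (length(hit) == 0L) {
    return(list(sequence = paste(s, collapse = ""),
                events = tibble(pos = integer(), from = character(),
                                to = character())))
  }
  to <- vapply(hit, function(i) {
    d <- dests[[s[i]]]
    sample(names(d), 1L, prob = d)
  }, "")
  events <- tibble(pos = hit, from = s[hit], to = to)
  s[hit] <- to
  list(sequence = paste(s, collapse = ""), events = events)
}
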