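# Coordinates are 0-based half-open on the plus strand throughout the package
# internals; GFF3 (1-based closed) is converted at the import boundary, BED is
# native half-open.

#' Find ORFs in a transcript sequence
#'
#' getorf-style extraction: in each of the three reading frames of the given
#' (single-stranded) sequence, every stop codon is paired with the most 5'
#' in-frame `ATG` downstream of the previous stop, i.e. the longest ORF ending
#' at that stop. ORFs shorter than `min_len` nucleotides are dropped;
#' `min_len` counts the ORF including its terminal stop codon (30 nt = 10
#' codons).
#'
#' @param sequence a single DNA string (character or `DNAString`).
#' @param min_len minimum ORF length in nucleotides, stop codon included.
#' @param seq_id identifier recorded in the output.
#' @return Tibble with columns `seq_id`, `start`, `end` (0-based half-open,
#'   in the coordinates and orientation of `sequence`), `frame_offset`,
#'   `length_nt`, `sequence`, `is_sub_orf`, `stop_anchor` (0-based start of
#'   the terminal stop codon).
#' @examples
#' find_orfs("ATGAAATGA", min_len = 9)
#' @export
find_orfs <- function(sequence, min_len = 30, seq_id = "seq") {
  s <- .as_character_seqs(sequence)
  if (length(s) != 1L) abort("`sequence` must be a single sequence")
  n <- nchar(s)
  out <- list()
  for (f in 0:2) {
    n_cod <- (n - f) %/% 3L
    if (n_cod < 1L) next
    starts <- f + 3L * (seq_len(n_cod) - 1L) + 1L # 1-based substring starts
    cods <- substring(s, starts, starts + 2L)
    stop_idx <- which(cods %in% STOP_CODONS)
    atg_idx <- which(cods == "ATG")
    if (length(stop_idx) == 0L || length(atg_idx) == 0L) next
    prev_stop <- 0L
    for (j in stop_idx) {
      cand <- atg_idx[atg_idx > prev_stop & atg_idx < j]
      prev_stop <- j
      if (length(cand) == 0L) next
      i <- cand[1]
      len <- 3L * (j - i + 1L)
      if (len < min_len) next
      start0 <- f + 3L * (i - 1L)
      end0 <- f + 3L * j
      out[[length(out) + 1L]] <- tibble(
        seq_id = seq_id, start = start0, end = end0, frame_offset = f,
        length_nt = len, sequence = substr(s, start0 + 1L, end0),
        is_sub_orf = FALSE, stop_anchor = end0 - 3L
      )
    }
  }
  if (length(out) == 0L) {
    return(tibble(seq_id = character(), start = integer(), end = integer(),
                  frame_offset = integer(), length_nt = integer(),
                  sequence = character(), is_sub_orf = logical(),
                  stop_anchor = integer()))
  }
  bind_rows(out)
}

#' Sub-ORFs sharing a parent ORF's stop codon
#'
#' For each ORF, reports one record per internal in-frame `ATG` with at least
#' `min_len` nucleotides remaining up to (and including) the shared terminal
#' stop codon.
#'
#' @param orfs a tibble of ORFs as returned by [find_orfs()].
#' @param min_len minimum sub-ORF length in nucleotides.
#' @return Tibble of sub-ORF records (`is_sub_orf = TRUE`), sharing
#'   `stop_anchor` with their parents; empty if none qualify.
#' @export
sub_orfs <- function(orfs, min_len = 30) {
  rows <- list()
  for (r in seq_len(nrow(orfs))) {
    s <- orfs$sequence[r]
    n_cod <- nchar(s) %/% 3L
    cods <- substring(s, 3L * (seq_len(n_cod) - 1L) + 1L, 3L * seq_len(n_cod))
    internal_atg <- which(cods == "ATG")
    internal_atg <- internal_atg[internal_atg > 1L]
    for (t in internal_atg) {
      len <- 3L * (n_cod - t + 1L)
      if (len < min_len) next
      rows[[length(rows) + 1L]] <- tibble(
        seq_id = orfs$seq_id[r],
        start = orfs$start[r] + 3L * (t - 1L),
        end = orfs$end[r],
        frame_offset = orfs$frame_offset[r],
        length_nt = len,
        sequence = substr(s, 3L * (t - 1L) + 1L, nchar(s)),
        is_sub_orf = TRUE,
        stop_anchor = orfs$stop_anchor[r]
      )
    }
  }
  if (length(rows) == 0L) return(orfs[0, ])
  bind_rows(rows)
}

#' Antisense frame of overlap between an ORF and a sense CDS
#'
#' The antisense frame `d` is the codon-register offset between the antisense
#' ORF's codons and the sense CDS's codons, measured on the plus strand:
#' `d = 0` means exact antiparallel codon overlap; `d = 1` and `d = 2` mean
#' the antisense codons are shifted 1 or 2 nt toward the sense 5' end. With
#' 0-based half-open intervals this reduces to `d = (cds_start - as_end) mod
#' 3` for a plus-strand sense CDS and `d = (as_start - cds_end) mod 3` for a
#' minus-strand one; the result does not depend on which sense codon anchors
#' the comparison.
#'
#' @param as_start,as_end antisense ORF interval (0-based half-open, plus
#'   strand coordinates); vectorized.
#' @param as_strand,cds_strand strand characters; must be opposite.
#' @param cds_start,cds_end sense CDS interval.
#' @return Tibble with columns `frame` (`"as0"`, `"as1"`, `"as2"`),
#'   `frame_d` (0/1/2) and `overlap_fraction`.
#' @export
classify_frame <- function(as_start, as_end, as_strand,
                           cds_start, cds_end, cds_strand) {
  if (any(as_strand == cds_strand)) {
    abort("antisense ORF and sense CDS must be on opposite strands")
  }
  ov <- pmin(as_end, cds_end) - pmax(as_start, cds_start)
  if (any(ov <= 0)) abort("antisense ORF and sense CDS do not overlap")
  d <- ifelse(cds_strand == "+",
              (cds_start - as_end) %% 3L,
              (as_start - cds_end) %% 3L)
  tibble(frame = paste0("as", d), frame_d = as.integer(d),
         overlap_fraction = ov / (as_end - as_start))
}

# import helpers -----------------------------------------------------------

.ranges_tbl <- function(x, what = "ranges") {
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) abort(paste0(what, " file not found: ", x))
    x <- rtracklayer::import(x)
  }
  if (!inherits(x, "GRanges")) {
    abort(paste0("`", what, "` must be a GRanges or a GFF3/BED file path"))
  }
  ids <- NULL
  md <- S4Vectors::mcols(x)
  for (col in c("ID", "Name", "name")) {
    if (col %in% names(md) && !any(is.na(md[[col]]))) { ids <- as.character(md[[col]]); break }
  }
  if (is.null(ids)) ids <- paste0(what, "_", seq_along(x))
  tibble(
    seqnames = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1L, # to 0-based half-open
    end = GenomicRanges::end(x),
    strand = as.character(GenomicRanges::strand(x)),
    id = ids
  )
}

.load_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && is.null(names(genome))) {
    if (!file.exists(genome)) abort(paste0("genome file not found: ", genome))
    genome <- Biostrings::readDNAStringSet(genome)
  } else if (is.character(genome)) {
    if (is.null(names(genome))) abort("a character genome must be named by contig")
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (!inherits(genome, "DNAStringSet")) {
    abort("`genome` must be a DNAStringSet, a named character vector, or a FASTA path")
  }
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Scan antisense transcripts for ORFs and classify their frames
#'
#' The observed-ORF pipeline: extracts ORFs from each antisense transcript
#' with [find_orfs()] (the transcript is single-stranded, so only its own
#' three frames are scanned), maps them to genomic coordinates, retains those
#' overlapping an opposite-strand CDS by at least `min_overlap` of their
#' length, and classifies the frame of overlap. Each transcript range is
#' treated as unspliced; ORFs overlapping more than one qualifying CDS are
#' flagged (`multi_overlap`) and excluded from the per-frame summary.
#'
#' @param genome `DNAStringSet`, named character vector, or FASTA path.
#' @param cds sense CDS annotation: `GRanges` or GFF3/BED path.
#' @param transcripts antisense transcript annotation: `GRanges` or path.
#' @param min_len minimum ORF length in nucleotides (stop included).
#' @param min_overlap minimum fraction of the ORF overlapping the CDS
#'   (1.0 = wholly contained).
#' @param include_sub_orfs also report sub-ORFs ([sub_orfs()]).
#' @return An object of class `"asorf_scan"`: a list with tibbles `orfs`
#'   (one row per ORF x qualifying CDS, with genomic coordinates, frame and
#'   overlap fraction) and `summary` (per frame: count, median and cumulative
#'   length, counts with sub-ORFs).
#' @export
scan_antisense_transcripts <- function(genome, cds, transcripts,
                                       min_len = 30, min_overlap = 1.0,
                                       include_sub_orfs = FALSE) {
  genome <- .load_genome(genome)
  cds_tbl <- .ranges_tbl(cds, "cds")
  tx_tbl <- .ranges_tbl(transcripts, "transcript")
  missing_contig <- setdiff(unique(c(cds_tbl$seqnames, tx_tbl$seqnames)),
                            names(genome))
  if (length(missing_contig) > 0L) {
    abort(paste0("contig(s) absent from genome: ",
                 paste(missing_contig, collapse = ", ")))
  }
  all_orfs <- list()
  for (t in seq_len(nrow(tx_tbl))) {
    contig <- tx_tbl$seqnames[t]
    ts <- tx_tbl$start[t]; te <- tx_tbl$end[t]; tstrand <- tx_tbl$strand[t]
    seq <- substr(as.character(genome[[contig]]), ts + 1L, te)
    if (tstrand == "-") seq <- .revcomp(seq)
    orfs <- find_orfs(seq, min_len = min_len, seq_id = tx_tbl$id[t])
    if (include_sub_orfs && nrow(orfs) > 0L) {
      orfs <- bind_rows(orfs, sub_orfs(orfs, min_len = min_len))
    }
    if (nrow(orfs) == 0L) next
    # transcript-local -> genomic plus-strand coordinates
    if (tstrand == "-") {
      gstart <- te - orfs$end
      gend <- te - orfs$start
    } else {
      gstart <- ts + orfs$start
      gend <- ts + orfs$end
    }
    orfs$contig <- contig
    orfs$gstart <- gstart
    orfs$gend <- gend
    orfs$strand <- tstrand
    all_orfs[[length(all_orfs) + 1L]] <- orfs
  }
  empty_summary <- tibble(frame = c("as0", "as1", "as2"), n = 0L,
                          n_with_sub = 0L, median_length_nt = NA_real_,
                          cumulative_length_nt = 0)
  if (length(all_orfs) == 0L) {
    res <- list(orfs = tibble(), summary = empty_summary,
                min_len = min_len, min_overlap = min_overlap)
    class(res) <- "asorf_scan"
    return(res)
  }
  orfs <- bind_rows(all_orfs)
  # match each ORF against opposite-strand CDS ranges on the same contig
  rows <- list()
  for (r in seq_len(nrow(orfs))) {
    cand <- cds_tbl[cds_tbl$seqnames == orfs$contig[r] &
                      cds_tbl$strand != orfs$strand[r], , drop = FALSE]
    if (nrow(cand) == 0L) next
    ov <- pmin(orfs$gend[r], cand$end) - pmax(orfs$gstart[r], cand$start)
    frac <- ov / (orfs$gend[r] - orfs$gstart[r])
    hit <- which(frac >= min_overlap & ov > 0)
    if (length(hit) == 0L) next
    for (h in hit) {
      cf <- classify_frame(orfs$gstart[r], orfs$gend[r], orfs$strand[r],
                           cand$start[h], cand$end[h], cand$strand[h])
      row <- orfs[r, ]
      row$cds_id <- cand$id[h]
      row$frame <- cf$frame
      row$overlap_fraction <- cf$overlap_fraction
      row$multi_overlap <- length(hit) > 1L
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) {
    res <- list(orfs = tibble(), summary = empty_summary,
                min_len = min_len, min_overlap = min_overlap)
    class(res) <- "asorf_scan"
    return(res)
  }
  hits <- bind_rows(rows)
  usable <- hits[!hits$multi_overlap, , drop = FALSE]
  summarise_frame <- function(f) {
    sub <- usable[usable$frame == f, , drop = FALSE]
    main <- sub[!sub$is_sub_orf, , drop = FALSE]
    tibble(frame = f, n = nrow(main), n_with_sub = nrow(sub),
           median_length_nt = if (nrow(main)) median(main$length_nt) else NA_real_,
           cumulative_length_nt = sum(main$length_nt))
  }
  res <- list(
    orfs = hits,
    summary = bind_rows(lapply(c("as0", "as1", "as2"), summarise_frame)),
    min_len = min_len, min_overlap = min_overlap
  )
  class(res) <- "asorf_scan"
  res
}

#' @export
print.asorf_scan <- function(x, ...) {
  cat("<asorf_scan>", nrow(x$orfs), "ORF-CDS overlap records\n")
  print(x$summary)
  invisible(x)
}

#' Glance at a scan result
#' @param x an `"asorf_scan"` object.
#' @param ... unused.
#' @return One-row tibble with total counts and the settings used.
#' @export
glance.asorf_scan <- function(x, ...) {
  tibble(n_records = nrow(x$orfs),
         n_frame_classified = sum(x$summary$n),
         min_len = x$min_len, min_overlap = x$min_overlap)
}

#' Find intergenic ORFs in annotated regions
#'
#' Runs [find_orfs()] on both strands of each intergenic region.
#'
#' @inheritParams scan_antisense_transcripts
#' @param regions intergenic regions: `GRanges` or BED/GFF3 path.
#' @param strands strands to scan (default both).
#' @return Tibble of ORF records with genomic coordinates and `strand`.
#' @export
find_igorfs <- function(genome, regions, min_len = 30,
                        include_sub_orfs = FALSE, strands = c("+", "-")) {
  genome <- .load_genome(genome)
  reg <- .ranges_tbl(regions, "region")
  out <- list()
  for (r in seq_len(nrow(reg))) {
    if (!reg$seqnames[r] %in% names(genome)) {
      abort(paste0("contig absent from genome: ", reg$seqnames[r]))
    }
    seq <- substr(as.character(genome[[reg$seqnames[r]]]),
                  reg$start[r] + 1L, reg$end[r])
    for (st in strands) {
      s <- if (st == "-") .revcomp(seq) else seq
      orfs <- find_orfs(s, min_len = min_len, seq_id = reg$id[r])
      if (include_sub_orfs && nrow(orfs) > 0L) {
        orfs <- bind_rows(orfs, sub_orfs(orfs, min_len = min_len))
      }
      if (nrow(orfs) == 0L) next
      if (st == "-") {
        gstart <- reg$end[r] - orfs$end
        gend <- reg$end[r] - orfs$start
      } else {
        gstart <- reg$start[r] + orfs$start
        gend <- reg$start[r] + orfs$end
      }
      orfs$contig <- reg$seqnames[r]
      orfs$gstart <- gstart
      orfs$gend <- gend
      orfs$strand <- st
      out[[length(out) + 1L]] <- orfs
    }
  }
  if (length(out) == 0L) return(tibble())
  bind_rows(out)
}

#' Compare GC content of overlapping exons against all exons
#'
#' Computes per-sequence GC content for the set of coding exons that overlap
#' an antisense RNA and for the full exon set, reports both medians and a
#' one-tailed Mann-Whitney test of the default hypothesis that overlapping
#' exons have lower GC content.
#'
#' @param overlap_seqs sequences of exons with antisense overlap.
#' @param all_seqs sequences of all exons.
#' @param alternative passed to [length_comparison_test()]; default `"less"`.
#' @return One-row tibble: `median_overlap`, `median_all`, `U`, `p`.
#' @export
exon_gc_comparison <- function(overlap_seqs, all_seqs, alternative = "less") {
  ov <- .as_character_seqs(overlap_seqs)
  al <- .as_character_seqs(all_seqs)
  if (length(ov) == 0L || length(al) == 0L) abort("both exon sets must be nonempty")
  gc_ov <- vapply(ov, gc_content, 0, USE.NAMES = FALSE)
  gc_al <- vapply(al, gc_content, 0, USE.NAMES = FALSE)
  t <- length_comparison_test(gc_ov, gc_al, alternative = alternative)
  tibble(median_overlap = t$median_a, median_all = t$median_b,
         U = t$U, p = t$p)
}
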