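# Exhaustive enumeration tables: codon and dicodon state spaces, the
# frame-specific antisense stop-codon sets, and single-mutation edge lists.
# Everything here is deterministic combinatorics, built once and cached.

.all_kmers <- function(width) {
  grid <- expand.grid(rep(list(BASES), width), stringsAsFactors = FALSE)
  # first base varies slowest so indexing is base-4 big-endian
  do.call(paste0, rev(grid))
}

.trimers <- function() .cache_get("trimers", function() .all_kmers(3L))
.dicodons <- function() .cache_get("dicodons", function() .all_kmers(6L))

# antisense codon read off a sense dicodon:
# frame 1 -> reverse complement of positions 3-5 of the 6-mer,
# frame 2 -> reverse complement of positions 2-4.
.antisense_codon <- function(dicodons, frame) {
  from <- switch(frame, as1 = 3L, as2 = 2L,
                 abort("dicodon frames are 'as1' and 'as2'"))
  .revcomp3(substr(dicodons, from, from + 2L))
}

#' Enumerate sense dicodons overlapping an antisense stop codon
#'
#' Exhaustively enumerates all 4096 6-mers and returns those whose antisense
#' reading in the given frame is a stop codon (`TAA`, `TAG`, `TGA`), split
#' into the full set and the subset allowed in a coding sense ORF (neither
#' constituent sense codon a stop). In frame 1 an antisense codon covers
#' positions 3-5 of the sense dicodon; in frame 2, positions 2-4. For each
#' frame there are 3 x 4^3 = 192 overlapping dicodons; in frame 1 only 128 of
#' them are stop-free in the sense reading, while in frame 2 all 192 are.
#'
#' @param frame `"as1"` or `"as2"`.
#' @return A list with character vectors `overlapping_all` and
#'   `overlapping_allowed`.
#' @examples
#' length(enumerate_stop_dicodons("as1")$overlapping_allowed) # 128
#' @export
enumerate_stop_dicodons <- function(frame) {
  frame <- match.arg(frame, c("as1", "as2"))
  .cache_get(paste0("stopdic_", frame), function() {
    dic <- .dicodons()
    as_codon <- .antisense_codon(dic, frame)
    all_set <- dic[as_codon %in% STOP_CODONS]
    sense_free <- !(substr(all_set, 1, 3) %in% STOP_CODONS) &
      !(substr(all_set, 4, 6) %in% STOP_CODONS)
    list(
      overlapping_all = all_set,
      overlapping_allowed = all_set[sense_free]
    )
  })
}

# single-nucleotide mutation edge list over the full k-mer state space.
# Columns: from, to (state indices), pos (mutated position), fb, tb (bases).
.edge_list <- function(width) {
  .cache_get(paste0("edges_", width), function() {
    states <- if (width == 3L) .trimers() else .dicodons()
    n <- length(states)
    base_idx <- setNames(0:3, BASES)
    # index of each state in big-endian base 4 (+1)
    mat <- matrix(0L, nrow = n, ncol = width)
    for (i in seq_len(width)) mat[, i] <- base_idx[substr(states, i, i)]
    pow <- 4L^((width - 1L):0L)
    from <- rep(seq_len(n), each = width * 3L)
    pos <- rep(rep(seq_len(width), each = 3L), times = n)
    old <- mat[cbind(from, pos)]
    # for each (state, pos) the three alternative bases, as rotations of old
    alts <- vapply(0:3, function(o) (o + 1:3) %% 4L, integer(3))
    new <- alts[cbind(rep(1:3, times = length(from) / 3L), old + 1L)]
    to <- from + (new - old) * pow[pos]
    data.frame(
      from = from, to = to, pos = pos,
      fb = BASES[old + 1L], tb = BASES[new + 1L],
      stringsAsFactors = FALSE
    )
  })
}
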