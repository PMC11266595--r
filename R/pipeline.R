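#' Read a pipeline run configuration
#'
#' Plain-text `key = value` configuration (one pair per line, `#` comments).
#' Values that parse as numbers become numeric; `true`/`false` become
#' logical.
#'
#' @param path configuration file path.
#' @return Named list of settings.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) abort(paste0("malformed config line: ", lines[bad][1]))
  vals <- lapply(kv, function(p) {
    v <- p[2]
    if (tolower(v) %in% c("true", "false")) return(as.logical(toupper(v)))
    num <- suppressWarnings(as.numeric(v))
    if (!is.na(num)) num else v
  })
  setNames(vals, vapply(kv, `[[`, "", 1))
}

.cfg <- function(config, key, default = NULL) {
  if (!is.null(config[[key]])) config[[key]] else default
}

#' Run the end-to-end asORF analysis
#'
#' Orchestrates the full analysis on one set of inputs: model probability
#' curves (existence and gain/loss), the antisense ORF scan, expected-count
#' reports and the comparison statistics, all written as TSV files together
#' with a run manifest (settings, package version, output checksums).
#'
#' Inputs come either from files (`genome`, `cds`, `transcripts` keys) or
#' from the synthetic generator (`mode = synthetic`, with `seed`, `gc`,
#' `n_cds`, ... keys mapped onto [synthetic_genome_spec()]).
#'
#' @param config named list (see [read_run_config()]) or path to a config
#'   file.
#' @param out_dir output directory; defaults to the `out_dir` config key.
#' @return Invisibly, a named list of output file paths.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- read_run_config(config)
  }
  out_dir <- out_dir %||% .cfg(config, "out_dir") %||%
    abort("no output directory: set `out_dir`")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(.cfg(config, "seed", 1))
  g <- .cfg(config, "gc", 0.4)
  k_min <- .cfg(config, "k_min", 10)
  k_max <- .cfg(config, "k_max", 300)
  min_len <- .cfg(config, "min_len", 30)
  min_overlap <- .cfg(config, "min_overlap", 1.0)
  mode <- .cfg(config, "mode", "files")

  if (identical(mode, "synthetic")) {
    spec <- synthetic_genome_spec(
      seed = seed, g = g,
      n_cds = as.integer(.cfg(config, "n_cds", 10)),
      cds_codons = c(as.integer(.cfg(config, "cds_codons_min", 100)),
                     as.integer(.cfg(config, "cds_codons_max", 200))),
      intergenic_nt = c(as.integer(.cfg(config, "intergenic_min", 200)),
                        as.integer(.cfg(config, "intergenic_max", 400))),
      planted = NULL
    )
    gen <- generate_genome(spec)
    genome <- gen$genome; cds <- gen$cds; transcripts <- gen$transcripts
  } else {
    genome <- .load_genome(.cfg(config, "genome") %||%
                             abort("config key `genome` is required"))
    cds <- .cfg(config, "cds") %||% abort("config key `cds` is required")
    transcripts <- .cfg(config, "transcripts") %||%
      abort("config key `transcripts` is required")
  }

  tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- list()
  model <- gc_model(g)
  mspec <- mutation_spec(rate = .cfg(config, "rate", 1.7e-10))

  paths$existence <- tsv(orf_probability_curve(model, k_min, k_max),
                         "existence_curves.tsv")
  paths$gain_loss <- tsv(gain_loss_curve(model, mspec, k_min, k_max),
                         "gain_loss_curves.tsv")

  scan <- scan_antisense_transcripts(genome, cds, transcripts,
                                     min_len = min_len,
                                     min_overlap = min_overlap,
                                     include_sub_orfs = TRUE)
  if (nrow(scan$orfs) > 0L) {
    paths$orfs <- tsv(scan$orfs, "asorf_records.tsv")
  }
  paths$summary <- tsv(scan$summary, "frame_summary.tsv")

  # overlap regions = transcript x opposite-strand CDS intersections
  cds_tbl <- .ranges_tbl(cds, "cds")
  tx_tbl <- .ranges_tbl(transcripts, "transcript")
  regions <- list()
  for (t in seq_len(nrow(tx_tbl))) {
    cand <- cds_tbl[cds_tbl$seqnames == tx_tbl$seqnames[t] &
                      cds_tbl$strand != tx_tbl$strand[t], , drop = FALSE]
    ov_s <- pmax(tx_tbl$start[t], cand$start)
    ov_e <- pmin(tx_tbl$end[t], cand$end)
    keep <- which(ov_e > ov_s)
    for (i in keep) {
      seq <- substr(as.character(genome[[tx_tbl$seqnames[t]]]),
                    ov_s[i] + 1L, ov_e[i])
      regions[[length(regions) + 1L]] <- tibble(
        region_id = paste0(tx_tbl$id[t], ":", cand$id[i]),
        length = ov_e[i] - ov_s[i],
        gc = gc_content(seq)
      )
    }
  }
  if (length(regions) > 0L) {
    reg <- bind_rows(regions)
    expected <- expected_orf_count(reg, model = NULL, k_min = max(10, min_len / 3))
    observed <- scan$summary |>
      select("frame", n_observed = "n", n_observed_with_sub = "n_with_sub")
    paths$expected <- tsv(observed_vs_expected(observed, expected),
                          "expected_observed.tsv")
    counts <- setNames(scan$summary$n_with_sub, scan$summary$frame)
    loci <- setNames(expected$n_loci_total[match(scan$summary$frame,
                                                 expected$frame)],
                     scan$summary$frame)
    if (all(loci > 0) && sum(counts) > 0) {
      paths$stats <- tsv(frame_enrichment_test(counts, loci),
                         "frame_enrichment.tsv")
    }
  }

  manifest <- tibble(
    key = c("asorf_version", "seed",
            paste0("config.", names(config)),
            paste0("md5.", basename(unlist(paths)))),
    value = c(as.character(packageVersion("asorf")), as.character(seed),
              vapply(config, function(v) paste(format(v), collapse = ","), ""),
              unname(tools::md5sum(unlist(paths))))
  )
  paths$manifest <- tsv(manifest, "manifest.tsv")
  inform(paste0("pipeline complete: ", length(paths), " outputs in ", out_dir))
  invisible(paths)
}
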