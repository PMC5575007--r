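#' Assemble a cohort run configuration
#'
#' Bundles and validates every parameter of an end-to-end run: the motif
#' scan, the optional seed-search stage (run when target mRNAs are given)
#' and the optional architecture stage (run when structures are given).
#' The configuration is echoed into every output bundle for provenance.
#'
#' @param fasta Path to the cohort FASTA (sRNAs).
#' @param out_dir Output directory (created if needed).
#' @param n_arn_min,window_nt,max_nf,max_gaps Motif-scan parameters, see
#'   [pattern_params()].
#' @param mrna_fasta Optional FASTA of target mRNA (windows) for the seed
#'   stage.
#' @param structures Optional dot-bracket file for the architecture stage.
#' @param allow_wobble Seed stage: count G:U pairs.
#' @param min_u_run,polyU_window Architecture stage: poly(U) tail
#'   definition, see [polyU_distance()].
#' @param spacing_band Architecture stage: bipartite spacing band.
#' @param write_bed Also write a BED version of the region report.
#' @return A `run_config` object.
#' @export
run_config <- function(fasta, out_dir, n_arn_min = 4L, window_nt = 20L,
                       max_nf = 2L, max_gaps = 2L, mrna_fasta = NULL,
                       structures = NULL, allow_wobble = FALSE,
                       min_u_run = 4L, polyU_window = 15L,
                       spacing_band = c(40L, 80L), write_bed = TRUE) {
  cfg <- list(fasta = fasta, out_dir = out_dir,
              params = pattern_params(n_arn_min, max_nf, max_gaps, window_nt),
              mrna_fasta = mrna_fasta, structures = structures,
              allow_wobble = isTRUE(allow_wobble),
              min_u_run = as.integer(min_u_run),
              polyU_window = as.integer(polyU_window),
              spacing_band = as.integer(spacing_band),
              write_bed = isTRUE(write_bed))
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()] (`fasta`, `out_dir`,
#' `n_arn_min`, `window_nt`, `max_nonfunctional`, `max_gaps`,
#' `mrna_fasta`, `structures`, `allow_wobble`, `min_u_run`,
#' `polyU_window`, `spacing_band`, `write_bed`).
#'
#' @param path Path to the YAML file.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(fasta = y$fasta, out_dir = y$out_dir,
             n_arn_min = y$n_arn_min %||% 4L,
             window_nt = y$window_nt %||% 20L,
             max_nf = y$max_nonfunctional %||% 2L,
             max_gaps = y$max_gaps %||% 2L,
             mrna_fasta = y$mrna_fasta, structures = y$structures,
             allow_wobble = y$allow_wobble %||% FALSE,
             min_u_run = y$min_u_run %||% 4L,
             polyU_window = y$polyU_window %||% 15L,
             spacing_band = unlist(y$spacing_band) %||% c(40L, 80L),
             write_bed = y$write_bed %||% TRUE)
}

#' Run the cohort pipeline: scan, optional seeds, optional architecture
#'
#' Scans every sequence in the cohort FASTA with the configured refined
#' pattern, merges matches into regions, and writes a report bundle to
#' `out_dir`: `regions.tsv` (and `regions.bed`), `per_sequence.tsv`, a
#' machine-readable `summary.json` (schema version, full parameter echo,
#' regions-per-sequence histogram over bins 0,1,2,3,4,5+), and `run.log`.
#' If target mRNAs are configured, all sRNA x mRNA seed searches are run
#' and written to `seeds.tsv`; if structures are configured, per-region
#' structural context and poly(U) distances go to `architecture.tsv`.
#' Reruns of the same configuration produce byte-identical bundles.
#'
#' @param config A [run_config()] object.
#' @return Invisibly, a list with the `arn_scan` object, stage tables and
#'   output paths.
#' @export
run_cohort <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- "scan"
  result <- tryCatch({
    seqs <- read_fasta(config$fasta)
    scan <- scan_set(seqs, config$params)
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(regions = file.path(config$out_dir, "regions.tsv"),
                  per_seq = file.path(config$out_dir, "per_sequence.tsv"),
                  summary = file.path(config$out_dir, "summary.json"),
                  log = file.path(config$out_dir, "run.log"))
    write_regions(scan$regions, paths$regions, "tsv")
    if (config$write_bed) {
      paths$bed <- file.path(config$out_dir, "regions.bed")
      write_regions(scan$regions, paths$bed, "bed")
    }
    utils::write.table(scan$per_seq, paths$per_seq, sep = "\t",
                       quote = FALSE, row.names = FALSE)

    seeds_tab <- NULL
    if (!is.null(config$mrna_fasta)) {
      stage <- "seeds"
      mrnas <- read_fasta(config$mrna_fasta)
      seeds_tab <- do.call(rbind, unlist(lapply(seqs, function(s)
        lapply(mrnas, function(m)
          as.data.frame(find_seeds(s, m,
                                   allow_wobble = config$allow_wobble)))),
        recursive = FALSE))
      rownames(seeds_tab) <- NULL
      paths$seeds <- file.path(config$out_dir, "seeds.tsv")
      utils::write.table(seeds_tab, paths$seeds, sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }

    arch_tab <- NULL
    if (!is.null(config$structures)) {
      stage <- "architecture"
      structs <- read_dotbracket(config$structures)
      rows <- list()
      for (id in names(structs)) {
        if (!id %in% names(seqs)) next
        regs <- merge_matches(scan$matches[[id]])
        for (i in seq_len(nrow(regs))) {
          ctx <- motif_context(regs[i, , drop = FALSE], structs[[id]])
          du <- polyU_distance(seqs[[id]], regs[i, , drop = FALSE],
                               min_u_run = config$min_u_run,
                               search_window = config$polyU_window)
          rows[[length(rows) + 1L]] <- data.frame(
            seq_id = id, start = regs$start[i], end = regs$end[i],
            context = ctx$context,
            unpaired_fraction = round(ctx$unpaired_fraction, 3),
            polyU_distance = du, stringsAsFactors = FALSE)
        }
      }
      arch_tab <- if (length(rows))
        do.call(rbind, c(rows, list(make.row.names = FALSE))) else NULL
      paths$architecture <- file.path(config$out_dir, "architecture.tsv")
      utils::write.table(
        arch_tab %||% data.frame(seq_id = character(0)),
        paths$architecture, sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "summary"
    summary_obj <- list(
      schema_version = "1.0",
      package_version = as.character(utils::packageVersion("arnscan")),
      parameters = c(unclass(config$params),
                     list(allow_wobble = config$allow_wobble,
                          min_u_run = config$min_u_run,
                          polyU_window = config$polyU_window,
                          spacing_band = config$spacing_band)),
      n_sequences = nrow(scan$per_seq),
      n_regions = nrow(scan$regions),
      histogram = as.list(scan$histogram))
    jsonlite::write_json(summary_obj, paths$summary, auto_unbox = TRUE,
                         pretty = TRUE)
    writeLines(c(
      paste0("arnscan ", utils::packageVersion("arnscan")),
      paste0("R ", getRversion()),
      paste0("fasta: ", config$fasta),
      paste0("parameters: n_arn_min=", config$params$n_arn_min,
             " window_nt=", config$params$window_nt,
             " max_nf=", config$params$max_nf,
             " max_gaps=", config$params$max_gaps),
      paste0("sequences: ", nrow(scan$per_seq)),
      paste0("regions: ", nrow(scan$regions))), paths$log)
    list(scan = scan, seeds = seeds_tab, architecture = arch_tab,
         paths = paths, config = config)
  }, error = function(e) {
    stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(result)
}
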