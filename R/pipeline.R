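#' Pipeline configuration
#'
#' Bundles everything the end-to-end run needs: codon design parameters, the
#' building-block table (path or data frame), tag schema, ground truth,
#' selection parameters, output directory and one global seed that is fanned
#' out deterministically to every stochastic stage (so stages rerun
#' standalone reproduce the pipeline's results).
#'
#' @param blocks building-block CSV path or data frame; `NULL` uses
#'   [demo_building_blocks()].
#' @param out_dir artifact directory (created if missing).
#' @param codon_config a [codon_design_config()].
#' @param truth a [ground_truth()]; `NULL` plants the demo sulfonamide
#'   target binder and imidazole bead binder.
#' @param selection a [selection_config()] (its seed is overridden by
#'   `seed`).
#' @param hp a [headpiece()].
#' @param structures build payload structures during enumeration.
#' @param seed global seed.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(blocks = NULL, out_dir = "delforge_run",
                            codon_config = codon_design_config(),
                            truth = NULL, selection = selection_config(),
                            hp = headpiece(), structures = TRUE, seed = 1L) {
  if (is.character(blocks) && !file.exists(blocks))
    stop("building-block file not found: ", blocks)
  structure(list(blocks = blocks, out_dir = out_dir, codon_config = codon_config,
                 truth = truth, selection = selection, hp = hp,
                 structures = isTRUE(structures), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Flat YAML keys mirror the constructor arguments; nested sections
#' `codon_config`, `selection` and `truth` are passed to the corresponding
#' constructors.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    blocks = y$blocks, out_dir = y$out_dir %||% "delforge_run",
    codon_config = do.call(codon_design_config, y$codon_config %||% list()),
    truth = if (!is.null(y$truth)) do.call(ground_truth, y$truth),
    selection = do.call(selection_config, y$selection %||% list()),
    structures = y$structures %||% TRUE, seed = y$seed %||% 1L)
}

#' Run the full DEL workflow
#'
#' Executes codon design, library enumeration, descriptor profiling,
#' selection simulation, read generation and decoding in sequence, writing
#' every artifact under `config$out_dir`: `codons.csv`, `library.csv`,
#' `descriptors.csv`, `summary.csv`, `reads.fastq`, `truth.json`,
#' `counts.csv`, `marginals.csv` and `report.json`. Outputs are pure
#' functions of (inputs, seed); rerunning with the same config reproduces
#' them byte for byte.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return (invisibly) a list with the in-memory stage results and artifact
#'   paths.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message("[delforge] ", ...)
  blocks <- config$blocks
  if (is.null(blocks)) blocks <- demo_building_blocks()
  else if (is.character(blocks)) blocks <- read_building_blocks(blocks)
  else validate_building_blocks(blocks)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(config$out_dir, f)

  say("designing codon sets (L = ", config$codon_config$length, ")")
  sets <- generate_codon_sets(config$codon_config)
  write_codon_csv(sets, path("codons.csv"))

  say("enumerating library (", library_size(sum(blocks$cycle == 1) - 2,
      sum(blocks$cycle == 2) - 2, sum(blocks$cycle == 3) - 2), " members)")
  lib <- enumerate_library(blocks, sets, config$hp, structures = config$structures)
  write_library(lib, path("library.csv"))
  schema <- attr(lib, "schema")

  desc <- NULL
  if (config$structures) {
    say("profiling descriptors")
    payload <- unique(lib$product[!lib$is_truncate])
    desc <- compute_descriptors(payload, payload)
    write.csv(desc, path("descriptors.csv"), row.names = FALSE)
    write.csv(summarize_properties(desc[, -1]), path("summary.csv"), row.names = FALSE)
  }

  truth <- config$truth
  if (is.null(truth)) {
    c3 <- blocks$id[blocks$cycle == 3]
    truth <- ground_truth(
      target_binder_block_ids = grep("sulfamoyl", c3, value = TRUE),
      bead_binder_block_ids = grep("imidazole", c3, value = TRUE))
  }
  cfg <- config$selection
  cfg$seed <- config$seed
  say("simulating selection (", cfg$rounds, " rounds, preclear = ", cfg$preclear, ")")
  sel <- simulate_selection(lib, truth, cfg)
  reads <- generate_reads(sel, cfg)
  write_fastq(reads, path("reads.fastq"))
  write_truth(truth, cfg, path("truth.json"))

  say("decoding ", length(reads), " reads")
  counts <- count_reads(reads, schema, sets, blocks)
  write.csv(as.data.frame(counts), path("counts.csv"), row.names = FALSE)
  report <- enrichment_report(counts, blocks)
  marg <- do.call(rbind, lapply(1:3, function(cy)
    cbind(cycle = cy, report[[cy]])))
  write.csv(marg, path("marginals.csv"), row.names = FALSE)

  top3 <- report$cycle3$id[1]
  jsonlite::write_json(list(
    seed = config$seed,
    n_members = nrow(lib),
    reads_total = attr(counts, "total_reads"),
    reads_assigned = sum(counts$count),
    unassigned = as.list(attr(counts, "unassigned")),
    top_block_per_cycle = lapply(report, function(m) m$id[1]),
    planted_target = truth$target_binder_block_ids,
    planted_bead_binder = truth$bead_binder_block_ids,
    target_recovered = top3 %in% c(truth$target_binder_block_ids,
                                   truth$bead_binder_block_ids)),
    path("report.json"), auto_unbox = TRUE, digits = NA)
  say("done; artifacts in ", config$out_dir)
  invisible(list(blocks = blocks, codon_sets = sets, library = lib,
                 descriptors = desc, selection = sel, counts = counts,
                 report = report, out_dir = config$out_dir))
}
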