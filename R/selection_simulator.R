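#' Ground truth for a simulated selection
#'
#' Declares which cycle-3 building blocks truly bind the immobilised target
#' (the sulfonamide positive-control analogue) and which bind the bead matrix
#' itself (the imidazole analogue), together with the per-round retention
#' probabilities.
#'
#' @param target_binder_block_ids cycle-3 block ids with true target affinity.
#' @param bead_binder_block_ids cycle-3 block ids retained by the bare beads.
#' @param p_target per-round retention probability of target binders.
#' @param p_bead per-round bead-retention probability.
#' @param p_background per-round nonspecific retention probability.
#' @return an object of class `ground_truth`.
#' @export
ground_truth <- function(target_binder_block_ids, bead_binder_block_ids = character(),
                         p_target = 0.3, p_bead = 0.5, p_background = 0.005) {
  for (p in c(p_target, p_bead, p_background))
    if (p <= 0 || p > 1) stop("retention probabilities must lie in (0, 1]")
  if (p_target < p_background) stop("p_target must be at least p_background")
  structure(list(target_binder_block_ids = as.character(target_binder_block_ids),
                 bead_binder_block_ids = as.character(bead_binder_block_ids),
                 p_target = p_target, p_bead = p_bead, p_background = p_background),
            class = "ground_truth")
}

#' Selection / sequencing simulation parameters
#'
#' @param copies_per_member starting copies of every library member (the
#'   screening protocol used roughly one million copies per compound).
#' @param rounds number of selection rounds (default 2).
#' @param preclear incubate with a half portion of bare beads first and carry
#'   the supernatant into round 1, depleting bead binders.
#' @param preclear_bead_fraction fraction of the bead dose used for
#'   pre-clearing (default 0.5).
#' @param blocking_factor multiplier (< 1 to enable) applied to
#'   `p_background` to model blocking DNA in the incubation.
#' @param read_depth number of sequencing reads drawn after the final round.
#' @param substitution_error_rate i.i.d. per-base substitution probability.
#' @param seed integer seed controlling the whole simulation.
#' @return an object of class `selection_config`.
#' @export
selection_config <- function(copies_per_member = 1e6, rounds = 2L, preclear = FALSE,
                             preclear_bead_fraction = 0.5, blocking_factor = 1,
                             read_depth = 2e5, substitution_error_rate = 0.005,
                             seed = 1L) {
  if (rounds < 1) stop("rounds must be >= 1")
  if (read_depth < 0) stop("read_depth must be >= 0")
  if (substitution_error_rate < 0 || substitution_error_rate >= 0.25)
    stop("substitution_error_rate must lie in [0, 0.25)")
  if (preclear_bead_fraction < 0 || preclear_bead_fraction > 1)
    stop("preclear_bead_fraction must lie in [0, 1]")
  if (blocking_factor <= 0 || blocking_factor > 1)
    stop("blocking_factor must lie in (0, 1]")
  structure(list(copies_per_member = copies_per_member, rounds = as.integer(rounds),
                 preclear = isTRUE(preclear),
                 preclear_bead_fraction = preclear_bead_fraction,
                 blocking_factor = blocking_factor, read_depth = read_depth,
                 substitution_error_rate = substitution_error_rate,
                 seed = as.integer(seed)),
            class = "selection_config")
}

# Deterministic per-stage seed fan-out from one global seed.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

member_retention <- function(library, truth, cfg) {
  p <- rep(truth$p_background * cfg$blocking_factor, nrow(library))
  p[library$bb3_id %in% truth$bead_binder_block_ids] <- truth$p_bead
  p[library$bb3_id %in% truth$target_binder_block_ids] <- truth$p_target
  p
}

#' Simulate affinity selection of an encoded library
#'
#' Runs the binomial selection cascade: every member starts at
#' `copies_per_member` copies; optionally a pre-clearing pass against bare
#' beads removes `Binomial(copies, p_bead * preclear_bead_fraction)` copies
#' from bead binders; then each round retains
#' `Binomial(copies, p_i)` copies, where `p_i` is `p_target` for members
#' whose cycle-3 block is a target binder, `p_bead` for bead binders, and
#' `blocking_factor * p_background` otherwise. PCR is modelled as uniform
#' amplification (the multinomial read draw absorbs it).
#'
#' @param library a `del_library` data frame (see [enumerate_library()]).
#' @param truth a [ground_truth()].
#' @param cfg a [selection_config()].
#' @return the library with columns `initial_copies`, `retention_p` and
#'   `abundance` (surviving copies after the final round) appended; class
#'   `del_selection`.
#' @export
simulate_selection <- function(library, truth, cfg) {
  stopifnot(is.data.frame(library), inherits(truth, "ground_truth"),
            inherits(cfg, "selection_config"))
  set.seed(derive_seed(cfg$seed, "selection"))
  n <- nrow(library)
  copies <- rep(round(cfg$copies_per_member), n)
  p <- member_retention(library, truth, cfg)
  if (cfg$preclear) {
    bead <- library$bb3_id %in% truth$bead_binder_block_ids
    if (any(bead)) {
      removed <- rbinom(sum(bead), copies[bead],
                        truth$p_bead * cfg$preclear_bead_fraction)
      copies[bead] <- copies[bead] - removed
    }
  }
  for (r in seq_len(cfg$rounds)) copies <- rbinom(n, copies, p)
  if (sum(copies) == 0)
    stop("no molecules survived the selection; increase copies_per_member or ",
         "retention probabilities")
  out <- library
  out$initial_copies <- round(cfg$copies_per_member)
  out$retention_p <- p
  out$abundance <- copies
  structure(out, class = c("del_selection", class(library)),
            truth = truth, config = cfg)
}

#' Draw sequencing reads from a selected pool
#'
#' Draws `read_depth` reads multinomially in proportion to post-selection
#' abundance, then applies i.i.d. per-base substitution errors to each
#' member's DNA tag. Base qualities are a constant placeholder.
#'
#' @param selected a `del_selection` (or any data frame with `tag` and
#'   `abundance` columns).
#' @param cfg the [selection_config()] (depth, error rate, seed).
#' @return character vector of reads, named `read1 ... readN`.
#' @export
generate_reads <- function(selected, cfg) {
  stopifnot(all(c("tag", "abundance") %in% names(selected)))
  if (sum(selected$abundance) <= 0) stop("total abundance must be positive")
  set.seed(derive_seed(cfg$seed, "reads"))
  depth <- round(cfg$read_depth)
  if (depth == 0) return(setNames(character(0), character(0)))
  counts <- as.vector(rmultinom(1, depth, selected$abundance))
  reads <- rep(selected$tag, counts)
  reads <- reads[sample.int(length(reads))]
  reads <- mutate_reads(reads, cfg$substitution_error_rate)
  setNames(reads, paste0("read", seq_along(reads)))
}

# Apply i.i.d. substitution errors; only reads drawing >= 1 error are edited.
mutate_reads <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  L <- nchar(reads)
  nerr <- rbinom(length(reads), L, rate)
  hit <- which(nerr > 0)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    pos <- sample.int(L[i], nerr[i])
    chars <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) chars[p] <- sample(setdiff(bases, chars[p]), 1)
    reads[i] <- paste(chars, collapse = "")
  }
  reads
}

#' FASTQ input and output
#'
#' Minimal plain-text FASTQ handling for simulated reads: four-line records
#' with a constant quality placeholder. `read_fastq()` validates record
#' structure and reports the first malformed record by number.
#'
#' @param reads named character vector of reads.
#' @param path file path.
#' @param quality quality character replicated across each read.
#' @return `read_fastq()` a named character vector of sequences; the writer
#'   returns `path` invisibly.
#' @export
write_fastq <- function(reads, path, quality = "I") {
  ids <- names(reads) %||% paste0("read", seq_along(reads))
  lines <- as.vector(rbind(paste0("@", ids), unname(reads), "+",
                           vapply(nchar(reads), function(n)
                             strrep(quality, n), character(1))))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) return(setNames(character(0), character(0)))
  if (length(lines) %% 4 != 0)
    stop("malformed FASTQ: ", length(lines), " lines is not a multiple of 4")
  rec <- matrix(lines, nrow = 4)
  bad <- which(!startsWith(rec[1, ], "@") | !startsWith(rec[3, ], "+") |
                 nchar(rec[2, ]) != nchar(rec[4, ]))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], " (lines ", (bad[1] - 1) * 4 + 1,
         "-", bad[1] * 4, ")")
  setNames(rec[2, ], sub("^@", "", sub(" .*", "", rec[1, ])))
}

#' Persist and reload simulation ground truth
#'
#' Writes a JSON sidecar with everything needed to score recovery: the truth
#' sets, all probabilities, the selection configuration and seed, plus a
#' schema version for forward compatibility.
#'
#' @param truth a [ground_truth()].
#' @param cfg a [selection_config()].
#' @param path JSON file path.
#' @return `read_truth()` a list with elements `truth` (class `ground_truth`),
#'   `config` (class `selection_config`) and `schema_version`.
#' @export
write_truth <- function(truth, cfg, path) {
  jsonlite::write_json(list(schema_version = 1L,
                            truth = unclass(truth), config = unclass(cfg)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("truth file not found: ", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  truth <- do.call(ground_truth, c(list(
    target_binder_block_ids = as.character(x$truth$target_binder_block_ids),
    bead_binder_block_ids = as.character(x$truth$bead_binder_block_ids)),
    x$truth[c("p_target", "p_bead", "p_background")]))
  cfg <- do.call(selection_config, x$config)
  list(truth = truth, config = cfg, schema_version = x$schema_version)
}
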