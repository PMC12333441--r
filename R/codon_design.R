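#' DNA sequence utilities for codon design
#'
#' `hamming_distance()` counts positions at which two equal-length DNA strings
#' differ; `reverse_complement()` returns the reversed Watson-Crick complement;
#' `is_palindrome()` tests whether a sequence equals its own reverse complement
#' (only possible for even lengths); `has_hairpin()` tests for an intramolecular
#' stem-loop: two substrings of length `min_stem` that are reverse complements
#' of one another, separated by at least `min_loop` bases.
#'
#' @param a,b,seq character vectors of DNA sequences over `A`, `C`, `G`, `T`.
#' @param min_stem minimum paired stem length in bases (>= 2).
#' @param min_loop minimum unpaired loop length in bases (>= 0).
#' @return `hamming_distance()` an integer vector; `reverse_complement()` a
#'   character vector; `is_palindrome()` and `has_hairpin()` logical vectors.
#' @examples
#' hamming_distance("ACGT", "TGCA")
#' reverse_complement("GAT")
#' is_palindrome("GAATTC")
#' has_hairpin("GGGGAAAACCCC", min_stem = 4, min_loop = 3)
#' @name dna-utils
NULL

check_dna <- function(x, arg = deparse(substitute(x))) {
  if (!is.character(x) || anyNA(x)) stop(arg, " must be a character vector without NA")
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    stop("non-ACGT character in ", arg, ": ", sQuote(x[which(bad)[1]]))
  }
  invisible(x)
}

#' @rdname dna-utils
#' @export
hamming_distance <- function(a, b) {
  check_dna(a, "a"); check_dna(b, "b")
  if (length(a) != length(b)) {
    if (length(a) == 1L) a <- rep(a, length(b))
    else if (length(b) == 1L) b <- rep(b, length(a))
    else stop("a and b must have the same length")
  }
  if (any(nchar(a) != nchar(b))) stop("sequences must have equal length")
  cpp_hamming_pairs(a, b)
}

#' @rdname dna-utils
#' @export
reverse_complement <- function(seq) {
  check_dna(seq, "seq")
  comp <- chartr("ACGT", "TGCA", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1))
}

#' @rdname dna-utils
#' @export
is_palindrome <- function(seq) {
  check_dna(seq, "seq")
  seq == reverse_complement(seq)
}

#' @rdname dna-utils
#' @export
has_hairpin <- function(seq, min_stem = 4L, min_loop = 3L) {
  check_dna(seq, "seq")
  if (min_stem < 2) stop("min_stem must be >= 2")
  if (min_loop < 0) stop("min_loop must be >= 0")
  cpp_has_hairpin(seq, as.integer(min_stem), as.integer(min_loop))
}

#' Configuration for per-cycle DNA codon design
#'
#' Collects the constraints under which per-cycle codon (barcode) sets are
#' generated: codon length, minimum pairwise Hamming distance (3 by default,
#' which permits unique correction of any single substitution), GC-content
#' window, maximum homopolymer run, hairpin geometry, and the number of codons
#' required per cycle (200 by default). Set `gc_min = 0`, `gc_max = 1` and
#' `max_homopolymer = length` to disable the composition filters and retain
#' only the distance/palindrome/hairpin constraints.
#'
#' @param length codon length in bases.
#' @param min_distance minimum pairwise Hamming distance within a cycle set.
#' @param gc_min,gc_max allowed GC fraction range.
#' @param max_homopolymer longest allowed single-base run.
#' @param hairpin_min_stem,hairpin_min_loop hairpin stem/loop geometry passed
#'   to [has_hairpin()].
#' @param n_required codons required per cycle.
#' @param candidate_order `"lexicographic"` scans all `4^length` candidates in
#'   lexicographic order (a fully deterministic lexicode); `"seeded_shuffle"`
#'   scans a seeded random permutation instead.
#' @param seed integer seed used only for `candidate_order = "seeded_shuffle"`.
#' @return an object of class `codon_design_config`.
#' @export
codon_design_config <- function(length = 12L, min_distance = 3L,
                                gc_min = 0.25, gc_max = 0.75,
                                max_homopolymer = 3L,
                                hairpin_min_stem = 4L, hairpin_min_loop = 3L,
                                n_required = 200L,
                                candidate_order = c("lexicographic", "seeded_shuffle"),
                                seed = 1L) {
  candidate_order <- match.arg(candidate_order)
  length <- as.integer(length); min_distance <- as.integer(min_distance)
  if (min_distance < 1) stop("min_distance must be >= 1")
  if (length < min_distance)
    stop("codon length (", length, ") must be >= min_distance (", min_distance,
         "): distance ", min_distance, " is impossible at length ", length)
  if (gc_min < 0 || gc_max > 1 || gc_min > gc_max)
    stop("need 0 <= gc_min <= gc_max <= 1")
  if (max_homopolymer < 1) stop("max_homopolymer must be >= 1")
  if (hairpin_min_stem < 2) stop("hairpin_min_stem must be >= 2")
  if (n_required < 1) stop("n_required must be >= 1")
  if (length > 13L) stop("codon lengths above 13 are not supported by the exhaustive scan")
  structure(list(length = length, min_distance = min_distance,
                 gc_min = gc_min, gc_max = gc_max,
                 max_homopolymer = as.integer(max_homopolymer),
                 hairpin_min_stem = as.integer(hairpin_min_stem),
                 hairpin_min_loop = as.integer(hairpin_min_loop),
                 n_required = as.integer(n_required),
                 candidate_order = candidate_order, seed = as.integer(seed)),
            class = "codon_design_config")
}

#' @export
print.codon_design_config <- function(x, ...) {
  cat("codon design config: L =", x$length, " d >=", x$min_distance,
      " GC [", x$gc_min, ",", x$gc_max, "] homopolymer <=", x$max_homopolymer,
      "\n  hairpin stem >=", x$hairpin_min_stem, "loop >=", x$hairpin_min_loop,
      " n =", x$n_required, " order =", x$candidate_order, "\n")
  invisible(x)
}

#' Generate a per-cycle codon set by greedy accretion
#'
#' Scans candidate sequences in the configured order and accepts a candidate
#' iff it passes the GC / homopolymer / palindrome / hairpin filters and keeps
#' Hamming distance >= `min_distance` to every previously accepted codon,
#' stopping once `n_required` codons are found. The result is deterministic
#' given the configuration (and seed, for shuffled order).
#'
#' @param config a [codon_design_config()].
#' @param cycle_id synthesis cycle the set encodes (1-3).
#' @param exclude codons already assigned to other cycles; candidates must keep
#'   Hamming distance >= `exclude_min_distance` from them.
#' @param exclude_min_distance 1 (default) merely forbids reuse of an excluded
#'   codon; set to `config$min_distance` to enforce cross-cycle separation.
#' @return an object of class `codon_set`: list with `cycle_id`, `codons`
#'   (character vector) and `config`.
#' @seealso [validate_codon_set()], [generate_codon_sets()]
#' @export
generate_codon_set <- function(config, cycle_id = 1L, exclude = character(),
                               exclude_min_distance = 1L) {
  stopifnot(inherits(config, "codon_design_config"))
  if (length(exclude)) check_dna(exclude, "exclude")
  order <- NULL
  if (config$candidate_order == "seeded_shuffle") {
    total <- 4^config$length
    order <- withr_seed(config$seed, sample.int(total))
  }
  codons <- cpp_generate_codons(config$length, config$min_distance,
                                config$gc_min, config$gc_max,
                                config$max_homopolymer,
                                config$hairpin_min_stem, config$hairpin_min_loop,
                                config$n_required, order,
                                as.character(exclude),
                                as.integer(exclude_min_distance))
  if (length(codons) < config$n_required)
    stop("candidate space exhausted: found only ", length(codons), " of ",
         config$n_required, " codons at length ", config$length,
         " and distance ", config$min_distance)
  structure(list(cycle_id = as.integer(cycle_id), codons = codons, config = config),
            class = "codon_set")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' @export
print.codon_set <- function(x, ...) {
  cat("codon set, cycle", x$cycle_id, ":", length(x$codons), "codons of length",
      x$config$length, "\n  first:", paste(head(x$codons, 3), collapse = " "), "...\n")
  invisible(x)
}

#' Generate codon sets for all synthesis cycles
#'
#' Runs [generate_codon_set()] once per cycle. Later cycles exclude the exact
#' sequences already used (so the three sets are disjoint); with
#' `cross_cycle = TRUE` the full `min_distance` separation is enforced across
#' cycles as well.
#'
#' @inheritParams generate_codon_set
#' @param n_cycles number of synthesis cycles.
#' @param cross_cycle enforce `min_distance` between cycles, not just within.
#' @return a list of `codon_set`, one per cycle.
#' @export
generate_codon_sets <- function(config, n_cycles = 3L, cross_cycle = FALSE) {
  sets <- vector("list", n_cycles)
  used <- character()
  for (cyc in seq_len(n_cycles)) {
    sets[[cyc]] <- generate_codon_set(config, cycle_id = cyc, exclude = used,
                                      exclude_min_distance =
                                        if (cross_cycle) config$min_distance else 1L)
    used <- c(used, sets[[cyc]]$codons)
  }
  sets
}

#' Validate a codon set against its design constraints
#'
#' Exhaustively recomputes the minimum pairwise Hamming distance over all
#' codon pairs and re-applies the alphabet, GC, homopolymer, palindrome and
#' hairpin predicates, reporting violations rather than erroring. A set
#' produced by [generate_codon_set()] always validates clean.
#'
#' @param set a `codon_set` (or plain character vector plus `config`).
#' @param config used when `set` is a bare character vector.
#' @return a list of class `codon_validation` with elements `n`,
#'   `min_distance`, `gc_range`, `palindromes`, `hairpins`, `homopolymer`,
#'   `gc_violations`, `duplicated`, and logical `clean`.
#' @export
validate_codon_set <- function(set, config = NULL) {
  if (inherits(set, "codon_set")) { config <- set$config; codons <- set$codons }
  else codons <- set
  if (is.null(config)) stop("config required when validating a bare codon vector")
  check_dna(codons, "codons")
  gc <- vapply(strsplit(codons, "", fixed = TRUE),
               function(x) mean(x %in% c("G", "C")), numeric(1))
  runs <- vapply(strsplit(codons, "", fixed = TRUE),
                 function(x) max(rle(x)$lengths), numeric(1))
  res <- list(
    n = length(codons),
    min_distance = if (length(codons) >= 2) cpp_min_pairwise_distance(codons) else NA_integer_,
    gc_range = range(gc),
    gc_violations = which(gc < config$gc_min - 1e-9 | gc > config$gc_max + 1e-9),
    homopolymer = which(runs > config$max_homopolymer),
    palindromes = which(is_palindrome(codons)),
    hairpins = which(has_hairpin(codons, config$hairpin_min_stem, config$hairpin_min_loop)),
    duplicated = which(duplicated(codons)),
    wrong_length = which(nchar(codons) != config$length)
  )
  res$clean <- (is.na(res$min_distance) || res$min_distance >= config$min_distance) &&
    !length(res$gc_violations) && !length(res$homopolymer) &&
    !length(res$palindromes) && !length(res$hairpins) &&
    !length(res$duplicated) && !length(res$wrong_length)
  structure(res, class = "codon_validation")
}

#' @export
print.codon_validation <- function(x, ...) {
  cat("codon set validation: n =", x$n, " min pairwise distance =", x$min_distance,
      "\n  GC range [", round(x$gc_range[1], 3), ",", round(x$gc_range[2], 3), "]",
      " palindromes:", length(x$palindromes), " hairpins:", length(x$hairpins),
      " status:", if (x$clean) "clean" else "VIOLATIONS", "\n")
  invisible(x)
}

#' Read and write codon sets
#'
#' Codon sets are serialised as CSV with columns `cycle_id`, `codon_index`,
#' `sequence`, or as FASTA with record ids `cycle{c}_{idx}`.
#'
#' @param sets a list of `codon_set` objects (or a single one).
#' @param path output/input file path.
#' @return `read_codon_csv()` returns a list of `codon_set` objects (with a
#'   minimal reconstructed config); the writers return `path` invisibly.
#' @name codon-io
NULL

as_codon_set_list <- function(sets) {
  if (inherits(sets, "codon_set")) list(sets) else sets
}

#' @rdname codon-io
#' @export
write_codon_csv <- function(sets, path) {
  sets <- as_codon_set_list(sets)
  df <- do.call(rbind, lapply(sets, function(s)
    data.frame(cycle_id = s$cycle_id, codon_index = seq_along(s$codons),
               sequence = s$codons)))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname codon-io
#' @export
write_codon_fasta <- function(sets, path) {
  sets <- as_codon_set_list(sets)
  lines <- unlist(lapply(sets, function(s)
    rbind(sprintf(">cycle%d_%d", s$cycle_id, seq_along(s$codons)), s$codons)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname codon-io
#' @export
read_codon_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("cycle_id", "codon_index", "sequence")
  if (!all(need %in% names(df))) stop("codon CSV must have columns ", paste(need, collapse = ", "))
  check_dna(df$sequence, "sequence")
  unname(lapply(split(df, df$cycle_id), function(d) {
    d <- d[order(d$codon_index), ]
    L <- unique(nchar(d$sequence))
    if (length(L) != 1) stop("mixed codon lengths in cycle ", d$cycle_id[1])
    cfg <- codon_design_config(length = L, n_required = nrow(d),
                               gc_min = 0, gc_max = 1, max_homopolymer = L)
    structure(list(cycle_id = d$cycle_id[1], codons = d$sequence, config = cfg),
              class = "codon_set")
  }))
}
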