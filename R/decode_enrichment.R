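#' Match an observed codon against a cycle's codon set
#'
#' Exact matches decode directly; otherwise, if exactly one set member lies
#' within Hamming distance 1 the read is corrected to it - unique correction
#' of any single substitution is guaranteed when the set was designed at
#' minimum pairwise distance 3. Anything else is unassigned with a reason.
#'
#' @param observed observed codon string(s).
#' @param set a `codon_set` or character vector of codons.
#' @return a data.frame with columns `index` (into the set, `NA` if
#'   unassigned) and `reason` (`""`, `"length"`, `"too_many_errors"` or
#'   `"ambiguous"`).
#' @export
match_codon <- function(observed, set) {
  codons <- if (inherits(set, "codon_set")) set$codons else set
  L <- nchar(codons[1])
  n <- length(observed)
  index <- rep(NA_integer_, n)
  reason <- character(n)
  bad_len <- nchar(observed) != L
  reason[bad_len] <- "length"
  exact <- match(observed, codons)
  index[!bad_len] <- exact[!bad_len]
  todo <- which(is.na(index) & !bad_len)
  for (i in todo) {
    d <- cpp_hamming_to_ref(codons, observed[i])
    near <- which(d <= 1)
    if (length(near) == 1) index[i] <- near
    else reason[i] <- if (length(near) > 1) "ambiguous" else "too_many_errors"
  }
  data.frame(index = index, reason = reason)
}

codon_offsets <- function(schema) {
  schema$headpiece_length + (seq_len(schema$n_cycles) - 1) * schema$codon_length + 1
}

#' Decode reads to building-block index triples
#'
#' Positionally slices each read according to the tag schema, verifies the 3'
#' constant region within the schema's mismatch budget, and matches each
#' codon via [match_codon()]. A read failing any step is unassigned, with the
#' reason tallied.
#'
#' @param reads character vector of read sequences.
#' @param schema the [tag_schema()] used at enumeration.
#' @param codon_sets list of the three cycle `codon_set`s.
#' @return data.frame with columns `i1`, `i2`, `i3` (codon indices, `NA` when
#'   unassigned) and `reason`.
#' @export
decode_reads <- function(reads, schema, codon_sets) {
  n <- length(reads)
  out <- data.frame(i1 = rep(NA_integer_, n), i2 = rep(NA_integer_, n),
                    i3 = rep(NA_integer_, n), reason = character(n))
  if (!n) return(out)
  full <- tag_length(schema)
  bad_len <- nchar(reads) != full
  out$reason[bad_len] <- "length"
  ok <- !bad_len
  if (nzchar(schema$primer3)) {
    pstart <- schema$headpiece_length + schema$n_cycles * schema$codon_length + 1
    obs_primer <- substr(reads, pstart, pstart + nchar(schema$primer3) - 1)
    mism <- rep(NA_integer_, n)
    mism[ok] <- cpp_hamming_to_ref(obs_primer[ok], schema$primer3)
    fail <- ok & mism > schema$max_primer_mismatch
    out$reason[fail] <- "constant_region"
    ok <- ok & !fail
  }
  offs <- codon_offsets(schema)
  for (cy in seq_len(schema$n_cycles)) {
    obs <- substr(reads, offs[cy], offs[cy] + schema$codon_length - 1)
    # match unique observed codons once, then map back to reads
    uobs <- unique(obs[ok])
    if (!length(uobs)) break
    m <- match_codon(uobs, codon_sets[[cy]])
    pick <- match(obs, uobs)
    idx <- m$index[pick]
    rsn <- m$reason[pick]
    fail <- ok & is.na(idx)
    out$reason[fail] <- paste0("codon", cy, "_", rsn[fail])
    out[[paste0("i", cy)]][ok] <- idx[ok]
    ok <- ok & !fail
  }
  out$i1[!ok] <- NA_integer_; out$i2[!ok] <- NA_integer_; out$i3[!ok] <- NA_integer_
  out
}

#' Count decoded reads per barcode combination
#'
#' Decodes every read and sums counts for unique (cycle 1, cycle 2, cycle 3)
#' barcode combinations, the selection readout statistic. Unassigned reads
#' are tallied by reason; counts plus unassigned always equal the number of
#' reads processed.
#'
#' @param reads a character vector of reads, or a FASTQ file path.
#' @param schema the [tag_schema()].
#' @param codon_sets list of the three cycle `codon_set`s.
#' @param blocks optional building-block table used to translate codon
#'   indices to block ids (otherwise ids are `cycle<c>_<index>`).
#' @return data.frame of class `del_counts` with columns `bb1_id`, `bb2_id`,
#'   `bb3_id`, `count`, ordered by decreasing count; attributes
#'   `total_reads`, `unassigned` (named tally by reason).
#' @export
count_reads <- function(reads, schema, codon_sets, blocks = NULL) {
  if (length(reads) == 1 && !grepl("^[ACGTN]+$", reads) && file.exists(reads))
    reads <- read_fastq(reads)
  codon_sets <- lapply(1:3, function(cy) {
    cods <- if (inherits(codon_sets[[cy]], "codon_set")) codon_sets[[cy]]$codons
            else codon_sets[[cy]]
    # only codons actually ligated to a well can occur in valid reads
    if (!is.null(blocks)) cods[seq_len(min(length(cods), sum(blocks$cycle == cy)))]
    else cods
  })
  dec <- decode_reads(unname(reads), schema, codon_sets)
  assigned <- !is.na(dec$i1) & !is.na(dec$i2) & !is.na(dec$i3)
  ids <- lapply(1:3, function(cy) {
    n_set <- length(if (inherits(codon_sets[[cy]], "codon_set"))
      codon_sets[[cy]]$codons else codon_sets[[cy]])
    if (is.null(blocks)) sprintf("cycle%d_%d", cy, seq_len(n_set))
    else {
      b <- blocks[blocks$cycle == cy, , drop = FALSE]
      c(b$id, sprintf("cycle%d_%d", cy, seq_len(max(0, n_set - nrow(b))) + nrow(b)))
    }
  })
  if (any(assigned)) {
    key <- data.frame(bb1_id = ids[[1]][dec$i1[assigned]],
                      bb2_id = ids[[2]][dec$i2[assigned]],
                      bb3_id = ids[[3]][dec$i3[assigned]])
    tab <- aggregate(list(count = rep(1L, nrow(key))), key, sum)
    tab <- tab[order(-tab$count, tab$bb1_id, tab$bb2_id, tab$bb3_id), ]
    rownames(tab) <- NULL
  } else {
    tab <- data.frame(bb1_id = character(), bb2_id = character(),
                      bb3_id = character(), count = integer())
  }
  unass <- table(dec$reason[!assigned])
  structure(tab, class = c("del_counts", "data.frame"),
            total_reads = length(reads),
            unassigned = setNames(as.integer(unass), names(unass)))
}

#' Per-cycle enrichment report
#'
#' Sums the count table into per-cycle marginal counts per building block,
#' ranks blocks within each cycle, and flags control (truncate) codons so
#' truncate-driven signal is visible. With a baseline count table (naive
#' library or no-target control) a normalized enrichment ratio
#' `(selected frequency) / (baseline frequency)` with pseudocount 1 is added;
#' raw summed counts remain the primary statistic.
#'
#' @param table a `del_counts` from [count_reads()].
#' @param blocks optional building-block table (to flag control roles).
#' @param baseline optional `del_counts` to normalise against.
#' @return list of class `del_enrichment` with one data.frame per cycle
#'   (`id`, `count`, `frequency`, `rank`, `is_control`, optionally `ratio`).
#' @export
enrichment_report <- function(table, blocks = NULL, baseline = NULL) {
  if (!nrow(table)) stop("empty count table")
  total <- sum(table$count)
  ctrl_ids <- if (!is.null(blocks))
    blocks$id[blocks$role %in% c("control_no_acid", "control_no_reagent")] else character()
  marg <- lapply(1:3, function(cy) {
    col <- paste0("bb", cy, "_id")
    m <- aggregate(list(count = table$count), list(id = table[[col]]), sum)
    if (!is.null(baseline) && nrow(baseline)) {
      b <- aggregate(list(bcount = baseline$count), list(id = baseline[[col]]), sum)
      m <- merge(m, b, all.x = TRUE)
      m$bcount[is.na(m$bcount)] <- 0L
      m$ratio <- ((m$count + 1) / (total + nrow(m))) /
        ((m$bcount + 1) / (sum(baseline$count) + nrow(m)))
      m$bcount <- NULL
    }
    m <- m[order(-m$count, m$id), ]
    m$frequency <- m$count / total
    m$rank <- seq_len(nrow(m))
    m$is_control <- m$id %in% ctrl_ids
    rownames(m) <- NULL
    m
  })
  names(marg) <- paste0("cycle", 1:3)
  structure(marg, class = "del_enrichment", total_assigned = total)
}

#' @export
print.del_enrichment <- function(x, n = 5, ...) {
  for (cy in names(x)) {
    cat(cy, "top blocks:\n")
    print(head(x[[cy]], n))
  }
  invisible(x)
}

#' Chi-square uniformity test of a cycle marginal
#'
#' Tests whether the marginal counts of one cycle are consistent with uniform
#' sampling across its blocks (the expectation for cycles carrying no
#' enriched building block).
#'
#' @param report a `del_enrichment` from [enrichment_report()].
#' @param cycle which cycle marginal to test (1-3).
#' @return an `htest` from [stats::chisq.test()].
#' @export
cycle_uniformity_test <- function(report, cycle) {
  m <- report[[paste0("cycle", cycle)]]
  chisq.test(m$count)
}
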