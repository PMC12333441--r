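test_that("hamming distance counts substitutions and enforces equal length", {
  expect_identical(hamming_distance("AAAA", "AAAA"), 0L)
  expect_identical(hamming_distance("AAAA", "AAAT"), 1L)
  expect_identical(hamming_distance("ACGT", "TGCA"), 4L)
  expect_identical(hamming_distance("ACGT", "TGCA"), hamming_distance("TGCA", "ACGT"))
  expect_error(hamming_distance("AAA", "AAAA"), "length")
  expect_error(hamming_distance("ACGX", "ACGT"), "non-ACGT")
})

test_that("reverse complement is a correct involution", {
  expect_identical(reverse_complement("AAAA"), "TTTT")
  expect_identical(reverse_complement("ACGT"), "ACGT")
  expect_identical(reverse_complement("GAT"), "ATC")
  expect_error(reverse_complement("ACGU"), "non-ACGT")
  set.seed(11)
  seqs <- vapply(1:50, function(i)
    paste(sample(c("A", "C", "G", "T"), 12, TRUE), collapse = ""), character(1))
  expect_identical(reverse_complement(reverse_complement(seqs)), seqs)
})

test_that("palindrome predicate matches the reverse-complement definition", {
  expect_true(is_palindrome("GAATTC"))
  expect_false(is_palindrome("AAAA"))
  expect_false(is_palindrome("ACGTA"))  # odd length can never be palindromic
  set.seed(12)
  odd <- vapply(1:30, function(i)
    paste(sample(c("A", "C", "G", "T"), 11, TRUE), collapse = ""), character(1))
  expect_false(any(is_palindrome(odd)))
})

test_that("hairpin predicate agrees with brute force, exhaustively and at random", {
  expect_true(has_hairpin("GGGGAAAACCCC", 4, 3))
  expect_false(has_hairpin("AAAAAAAAAAAA", 4, 3))
  expect_false(has_hairpin("ACGT", 4, 3))
  # exhaustive over all sequences of length 6-7 with a small stem geometry
  bases <- c("A", "C", "G", "T")
  for (L in 6:7) {
    seqs <- do.call(paste0, expand.grid(rep(list(bases), L)))
    got <- has_hairpin(seqs, min_stem = 2, min_loop = 1)
    want <- vapply(seqs, brute_hairpin, logical(1), min_stem = 2, min_loop = 1)
    expect_identical(got, unname(want))
  }
  # random length-12 at the default geometry
  set.seed(13)
  seqs <- vapply(1:1000, function(i) paste(sample(bases, 12, TRUE), collapse = ""),
                 character(1))
  got <- has_hairpin(seqs, 4, 3)
  want <- vapply(seqs, brute_hairpin, logical(1), min_stem = 4, min_loop = 3)
  expect_identical(got, unname(want))
})

test_that("config validation rejects impossible geometries", {
  expect_error(codon_design_config(length = 2, min_distance = 3), "impossible")
  expect_error(codon_design_config(gc_min = 0.8, gc_max = 0.2), "gc_min")
  expect_error(codon_design_config(min_distance = 0), "min_distance")
})

test_that("greedy generator reaches 200 codons per cycle at defaults, all constraints verified", {
  cfg <- codon_design_config()
  set <- generate_codon_set(cfg, cycle_id = 1)
  expect_length(set$codons, 200)
  expect_identical(unique(nchar(set$codons)), 12L)
  v <- validate_codon_set(set)
  expect_true(v$clean)
  expect_gte(v$min_distance, 3)
  expect_length(v$palindromes, 0)
  expect_length(v$hairpins, 0)
  # independent pairwise re-check on a subsample via the scalar distance
  idx <- seq(1, 200, by = 20)
  for (i in idx) for (j in idx) if (i < j)
    expect_gte(hamming_distance(set$codons[i], set$codons[j]), 3)
})

test_that("tiny candidate spaces: perfect length-3 code found, exhaustion reported", {
  cfg <- codon_design_config(length = 3, min_distance = 3, gc_min = 0, gc_max = 1,
                             max_homopolymer = 3, n_required = 4)
  set <- generate_codon_set(cfg)
  expect_length(set$codons, 4)
  expect_identical(validate_codon_set(set)$min_distance, 3L)
  cfg_big <- codon_design_config(length = 3, min_distance = 3, gc_min = 0, gc_max = 1,
                                 max_homopolymer = 3, n_required = 5)
  expect_error(generate_codon_set(cfg_big), "found only 4 of 5")
})

test_that("generation is deterministic and cycle sets are disjoint", {
  cfg <- toy_codon_config()
  expect_identical(generate_codon_set(cfg)$codons, generate_codon_set(cfg)$codons)
  cfgS <- toy_codon_config(candidate_order = "seeded_shuffle", seed = 7)
  expect_identical(generate_codon_set(cfgS)$codons, generate_codon_set(cfgS)$codons)
  expect_false(identical(generate_codon_set(cfg)$codons, generate_codon_set(cfgS)$codons))
  sets <- generate_codon_sets(cfg)
  all_codons <- unlist(lapply(sets, `[[`, "codons"))
  expect_false(anyDuplicated(all_codons) > 0)
  for (s in sets) expect_true(validate_codon_set(s)$clean)
})

test_that("cross-cycle distance flag separates cycles by min_distance", {
  cfg <- toy_codon_config()
  sets <- generate_codon_sets(cfg, cross_cycle = TRUE)
  pooled <- unlist(lapply(sets, `[[`, "codons"))
  expect_gte(validate_codon_set(pooled, cfg)$min_distance, cfg$min_distance)
})

test_that("single-error correction holds exhaustively for a generated set", {
  cfg <- toy_codon_config()
  set <- generate_codon_set(cfg)
  for (cod in set$codons) {
    for (mut in all_single_mutants(cod)) {
      d <- hamming_distance(rep(mut, length(set$codons)), set$codons)
      expect_identical(set$codons[d <= 1], cod)
    }
  }
})

test_that("validation reports violations in hand-built sets", {
  cfg <- codon_design_config(length = 4, min_distance = 3, gc_min = 0, gc_max = 1,
                             max_homopolymer = 4, n_required = 2)
  clean <- validate_codon_set(c("AAAA", "TTTT"), cfg)
  expect_true(clean$clean)
  expect_identical(clean$min_distance, 4L)
  dirty <- validate_codon_set(c("AAAA", "AAAT"), cfg)
  expect_false(dirty$clean)
  expect_identical(dirty$min_distance, 1L)
})

test_that("codon CSV and FASTA round-trip", {
  cfg <- toy_codon_config()
  sets <- generate_codon_sets(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_codon_csv(sets, csv)
  back <- read_codon_csv(csv)
  expect_identical(lapply(back, `[[`, "codons"), lapply(sets, `[[`, "codons"))
  fa <- withr::local_tempfile(fileext = ".fasta")
  write_codon_fasta(sets[[1]], fa)
  lines <- readLines(fa)
  expect_identical(lines[1], ">cycle1_1")
  expect_identical(lines[2], sets[[1]]$codons[1])
})
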