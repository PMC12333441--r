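dec_fixture <- function() {
  blocks <- demo_building_blocks()
  sets <- generate_codon_sets(toy_codon_config())
  lib <- enumerate_library(blocks, sets, structures = FALSE)
  list(blocks = blocks, sets = sets, lib = lib, schema = attr(lib, "schema"))
}

test_that("codon matching corrects exactly one substitution, never more", {
  set <- generate_codon_set(toy_codon_config())
  # exact matches
  m <- match_codon(set$codons, set)
  expect_identical(m$index, seq_along(set$codons))
  # every single mutant decodes back to its source, uniquely
  for (i in seq_along(set$codons)) {
    muts <- all_single_mutants(set$codons[i])
    mm <- match_codon(muts, set)
    expect_true(all(mm$index == i))
  }
  # a sequence at distance >= 2 from every codon (found by double mutation
  # and verified by brute-force distance scan) is rejected, not mis-assigned
  far <- NULL
  for (dbl in unlist(lapply(all_single_mutants(set$codons[1]), all_single_mutants))) {
    if (all(hamming_distance(rep(dbl, length(set$codons)), set$codons) >= 2)) {
      far <- dbl; break
    }
  }
  expect_false(is.null(far))
  m2 <- match_codon(far, set)
  expect_true(is.na(m2$index))
  expect_match(m2$reason, "too_many_errors|ambiguous")
  # wrong length
  m3 <- match_codon("AAA", set)
  expect_true(is.na(m3$index))
  expect_identical(m3$reason, "length")
})

test_that("decoder never cross-assigns any single mutant of any tag", {
  fx <- dec_fixture()
  truth_idx <- match(fx$lib$tag, fx$lib$tag)
  for (r in seq_len(min(nrow(fx$lib), 25))) {
    muts <- all_single_mutants(fx$lib$tag[r])
    dec <- decode_reads(muts, fx$schema, fx$sets)
    assigned <- !is.na(dec$i1)
    # every assigned mutant decodes to the original member's triple
    orig <- decode_reads(fx$lib$tag[r], fx$schema, fx$sets)
    expect_true(all(dec$i1[assigned] == orig$i1))
    expect_true(all(dec$i2[assigned] == orig$i2))
    expect_true(all(dec$i3[assigned] == orig$i3))
    # mutants inside codons are always recovered; only primer-region mutants
    # beyond the mismatch budget may drop
    expect_gte(sum(assigned), length(muts) - 3 * nchar(fx$schema$primer3))
  }
})

test_that("reads decode positionally with primer verification", {
  fx <- dec_fixture()
  tag <- fx$lib$tag[1]
  dec <- decode_reads(tag, fx$schema, fx$sets)
  expect_false(anyNA(dec$i1))
  # one substitution inside codon 2 still decodes
  mut <- tag
  pos <- fx$schema$headpiece_length + fx$schema$codon_length + 1
  substr(mut, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                   substr(tag, pos, pos))[1]
  dec2 <- decode_reads(mut, fx$schema, fx$sets)
  expect_identical(dec2[, 1:3], dec[, 1:3])
  # scrambled primer region fails the constant-region check
  scram <- paste0(substr(tag, 1, nchar(tag) - 10), "AAAAAAAAAA")
  if (substr(tag, nchar(tag) - 9, nchar(tag)) == "AAAAAAAAAA") skip("degenerate primer")
  dec3 <- decode_reads(scram, fx$schema, fx$sets)
  expect_true(is.na(dec3$i1))
  expect_identical(dec3$reason, "constant_region")
})

test_that("count table conserves reads and aggregates duplicates", {
  fx <- dec_fixture()
  reads <- rep(fx$lib$tag[5], 10)
  ct <- count_reads(reads, fx$schema, fx$sets, fx$blocks)
  expect_identical(nrow(ct), 1L)
  expect_identical(ct$count, 10L)
  expect_identical(ct$bb1_id, fx$lib$bb1_id[5])
  expect_identical(sum(attr(ct, "unassigned")), 0L)
  # empty input
  ct0 <- count_reads(character(0), fx$schema, fx$sets, fx$blocks)
  expect_identical(nrow(ct0), 0L)
  expect_identical(attr(ct0, "total_reads"), 0L)
})

test_that("error-free simulated reads are fully assigned and conserved", {
  fx <- dec_fixture()
  truth <- ground_truth("C3_sulfamoylbenzoic")
  cfg <- selection_config(copies_per_member = 1e4, read_depth = 10000,
                          substitution_error_rate = 0, seed = 31)
  sel <- simulate_selection(fx$lib, truth, cfg)
  ct <- count_reads(generate_reads(sel, cfg), fx$schema, fx$sets, fx$blocks)
  expect_identical(sum(ct$count), 10000L)
  expect_identical(sum(attr(ct, "unassigned")), 0L)
})

test_that("count conservation holds under sequencing errors", {
  fx <- dec_fixture()
  truth <- ground_truth("C3_sulfamoylbenzoic")
  cfg <- selection_config(copies_per_member = 1e4, read_depth = 5000,
                          substitution_error_rate = 0.02, seed = 32)
  sel <- simulate_selection(fx$lib, truth, cfg)
  reads <- generate_reads(sel, cfg)
  ct <- count_reads(reads, fx$schema, fx$sets, fx$blocks)
  expect_identical(sum(ct$count) + sum(attr(ct, "unassigned")), length(reads))
  expect_gt(sum(attr(ct, "unassigned")), 0)  # at this rate some reads must drop
})

test_that("enrichment report ranks the planted binder first with uniform cycles 1-2", {
  fx <- dec_fixture()
  truth <- ground_truth("C3_sulfamoylbenzoic")
  cfg <- selection_config(seed = 33, read_depth = 50000)
  sel <- simulate_selection(fx$lib, truth, cfg)
  ct <- count_reads(generate_reads(sel, cfg), fx$schema, fx$sets, fx$blocks)
  rep <- enrichment_report(ct, fx$blocks)
  expect_identical(rep$cycle3$id[1], "C3_sulfamoylbenzoic")
  expect_gt(cycle_uniformity_test(rep, 1)$p.value, 0.01)
  expect_gt(cycle_uniformity_test(rep, 2)$p.value, 0.01)
  # marginals each sum to the assigned total
  for (cy in 1:3) expect_identical(sum(rep[[paste0("cycle", cy)]]$count), sum(ct$count))
  expect_true(all(rep$cycle3$is_control == grepl("ctrl", rep$cycle3$id)))
})

test_that("uniform counts give flat marginals and unit baseline ratios", {
  fx <- dec_fixture()
  tab <- structure(data.frame(bb1_id = fx$lib$bb1_id, bb2_id = fx$lib$bb2_id,
                              bb3_id = fx$lib$bb3_id, count = 2L),
                   class = c("del_counts", "data.frame"))
  rep <- enrichment_report(tab, fx$blocks, baseline = tab)
  expect_true(all(rep$cycle1$count == rep$cycle1$count[1]))
  expect_true(all(abs(rep$cycle3$ratio - 1) < 1e-9))
  expect_error(enrichment_report(tab[0, ], fx$blocks), "empty")
})
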