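# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain-R brute force and hand atomic-mass sums.

# Brute-force hairpin search: explicit triple loop over (i, j, k).
brute_hairpin <- function(seq, min_stem, min_loop) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  for (k in min_stem:n) {
    for (i in seq_len(n)) {
      if (i + k - 1 > n) next
      for (j in seq_len(n)) {
        if (j < i + k + min_loop || j + k - 1 > n) next
        s1 <- x[i:(i + k - 1)]
        s2 <- x[j:(j + k - 1)]
        if (all(s2 == rev(unname(comp[s1])))) return(TRUE)
      }
    }
  }
  FALSE
}

# All 3L single-substitution mutants of a sequence.
all_single_mutants <- function(seq) {
  x <- strsplit(seq, "")[[1]]
  out <- character(0)
  for (p in seq_along(x)) {
    for (b in setdiff(c("A", "C", "G", "T"), x[p])) {
      y <- x; y[p] <- b
      out <- c(out, paste(y, collapse = ""))
    }
  }
  out
}

# Average molecular mass from a molecular formula string like "C3H7NO".
formula_mass <- function(formula) {
  masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06)
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  total <- 0
  for (t in toks) {
    el <- gsub("[0-9]", "", t)
    ct <- gsub("[A-Za-z]", "", t)
    total <- total + masses[[el]] * if (nzchar(ct)) as.integer(ct) else 1L
  }
  total
}

WATER_MASS <- formula_mass("H2O")        # 18.015
FMOC_LOSS_MASS <- formula_mass("C15H10O2")  # 222.239

# Open Babel average MW for a SMILES, via the toolkit directly (not through
# the package's descriptor surface).
ob_mw <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  ChemmineR::propOB(sdf)$MW
}

ob_inchi <- function(smiles) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(smiles))
  ChemmineR::propOB(sdf)$InChI
}

# RDKit (python) oracle: returns InChI of a SMILES, or NA if python/rdkit
# is unavailable.
rdkit_inchi <- function(smiles) {
  script <- sprintf(
    "from rdkit import Chem\nprint(Chem.MolToInchi(Chem.MolFromSmiles('%s')))", smiles)
  out <- tryCatch(
    suppressWarnings(system2("python", "-", input = script, stdout = TRUE, stderr = FALSE)),
    error = function(e) NA_character_)
  if (length(out) < 1 || is.na(out[1]) || !nzchar(out[1])) NA_character_ else out[length(out)]
}

toy_codon_config <- function(...) {
  codon_design_config(length = 6, min_distance = 3, gc_min = 0, gc_max = 1,
                      max_homopolymer = 6, n_required = 8, ...)
}
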