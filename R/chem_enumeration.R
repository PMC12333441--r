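#' Building-block tables
#'
#' A building-block table is a data frame with columns `id`, `cycle` (1-3),
#' `role` (`fmoc_amino_acid`, `capping_acid`, `control_no_acid`,
#' `control_no_reagent`) and `smiles` (empty for controls).
#' `read_building_blocks()` loads and validates such a CSV: ids must be
#' unique, every structure must parse, cycle-1/2 reagents must be N-Fmoc
#' amino acids (exactly one carboxylic acid and one Fmoc carbamate) and
#' cycle-3 reagents must carry at least one carboxylic acid.
#' `add_controls()` appends the two control pseudo-wells to each cycle.
#'
#' @param path CSV file path.
#' @param validate run the structure checks (parse + role invariants).
#' @param blocks a building-block data frame.
#' @return a validated building-block data frame.
#' @export
read_building_blocks <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("building-block file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "cycle", "role", "smiles")
  if (!all(need %in% names(df)))
    stop("building-block CSV must have columns ", paste(need, collapse = ", "))
  df$smiles[is.na(df$smiles)] <- ""
  if (validate) validate_building_blocks(df)
  df
}

#' @rdname read_building_blocks
#' @export
validate_building_blocks <- function(blocks) {
  roles <- c("fmoc_amino_acid", "capping_acid", "control_no_acid", "control_no_reagent")
  bad_role <- !blocks$role %in% roles
  if (any(bad_role))
    stop("unknown role ", sQuote(blocks$role[which(bad_role)[1]]),
         " at row ", which(bad_role)[1])
  dup <- duplicated(blocks$id)
  if (any(dup)) stop("duplicate building-block id ", sQuote(blocks$id[which(dup)[1]]),
                     " at row ", which(dup)[1])
  if (any(!blocks$cycle %in% 1:3)) stop("cycle must be 1, 2 or 3")
  for (r in seq_len(nrow(blocks))) {
    role <- blocks$role[r]
    if (role %in% c("control_no_acid", "control_no_reagent")) {
      if (nzchar(blocks$smiles[r]))
        stop("control block ", sQuote(blocks$id[r]), " must have empty structure (row ", r, ")")
      next
    }
    mol <- tryCatch(parse_smiles(blocks$smiles[r]),
                    error = function(e) stop("row ", r, " (", blocks$id[r], "): ",
                                             conditionMessage(e), call. = FALSE))
    n_acid <- nrow(find_carboxyl(mol))
    n_fmoc <- nrow(find_fmoc(mol))
    if (role == "fmoc_amino_acid" && (n_acid != 1 || n_fmoc != 1))
      stop("row ", r, " (", blocks$id[r], "): an N-Fmoc amino acid needs exactly one ",
           "carboxylic acid and one Fmoc carbamate (found ", n_acid, " / ", n_fmoc, ")")
    if (role == "capping_acid" && n_acid < 1)
      stop("row ", r, " (", blocks$id[r], "): a capping acid needs a carboxylic acid group")
  }
  invisible(blocks)
}

#' @rdname read_building_blocks
#' @export
add_controls <- function(blocks) {
  ctrl <- do.call(rbind, lapply(sort(unique(blocks$cycle)), function(cy)
    data.frame(id = sprintf("C%d_ctrl_%s", cy, c("noacid", "noreagent")),
               cycle = cy,
               role = c("control_no_acid", "control_no_reagent"),
               smiles = "")))
  rbind(blocks, ctrl)
}

#' Demonstration building-block set
#'
#' A small, fully synthetic well plate mirroring the library topology: five
#' N-Fmoc amino acids in each of cycles 1 and 2, and four capping acids in
#' cycle 3 - including 4-sulfamoylbenzoic acid (the canonical carbonic
#' anhydrase pharmacophore used as the in-built positive control) and
#' imidazole-4-carboxylic acid (the bead-binding false positive). With the
#' two control wells per cycle this gives a 7 x 7 x 6 = 294-member library.
#'
#' @param controls append the control wells (default `TRUE`).
#' @return a building-block data frame.
#' @export
demo_building_blocks <- function(controls = TRUE) {
  fmoc <- function(core) sprintf(core, "NC(=O)OCC1c2ccccc2-c2ccccc21")
  aa <- c(gly = fmoc("OC(=O)C%s"),
          ala = fmoc("CC(%s)C(=O)O"),
          val = fmoc("CC(C)C(%s)C(=O)O"),
          leu = fmoc("CC(C)CC(%s)C(=O)O"),
          phe = fmoc("OC(=O)C(Cc1ccccc1)%s"))
  caps <- c(benzoic = "OC(=O)c1ccccc1",
            acetic = "CC(=O)O",
            sulfamoylbenzoic = "NS(=O)(=O)c1ccc(C(=O)O)cc1",
            imidazole4carboxylic = "OC(=O)c1c[nH]cn1")
  blocks <- rbind(
    data.frame(id = paste0("C1_", names(aa)), cycle = 1, role = "fmoc_amino_acid", smiles = unname(aa)),
    data.frame(id = paste0("C2_", names(aa)), cycle = 2, role = "fmoc_amino_acid", smiles = unname(aa)),
    data.frame(id = paste0("C3_", names(caps)), cycle = 3, role = "capping_acid", smiles = unname(caps)))
  if (controls) blocks <- add_controls(blocks)
  validate_building_blocks(blocks)
}

#' The DNA headpiece
#'
#' The starting material for on-DNA synthesis: a short single-stranded DNA
#' oligo (14 nt by default) carrying the chemical attachment point. The
#' payload chemistry is modelled on a surrogate aminated linker rather than
#' the full DNA adduct; the DNA itself is tracked as a sequence string.
#'
#' @param dna_sequence the headpiece sequence (14 bases).
#' @param linker_amine SMILES of the surrogate linker presenting the single
#'   reactive amine.
#' @return an object of class `headpiece`.
#' @export
headpiece <- function(dna_sequence = "GAGTCATGACGTCA", linker_amine = "NCCOCC") {
  check_dna(dna_sequence, "dna_sequence")
  if (nchar(dna_sequence) != 14) stop("headpiece DNA must be 14 bases")
  mol <- parse_smiles(linker_amine, "linker_amine SMILES")
  if (!length(find_amines(mol))) stop("linker_amine must carry a free amine")
  structure(list(dna_sequence = dna_sequence, linker_amine = linker_amine),
            class = "headpiece")
}

#' Tag architecture
#'
#' Describes how a member's full DNA tag is assembled: headpiece, one codon
#' per cycle (no constant regions between codons by default), and a fixed
#' 3' primer region. The decoder slices reads positionally from this schema.
#'
#' @param codon_length codon length in bases.
#' @param headpiece_length length of the headpiece prefix.
#' @param n_cycles number of codons in the tag.
#' @param primer3 fixed 3' constant region appended after the last codon.
#' @param max_primer_mismatch mismatch budget when verifying the constant
#'   region during decoding.
#' @return an object of class `tag_schema`.
#' @export
tag_schema <- function(codon_length = 12L, headpiece_length = 14L, n_cycles = 3L,
                       primer3 = "AGCTTGCACT", max_primer_mismatch = 1L) {
  if (nzchar(primer3)) check_dna(primer3, "primer3")
  structure(list(codon_length = as.integer(codon_length),
                 headpiece_length = as.integer(headpiece_length),
                 n_cycles = as.integer(n_cycles), primer3 = primer3,
                 max_primer_mismatch = as.integer(max_primer_mismatch)),
            class = "tag_schema")
}

tag_length <- function(schema) {
  schema$headpiece_length + schema$n_cycles * schema$codon_length + nchar(schema$primer3)
}

#' Closed-form library size
#'
#' Number of encoded members of the three-cycle library including the control
#' wells: `(n1 + c) * (n2 + c) * (n3 + c)` for `c` controls per cycle.
#'
#' @param n1,n2,n3 number of chemical building blocks per cycle.
#' @param controls_per_cycle control wells per cycle (default 2).
#' @return integer (double if the product exceeds integer range).
#' @examples
#' library_size(142, 142, 147)  # the 3 million-member design
#' @export
library_size <- function(n1, n2, n3, controls_per_cycle = 2L) {
  for (v in list(n1, n2, n3, controls_per_cycle))
    if (length(v) != 1 || is.na(v) || v < 0) stop("all inputs must be non-negative scalars")
  (n1 + controls_per_cycle) * (n2 + controls_per_cycle) * (n3 + controls_per_cycle)
}

#' Enumerate the encoded combinatorial library
#'
#' Walks every (cycle 1, cycle 2, cycle 3) well combination and builds each
#' member's payload structure - couple, deprotect, couple, deprotect, cap,
#' with control wells carrying the unreacted intermediate forward - and its
#' full DNA tag (headpiece + codon1 + codon2 + codon3 + 3' primer). Codons
#' are assigned injectively within each cycle in block order. Intermediates
#' are cached per cycle-1 block and per (cycle-1, cycle-2) pair, so the
#' chemistry cost is n1 + n1*n2 + n1*n2*n3 transforms.
#'
#' @param blocks a validated building-block table (with controls included).
#' @param codon_sets list of three `codon_set` objects (see
#'   [generate_codon_sets()]).
#' @param hp a [headpiece()].
#' @param schema a [tag_schema()].
#' @param structures build payload SMILES (`TRUE`) or tags only (`FALSE`,
#'   fast: no chemistry, suitable for full-scale combinatorics).
#' @return a data.frame of class `del_library` with columns `bb1_id`,
#'   `bb2_id`, `bb3_id`, `product` (empty in tag-only mode), `tag`,
#'   `is_truncate`, and the schema/blocks attached as attributes.
#' @export
enumerate_library <- function(blocks, codon_sets, hp = headpiece(),
                              schema = NULL, structures = TRUE) {
  stopifnot(is.data.frame(blocks), length(codon_sets) == 3)
  by_cycle <- lapply(1:3, function(cy) blocks[blocks$cycle == cy, , drop = FALSE])
  if (any(vapply(by_cycle, nrow, integer(1)) == 0))
    return(empty_library(schema %||% tag_schema()))
  codons <- lapply(1:3, function(cy) {
    s <- codon_sets[[cy]]
    cods <- if (inherits(s, "codon_set")) s$codons else s
    n <- nrow(by_cycle[[cy]])
    if (n > length(cods))
      stop("cycle ", cy, " has ", n, " wells but only ", length(cods), " codons")
    if (anyDuplicated(cods[seq_len(n)])) stop("duplicate codon assignment in cycle ", cy)
    cods[seq_len(n)]
  })
  L <- unique(nchar(unlist(codons)))
  if (length(L) != 1) stop("all codons must share one length")
  if (is.null(schema)) schema <- tag_schema(codon_length = L)
  if (schema$codon_length != L) stop("schema codon_length does not match codon sets")
  if (schema$headpiece_length != nchar(hp$dna_sequence))
    stop("schema headpiece_length does not match headpiece")

  n <- vapply(by_cycle, nrow, integer(1))
  grid <- expand.grid(i3 = seq_len(n[3]), i2 = seq_len(n[2]), i1 = seq_len(n[1]))
  is_ctrl <- lapply(by_cycle, function(b) b$role %in% c("control_no_acid", "control_no_reagent"))
  tags <- paste0(hp$dna_sequence,
                 codons[[1]][grid$i1], codons[[2]][grid$i2], codons[[3]][grid$i3],
                 schema$primer3)
  if (anyDuplicated(tags)) stop("tags are not unique; check codon assignment")
  out <- data.frame(bb1_id = by_cycle[[1]]$id[grid$i1],
                    bb2_id = by_cycle[[2]]$id[grid$i2],
                    bb3_id = by_cycle[[3]]$id[grid$i3],
                    product = "",
                    tag = tags,
                    is_truncate = is_ctrl[[1]][grid$i1] | is_ctrl[[2]][grid$i2] |
                      is_ctrl[[3]][grid$i3])

  if (structures) {
    step <- function(substrate, block, cap = FALSE) {
      if (block$role %in% c("control_no_acid", "control_no_reagent"))
        return(apply_control(substrate, block))
      p <- tryCatch(couple_amide(substrate, block$smiles),
                    error = function(e) stop("chemistry failed on block ", sQuote(block$id),
                                             ": ", conditionMessage(e), call. = FALSE))
      if (cap) p else tryCatch(deprotect_fmoc(p),
                               error = function(e) stop("chemistry failed on block ",
                                                        sQuote(block$id), ": ",
                                                        conditionMessage(e), call. = FALSE))
    }
    int1 <- vapply(seq_len(n[1]), function(i)
      step(hp$linker_amine, by_cycle[[1]][i, ]), character(1))
    int2 <- matrix("", n[1], n[2])
    for (i in seq_len(n[1])) for (j in seq_len(n[2]))
      int2[i, j] <- step(int1[i], by_cycle[[2]][j, ])
    prod_cache <- array("", c(n[1], n[2], n[3]))
    for (i in seq_len(n[1])) for (j in seq_len(n[2])) for (k in seq_len(n[3]))
      prod_cache[i, j, k] <- step(int2[i, j], by_cycle[[3]][k, ], cap = TRUE)
    out$product <- prod_cache[cbind(grid$i1, grid$i2, grid$i3)]
  }
  structure(out, class = c("del_library", "data.frame"),
            schema = schema, headpiece = hp, blocks = blocks)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

empty_library <- function(schema) {
  structure(data.frame(bb1_id = character(), bb2_id = character(),
                       bb3_id = character(), product = character(),
                       tag = character(), is_truncate = logical()),
            class = c("del_library", "data.frame"), schema = schema)
}

#' Read and write enumerated libraries
#'
#' The library CSV holds columns `bb1_id`, `bb2_id`, `bb3_id`, `product`,
#' `tag`, `is_truncate`; the round trip is lossless. `write_tags_fasta()`
#' emits each member's tag as a FASTA record named `bb1|bb2|bb3`.
#'
#' @param members a `del_library` data frame.
#' @param path file path.
#' @return `read_library()` the data frame; writers return `path` invisibly.
#' @export
write_library <- function(members, path) {
  write.csv(as.data.frame(members)[, c("bb1_id", "bb2_id", "bb3_id", "product",
                                       "tag", "is_truncate")],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path) {
  if (!file.exists(path)) stop("library file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  df$product[is.na(df$product)] <- ""
  df$is_truncate <- as.logical(df$is_truncate)
  check_dna(df$tag, "tag")
  structure(df, class = c("del_library", "data.frame"))
}

#' @rdname write_library
#' @export
write_tags_fasta <- function(members, path) {
  ids <- paste(members$bb1_id, members$bb2_id, members$bb3_id, sep = "|")
  writeLines(as.vector(rbind(paste0(">", ids), members$tag)), path)
  invisible(path)
}
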