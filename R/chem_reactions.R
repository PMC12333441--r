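#' Amide coupling of a free amine with a carboxylic acid
#'
#' Forms the amide bond between the (single) reactive primary or secondary
#' amine of `amine_substrate` and the carboxylic acid group of `acid`, with
#' loss of water, mirroring the on-DNA DMTMM-mediated coupling used at every
#' library cycle. When the substrate carries more than one eligible amine the
#' alpha-amino-acid pattern (N-C-C(=O)) is preferred and a warning is issued;
#' when the acid carries more than one carboxyl the first in canonical order
#' is acylated, with a warning.
#'
#' @param amine_substrate SMILES of the amine-bearing substrate.
#' @param acid SMILES of the carboxylic acid.
#' @return canonical SMILES of the amide product.
#' @examples
#' couple_amide("CN", "CC(=O)O")  # N-methylacetamide
#' @seealso [deprotect_fmoc()], [apply_control()]
#' @export
couple_amide <- function(amine_substrate, acid) {
  sub_mol <- parse_smiles(amine_substrate, "amine substrate SMILES")
  acid_mol <- parse_smiles(acid, "acid SMILES")
  amines <- find_amines(sub_mol)
  if (!length(amines))
    stop("no free primary/secondary amine on substrate ", sQuote(amine_substrate))
  if (length(amines) > 1)
    warning("multiple eligible amines on substrate; coupling at the first (alpha-preferred) match")
  acids <- find_carboxyl(acid_mol)
  if (!nrow(acids))
    stop("no carboxylic acid group on acid ", sQuote(acid))
  if (nrow(acids) > 1)
    warning("multiple carboxylic acid groups on acid; coupling at the first match")
  n_idx <- amines[1]
  # drop the hydroxyl oxygen from the acid, then join N to the acyl carbon
  acid_cut <- delete_atoms(acid_mol, acids[1, "o_hydroxyl"])
  c_idx <- acids[1, "c_acid"] - sum(acids[1, "o_hydroxyl"] < acids[1, "c_acid"])
  joined <- merge_mols(sub_mol, acid_cut)
  joined <- add_bond(joined, n_idx, length(sub_mol$atoms) + c_idx, 1L)
  mol_to_smiles(joined)
}

#' Remove an Fmoc protecting group
#'
#' Cleaves the single fluorenylmethyloxycarbonyl carbamate of `product`,
#' releasing the free amine (the in-silico counterpart of piperidine
#' deprotection). The molecular mass decreases by that of dibenzofulvene +
#' CO2 (C15H10O2, 222.24 Da average).
#'
#' @param product SMILES of an Fmoc-protected molecule.
#' @return canonical SMILES with the carbamate replaced by the free amine.
#' @export
deprotect_fmoc <- function(product) {
  mol <- parse_smiles(product, "product SMILES")
  hits <- find_fmoc(mol)
  if (nrow(hits) == 0) stop("no Fmoc carbamate found in ", sQuote(product))
  if (nrow(hits) > 1) stop("more than one Fmoc carbamate found in ", sQuote(product))
  cut <- remove_bond(mol, hits[1, "n"], hits[1, "c_carbamate"])
  mol_to_smiles(delete_atoms(cut, component_of(cut, hits[1, "c_carbamate"])))
}

#' Does a molecule carry an Fmoc carbamate?
#'
#' @param smiles SMILES string.
#' @return logical.
#' @export
has_fmoc <- function(smiles) {
  nrow(find_fmoc(parse_smiles(smiles))) > 0
}

#' Carry a substrate through a control well
#'
#' Control wells ("no acid" and "no reagents") leave the chemical substrate
#' untouched; only the DNA codon is still ligated, so truncated side-products
#' stay identifiable in selection data. The two control types differ only in
#' provenance metadata.
#'
#' @param substrate SMILES of the current intermediate.
#' @param control a single-row building-block record (see
#'   [read_building_blocks()]) whose `role` is `control_no_acid` or
#'   `control_no_reagent`.
#' @return `substrate`, unchanged.
#' @export
apply_control <- function(substrate, control) {
  role <- if (is.list(control) || is.data.frame(control)) control$role else control
  if (!role %in% c("control_no_acid", "control_no_reagent"))
    stop("apply_control expects a control block, got role ", sQuote(role))
  substrate
}
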