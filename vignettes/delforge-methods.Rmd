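---
title: "delforge: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{delforge: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(delforge)
```

`delforge` models the computational side of a three-cycle amide-coupled
DNA-encoded library (DEL): barcode design, in-silico synthesis, property
profiling, affinity-selection simulation and sequence decoding. This
vignette records the models, the parameters that matter, and the design
choices made where more than one reasonable option existed.

## Error-tolerant codon design

Each synthesis cycle is encoded by a short DNA codon ligated to the growing
tag. The codon sets are built by greedy accretion over the `4^L` candidate
sequences (a *lexicode*): a candidate is accepted iff it passes all
composition filters and keeps Hamming distance `>= min_distance` to every
codon accepted so far, stopping at `n_required`. With the default minimum
distance of 3, any single substitution leaves a read strictly closer to its
true codon than to any other, so the decoder can correct one error per
codon, uniquely — a property the test suite verifies exhaustively over all
`200 x 3L` single mutants.

Defaults and why:

* `length = 12` bases. Codon length is a free design parameter here;
  12-mers comfortably yield 200 codewords at distance 3 under all filters
  (the default scan reaches 200 after a few thousand candidates) while
  keeping the full tag at 60 bases.
* `min_distance = 3`, `n_required = 200` per cycle — the encoding
  guarantees the library was designed around.
* GC fraction in `[0.25, 0.75]` and homopolymer runs `<= 3`: standard
  sequencing-robustness filters. They are configurable and can be disabled
  (`gc_min = 0`, `gc_max = 1`, `max_homopolymer = length`) to study the
  bare distance/palindrome/hairpin constraint set.
* Palindrome filter: a sequence equal to its own reverse complement can
  self-anneal intermolecularly; such codons are rejected.
* Hairpin filter: a codon is rejected if any two substrings of length
  `>= 4` (stem), separated by `>= 3` unpaired bases (loop), are reverse
  complements — the canonical minimal DNA hairpin geometry. The predicate
  is purely combinatorial; thermodynamic (free-energy) structure prediction
  is deliberately out of scope.
* Candidate order is lexicographic by default, making the generator a pure
  function of its configuration. A seeded shuffle is available when more
  heterogeneous sets are wanted; it permutes the whole candidate space, so
  it is limited to `L <= 13`.

Cycles 2 and 3 continue the same scan while excluding codons already used,
so the three sets are disjoint; the pairwise-distance guarantee is enforced
*within* each cycle (decoding is positional, so cross-cycle confusability
does not arise). `cross_cycle = TRUE` additionally enforces the full
distance between cycles for users who want one pooled code.

## In-silico library synthesis

The library topology is: surrogate linker amine → cycle-1 N-Fmoc amino acid
(amide coupling, then Fmoc removal) → cycle-2 N-Fmoc amino acid (likewise)
→ cycle-3 capping carboxylic acid. Each cycle also contains two control
wells — one run without any acid, one with no reagents at all — which leave
the substrate untouched but still receive a codon, so truncated
side-products remain identifiable in selection data. In silico the two
control types are chemically identical (the unreacted amine is carried
forward); they keep distinct codons and roles so the decoder can
distinguish them. A member is flagged `is_truncate` iff any of its three
wells is a control, giving the closed-form library size
`(n1 + 2)(n2 + 2)(n3 + 2)`.

The reaction transforms are graph edits on the molecule's connection table:

* *Amide coupling* deletes the acid's hydroxyl oxygen and bonds the acyl
  carbon to the substrate's amine nitrogen (mass balance: the sum of the
  parts minus one water, which the tests check against independent
  atomic-mass summation to 0.01 Da).
* *Fmoc removal* cuts the carbamate N–C bond and discards the fragment
  containing the carbamate carbon (mass loss C15H10O2, 222.24 Da).

Eligible coupling amines are acyclic N–H nitrogens with no double/triple
bonds that are not amide, carbamate or sulfonamide nitrogens; anilines
remain eligible. When several amines qualify, the α-amino-acid pattern
(N–C–C(=O)) is preferred and a warning is raised — the monomer curation
this design assumes makes such ambiguity rare. The payload is modelled on a
small surrogate aminated linker (`NCCOCC`) rather than the full DNA-oligo
adduct: descriptors, reactions and shape analysis all operate on the
payload, while DNA is tracked as a sequence string. Molecule parsing,
canonical SMILES and the standard descriptors go through Open Babel
(ChemmineR/ChemmineOB).

The DNA headpiece is a fixed 14-base oligo; the default tag schema places
the three codons immediately after it and closes with a fixed 10-base 3'
primer region, giving 60-base tags. Constant regions are configurable
because real tag architectures vary.

## Property profiling

Six descriptors summarise lead-likeness: average molecular weight, Open
Babel's atom-contribution log P (log P implementations differ between
toolkits, so cross-toolkit agreement is approximate by nature — the method
is therefore named in the documentation), hydrogen-bond donors, Ertl TPSA,
rotatable bonds (acyclic single bonds between non-terminal heavy atoms,
amide C–N excluded, the common medicinal-chemistry convention) and aromatic
rings (unique 5–7-membered aromatic rings by SMARTS matching; plain
smallest-ring counting over-counts fused systems).

Diversity embeddings use PCA over either the z-scored descriptor matrix
(default) or hashed atom-pair fingerprints; components are sign-fixed
(largest-magnitude loading positive) so embeddings are deterministic.
Molecular shape uses the PMI triangle: one deterministic Open Babel 3D
embedding with force-field refinement per molecule, inertia tensor about
the centre of mass, and the normalized ratios `npr1 = I1/I3`,
`npr2 = I2/I3`. A single deterministic conformer is used rather than a
seeded ensemble: the generator is reproducible run-to-run, and for the
reference shapes (rods, discs, spheres) the minimum-energy conformer is
unambiguous. Shape coordinates for highly flexible members should be read
as one representative conformer, not an ensemble average.

## Selection simulation

The simulator is a binomial survival cascade, the natural stochastic model
for independent molecules with per-round retention probabilities:

* every member starts at `copies_per_member` copies (default `1e6`,
  matching the roughly one-million-copies-per-compound input the screening
  protocol uses);
* retention is assigned at the cycle-3 building-block level — `p_target`
  (default 0.3) for planted target binders, `p_bead` (0.5) for bead
  binders, `p_background` (0.005) otherwise — because the readout of
  interest is cycle-3 marginal enrichment; a member-level override is
  possible by editing the retention column;
* optional pre-clearing first removes `Binomial(copies, p_bead * fraction)`
  copies from bead binders (default fraction 0.5, i.e. a half portion of
  beads). Background depletion during pre-clearing is neglected — at
  `p_background` of a fraction of a percent it is a sub-percent effect —
  so target binders are unaffected in expectation;
* each selection round then draws `Binomial(copies, p_i)` survivors
  (2 rounds by default);
* a blocking agent in the incubation is modelled as a multiplicative
  factor on `p_background` only: blocking reduces nonspecific retention
  but does not remove genuine bead binding;
* sequencing draws `read_depth` reads multinomially in proportion to final
  abundance (PCR is treated as uniform amplification, which the multinomial
  absorbs; a per-member amplification bias would multiply the weights and
  can be added by scaling the abundance column), then applies i.i.d.
  per-base substitutions at `substitution_error_rate` (default 0.005).
  Indels are not modelled because decoding is positional; quality scores
  are a constant placeholder.

One global seed is fanned out deterministically to each stochastic stage,
so a pipeline run and the equivalent standalone stage calls produce
identical artifacts, byte for byte.

What the generator emulates — and does not. It reproduces the *structure*
of a selection experiment: copy-number scale, round-to-round binomial
attrition, bead-binding artefacts, pre-clearing, sequencing noise, and the
resulting count statistics. It does not model binding kinetics or
thermodynamics, bead-capacity saturation, PCR bias, chimeric reads or
cross-pool contamination. Tests passing on synthetic data therefore
demonstrate that the decoding and enrichment logic is correct under the
stated noise model, not that real selections are free of these additional
effects.

## Decoding and enrichment

Reads are parsed positionally from the tag schema. The 3' constant region
is verified within a configurable mismatch budget (default 1); each codon
is matched exactly or corrected if exactly one codon of that cycle's set
lies within distance 1. Only codons actually assigned to wells participate
in matching. Unassigned reads are tallied by reason (length, constant
region, per-cycle codon failure), and the invariant
`sum(counts) + unassigned == reads` holds on every input. Reads are matched
in the forward orientation; reverse-complement scanning belongs to the tag
architecture of a specific sequencing setup and is out of scope.

Raw summed counts per unique barcode combination are the primary statistic,
exactly as a selection readout reports them; normalized ratios against a
baseline run (pseudocount 1) are available but clearly secondary. The
per-cycle marginal report flags control codons so truncate-driven signal is
visible. For cycles expected to carry no signal, a chi-square uniformity
test over the marginal is provided; a single planned test is reported with
its raw p-value.

## Numerical and testing choices

* Average atomic masses are used throughout (Open Babel MW); mass-balance
  assertions use a 0.05 Da tolerance, far above the rounding differences
  between mass conventions.
* The hairpin predicate is cross-checked against an independent brute-force
  triple loop, exhaustively for all sequences up to length 7 and on 1 000
  random 12-mers — problem sizes chosen so the exhaustive oracle stays
  cheap while covering every stem/loop geometry the filter can encounter
  at codon scale.
* Desk-scale recovery experiments use the 7 × 7 × 6 demonstration plate,
  20 seeded replicates, 200 000 reads per replicate and the default noise
  settings; the planted cycle-3 binder must top the cycle-3 marginal in at
  least 19 of 20 replicates while cycles 1–2 stay uniform at
  `alpha = 0.01` in at least 18 of 20. Pre-clearing comparisons pair the
  two conditions on the same seed. These sizes make the stochastic
  assertions sharp (the expected effects are tens of standard errors)
  while keeping the whole suite inside a few minutes.
* Degenerate inputs are defined errors, not silent results: zero surviving
  molecules, empty descriptor tables, fewer compounds than PCA components,
  exhausted codon candidate spaces and malformed FASTQ records all raise
  informative conditions.

## Known limitations

* The chemistry layer assumes neutral organic molecules with standard
  valences (the chemistry this library design uses); charged or
  organometallic building blocks are rejected at parse time.
* Aromatic ring counting relies on Open Babel's aromaticity perception via
  SMARTS; exotic ring systems may be judged differently by other toolkits,
  as may log P.
* The selection model is intentionally coarse: retention probabilities are
  constants per building block, not functions of concentration or
  affinity; enrichment statistics beyond counts and ratios (e.g. negative
  binomial testing) are out of scope.
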