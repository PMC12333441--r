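ATOMIC_MASS <- c(H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
                 F = 18.998, Si = 28.085, P = 30.974, S = 32.06,
                 Cl = 35.45, Br = 79.904, I = 126.904)

#' Lead-likeness descriptors
#'
#' Computes the six descriptors used to profile the library: molecular weight
#' (`mwt`, Da, average masses), calculated log P (`clogp`, Open Babel's
#' atom-contribution model), hydrogen-bond donor count (`hbd`), topological
#' polar surface area (`tpsa`, A^2, Ertl group contributions), rotatable bond
#' count (`nrb`, acyclic single bonds between non-terminal heavy atoms,
#' amide C-N bonds excluded) and aromatic ring count (`nar`, unique 5-7
#' membered aromatic rings). Profiling operates on payload structures; DNA is
#' excluded throughout.
#'
#' @param smiles character vector of SMILES.
#' @param ids optional member ids (defaults to names or index).
#' @return a data.frame with columns `member_id`, `mwt`, `clogp`, `hbd`,
#'   `tpsa`, `nrb`, `nar`.
#' @examples
#' compute_descriptors(c(benzene = "c1ccccc1", butane = "CCCC"))
#' @export
compute_descriptors <- function(smiles, ids = NULL) {
  if (!length(smiles)) stop("no structures supplied")
  ids <- ids %||% names(smiles) %||% as.character(seq_along(smiles))
  ok <- vapply(smiles, smiles_syntax_ok, logical(1))
  if (any(!ok)) stop("unparsable structure for member ",
                     sQuote(ids[which(!ok)[1]]), ": ", sQuote(smiles[which(!ok)[1]]))
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(setNames(smiles, ids)))
  bad <- which(vapply(seq_along(smiles), function(i)
    nrow(ChemmineR::atomblock(sdf[[i]])) == 0, logical(1)))
  if (length(bad)) stop("unparsable structure for member ", sQuote(ids[bad[1]]))
  p <- ChemmineR::propOB(sdf)
  rot <- ChemmineR::smartsSearchOB(sdf, "[!$(*#*)&!D1]-&!@[!$(*#*)&!D1]", uniqueMatches = TRUE)
  amide <- ChemmineR::smartsSearchOB(sdf, "[NX3]-&!@[CX3]=[OX1]", uniqueMatches = TRUE)
  nar <- Reduce(`+`, lapply(c("[a]1[a][a][a][a]1", "[a]1[a][a][a][a][a]1",
                              "[a]1[a][a][a][a][a][a]1"), function(sm)
    ChemmineR::smartsSearchOB(sdf, sm, uniqueMatches = TRUE)))
  data.frame(member_id = ids, mwt = p$MW, clogp = p$logP, hbd = as.integer(p$HBD),
             tpsa = p$TPSA, nrb = as.integer(rot - amide), nar = as.integer(nar),
             row.names = NULL)
}

#' Summary statistics of a descriptor table
#'
#' Arithmetic mean and standard deviation (sample by default, population on
#' request) of each descriptor over a compound set.
#'
#' @param records a descriptor data.frame from [compute_descriptors()] (any
#'   data.frame whose numeric columns are to be summarised).
#' @param std `"sample"` (n-1 denominator, default) or `"population"`.
#' @return a data.frame with columns `descriptor`, `mean`, `sd`, `n`.
#' @export
summarize_properties <- function(records, std = c("sample", "population")) {
  std <- match.arg(std)
  if (!nrow(records)) stop("empty descriptor table")
  num <- names(records)[vapply(records, is.numeric, logical(1))]
  n <- nrow(records)
  means <- vapply(records[num], mean, numeric(1))
  sds <- vapply(records[num], function(x) {
    if (n == 1) return(0)
    s <- sd(x)
    if (std == "population") s * sqrt((n - 1) / n) else s
  }, numeric(1))
  data.frame(descriptor = num, mean = unname(means), sd = unname(sds), n = n,
             row.names = NULL)
}

#' Principal components embedding of a feature matrix
#'
#' Thin wrapper around [stats::prcomp()] for chemical-space diversity
#' analysis: centred (and optionally unit-variance scaled) PCA with a fixed
#' sign convention - each component is oriented so its largest-magnitude
#' loading is positive, making the embedding fully deterministic. Constant
#' columns are dropped before scaling.
#'
#' @param x numeric matrix or data.frame (compounds in rows).
#' @param n_components number of components to keep.
#' @param scale. scale columns to unit variance (default `TRUE`).
#' @return a list of class `del_pca`: `scores` (n x k), `loadings`,
#'   `explained_variance` (proportions, decreasing), `center`, `scale`.
#' @export
pca_embed <- function(x, n_components = 2L, scale. = TRUE) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least two compounds for a PCA")
  if (n_components > min(dim(x)))
    stop("fewer compounds/features than requested components")
  keep <- apply(x, 2, function(col) length(unique(col)) > 1)
  if (scale. && !all(keep)) x <- x[, keep, drop = FALSE]
  if (ncol(x) < n_components) stop("not enough varying features for ", n_components, " components")
  fit <- prcomp(x, center = TRUE, scale. = scale.)
  k <- seq_len(n_components)
  flip <- vapply(k, function(j) {
    l <- fit$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(fit$x[, k, drop = FALSE], 2, flip, `*`)
  loadings <- sweep(fit$rotation[, k, drop = FALSE], 2, flip, `*`)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  structure(list(scores = scores, loadings = loadings,
                 explained_variance = ev[k], center = fit$center,
                 scale = if (scale.) fit$scale else NULL),
            class = "del_pca")
}

#' Hashed substructure fingerprints for a compound set
#'
#' Atom-pair descriptors (ChemmineR) folded by modulo hashing into a
#' fixed-width binary matrix, the feature basis offered for
#' fingerprint-space PCA (the descriptor basis being the default).
#'
#' @param smiles character vector of SMILES.
#' @param bits fingerprint width.
#' @return a binary matrix with one row per compound.
#' @export
fingerprint_matrix <- function(smiles, bits = 1024L) {
  sdf <- suppressWarnings(ChemmineR::smiles2sdf(
    setNames(smiles, paste0("cmp", seq_along(smiles)))))
  ap <- ChemmineR::sdf2ap(sdf)
  pairs <- ChemmineR::ap(ap)
  fp <- matrix(0L, length(pairs), bits)
  for (i in seq_along(pairs)) fp[i, unique(pairs[[i]] %% bits) + 1L] <- 1L
  fp
}

#' Normalized principal-moments-of-inertia shape coordinates
#'
#' Embeds each structure in 3D (one deterministic Open Babel conformer with
#' force-field refinement, hydrogens explicit), computes the principal
#' moments of inertia I1 <= I2 <= I3 about the centre of mass, and returns
#' the normalized ratios npr1 = I1/I3, npr2 = I2/I3. Points live in the PMI
#' triangle - rod (0,1), disc (0.5,0.5), sphere (1,1) - with
#' npr1 <= npr2 and npr1 + npr2 >= 1. Structures that fail to embed yield
#' `NA` with a warning.
#'
#' @param smiles character vector of SMILES.
#' @param ids optional ids.
#' @return data.frame with `member_id`, `npr1`, `npr2`.
#' @export
pmi_coordinates <- function(smiles, ids = NULL) {
  ids <- ids %||% names(smiles) %||% as.character(seq_along(smiles))
  res <- t(vapply(seq_along(smiles), function(i) {
    mb <- tryCatch(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles[i], "\n"),
      options = data.frame(names = "gen3d", args = "")),
      error = function(e) "")
    xyz <- tryCatch(parse_molblock_coords(mb), error = function(e) NULL)
    if (is.null(xyz)) {
      warning("3D embedding failed for ", sQuote(ids[i]), "; skipped")
      return(c(NA_real_, NA_real_))
    }
    inertia_ratios(xyz$coords, ATOMIC_MASS[xyz$elements])
  }, numeric(2)))
  data.frame(member_id = ids, npr1 = res[, 1], npr2 = res[, 2], row.names = NULL)
}

parse_molblock_coords <- function(mb) {
  lines <- strsplit(mb, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4) stop("no molblock")
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  if (is.na(na) || na < 1) stop("empty molblock")
  atom_lines <- lines[5:(4 + na)]
  coords <- matrix(as.numeric(c(substr(atom_lines, 1, 10), substr(atom_lines, 11, 20),
                                substr(atom_lines, 21, 30))), ncol = 3)
  elements <- trimws(substr(atom_lines, 32, 34))
  list(coords = coords, elements = elements)
}

inertia_ratios <- function(coords, masses) {
  com <- colSums(coords * masses) / sum(masses)
  r <- sweep(coords, 2, com)
  ixx <- sum(masses * (r[, 2]^2 + r[, 3]^2))
  iyy <- sum(masses * (r[, 1]^2 + r[, 3]^2))
  izz <- sum(masses * (r[, 1]^2 + r[, 2]^2))
  ixy <- -sum(masses * r[, 1] * r[, 2])
  ixz <- -sum(masses * r[, 1] * r[, 3])
  iyz <- -sum(masses * r[, 2] * r[, 3])
  tensor <- matrix(c(ixx, ixy, ixz, ixy, iyy, iyz, ixz, iyz, izz), 3, 3)
  ev <- sort(eigen(tensor, symmetric = TRUE, only.values = TRUE)$values)
  c(npr1 = ev[1] / ev[3], npr2 = ev[2] / ev[3])
}

#' Load an external SMILES set for comparative profiling
#'
#' Reads a plain SMILES file (one `SMILES[ \t]id` record per line, `#`
#' comments ignored), e.g. a vendor screening collection to profile alongside
#' the library.
#'
#' @param path file path.
#' @return data.frame with columns `smiles`, `id`.
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stop("SMILES file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[ \t]+")
  data.frame(smiles = vapply(parts, `[`, character(1), 1),
             id = vapply(seq_along(parts), function(i)
               if (length(parts[[i]]) > 1) parts[[i]][2] else as.character(i), character(1)))
}
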