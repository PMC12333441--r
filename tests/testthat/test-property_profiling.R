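test_that("descriptor counts match definitions on reference molecules", {
  d <- compute_descriptors(c(benzene = "c1ccccc1", butane = "CCCC",
                             naphthalene = "c1ccc2ccccc2c1", imidazole = "c1c[nH]cn1",
                             biphenyl = "c1ccc(-c2ccccc2)cc1"))
  expect_identical(d$nar, c(1L, 0L, 2L, 1L, 2L))
  expect_identical(d$hbd[1:2], c(0L, 0L))
  expect_identical(d$nrb, c(0L, 1L, 0L, 0L, 1L))
  expect_identical(d$member_id[1], "benzene")
  # determinism
  expect_identical(compute_descriptors("c1ccccc1"), compute_descriptors("c1ccccc1"))
  expect_error(compute_descriptors("C("), "unparsable")
})

test_that("glycylglycine HBD/TPSA match a hand group-contribution sum", {
  d <- compute_descriptors("NCC(=O)NCC(=O)O")
  # Ertl contributions: NH2 26.02 + amide NH 12.03 + 2x =O 17.07 + OH 20.23
  expect_equal(d$tpsa, 26.02 + 12.03 + 2 * 17.07 + 20.23, tolerance = 0.01)
  expect_identical(d$hbd, 3L)  # NH2, amide NH, COOH
  expect_equal(d$mwt, formula_mass("C4H8N2O3"), tolerance = 0.01)
})

test_that("summaries compute means and the requested std flavour", {
  rec <- data.frame(mwt = c(100, 300))
  s <- summarize_properties(rec)
  expect_equal(s$mean, 200)
  expect_equal(s$sd, sd(c(100, 300)))
  same <- data.frame(mwt = rep(250, 5))
  expect_equal(summarize_properties(same)$sd, 0)
  pop <- summarize_properties(rec, std = "population")
  expect_equal(pop$sd, 100)
  expect_error(summarize_properties(rec[0, , drop = FALSE]), "empty")
  # duplicating a set leaves the mean identical; sample std only changes by
  # the (n-1) correction
  x <- data.frame(v = rnorm(20, 10, 2))
  dup <- rbind(x, x)
  expect_equal(summarize_properties(dup)$mean, summarize_properties(x)$mean)
  expect_equal(summarize_properties(dup, "population")$sd,
               summarize_properties(x, "population")$sd)
})

test_that("summarize recovers generator moments within 3 standard errors", {
  set.seed(101)
  n <- 1000
  gen <- list(mwt = c(438, 69), clogp = c(1.7, 1.3), tpsa = c(106, 19))
  rec <- as.data.frame(lapply(gen, function(g) rnorm(n, g[1], g[2])))
  s <- summarize_properties(rec)
  for (i in seq_along(gen)) {
    se <- gen[[i]][2] / sqrt(n)
    expect_lt(abs(s$mean[i] - gen[[i]][1]), 3 * se)
  }
})

test_that("PCA embedding is deterministic, ordered and sign-fixed", {
  set.seed(7)
  x <- cbind(a = 1:20, b = (1:20) * 2 + rnorm(20, 0, 1e-6), c = rnorm(20))
  p <- pca_embed(x)
  expect_gt(p$explained_variance[1], 0.6)
  expect_true(all(diff(p$explained_variance) <= 0))
  expect_lte(sum(p$explained_variance), 1 + 1e-9)
  # orthogonal scores
  expect_equal(unname(crossprod(p$scores)[1, 2]), 0, tolerance = 1e-6)
  # sign convention: largest-magnitude loading positive
  for (j in 1:2) expect_gt(p$loadings[which.max(abs(p$loadings[, j])), j], 0)
  expect_identical(pca_embed(x)$scores, p$scores)
  expect_error(pca_embed(x[1, , drop = FALSE]), "two compounds")
  expect_error(pca_embed(x, n_components = 5), "components")
  # collinear points: first component captures everything
  line <- cbind(1:10, (1:10) * 3)
  expect_equal(pca_embed(line, scale. = FALSE)$explained_variance[1], 1)
})

test_that("a 2-D embedding separates three synthetic descriptor clusters", {
  skip_if_not_installed("cluster")
  set.seed(42)
  centers <- matrix(c(0, 0, 0, 0, 0, 0,
                      8, 8, 0, 0, 0, 0,
                      0, 0, 8, 8, 0, 0), 3, byrow = TRUE)
  x <- do.call(rbind, lapply(1:3, function(k)
    sweep(matrix(rnorm(40 * 6), 40), 2, centers[k, ], `+`)))
  lab <- rep(1:3, each = 40)
  emb <- pca_embed(x, scale. = FALSE)$scores
  sil <- cluster::silhouette(lab, dist(emb))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("fingerprints are binary, fixed width and structure-sensitive", {
  fp <- fingerprint_matrix(c("c1ccccc1", "CCCC", "c1ccccc1"), bits = 256)
  expect_identical(dim(fp), c(3L, 256L))
  expect_true(all(fp %in% 0:1))
  expect_identical(fp[1, ], fp[3, ])
  expect_false(identical(fp[1, ], fp[2, ]))
})

test_that("PMI coordinates land on the canonical shape corners", {
  pm <- pmi_coordinates(c(rod = "C#CC#C", disc = "c1ccccc1",
                          sphere = "C1C2CC3CC1CC(C2)C3"))
  expect_equal(pm$npr1[1], 0, tolerance = 0.05)
  expect_equal(pm$npr2[1], 1, tolerance = 0.05)
  expect_equal(pm$npr1[2], 0.5, tolerance = 0.05)
  expect_equal(pm$npr2[2], 0.5, tolerance = 0.05)
  expect_equal(pm$npr1[3], 1, tolerance = 0.05)
  expect_equal(pm$npr2[3], 1, tolerance = 0.05)
})

test_that("PMI triangle invariants hold for library payloads", {
  lib <- enumerate_library(demo_building_blocks(), generate_codon_sets(toy_codon_config()))
  payload <- head(unique(lib$product[!lib$is_truncate]), 8)
  pm <- pmi_coordinates(payload)
  expect_false(anyNA(pm$npr1))
  expect_true(all(pm$npr1 <= pm$npr2 + 1e-6))
  expect_true(all(pm$npr1 + pm$npr2 >= 1 - 1e-6))
  expect_true(all(pm$npr1 >= 0 & pm$npr2 <= 1 + 1e-6))
})

test_that("adamantane inertia ratios agree with a direct tensor computation", {
  # independent check: recompute the tensor from raw coordinates with the
  # textbook formula on a fresh embedding
  mb <- ChemmineOB::convertFormat("SMI", "SDF", "C1C2CC3CC1CC(C2)C3\n",
                                  options = data.frame(names = "gen3d", args = ""))
  lines <- strsplit(mb, "\n")[[1]]
  na <- as.integer(substr(lines[4], 1, 3))
  al <- lines[5:(4 + na)]
  xyz <- cbind(as.numeric(substr(al, 1, 10)), as.numeric(substr(al, 11, 20)),
               as.numeric(substr(al, 21, 30)))
  el <- trimws(substr(al, 32, 34))
  m <- c(C = 12.011, H = 1.008)[el]
  com <- colSums(xyz * m) / sum(m)
  r <- sweep(xyz, 2, com)
  I <- matrix(0, 3, 3)
  for (i in seq_len(nrow(r)))
    I <- I + m[i] * (sum(r[i, ]^2) * diag(3) - outer(r[i, ], r[i, ]))
  ev <- sort(eigen(I, symmetric = TRUE)$values)
  pm <- pmi_coordinates("C1C2CC3CC1CC(C2)C3")
  expect_equal(pm$npr1, ev[1] / ev[3], tolerance = 1e-6)
  expect_equal(pm$npr2, ev[2] / ev[3], tolerance = 1e-6)
})

test_that("external SMILES loader parses records and comments", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("# synthetic comparison set", "c1ccccc1 benzene", "CCO"), path)
  df <- read_smiles_file(path)
  expect_identical(df$smiles, c("c1ccccc1", "CCO"))
  expect_identical(df$id[1], "benzene")
})
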