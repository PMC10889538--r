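test_that("rank-1 displacements give a single dominant mode", {
  toy <- toy_protein()
  n <- 50
  set.seed(6)
  amp <- rnorm(n)
  dirvec <- rep(0, length(toy$conformation))
  sel <- select_atoms(toy$topology, region = "L-loop", atom_names = "CA")
  dirvec[confens:::xyz_index(sel[1])] <- c(1, 2, 2) / 3
  xyz <- matrix(rep(toy$conformation, n), nrow = n, byrow = TRUE) +
    outer(amp, dirvec)
  ens <- ensemble(toy$topology, xyz)
  pc <- pca_ensemble(ens, selection = sel, fit = FALSE)
  expect_gte(pc$explained_variance[1], 1 - 1e-8)
  ## projecting the mean structure gives zero coordinates
  mens <- ensemble(toy$topology, matrix(rep(toy$conformation, 1), nrow = 1,
                                        byrow = TRUE))
  mens$xyz[1, confens:::xyz_index(sel)] <- pc$mean
  pr <- project_ensemble(mens, pc, fit = FALSE)
  expect_lt(max(abs(as.matrix(pr[, grep("^PC", names(pr)), drop = FALSE]))),
            1e-8)
})

test_that("eigenvalues obey the trace identity and match a dense eigensolver", {
  sm <- planted_well_ensemble(200, seed = 31, populations = c(0.7, 0.3))
  sel <- sm$selection
  pc <- pca_ensemble(sm$ensemble, selection = sel, fit = FALSE)
  f <- rmsf(sm$ensemble, selection = sel, fit = FALSE, unbiased = TRUE)
  expect_equal(sum(pc$eigenvalues), sum(f^2), tolerance = 1e-6)
  ## per-atom identity: rmsf_i^2 = sum_k eigenvalue_k * |mode_k(atom i)|^2
  amp2 <- vapply(seq_along(sel), function(i) {
    rows <- (3 * (i - 1) + 1):(3 * i)
    sum(pc$eigenvalues * colSums(pc$modes[rows, , drop = FALSE]^2))
  }, numeric(1))
  expect_equal(f^2, amp2, tolerance = 1e-6)
  ## dense covariance eigendecomposition oracle (30 atoms, 200 frames)
  X <- sm$ensemble$xyz[, confens:::xyz_index(sel[1:30]), drop = FALSE]
  pc30 <- pca_ensemble(ensemble(topology(sm$ensemble$topology$atoms[sel[1:30], ]),
                                X), fit = FALSE)
  ev <- eigen(cov(X), symmetric = TRUE)$values
  k <- length(pc30$eigenvalues)
  expect_equal(pc30$eigenvalues, ev[1:k], tolerance = 1e-8)
  ## orthonormal modes
  G <- crossprod(pc$modes)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_true(all(diff(pc$eigenvalues) <= 1e-12))
  expect_equal(sum(pc$explained_variance), 1, tolerance = 1e-12)
})

test_that("projection variances equal eigenvalues and reconstruction is exact", {
  sm <- planted_well_ensemble(150, seed = 17, populations = c(0.6, 0.4))
  sel <- sm$selection
  pc <- pca_ensemble(sm$ensemble, selection = sel, fit = FALSE)
  proj <- project_ensemble(sm$ensemble, pc, n_modes = 3, fit = FALSE)
  expect_equal(var(proj$PC1), pc$eigenvalues[1], tolerance = 1e-8)
  expect_equal(var(proj$PC2), pc$eigenvalues[2], tolerance = 1e-8)
  ## all-mode reconstruction reproduces the fitted coordinates
  Xc <- sweep(pc$fitted_xyz, 2, pc$mean)
  P <- Xc %*% pc$modes
  recon <- P %*% t(pc$modes)
  expect_lt(max(abs(recon - Xc)), 1e-6)
  ## per-source clouds keep their labels
  sm$ensemble$source <- rep(c("WT", "MUT"), length.out = 150)
  pr <- project_ensemble(sm$ensemble, pc, fit = FALSE)
  expect_setequal(unique(pr$source), c("WT", "MUT"))
})

test_that("explained variances are invariant under rigid pre-rotation of all frames", {
  sm <- planted_well_ensemble(80, seed = 23, populations = c(0.5, 0.5))
  sel <- sm$selection
  pc1 <- pca_ensemble(sm$ensemble, selection = sel)
  R <- confens:::rotation_between(c(1, 0, 0), c(0, 0, 1))
  rot <- sm$ensemble
  for (i in seq_len(nrow(rot$xyz))) {
    m <- matrix(rot$xyz[i, ], ncol = 3, byrow = TRUE) %*% t(R)
    rot$xyz[i, ] <- as.vector(t(sweep(m, 2, c(4, -3, 9), `+`)))
  }
  pc2 <- pca_ensemble(rot, selection = sel)
  expect_equal(pc1$explained_variance[1:5], pc2$explained_variance[1:5],
               tolerance = 1e-6)
})

test_that("mode displacement arrows honour the amplitude threshold", {
  toy <- toy_protein()
  n <- 60
  set.seed(12)
  sel <- select_atoms(toy$topology, region = "L-loop", atom_names = "CA")
  xyz <- matrix(rep(toy$conformation, n), nrow = n, byrow = TRUE)
  ## one atom oscillating along x, scaled to sample sd exactly 3
  cols <- confens:::xyz_index(sel[5])[1]
  wave <- sin(2 * pi * seq_len(n) / n)
  xyz[, cols] <- xyz[, cols] + 3 * wave / sd(wave)
  ens <- ensemble(toy$topology, xyz)
  pc <- pca_ensemble(ens, selection = sel, fit = FALSE)
  arr <- mode_displacements(pc, 1, amplitude_threshold = 2)
  shown <- arr[arr$displayed, ]
  expect_equal(nrow(shown), 1)
  expect_equal(shown$amplitude, 3, tolerance = 1e-6)
  expect_equal(sum(mode_displacements(pc, 1, 0)$displayed), length(sel))
  expect_equal(sum(mode_displacements(pc, 1, 99)$displayed), 0)
})

test_that("cross-correlation has unit diagonal, tracks rigid blocks, and matches bio3d", {
  toy <- toy_protein()
  n <- 300
  set.seed(14)
  sel <- select_atoms(toy$topology, region = "L-loop", atom_names = "CA")[1:20]
  xyz <- matrix(rep(toy$conformation, n), nrow = n, byrow = TRUE)
  drive <- rnorm(n)
  ## atoms 1,2 move together along x; atom 3 mirrored; others independent
  c1 <- confens:::xyz_index(sel[1])[1]
  c2 <- confens:::xyz_index(sel[2])[1]
  c3 <- confens:::xyz_index(sel[3])[1]
  xyz[, c1] <- xyz[, c1] + drive
  xyz[, c2] <- xyz[, c2] + drive
  xyz[, c3] <- xyz[, c3] - drive
  for (k in 4:20) {
    ck <- confens:::xyz_index(sel[k])
    xyz[, ck] <- xyz[, ck] + matrix(rnorm(3 * n, sd = 0.3), ncol = 3)
  }
  ens <- ensemble(toy$topology, xyz)
  cc <- cross_correlation(ens, selection = sel, fit = FALSE)
  expect_equal(unname(diag(cc)), rep(1, 20))
  ## a static atom gets a zeroed row/column with unit diagonal, plus warning
  sel21 <- select_atoms(toy$topology, region = "L-loop", atom_names = "CA")[1:21]
  expect_warning(cc21 <- cross_correlation(ens, selection = sel21, fit = FALSE),
                 "zero-variance")
  expect_equal(unname(cc21[21, 21]), 1)
  expect_equal(max(abs(cc21[21, -21])), 0)
  expect_equal(unname(cc[1, 2]), 1, tolerance = 1e-8)
  expect_equal(unname(cc[1, 3]), -1, tolerance = 1e-8)
  expect_true(all(cc >= -1 - 1e-12 & cc <= 1 + 1e-12))
  expect_equal(unname(cc), unname(t(cc)))
  ## positive semidefinite up to numerics
  expect_gte(min(eigen(cc[4:20, 4:20], symmetric = TRUE)$values), -1e-8)
  skip_if_not_installed("bio3d")
  dccm_ref <- bio3d::dccm(ens$xyz[, confens:::xyz_index(sel[4:20])])
  expect_equal(unname(cc[4:20, 4:20]), unname(dccm_ref[, ]), tolerance = 1e-6)
})

test_that("residue correlation profiles extract labelled rows", {
  sm <- planted_well_ensemble(60, seed = 2, populations = c(0.5, 0.5))
  sel <- sm$selection
  cc <- cross_correlation(sm$ensemble, selection = sel, fit = FALSE)
  res <- as.integer(rownames(cc))[3]
  prof <- residue_correlation_profile(cc, res, top = sm$ensemble$topology)
  expect_equal(prof$correlation[prof$residue == res], 1)
  expect_equal(prof$correlation, as.numeric(cc[3, ]))
  expect_true(all(prof$region == "L-loop"))
  expect_error(residue_correlation_profile(cc, 9999), "not in")
})
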