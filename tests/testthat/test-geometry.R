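test_that("superposition handles identity, translation and matches the rotation-grid oracle", {
  set.seed(101)
  x <- rnorm(12)
  s <- superpose(x, x)
  expect_equal(s$rmsd, 0, tolerance = 1e-10)
  expect_equal(s$rotation, diag(3), tolerance = 1e-8)
  xt <- as.vector(t(sweep(matrix(x, ncol = 3, byrow = TRUE), 2, c(5, 0, 0), `+`)))
  expect_equal(superpose(xt, x)$rmsd, 0, tolerance = 1e-10)
  ## oracle agreement on random 4-atom toys
  for (i in 1:25) {
    A <- matrix(rnorm(12, sd = 2), ncol = 3)
    B <- matrix(rnorm(12, sd = 2), ncol = 3)
    ana <- superpose(as.vector(t(A)), as.vector(t(B)))$rmsd
    bf <- brute_force_rmsd(A, B)
    expect_lt(abs(ana - bf), 1e-2)
    expect_lte(ana, bf + 1e-9)     # analytic fit is the global minimum
  }
  expect_error(superpose(rnorm(6), rnorm(6)), ">= 3")
  line <- as.vector(t(cbind(1:4, 0, 0)))
  expect_error(superpose(line, line + 1), "collinear")
})

test_that("rmsd_series is zero on rigid motions and bimodal on two wells", {
  toy <- toy_protein()
  top <- toy$topology
  R <- confens:::rotation_between(c(0, 0, 1), c(1, 1, 1) / sqrt(3))
  rot <- as.vector(t(matrix(toy$conformation, ncol = 3, byrow = TRUE) %*% t(R)))
  ens <- ensemble(top, rbind(toy$conformation, rot))
  expect_equal(rmsd_series(ens, toy$conformation), c(0, 0), tolerance = 1e-8)
  ## two wells 6 A apart -> modes near 0 and 6
  sm <- planted_well_ensemble(400, seed = 3, populations = c(0.5, 0.5),
                              sep = 6, spread = 0.3)
  sel <- sm$selection
  ref <- displace_region(toy$conformation, top, "L-loop", c(0, 0, 0))
  r <- rmsd_series(sm$ensemble, ref, selection = sel, fit = FALSE)
  g <- sm$ground_truth$frame_labels
  expect_lt(abs(median(r[g == 1]) - sqrt(6 * 0.3^2)), 0.3)
  expect_lt(abs(median(r[g == 2]) - 6), 0.3)
})

test_that("rmsd is a pseudometric and fitting never increases it", {
  set.seed(7)
  confs <- replicate(6, rnorm(30), simplify = FALSE)
  for (i in 1:5) {
    a <- confs[[i]]; b <- confs[[i + 1]]; c <- confs[[1]]
    dab <- superpose(a, b)$rmsd
    expect_equal(dab, superpose(b, a)$rmsd, tolerance = 1e-8)
    unfitted <- confens:::coord_rmsd(a, b)
    expect_lte(dab, unfitted + 1e-9)
    ## triangle inequality on the unfitted pseudometric
    expect_lte(confens:::coord_rmsd(a, c),
               confens:::coord_rmsd(a, b) + confens:::coord_rmsd(b, c) + 1e-9)
  }
})

test_that("rmsf recovers the planted jitter scale sigma*sqrt(3)", {
  toy <- toy_protein()
  n_at <- n_atoms(toy$topology)
  nf <- 5000
  set.seed(21)
  xyz <- matrix(rep(toy$conformation, nf), nrow = nf, byrow = TRUE)
  jit_atom <- 30
  cols <- (3 * jit_atom - 2):(3 * jit_atom)
  xyz[, cols] <- xyz[, cols] + matrix(rnorm(3 * nf, sd = 0.5), ncol = 3)
  ens <- ensemble(toy$topology, xyz)
  f <- rmsf(ens, fit = FALSE)
  expect_lt(abs(f[jit_atom] - 0.5 * sqrt(3)) / (0.5 * sqrt(3)), 0.05)
  expect_lt(max(f[-jit_atom]), 1e-10)
  ## static ensemble -> all zero
  stat <- ensemble(toy$topology, matrix(rep(toy$conformation, 3),
                                        nrow = 3, byrow = TRUE))
  expect_equal(max(rmsf(stat, fit = FALSE)), 0)
  expect_warning(one <- rmsf(subset_frames(stat, 1)), "single-frame")
  expect_equal(one, rep(0, n_at))
})

test_that("radius of gyration matches closed forms and brute force, and is rigid-invariant", {
  at1 <- data.frame(serial = 1, name = "CA", element = "C", resid = 1L,
                    resname = "ALA", chain = "A")
  expect_equal(radius_of_gyration(c(1, 2, 3), topology(at1)), 0)
  at2 <- data.frame(serial = 1:2, name = "CA", element = "C", resid = 1:2,
                    resname = "ALA", chain = "A")
  expect_equal(radius_of_gyration(c(0, 0, 0, 2, 0, 0), topology(at2)), 1)
  ## brute-force direct evaluation on random structures
  set.seed(33)
  at <- data.frame(serial = 1:50, name = "CA",
                   element = sample(c("C", "N", "O", "S"), 50, TRUE),
                   resid = 1:50, resname = "ALA", chain = "A")
  top <- topology(at)
  x <- rnorm(150, sd = 4)
  m <- matrix(x, ncol = 3, byrow = TRUE)
  w <- top$atoms$mass
  com <- colSums(m * w) / sum(w)
  direct <- sqrt(sum(w * rowSums(sweep(m, 2, com)^2)) / sum(w))
  expect_equal(radius_of_gyration(x, top), direct, tolerance = 1e-10)
  ## rigid invariance
  R <- confens:::rotation_between(c(1, 0, 0), c(0, 1, 1) / sqrt(2))
  xr <- as.vector(t(sweep(m %*% t(R), 2, c(3, -2, 7), `+`)))
  expect_equal(radius_of_gyration(xr, top), direct, tolerance = 1e-10)
  expect_error(radius_of_gyration(x, top, selection = integer(0)), "empty")
})

test_that("helix axes are stable, track rigid rotations, and export 50% elongation", {
  h <- build_ideal_helix(12, "alpha")
  top <- h$topology
  ## rotate whole helix so its CA1->CA12 axis lies along z
  m <- matrix(h$conformation, ncol = 3, byrow = TRUE)
  ca <- m[top$atoms$name == "CA", ]
  R <- confens:::rotation_between((ca[12, ] - ca[1, ]) /
                                    sqrt(sum((ca[12, ] - ca[1, ])^2)),
                                  c(0, 0, 1))
  mz <- m %*% t(R)
  conf <- as.vector(t(mz))
  top2 <- topology(top$atoms, helices = list(helix = c(1L, 12L)))
  ens <- ensemble(top2, rbind(conf, conf, conf))
  ax <- helix_axis_drift(ens, "helix")
  expect_equal(unname(as.matrix(ax[, c("dx", "dy", "dz")])),
               matrix(rep(c(0, 0, 1), 3), ncol = 3, byrow = TRUE),
               tolerance = 1e-6)
  ## extension: +25% per end
  len <- sqrt((ax$x2 - ax$x1)^2 + (ax$y2 - ax$y1)^2 + (ax$z2 - ax$z1)^2)
  elen <- sqrt((ax$ex2 - ax$ex1)^2 + (ax$ey2 - ax$ey1)^2 + (ax$ez2 - ax$ez1)^2)
  expect_equal(elen / len, rep(1.5, 3), tolerance = 1e-9)
  ## 90-degree rigid rotation between frames: unfitted axes differ by 90 deg
  Rx <- matrix(c(1, 0, 0, 0, 0, -1, 0, 1, 0), 3, byrow = TRUE)
  conf90 <- as.vector(t(mz %*% t(Rx)))
  ens2 <- ensemble(top2, rbind(conf, conf90))
  ax2 <- helix_axis_drift(ens2, "helix", fit = FALSE)
  d1 <- unlist(ax2[1, c("dx", "dy", "dz")])
  d2 <- unlist(ax2[2, c("dx", "dy", "dz")])
  expect_equal(acos(sum(d1 * d2)) * 180 / pi, 90, tolerance = 1e-6)
  ## with superposition the fit undoes the rigid motion: zero angular spread
  ax3 <- helix_axis_drift(ens2, "helix")
  d3 <- unlist(ax3[1, c("dx", "dy", "dz")])
  d4 <- unlist(ax3[2, c("dx", "dy", "dz")])
  expect_equal(sum(d3 * d4), 1, tolerance = 1e-6)
})

test_that("density profiles integrate to one and recover planted modes", {
  d <- density_profile(rep(2, 10), bin = 0.1)
  expect_equal(sum(d$density) * 0.1, 1, tolerance = 1e-6)
  expect_equal(sum(d$density > 0), 1)
  set.seed(9)
  z <- rnorm(1e5)
  dz <- density_profile(z, from = -4, to = 4, bin = 0.1)
  expect_equal(sum(dz$density) * 0.1, 1, tolerance = 1e-3)
  expect_lt(max(abs(dz$density - dnorm(dz$mid))), 0.02)
  bi <- c(rnorm(5e4, -3, 0.3), rnorm(5e4, 3, 0.3))
  db <- density_profile(bi, bin = 0.1)
  peaks <- db$mid[order(db$density, decreasing = TRUE)[1:2]]
  expect_lt(min(abs(sort(peaks) - c(-3, 3))), 0.1 + 1e-9)
  expect_error(density_profile(c(1)), ">= 2")
  expect_error(density_profile(c(1, 2), from = 1, to = 1), "zero-width")
})
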