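test_that("kNN density is flat on uniform points and tracks mixture populations", {
  set.seed(55)
  n <- 10000
  g <- as.matrix(expand.grid(seq(0, 1, length.out = 100),
                             seq(0, 1, length.out = 100)))
  dens <- knn_density(g, k = 100)
  ## away from edges the uniform law gives near-constant density
  interior <- g[, 1] > 0.15 & g[, 1] < 0.85 & g[, 2] > 0.15 & g[, 2] < 0.85
  expect_lt(max(dens[interior]) / min(dens[interior]), 1.3)
  ## two-Gaussian mixture: density ratio at the centres ~ population ratio
  lab <- sample(1:2, n, TRUE, prob = c(2 / 3, 1 / 3))
  pts <- matrix(rnorm(2 * n, sd = 0.5), ncol = 2)
  pts[lab == 2, 1] <- pts[lab == 2, 1] + 10
  at_centres <- knn_density(pts, k = 100,
                            eval_points = rbind(c(0, 0), c(10, 0)))
  expect_lt(abs(at_centres[1] / at_centres[2] - 2), 0.3)   # within 15%
  expect_error(knn_density(pts[1:50, ], k = 50), "more than k")
  dup <- rbind(matrix(0, 150, 2), matrix(rnorm(100), 50, 2))
  expect_warning(knn_density(dup, k = 100), "floored")
})

test_that("the landscape obeys the Boltzmann relation with a zero minimum and linear T scaling", {
  set.seed(77)
  pts <- matrix(rnorm(4000, sd = 0.8), ncol = 2)
  fes <- free_energy_landscape(pts, T = 310)
  expect_equal(min(fes$dG), 0)
  expect_equal(fes$kB * fes$T, 0.6160, tolerance = 1e-3)
  expect_true(all(fes$dG >= 0))
  expect_equal(sum(fes$dG == 0), 1)                  # unique global minimum
  ## dG = -kBT ln(P/Pmax) node by node
  expect_equal(fes$dG, -fes$kB * 310 * log(fes$P / fes$Pmax),
               tolerance = 1e-12)
  fes2 <- free_energy_landscape(pts, T = 620)
  expect_equal(fes2$dG, 2 * fes$dG, tolerance = 1e-9)
  expect_error(free_energy_landscape(pts[0, , drop = FALSE]), "empty")
  expect_error(free_energy_landscape(pts, T = -1), "positive")
})

test_that("well detection separates planted minima and merges shallow ones", {
  ## analytic two-well surface: sum of two inverted Gaussians
  g <- seq(-3, 3, length.out = 80)
  P1 <- outer(exp(-(g + 1.5)^2 / 0.18), exp(-g^2 / 0.18))
  P2 <- outer(exp(-(g - 1.5)^2 / 0.18), exp(-g^2 / 0.18))
  P <- 0.75 * P1 / sum(P1) + 0.25 * P2 / sum(P2)
  surf <- structure(list(R1 = g, R2 = g, P = P,
                         dG = -1.9872e-3 * 310 * log(P / max(P)),
                         Pmax = max(P), kB = 1.9872e-3, T = 310,
                         points = cbind(c(-1.5, 1.5), c(0, 0)),
                         source = c("a", "b")),
                    class = "FESurface")
  wells <- detect_wells(surf, min_barrier = 0.5)
  expect_equal(length(wells), 2)
  mins <- sort(vapply(wells, function(w) w$minimum[["R1"]], numeric(1)))
  spacing <- diff(g)[1]
  expect_lt(abs(mins[1] + 1.5), spacing + 1e-9)
  expect_lt(abs(mins[2] - 1.5), spacing + 1e-9)
  expect_equal(wells[[1]]$depth, 0)
  ## merge rule: barrier below threshold collapses to one well
  wells_merged <- detect_wells(surf, min_barrier = 100)
  expect_equal(length(wells_merged), 1)
  ## monotone bowl -> single well at the bottom
  Pb <- outer(exp(-g^2), exp(-g^2))
  bowl <- surf
  bowl$P <- Pb / sum(Pb); bowl$Pmax <- max(bowl$P)
  bowl$dG <- -1.9872e-3 * 310 * log(bowl$P / bowl$Pmax)
  wb <- detect_wells(bowl, min_barrier = 0.5)
  expect_equal(length(wb), 1)
  expect_lt(abs(wb[[1]]$minimum[["R1"]]), spacing)
})

test_that("well depths recover planted population ratios (Boltzmann inversion)", {
  deltas <- vapply(1:3, function(s) {
    set.seed(100 + s)
    n <- 6000
    lab <- sample(1:2, n, TRUE, prob = c(0.75, 0.25))
    pts <- matrix(rnorm(2 * n, sd = 1), ncol = 2)
    pts[lab == 2, 1] <- pts[lab == 2, 1] + 8
    fes <- free_energy_landscape(pts, T = 310)
    wells <- detect_wells(fes, min_barrier = 0.5)
    expect_equal(length(wells), 2)
    wells[[2]]$depth
  }, numeric(1))
  expect_lt(abs(mean(deltas) - 1.9872e-3 * 310 * log(3)), 0.1)
})

test_that("well composition decomposes by source with binomial accuracy", {
  set.seed(9)
  n <- 4000
  lab <- sample(1:2, n, TRUE, prob = c(0.5, 0.5))
  pts <- matrix(rnorm(2 * n, sd = 0.8), ncol = 2)
  pts[lab == 2, 1] <- pts[lab == 2, 1] + 8
  src <- ifelse(lab == 1, "WT", "MUT")
  ## single source: every well 100% that source
  fes1 <- free_energy_landscape(pts[lab == 1, ], T = 310)
  w1 <- detect_wells(fes1, 0.5)
  comp1 <- well_composition(w1, fes1$source)
  expect_true(all(comp1$percent == 100))
  ## two sources in disjoint wells
  fes <- free_energy_landscape(data.frame(PC1 = pts[, 1], PC2 = pts[, 2],
                                          source = src), T = 310)
  wells <- detect_wells(fes, 0.5)
  comp <- well_composition(wells, fes$source)
  for (w in unique(comp$well)) {
    expect_gte(max(comp$percent[comp$well == w]), 99)
  }
  ## 60/40 planted inside one well
  m <- 3000
  one <- matrix(rnorm(2 * m, sd = 0.5), ncol = 2)
  srcs <- sample(c("A", "B"), m, TRUE, prob = c(0.6, 0.4))
  fes2 <- free_energy_landscape(data.frame(PC1 = one[, 1], PC2 = one[, 2],
                                           source = srcs), T = 310)
  w2 <- detect_wells(fes2, 0.5)
  main <- which.max(vapply(w2, function(w) length(w$frames), numeric(1)))
  comp2 <- well_composition(w2, fes2$source)
  pa <- comp2$percent[comp2$well == w2[[main]]$label & comp2$source == "A"] / 100
  expect_lt(abs(pa - mean(srcs == "A")), 3 * sqrt(0.6 * 0.4 / m) + 0.02)
})
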