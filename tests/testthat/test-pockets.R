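test_that("planted spherical cavities are measured within 15% of the closed form", {
  sh <- plant_cavity_shell(3)
  cm <- cavity_map(sh$conformation, sh$topology)
  expect_lt(abs(cm$volume - sh$ground_truth$volume) / sh$ground_truth$volume,
            0.15)
  ## convex blob encloses nothing
  set.seed(2)
  at <- data.frame(serial = 1:20, name = "CB", element = "C", resid = 1:20,
                   resname = "ALA", chain = "A")
  blob <- as.vector(t(matrix(rnorm(60, sd = 1.5), ncol = 3)))
  expect_equal(cavity_map(blob, topology(at))$volume, 0)
  ## probe too large to fit between shell and centre -> nothing detected
  tiny <- plant_cavity_shell(2, probe = 1.4)
  expect_equal(cavity_map(tiny$conformation, tiny$topology, probe = 3.5)$volume, 0)
})

test_that("cavity volume is monotone non-increasing in probe radius", {
  sh <- plant_cavity_shell(3)
  vols <- vapply(c(1.0, 1.4, 1.8, 2.2), function(p)
    cavity_map(sh$conformation, sh$topology, probe = p)$volume, numeric(1))
  expect_true(all(diff(vols) <= 0))
})

test_that("cavity detection is invariant under rigid motion of structure and grid", {
  sh <- plant_cavity_shell(3)
  v1 <- cavity_map(sh$conformation, sh$topology)$volume
  R <- confens:::rotation_between(c(1, 0, 0), c(1, 1, 0) / sqrt(2))
  m <- matrix(sh$conformation, ncol = 3, byrow = TRUE) %*% t(R)
  m <- sweep(m, 2, c(30, -12, 5), `+`)
  v2 <- cavity_map(as.vector(t(m)), sh$topology)$volume
  expect_lt(abs(v1 - v2) / v1, 0.1)     # grid re-registration tolerance
})

test_that("frequency maps expose persistent pockets at the isovalue and label by volume", {
  sh <- plant_cavity_shell(3)
  top <- sh$topology
  open <- sh$conformation
  ## closed frame: shrink the shell until probe exclusion fills the interior
  closed <- as.vector(t(matrix(open, ncol = 3, byrow = TRUE) * 0.45))
  ## permanent cavity: present in every frame
  ens_perm <- ensemble(top, rbind(open, open, open, open, open))
  mp <- pocket_frequency_map(ens_perm, isovalue = 0.5)
  expect_equal(nrow(mp$pockets), 1)
  region_freq <- mp$frequency[mp$components == 1]
  expect_true(all(region_freq == 1))
  ## 40% occupancy: 2 open of 5 -> invisible at 0.5, visible at 0.3
  ens40 <- ensemble(top, rbind(open, open, closed, closed, closed))
  m05 <- pocket_frequency_map(ens40, isovalue = 0.5)
  expect_equal(nrow(m05$pockets), 0)
  m03 <- pocket_frequency_map(ens40, isovalue = 0.3)
  expect_gte(nrow(m03$pockets), 1)
  ## volume series: zero in closed frames, positive in open frames
  v <- pocket_volume_series(m03, "P1")
  expect_true(all(v[1:2] > 50))
  expect_true(all(v[3:5] == 0))
})

test_that("two disjoint cavities are labelled P1 (larger) then P2", {
  s_big <- plant_cavity_shell(3.5, center = c(0, 0, 0))
  s_small <- plant_cavity_shell(2.5, shell_atoms = 250, center = c(25, 0, 0))
  at <- rbind(s_big$topology$atoms, s_small$topology$atoms)
  at$serial <- seq_len(nrow(at)); at$resid <- seq_len(nrow(at))
  top <- topology(at)
  conf <- c(s_big$conformation, s_small$conformation)
  ens <- ensemble(top, rbind(conf, conf))
  mp <- pocket_frequency_map(ens, isovalue = 0.5)
  expect_equal(nrow(mp$pockets), 2)
  expect_gt(mp$pockets$mean_volume[1], mp$pockets$mean_volume[2])
  v1 <- mean(pocket_volume_series(mp, "P1"))
  v2 <- mean(pocket_volume_series(mp, "P2"))
  expect_lt(abs(v1 - 4 / 3 * pi * 3.5^3) / (4 / 3 * pi * 3.5^3), 0.15)
  expect_lt(abs(v2 - 4 / 3 * pi * 2.5^3) / (4 / 3 * pi * 2.5^3), 0.15)
})

test_that("lining residues, arginine orientation and hydrophobicity behave as defined", {
  sh <- plant_cavity_shell(3, resname = "ALA")
  cm <- cavity_map(sh$conformation, sh$topology)
  lr <- lining_residues(sh$conformation, sh$topology, cm$nodes_xyz,
                        cutoff = 4)
  ## every shell residue lines the spherical cavity
  expect_setequal(lr$residues$resid, sh$topology$atoms$resid)
  expect_equal(lr$n_arginine, 0)
  ## arginine pointing at / away from the centroid
  mk_arg <- function(flip) {
    at <- data.frame(serial = 1:2, name = c("CA", "CZ"), element = c("C", "C"),
                     resid = 1L, resname = "ARG", chain = "A")
    ca <- c(8, 0, 0)
    cz <- if (flip) c(12, 0, 0) else c(4, 0, 0)
    lining_residues(as.vector(t(rbind(ca, cz))), topology(at),
                    pocket_nodes = rbind(c(0, 0, 0), c(0.5, 0, 0)),
                    cutoff = 10)
  }
  inw <- mk_arg(FALSE)
  expect_equal(inw$n_arginine, 1)
  expect_true(inw$arginine$inward)
  expect_false(mk_arg(TRUE)$arginine$inward)
  ## hydrophobicity: scale extremes and exact mean
  expect_equal(as.numeric(hydrophobicity_score(rep("ILE", 4))), 4.5)
  expect_equal(as.numeric(hydrophobicity_score(rep("ARG", 3))), -4.5)
  expect_equal(as.numeric(hydrophobicity_score(c("ILE", "ARG"))), 0)
  expect_true(is.na(hydrophobicity_score(character(0))))
  expect_equal(attr(hydrophobicity_score("ALA"), "scale"), "Kyte-Doolittle")
})
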