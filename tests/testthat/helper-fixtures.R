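# Shared fixtures: all inputs are generated in code at test time.

toy_protein <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_two_domain_toy()
    cache
  }
})

# Minimal donor(N-H)...acceptor(O) triple with exact D...A distance and
# exact pseudo-valent angle at the H atom.
hbond_triple <- function(dDA, angle_deg) {
  at <- data.frame(serial = 1:3, name = c("N", "H", "O"),
                   element = c("N", "H", "O"),
                   resid = c(1L, 1L, 5L), resname = "GLY", chain = "A")
  top <- topology(at)
  N <- c(0, 0, 0); H <- c(1, 0, 0)
  th <- angle_deg * pi / 180
  ha <- cos(th) + sqrt(dDA^2 - sin(th)^2)   # law of cosines, |H-A|
  A <- H + ha * c(-cos(th), sin(th), 0)
  list(topology = top, conformation = as.vector(t(rbind(N, H, A))))
}

# Ensemble drawn from k wells planted on the toy loop, pairwise `sep`
# Angstrom apart (CA RMSD), with known populations.
planted_well_ensemble <- function(n_frames, seed, populations,
                                  sep = 8, spread = 0.5) {
  toy <- toy_protein()
  top <- toy$topology
  shifts <- list(c(0, 0, 0), c(sep, 0, 0), c(sep / 2, sep * sqrt(3) / 2, 0))
  k <- length(populations)
  stopifnot(k <= 3)
  wells <- lapply(seq_len(k), function(i)
    list(center = displace_region(toy$conformation, top, "L-loop", shifts[[i]]),
         population = populations[i], spread = spread))
  sm <- sample_mixture_ensemble(toy$conformation, top, wells, n_frames, seed,
                                selection = select_atoms(top, region = "L-loop"))
  sm$selection <- select_atoms(top, region = "L-loop", atom_names = "CA")
  sm
}

# Brute-force rotation-search RMSD oracle: coarse Euler grid refined to a
# 1-degree grid around the best coarse rotation.  Uses
# ||A R' - B||^2 = ||A||^2 + ||B||^2 - 2 tr(R H), H = A'B, so each grid is
# one matrix-vector product.
euler_rot <- function(a, b, c) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cc <- cos(c); sc <- sin(c)
  Rz1 <- matrix(c(ca, -sa, 0, sa, ca, 0, 0, 0, 1), 3, byrow = TRUE)
  Ry <- matrix(c(cb, 0, sb, 0, 1, 0, -sb, 0, cb), 3, byrow = TRUE)
  Rz2 <- matrix(c(cc, -sc, 0, sc, cc, 0, 0, 0, 1), 3, byrow = TRUE)
  Rz1 %*% Ry %*% Rz2
}

rotation_grid <- function(astep, arange = c(0, 2 * pi),
                          brange = c(0, pi), crange = c(0, 2 * pi)) {
  a <- seq(arange[1], arange[2], by = astep)
  b <- seq(brange[1], brange[2], by = astep)
  c <- seq(crange[1], crange[2], by = astep)
  g <- expand.grid(a = a, b = b, c = c)
  t(apply(g, 1, function(r) as.vector(euler_rot(r[1], r[2], r[3]))))
}

.coarse_grid <- NULL
brute_force_rmsd <- function(A, B) {
  # A, B: n x 3 coordinate matrices
  if (is.null(.coarse_grid))
    .coarse_grid <<- rotation_grid(6 * pi / 180)
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  H <- crossprod(Ac, Bc)
  const <- sum(Ac^2) + sum(Bc^2)
  tr_for <- function(G) G %*% as.vector(t(H))   # tr(R H) rowwise
  best <- function(G, angles) {
    tr <- tr_for(G)
    i <- which.max(tr)
    list(val = sqrt(pmax(0, const - 2 * tr[i]) / nrow(A)), i = i)
  }
  g <- expand.grid(a = seq(0, 2 * pi, by = 6 * pi / 180),
                   b = seq(0, pi, by = 6 * pi / 180),
                   c = seq(0, 2 * pi, by = 6 * pi / 180))
  b1 <- best(.coarse_grid)
  ctr <- as.numeric(g[b1$i, ])
  step <- pi / 180
  fine <- rotation_grid(step,
                        arange = ctr[1] + c(-6, 6) * step,
                        brange = pmin(pi, pmax(0, ctr[2] + c(-6, 6) * step)),
                        crange = ctr[3] + c(-6, 6) * step)
  tr <- fine %*% as.vector(t(H))
  sqrt(pmax(0, const - 2 * max(tr)) / nrow(A))
}
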