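## Canonical backbone internal coordinates (lengths in Angstrom, angles deg)
.bb_geom <- list(b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329,
                 b_c_o = 1.231, b_n_h = 1.010,
                 a_n_ca_c = 111.2, a_ca_c_n = 116.2, a_c_n_ca = 121.7,
                 a_ca_c_o = 120.8, omega = 180)

## Canonical helix dihedrals (phi, psi) in degrees
.helix_dihedrals <- list(alpha = c(-57, -47),
                         three_ten = c(-49, -26),
                         pi = c(-57, -70))

## Place atom D given A-B-C using bond length |CD|, angle B-C-D and
## dihedral A-B-C-D (NeRF construction).
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180; tor <- torsion * pi / 180
  bc <- c - b; bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d2 <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), -bond * sin(ang) * sin(tor))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

## dihedral angle (deg) of points a-b-c-d
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

## Build a backbone (N, H, CA, C, O per residue) from per-residue phi/psi.
## Returns list(atoms data.frame, coords N x 3 matrix).
build_backbone <- function(phi, psi, resnames = NULL, first_resid = 1,
                           chain = "A") {
  n <- length(phi)
  stopifnot(length(psi) == n)
  if (is.null(resnames)) resnames <- rep("ALA", n)
  resnames <- rep_len(resnames, n)
  g <- .bb_geom
  N <- CA <- C <- O <- H <- matrix(NA_real_, n, 3)
  ## seed residue 1 in the xy-plane
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(g$b_n_ca, 0, 0)
  ang <- g$a_n_ca_c * pi / 180
  C[1, ] <- CA[1, ] + g$b_ca_c * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n)) {
    if (i > 1) {
      ## N(i) placed by psi(i-1); CA(i) by omega; C(i) by phi(i)
      N[i, ] <- place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ],
                           g$b_c_n, g$a_ca_c_n, psi[i - 1])
      CA[i, ] <- place_atom(CA[i - 1, ], C[i - 1, ], N[i, ],
                            g$b_n_ca, g$a_c_n_ca, g$omega)
      C[i, ] <- place_atom(C[i - 1, ], N[i, ], CA[i, ],
                           g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    O[i, ] <- place_atom(N[i, ], CA[i, ], C[i, ],
                         g$b_c_o, g$a_ca_c_o, psi[i] + 180)
    if (i > 1) {
      ## amide H anti-bisecting C(prev)-N and CA-N
      u <- N[i, ] - C[i - 1, ]; u <- u / sqrt(sum(u^2))
      v <- N[i, ] - CA[i, ]; v <- v / sqrt(sum(v^2))
      w <- u + v; w <- w / sqrt(sum(w^2))
      H[i, ] <- N[i, ] + g$b_n_h * w
    } else {
      H[i, ] <- N[i, ] - g$b_n_h * (CA[i, ] - N[i, ]) / sqrt(sum((CA[i, ] - N[i, ])^2))
    }
  }
  names_per_res <- c("N", "H", "CA", "C", "O")
  atoms <- data.frame(
    serial = seq_len(5L * n),
    name = rep(names_per_res, n),
    element = rep(c("N", "H", "C", "C", "O"), n),
    resid = rep(first_resid + seq_len(n) - 1L, each = 5),
    resname = rep(resnames, each = 5),
    chain = chain,
    stringsAsFactors = FALSE)
  coords <- matrix(NA_real_, 5L * n, 3)
  for (i in seq_len(n)) {
    coords[5 * (i - 1) + 1:5, ] <- rbind(N[i, ], H[i, ], CA[i, ], C[i, ], O[i, ])
  }
  list(atoms = atoms, coords = coords)
}

#' Build an ideal helix
#'
#' Places backbone atoms (N, H, CA, C, O) from the canonical (phi, psi) of
#' the requested helix type: alpha (-57, -47), 3-10 (-49, -26),
#' pi (-57, -70).  Amide hydrogens are explicit so hydrogen-bond geometry
#' is computable downstream.
#'
#' @param n_residues number of residues (>= 4).
#' @param helix_type one of "alpha", "three_ten", "pi".
#' @param resnames residue names (default ALA).
#' @param first_resid first residue number.
#' @return list with `topology` ([Topology]) and `conformation` (flat xyz).
#' @export
build_ideal_helix <- function(n_residues, helix_type = c("alpha", "three_ten", "pi"),
                              resnames = "ALA", first_resid = 1) {
  helix_type <- match.arg(helix_type)
  if (n_residues < 4) stop("a helix needs >= 4 residues")
  dh <- .helix_dihedrals[[helix_type]]
  bb <- build_backbone(rep(dh[1], n_residues), rep(dh[2], n_residues),
                       resnames = resnames, first_resid = first_resid)
  list(topology = topology(bb$atoms),
       conformation = as_xyz_vector(bb$coords))
}

#' Build a two-domain toy protein
#'
#' A bundle of ideal alpha-helices (the stable "transmembrane" domain,
#' regions TM1, TM2, ...) plus an attached non-helical coil region
#' (region "L-loop") emulating an intrinsically disordered loop.  The loop
#' backbone uses smoothly varying non-helical dihedrals, so it assigns as
#' coil but remains compact.  Geometry is deterministic.
#'
#' @param stable_helices number of bundle helices (>= 1).
#' @param loop_length loop residues (>= 10).
#' @param helix_length residues per bundle helix.
#' @return list with `topology` and `conformation`; regions `TM1..TMk` and
#'   `L-loop` (and helix entry `H1-L` covering a short central loop stretch)
#'   are registered in the topology.
#' @export
build_two_domain_toy <- function(stable_helices = 4, loop_length = 45,
                                 helix_length = 18) {
  if (stable_helices < 1) stop("need >= 1 stable helix")
  if (loop_length < 10) stop("loop_length must be >= 10")
  dh <- .helix_dihedrals$alpha
  atoms <- NULL; coords <- NULL
  regions <- list()
  resid0 <- 1L
  ## helix bundle on a square lattice, alternating up/down
  spacing <- 10
  grid <- cbind(rep(c(0, 1), length.out = stable_helices) * spacing,
                floor((seq_len(stable_helices) - 1) / 2) * spacing)
  for (h in seq_len(stable_helices)) {
    bb <- build_backbone(rep(dh[1], helix_length), rep(dh[2], helix_length),
                         resnames = "LEU", first_resid = resid0)
    xyz <- bb$coords
    ## orient helix axis along z
    ca <- xyz[bb$atoms$name == "CA", ]
    axis <- ca[nrow(ca), ] - ca[1, ]; axis <- axis / sqrt(sum(axis^2))
    R <- rotation_between(axis, c(0, 0, (-1)^(h + 1)))
    xyz <- sweep(xyz, 2, colMeans(xyz)) %*% t(R)
    xyz <- sweep(xyz, 2, c(grid[h, 1], grid[h, 2], 0), `+`)
    atoms <- rbind(atoms, bb$atoms)
    coords <- rbind(coords, xyz)
    regions[[paste0("TM", h)]] <- c(resid0, resid0 + helix_length - 1L)
    resid0 <- resid0 + helix_length
    if (h == 1) {
      ## loop inserted after the first helix
      i <- seq_len(loop_length)
      phi <- -80 + 15 * sin(i / 2)
      psi <- 135 + 20 * cos(i / 3)
      loop_seq <- rep(c("SER", "ARG", "LEU", "ASP", "ALA", "GLY", "VAL",
                        "GLU", "THR"), length.out = loop_length)
      bb2 <- build_backbone(phi, psi, resnames = loop_seq, first_resid = resid0)
      xyz2 <- sweep(bb2$coords, 2, colMeans(bb2$coords))
      ## park the loop above the bundle
      xyz2 <- sweep(xyz2, 2, c(spacing / 2, spacing / 2,
                               helix_length * 1.5 / 2 + 12), `+`)
      atoms <- rbind(atoms, bb2$atoms)
      coords <- rbind(coords, xyz2)
      regions[["L-loop"]] <- c(resid0, resid0 + loop_length - 1L)
      resid0 <- resid0 + loop_length
    }
  }
  atoms$serial <- seq_len(nrow(atoms))
  loop_rng <- regions[["L-loop"]]
  mid <- floor((loop_rng[1] + loop_rng[2]) / 2)
  helices <- list("H1-L" = c(mid - 1L, mid + 2L))
  list(topology = topology(atoms, regions = regions, helices = helices),
       conformation = as_xyz_vector(coords))
}

## proper rotation taking unit vector a to unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
         a[1] * b[2] - a[2] * b[1])
  c_ <- sum(a * b)
  if (abs(c_ + 1) < 1e-12) {                    # antiparallel: rotate pi about
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- c(a[2] * p[3] - a[3] * p[2], a[3] * p[1] - a[1] * p[3],
           a[1] * p[2] - a[2] * p[1])
    v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

#' Displace a region of a conformation rigidly
#'
#' Convenience for constructing well centres: adds `delta` to every atom of
#' `region`.
#'
#' @param conformation flat xyz vector.
#' @param top matching [Topology].
#' @param region region name.
#' @param delta length-3 displacement (Angstrom).
#' @return flat xyz vector.
#' @export
displace_region <- function(conformation, top, region, delta) {
  sel <- select_atoms(top, region = region)
  m <- as_coord_matrix(conformation)
  m[sel, ] <- sweep(m[sel, , drop = FALSE], 2, delta, `+`)
  as_xyz_vector(m)
}

#' Sample an ensemble from a mixture of conformational wells
#'
#' Frames are drawn i.i.d. from a mixture of Gaussian wells: a well is
#' chosen with its stated population, then isotropic Gaussian noise of the
#' well's spread (per coordinate, Angstrom) is added to the well centre.
#' Only the atoms in `selection` are perturbed (default: all), emulating
#' quasi-independent domain dynamics (a mobile loop over a rigid scaffold).
#'
#' @param base flat xyz vector used for unperturbed atoms.
#' @param topology matching [Topology].
#' @param wells list of wells, each `list(center =, population =, spread =)`
#'   with `center` a flat xyz vector.
#' @param n_frames number of frames (>= number of wells).
#' @param seed integer RNG seed (same seed => identical ensemble).
#' @param selection atom indices to perturb (default all atoms).
#' @param stride frame interval in ps.
#' @param source source label for the frames.
#' @return list with `ensemble` ([Ensemble]) and `ground_truth`
#'   (`frame_labels`: the well index of every frame; `populations`).
#' @export
sample_mixture_ensemble <- function(base, topology, wells, n_frames, seed,
                                    selection = NULL, stride = 100,
                                    source = "protein") {
  pops <- vapply(wells, function(w) w$population, numeric(1))
  if (abs(sum(pops) - 1) > 1e-9) stop("well populations must sum to 1")
  if (any(vapply(wells, function(w) w$spread, numeric(1)) < 0))
    stop("well spread must be non-negative")
  if (n_frames < length(wells)) stop("n_frames < number of wells")
  if (is.null(selection)) selection <- seq_len(n_atoms(topology))
  ii <- xyz_index(selection)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  labels <- sample.int(length(wells), n_frames, replace = TRUE, prob = pops)
  xyz <- matrix(rep(base, n_frames), nrow = n_frames, byrow = TRUE)
  for (f in seq_len(n_frames)) {
    w <- wells[[labels[f]]]
    xyz[f, ii] <- w$center[ii] + rnorm(length(ii), sd = w$spread)
  }
  ens <- ensemble(topology, xyz, source = source, stride = stride)
  list(ensemble = ens,
       ground_truth = list(frame_labels = labels, populations = pops))
}

#' Plant a hollow spherical shell enclosing a cavity
#'
#' Carbon-bearing pseudo-residues are placed on a Fibonacci sphere of
#' radius `radius + vdW + probe`, so that the probe-excluded interior is a
#' cavity of (analytic) radius `radius` and volume `4/3 pi radius^3`.
#' Errors out if the shell is too sparse to seal (neighbouring shell atoms
#' no longer overlap at van der Waals range).
#'
#' @param radius interior cavity radius (Angstrom); must exceed
#'   `probe + spacing`.
#' @param shell_atoms number of shell atoms.
#' @param probe probe radius the downstream detector will use (default 1.4).
#' @param spacing downstream grid spacing (default 0.5).
#' @param resname residue name given to the shell pseudo-residues.
#' @param center cavity centre (length 3).
#' @return list with `topology`, `conformation` and `ground_truth`
#'   (`volume`, `center`, `radius`).
#' @export
plant_cavity_shell <- function(radius, shell_atoms = 300, probe = 1.4,
                               spacing = 0.5, resname = "ALA",
                               center = c(0, 0, 0)) {
  if (radius < probe + spacing)
    stop("radius must be >= probe radius + grid spacing")
  vdw <- .vdw_radii[["C"]]
  R <- radius + vdw + probe
  ## Fibonacci sphere
  i <- seq_len(shell_atoms) - 0.5
  phi <- acos(1 - 2 * i / shell_atoms)
  theta <- pi * (1 + sqrt(5)) * i
  pts <- R * cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  ## leak test: nearest-neighbour shell spacing must keep vdW spheres overlapping
  d2 <- as.matrix(dist(pts))
  diag(d2) <- Inf
  max_gap <- max(apply(d2, 1, min))
  if (max_gap > 2 * vdw)
    stop("shell too sparse to enclose the cavity (max neighbour gap ",
         round(max_gap, 2), " A > vdW diameter ", 2 * vdw,
         " A); increase shell_atoms")
  pts <- sweep(pts, 2, center, `+`)
  atoms <- data.frame(serial = seq_len(shell_atoms),
                      name = "CB", element = "C",
                      resid = seq_len(shell_atoms),
                      resname = resname, chain = "A",
                      stringsAsFactors = FALSE)
  list(topology = topology(atoms),
       conformation = as_xyz_vector(pts),
       ground_truth = list(volume = 4 / 3 * pi * radius^3,
                           center = center, radius = radius))
}
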