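#' Least-squares superposition of two conformations
#'
#' Kabsch algorithm: the rigid motion (proper rotation + translation)
#' minimising the RMSD between the selected atoms of `mobile` and
#' `reference`.  The fit is computed on the selection and applied to the
#' whole conformation.
#'
#' @param mobile,reference flat xyz coordinate vectors (same atom count).
#' @param selection integer atom indices used for the fit (>= 3,
#'   non-collinear); default all atoms.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3),
#'   `rmsd` (Angstrom, on the selection), and `fitted` (the transformed
#'   mobile conformation, flat xyz vector).
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  if (length(mobile) != length(reference))
    stop("coordinate vectors differ in length")
  n <- length(mobile) / 3
  if (is.null(selection)) selection <- seq_len(n)
  if (length(selection) < 3) stop("selection needs >= 3 atoms")
  A <- as_coord_matrix(mobile)[selection, , drop = FALSE]
  B <- as_coord_matrix(reference)[selection, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  if (qr(Ac)$rank < 2) stop("collinear (or degenerate) selection")
  H <- crossprod(Ac, Bc)                   # 3x3 covariance
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)   # maps mobile frame -> reference
  fitA <- Ac %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitA - Bc)^2)))
  M <- as_coord_matrix(mobile)
  fitted <- sweep(sweep(M, 2, ca) %*% t(R), 2, cb, `+`)
  list(rotation = R, translation = as.numeric(cb - R %*% ca),
       rmsd = rmsd, fitted = as_xyz_vector(fitted))
}

## RMSD between two flat xyz vectors on a selection, without fitting
coord_rmsd <- function(a, b, selection = NULL) {
  if (is.null(selection)) {
    d <- a - b
    sqrt(sum(d^2) / (length(a) / 3))
  } else {
    ii <- xyz_index(selection)
    d <- a[ii] - b[ii]
    sqrt(sum(d^2) / length(selection))
  }
}

#' Per-frame RMSD of an ensemble to a reference conformation
#'
#' Each frame is least-squares fitted to the reference on `selection`
#' before the deviation is measured (set `fit = FALSE` to measure raw
#' coordinate RMSD of already-superposed frames).
#'
#' @param ens an [Ensemble].
#' @param reference flat xyz vector (e.g. `get_frame(ens, 1)`).
#' @param selection atom indices; default all atoms.
#' @param fit logical, superpose each frame first (default TRUE).
#' @return numeric vector, one RMSD (Angstrom) per frame.
#' @export
rmsd_series <- function(ens, reference, selection = NULL, fit = TRUE) {
  nf <- n_frames(ens)
  if (fit) {
    vapply(seq_len(nf), function(i)
      superpose(ens$xyz[i, ], reference, selection)$rmsd, numeric(1))
  } else {
    sel <- if (is.null(selection)) seq_len(n_atoms(ens$topology)) else selection
    ii <- xyz_index(sel)
    D <- sweep(ens$xyz[, ii, drop = FALSE], 2, reference[ii])
    sqrt(rowSums(D^2) / length(sel))
  }
}

#' Fit every frame of an ensemble onto a reference conformation
#'
#' @param ens an [Ensemble].
#' @param reference flat xyz vector; default frame 1.
#' @param selection atom indices used for the fit.
#' @return the superposed [Ensemble].
#' @export
fit_ensemble <- function(ens, reference = NULL, selection = NULL) {
  if (is.null(reference)) reference <- get_frame(ens, 1)
  out <- ens
  for (i in seq_len(n_frames(ens)))
    out$xyz[i, ] <- superpose(ens$xyz[i, ], reference, selection)$fitted
  out
}

#' Root-mean-square fluctuation per atom
#'
#' Frames are superposed onto frame 1 on `selection`, then
#' `RMSF_i = sqrt(mean_t ||r_i(t) - <r_i>||^2)` about each selected atom's
#' ensemble-mean position.
#'
#' @param ens an [Ensemble].
#' @param selection atom indices (default all).
#' @param fit superpose internally first (default TRUE).
#' @param unbiased divide squared fluctuations by `n - 1` instead of `n`;
#'   with `unbiased = TRUE` the PCA eigenvalue sum equals `sum(rmsf^2)`
#'   exactly (both then use the sample covariance normalisation).
#' @return numeric vector, one value (Angstrom) per selected atom.
#' @export
rmsf <- function(ens, selection = NULL, fit = TRUE, unbiased = FALSE) {
  sel <- if (is.null(selection)) seq_len(n_atoms(ens$topology)) else selection
  if (n_frames(ens) < 2) {
    warning("single-frame ensemble: RMSF is identically zero")
    return(rep(0, length(sel)))
  }
  if (fit) ens <- fit_ensemble(ens, selection = sel)
  X <- ens$xyz[, xyz_index(sel), drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  msf <- colMeans(Xc^2)                    # per-coordinate variance
  if (unbiased) msf <- msf * nrow(X) / (nrow(X) - 1)
  per_atom <- matrix(msf, ncol = 3, byrow = TRUE)
  sqrt(rowSums(per_atom))
}

#' Radius of gyration
#'
#' Mass-weighted radius of gyration
#' `Rg = sqrt( sum_i m_i r_i^2 / sum_i m_i )` with `r_i` the distance of
#' atom i from the selection's centre of mass.  The default selection is
#' all non-hydrogen atoms.
#'
#' @param conformation flat xyz vector.
#' @param topology the matching [Topology] (supplies masses).
#' @param selection atom indices; default all heavy atoms.
#' @return Rg in Angstrom.
#' @export
radius_of_gyration <- function(conformation, topology, selection = NULL) {
  if (is.null(selection)) selection <- select_atoms(topology, heavy = TRUE)
  if (length(selection) == 0) stop("empty selection")
  m <- topology$atoms$mass[selection]
  X <- as_coord_matrix(conformation)[selection, , drop = FALSE]
  com <- colSums(X * m) / sum(m)
  Xc <- sweep(X, 2, com)
  sqrt(sum(m * rowSums(Xc^2)) / sum(m))
}

#' Per-frame radius of gyration over an ensemble
#' @inheritParams radius_of_gyration
#' @param ens an [Ensemble].
#' @return numeric vector, one Rg per frame.
#' @export
rg_series <- function(ens, selection = NULL) {
  vapply(seq_len(n_frames(ens)), function(i)
    radius_of_gyration(ens$xyz[i, ], ens$topology, selection), numeric(1))
}

#' Helix-axis drift over an ensemble
#'
#' The axis of a helix in each frame is the line connecting the C-alpha
#' atoms of its first and last residues, after superposing the frame onto a
#' projection frame.  Exported endpoints are elongated by 25% at each end
#' (50% total) for display; the stored direction is the unextended unit
#' vector.
#'
#' @param ens an [Ensemble].
#' @param helix length-2 residue range `c(first, last)` or the name of a
#'   helix registered in the topology.
#' @param projection_frame flat xyz vector all frames are fitted onto
#'   (default frame 1); the fit uses `fit_selection`.
#' @param fit_selection atom indices for the superposition (default all
#'   C-alpha atoms).
#' @param fit superpose frames onto the projection frame first (default
#'   TRUE; FALSE analyses raw per-frame axes, e.g. for pre-fitted data).
#' @return data.frame with one row per frame: raw and extended endpoints
#'   plus the unit direction (`dx`,`dy`,`dz`).
#' @export
helix_axis_drift <- function(ens, helix, projection_frame = NULL,
                             fit_selection = NULL, fit = TRUE) {
  top <- ens$topology
  if (is.character(helix)) {
    rng <- top$helices[[helix]]
    if (is.null(rng)) rng <- top$regions[[helix]]
    if (is.null(rng)) stop("unknown helix: ", helix)
    helix <- rng
  }
  i1 <- select_atoms(top, resid = helix[1], atom_names = "CA")
  i2 <- select_atoms(top, resid = helix[2], atom_names = "CA")
  if (length(i1) != 1 || length(i2) != 1)
    stop("helix range must have a single CA at each end")
  if (is.null(projection_frame)) projection_frame <- get_frame(ens, 1)
  if (is.null(fit_selection)) fit_selection <- select_atoms(top, atom_names = "CA")
  rows <- lapply(seq_len(n_frames(ens)), function(f) {
    xyz <- if (fit) superpose(ens$xyz[f, ], projection_frame, fit_selection)$fitted
           else ens$xyz[f, ]
    m <- as_coord_matrix(xyz)
    a <- m[i1, ]; b <- m[i2, ]
    v <- b - a
    len <- sqrt(sum(v^2))
    if (len < 1e-6) {
      warning("coincident helix endpoints in frame ", f, "; skipped")
      return(NULL)
    }
    u <- v / len
    ea <- a - 0.25 * v; eb <- b + 0.25 * v   # +50% total length, display only
    data.frame(frame = f, time = ens$time[f],
               x1 = a[1], y1 = a[2], z1 = a[3],
               x2 = b[1], y2 = b[2], z2 = b[3],
               ex1 = ea[1], ey1 = ea[2], ez1 = ea[3],
               ex2 = eb[1], ey2 = eb[2], ez2 = eb[3],
               dx = u[1], dy = u[2], dz = u[3])
  })
  do.call(rbind, rows)
}

#' Normalised probability density of a scalar series
#'
#' Fixed-width histogram density: deterministic, integrates to 1 over the
#' grid (`sum(density) * bin == 1`).
#'
#' @param values numeric vector (>= 2 values).
#' @param from,to grid range; default data range padded by one bin.
#' @param bin bin width (default 0.1, in the units of `values`).
#' @return data.frame with bin `mid` points and `density`.
#' @export
density_profile <- function(values, from = NULL, to = NULL, bin = 0.1) {
  if (length(values) < 2) stop(">= 2 values required")
  if (bin <= 0) stop("bin width must be positive")
  if (is.null(from)) from <- min(values) - bin
  if (is.null(to)) to <- max(values) + bin
  if (to <= from) stop("zero-width grid")
  breaks <- seq(from, to + bin, by = bin)
  values <- values[values >= from & values <= to]  # off-grid values dropped
  if (!length(values)) stop("no values on the grid")
  h <- hist(values, breaks = breaks, plot = FALSE, right = FALSE)
  data.frame(mid = h$mids, density = h$counts / (length(values) * bin))
}
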