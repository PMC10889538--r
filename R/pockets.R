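## Kyte-Doolittle hydropathy scale (max ILE 4.5, min ARG -4.5)
.kyte_doolittle <- c(ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5,
                     MET = 1.9, ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8,
                     TRP = -0.9, TYR = -1.3, PRO = -1.6, HIS = -3.2,
                     GLU = -3.5, GLN = -3.5, ASP = -3.5, ASN = -3.5,
                     LYS = -3.9, ARG = -4.5)

## 14 burial-ray directions: 6 axes + 8 cube diagonals
.burial_rays <- {
  ax <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
              c(0, 0, 1), c(0, 0, -1))
  dg <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) / sqrt(3)
  unname(rbind(ax, dg))
}

## shared grid definition over a coordinate bounding box
.make_grid <- function(coord_min, coord_max, spacing, margin) {
  origin <- coord_min - margin
  dims <- pmax(2L, as.integer(ceiling((coord_max + margin - origin) / spacing)) + 1L)
  list(origin = origin, dims = dims, spacing = spacing)
}

## occupancy array: TRUE where a grid node lies within radius[i] of atom i
.occupancy <- function(grid, coords, radii) {
  occ <- array(FALSE, grid$dims)
  sp <- grid$spacing
  for (a in seq_len(nrow(coords))) {
    r <- radii[a]
    lo <- pmax(1L, as.integer(floor((coords[a, ] - r - grid$origin) / sp)) + 1L)
    hi <- pmin(grid$dims, as.integer(ceiling((coords[a, ] + r - grid$origin) / sp)) + 1L)
    if (any(lo > hi)) next
    xs <- grid$origin[1] + (lo[1]:hi[1] - 1) * sp
    ys <- grid$origin[2] + (lo[2]:hi[2] - 1) * sp
    zs <- grid$origin[3] + (lo[3]:hi[3] - 1) * sp
    dx2 <- (xs - coords[a, 1])^2
    dy2 <- (ys - coords[a, 2])^2
    dz2 <- (zs - coords[a, 3])^2
    within <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r^2
    occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] | within
  }
  occ
}

#' Grid-based cavity detection for one conformation
#'
#' A node of a regular grid over the structure is a cavity node iff
#' (a) it lies farther than `vdW + probe` from every atom centre, and
#' (b) it is buried: at least `n_hits` of `m_rays` evenly spread rays from
#' the node intersect the protein (enter an atom's van der Waals sphere)
#' within `ray_length`.  Deterministic alternative to alpha-sphere pocket
#' detectors: volumes, frequency maps and lining residues are comparable
#' in kind, not numerically identical, to those tools.
#'
#' @param conformation flat xyz vector.
#' @param top matching [Topology] (elements give vdW radii: C 1.70, N 1.55,
#'   O 1.52, S 1.80, H 1.20 A).
#' @param spacing grid spacing in Angstrom (default 0.5).
#' @param probe probe radius (default 1.4 A).
#' @param m_rays,n_hits burial criterion (default 14 rays, 9 hits).
#' @param ray_length burial search range (default 15 A).
#' @param grid optional precomputed grid (for ensemble comparability).
#' @return list of class `CavityMap`: `grid`, logical `cavity` array,
#'   `volume` (A^3), `nodes_xyz` (cavity node coordinates).
#' @export
cavity_map <- function(conformation, top, spacing = 0.5, probe = 1.4,
                       m_rays = 14, n_hits = 9, ray_length = 15,
                       grid = NULL) {
  m <- as_coord_matrix(conformation)
  if (nrow(m) == 0) stop("empty structure")
  vdw <- .vdw_radii[top$atoms$element]
  vdw[is.na(vdw)] <- 1.7
  if (is.null(grid))
    grid <- .make_grid(apply(m, 2, min), apply(m, 2, max), spacing,
                       margin = max(vdw) + probe + spacing)
  occ_vdw <- .occupancy(grid, m, vdw)
  occ_excl <- .occupancy(grid, m, vdw + probe)
  cand <- which(!occ_excl)
  if (!length(cand)) {
    return(structure(list(grid = grid, cavity = array(FALSE, grid$dims),
                          volume = 0, nodes_xyz = matrix(0, 0, 3)),
                     class = "CavityMap"))
  }
  d <- grid$dims
  ijk <- cbind((cand - 1L) %% d[1],
               ((cand - 1L) %/% d[1]) %% d[2],
               (cand - 1L) %/% (d[1] * d[2]))    # 0-based
  sp <- grid$spacing
  steps <- seq_len(floor(ray_length / sp))
  rays <- .burial_rays[seq_len(min(m_rays, nrow(.burial_rays))), , drop = FALSE]
  hits <- matrix(FALSE, length(cand), nrow(rays))
  for (r in seq_len(nrow(rays))) {
    hit <- rep(FALSE, length(cand))
    for (s in steps) {
      off <- round(rays[r, ] * s)                # node offset in grid units
      ii <- ijk[, 1] + off[1]; jj <- ijk[, 2] + off[2]; kk <- ijk[, 3] + off[3]
      ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3]
      lin <- 1L + ii + jj * d[1] + kk * d[1] * d[2]
      upd <- ok & !hit
      if (any(upd)) hit[upd] <- occ_vdw[lin[upd]]
    }
    hits[, r] <- hit
  }
  buried <- rowSums(hits) >= n_hits
  cavity <- array(FALSE, d)
  cavity[cand[buried]] <- TRUE
  nodes_xyz <- cbind(grid$origin[1] + ijk[buried, 1] * sp,
                     grid$origin[2] + ijk[buried, 2] * sp,
                     grid$origin[3] + ijk[buried, 3] * sp)
  structure(list(grid = grid, cavity = cavity,
                 volume = sum(cavity) * sp^3,
                 nodes_xyz = nodes_xyz),
            class = "CavityMap")
}

#' @export
print.CavityMap <- function(x, ...) {
  cat("Cavity map:", sum(x$cavity), "nodes, volume",
      sprintf("%.1f A^3", x$volume), "\n")
  invisible(x)
}

## 26-connectivity components of a logical 3D array; returns integer array
.connected_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nodes <- which(mask)
  if (!length(nodes)) return(lab)
  nxt <- 1L
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  for (start in nodes) {
    if (lab[start] != 0L) next
    lab[start] <- nxt
    queue <- start
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      i <- (cur - 1L) %% d[1]; j <- ((cur - 1L) %/% d[1]) %% d[2]
      k <- (cur - 1L) %/% (d[1] * d[2])
      ii <- i + offs[, 1]; jj <- j + offs[, 2]; kk <- k + offs[, 3]
      ok <- ii >= 0 & ii < d[1] & jj >= 0 & jj < d[2] & kk >= 0 & kk < d[3]
      lin <- 1L + ii[ok] + jj[ok] * d[1] + kk[ok] * d[1] * d[2]
      new <- lin[mask[lin] & lab[lin] == 0L]
      if (length(new)) {
        lab[new] <- nxt
        queue <- c(queue, new)
      }
    }
    nxt <- nxt + 1L
  }
  lab
}

#' Ensemble pocket-frequency map
#'
#' Computes a cavity map per frame on one shared grid (frames must be
#' superposed to a common reference beforehand), takes the per-node
#' frequency (fraction of frames in which the node is cavity), thresholds
#' it at `isovalue`, and labels 26-connected components P1, P2, ... by
#' decreasing mean per-frame volume.
#'
#' @param ens a superposed [Ensemble].
#' @param isovalue frequency threshold (default 0.5).
#' @param ... passed to [cavity_map()].
#' @return list of class `PocketMap`: `grid`, `frequency` array,
#'   `isovalue`, `components` (integer array, 0 = none), `pockets`
#'   (data.frame label/nodes/mean_volume), `per_frame` (list of per-frame
#'   cavity arrays).
#' @export
pocket_frequency_map <- function(ens, isovalue = 0.5, ...) {
  nf <- n_frames(ens)
  allm <- as_coord_matrix(as.vector(t(ens$xyz)))
  grid <- NULL
  freq <- NULL
  maps <- vector("list", nf)
  dots <- list(...)
  spacing <- if (!is.null(dots$spacing)) dots$spacing else 0.5
  probe <- if (!is.null(dots$probe)) dots$probe else 1.4
  grid <- .make_grid(apply(allm, 2, min), apply(allm, 2, max), spacing,
                     margin = 1.9 + probe + spacing)
  for (f in seq_len(nf)) {
    maps[[f]] <- cavity_map(ens$xyz[f, ], ens$topology, grid = grid, ...)
    freq <- if (is.null(freq)) maps[[f]]$cavity + 0 else freq + maps[[f]]$cavity
  }
  freq <- freq / nf
  mask <- freq >= isovalue
  comp <- .connected_components(mask)
  ncomp <- max(comp)
  if (ncomp > 0) {
    mean_vol <- vapply(seq_len(ncomp), function(cc) {
      region <- comp == cc
      mean(vapply(maps, function(mp) sum(mp$cavity & region), numeric(1))) *
        grid$spacing^3
    }, numeric(1))
    ord <- order(mean_vol, decreasing = TRUE)
    relab <- array(0L, dim(comp))
    for (r in seq_along(ord)) relab[comp == ord[r]] <- r
    comp <- relab
    pockets <- data.frame(label = paste0("P", seq_along(ord)),
                          nodes = vapply(seq_along(ord), function(r)
                            sum(comp == r), integer(1)),
                          mean_volume = mean_vol[ord])
  } else {
    pockets <- data.frame(label = character(), nodes = integer(),
                          mean_volume = numeric())
  }
  structure(list(grid = grid, frequency = freq, isovalue = isovalue,
                 components = comp, pockets = pockets, per_frame = maps),
            class = "PocketMap")
}

#' @export
print.PocketMap <- function(x, ...) {
  cat("Pocket map (isovalue", x$isovalue, "):", nrow(x$pockets), "pocket(s)\n")
  if (nrow(x$pockets))
    print(x$pockets, row.names = FALSE)
  invisible(x)
}

#' Per-frame volume series of one pocket
#'
#' Volume of the frame's cavity nodes falling inside the pocket's grid
#' region; zero when the (transient) pocket is closed in a frame.
#'
#' @param map a `PocketMap`.
#' @param pocket pocket label (e.g. "P1") or component number.
#' @return numeric vector, one volume (A^3) per frame.
#' @export
pocket_volume_series <- function(map, pocket = "P1") {
  cc <- if (is.character(pocket)) match(pocket, map$pockets$label)
        else as.integer(pocket)
  if (is.na(cc)) stop("unknown pocket: ", pocket)
  region <- map$components == cc
  vapply(map$per_frame, function(mp) sum(mp$cavity & region), numeric(1)) *
    map$grid$spacing^3
}

#' Residues lining a pocket
#'
#' Residues with at least one heavy atom within `cutoff` of a pocket node,
#' with an arginine count and a per-arginine orientation flag: an arginine
#' points inward iff its CA -> CZ vector has positive projection on
#' CA -> pocket centroid.
#'
#' @param conformation flat xyz vector.
#' @param top matching [Topology].
#' @param pocket_nodes matrix of pocket node coordinates (e.g.
#'   `cavity_map(...)$nodes_xyz`).
#' @param cutoff distance cutoff (default 4 A).
#' @return list: `residues` (data.frame resid/resname/min_distance),
#'   `n_arginine`, `arginine` (data.frame resid/inward).
#' @export
lining_residues <- function(conformation, top, pocket_nodes, cutoff = 4) {
  if (is.null(dim(pocket_nodes)) || nrow(pocket_nodes) == 0)
    return(list(residues = data.frame(), n_arginine = 0L,
                arginine = data.frame()))
  m <- as_coord_matrix(conformation)
  at <- top$atoms
  heavy <- which(at$element != "H")
  H <- m[heavy, , drop = FALSE]
  D2 <- outer(rowSums(H^2), rowSums(pocket_nodes^2), `+`) -
    2 * H %*% t(pocket_nodes)
  mind <- sqrt(pmax(0, apply(D2, 1, min)))
  near <- mind <= cutoff
  resn <- at$resid[heavy]
  lining <- sort(unique(resn[near]))
  if (!length(lining))
    return(list(residues = data.frame(), n_arginine = 0L,
                arginine = data.frame()))
  rows <- data.frame(
    resid = lining,
    resname = vapply(lining, function(r) at$resname[at$resid == r][1], ""),
    min_distance = vapply(lining, function(r) min(mind[resn == r]), 0))
  centroid <- colMeans(pocket_nodes)
  args <- rows$resid[rows$resname == "ARG"]
  arg_rows <- lapply(args, function(r) {
    ca <- which(at$resid == r & at$name == "CA")
    cz <- which(at$resid == r & at$name == "CZ")
    if (!length(ca) || !length(cz)) return(NULL)
    v1 <- m[cz[1], ] - m[ca[1], ]
    v2 <- centroid - m[ca[1], ]
    data.frame(resid = r, inward = sum(v1 * v2) > 0)
  })
  arg_df <- do.call(rbind, arg_rows)
  if (is.null(arg_df)) arg_df <- data.frame()
  list(residues = rows, n_arginine = length(args), arginine = arg_df)
}

#' Mean hydrophobicity of a lining residue set
#'
#' Arithmetic mean of the Kyte-Doolittle hydropathy values of the lining
#' residues (scale: ILE 4.5 most hydrophobic ... ARG -4.5 least).  The
#' scale name is recorded as an attribute.
#'
#' @param resnames character vector of 3-letter residue codes (non-empty).
#' @return numeric score with attribute `scale = "Kyte-Doolittle"`; NA
#'   (missing) for an empty input.
#' @export
hydrophobicity_score <- function(resnames) {
  if (!length(resnames)) return(structure(NA_real_, scale = "Kyte-Doolittle"))
  vals <- .kyte_doolittle[toupper(resnames)]
  structure(mean(vals, na.rm = TRUE), scale = "Kyte-Doolittle")
}
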