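## Boltzmann constant in kcal/(mol K)
.kB <- 1.9872e-3

#' k-nearest-neighbour density estimate in 2D
#'
#' Density at an evaluation point x is proportional to
#' `k / (n * pi * d_k(x)^2)` with `d_k` the distance to the k-th nearest
#' sample point; the values are normalised to sum to 1 over the
#' evaluation points.  Vanishing `d_k` (duplicated points) is floored.
#'
#' @param points n x 2 matrix of sample points (n >= k + 1).
#' @param k neighbour count.
#' @param eval_points m x 2 matrix where the density is evaluated
#'   (default: the sample points themselves).
#' @param floor_d lower bound on `d_k` (default 0; a warning is issued and
#'   the spacing/10 floor applied when duplicates collapse `d_k` to 0).
#' @return numeric vector of probabilities summing to 1 over `eval_points`.
#' @export
knn_density <- function(points, k, eval_points = points, floor_d = 0) {
  points <- as.matrix(points); eval_points <- as.matrix(eval_points)
  n <- nrow(points)
  if (n < k + 1) stop("need more than k sample points")
  m <- nrow(eval_points)
  dk <- numeric(m)
  self <- identical(dim(points), dim(eval_points)) &&
    isTRUE(all.equal(points, eval_points))
  chunk <- max(1L, floor(2e6 / n))
  px2 <- rowSums(points^2)
  for (s in seq(1, m, by = chunk)) {
    idx <- s:min(m, s + chunk - 1)
    E <- eval_points[idx, , drop = FALSE]
    D2 <- outer(rowSums(E^2), px2, `+`) - 2 * E %*% t(points)
    D2[D2 < 0] <- 0
    kk <- if (self) k + 1L else k       # skip the point itself
    dk[idx] <- sqrt(apply(D2, 1, function(r) sort.int(r, partial = kk)[kk]))
  }
  if (any(dk <= 0)) {
    if (floor_d <= 0) {
      rng <- apply(points, 2, function(z) diff(range(z)))
      floor_d <- max(max(rng) / 1000, 1e-8)
    }
    warning("duplicate points: k-th neighbour distance floored at ",
            signif(floor_d, 3))
    dk <- pmax(dk, floor_d)
  }
  dens <- k / (n * pi * dk^2)
  dens / sum(dens)
}

#' Free-energy landscape on two reaction coordinates
#'
#' Relative Gibbs free energy `dG(R1,R2) = -kB T ln(P(R1,R2) / Pmax)` on a
#' regular grid over the first two projection coordinates, with the state
#' probability P estimated by the k-nearest-neighbour scheme.  The global
#' minimum is exactly 0 (at the maximum-probability node).
#'
#' @param projections data.frame from [project_ensemble()] (columns PC1,
#'   PC2, optionally `source`), or an n x 2 matrix.
#' @param T temperature in K (default 310).
#' @param k kNN parameter; default `ceiling(sqrt(n))`.
#' @param grid_size nodes per axis (default 100).
#' @param margin fractional range padding (default 0.05).
#' @return list of class `FESurface`: grid axes `R1`, `R2`, matrices `P`
#'   and `dG` (kcal/mol), `Pmax`, `kB`, `T`, `k`, the input `points` and
#'   per-point `source` labels.
#' @export
free_energy_landscape <- function(projections, T = 310, k = NULL,
                                  grid_size = 100, margin = 0.05) {
  if (T <= 0) stop("temperature must be positive")
  if (is.data.frame(projections)) {
    pts <- as.matrix(projections[, c("PC1", "PC2")])
    src <- if ("source" %in% names(projections)) projections$source
           else rep("all", nrow(pts))
  } else {
    pts <- as.matrix(projections)[, 1:2, drop = FALSE]
    src <- rep("all", nrow(pts))
  }
  n <- nrow(pts)
  if (n == 0) stop("empty projections")
  if (is.null(k)) k <- ceiling(sqrt(n))
  pad <- function(z) {
    r <- range(z); w <- diff(r)
    if (w == 0) w <- 1
    c(r[1] - margin * w, r[2] + margin * w)
  }
  rx <- pad(pts[, 1]); ry <- pad(pts[, 2])
  R1 <- seq(rx[1], rx[2], length.out = grid_size)
  R2 <- seq(ry[1], ry[2], length.out = grid_size)
  nodes <- cbind(rep(R1, times = grid_size), rep(R2, each = grid_size))
  P <- knn_density(pts, k, eval_points = nodes,
                   floor_d = min(diff(R1)[1], diff(R2)[1]) / 10)
  Pm <- matrix(P, grid_size, grid_size)      # [R1 index, R2 index]
  Pmax <- max(Pm)
  dG <- -.kB * T * log(Pm / Pmax)
  structure(list(R1 = R1, R2 = R2, P = Pm, dG = dG, Pmax = Pmax,
                 kB = .kB, T = T, k = k, points = pts, source = src),
            class = "FESurface")
}

#' @export
print.FESurface <- function(x, ...) {
  cat("Free-energy surface:", length(x$R1), "x", length(x$R2),
      "grid, T =", x$T, "K, k =", x$k, "\n")
  cat("  dG range: 0 -", sprintf("%.2f kcal/mol", max(x$dG[is.finite(x$dG)])), "\n")
  invisible(x)
}

#' Detect wells on a free-energy surface
#'
#' Persistence watershed on the grid: nodes are flooded in order of
#' increasing dG, growing basins from local minima; when two basins meet,
#' the shallower one is merged into the deeper if its barrier (meeting
#' level minus its minimum) is below `min_barrier`.  Wells are labelled
#' W1, W2, ... by increasing minimum dG (so W1 has depth 0 relative to the
#' landscape minimum), and ensemble frames are attributed to the basin of
#' their nearest grid node.
#'
#' @param surface a `FESurface`.
#' @param min_barrier merge threshold in kcal/mol (default 0.5).
#' @param max_dG ignore nodes above this level (default: all finite).
#' @return list of `Well`s: each has `label`, `minimum` (R1, R2), `depth`
#'   (kcal/mol above the global minimum), `frames` (indices of member
#'   points) and `nodes` (grid node indices); plus a `basin` matrix.
#' @export
detect_wells <- function(surface, min_barrier = 0.5, max_dG = Inf) {
  g <- surface$dG
  n1 <- nrow(g); n2 <- ncol(g)
  ord <- order(g)                         # ascending dG
  basin <- matrix(0L, n1, n2)
  parent <- integer(0)                    # union-find over basins
  minval <- numeric(0)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  neighbours <- function(i, j) {
    di <- rep(-1:1, times = 3); dj <- rep(-1:1, each = 3)
    ii <- i + di; jj <- j + dj
    ok <- ii >= 1 & ii <= n1 & jj >= 1 & jj <= n2 & !(di == 0 & dj == 0)
    cbind(ii[ok], jj[ok])
  }
  for (lin in ord) {
    val <- g[lin]
    if (!is.finite(val) || val > max_dG) next
    i <- (lin - 1) %% n1 + 1; j <- (lin - 1) %/% n1 + 1
    nb <- neighbours(i, j)
    labs <- unique(basin[nb])
    labs <- labs[labs > 0]
    labs <- unique(vapply(labs, find, integer(1)))
    if (length(labs) == 0) {
      parent <- c(parent, length(parent) + 1L)
      minval <- c(minval, val)
      basin[i, j] <- length(parent)
    } else if (length(labs) == 1) {
      basin[i, j] <- labs
    } else {
      ## meeting point: merge basins whose barrier is below threshold
      deepest <- labs[which.min(minval[labs])]
      for (b in setdiff(labs, deepest)) {
        if (val - minval[b] < min_barrier) parent[b] <- deepest
      }
      basin[i, j] <- find(deepest)
    }
  }
  if (!length(parent)) stop("no finite nodes on the surface")
  basin_final <- basin
  pos <- basin > 0
  basin_final[pos] <- vapply(basin[pos], find, integer(1))
  roots <- sort(unique(basin_final[basin_final > 0]))
  depth_min <- vapply(roots, function(r) min(g[basin_final == r]), numeric(1))
  ord2 <- order(depth_min)
  wells <- lapply(seq_along(ord2), function(w) {
    r <- roots[ord2[w]]
    nodes <- which(basin_final == r)
    mnode <- nodes[which.min(g[nodes])]
    mi <- (mnode - 1) %% n1 + 1; mj <- (mnode - 1) %/% n1 + 1
    list(label = paste0("W", w),
         minimum = c(R1 = surface$R1[mi], R2 = surface$R2[mj]),
         depth = g[mnode] - min(g[is.finite(g)]),
         nodes = nodes, frames = integer(0))
  })
  ## attribute sample points to basins via the nearest node
  bi <- findInterval(surface$points[, 1],
                     surface$R1 + c(diff(surface$R1) / 2, Inf)) + 1L
  bj <- findInterval(surface$points[, 2],
                     surface$R2 + c(diff(surface$R2) / 2, Inf)) + 1L
  bi <- pmin(pmax(bi, 1L), n1); bj <- pmin(pmax(bj, 1L), n2)
  plab <- basin_final[cbind(bi, bj)]
  for (w in seq_along(wells)) {
    r <- roots[ord2[w]]
    wells[[w]]$frames <- which(plab == r)
  }
  attr(wells, "basin") <- basin_final
  class(wells) <- "WellList"
  wells
}

#' @export
print.WellList <- function(x, ...) {
  for (w in x)
    cat(w$label, ": depth", sprintf("%.3f kcal/mol,", w$depth),
        length(w$frames), "frames\n")
  invisible(x)
}

#' Per-well source composition
#'
#' For each well, the percentage of member frames contributed by every
#' source label; the majority source is flagged.
#'
#' @param wells a `WellList` from [detect_wells()].
#' @param source per-point source labels (default: taken from the surface
#'   stored with the wells' frames indices — pass `surface$source`).
#' @return data.frame: well, source, percent, majority.
#' @export
well_composition <- function(wells, source) {
  rows <- list()
  for (w in wells) {
    if (!length(w$frames)) {
      warning("well ", w$label, " has no member frames; omitted")
      next
    }
    tab <- 100 * table(source[w$frames]) / length(w$frames)
    rows[[length(rows) + 1]] <- data.frame(
      well = w$label, source = names(tab), percent = as.numeric(tab),
      majority = as.numeric(tab) == max(as.numeric(tab)),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
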