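## Reduced 5-letter secondary-structure alphabet
.ss_reduce_map <- c(H = "alpha", G = "three_ten", I = "pi", E = "strand",
                    B = "none", T = "none", S = "none", C = "none")

#' Assign per-residue secondary structure (DSSP-style)
#'
#' Re-implementation of the Kabsch-Sander assignment on backbone geometry:
#' the electrostatic H-bond energy
#' `E = 0.084 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN) * 332` kcal/mol defines
#' a backbone H-bond when `E < -0.5`; n-turn patterns (i -> i+3/4/5) yield
#' G/H/I helices (two consecutive turns required), bridge patterns yield
#' E/B strands, remaining turns/bends give T/S, else C.  Missing amide
#' hydrogens are reconstructed 1.01 A from N, anti-bisecting the
#' C(prev)-N and CA-N directions.  Chain breaks (consecutive CA > 4.5 A)
#' split the assignment into independent segments.
#'
#' @param conformation flat xyz vector.
#' @param top matching [Topology] (backbone N, CA, C, O required).
#' @return character vector of full-alphabet letters
#'   (H,G,I,E,B,T,S,C), one per residue, named by residue number.
#' @export
assign_secondary_structure <- function(conformation, top) {
  at <- top$atoms
  m <- as_coord_matrix(conformation)
  resids <- unique(at$resid)
  n <- length(resids)
  idx_of <- function(r, nm) {
    i <- which(at$resid == r & at$name == nm)
    if (length(i)) i[1] else NA_integer_
  }
  Ni <- vapply(resids, idx_of, integer(1), nm = "N")
  CAi <- vapply(resids, idx_of, integer(1), nm = "CA")
  Ci <- vapply(resids, idx_of, integer(1), nm = "C")
  Oi <- vapply(resids, idx_of, integer(1), nm = "O")
  Hi <- vapply(resids, idx_of, integer(1), nm = "H")
  if (anyNA(Ni) || anyNA(CAi) || anyNA(Ci) || anyNA(Oi))
    stop("backbone N, CA, C, O required for every residue")
  if (n < 3) {
    ss <- rep("C", n); names(ss) <- resids
    return(ss)
  }
  ## chain segmentation on CA-CA distance / numbering gaps
  seg <- integer(n); seg[1] <- 1L
  for (i in 2:max(2, n)) {
    gap <- resids[i] != resids[i - 1] + 1
    dca <- sqrt(sum((m[CAi[i], ] - m[CAi[i - 1], ])^2))
    seg[i] <- if (gap || dca > 4.5) seg[i - 1] + 1L else seg[i - 1]
  }
  ## amide H: explicit if present, else reconstructed (first residue of a
  ## segment and prolines have no donor)
  Hpos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (i > 1 && seg[i] == seg[i - 1] && at$resname[Ni[i]] != "PRO") {
      if (!is.na(Hi[i])) {
        Hpos[i, ] <- m[Hi[i], ]
      } else {
        u <- m[Ni[i], ] - m[Ci[i - 1], ]; u <- u / sqrt(sum(u^2))
        v <- m[Ni[i], ] - m[CAi[i], ]; v <- v / sqrt(sum(v^2))
        w <- u + v; w <- w / sqrt(sum(w^2))
        Hpos[i, ] <- m[Ni[i], ] + 1.01 * w
      }
    }
  }
  ## Kabsch-Sander H-bond energies: hb[i, j] TRUE if CO(i) accepts NH(j)
  hb <- matrix(FALSE, n, n)
  q <- 0.084 * 332
  for (j in seq_len(n)) {
    if (any(is.na(Hpos[j, ]))) next
    for (i in seq_len(n)) {
      if (abs(i - j) < 2 && seg[i] == seg[j]) next  # no bond to self/neighbour
      if (i == j) next
      rON <- sqrt(sum((m[Oi[i], ] - m[Ni[j], ])^2))
      if (rON > 5.2) next                            # distance screen
      rCH <- sqrt(sum((m[Ci[i], ] - Hpos[j, ])^2))
      rOH <- sqrt(sum((m[Oi[i], ] - Hpos[j, ])^2))
      rCN <- sqrt(sum((m[Ci[i], ] - m[Ni[j], ])^2))
      E <- q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      if (E < -0.5) hb[i, j] <- TRUE
    }
  }
  same_seg_span <- function(i, j) seg[i] == seg[j]
  turn <- function(nlen) {
    t <- rep(FALSE, n)
    for (i in seq_len(n - nlen)) {
      if (same_seg_span(i, i + nlen) && hb[i, i + nlen]) t[i] <- TRUE
    }
    t
  }
  t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
  ss <- rep("C", n)
  ## bridges (strands)
  bridge <- matrix(FALSE, n, n)
  for (i in 2:(n - 1)) for (j in 2:(n - 1)) {
    if (abs(i - j) < 3) next
    par <- (hb[i - 1, j] && hb[j, i + 1]) || (hb[j - 1, i] && hb[i, j + 1])
    anti <- (hb[i, j] && hb[j, i]) || (hb[i - 1, j + 1] && hb[j - 1, i + 1])
    if (par || anti) bridge[i, j] <- TRUE
  }
  has_bridge <- apply(bridge, 1, any)
  ## ladders: consecutive bridged residues -> E, isolated -> B
  for (i in which(has_bridge)) {
    neigh <- (i > 1 && has_bridge[i - 1]) || (i < n && has_bridge[i + 1])
    ss[i] <- if (neigh) "E" else "B"
  }
  ## helices: two consecutive n-turns, priority H > G > I (E kept over G/I)
  mark_helix <- function(ss, t, nlen, letter, over = c("C", "T", "S", "B")) {
    if (n - nlen < 2) return(ss)
    for (i in 2:(n - nlen)) {
      if (t[i - 1] && t[i]) {
        span <- i:(i + nlen - 1)
        if (all(ss[span] %in% c(over, letter))) ss[span] <- letter
      }
    }
    ss
  }
  ss <- mark_helix(ss, t4, 4, "H", over = c("C", "T", "S", "B", "E", "G", "I"))
  ss <- mark_helix(ss, t3, 3, "G")
  ss <- mark_helix(ss, t5, 5, "I")
  ## single turns -> T
  for (nlen in c(3, 4, 5)) {
    t <- list(`3` = t3, `4` = t4, `5` = t5)[[as.character(nlen)]]
    for (i in which(t)) {
      span <- (i + 1):(i + nlen - 1)
      span <- span[span <= n]
      ss[span][ss[span] == "C"] <- "T"
    }
  }
  ## bends: CA direction change > 70 degrees
  for (i in if (n >= 5) 3:(n - 2) else integer(0)) {
    if (!same_seg_span(i - 2, i + 2)) next
    u <- m[CAi[i], ] - m[CAi[i - 2], ]
    v <- m[CAi[i + 2], ] - m[CAi[i], ]
    ang <- acos(pmin(1, pmax(-1, sum(u * v) / sqrt(sum(u^2) * sum(v^2))))) * 180 / pi
    if (ang > 70 && ss[i] == "C") ss[i] <- "S"
  }
  names(ss) <- resids
  ss
}

#' Reduce a full DSSP assignment to the 5-letter alphabet
#'
#' Mapping: H -> alpha, G -> three_ten, I -> pi, E -> strand, everything
#' else (B, T, S, C) -> none.  Idempotent on already-reduced input.
#'
#' @param full character vector of full-alphabet letters.
#' @return character vector over \{none, alpha, three_ten, pi, strand\}.
#' @export
reduce_alphabet <- function(full) {
  if (!length(full)) return(character(0))
  if (all(full %in% c("none", "alpha", "three_ten", "pi", "strand")))
    return(full)
  bad <- setdiff(unique(full), names(.ss_reduce_map))
  if (length(bad)) stop("unknown secondary-structure letter(s): ",
                        paste(bad, collapse = ", "))
  out <- unname(.ss_reduce_map[full])
  names(out) <- names(full)
  out
}

#' Helical content of a region
#'
#' Percentage of residues in the region assigned alpha, 3-10 or pi helix.
#'
#' @param assignment reduced (or full) assignment named by residue number.
#' @param region length-2 residue range; default all residues.
#' @return percentage in [0, 100].
#' @export
helical_content <- function(assignment, region = NULL) {
  red <- reduce_alphabet(assignment)
  if (!is.null(region)) {
    r <- as.integer(names(red))
    red <- red[r >= region[1] & r <= region[2]]
  }
  if (!length(red)) stop("empty region")
  100 * mean(red %in% c("alpha", "three_ten", "pi"))
}

#' Jaccard dissimilarity between two secondary-structure assignments
#'
#' Each conformation is represented as the set of (residue, reduced letter)
#' pairs with letter != none; the distance is `1 - |A n B| / |A u B|`.
#' Two fully unstructured assignments have distance 0.
#'
#' @param a,b reduced (or full) assignments of equal length.
#' @return dissimilarity in [0, 1].
#' @export
ss_distance <- function(a, b) {
  if (length(a) != length(b)) stop("assignments differ in length")
  ra <- reduce_alphabet(a); rb <- reduce_alphabet(b)
  ia <- which(ra != "none"); ib <- which(rb != "none")
  A <- paste(ia, ra[ia]); B <- paste(ib, rb[ib])
  uni <- length(union(A, B))
  if (uni == 0) return(0)
  1 - length(intersect(A, B)) / uni
}

#' Cluster conformations by secondary-structure pattern
#'
#' Pairwise Jaccard distances between per-frame reduced assignments,
#' complete-linkage hierarchical clustering, tree cut at every pruning
#' distance in `seq(0.05, 1, 0.05)`; the cut maximising the silhouette
#' score (computed on the precomputed distances) is retained, ties going
#' to the smaller distance.  If every cut yields a single cluster the
#' silhouette is reported as NA.
#'
#' @param assignments list of per-frame assignments (>= 3 frames), or a
#'   character matrix frames x residues.
#' @param prune_distances swept cut heights.
#' @return list of class `SSClusterResult`: `labels` (per frame),
#'   `distance` (chosen cut), `sweep` (distance, n_clusters, silhouette),
#'   `consensus` (per-cluster modal reduced string), `dist` (the distance
#'   matrix).
#' @export
cluster_by_ss <- function(assignments,
                          prune_distances = seq(0.05, 1, by = 0.05)) {
  if (is.matrix(assignments))
    assignments <- lapply(seq_len(nrow(assignments)), function(i) assignments[i, ])
  nf <- length(assignments)
  if (nf < 3) stop(">= 3 frames required")
  red <- lapply(assignments, reduce_alphabet)
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1)) for (j in (i + 1):nf) {
    D[i, j] <- D[j, i] <- ss_distance(red[[i]], red[[j]])
  }
  hc <- hclust(as.dist(D), method = "complete")
  sweep_rows <- lapply(prune_distances, function(h) {
    lab <- cutree(hc, h = h)
    k <- length(unique(lab))
    sil <- if (k > 1 && k < nf) {
      mean(cluster::silhouette(lab, dmatrix = D)[, "sil_width"])
    } else NA_real_
    list(h = h, k = k, sil = sil, lab = lab)
  })
  sweep <- data.frame(distance = vapply(sweep_rows, `[[`, 0, "h"),
                      n_clusters = vapply(sweep_rows, `[[`, 0L, "k"),
                      silhouette = vapply(sweep_rows, `[[`, 0, "sil"))
  if (all(is.na(sweep$silhouette))) {
    best <- length(sweep_rows)          # all-identical case: one cluster
    labels <- sweep_rows[[best]]$lab
    chosen <- sweep$distance[best]
    sil <- NA_real_
  } else {
    best <- which(sweep$silhouette == max(sweep$silhouette, na.rm = TRUE))[1]
    labels <- sweep_rows[[best]]$lab
    chosen <- sweep$distance[best]
    sil <- sweep$silhouette[best]
  }
  consensus <- lapply(split(seq_len(nf), labels), function(idx) {
    mat <- do.call(rbind, red[idx])
    apply(mat, 2, function(col) names(sort(table(col), decreasing = TRUE))[1])
  })
  structure(list(labels = labels, distance = chosen, silhouette = sil,
                 sweep = sweep, consensus = consensus, dist = D),
            class = "SSClusterResult")
}

#' @export
print.SSClusterResult <- function(x, ...) {
  cat("SS clustering:", length(unique(x$labels)), "clusters at pruning distance",
      x$distance, "(silhouette", format(x$silhouette, digits = 3), ")\n")
  invisible(x)
}
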