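## run expr with a local RNG seed, restoring global state afterwards
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## frames x references RMSD matrix on a selection (no fitting: frames are
## assumed pre-superposed on the relevant scaffold, as in loop clustering
## after a domain fit)
.rmsd_to_refs <- function(xyz, ref_rows, sel_xyz) {
  X <- xyz[, sel_xyz, drop = FALSE]
  R <- xyz[ref_rows, sel_xyz, drop = FALSE]
  na <- length(sel_xyz) / 3
  out <- matrix(NA_real_, nrow(X), length(ref_rows))
  for (k in seq_along(ref_rows)) {
    D <- sweep(X, 2, R[k, ])
    out[, k] <- sqrt(rowSums(D^2) / na)
  }
  out
}

#' Reference-based RMSD clustering of an ensemble
#'
#' Ensemble-convergence clustering: (i) a reference frame is chosen at
#' random from the remaining pool and every frame within RMSD `cutoff_r`
#' of it is removed; this repeats until the pool is empty, producing
#' references pairwise more than `cutoff_r` apart.  (ii) every frame is
#' assigned to its nearest reference; frames farther than `cutoff_r` from
#' all references stay unassigned and reduce the coverage.  Clusters are
#' renamed C1, C2, ... by decreasing population.
#'
#' Frames are expected to be pre-superposed on the relevant scaffold
#' (e.g. fitted on a stable domain before clustering a mobile loop); the
#' RMSD on `selection` is computed without refitting unless `fit = TRUE`.
#'
#' @param ens an [Ensemble].
#' @param selection atom indices the RMSD is computed on.
#' @param cutoff_r RMSD cutoff r in Angstrom (> 0); the operating default
#'   is 4.
#' @param seed integer seed for the random reference choice.
#' @param fit superpose each frame pair on the selection before the RMSD.
#' @return list of class `ClusterResult`: `cutoff`, `references` (frame
#'   indices), `labels` (per frame, NA when unassigned), `populations`
#'   (fractions of all frames, by cluster), `medoids`, `coverage`.
#' @export
reference_cluster <- function(ens, selection = NULL, cutoff_r = 4, seed = 1,
                              fit = FALSE) {
  nf <- n_frames(ens)
  if (nf == 0) stop("empty ensemble")
  if (cutoff_r <= 0) stop("cutoff_r must be positive")
  sel <- if (is.null(selection)) seq_len(n_atoms(ens$topology)) else selection
  sel_xyz <- xyz_index(sel)
  refs <- integer(0)
  remaining <- seq_len(nf)
  with_seed(seed, {
    while (length(remaining)) {
      pick <- remaining[sample.int(length(remaining), 1)]
      refs <- c(refs, pick)
      if (fit) {
        d <- vapply(remaining, function(i)
          superpose(ens$xyz[i, ], ens$xyz[pick, ], sel)$rmsd, numeric(1))
      } else {
        D <- sweep(ens$xyz[remaining, sel_xyz, drop = FALSE], 2,
                   ens$xyz[pick, sel_xyz])
        d <- sqrt(rowSums(D^2) / length(sel))
      }
      remaining <- remaining[d > cutoff_r]
    }
  })
  if (fit) {
    dmat <- vapply(refs, function(r) vapply(seq_len(nf), function(i)
      superpose(ens$xyz[i, ], ens$xyz[r, ], sel)$rmsd, numeric(1)),
      numeric(nf))
    dmat <- matrix(dmat, nrow = nf)
  } else {
    dmat <- .rmsd_to_refs(ens$xyz, refs, sel_xyz)
  }
  nearest <- apply(dmat, 1, which.min)      # ties: lower reference index
  mind <- dmat[cbind(seq_len(nf), nearest)]
  labels_raw <- ifelse(mind <= cutoff_r, nearest, NA_integer_)
  ## rename by population
  tab <- table(factor(labels_raw, levels = seq_along(refs)))
  ord <- order(tab, decreasing = TRUE)
  rank_of <- integer(length(refs)); rank_of[ord] <- seq_along(refs)
  labels <- ifelse(is.na(labels_raw), NA_integer_, rank_of[labels_raw])
  keep <- which(as.integer(tab[ord]) > 0)
  populations <- as.numeric(tab[ord][keep]) / nf
  medoids <- vapply(keep, function(k) {
    members <- which(labels == k)
    medoid(ens, members, selection = sel, fit = fit)
  }, integer(1))
  structure(list(cutoff = cutoff_r, references = refs[ord][keep],
                 labels = labels, populations = populations,
                 medoids = medoids,
                 coverage = mean(!is.na(labels))),
            class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
  cat("RMSD clustering (r =", x$cutoff, "A):", length(x$populations),
      "clusters, coverage", sprintf("%.1f%%", 100 * x$coverage), "\n")
  cat("  populations:", paste(sprintf("%.1f%%", 100 * x$populations),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Sweep the clustering cutoff
#'
#' Runs [reference_cluster()] at every cutoff in `seq(r_min, r_max, step)`
#' (default 2.4 to 7.0 A in 0.2 A steps, 24 values) with the same seed
#' policy, tabulating cluster count and coverage; the 4 A operating point
#' is flagged.
#'
#' @inheritParams reference_cluster
#' @param r_min,r_max,step sweep definition in Angstrom.
#' @return data.frame (r, n_clusters, coverage, operating_point).
#' @export
cutoff_sweep <- function(ens, selection = NULL, r_min = 2.4, r_max = 7.0,
                         step = 0.2, seed = 1) {
  if (r_min >= r_max) stop("r_min must be < r_max")
  rs <- seq(r_min, r_max, by = step)
  rows <- lapply(rs, function(r) {
    cl <- reference_cluster(ens, selection, cutoff_r = r, seed = seed)
    data.frame(r = r, n_clusters = length(cl$populations),
               coverage = cl$coverage)
  })
  out <- do.call(rbind, rows)
  out$operating_point <- abs(out$r - 4.0) < 1e-9
  out
}

#' Medoid frame of a cluster
#'
#' The member minimising mean RMSD to all other members.  Exhaustive for
#' up to `max_exact` members; larger clusters are subsampled
#' deterministically (every k-th member).  Ties break to the lowest frame
#' index.
#'
#' @param ens an [Ensemble].
#' @param members frame indices of the cluster (>= 1).
#' @param selection atom indices for the RMSD.
#' @param fit superpose pairs before the RMSD.
#' @param max_exact exhaustive-evaluation limit (default 2000).
#' @return the medoid frame index.
#' @export
medoid <- function(ens, members, selection = NULL, fit = FALSE,
                   max_exact = 2000) {
  stopifnot(length(members) >= 1)
  if (length(members) == 1) return(members)
  eval_set <- members
  if (length(members) > max_exact)
    eval_set <- members[seq(1, length(members),
                            by = ceiling(length(members) / max_exact))]
  sel <- if (is.null(selection)) seq_len(n_atoms(ens$topology)) else selection
  sel_xyz <- xyz_index(sel)
  if (fit) {
    md <- vapply(members, function(i) {
      mean(vapply(eval_set[eval_set != i], function(j)
        superpose(ens$xyz[i, ], ens$xyz[j, ], sel)$rmsd, numeric(1)))
    }, numeric(1))
  } else {
    X <- ens$xyz[eval_set, sel_xyz, drop = FALSE]
    md <- vapply(members, function(i) {
      D <- sweep(X, 2, ens$xyz[i, sel_xyz])
      d <- sqrt(rowSums(D^2) / length(sel))
      sum(d) / max(1, length(eval_set) - (i %in% eval_set))
    }, numeric(1))
  }
  members[which.min(md)]
}
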