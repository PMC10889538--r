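#' Cartesian principal component analysis of an ensemble
#'
#' Frames are iteratively least-squares fitted to their running average on
#' the selection (until the average moves by <= 1e-6 A, max 10 iterations),
#' then the centred frames x coordinates matrix is decomposed by SVD.
#' Eigenvalue k is `(singular value k)^2 / (n_frames - 1)` (the variance,
#' in A^2, along mode k); explained fractions are eigenvalues over their
#' sum.
#'
#' @param ens an [Ensemble] (>= 2 frames).
#' @param selection atom indices (e.g. C-alpha or backbone); default all.
#' @param fit iteratively superpose onto the average first (default TRUE;
#'   set FALSE for pre-fitted or synthetic translation-only data).
#' @return list of class `PCAModel`: `mean` (flat xyz of the selection),
#'   `modes` (3N x m orthonormal columns), `eigenvalues`,
#'   `explained_variance`, `cumulative_variance`, `selection`,
#'   `fitted_xyz` (frames x 3N matrix of fitted selected coordinates).
#' @export
pca_ensemble <- function(ens, selection = NULL, fit = TRUE) {
  nf <- n_frames(ens)
  if (nf < 2) stop(">= 2 frames required")
  sel <- if (is.null(selection)) seq_len(n_atoms(ens$topology)) else selection
  if (nf < length(sel) / 3)
    warning("fewer frames than a third of the selection size; ",
            "the mode spectrum will be rank-deficient")
  X <- ens$xyz[, xyz_index(sel), drop = FALSE]
  if (fit) {
    ref <- X[1, ]
    nsel <- seq_along(sel)
    for (it in seq_len(10)) {
      for (i in seq_len(nf))
        X[i, ] <- superpose(X[i, ], ref, nsel)$fitted
      newref <- colMeans(X)
      delta <- sqrt(max(rowSums(as_coord_matrix(newref - ref)^2)))
      ref <- newref
      if (delta <= 1e-6) break
    }
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sv <- svd(Xc)
  eig <- sv$d^2 / (nf - 1)
  keep <- which(eig > max(eig) * 1e-12)
  eig <- eig[keep]
  structure(list(mean = mu, modes = sv$v[, keep, drop = FALSE],
                 eigenvalues = eig,
                 explained_variance = eig / sum(eig),
                 cumulative_variance = cumsum(eig / sum(eig)),
                 selection = sel, fitted_xyz = X),
            class = "PCAModel")
}

#' @export
print.PCAModel <- function(x, ...) {
  cat("PCA model:", length(x$selection), "atoms,",
      length(x$eigenvalues), "modes\n")
  ev <- utils::head(100 * x$explained_variance, 3)
  cat("  explained variance (PC1..):",
      paste(sprintf("%.1f%%", ev), collapse = ", "), "\n")
  invisible(x)
}

#' Project an ensemble onto principal modes
#'
#' Each frame is fitted to the model mean on the model selection, centred,
#' and projected on the first `n_modes` modes.  Projections carry the
#' frame's source label.
#'
#' @param ens an [Ensemble] over the same topology/selection as the model.
#' @param model a `PCAModel`.
#' @param n_modes retained modes (default 3).
#' @param fit superpose onto the model mean first (default TRUE).
#' @return data.frame with columns `PC1..PCk`, `source`, `time`.
#' @export
project_ensemble <- function(ens, model, n_modes = 3, fit = TRUE) {
  sel <- model$selection
  if (max(sel) > n_atoms(ens$topology))
    stop("model selection incompatible with the ensemble")
  X <- ens$xyz[, xyz_index(sel), drop = FALSE]
  if (ncol(X) != length(model$mean)) stop("selection size mismatch")
  nf <- nrow(X)
  if (fit) {
    nsel <- seq_along(sel)
    for (i in seq_len(nf)) X[i, ] <- superpose(X[i, ], model$mean, nsel)$fitted
  }
  n_modes <- min(n_modes, ncol(model$modes))
  P <- sweep(X, 2, model$mean) %*% model$modes[, seq_len(n_modes), drop = FALSE]
  out <- as.data.frame(P)
  names(out) <- paste0("PC", seq_len(n_modes))
  out$source <- ens$source
  out$time <- ens$time
  out
}

#' Per-atom displacement arrows for one PCA mode
#'
#' Arrow for atom i is the mode's 3-vector component scaled by
#' `sqrt(eigenvalue)` (an RMS amplitude in Angstrom).  All atoms are
#' retained in the result; the `displayed` flag marks those at or above
#' the amplitude threshold (porcupine-plot convention, default 2 A).
#'
#' @param model a `PCAModel`.
#' @param mode mode number.
#' @param amplitude_threshold display threshold in Angstrom.
#' @return data.frame: atom (index within the selection), `dx,dy,dz`
#'   (arrow, A), `amplitude`, `displayed`.
#' @export
mode_displacements <- function(model, mode = 1, amplitude_threshold = 2) {
  if (mode < 1 || mode > ncol(model$modes)) stop("mode out of range")
  v <- model$modes[, mode] * sqrt(model$eigenvalues[mode])
  m <- as_coord_matrix(v)
  amp <- sqrt(rowSums(m^2))
  data.frame(atom = model$selection, dx = m[, 1], dy = m[, 2], dz = m[, 3],
             amplitude = amp, displayed = amp >= amplitude_threshold)
}

#' Dynamic cross-correlation matrix
#'
#' Normalised covariance of atomic displacements about each atom's mean
#' position after fitting:
#' `C_ij = <dr_i . dr_j> / sqrt(<dr_i^2><dr_j^2>)`, values in [-1, 1] with
#' unit diagonal.  Zero-variance atoms get a zero row/column (diagonal
#' kept at 1) with a warning.
#'
#' @param ens an [Ensemble].
#' @param selection atom indices (typically the C-alpha set).
#' @param fit superpose all frames onto frame 1 on the selection first.
#' @return matrix of class `CorrelationMatrix` labelled by residue number.
#' @export
cross_correlation <- function(ens, selection = NULL, fit = TRUE) {
  sel <- if (is.null(selection)) select_atoms(ens$topology, atom_names = "CA")
         else selection
  if (fit) ens <- fit_ensemble(ens, selection = sel)
  X <- ens$xyz[, xyz_index(sel), drop = FALSE]
  Xc <- sweep(X, 2, colMeans(X))
  n <- length(sel); nf <- nrow(X)
  ## <dr_i . dr_j> = sum over x,y,z of covariances
  C3 <- crossprod(Xc) / nf                    # 3n x 3n second moments
  ix <- function(i) (3 * (i - 1) + 1):(3 * i)
  dots <- matrix(0, n, n)
  for (a in 1:3) {
    idx <- seq(a, 3 * n, by = 3)
    dots <- dots + C3[idx, idx]
  }
  v <- diag(dots)
  zero <- v <= 1e-12
  if (any(zero)) warning(sum(zero), " zero-variance atom(s); row/column zeroed")
  denom <- sqrt(outer(pmax(v, 1e-300), pmax(v, 1e-300)))
  C <- dots / denom
  C[zero, ] <- 0; C[, zero] <- 0
  diag(C) <- 1
  rn <- ens$topology$atoms$resid[sel]
  dimnames(C) <- list(rn, rn)
  class(C) <- c("CorrelationMatrix", class(C))
  C
}

#' Correlation profile of one residue
#'
#' Extracts the cross-correlation row of a residue and labels each entry
#' with the topology region it falls in.
#'
#' @param matrix a `CorrelationMatrix`.
#' @param residue residue number (must label a row).
#' @param top optional [Topology] supplying region labels.
#' @return data.frame: `residue`, `correlation`, `region`.
#' @export
residue_correlation_profile <- function(matrix, residue, top = NULL) {
  rn <- as.integer(rownames(matrix))
  i <- match(residue, rn)
  if (is.na(i)) stop("residue ", residue, " not in the matrix")
  region <- rep(NA_character_, length(rn))
  if (!is.null(top)) {
    for (nm in names(top$regions)) {
      rng <- top$regions[[nm]]
      region[rn >= rng[1] & rn <= rng[2]] <- nm
    }
  }
  data.frame(residue = rn, correlation = as.numeric(matrix[i, ]),
             region = region)
}
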