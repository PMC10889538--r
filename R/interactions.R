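## Hydrophobic residue set (side-chain contact analysis); configurable.
.hydrophobic_residues <- c("ALA", "VAL", "LEU", "ILE", "MET", "PHE", "TRP", "PRO")

## basic side-chain N donors and acidic carboxylate O acceptors (salt bridges)
.basic_sc_n <- list(ARG = c("NE", "NH1", "NH2"), LYS = "NZ",
                    HIS = c("ND1", "NE2"))
.acidic_sc_o <- list(ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"))

#' Detect hydrogen bonds in one conformation
#'
#' Geometric criterion on heavy N/O atoms: a (donor D, hydrogen H,
#' acceptor A) triple is a hydrogen bond when the donor bears an explicit
#' covalent H (within 1.25 A), D...A <= `dist_cutoff` (boundary inclusive)
#' and the pseudo-valent angle at the H atom, D-H...A, is strictly greater
#' than `angle_cutoff`.  Covalently bound D/A pairs (< 1.8 A) are excluded.
#' Donors without a resolvable hydrogen are skipped with a warning.
#'
#' @param conformation flat xyz vector.
#' @param top matching [Topology].
#' @param dist_cutoff donor-acceptor distance cutoff (default 3.6 A).
#' @param angle_cutoff angle threshold in degrees (default 90, exclusive).
#' @param warn_no_h warn about N/O donors lacking an attached hydrogen.
#' @return data.frame of contact records: donor/acceptor atom indices and
#'   labels, `distance` (D...A), `angle` (at H), `kind = "hbond"`.
#' @export
detect_hbonds <- function(conformation, top, dist_cutoff = 3.6,
                          angle_cutoff = 90, warn_no_h = FALSE) {
  at <- top$atoms
  m <- as_coord_matrix(conformation)
  heavy_no <- which(at$element %in% c("N", "O"))
  hyd <- which(at$element == "H")
  if (length(heavy_no) < 2) return(.empty_contacts())
  ## attach each H to its nearest N/O within 1.25 A
  h_of <- vector("list", nrow(at))
  for (h in hyd) {
    d <- sqrt(colSums((t(m[heavy_no, , drop = FALSE]) - m[h, ])^2))
    j <- which.min(d)
    if (d[j] <= 1.25) h_of[[heavy_no[j]]] <- c(h_of[[heavy_no[j]]], h)
  }
  donors <- heavy_no[vapply(h_of[heavy_no], length, integer(1)) > 0]
  if (warn_no_h && length(setdiff(heavy_no[at$element[heavy_no] == "N"], donors)))
    warning("N/O donors without resolvable H skipped")
  rows <- list()
  for (d in donors) {
    dv <- sqrt(colSums((t(m[heavy_no, , drop = FALSE]) - m[d, ])^2))
    cand <- heavy_no[dv <= dist_cutoff & dv > 1.8 & heavy_no != d]
    for (a in cand) {
      for (h in h_of[[d]]) {
        v1 <- m[d, ] - m[h, ]; v2 <- m[a, ] - m[h, ]
        ang <- acos(pmin(1, pmax(-1, sum(v1 * v2) /
                                   sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
        if (ang > angle_cutoff) {
          rows[[length(rows) + 1]] <- data.frame(
            donor = d, hydrogen = h, acceptor = a,
            donor_label = .atom_label(at, d),
            acceptor_label = .atom_label(at, a),
            distance = sqrt(sum((m[d, ] - m[a, ])^2)),
            angle = ang, kind = "hbond", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) return(.empty_contacts())
  out <- do.call(rbind, rows)
  ## one record per (D, H, A); drop duplicated D-A via different H? keep all
  out
}

.empty_contacts <- function() {
  data.frame(donor = integer(), hydrogen = integer(), acceptor = integer(),
             donor_label = character(), acceptor_label = character(),
             distance = numeric(), angle = numeric(), kind = character(),
             stringsAsFactors = FALSE)
}

.atom_label <- function(at, i) {
  paste0(at$resname[i], at$resid[i], ":", at$name[i])
}

#' Hydrogen-bond occurrence over an ensemble
#'
#' Aggregates per-frame detections into one time series per (donor heavy
#' atom, acceptor heavy atom) pair (over all hydrogens of the donor) and
#' retains pairs present in at least `min_frequency` of frames.  The
#' per-frame strength is the donor-acceptor distance mapped linearly onto
#' the 2.6 A (strongest, 1) to 3.6 A (weakest, 0) scale.
#'
#' @param ens an [Ensemble] with explicit hydrogens.
#' @param min_frequency retention threshold on the fraction of frames
#'   (default 0.6).
#' @param ... passed to [detect_hbonds()].
#' @return data.frame with one row per retained pair: labels, `frequency`,
#'   `mean_distance`; attributes `presence` and `strength` hold the
#'   pair x frame matrices.
#' @export
hbond_occurrence <- function(ens, min_frequency = 0.6, ...) {
  nf <- n_frames(ens)
  per_frame <- lapply(seq_len(nf), function(f)
    detect_hbonds(ens$xyz[f, ], ens$topology, ...))
  keys <- unique(do.call(rbind, lapply(per_frame, function(df)
    df[, c("donor", "acceptor")])))
  if (is.null(keys) || nrow(keys) == 0) {
    out <- data.frame(donor = integer(), acceptor = integer(),
                      donor_label = character(), acceptor_label = character(),
                      frequency = numeric(), mean_distance = numeric())
    attr(out, "presence") <- matrix(0, 0, nf)
    return(out)
  }
  key_id <- paste(keys$donor, keys$acceptor)
  presence <- matrix(FALSE, nrow(keys), nf,
                     dimnames = list(key_id, NULL))
  dists <- matrix(NA_real_, nrow(keys), nf, dimnames = list(key_id, NULL))
  for (f in seq_len(nf)) {
    df <- per_frame[[f]]
    if (!nrow(df)) next
    id <- paste(df$donor, df$acceptor)
    for (k in unique(id)) {
      presence[k, f] <- TRUE
      dists[k, f] <- min(df$distance[id == k])
    }
  }
  freq <- rowMeans(presence)
  keep <- freq >= min_frequency
  at <- ens$topology$atoms
  out <- data.frame(donor = keys$donor[keep], acceptor = keys$acceptor[keep],
                    donor_label = vapply(keys$donor[keep], function(i) .atom_label(at, i), ""),
                    acceptor_label = vapply(keys$acceptor[keep], function(i) .atom_label(at, i), ""),
                    frequency = freq[keep],
                    mean_distance = rowMeans(dists, na.rm = TRUE)[keep],
                    stringsAsFactors = FALSE)
  strength <- hbond_strength(dists[keep, , drop = FALSE])
  attr(out, "presence") <- presence[keep, , drop = FALSE]
  attr(out, "strength") <- strength
  out
}

#' Map donor-acceptor distances onto the hydrogen-bond strength scale
#'
#' Linear scale from the strongest bonds at 2.6 A (value 1) to the weakest
#' at 3.6 A (value 0); distances outside the range are clamped.
#'
#' @param distance numeric vector/matrix of D...A distances (A).
#' @return values in [0, 1] with the shape of the input.
#' @export
hbond_strength <- function(distance) {
  s <- (3.6 - distance) / (3.6 - 2.6)
  s[] <- pmin(1, pmax(0, s))
  s
}

#' Detect hydrophobic (van der Waals) contacts
#'
#' Two hydrophobic residues are in contact when any pair of their
#' side-chain carbon atoms is within `cutoff` (default 4 A).  Sequence
#' neighbours (|i - j| < `min_separation`) are excluded; glycine has no
#' side-chain carbon and never qualifies.
#'
#' @param conformation flat xyz vector.
#' @param top matching [Topology].
#' @param cutoff distance cutoff (default 4 A).
#' @param residues hydrophobic residue set (default ALA, VAL, LEU, ILE,
#'   MET, PHE, TRP, PRO).
#' @param min_separation minimum |resid difference| (default 2).
#' @return data.frame of residue-pair contact records with the minimum
#'   side-chain C-C distance and `kind = "hydrophobic"`.
#' @export
detect_hydrophobic_contacts <- function(conformation, top, cutoff = 4,
                                        residues = .hydrophobic_residues,
                                        min_separation = 2) {
  at <- top$atoms
  m <- as_coord_matrix(conformation)
  sc_c <- which(at$element == "C" & !(at$name %in% c("C", "CA")) &
                  at$resname %in% residues)
  if (length(sc_c) < 2) return(data.frame())
  res <- sort(unique(at$resid[sc_c]))
  rows <- list()
  for (i in seq_along(res)) for (j in seq_along(res)) {
    if (j <= i) next
    if (abs(res[j] - res[i]) < min_separation) next
    ai <- sc_c[at$resid[sc_c] == res[i]]
    aj <- sc_c[at$resid[sc_c] == res[j]]
    d <- sqrt(pmax(0, outer(rowSums(m[ai, , drop = FALSE]^2),
                            rowSums(m[aj, , drop = FALSE]^2), `+`) -
                     2 * m[ai, , drop = FALSE] %*% t(m[aj, , drop = FALSE])))
    dmin <- min(d)
    if (dmin <= cutoff) {
      ri <- which(at$resid == res[i])[1]; rj <- which(at$resid == res[j])[1]
      rows[[length(rows) + 1]] <- data.frame(
        resid_i = res[i], resid_j = res[j],
        resname_i = at$resname[ri], resname_j = at$resname[rj],
        distance = dmin, kind = "hydrophobic", stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}

#' Re-label salt-bridge hydrogen bonds
#'
#' A hydrogen bond is a salt bridge when one partner is a basic side-chain
#' nitrogen (Arg NE/NH1/NH2, Lys NZ, His ND1/NE2) and the other an acidic
#' side-chain carboxylate oxygen (Asp OD1/OD2, Glu OE1/OE2), in either
#' donor/acceptor role.
#'
#' @param hbonds output of [detect_hbonds()].
#' @param top matching [Topology].
#' @return the input with `kind` set to `"salt_bridge"` where applicable.
#' @export
annotate_salt_bridges <- function(hbonds, top) {
  if (!nrow(hbonds)) return(hbonds)
  at <- top$atoms
  is_basic_n <- function(i) {
    nm <- .basic_sc_n[[at$resname[i]]]
    !is.null(nm) && at$name[i] %in% nm
  }
  is_acidic_o <- function(i) {
    nm <- .acidic_sc_o[[at$resname[i]]]
    !is.null(nm) && at$name[i] %in% nm
  }
  for (r in seq_len(nrow(hbonds))) {
    d <- hbonds$donor[r]; a <- hbonds$acceptor[r]
    if ((is_basic_n(d) && is_acidic_o(a)) || (is_acidic_o(d) && is_basic_n(a)))
      hbonds$kind[r] <- "salt_bridge"
  }
  hbonds
}
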