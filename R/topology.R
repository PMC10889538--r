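#' @keywords internal
#' @importFrom stats dist hclust cutree as.dist rnorm sd
#' @importFrom graphics hist
#' @importFrom utils head
"_PACKAGE"

## Standard atomic masses (amu) for the elements seen in protein structures.
.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, P = 30.974, SE = 78.971, FE = 55.845)

## Fixed van der Waals radius table (Angstrom) used by cavity detection.
.vdw_radii <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, H = 1.20,
                P = 1.80, SE = 1.90, FE = 1.40)

#' Infer the element symbol from a PDB atom name
#'
#' Strips digits and primes, then matches the leading characters against the
#' known element table.  Two-letter elements (SE, FE) are recognised before
#' one-letter ones.
#'
#' @param name character vector of atom names (e.g. "CA", "OD1", "1HB").
#' @return character vector of element symbols.
#' @keywords internal
guess_element <- function(name) {
  stripped <- toupper(gsub("[0-9']", "", name))
  two <- substr(stripped, 1, 2)
  one <- substr(stripped, 1, 1)
  ifelse(two %in% c("SE", "FE"), two, one)
}

#' Build a protein topology
#'
#' A `Topology` holds the ordered atom table shared by every frame of an
#' [Ensemble], plus named residue regions (e.g. a disordered loop, the
#' transmembrane helices) and named helix definitions used by axis-drift
#' analysis.
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`,
#'   `resid` (1-based biological residue number), `resname` (3-letter code),
#'   `chain`; optional `mass`.  Missing elements are inferred from names,
#'   missing masses from elements.
#' @param regions named list of length-2 integer vectors `c(first, last)`
#'   residue ranges.
#' @param helices named list of length-2 integer vectors, helix residue ranges.
#' @return object of class `Topology`.
#' @export
topology <- function(atoms, regions = list(), helices = list()) {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "resid", "resname")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (is.null(atoms$chain)) atoms$chain <- "A"
  if (is.null(atoms$element) || anyNA(atoms$element) || any(atoms$element == "")) {
    el <- if (is.null(atoms$element)) rep(NA_character_, n) else as.character(atoms$element)
    bad <- is.na(el) | el == ""
    el[bad] <- guess_element(atoms$name[bad])
    atoms$element <- el
  }
  atoms$element <- toupper(atoms$element)
  if (is.null(atoms$mass)) {
    m <- .element_masses[atoms$element]
    if (anyNA(m)) {
      warning("unknown element(s): ",
              paste(unique(atoms$element[is.na(m)]), collapse = ", "),
              "; assigning default mass 12.011")
      m[is.na(m)] <- 12.011
    }
    atoms$mass <- unname(m)
  }
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  resids <- unique(atoms$resid)
  chk_range <- function(rng, what) {
    if (length(rng) != 2 || rng[1] > rng[2])
      stop("bad ", what, " range")
    if (!all(seq(rng[1], rng[2]) %in% resids))
      stop(what, " range [", rng[1], ",", rng[2], "] outside the sequence")
  }
  for (nm in names(regions)) chk_range(regions[[nm]], paste0("region '", nm, "'"))
  for (nm in names(helices)) chk_range(helices[[nm]], paste0("helix '", nm, "'"))
  structure(list(atoms = atoms, regions = regions, helices = helices),
            class = "Topology")
}

#' @export
print.Topology <- function(x, ...) {
  cat("Topology:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$resid)), "residues\n")
  if (length(x$regions))
    cat("  regions:", paste(names(x$regions), collapse = ", "), "\n")
  if (length(x$helices))
    cat("  helices:", paste(names(x$helices), collapse = ", "), "\n")
  invisible(x)
}

n_atoms <- function(top) nrow(top$atoms)

#' Select atom indices from a topology
#'
#' @param top a [Topology].
#' @param region name of a registered region (or NULL for the whole chain).
#' @param atom_names restrict to these atom names (e.g. "CA", or the
#'   backbone set `c("N","H","CA","C","O")`).
#' @param heavy if TRUE drop hydrogens.
#' @param resid explicit residue numbers (overrides `region`).
#' @return integer vector of atom indices (1-based, topology order).
#' @export
select_atoms <- function(top, region = NULL, atom_names = NULL,
                         heavy = FALSE, resid = NULL) {
  at <- top$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(resid)) {
    keep <- keep & at$resid %in% resid
  } else if (!is.null(region)) {
    rng <- top$regions[[region]]
    if (is.null(rng)) rng <- top$helices[[region]]
    if (is.null(rng)) stop("unknown region: ", region)
    keep <- keep & at$resid >= rng[1] & at$resid <= rng[2]
  }
  if (!is.null(atom_names)) keep <- keep & at$name %in% atom_names
  if (heavy) keep <- keep & at$element != "H"
  which(keep)
}

## xyz-vector indices (x1,y1,z1,x2,...) for a set of atom indices
xyz_index <- function(atom_idx) {
  as.vector(rbind(3L * atom_idx - 2L, 3L * atom_idx - 1L, 3L * atom_idx))
}

## reshape a flat xyz vector to an N x 3 matrix and back
as_coord_matrix <- function(xyz) matrix(xyz, ncol = 3, byrow = TRUE)
as_xyz_vector <- function(m) as.vector(t(m))
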