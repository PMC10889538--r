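#' Construct a conformational ensemble
#'
#' An `Ensemble` is an ordered set of conformations (frames) sharing one
#' [Topology].  Coordinates are stored as an `nframes x 3N` matrix in
#' x1,y1,z1,x2,... order; each frame carries a time stamp (ps) and a
#' source-protein label so that concatenated multi-protein ensembles keep
#' track of frame provenance.
#'
#' @param topology a [Topology].
#' @param xyz numeric matrix, one row per frame, `3 * n_atoms` columns.
#' @param time numeric vector of frame times in ps (default `0, stride, ...`).
#' @param source character vector of per-frame source labels (recycled).
#' @param stride recording interval in ps between retained frames.
#' @return object of class `Ensemble`.
#' @export
ensemble <- function(topology, xyz, time = NULL, source = "protein",
                     stride = 100) {
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  if (ncol(xyz) != 3L * n_atoms(topology))
    stop("coordinate count (", ncol(xyz) / 3, " atoms) does not match topology (",
         n_atoms(topology), " atoms)")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  nf <- nrow(xyz)
  if (is.null(time)) time <- (seq_len(nf) - 1) * stride
  if (length(time) != nf) stop("time length != frame count")
  source <- rep_len(as.character(source), nf)
  for (s in unique(source)) {
    ts <- time[source == s]
    if (length(ts) > 1 && any(diff(ts) <= 0))
      stop("frame times must be strictly increasing within source '", s, "'")
  }
  structure(list(topology = topology, xyz = xyz, time = time,
                 source = source, stride = stride),
            class = "Ensemble")
}

#' @export
print.Ensemble <- function(x, ...) {
  cat("Ensemble:", nrow(x$xyz), "frames x", n_atoms(x$topology), "atoms;",
      "sources:", paste(unique(x$source), collapse = ", "), "\n")
  invisible(x)
}

n_frames <- function(ens) nrow(ens$xyz)

#' Extract one frame of an ensemble as a flat coordinate vector
#' @param ens an [Ensemble].
#' @param i frame index.
#' @return numeric xyz vector of length `3 * n_atoms`.
#' @export
get_frame <- function(ens, i) {
  stopifnot(i >= 1, i <= n_frames(ens))
  ens$xyz[i, ]
}

#' Keep a subset of frames
#' @param ens an [Ensemble].
#' @param idx frame indices to retain (order preserved).
#' @return an [Ensemble].
#' @export
subset_frames <- function(ens, idx) {
  ensemble(ens$topology, ens$xyz[idx, , drop = FALSE],
           time = ens$time[idx], source = ens$source[idx],
           stride = ens$stride)
}

#' Read a multi-model PDB file as an Ensemble
#'
#' Parsing is delegated to `bio3d::read.pdb()` when bio3d is installed
#' (the normal case); a minimal fixed-column reader is used otherwise.
#' Atom order must be identical across MODEL blocks; masses are assigned
#' from the element.
#'
#' @param path PDB file with >= 1 MODEL (or a single coordinate set).
#' @param regions,helices passed to [topology()].
#' @param source source label applied to every frame.
#' @param stride time between frames (ps); frames get `time = (i-1)*stride`.
#' @return an [Ensemble].
#' @export
read_multi_model_pdb <- function(path, regions = list(), helices = list(),
                                 source = "protein", stride = 100) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  model_starts <- grep("^MODEL", lines)
  if (length(model_starts) > 1) {
    ## consistency check before handing off to the parser
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) != length(model_starts))
      stop("malformed PDB: MODEL/ENDMDL mismatch")
    counts <- mapply(function(a, b) sum(is_atom[a:b]), model_starts, model_ends)
    if (length(unique(counts)) != 1)
      stop("inconsistent atom count between MODEL blocks: ",
           paste(unique(counts), collapse = " vs "))
  }
  if (requireNamespace("bio3d", quietly = TRUE)) {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    at <- pdb$atom
    atoms <- data.frame(serial = at$eleno, name = at$elety,
                        element = ifelse(is.na(at$elesy) | at$elesy == "",
                                         NA_character_, toupper(at$elesy)),
                        resid = at$resno, resname = at$resid,
                        chain = ifelse(is.na(at$chain), "A", at$chain),
                        stringsAsFactors = FALSE)
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  } else {
    parsed <- .parse_pdb_lines(lines, is_atom, model_starts)
    atoms <- parsed$atoms
    xyz <- parsed$xyz
  }
  top <- topology(atoms, regions = regions, helices = helices)
  ensemble(top, xyz, source = source, stride = stride)
}

## fallback fixed-column PDB reader (used only without bio3d)
.parse_pdb_lines <- function(lines, is_atom, model_starts) {
  if (length(model_starts) == 0) model_starts <- 0
  first_block <- if (model_starts[1] > 0) {
    ends <- grep("^ENDMDL", lines)
    lines[model_starts[1]:ends[1]]
  } else lines
  al <- first_block[grepl("^(ATOM  |HETATM)", first_block)]
  num <- function(x) as.numeric(trimws(x))
  atoms <- data.frame(
    serial = as.integer(trimws(substr(al, 7, 11))),
    name = trimws(substr(al, 13, 16)),
    element = trimws(substr(al, 77, 78)),
    resid = as.integer(trimws(substr(al, 23, 26))),
    resname = trimws(substr(al, 18, 20)),
    chain = trimws(substr(al, 22, 22)),
    stringsAsFactors = FALSE)
  atoms$chain[atoms$chain == ""] <- "A"
  all_atoms <- lines[is_atom]
  coords <- cbind(num(substr(all_atoms, 31, 38)),
                  num(substr(all_atoms, 39, 46)),
                  num(substr(all_atoms, 47, 54)))
  nmod <- max(1L, length(model_starts[model_starts > 0]))
  xyz <- matrix(as_xyz_vector(coords), nrow = nmod, byrow = TRUE)
  list(atoms = atoms, xyz = xyz)
}

#' Write an Ensemble as a multi-model PDB file
#'
#' Standard MODEL/ENDMDL records, fixed-width coordinate fields with three
#' decimals.  Writing then re-reading reproduces coordinates to the PDB
#' precision of 1e-3 Angstrom, and a second write of the re-read ensemble is
#' byte-identical.
#'
#' @param ens non-empty [Ensemble].
#' @param path output file path.
#' @export
write_multi_model_pdb <- function(ens, path) {
  if (!inherits(ens, "Ensemble") || n_frames(ens) == 0)
    stop("non-empty Ensemble required")
  at <- ens$topology$atoms
  ## PDB atom-name column convention: names of < 4 chars start in column 14
  nm <- ifelse(nchar(at$name) >= 4, substr(at$name, 1, 4),
               sprintf(" %-3s", at$name))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (f in seq_len(n_frames(ens))) {
    writeLines(sprintf("MODEL     %4d", f), con)
    m <- as_coord_matrix(ens$xyz[f, ])
    writeLines(sprintf("ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                       at$serial, nm, at$resname, at$chain, at$resid,
                       m[, 1], m[, 2], m[, 3], 1, 0, at$element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Concatenate ensembles into a labelled merged ensemble
#'
#' Frames are stacked in input order and each frame keeps (or is given) a
#' source label, so that merged multi-protein analyses can be decomposed by
#' source afterwards.  Topologies must agree on atom names and residue
#' numbers; for cross-protein merges the caller should first restrict each
#' ensemble to a shared selection (typically backbone or C-alpha atoms).
#'
#' @param ensembles list of [Ensemble]s with compatible topologies.
#' @param labels optional character vector, one label per ensemble; default
#'   keeps each ensemble's own source labels.
#' @return an [Ensemble] whose frame count is the sum of the inputs'.
#' @export
concatenate <- function(ensembles, labels = NULL) {
  stopifnot(length(ensembles) >= 1)
  if (length(ensembles) == 1 && is.null(labels)) return(ensembles[[1]])
  ref <- ensembles[[1]]$topology$atoms
  for (e in ensembles[-1]) {
    a <- e$topology$atoms
    if (nrow(a) != nrow(ref) || !all(a$name == ref$name) ||
        !all(a$resid == ref$resid))
      stop("topology mismatch between ensembles (atom names/order differ)")
  }
  if (!is.null(labels) && length(labels) != length(ensembles))
    stop("one label per ensemble required")
  xyz <- do.call(rbind, lapply(ensembles, function(e) e$xyz))
  time <- unlist(lapply(ensembles, function(e) e$time))
  src <- unlist(lapply(seq_along(ensembles), function(i) {
    if (is.null(labels)) ensembles[[i]]$source
    else rep(labels[i], n_frames(ensembles[[i]]))
  }))
  ensemble(ensembles[[1]]$topology, xyz, time = time, source = src,
           stride = ensembles[[1]]$stride)
}

#' Restrict an ensemble to an atom selection
#'
#' @param ens an [Ensemble].
#' @param sel integer atom indices (from [select_atoms()]).
#' @return an [Ensemble] over the selected atoms only.
#' @export
select_ensemble <- function(ens, sel) {
  at <- ens$topology$atoms[sel, , drop = FALSE]
  top <- topology(at, regions = ens$topology$regions,
                  helices = ens$topology$helices)
  ensemble(top, ens$xyz[, xyz_index(sel), drop = FALSE],
           time = ens$time, source = ens$source, stride = ens$stride)
}

#' Stride-sample an ensemble
#'
#' Retains frames at the requested time interval (e.g. one frame per 100 ps
#' from a 10-ps recording), per source, preserving order.
#'
#' @param ens an [Ensemble].
#' @param step desired interval in ps; must be a positive multiple of the
#'   current stride.
#' @return an [Ensemble].
#' @export
stride_sample <- function(ens, step) {
  if (step < ens$stride) stop("step (", step, " ps) smaller than current stride (",
                              ens$stride, " ps)")
  k <- step / ens$stride
  if (abs(k - round(k)) > 1e-9) stop("step must be a multiple of the stride")
  k <- as.integer(round(k))
  if (k == 1L) return(ens)
  idx <- unlist(lapply(unique(ens$source), function(s) {
    which(ens$source == s)[seq(1L, sum(ens$source == s), by = k)]
  }))
  idx <- sort(idx)
  out <- subset_frames(ens, idx)
  out$stride <- step
  out
}
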