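# Topology/trajectory input and per-residue geometry: phi dihedrals and
# minimum heavy-atom distances. Reading standard formats is delegated to
# bio3d; all derived quantities are computed here.

new_structure <- function(atoms, xyz_ref) {
  stopifnot(is.data.frame(atoms), nrow(atoms) == nrow(xyz_ref))
  key <- paste(atoms$chain, atoms$resno)
  ures <- !duplicated(key)
  residues <- data.frame(
    chain = atoms$chain[ures],
    resno = atoms$resno[ures],
    resid = atoms$resid[ures],
    stringsAsFactors = FALSE
  )
  residues$label <- paste0(residues$chain, ":", residues$resno)
  if (anyDuplicated(residues$label))
    stop("residue indices must be unique within a chain")
  atoms$res_idx <- match(key, key[ures])
  structure(
    list(atoms = atoms, residues = residues, xyz_ref = xyz_ref),
    class = "ap_structure"
  )
}

#' Read a PDB topology
#'
#' Loads a PDB file with [bio3d::read.pdb()] and assembles the residue-indexed
#' atom table used by the rest of the pipeline. Only `ATOM` records are kept;
#' for alternate locations the highest-occupancy altloc of each atom is
#' retained. Hydrogens are flagged non-heavy. Residues with missing backbone
#' atoms (N, CA, C) trigger a warning and are later masked as phi-undefined.
#'
#' @param path Path to a PDB file.
#' @return An object of class `ap_structure` with components `atoms`
#'   (data frame: `eleno`, `elety`, `resid`, `resno`, `chain`, `is_heavy`,
#'   `res_idx`), `residues` (one row per residue, with `label` =
#'   `"<chain>:<resno>"`), and `xyz_ref` (reference coordinates, Angstrom).
#' @export
read_topology <- function(path) {
  if (!file.exists(path)) stop("topology file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE),
                  error = function(e) stop("failed to parse PDB '", path, "': ",
                                           conditionMessage(e)))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0) stop("no ATOM records in ", path)
  at$chain[is.na(at$chain) | at$chain == ""] <- "A"
  # altloc: keep highest occupancy per (chain, resno, atom name)
  if (any(!is.na(at$alt) & at$alt != "")) {
    at$o[is.na(at$o)] <- 1
    ord <- order(paste(at$chain, at$resno, at$elety), -at$o, at$eleno)
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
    at <- at[order(at$eleno), , drop = FALSE]
  }
  elety <- trimws(at$elety)
  is_h <- grepl("^[0-9]*H", elety)
  atoms <- data.frame(
    eleno = at$eleno, elety = elety, resid = at$resid,
    resno = at$resno, chain = at$chain, is_heavy = !is_h,
    stringsAsFactors = FALSE
  )
  xyz <- cbind(at$x, at$y, at$z)
  s <- new_structure(atoms, xyz)
  miss <- vapply(seq_len(nrow(s$residues)), function(i) {
    nm <- atoms$elety[s$atoms$res_idx == i]
    !all(c("N", "CA", "C") %in% nm)
  }, logical(1))
  if (any(miss))
    warning("residue(s) missing backbone atoms (phi will be undefined): ",
            paste(s$residues$label[miss], collapse = ", "))
  s
}

#' Read a DCD trajectory
#'
#' Loads a binary DCD trajectory with [bio3d::read.dcd()] and checks that its
#' atom count matches the topology.
#'
#' @param structure An `ap_structure` from [read_topology()].
#' @param path Path to a DCD file.
#' @return An object of class `ap_trajectory`: list with `xyz` (frames x 3N
#'   coordinate matrix, Angstrom), `nframes`, `natom`.
#' @export
read_trajectory <- function(structure, path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  natom_t <- ncol(xyz) / 3
  natom_s <- nrow(structure$atoms)
  if (natom_t != natom_s)
    stop("atom count mismatch: trajectory has ", natom_t,
         " atoms, topology has ", natom_s)
  if (nrow(xyz) < 1) stop("trajectory contains zero frames")
  new_trajectory(xyz)
}

new_trajectory <- function(xyz) {
  structure(list(xyz = xyz, nframes = nrow(xyz), natom = ncol(xyz) / 3),
            class = "ap_trajectory")
}

# frames x 3 coordinates of atom i across a trajectory (or reference coords).
traj_atom_xyz <- function(structure, trajectory, i) {
  if (is.null(trajectory)) {
    matrix(structure$xyz_ref[i, ], nrow = 1)
  } else {
    trajectory$xyz[, (3 * i - 2):(3 * i), drop = FALSE]
  }
}

# For each residue, the atom indices of its phi-defining quartet
# C(i-1), N(i), CA(i), C(i), or NULL if phi is undefined.
phi_atom_indices <- function(structure) {
  res <- structure$residues
  at <- structure$atoms
  find_atom <- function(ri, name) {
    w <- which(at$res_idx == ri & at$elety == name)
    if (length(w)) w[1] else NA_integer_
  }
  lapply(seq_len(nrow(res)), function(i) {
    if (i == 1) return(NULL)
    # preceding residue: same chain, immediately preceding sequence number
    if (res$chain[i - 1] != res$chain[i] ||
        res$resno[i - 1] != res$resno[i] - 1) return(NULL)
    idx <- c(find_atom(i - 1, "C"), find_atom(i, "N"),
             find_atom(i, "CA"), find_atom(i, "C"))
    if (anyNA(idx)) return(NULL)
    idx
  })
}

#' Per-frame phi dihedral angles
#'
#' Computes the backbone phi torsion C(i-1)-N(i)-CA(i)-C(i) for every residue
#' and frame, in degrees wrapped to `[-180, 180)`. The first residue of each
#' chain has no preceding carbonyl carbon and is undefined (`NA`), as is any
#' residue lacking backbone atoms or, per frame, any near-collinear quartet.
#'
#' @param structure An `ap_structure`.
#' @param trajectory An `ap_trajectory`, or `NULL` to use the reference
#'   coordinates as a single frame.
#' @return An `ap_dihedrals` object: a frames x residues numeric matrix
#'   (degrees) with residue labels as column names and attributes `valid`
#'   (logical, per residue) and `labels`.
#' @export
compute_phi <- function(structure, trajectory = NULL) {
  quartets <- phi_atom_indices(structure)
  res <- structure$residues
  nf <- if (is.null(trajectory)) 1L else trajectory$nframes
  out <- matrix(NA_real_, nf, nrow(res), dimnames = list(NULL, res$label))
  for (i in seq_along(quartets)) {
    q <- quartets[[i]]
    if (is.null(q)) next
    out[, i] <- dihedral_angle(
      traj_atom_xyz(structure, trajectory, q[1]),
      traj_atom_xyz(structure, trajectory, q[2]),
      traj_atom_xyz(structure, trajectory, q[3]),
      traj_atom_xyz(structure, trajectory, q[4])
    )
  }
  valid <- !vapply(quartets, is.null, logical(1))
  ncoll <- sum(is.na(out[, valid, drop = FALSE]))
  if (ncoll > 0)
    warning(ncoll, " frame/residue phi value(s) undefined ",
            "(collinear defining atoms)")
  new_dihedrals(out, valid)
}

new_dihedrals <- function(mat, valid = NULL) {
  if (is.null(valid)) valid <- apply(mat, 2, function(x) any(!is.na(x)))
  structure(mat, valid = valid, labels = colnames(mat),
            class = c("ap_dihedrals", "matrix", "array"))
}

#' Minimum inter-residue heavy-atom distances
#'
#' Entry (i, j) is the minimum over the selected frames, and over all heavy
#' atom pairs, of the Euclidean distance between residues i and j (Angstrom).
#' Used for the contact-graph cutoff, the distant-pair selection and the
#' path-overlap metric.
#'
#' @param structure An `ap_structure`.
#' @param trajectory An `ap_trajectory` or `NULL` (reference coordinates).
#' @param frames Frame selection: `"first"` (default), `"all"`, or an integer
#'   vector of frame indices.
#' @return An `ap_distmat`: symmetric residues x residues matrix (labels as
#'   dimnames) with zero diagonal and attribute `frames` recording the
#'   selection.
#' @export
residue_min_distances <- function(structure, trajectory = NULL,
                                  frames = "first") {
  nf <- if (is.null(trajectory)) 1L else trajectory$nframes
  sel <- if (identical(frames, "first")) 1L
         else if (identical(frames, "all")) seq_len(nf)
         else as.integer(frames)
  if (length(sel) == 0) stop("empty frame selection")
  if (any(sel < 1 | sel > nf)) stop("frame selection out of range")
  heavy <- which(structure$atoms$is_heavy)
  ri <- structure$atoms$res_idx[heavy]
  nres <- nrow(structure$residues)
  groups <- split(seq_along(heavy), ri)
  d2min <- matrix(Inf, nres, nres)
  for (f in sel) {
    X <- if (is.null(trajectory)) structure$xyz_ref[heavy, , drop = FALSE]
         else matrix(trajectory$xyz[f, ], ncol = 3, byrow = TRUE)[heavy, , drop = FALSE]
    sq <- rowSums(X^2)
    D2 <- outer(sq, sq, "+") - 2 * tcrossprod(X)
    for (gi in seq_along(groups)) {
      rows <- groups[[gi]]
      cm <- if (length(rows) == 1) D2[rows, ] else
        do.call(pmin, lapply(rows, function(r) D2[r, ]))
      i <- as.integer(names(groups)[gi])
      for (gj in seq_along(groups)) {
        j <- as.integer(names(groups)[gj])
        v <- min(cm[groups[[gj]]])
        if (v < d2min[i, j]) d2min[i, j] <- v
      }
    }
  }
  d <- sqrt(pmax(d2min, 0))
  diag(d) <- 0
  dimnames(d) <- list(structure$residues$label, structure$residues$label)
  base::structure(d, frames = sel, class = c("ap_distmat", "matrix", "array"))
}

#' @export
print.ap_structure <- function(x, ...) {
  cat("MD topology:", nrow(x$atoms), "atoms,",
      nrow(x$residues), "residues,",
      length(unique(x$residues$chain)), "chain(s)\n")
  invisible(x)
}

#' @export
print.ap_trajectory <- function(x, ...) {
  cat("MD trajectory:", x$nframes, "frames,", x$natom, "atoms\n")
  invisible(x)
}
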