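# Synthetic fixtures: small chain structures and trajectories with planted,
# tunable dihedral correlations, so every pipeline stage can be exercised
# without external MD data. The coupling model is a per-frame hidden
# categorical state with m angular sectors: each coupled residue's phi falls
# in the latent sector with probability kappa + (1 - kappa)/m and in a
# uniformly chosen sector otherwise, giving a closed-form mutual information
# for use as an analytic oracle. The PDB and DCD writers live here, not in
# the reader module, so round-trip tests cross the module boundary.

#' Build a synthetic extended-chain structure
#'
#' Lays `n_residues` minimal backbones (N, CA, C per residue) along the x
#' axis with `ca_spacing` between consecutive C-alpha atoms, so that
#' sequence-adjacent residues are within the 5 Angstrom contact cutoff while
#' residues four or more apart exceed the 12 Angstrom separation cutoff.
#' With `n_chains > 1`, parallel chains (A, B, ...) are stacked `chain_sep`
#' apart in y, close enough that cross-chain contacts ("rungs") exist and the
#' contact graph offers alternative routes.
#'
#' @param n_residues Residues per chain (>= 4).
#' @param ca_spacing C-alpha spacing in Angstrom (default 3.8).
#' @param n_chains Number of parallel chains (default 1).
#' @param chain_sep Inter-chain spacing in Angstrom (default 4.6).
#' @param pdb_file Optional path; when given, a PDB file is written.
#' @return An `ap_structure`.
#' @export
make_chain_structure <- function(n_residues, ca_spacing = 3.8, n_chains = 1,
                                 chain_sep = 4.6, pdb_file = NULL) {
  stopifnot(n_residues >= 4, n_chains >= 1)
  chains <- LETTERS[seq_len(n_chains)]
  rows <- list()
  for (ci in seq_len(n_chains)) {
    y0 <- chain_sep * (ci - 1)
    for (i in seq_len(n_residues)) {
      cax <- ca_spacing * (i - 1)
      rows[[length(rows) + 1]] <- data.frame(
        elety = c("N", "CA", "C"),
        resid = "ALA", resno = i, chain = chains[ci],
        x = c(cax - 1.45, cax, cax + 0.55),
        y = c(y0, y0, y0 + 1.40),
        z = 0,
        stringsAsFactors = FALSE
      )
    }
  }
  df <- do.call(rbind, rows)
  df$eleno <- seq_len(nrow(df))
  df$is_heavy <- TRUE
  s <- new_structure(
    df[, c("eleno", "elety", "resid", "resno", "chain", "is_heavy")],
    unname(as.matrix(df[, c("x", "y", "z")]))
  )
  if (!is.null(pdb_file)) write_fixture_pdb(s, pdb_file)
  s
}

#' Write an `ap_structure` as a minimal PDB file
#'
#' Fixed-column ATOM records with TER between chains; intended for fixture
#' round trips against [read_topology()].
#'
#' @param structure An `ap_structure`.
#' @param path Output PDB path.
#' @return `path`, invisibly.
#' @export
write_fixture_pdb <- function(structure, path) {
  at <- structure$atoms
  xyz <- structure$xyz_ref
  lines <- character(0)
  for (i in seq_len(nrow(at))) {
    name4 <- if (nchar(at$elety[i]) < 4) sprintf(" %-3s", at$elety[i])
             else at$elety[i]
    elem <- substr(at$elety[i], 1, 1)
    lines <- c(lines, sprintf(
      "ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      at$eleno[i], name4, at$resid[i], at$chain[i], at$resno[i],
      xyz[i, 1], xyz[i, 2], xyz[i, 3], elem))
    last_of_chain <- i == nrow(at) || at$chain[i + 1] != at$chain[i]
    if (last_of_chain)
      lines <- c(lines, sprintf("TER   %5d      %-3s %1s%4d",
                                at$eleno[i] + 1, at$resid[i], at$chain[i],
                                at$resno[i]))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Write an `ap_trajectory` as a binary DCD file
#'
#' Minimal CHARMM-style DCD writer (little-endian, float32 coordinates, no
#' unit cell); validated against [bio3d::read.dcd()].
#'
#' @param trajectory An `ap_trajectory`.
#' @param path Output DCD path.
#' @return `path`, invisibly.
#' @export
write_fixture_dcd <- function(trajectory, path) {
  xyz <- trajectory$xyz
  nframes <- nrow(xyz); natom <- ncol(xyz) / 3
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(payload) {
    writeBin(length(payload), con, size = 4, endian = "little")
    writeBin(payload, con)
    writeBin(length(payload), con, size = 4, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nframes; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nframes
  icntrl[20] <- 24L
  rec(c(charToRaw("CORD"),
        writeBin(icntrl, raw(), size = 4, endian = "little")))
  rec(c(writeBin(1L, raw(), size = 4, endian = "little"),
        charToRaw(sprintf("%-80s", "allopath synthetic trajectory"))))
  rec(writeBin(as.integer(natom), con = raw(), size = 4, endian = "little"))
  xi <- 3 * seq_len(natom) - 2
  for (f in seq_len(nframes)) {
    for (off in 0:2)
      rec(writeBin(as.numeric(xyz[f, xi + off]), raw(), size = 4,
                   endian = "little"))
  }
  invisible(path)
}

# Draw the planted phi target matrix (frames x residues, NA for residues
# without phi) under the latent-sector coupling model.
draw_coupled_phi <- function(structure, frames, coupled, kappa, m, seed) {
  res <- structure$residues
  nres <- nrow(res)
  has_phi <- !vapply(phi_atom_indices(structure), is.null, logical(1))
  w <- 360 / m
  with_seed(seed, {
    z <- sample.int(m, frames, replace = TRUE)   # latent state per frame
    phi <- matrix(NA_real_, frames, nres, dimnames = list(NULL, res$label))
    for (j in which(has_phi)) {
      if (res$label[j] %in% coupled) {
        follow <- stats::runif(frames) < kappa
        sector <- ifelse(follow, z, sample.int(m, frames, replace = TRUE))
        phi[, j] <- -180 + (sector - 1) * w + stats::runif(frames) * w
      } else {
        phi[, j] <- stats::runif(frames, -180, 180)
      }
    }
    list(phi = phi, z = z, has_phi = has_phi)
  })
}

#' Synthesize a trajectory with planted dihedral correlations
#'
#' Draws target phi angles under the latent-sector coupling model (coupling
#' strength `kappa` in `[0, 1]`, `m` angular sectors; `kappa = 0` gives fully
#' independent residues, `kappa = 1` deterministic copies of the latent
#' state), then rotates each residue's carbonyl carbon about its N-CA bond
#' axis, frame by frame, so that [compute_phi()] recovers the planted angles
#' to well below 1e-3 degrees. N and CA atoms stay fixed, so contact
#' distances are essentially those of the reference structure.
#'
#' @param structure An `ap_structure` from [make_chain_structure()].
#' @param frames Number of frames.
#' @param coupled Residue labels to couple (default: all phi-bearing
#'   residues of chain A).
#' @param kappa Coupling strength in `[0, 1]` (default 0.9).
#' @param m Number of latent sectors (default 4).
#' @param seed Integer seed (default 0).
#' @param dcd_file Optional path; when given, the trajectory is written as
#'   DCD.
#' @return List: `trajectory` (`ap_trajectory`), `phi` (planted
#'   `ap_dihedrals`), `coupled`, `latent` (per-frame latent state).
#' @export
make_coupled_trajectory <- function(structure, frames, coupled = NULL,
                                    kappa = 0.9, m = 4, seed = 0,
                                    dcd_file = NULL) {
  stopifnot(frames >= 1, kappa >= 0, kappa <= 1, m >= 2)
  res <- structure$residues
  quartets <- phi_atom_indices(structure)
  has_phi <- !vapply(quartets, is.null, logical(1))
  if (is.null(coupled)) {
    coupled <- res$label[has_phi & res$chain == res$chain[1]]
  } else {
    bad <- setdiff(coupled, res$label[has_phi])
    if (length(bad))
      stop("coupled residues without a defined phi: ",
           paste(bad, collapse = ", "))
  }
  drawn <- draw_coupled_phi(structure, frames, coupled, kappa, m, seed)
  natom <- nrow(structure$atoms)
  xyz <- matrix(rep(as.numeric(t(structure$xyz_ref)), each = frames),
                frames, 3 * natom)
  cols <- function(i) (3 * i - 2):(3 * i)
  # solve sequentially along each chain: placing C(i) fixes phi(i) exactly
  # given the already-placed C(i-1)
  for (j in seq_len(nrow(res))) {
    q <- quartets[[j]]
    if (is.null(q)) next
    target <- drawn$phi[, j]
    cprev <- xyz[, cols(q[1]), drop = FALSE]
    npos <- structure$xyz_ref[q[2], ]
    capos <- structure$xyz_ref[q[3], ]
    cref <- structure$xyz_ref[q[4], ]
    d0 <- dihedral_angle(cprev,
                         matrix(npos, frames, 3, byrow = TRUE),
                         matrix(capos, frames, 3, byrow = TRUE),
                         matrix(cref, frames, 3, byrow = TRUE))
    alpha <- (d0 - target) * pi / 180  # +rotation about N->CA lowers phi
    axis <- capos - npos
    vrot <- rotate_about_axis(
      matrix(cref - capos, frames, 3, byrow = TRUE), axis, alpha)
    xyz[, cols(q[4])] <- vrot + matrix(capos, frames, 3, byrow = TRUE)
  }
  traj <- new_trajectory(xyz)
  if (!is.null(dcd_file)) write_fixture_dcd(traj, dcd_file)
  list(trajectory = traj,
       phi = new_dihedrals(drawn$phi, has_phi),
       coupled = coupled, latent = drawn$z)
}

#' Closed-form NMI of the latent-sector coupling model
#'
#' Expected sector-level mutual information and NMI between two residues
#' coupled to the same latent state with strength `kappa`, under sector-
#' aligned binning (the population values the histogram estimator converges
#' to). Used as an analytic oracle in tests.
#'
#' @param kappa Coupling strength in `[0, 1]`.
#' @param m Number of sectors.
#' @return List with `mi` (bits), `h` (marginal sector entropy, bits) and
#'   `nmi`.
#' @export
coupling_model_nmi <- function(kappa, m = 4) {
  # P(x = a | z) = kappa [a == z] + (1 - kappa)/m ; z uniform over m
  p_same <- kappa + (1 - kappa) / m
  p_diff <- (1 - kappa) / m
  # joint over (x, y): condition on z
  p_xy_eq <- (p_same^2 + (m - 1) * p_diff^2) / m        # x == y (any value)
  p_xy_ne <- (2 * p_same * p_diff + (m - 2) * p_diff^2) / m
  px <- 1 / m
  terms <- c(m * p_xy_eq * log2(p_xy_eq / (px * px)),
             m * (m - 1) * p_xy_ne *
               (if (p_xy_ne > 0) log2(p_xy_ne / (px * px)) else 0))
  mi <- sum(terms)
  h <- log2(m)
  list(mi = mi, h = h, nmi = mi / h)
}

#' Generate planted path bundles for clustering tests
#'
#' Builds `n_bundles` spatially separated groups of synthetic paths: each
#' bundle owns a compact blob of residues (pairwise within the overlap
#' cutoff) and bundle centers are far apart, so within-bundle dissimilarity
#' is near 0 and between-bundle dissimilarity is 1. The true labels are
#' recoverable exactly.
#'
#' @param n_bundles Number of bundles (default 2).
#' @param paths_per_bundle Paths per bundle (default 10).
#' @param path_length Residues per path (default 5).
#' @param residues_per_bundle Residue pool per bundle (default
#'   `path_length + 3`).
#' @param bundle_gap Distance between bundle centers in Angstrom (default
#'   60).
#' @param blob_radius Radius of each bundle's residue blob (default 4).
#' @param seed Integer seed.
#' @return List: `paths` (`ap_pathset`), `dist` (`ap_distmat` of synthetic
#'   residue positions), `truth` (per-path bundle id).
#' @export
make_planted_bundles <- function(n_bundles = 2, paths_per_bundle = 10,
                                 path_length = 5, residues_per_bundle = NULL,
                                 bundle_gap = 60, blob_radius = 4, seed = 0) {
  stopifnot(n_bundles >= 1, paths_per_bundle >= 1, path_length >= 2)
  if (is.null(residues_per_bundle))
    residues_per_bundle <- path_length + 3
  stopifnot(residues_per_bundle >= path_length)
  with_seed(seed, {
    labels <- character(0); pos <- NULL; truth <- integer(0)
    paths <- list()
    for (b in seq_len(n_bundles)) {
      center <- c(bundle_gap * (b - 1), 0, 0)
      lab_b <- sprintf("b%dr%d", b, seq_len(residues_per_bundle))
      pos_b <- matrix(stats::runif(residues_per_bundle * 3, -blob_radius,
                                   blob_radius),
                      ncol = 3, byrow = TRUE) +
        matrix(center, residues_per_bundle, 3, byrow = TRUE)
      labels <- c(labels, lab_b); pos <- rbind(pos, pos_b)
      for (p in seq_len(paths_per_bundle)) {
        residues <- sample(lab_b, path_length)
        paths[[length(paths) + 1]] <- base::structure(
          list(residues = residues,
               score = n_bundles * paths_per_bundle -
                 (length(paths)) * 0.01,
               key = paste(residues, collapse = "-")),
          class = "ap_path")
        truth <- c(truth, b)
      }
    }
    d <- as.matrix(stats::dist(pos))
    dimnames(d) <- list(labels, labels)
    d <- base::structure(d, frames = 1L,
                         class = c("ap_distmat", "matrix", "array"))
    tab <- data.frame(
      source = vapply(paths, function(p) p$residues[1], character(1)),
      target = vapply(paths, function(p) p$residues[length(p$residues)],
                      character(1)),
      length = rep(path_length, length(paths)),
      score = vapply(paths, `[[`, numeric(1), "score"),
      stringsAsFactors = FALSE)
    ps <- base::structure(
      list(paths = paths, table = tab, k = length(paths),
           n_candidates = length(paths), n_unreachable = 0L),
      class = "ap_pathset")
    list(paths = ps, dist = d, truth = truth)
  })
}
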