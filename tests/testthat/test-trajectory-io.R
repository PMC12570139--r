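# Topology/trajectory reading and residue geometry.

test_that("synthetic PDB round-trips through the topology reader", {
  pdb <- tempfile(fileext = ".pdb")
  s <- make_chain_structure(4, pdb_file = pdb)
  s2 <- read_topology(pdb)
  expect_equal(nrow(s2$residues), 4)
  expect_equal(s2$residues$label, s$residues$label)
  expect_true(all(s2$atoms$is_heavy))
  expect_equal(s2$xyz_ref, s$xyz_ref, tolerance = 1e-3)
  # first residue has no preceding carbonyl carbon: phi undefined
  phi <- compute_phi(s2)
  expect_true(all(is.na(phi[, 1])))
  expect_false(anyNA(phi[, 2:4]))
})

test_that("each chain's first residue is phi-undefined in multi-chain systems", {
  s <- make_chain_structure(5, n_chains = 2)
  phi <- compute_phi(s)
  expect_true(all(is.na(phi[, "A:1"])))
  expect_true(all(is.na(phi[, "B:1"])))
  expect_false(anyNA(phi[, c("A:3", "B:3")]))
  expect_equal(ncol(phi), 10)
})

test_that("a residue lacking a backbone atom is warned about and masked", {
  pdb <- tempfile(fileext = ".pdb")
  s <- make_chain_structure(5, pdb_file = pdb)
  lines <- readLines(pdb)
  # drop residue 3's N atom
  drop <- grep("^ATOM", lines)[which(s$atoms$resno == 3 & s$atoms$elety == "N")]
  writeLines(lines[-drop], pdb)
  expect_warning(s2 <- read_topology(pdb), "missing backbone")
  phi <- compute_phi(s2)
  expect_true(all(is.na(phi[, "A:3"])))
  expect_false(anyNA(phi[, "A:5"]))
})

test_that("DCD round-trips and atom-count mismatches are fatal", {
  s <- make_chain_structure(4)
  dcd <- tempfile(fileext = ".dcd")
  sim <- make_coupled_trajectory(s, frames = 100, seed = 3, dcd_file = dcd)
  traj <- read_trajectory(s, dcd)
  expect_equal(traj$nframes, 100)
  expect_equal(traj$natom, nrow(s$atoms))
  expect_equal(traj$xyz, sim$trajectory$xyz, tolerance = 1e-5)
  s_big <- make_chain_structure(6)
  expect_error(read_trajectory(s_big, dcd), "atom count mismatch.*12.*18|18.*12")
  # single-frame trajectory is valid
  dcd1 <- tempfile(fileext = ".dcd")
  make_coupled_trajectory(s, frames = 1, seed = 3, dcd_file = dcd1)
  expect_equal(read_trajectory(s, dcd1)$nframes, 1)
})

test_that("planar quartets give the textbook cis/trans dihedrals", {
  trans <- allopath:::dihedral_angle(c(0, 1, 0), c(0, 0, 0),
                                     c(1, 0, 0), c(1, -1, 0))
  cis <- allopath:::dihedral_angle(c(0, 1, 0), c(0, 0, 0),
                                   c(1, 0, 0), c(1, 1, 0))
  expect_equal(trans, -180)  # 180 wrapped into [-180, 180)
  expect_equal(cis, 0)
})

test_that("phi matches an independent torsion computation on random frames", {
  s <- make_chain_structure(6)
  sim <- make_coupled_trajectory(s, frames = 25, kappa = 0.5, seed = 11)
  phi <- compute_phi(s, sim$trajectory)
  quartets <- allopath:::phi_atom_indices(s)
  for (j in which(!vapply(quartets, is.null, logical(1)))) {
    q <- quartets[[j]]
    for (f in c(1, 10, 25)) {
      pts <- t(vapply(q, function(i) sim$trajectory$xyz[f, (3 * i - 2):(3 * i)],
                      numeric(3)))
      # bio3d uses the opposite sign convention for torsions
      ref <- -bio3d::torsion.xyz(as.numeric(t(pts)), atm.inc = 4)
      dd <- (phi[f, j] - ref + 180) %% 360 - 180
      expect_lt(abs(dd), 1e-6)
    }
  }
})

test_that("phi is invariant under rigid-body motion of every frame", {
  s <- make_chain_structure(5)
  sim <- make_coupled_trajectory(s, frames = 40, kappa = 0.7, seed = 5)
  phi0 <- compute_phi(s, sim$trajectory)
  set.seed(42)
  ax <- rnorm(3); ang <- runif(1, 0, 2 * pi); shift <- rnorm(3, sd = 10)
  xyz <- sim$trajectory$xyz
  natom <- ncol(xyz) / 3
  for (f in seq_len(nrow(xyz))) {
    m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    m <- allopath:::rotate_about_axis(m, ax, ang) +
      matrix(shift, natom, 3, byrow = TRUE)
    xyz[f, ] <- as.numeric(t(m))
  }
  phi1 <- compute_phi(s, allopath:::new_trajectory(xyz))
  dd <- (unclass(phi1) - unclass(phi0) + 180) %% 360 - 180
  expect_lt(max(abs(dd), na.rm = TRUE), 1e-6)
})

test_that("phi computed on a trajectory equals frame-by-frame computation", {
  s <- make_chain_structure(5)
  sim <- make_coupled_trajectory(s, frames = 10, kappa = 0.5, seed = 9)
  phi_all <- compute_phi(s, sim$trajectory)
  for (f in c(1, 5, 10)) {
    single <- allopath:::new_trajectory(sim$trajectory$xyz[f, , drop = FALSE])
    expect_equal(unclass(compute_phi(s, single))[1, ],
                 unclass(phi_all)[f, ])
  }
})

test_that("residue minimum distances match a brute-force atom-pair scan", {
  s <- make_chain_structure(6)
  sim <- make_coupled_trajectory(s, frames = 3, kappa = 0.5, seed = 2)
  d <- residue_min_distances(s, sim$trajectory, frames = "all")
  expect_true(isSymmetric(unclass(d)))
  expect_true(all(diag(d) == 0))
  # brute force: min over frames and over all heavy-atom pairs
  nres <- nrow(s$residues)
  ref <- matrix(Inf, nres, nres)
  for (f in 1:3) {
    X <- matrix(sim$trajectory$xyz[f, ], ncol = 3, byrow = TRUE)
    for (a in seq_len(nrow(X))) {
      for (b in seq_len(nrow(X))) {
        i <- s$atoms$res_idx[a]; j <- s$atoms$res_idx[b]
        v <- sqrt(sum((X[a, ] - X[b, ])^2))
        if (v < ref[i, j]) ref[i, j] <- v
      }
    }
  }
  diag(ref) <- 0
  expect_equal(unclass(d), ref, ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("distance frame selection takes the minimum over selected frames", {
  # two single-atom "residues": 6 A apart in frame 1, 4.5 A in frame 2
  atoms <- data.frame(eleno = 1:2, elety = "CA", resid = "GLY",
                      resno = 1:2, chain = "A", is_heavy = TRUE,
                      stringsAsFactors = FALSE)
  s <- allopath:::new_structure(atoms, matrix(c(0, 0, 0, 6, 0, 0), 2, 3,
                                              byrow = TRUE))
  xyz <- rbind(c(0, 0, 0, 6, 0, 0), c(0, 0, 0, 4.5, 0, 0))
  traj <- allopath:::new_trajectory(xyz)
  expect_equal(residue_min_distances(s, traj, frames = "first")[1, 2], 6)
  expect_equal(residue_min_distances(s, traj, frames = "all")[1, 2], 4.5)
  expect_equal(residue_min_distances(s, traj, frames = 2)[1, 2], 4.5)
  expect_error(residue_min_distances(s, traj, frames = integer(0)), "empty")
})
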