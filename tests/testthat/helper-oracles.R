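# Shared fixtures and independent brute-force oracles. Oracles deliberately
# re-derive results from first principles (plain loops, explicit formulas)
# and never call the implementation paths they check.

# --- random toy structures (uses the calling test's RNG state) -------------

# atoms jittered on a cubic lattice: spacing 1.4 A, jitter 0.25 A, so all
# pairwise distances stay >= 1.4 - 2*0.25*sqrt(3) > 0.5 A
rand_mol <- function(n_at = NULL, palette = c("H", "C", "O"), id = "t") {
  if (is.null(n_at)) n_at <- sample(2:6, 1)
  grid <- as.matrix(expand.grid(0:2, 0:2, 0:2)) * 1.4
  coords <- grid[sample(nrow(grid), n_at), , drop = FALSE] +
    matrix(stats::runif(3 * n_at, -0.25, 0.25), n_at)
  molecule(sample(palette, n_at, replace = TRUE), coords, id = id)
}

rand_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3))
  r <- qr.Q(qr_)
  if (det(r) < 0) r[, 1] <- -r[, 1]
  r
}

rigid_motion <- function(mol) {
  r <- rand_rotation()
  shift <- stats::rnorm(3, sd = 5)
  molecule(mol$elements, sweep(mol$coords %*% r, 2, -shift), id = mol$id)
}

permute_atoms <- function(mol) {
  p <- sample(length(mol$elements))
  molecule(mol$elements[p], mol$coords[p, , drop = FALSE], id = mol$id)
}

# --- brute-force Coulomb matrix + bagging oracle ---------------------------

brute_cm <- function(mol) {
  z <- atomic_number(mol$elements)
  n <- length(z)
  cm <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) cm[i, j] <- 0.5 * z[i]^2.4
    else {
      r <- sqrt(sum((mol$coords[i, ] - mol$coords[j, ])^2)) /
        qd_constants()$bohr_angstrom
      cm[i, j] <- z[i] * z[j] / r
    }
  }
  cm
}

brute_bob <- function(mol, spec) {
  cm <- brute_cm(mol)
  z <- atomic_number(mol$elements)
  out <- numeric(0)
  for (k in seq_along(spec$universe)) {
    vals <- sort(diag(cm)[z == spec$universe[k]], decreasing = TRUE)
    out <- c(out, vals, numeric(spec$atom_bags[k] - length(vals)))
  }
  universe <- spec$universe
  bag_i <- 0L
  for (a in seq_along(universe)) for (b in a:length(universe)) {
    bag_i <- bag_i + 1L
    vals <- c()
    for (i in seq_along(z)) for (j in seq_along(z)) {
      if (i < j && ((z[i] == universe[a] && z[j] == universe[b]) ||
                    (z[i] == universe[b] && z[j] == universe[a])))
        vals <- c(vals, cm[i, j])
    }
    vals <- sort(vals, decreasing = TRUE)
    out <- c(out, vals, numeric(spec$bond_bags[bag_i] - length(vals)))
  }
  out
}

# --- brute-force exact-greedy tree oracle ----------------------------------

brute_tree <- function(x, g, h, lambda, gamma, max_depth, min_child = 1L,
                       depth = 0L) {
  G <- sum(g); H <- sum(h); n <- nrow(x)
  leaf <- list(leaf = TRUE, weight = -G / (H + lambda))
  if (depth >= max_depth || n < 2L * min_child) return(leaf)
  best_gain <- 0
  best <- NULL
  for (f in seq_len(ncol(x))) {
    for (thr in sort(unique(x[, f]))[-1]) {
      # threshold between consecutive distinct values, matching midpoints
      lower <- max(x[x[, f] < thr, f])
      t_mid <- (lower + thr) / 2
      left <- x[, f] < t_mid
      if (sum(left) < min_child || sum(!left) < min_child) next
      GL <- sum(g[left]); HL <- sum(h[left])
      GR <- G - GL; HR <- H - HL
      gain <- 0.5 * (GL^2 / (HL + lambda) + GR^2 / (HR + lambda) -
                       G^2 / (H + lambda)) - gamma
      if (gain > best_gain) {
        best_gain <- gain
        best <- list(feature = f, threshold = t_mid, gain = gain)
      }
    }
  }
  if (is.null(best)) return(leaf)
  left <- x[, best$feature] < best$threshold
  c(best, list(leaf = FALSE,
               left = brute_tree(x[left, , drop = FALSE], g[left], h[left],
                                 lambda, gamma, max_depth, min_child,
                                 depth + 1L),
               right = brute_tree(x[!left, , drop = FALSE], g[!left],
                                  h[!left], lambda, gamma, max_depth,
                                  min_child, depth + 1L)))
}

expect_same_tree <- function(node, oracle, tol = 1e-10) {
  expect_identical(isTRUE(node$leaf), isTRUE(oracle$leaf))
  if (isTRUE(oracle$leaf)) {
    expect_equal(node$weight, oracle$weight, tolerance = tol)
  } else {
    expect_identical(node$feature, oracle$feature)
    expect_equal(node$threshold, oracle$threshold, tolerance = tol)
    expect_equal(node$gain, oracle$gain, tolerance = tol)
    expect_same_tree(node$left, oracle$left, tol)
    expect_same_tree(node$right, oracle$right, tol)
  }
}

# --- brute-force farthest point sampling -----------------------------------

brute_fps <- function(x, n, start) {
  d <- as.matrix(stats::dist(x))
  sel <- start
  while (length(sel) < n) {
    best_i <- NA_integer_; best_d <- -Inf
    for (i in seq_len(nrow(x))) {
      if (i %in% sel) next
      mind <- min(d[i, sel])
      if (mind > best_d) { best_d <- mind; best_i <- i }
    }
    sel <- c(sel, best_i)
  }
  sel
}

# --- tight-binding fixture texts -------------------------------------------

tb_detailed_fixture <- function() c(
  "Fermi level: -4.20 eV",
  "Band energy: -14.30 eV",
  "Number of electrons: 4",
  "Energy H0: -20.50 eV",
  "Energy SCC: -0.45 eV",
  "Third order energy: -0.03 eV",
  "Repulsive energy: 0.80 eV",
  "MBD energy: -0.15 eV",
  "Dipole moment: 0.1 0.0 0.0 eA",
  "Eigenvalues /eV:",
  " -9.50  2.0",
  " -6.20  2.0",
  " -1.10  0.0",
  "  0.70  0.0",
  "Mulliken charges:",
  "  0.12",
  " -0.12")

tb_tagged_fixture <- function() c(
  "# tagged tight-binding results",
  "fermi_level = -4.20 eV",
  "band_energy = -14.30 eV",
  "n_electrons = 4",
  "e_h0 = -20.50 eV",
  "e_scc = -0.45 eV",
  "e_3rd = -0.03 eV",
  "e_rep = 0.80 eV",
  "e_mbd = -0.15 eV",
  "dipole = 0.1 0.0 0.0 eA",
  "eigenvalues = -9.50 -6.20 -1.10 0.70 eV",
  "occupations = 2 2 0 0",
  "mulliken = 0.12 -0.12")

# a tiny internally consistent record for descriptor tests
fixture_record <- function(n_atoms = 3, n_occ = 5, gap = 2.0) {
  occ <- seq(-12, by = 1.2, length.out = n_occ)
  virt <- occ[n_occ] + gap + seq(0, by = 0.9, length.out = 5)
  q <- seq_len(n_atoms) * 0.01
  q <- q - mean(q)
  qm_record(E_Fermi = occ[n_occ] + gap / 2, E_band = 2 * sum(occ),
            NE = 2 * n_occ, E_H0 = -50, E_scc = -0.4, E_3rd = -0.02,
            E_rep = 1.1, E_mbd = -0.3, mu_TB_vec = c(0.3, -0.1, 0.2),
            mo_energies = c(occ, virt), homo_index = n_occ, mulliken = q)
}
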