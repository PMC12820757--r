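bohr <- qd_constants()$bohr_angstrom

test_that("Coulomb matrix matches its defining formula", {
  expect_equal(coulomb_matrix(molecule("H", c(0, 0, 0))),
               matrix(0.5, 1, 1))
  h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, bohr)))
  expect_equal(coulomb_matrix(h2), rbind(c(0.5, 1), c(1, 0.5)),
               tolerance = 1e-12)
  # heteronuclear check against the brute-force construction
  set.seed(3)
  m <- rand_mol(5, palette = c("C", "O", "H"))
  expect_equal(coulomb_matrix(m), brute_cm(m), tolerance = 1e-12)
  bad <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0)))
  expect_error(coulomb_matrix(bad), "degenerate")
})

test_that("bag layouts are sized by dataset maxima", {
  h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)), id = "h2")
  spec <- fit_bag_spec(list(h2))
  expect_equal(unname(spec$atom_bags), 2L)
  expect_equal(unname(spec$bond_bags), 1L)

  h2o <- molecule(c("O", "H", "H"),
                  rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
                  id = "h2o")
  spec2 <- fit_bag_spec(list(h2o, h2))
  expect_equal(spec2$atom_bags, c(H = 2L, O = 1L))
  expect_equal(spec2$bond_bags, c(HH = 1L, HO = 2L, OO = 0L))

  he <- molecule("He", c(0, 0, 0))
  spec3 <- fit_bag_spec(list(he))
  expect_true(all(spec3$bond_bags == 0L))
  expect_error(fit_bag_spec(list()), "empty")
})

test_that("bob_vector bags the Coulomb matrix with padding", {
  h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, bohr)), id = "h2")
  spec <- fit_bag_spec(list(h2))
  expect_equal(unname(bob_vector(h2, spec)), c(0.5, 0.5, 1.0),
               tolerance = 1e-12)
  # padding under an enlarged bond bag
  spec_pad <- spec
  spec_pad$bond_bags[] <- 3L
  spec_pad$length <- sum(spec_pad$atom_bags) + sum(spec_pad$bond_bags)
  expect_equal(unname(bob_vector(h2, spec_pad)), c(0.5, 0.5, 1, 0, 0),
               tolerance = 1e-12)
  # overflow is a spec mismatch
  h3 <- molecule(c("H", "H", "H"), diag(3), id = "h3")
  expect_error(bob_vector(h3, spec), "overflows")
  expect_error(bob_vector(molecule("O", c(0, 0, 0)), spec),
               "outside the bag universe")
})

test_that("bob_vector equals independent bagging of brute-force CMs", {
  set.seed(11)
  mols <- lapply(1:12, function(i) rand_mol(id = paste0("b", i)))
  spec <- fit_bag_spec(mols)
  for (m in mols)
    expect_equal(unname(bob_vector(m, spec)), brute_bob(m, spec),
                 tolerance = 1e-12)
})

test_that("SLATM blocks evaluate the defining sums", {
  s1 <- slatm_spec(1L)
  v <- slatm_vector(molecule("H", c(0, 0, 0)), s1)
  expect_equal(unname(v[1]), 1)          # count * Z
  expect_true(all(v[-1] == 0))           # no pairs, no triples

  # two-body spectrum at the pair distance
  ss <- slatm_spec(1L, r_min = 0.97, r_cut = 1.03, dr = 0.03, sigma2 = 0.05)
  h2 <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 1.0)))
  v2 <- slatm_vector(h2, ss)
  expect_equal(unname(v2[["2b_HH_2"]]),
               1 / (0.05 * sqrt(2 * pi)) * 0.03, tolerance = 1e-6)

  # equilateral triangle: angular peak at pi/3 with ATM weight 1 + 3/8
  h3 <- molecule(c("H", "H", "H"),
                 rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0)))
  s3 <- slatm_spec(1L)
  v3 <- slatm_vector(h3, s3)
  three <- v3[startsWith(names(v3), "3b_")]
  grid <- s3$t_grid
  peak_idx <- which.max(three)
  expect_lt(abs(grid[((peak_idx - 1) %% length(grid)) + 1] - pi / 3),
            s3$dtheta)
  # integrating out the smearing recovers 3 triples x ATM factor / r^9
  expect_equal(sum(three), 3 * (1 + 3 * 0.5^3) * 1.0, tolerance = 1e-3)
  expect_error(slatm_vector(molecule("O", c(0, 0, 0)), s1),
               "outside the SLATM universe")
})

test_that("descriptors are invariant to rigid motion and permutation", {
  set.seed(21)
  mols <- lapply(1:10, function(i) rand_mol(id = paste0("inv", i)))
  space <- fit_descriptor_space(mols)
  for (m in mols[1:4]) {
    b0 <- bob_vector(m, space$bag)
    s0 <- slatm_vector(m, space$slatm)
    e0 <- sort(eigen(coulomb_matrix(m), only.values = TRUE)$values)
    for (k in 1:3) {
      mm <- rigid_motion(m)
      expect_lt(sqrt(sum((bob_vector(mm, space$bag) - b0)^2)) /
                  sqrt(sum(b0^2)), 1e-8)
      expect_lt(sqrt(sum((slatm_vector(mm, space$slatm) - s0)^2)) /
                  sqrt(sum(s0^2)), 1e-8)
      ee <- sort(eigen(coulomb_matrix(mm), only.values = TRUE)$values)
      expect_equal(ee, e0, tolerance = 1e-8)
      mp <- permute_atoms(m)
      expect_equal(bob_vector(mp, space$bag), b0, tolerance = 1e-12)
      expect_equal(slatm_vector(mp, space$slatm), s0, tolerance = 1e-12)
    }
  }
})

test_that("SLATM is smooth under small coordinate perturbations", {
  set.seed(31)
  m <- rand_mol(5)
  space <- fit_descriptor_space(list(m))
  s0 <- slatm_vector(m, space$slatm)
  m2 <- m
  m2$coords[2, 1] <- m2$coords[2, 1] + 1e-4
  s1 <- slatm_vector(molecule(m2$elements, m2$coords), space$slatm)
  rel <- sqrt(sum((s1 - s0)^2)) / sqrt(sum(s0^2))
  expect_lt(rel, 1e-2)
  expect_gt(rel, 0)  # it does respond, continuously
})

test_that("all vectors under one spec share a fixed length", {
  set.seed(41)
  mols <- lapply(1:8, function(i) rand_mol(id = paste0("fl", i)))
  space <- fit_descriptor_space(mols)
  bl <- geometry_block(mols, space$bag)
  sl <- geometry_block(mols, space$slatm)
  expect_identical(ncol(bl$matrix), space$bag$length)
  expect_identical(ncol(sl$matrix), space$slatm$length)
  expect_identical(nrow(sl$matrix), 8L)
})
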