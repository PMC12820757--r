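test_that("Kabsch RMSD is zero for congruent structures and symmetric", {
  set.seed(33)
  # tabulated two-point case: centered offsets differ by 0.5 per atom
  a <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  b <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(kabsch_rmsd(a, b), 0.5, tolerance = 1e-12)
  expect_equal(kabsch_rmsd(b, a), kabsch_rmsd(a, b), tolerance = 1e-10)

  rot90z <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))
  m <- rand_mol(5)
  moved <- molecule(m$elements, sweep(m$coords %*% t(rot90z), 2, -3))
  expect_lt(kabsch_rmsd(m, moved), 1e-10)

  for (i in 1:50) {
    mm <- rand_mol(4)
    expect_lt(kabsch_rmsd(mm, rigid_motion(mm)), 1e-10)
  }
  mism <- molecule(c("H", "O"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_error(kabsch_rmsd(a, mism), "element sequences differ")
})

test_that("reflections are not counted as congruences", {
  set.seed(34)
  m <- rand_mol(5)
  mirrored <- molecule(m$elements, m$coords %*% diag(c(-1, 1, 1)))
  # a chiral cloud only superposes up to proper rotations
  expect_gt(kabsch_rmsd(m, mirrored), 1e-4)
})

test_that("admission applies the energy window and RMSD distinctness", {
  kcal <- qd_constants()$kcalmol_ev
  base <- molecule(c("O", "H"), rbind(c(0, 0, 0), c(1, 0, 0)), id = "c0")
  stretch <- function(d) molecule(c("O", "H"),
                                  rbind(c(0, 0, 0), c(d, 0, 0)), id = "c")
  # energies in eV relative to the reference, conformers visibly distinct
  ens <- conformer_ensemble("m", list(base, stretch(1.5), stretch(2.0)),
                            energies = c(0, 5 * kcal, 13 * kcal))
  kept <- admit_ensemble(ens, ref = 1, curation_config())
  expect_length(kept$conformers, 2L)  # 13 kcal/mol falls outside the window
  expect_identical(attr(kept, "report")$status,
                   c("reference", "kept", "energy_window"))

  # duplicates of the reference are redundant
  dup <- conformer_ensemble("m", list(base, base), energies = c(0, 0))
  kept2 <- admit_ensemble(dup, 1, curation_config())
  expect_length(kept2$conformers, 1L)

  far <- conformer_ensemble("m", list(base, stretch(1.4)),
                            energies = c(0, 20 * kcal))
  expect_length(admit_ensemble(far, 1)$conformers, 1L)
  expect_error(admit_ensemble(ens, ref = 9), "out of range")
})

test_that("RMSD clustering keeps lowest-energy representatives", {
  base <- molecule(c("O", "H", "H"),
                   rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)), id = "a")
  twin <- molecule(base$elements, sweep(base$coords %*% rand_rotation(),
                                        2, -2), id = "b")
  far <- molecule(base$elements,
                  rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)), id = "c")
  ens <- conformer_ensemble("m", list(base, twin, far),
                            energies = c(-1.0, -1.2, -0.9))
  cfg <- curation_config(cluster_cut = 1.0)
  reps <- cluster_conformers(ens, cfg)
  expect_length(reps$conformers, 2L)
  # the identical pair collapses to its lower-energy member
  expect_equal(sort(reps$energies), c(-1.2, -0.9))

  all_own <- cluster_conformers(ens, curation_config(cluster_cut = 0))
  expect_length(all_own$conformers, 3L)
  one <- cluster_conformers(ens, curation_config(cluster_cut = 100))
  expect_length(one$conformers, 1L)
  expect_equal(one$energies, -1.2)  # lowest energy wins the single cluster
  single <- conformer_ensemble("s", list(base), energies = -1)
  expect_length(cluster_conformers(single, cfg)$conformers, 1L)
})

test_that("element filtering reports offenders and is idempotent", {
  ch4 <- molecule(c("C", "H", "H", "H", "H"),
                  rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                        c(-1, 0, 0)), id = "ch4")
  sih4 <- molecule(c("Si", "H", "H", "H", "H"), ch4$coords, id = "sih4")
  allowed <- c("H", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")
  out <- filter_elements(list(ch4, sih4), allowed)
  expect_length(out$dataset, 1L)
  expect_identical(out$dataset[[1]]$id, "ch4")
  expect_identical(out$report$molecule_id, "sih4")
  expect_identical(out$report$offending, "Si")
  # idempotence
  again <- filter_elements(out$dataset, allowed)
  expect_identical(length(again$dataset), 1L)
  expect_identical(nrow(again$report), 0L)
  # identity when everything is allowed; empty input stays empty
  expect_length(filter_elements(list(ch4, sih4),
                                c(allowed, "Si"))$dataset, 2L)
  expect_length(filter_elements(list(), allowed)$dataset, 0L)

  # dataset variant also drops records and target rows
  recs <- list(ch4 = fixture_record(5), sih4 = fixture_record(5))
  tgt <- property_table(data.frame(molecule_id = c("ch4", "sih4"),
                                   LD50 = c(2, 3)),
                        c(LD50 = "log(mol/kg)"))
  ds <- qd_dataset(list(ch4, sih4), recs, tgt)
  fds <- filter_elements(ds, allowed)$dataset
  expect_length(fds$molecules, 1L)
  expect_identical(names(fds$records), "ch4")
  expect_identical(fds$targets$molecule_id, "ch4")
})

test_that("lowest-energy conformer selection breaks ties by first index", {
  m <- molecule(c("H", "H"), rbind(c(0, 0, 0), c(1, 0, 0)))
  mk <- function(e) {
    mm <- m; mm$energy_tb <- e
    mm
  }
  groups <- list(
    a = conformer_ensemble("a", list(mk(-1.0), mk(-1.2), mk(-0.9))),
    b = conformer_ensemble("b", list(mk(-1.0), mk(-1.0))),
    c = conformer_ensemble("c", list(mk(0.5))))
  sel <- select_lowest_energy(groups)
  expect_equal(sel$a$energy_tb, -1.2)
  expect_equal(sel$b$energy_tb, -1.0)  # tie resolves to the first
  expect_equal(sel$c$energy_tb, 0.5)
  expect_error(conformer_ensemble("x", list(m)), "finite energies")
})
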