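test_that("read_xyz parses minimal, annotated and multi-frame input", {
  m <- read_xyz("1\n\nH 0 0 0")[[1]]
  expect_identical(m$elements, "H")
  expect_equal(m$coords, matrix(0, 1, 3))

  m <- read_xyz("2\nid=m1 energy=-1.5\nH 0 0 0\nH 0 0 0.74")[[1]]
  expect_identical(m$id, "m1")
  expect_equal(m$energy_tb, -1.5)
  expect_identical(n_atoms(m), 2L)

  two <- read_xyz(c("1", "", "H 0 0 0", "1", "", "O 0 0 1.2"))
  expect_length(two, 2L)
  expect_identical(two[[2]]$elements, "O")
})

test_that("read_xyz reports malformed input with line numbers", {
  expect_error(read_xyz("2\n\nXx 0 0 0\nH 0 0 1"), "line 3.*Xx")
  expect_error(read_xyz("x\n\nH 0 0 0"), "malformed atom-count")
  expect_error(read_xyz("1\n\nH 0 zz 0"), "line 3.*coordinate")
  expect_error(read_xyz("3\n\nH 0 0 0\nH 0 0 1"), "ends early")
})

test_that("XYZ writer round-trips random molecules through the reader", {
  set.seed(42)
  for (i in 1:100) {
    m <- rand_mol(id = paste0("rt", i))
    m$energy_tb <- stats::rnorm(1)
    back <- read_xyz(paste(write_xyz(m), collapse = "\n"))[[1]]
    expect_identical(back$elements, m$elements)
    expect_identical(back$id, m$id)
    expect_lt(max(abs(back$coords - m$coords)), 1e-9)
    expect_equal(back$energy_tb, m$energy_tb, tolerance = 1e-9)
  }
})

test_that("both tight-binding dialects parse the same fixture content", {
  for (rec in list(parse_tb_results(tb_detailed_fixture(), "detailed"),
                   parse_tb_results(tb_tagged_fixture(), "tagged"))) {
    expect_equal(rec$E_Fermi, -4.20)
    expect_equal(rec$E_band, -14.30)
    expect_equal(rec$NE, 4)
    expect_equal(rec$E_mbd, -0.15)
    expect_equal(rec$mu_TB_norm, 0.1)
    # gap from the eigenvalue list: eps_3 - eps_2
    expect_equal(rec$E_gap_TB, -1.10 - (-6.20), tolerance = 1e-12)
    expect_identical(rec$homo_index, 2L)
    expect_equal(sum(rec$mulliken), 0, tolerance = 1e-12)
  }
})

test_that("installed fixture files parse identically to the inline text", {
  det <- system.file("extdata", "tb_detailed_example.txt",
                     package = "quantdesc")
  tag <- system.file("extdata", "tb_tagged_example.txt",
                     package = "quantdesc")
  expect_equal(parse_tb_results(det, "detailed"),
               parse_tb_results(tb_detailed_fixture(), "detailed"))
  expect_equal(parse_tb_results(tag, "tagged"),
               parse_tb_results(tb_tagged_fixture(), "tagged"))
})

test_that("parser converts Hartree and atomic-unit dipoles to eV / eA", {
  hartree <- 27.211386245988
  lines <- c("fermi_level = -0.2 H", "band_energy = -1.0 H",
             "n_electrons = 2", "e_h0 = -1.5 H", "e_scc = -0.02 H",
             "e_3rd = -0.001 H", "e_rep = 0.05 H", "e_mbd = -0.01 H",
             "dipole = 0.5 0 0 au",
             "eigenvalues = -0.5 -0.2 0.1 0.3 H",
             "occupations = 2 0 0 0",
             "mulliken = 0.0 0.0")
  rec <- parse_tb_results(lines, "tagged")
  expect_equal(rec$E_Fermi, -0.2 * hartree, tolerance = 1e-12)
  expect_equal(rec$E_gap_TB, 0.3 * hartree, tolerance = 1e-9)
  expect_equal(rec$mu_TB_norm, 0.5 * 0.529177210903, tolerance = 1e-12)
})

test_that("parser flags missing fields, bad gaps and zero dipoles", {
  no_mull <- tb_detailed_fixture()[1:14]
  expect_error(parse_tb_results(no_mull, "detailed"), "mulliken")

  bad_gap <- c(tb_tagged_fixture(), "gap = 1.0 eV")
  expect_error(parse_tb_results(bad_gap, "tagged"), "integrity")

  zero_dip <- sub("dipole = 0.1 0.0 0.0 eA", "dipole = 0 0 0 eA",
                  tb_tagged_fixture(), fixed = TRUE)
  expect_equal(parse_tb_results(zero_dip, "tagged")$mu_TB_norm, 0)
})

test_that("dataset archive round-trips field-by-field", {
  empty <- qd_dataset(list())
  p <- withr::local_tempfile(fileext = ".json")
  save_dataset(empty, p)
  expect_length(load_dataset(p)$molecules, 0L)

  set.seed(7)
  mols <- lapply(1:3, function(i) rand_mol(id = paste0("m", i)))
  recs <- list(m1 = fixture_record(n_atoms(mols[[1]])),
               m2 = fixture_record(n_atoms(mols[[2]])))
  tgt <- property_table(
    data.frame(molecule_id = c("m1", "m2", "m3"),
               mu = c(0.11, 2.2, 3.14159265358979),
               E_AT = c(-31.25, -60.5, -90.125)),
    units = c(mu = "eA", E_AT = "eV"))
  ds <- qd_dataset(mols, recs, tgt, provenance = "unit-test fixture")
  save_dataset(ds, p)
  back <- load_dataset(p)
  expect_identical(length(back$molecules), 3L)
  for (i in 1:3)
    expect_lt(max(abs(back$molecules[[i]]$coords - mols[[i]]$coords)), 1e-12)
  expect_equal(back$records$m2$mo_energies, recs$m2$mo_energies,
               tolerance = 1e-12)
  expect_equal(back$targets$mu, tgt$mu, tolerance = 1e-12)
  expect_identical(attr(back$targets, "units"), attr(tgt, "units"))
  expect_identical(back$provenance, "unit-test fixture")
  expect_identical(dataset_n_max(back), dataset_n_max(ds))
})

test_that("archives with dangling record keys are rejected on load", {
  set.seed(8)
  ds <- qd_dataset(list(rand_mol(3, id = "m1")),
                   list(m1 = fixture_record(3)))
  p <- withr::local_tempfile(fileext = ".json")
  save_dataset(ds, p)
  # rename the molecule in the raw archive so the record key m1 dangles
  txt <- sub("\"id\":\"m1\"", "\"id\":\"renamed\"", readLines(p, warn = FALSE))
  writeLines(txt, p)
  expect_error(load_dataset(p), "record key")
  # a truncated archive errors instead of returning partial data
  trunc <- withr::local_tempfile(fileext = ".json")
  writeLines(substr(paste(txt, collapse = ""), 1, 50), trunc)
  expect_error(suppressWarnings(load_dataset(trunc)), "cannot load|archive")
})

test_that("property tables enforce keys and units", {
  expect_error(property_table(data.frame(mu = 1), c(mu = "eA")),
               "molecule_id")
  expect_error(property_table(data.frame(molecule_id = "a", mu = 1),
                              c()), "unit label")
  expect_error(property_table(
    data.frame(molecule_id = c("a", "a"), mu = 1:2), c(mu = "eA")),
    "duplicate")
})

test_that("qm_record enforces its invariants", {
  r <- fixture_record()
  expect_equal(r$mu_TB_norm, sqrt(sum(r$mu_TB_vec^2)), tolerance = 1e-12)
  expect_equal(r$E_gap_TB,
               r$mo_energies[r$homo_index + 1] - r$mo_energies[r$homo_index],
               tolerance = 1e-9)
  expect_error(qm_record(0, 0, 2, 0, 0, 0, 0, 0, c(0, 0, 0),
                         mo_energies = c(1, -1), homo_index = 1,
                         mulliken = 0), "ascending")
  expect_error(qm_record(0, 0, 2, 0, 0, 0, 0, 0, c(0, 0, 0),
                         mo_energies = c(-1, 1), homo_index = 1,
                         mulliken = c(0.5, 0.1)), "Mulliken")
})
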