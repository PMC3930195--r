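test_that("parse_structure reads heavy atoms and assigns radii", {
  txt <- pdb_text(
    pdb_atom_line(1, "N",  " ", "ALA", "A", 1, 0, 0, 0, elem = "N"),
    pdb_atom_line(2, "CA", " ", "ALA", "A", 1, 1.5, 0, 0, elem = "C"),
    pdb_atom_line(3, "O",  " ", "ALA", "A", 1, 2.5, 1, 0, elem = "O"))
  at <- parse_structure(txt)
  expect_equal(nrow(at), 3L)
  expect_equal(at$radius, c(1.65, 1.87, 1.40))
  expect_equal(at$residue_index, c(1L, 1L, 1L))
  expect_equal(at$residue_name, rep("ALA", 3L))
})

test_that("parse_structure keeps the highest-occupancy altloc", {
  txt <- pdb_text(
    pdb_atom_line(1, "CA", "A", "ALA", "A", 1, 0, 0, 0, occ = 0.6),
    pdb_atom_line(2, "CA", "B", "ALA", "A", 1, 5, 0, 0, occ = 0.4))
  at <- parse_structure(txt)
  expect_equal(nrow(at), 1L)
  expect_equal(at$x, 0)
  # occupancy wins even when the lower-occupancy record comes first
  txt2 <- pdb_text(
    pdb_atom_line(1, "CA", "A", "ALA", "A", 1, 0, 0, 0, occ = 0.3),
    pdb_atom_line(2, "CA", "B", "ALA", "A", 1, 5, 0, 0, occ = 0.7))
  expect_equal(parse_structure(txt2)$x, 5)
})

test_that("parse_structure rejects empty or unparseable content", {
  water <- pdb_text(
    pdb_atom_line(1, "O", " ", "HOH", "A", 1, 0, 0, 0, elem = "O",
                  record = "HETATM"))
  expect_error(parse_structure(water), "empty structure")
  hyd <- pdb_text(pdb_atom_line(1, "H", " ", "ALA", "A", 1, 0, 0, 0, elem = "H"))
  expect_error(parse_structure(hyd), "empty structure")
  selen <- pdb_text(
    pdb_atom_line(1, "CA", " ", "ALA", "A", 1, 0, 0, 0),
    pdb_atom_line(2, "X1", " ", "GLY", "A", 2, 3, 0, 0, elem = "X"))
  expect_error(parse_structure(selen), "unknown element 'X'")
})

test_that("parse_structure flattens residue numbering per chain", {
  txt <- pdb_text(
    pdb_atom_line(1, "CA", " ", "ALA", "A", 10, 0, 0, 0),
    pdb_atom_line(2, "CA", " ", "GLY", "A", 12, 4, 0, 0),
    pdb_atom_line(3, "CA", " ", "VAL", "B", 3, 8, 0, 0))
  at <- parse_structure(txt)
  expect_equal(at$residue_index, c(1L, 2L, 1L))
  expect_equal(at$chain, c("A", "A", "B"))
})

test_that("slice ASA reaches the isolated-sphere closed form", {
  one <- data.frame(x = 0, y = 0, z = 0, radius = 1.87)
  exact <- 4 * pi * (1.87 + 1.4)^2
  expect_lt(abs(lee_richards_asa(one, 1.4, 0.01) - exact) / exact, 0.005)
  # no occlusion beyond contact distance
  two <- data.frame(x = c(0, 7), y = 0, z = 0, radius = 1.87)
  expect_equal(lee_richards_asa(two, 1.4, 0.05), rep(exact, 2), tolerance = 1e-6)
})

test_that("point-sampling oracle handles the degenerate limits", {
  one <- data.frame(x = 0, y = 0, z = 0, radius = 1.87)
  expect_equal(shrake_rupley_asa(one, 1.4, 2000), 4 * pi * 3.27^2)
  engulfed <- data.frame(x = c(0, 0.2), y = 0, z = 0, radius = c(8, 1.4))
  expect_equal(shrake_rupley_asa(engulfed, 1.4, 1000)[2L], 0)
  expect_equal(lee_richards_asa(engulfed, 1.4, 0.05)[2L], 0)
})

test_that("slice method agrees with the point-sampling oracle on pairs", {
  pair <- data.frame(x = c(0, 3), y = 0, z = 0, radius = 1.87)
  lr <- lee_richards_asa(pair, 1.4, 0.05)
  sr <- shrake_rupley_asa(pair, 1.4, 2000)
  expect_lt(max(abs(lr - sr) / sr), 0.02)
})

test_that("coincident duplicate atoms contribute zero once", {
  dup <- data.frame(x = c(0, 0), y = 0, z = 0, radius = 1.87)
  exact <- 4 * pi * 3.27^2
  expect_equal(lee_richards_asa(dup, 1.4, 0.05), c(exact, 0), tolerance = 1e-9)
  expect_equal(shrake_rupley_asa(dup, 1.4, 1000), c(exact, 0))
})

test_that("non-finite coordinates are rejected", {
  bad <- data.frame(x = c(0, NaN), y = 0, z = 0, radius = 1.87)
  expect_error(lee_richards_asa(bad), "non-finite")
  expect_error(shrake_rupley_asa(bad), "non-finite")
})

test_that("adding an atom never increases any existing atom's ASA", {
  for (seed in 1:5) {
    at <- random_cluster(seed, n_max = 8L)
    base <- lee_richards_asa(at, 1.4, 0.05)
    set.seed(seed + 100)
    grown <- rbind(at, data.frame(x = runif(1, 0, 6), y = runif(1, 0, 6),
                                  z = runif(1, 0, 6), radius = 1.87))
    after <- lee_richards_asa(grown, 1.4, 0.05)[seq_len(nrow(at))]
    expect_true(all(after <= base + 1e-9))
  }
})

test_that("ASA is additive over non-interacting clusters", {
  a <- random_cluster(11, n_max = 5L)
  b <- random_cluster(12, n_max = 5L)
  b$x <- b$x + 50
  joint <- lee_richards_asa(rbind(a, b), 1.4, 0.05)
  expect_equal(joint, c(lee_richards_asa(a, 1.4, 0.05),
                        lee_richards_asa(b, 1.4, 0.05)), tolerance = 1e-12)
})

test_that("residue RSA is the percent of the reference area", {
  atoms <- data.frame(chain = "A", residue_index = c(1L, 1L, 2L),
                      residue_name = c("ALA", "ALA", "GLY"),
                      atom_name = "CB", x = 0, y = 0, z = 0, radius = 1.87)
  ref <- c(ALA = 100, GLY = 50)
  res <- residue_rsa(atoms, c(60, 40, 0), reference = ref)
  expect_equal(res$asa, c(100, 0))
  expect_equal(res$rsa, c(100, 0))
  res2 <- residue_rsa(atoms, c(25, 25, 10), reference = ref)
  expect_equal(res2$rsa, c(50, 20))
  expect_error(residue_rsa(atoms, c(1, 1, 1), reference = c(ALA = 100)),
               "GLY")
})

test_that("state classification uses a half-open 7 percent rule", {
  expect_equal(classify_state(c(7.1, 6.9, 7.0, 0)),
               c("exposed", "buried", "exposed", "buried"))
  expect_error(classify_state(-1), "non-negative")
  # exposed count is non-increasing in the threshold
  set.seed(3)
  rsa <- runif(200, 0, 60)
  counts <- vapply(seq(0, 50, 5),
                   function(th) sum(classify_state(rsa, th) == "exposed"), 0L)
  expect_true(all(diff(counts) <= 0L))
})

test_that("accessibility tables survive a TSV round trip", {
  sp <- fixture_spec(seed = 2, n_residues = 5, fold_style = "extended")
  res <- compute_accessibility(gen_structure(sp)$pdb,
                               reference = reference_asa("single-sphere"))
  path <- tempfile(fileext = ".tsv")
  write_rsa_tsv(res, path)
  expect_equal(read_rsa_tsv(path), res, tolerance = 1e-6)
})
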