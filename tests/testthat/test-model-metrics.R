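test_that("segment means map to the three B-factor classes at the stated thresholds", {
  m <- synthetic_chain(c(50, 130, 200))
  rep <- segment_bfactor_classify(m)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$class, c("full_side_chains", "poly_ala", "removed"))
  expect_equal(rep$mean_b, c(50, 130, 200))
  expect_equal(rep$res_start, c(1, 6, 11))
  expect_equal(rep$res_end, c(5, 10, 15))
})

test_that("boundary means of exactly 110 and 150 are poly-alanine", {
  m110 <- synthetic_chain(c(110, 110, 110))
  expect_true(all(segment_bfactor_classify(m110)$class == "poly_ala"))
  m150 <- synthetic_chain(c(150, 150, 150))
  expect_true(all(segment_bfactor_classify(m150)$class == "poly_ala"))
  m109 <- synthetic_chain(c(109.99, 109.99, 109.99))
  expect_true(all(segment_bfactor_classify(m109)$class == "full_side_chains"))
  m151 <- synthetic_chain(c(150.01, 150.01, 150.01))
  expect_true(all(segment_bfactor_classify(m151)$class == "removed"))
})

test_that("a trailing short segment is classified on its own mean", {
  m <- synthetic_chain(c(50, 130, 200))
  m7 <- atomic_model(dplyr::filter(m, resno <= 7))   # 5 + 2 residues
  rep <- segment_bfactor_classify(m7)
  expect_equal(nrow(rep), 2)
  expect_equal(rep$n_res, c(5L, 2L))
  expect_equal(rep$class, c("full_side_chains", "poly_ala"))
})

test_that("truncation edits atoms exactly as the report dictates", {
  m <- synthetic_chain(c(50, 130, 200))
  rep <- segment_bfactor_classify(m)
  out <- apply_truncation(m, rep)
  # brute-force expectation:
  # segment 1 (res 1-5, LEU, 7 atoms) kept in full: 35 atoms
  # segment 2 (res 6-10) -> poly-ala: LEU keep N,CA,C,O,CB (5), GLY at res 8
  #   keeps N,CA,C,O (4): 4 * 5 + 4 = 24 atoms, renamed ALA
  # segment 3 removed: 0 atoms
  expect_equal(nrow(out), 35 + 24)
  seg2 <- dplyr::filter(out, resno >= 6, resno <= 10)
  expect_true(all(seg2$resname == "ALA"))
  expect_true(all(seg2$atom %in% c("N", "CA", "C", "O", "CB")))
  expect_false(any(dplyr::filter(out, resno == 8)$atom == "CB"))
  expect_equal(nrow(dplyr::filter(out, resno > 10)), 0)
  # all-full model is untouched; all-removed model becomes empty
  mf <- synthetic_chain(c(10, 20, 30))
  expect_equal(nrow(apply_truncation(mf, segment_bfactor_classify(mf))),
               nrow(mf))
  mr <- synthetic_chain(c(500, 500, 500))
  expect_equal(nrow(apply_truncation(mr, segment_bfactor_classify(mr))), 0)
})

test_that("re-classifying a truncated model reproduces the kept classes", {
  m <- synthetic_chain(c(50, 130, 200))
  out <- apply_truncation(m, segment_bfactor_classify(m))
  rep2 <- segment_bfactor_classify(out)
  expect_equal(rep2$class, c("full_side_chains", "poly_ala"))
})

test_that("a regular hexagon yields six 120-degree angles summing to 720", {
  az <- (0:5) * 60 * pi / 180
  pts <- data.frame(chain = "A", resno = 1:6, resname = "ALA", atom = "CA",
                    x = 10 * cos(az), y = 10 * sin(az), z = 5, b = 30)
  m <- atomic_model(pts)
  ring <- ring_hexagon_angles(m, data.frame(chain = "A", resno = 1:6))
  expect_equal(ring$inner_angle, rep(120, 6), tolerance = 1e-6)
  expect_equal(attr(ring, "angle_sum"), 720, tolerance = 1e-6)
  expect_lt(attr(ring, "max_dev_120"), 1e-6)
})

test_that("a distorted hexagon matches an independent 2D trigonometric oracle", {
  az <- (0:5) * 60 * pi / 180
  uv <- cbind(10 * cos(az), 10 * sin(az))
  uv[3, ] <- uv[3, ] * 0.55                 # pull one vertex inward
  expected <- hexagon_angles_2d(uv)
  # embed in 3D with an arbitrary rotation + translation
  R <- rot_axis_angle(c(1, 2, 3), 37)
  xyz <- cbind(uv, 0) %*% t(R) + matrix(rep(c(5, -3, 12), each = 6), 6)
  m <- atomic_model(data.frame(chain = "B", resno = 1:6, resname = "ALA",
                               atom = "CA", x = xyz[, 1], y = xyz[, 2],
                               z = xyz[, 3], b = 1))
  ring <- ring_hexagon_angles(m, data.frame(chain = "B", resno = 1:6))
  expect_equal(ring$inner_angle, expected, tolerance = 1e-6)
  expect_equal(sum(ring$inner_angle), 720, tolerance = 1e-6)
})

test_that("ring angles are invariant under global rotation and translation", {
  set.seed(21)
  az <- sort(stats::runif(6, 0, 2 * pi))
  uv <- cbind(8 * cos(az), 8 * sin(az)) + matrix(stats::rnorm(12, 0, 0.4), 6)
  base <- atomic_model(data.frame(chain = "A", resno = 1:6, resname = "ALA",
                                  atom = "CA", x = uv[, 1], y = uv[, 2],
                                  z = 0, b = 1))
  r1 <- ring_hexagon_angles(base, data.frame(chain = "A", resno = 1:6))
  R <- rot_axis_angle(c(-1, 1, 2), 63)
  xyz <- as.matrix(base[, c("x", "y", "z")]) %*% t(R) +
    matrix(rep(c(-7, 2, 9), each = 6), 6)
  moved <- atomic_model(data.frame(chain = "A", resno = 1:6, resname = "ALA",
                                   atom = "CA", x = xyz[, 1], y = xyz[, 2],
                                   z = xyz[, 3], b = 1))
  r2 <- ring_hexagon_angles(moved, data.frame(chain = "A", resno = 1:6))
  expect_equal(r1$inner_angle, r2$inner_angle, tolerance = 1e-6)
})

test_that("missing atoms and collinear rings raise informative errors", {
  m <- synthetic_chain()
  expect_error(
    ring_hexagon_angles(m, data.frame(chain = "A", resno = c(1:5, 99))),
    "resno 99")
  line <- atomic_model(data.frame(chain = "A", resno = 1:6, resname = "ALA",
                                  atom = "CA", x = 1:6, y = 2 * (1:6),
                                  z = 0, b = 1))
  expect_error(ring_hexagon_angles(line, data.frame(chain = "A", resno = 1:6)),
               "collinear|degenerate")
})

test_that("models round-trip through PDB on disk", {
  dir <- withr::local_tempdir()
  m <- synthetic_chain(c(50, 130, 200))
  p <- file.path(dir, "chain.pdb")
  write_model(m, p)
  r <- read_model(p)
  expect_equal(nrow(r), nrow(m))
  expect_equal(r$b, m$b, tolerance = 1e-2)
  expect_equal(r$resname, m$resname)
  expect_equal(unname(as.matrix(r[, c("x", "y", "z")])),
               unname(as.matrix(m[, c("x", "y", "z")])), tolerance = 1e-3)
})

test_that("mmCIF models are read into the same atom table", {
  dir <- withr::local_tempdir()
  cif <- c(
    "data_test", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")),
    "ATOM 1 N N . ALA A 1 1 ? 1.0 2.0 3.0 1.00 50.0 ? 1 ALA A N 1",
    "ATOM 2 C CA . ALA A 1 1 ? 2.0 2.5 3.0 1.00 55.0 ? 1 ALA A CA 1")
  p <- file.path(dir, "mini.cif")
  writeLines(cif, p)
  m <- read_model(p)
  expect_equal(nrow(m), 2)
  expect_equal(m$atom, c("N", "CA"))
  expect_equal(m$b, c(50, 55))
  expect_error(read_model(file.path(dir, "x.xyz")), "unsupported")
})
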