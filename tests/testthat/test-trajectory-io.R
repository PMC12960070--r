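test_that("minimum image wraps into [-box/2, box/2) and is norm-minimizing", {
  expect_equal(minimum_image(c(0, 0, 0), c(1, 1, 1)), c(0, 0, 0))
  expect_equal(minimum_image(c(0.9, 0, 0), c(1, 1, 1)), c(-0.1, 0, 0))
  expect_equal(minimum_image(c(0.5, -0.5, 1.5), c(1, 1, 1)), c(-0.5, -0.5, -0.5))

  withr::with_seed(11, {
    box <- c(2.3, 1.7, 4.1)
    shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    for (rep in 1:50) {
      delta <- runif(3, -6, 6)
      w <- minimum_image(delta, box)
      # idempotent
      expect_equal(minimum_image(w, box), w, tolerance = 1e-12)
      # invariant under adding integer multiples of the box
      k <- sample(-3:3, 3, replace = TRUE)
      expect_equal(minimum_image(delta + k * box, box), w, tolerance = 1e-12)
      # norm-minimizing over the 27 neighbour images of the wrapped vector
      norms <- apply(sweep(shifts, 2, box, "*"), 1,
                     function(s) sqrt(sum((w + s)^2)))
      expect_lte(sqrt(sum(w^2)), min(norms) + 1e-12)
      expect_true(all(w >= -box / 2 - 1e-12 & w < box / 2))
    }
  })
})

test_that("molecules are made whole across the periodic boundary", {
  fr <- toy_frame(rbind(c(0.02, 0.5, 0.5), c(0.98, 0.5, 0.5)),
                  roles = c("cation", "cation"), molecule_id = c(1L, 1L),
                  box = c(1, 1, 1))
  m <- molecule_atoms(fr, 1L)
  expect_equal(nrow(m), 2)
  expect_lt(max(dist(as.matrix(m[, c("x", "y", "z")]))), 0.1)
  expect_error(molecule_atoms(fr, 99L), "not present")
})

test_that("synthetic frames round-trip through GRO and extended XYZ", {
  spec <- planted_spec(sizes = c(2, 1), n_cations = 2, n_anions = 1,
                       box = c(6, 6, 6), solvent_density = 0.1, seed = 5)
  fr <- plant_frame(spec)$frame

  xyz <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(fr, xyz)
  back <- read_frames(xyz)
  expect_length(back, 1)
  expect_equal(back[[1]]$atoms$molecule_id, fr$atoms$molecule_id)
  expect_equal(back[[1]]$atoms$role, fr$atoms$role)
  expect_equal(back[[1]]$atoms$x, fr$atoms$x, tolerance = 1e-5)

  gro <- withr::local_tempfile(fileext = ".gro")
  roles <- withr::local_tempfile(fileext = ".csv")
  write_gro(fr, gro)
  write_role_map(fr, roles)
  back2 <- read_frames(gro, roles = roles)[[1]]
  expect_equal(back2$atoms$role, fr$atoms$role)
  # GRO stores 3 decimals: positions preserved to 1e-3 nm up to box shifts
  d <- minimum_image(cbind(back2$atoms$x - fr$atoms$x,
                           back2$atoms$y - fr$atoms$y,
                           back2$atoms$z - fr$atoms$z), fr$box)
  expect_lt(max(abs(d)), 1e-3 + 1e-9)
})

test_that("multi-frame GRO keeps frame order and honours stride", {
  spec <- planted_spec(sizes = c(2), n_cations = 1, n_anions = 1,
                       box = c(6, 6, 6), solvent_density = 0.05, seed = 2)
  tt <- toy_trajectory(spec, n_frames = 4, hop_rate = 0, seed = 9)
  gro <- withr::local_tempfile(fileext = ".gro")
  roles <- withr::local_tempfile(fileext = ".csv")
  write_gro(tt$frames, gro)
  write_role_map(tt$frames[[1]], roles)
  back <- read_frames(gro, roles = roles)
  expect_length(back, 4)
  expect_equal(back[[3]]$atoms$x, tt$frames[[3]]$atoms$x, tolerance = 2e-3)
  expect_length(read_frames(gro, roles = roles, stride = 2), 2)
})

test_that("PDB coordinates are converted from Angstrom to nm", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "CRYST1   40.000   40.000   40.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  C1  CAT A   1      10.000  20.000  30.000  1.00  0.00           C",
    "ATOM      2  N1  ANI A   2      12.500  20.000  30.000  1.00  0.00           N",
    "END"), pdb)
  roles <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("molecule_id,role", "1,cation", "2,anion"), roles)
  fr <- read_frames(pdb, roles = roles)[[1]]
  expect_equal(fr$atoms$x[1], 1.000, tolerance = 1e-9)
  expect_equal(fr$box, c(4, 4, 4))
  expect_equal(fr$atoms$role, c("cation", "anion"))
})

test_that("malformed inputs fail with informative errors", {
  gro <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("title", "2",
               "    1CAT     X1    1   0.100   0.100   0.100",
               "    2ANI     X2    2   bad     0.200   0.200",
               "   5.0 5.0 5.0"), gro)
  roles_tb <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("molecule_id,role", "1,cation", "2,anion"), roles_tb)
  expect_error(read_frames(gro, roles = roles_tb), "line 4")

  # triclinic box rejected
  gro2 <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("title", "1",
               "    1CAT     X1    1   0.100   0.100   0.100",
               "   5.0 5.0 5.0 0.0 0.0 2.5 0.0 0.0 0.0"), gro2)
  expect_error(read_frames(gro2, roles = roles_tb), "triclinic|orthorhombic")

  # missing role mapping
  gro3 <- withr::local_tempfile(fileext = ".gro")
  writeLines(c("title", "1",
               "    7CAT     X1    1   0.100   0.100   0.100",
               "   5.0 5.0 5.0"), gro3)
  expect_error(read_frames(gro3, roles = roles_tb), "missing molecule")

  # role values outside the enum
  bad_roles <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("molecule_id,role", "1,lipid"), bad_roles)
  expect_error(read_role_map(bad_roles), "cation")
})

test_that("frame construction enforces the role and box invariants", {
  expect_error(toy_frame(c(0, 0, 0), roles = "cation", box = c(1, -1, 1)),
               "box")
  expect_error(
    md_frame(tibble::tibble(atom_id = 1:2, molecule_id = c(1L, 1L),
                            role = c("cation", "anion"),
                            x = 0, y = 0, z = 0), box = c(1, 1, 1)),
    "inconsistent roles")
})
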