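test_that("OpenDX write/read round trip is lossless", {
  set.seed(2)
  g <- grid3D(c(-1.5, 0.5, 2), 0.5, array(stats::rnorm(5 * 4 * 3) * 1e3,
                                          c(5, 4, 3)))
  path <- withr::local_tempfile(fileext = ".dx")
  writeDX(g, path, comment = "round trip fixture")
  g2 <- readDX(path)
  expect_equal(gridOrigin(g2), gridOrigin(g))
  expect_equal(gridSpacing(g2), gridSpacing(g))
  expect_equal(dim(gridValues(g2)), dim(gridValues(g)))
  expect_equal(gridValues(g2), gridValues(g), tolerance = 1e-7)
})

test_that("OpenDX data ordering is z-fastest", {
  path <- withr::local_tempfile(fileext = ".dx")
  writeLines(c(
    "object 1 class gridpositions counts 2 2 2",
    "origin 0 0 0",
    "delta 1 0 0", "delta 0 1 0", "delta 0 0 1",
    "object 2 class gridconnections counts 2 2 2",
    "object 3 class array type double rank 0 items 8 data follows",
    "0 1 2", "3 4 5", "6 7"), path)
  g <- readDX(path)
  # value at (ix, iy, iz) = 4(ix-1) + 2(iy-1) + (iz-1)
  for (ix in 1:2) for (iy in 1:2) for (iz in 1:2) {
    expect_equal(g@values[ix, iy, iz],
                 4 * (ix - 1) + 2 * (iy - 1) + (iz - 1))
  }
  # and the writer emits the same ordering back
  path2 <- withr::local_tempfile(fileext = ".dx")
  writeDX(g, path2)
  expect_equal(readDX(path2)@values, g@values)
})

test_that("malformed DX files fail loudly", {
  path <- withr::local_tempfile(fileext = ".dx")
  writeLines(c(
    "object 1 class gridpositions counts 2 2 2",
    "origin 0 0 0",
    "delta 1 0 0", "delta 0 1 0", "delta 0 0 1",
    "object 2 class gridconnections counts 2 2 2",
    "object 3 class array type double rank 0 items 8 data follows",
    "0 1 2", "3 4"), path)
  expect_error(readDX(path), "expected 8 values")
  writeLines(c("object 1 class gridpositions counts 2 2",
               "origin 0 0 0"), path)
  expect_error(readDX(path), "counts")
})

test_that("PQR reader extracts charges and radii", {
  path <- withr::local_tempfile(fileext = ".pqr")
  writeLines(c(
    "REMARK toy fixture",
    "ATOM      1  C1  LIG     1       0.000   0.500  -1.000  0.250 1.9080",
    "ATOM      2  O1  LIG     1       1.200   0.000   0.000 -0.250 1.6612"),
    path)
  sol <- readPQR(path)
  a <- soluteAtoms(sol)
  expect_equal(nrow(a), 2)
  expect_equal(a$charge, c(0.25, -0.25))
  expect_equal(a$x, c(0, 1.2))
  # default radius -> sigma convention: r treated as r_min/2 pair radius
  expect_equal(a$sigma, 2 * c(1.9080, 1.6612) * 2^(-1 / 6))
  expect_equal(netCharge(sol), 0, tolerance = 1e-6)
  # empty file errors
  writeLines("REMARK nothing here", path)
  expect_error(readPQR(path), "no ATOM")
})

test_that("grid alignment puts voxel centers on the common lattice", {
  # requested center rounds to the nearest lattice point (half-down ties)
  gm <- alignGrid(c(0.26, 0, 0), 0.5, c(5, 5, 5))
  expect_equal(gm$origin, c(-0.5, -1, -1))       # center voxel at x = 0.5
  # two aligned grids differ by a whole number of voxels
  gm2 <- alignGrid(c(3.1, -2.2, 0.7), 0.5, c(7, 7, 7))
  off <- (gm2$origin - gm$origin) / 0.5
  expect_equal(off, round(off))
  # voxel counts for a requested physical extent
  expect_equal(shapeForExtent(c(20.5, 20.5, 22.5), 0.5), c(41L, 41L, 45L))
})

test_that("map truncation is exact index slicing", {
  big <- grid3D(c(0, 0, 0), 0.5, array(seq_len(10^3), c(10, 10, 10)))
  win <- list(origin = c(1, 1.5, 2), spacing = 0.5, shape = c(3L, 4L, 2L))
  cut <- truncateGrid(big, win)
  expect_equal(cut@values,
               big@values[3:5, 4:7, 5:6])
  expect_error(truncateGrid(big, list(origin = c(1.25, 0, 0),
                                      spacing = 0.5, shape = c(2L, 2L, 2L))),
               "lattice")
  expect_error(truncateGrid(big, list(origin = c(4, 4, 4), spacing = 0.5,
                                      shape = c(5L, 5L, 5L))),
               "not contained")
})

test_that("voxelwise comparison works on lattice-aligned overlapping maps", {
  a <- grid3D(c(0, 0, 0), 0.5, array(stats::rnorm(8^3), c(8, 8, 8)))
  b <- grid3D(c(1, 1, 1), 0.5,
              array(0, c(6, 6, 6)))
  b@values <- a@values[3:8, 3:8, 3:8] * 2
  res <- compareMaps(a, b)
  expect_equal(res$n, 6^3)
  expect_equal(res$correlation, 1, tolerance = 1e-12)
  expect_equal(res$integral2, 2 * sum(a@values[3:8, 3:8, 3:8]) * 0.125)
})

test_that("shipped synthetic PQR fixtures load with the documented conventions", {
  p <- system.file("extdata", "water_solute.pqr", package = "solvmap")
  sol <- readPQR(p)
  a <- soluteAtoms(sol)
  expect_equal(nrow(a), 3)
  expect_equal(netCharge(sol), 0, tolerance = 1e-9)
  # radius -> sigma convention reproduces the water-model LJ diameters
  expect_equal(a$sigma, c(3.1507, 1.2363, 1.2363), tolerance = 1e-3)
})
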