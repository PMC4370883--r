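test_that("PDB records round-trip with stable order and 1e-3 A coordinates", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m, path)
  m2 <- read_pdb(path)
  expect_equal(m2$name, m$name)
  expect_equal(m2$resno, m$resno)
  expect_equal(coords(m2), coords(m), tolerance = 1e-3)
  # a second round trip is exact against the first read
  path2 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(m2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("a single ATOM record parses into fields verbatim", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  P   TOY A   1       1.000   2.000   3.000  1.00  0.00           P",
    "END"), path)
  m <- read_pdb(path)
  expect_equal(nrow(m), 1L)
  expect_equal(as.numeric(coords(m)), c(1, 2, 3))
  expect_equal(m$name, "P")
  expect_false(m$is_hydrogen)
})

test_that("hydrogen flags come from the element column or leading-H names", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  H5' TOY A   1       0.000   0.000   0.000  1.00  0.00           H",
    "ATOM      2  P   TOY A   1       1.000   0.000   0.000  1.00  0.00",
    "ATOM      3  HO2 TOY A   2       2.000   0.000   0.000  1.00  0.00",
    "END"), path)
  m <- read_pdb(path)
  expect_equal(m$is_hydrogen, c(TRUE, FALSE, TRUE))
})

test_that("unreadable or empty PDB input is a hard error naming the path", {
  expect_error(read_pdb("/nonexistent/file.pdb"), "file.pdb")
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", path)
  expect_error(read_pdb(path))
  expect_error(write_pdb(list(), withr::local_tempfile()), "atomic_model")
})

test_that("CCP4 write -> read round-trips bitwise at float32 precision", {
  vals <- array(as.numeric(1:64), c(4, 4, 4))
  g <- density_grid(vals, voxel_size = 2, origin = c(-4, 0, 6))
  path <- withr::local_tempfile(fileext = ".ccp4")
  write_ccp4(g, path)
  g2 <- read_ccp4(path)
  # values chosen exactly representable in float32
  expect_identical(as.numeric(g2$values), as.numeric(vals))
  expect_identical(dim(g2$values), dim(vals))
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$voxel_size, g$voxel_size)
})

test_that("CCP4 header carries cell = dims x voxel size and data statistics", {
  g <- density_grid(array(0, c(10, 10, 10)), voxel_size = 2)
  path <- withr::local_tempfile(fileext = ".ccp4")
  write_ccp4(g, path)
  con <- file(path, "rb")
  on.exit(close(con))
  words <- readBin(con, "integer", n = 19, size = 4, endian = "little")
  expect_equal(words[1:3], c(10L, 10L, 10L))   # NC, NR, NS
  expect_equal(words[4], 2L)                   # mode float32
  expect_equal(words[17:19], 1:3)              # MAPC, MAPR, MAPS
  seek(con, 4 * 10)
  cell <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  expect_equal(cell, c(20, 20, 20))
  seek(con, 4 * 19)
  dminmaxmean <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  expect_equal(dminmaxmean, c(0, 0, 0))        # constant-zero grid
})

test_that("axis permutation honors MAPC/MAPR/MAPS", {
  # hand-build a file with MAPC,MAPR,MAPS = 2,1,3: file columns run along
  # crystal y. A distinctive value is planted at world position
  # origin + (i,j,k)*voxel and must be found at grid index (i+1,j+1,k+1).
  nxyz <- c(3L, 4L, 5L)            # crystal-axis dims x,y,z
  vox <- c(2, 2, 2)
  arr <- array(0, nxyz)
  arr[2, 3, 4] <- 7                 # x-index 1, y-index 2, z-index 3 (0-based)
  file_arr <- aperm(arr, c(2, 1, 3))  # file order: (y, x, z)
  path <- withr::local_tempfile(fileext = ".ccp4")
  con <- file(path, "wb")
  wi <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4L, endian = "little")
  wi(dim(file_arr)); wi(2L); wi(c(0L, 0L, 0L)); wi(nxyz)
  wf(nxyz * vox); wf(c(90, 90, 90))
  wi(c(2L, 1L, 3L))                 # MAPC, MAPR, MAPS
  wf(c(0, 7, 0.1)); wi(1L); wi(0L); wi(rep(0L, 25))
  wf(c(10, 20, 30))                 # ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0, 0)), con)
  wf(1); wi(0L); writeBin(raw(800), con)
  wf(as.numeric(file_arr))
  close(con)
  g <- read_ccp4(path)
  expect_equal(dim(g$values), nxyz)
  expect_equal(g$values[2, 3, 4], 7)
  expect_equal(sum(g$values != 0), 1L)
  # world coordinate of that voxel: origin + index * voxel_size
  expect_equal(g$origin + c(1, 2, 3) * g$voxel_size, c(12, 24, 36))
})

test_that("NCSTART origin fallback applies when ORIGIN words are zero", {
  g <- density_grid(array(as.numeric(1:8), c(2, 2, 2)), voxel_size = 2,
                    origin = c(0, 0, 0))
  path <- withr::local_tempfile(fileext = ".ccp4")
  write_ccp4(g, path)
  # patch NCSTART/NRSTART/NSSTART to (1, 2, 3); ORIGIN stays zero
  con <- file(path, "r+b")
  seek(con, 4 * 4, rw = "write")
  writeBin(c(1L, 2L, 3L), con, size = 4L, endian = "little")
  close(con)
  g2 <- read_ccp4(path)
  expect_equal(g2$origin, c(1, 2, 3) * 2)
})

test_that("corrupt CCP4 input fails loudly", {
  path <- withr::local_tempfile(fileext = ".ccp4")
  writeBin(raw(100), path)
  expect_error(read_ccp4(path), "truncated|magic")
  g <- density_grid(array(as.numeric(1:8), c(2, 2, 2)), voxel_size = 2)
  write_ccp4(g, path)
  # truncate the data block
  raw_all <- readBin(path, "raw", n = file.size(path))
  writeBin(raw_all[1:(1024 + 4)], path)
  expect_error(read_ccp4(path), "truncated")
  # non-orthogonal cell
  write_ccp4(g, path)
  con <- file(path, "r+b")
  seek(con, 4 * 13, rw = "write")
  writeBin(as.numeric(c(90, 90, 120)), con, size = 4L, endian = "little")
  close(con)
  expect_error(read_ccp4(path), "non-orthogonal")
})
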