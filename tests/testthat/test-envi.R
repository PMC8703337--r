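# ENVI header/raw round trips, interleave handling and batch resolution.

test_that("cubes round-trip through write/read for every interleave and dtype", {
  for (il in c("bil", "bip", "bsq")) {
    for (dt in c(12L, 4L)) {
      cube <- random_cube(seed = 7L, interleave = il, dtype_code = dt)
      hp <- file.path(withr::local_tempdir(), "cube.hdr")
      write_envi(cube, hp)
      back <- read_envi(hp)
      expect_equal(back$data, cube$data, info = paste(il, dt))
      expect_equal(back$wavelengths, cube$wavelengths)
      expect_identical(back$interleave, il)
      expect_false(back$wavelengths_synthetic)
    }
  }
})

test_that("header-declared dimensions govern the cube shape", {
  cube <- hypercube(array(0, c(2, 640, 268)),
                    wavelengths = seq(600, 1700, length.out = 268))
  hp <- file.path(withr::local_tempdir(), "wide.hdr")
  write_envi(cube, hp)
  back <- read_envi(hp)
  expect_identical(dim(back)[2L], 640L)   # samples (x)
  expect_identical(dim(back)[3L], 268L)   # bands
})

test_that("BIL and BSQ on-disk layouts of the same values read back equal", {
  # independent byte-layout oracle: lay out the bytes by hand for both
  # interleaves and read them through the package
  ny <- 2L; nx <- 3L; L <- 2L
  vals <- array(seq_len(ny * nx * L), c(ny, nx, L))   # internal (y, x, band)
  dir <- withr::local_tempdir()
  write_one <- function(stem, interleave, ordered_vals) {
    writeLines(c("ENVI", sprintf("samples = %d", nx),
                 sprintf("lines = %d", ny), sprintf("bands = %d", L),
                 "header offset = 0", "data type = 2",
                 sprintf("interleave = %s", interleave), "byte order = 0"),
               file.path(dir, paste0(stem, ".hdr")))
    con <- file(file.path(dir, paste0(stem, ".raw")), "wb")
    writeBin(as.integer(ordered_vals), con, size = 2L, endian = "little")
    close(con)
  }
  # BIL: for each line y, for each band, the nx samples
  bil <- integer(0)
  for (y in seq_len(ny)) for (b in seq_len(L)) bil <- c(bil, vals[y, , b])
  # BSQ: for each band, for each line, the nx samples
  bsq <- integer(0)
  for (b in seq_len(L)) for (y in seq_len(ny)) bsq <- c(bsq, vals[y, , b])
  write_one("a_bil", "bil", bil)
  write_one("a_bsq", "bsq", bsq)
  ca <- read_envi(file.path(dir, "a_bil.hdr"))
  cb <- read_envi(file.path(dir, "a_bsq.hdr"))
  expect_equal(ca$data, cb$data)
  expect_equal(ca$data, array(as.numeric(vals), dim(vals)))
})

test_that("wavelength bookkeeping and missing wavelengths are handled", {
  cube <- hypercube(array(0, c(2, 2, 239)),
                    wavelengths = seq(655, 1642, length.out = 239))
  hp <- file.path(withr::local_tempdir(), "wl.hdr")
  write_envi(cube, hp)
  h <- seedhsi:::parse_envi_header(hp)
  expect_length(h$wavelength, 239L)

  # header without wavelengths -> synthetic 1..L, flagged
  nowl <- hypercube(array(1, c(2, 2, 4)))
  hp2 <- file.path(withr::local_tempdir(), "nowl.hdr")
  write_envi(nowl, hp2)
  back <- read_envi(hp2)
  expect_true(back$wavelengths_synthetic)
  expect_equal(back$wavelengths, as.numeric(1:4))
})

test_that("read errors are specific: missing data, bad interleave, size mismatch", {
  dir <- withr::local_tempdir()
  hp <- file.path(dir, "orphan.hdr")
  writeLines(c("ENVI", "samples = 2", "lines = 2", "bands = 1",
               "data type = 2", "interleave = bil"), hp)
  expect_error(read_envi(hp), "no data file")

  cube <- random_cube(1)
  hp2 <- file.path(dir, "c.hdr")
  write_envi(cube, hp2)
  # corrupt the declared size: more lines than the file holds
  txt <- sub("lines = 4", "lines = 400", readLines(hp2))
  writeLines(txt, hp2)
  expect_error(read_envi(hp2), "size mismatch")

  hp3 <- file.path(dir, "c2.hdr")
  write_envi(cube, hp3)
  txt <- sub("interleave = bil", "interleave = xyz", readLines(hp3))
  writeLines(txt, hp3)
  expect_error(read_envi(hp3), "interleave")
})

test_that("resolve_batch orders entries, reports orphans, tolerates no matches", {
  dir <- withr::local_tempdir()
  for (stem in c("b", "a")) write_envi(random_cube(1), file.path(dir, paste0(stem, ".hdr")))
  writeLines(c("ENVI", "samples = 1", "lines = 1", "bands = 1",
               "data type = 2", "interleave = bil"),
             file.path(dir, "orphan.hdr"))
  expect_warning(man <- resolve_batch(file.path(dir, "*.hdr")), "orphan")
  expect_identical(basename(man$header_path), c("a.hdr", "b.hdr"))
  expect_identical(basename(man$data_path), c("a.raw", "b.raw"))
  # idempotent / order-stable
  expect_warning(man2 <- resolve_batch(file.path(dir, "*.hdr")))
  expect_identical(man, man2)

  expect_warning(empty <- resolve_batch(file.path(dir, "nothing*.hdr")),
                 "no header")
  expect_identical(nrow(empty), 0L)
})
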