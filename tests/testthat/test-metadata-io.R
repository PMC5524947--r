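test_that("MRC volumes and stacks round-trip through disk", {
  set.seed(51)
  # values exactly representable in float32
  dat <- array(round(runif(32^3, -100, 100) * 4) / 4, c(32, 32, 32))
  vol <- map_volume(dat, voxel_size = 1.5)
  f <- tempfile(fileext = ".mrc")
  write_map(vol, f)
  back <- read_map(f)
  expect_identical(back$data, dat)
  expect_equal(back$voxel_size, 1.5, tolerance = 1e-6)

  stk <- particle_stack(array(round(rnorm(16 * 16 * 5) * 8) / 8, c(16, 16, 5)),
                        pixel_size = 2)
  fs <- tempfile(fileext = ".mrcs")
  write_stack(stk, fs)
  back2 <- read_stack(fs)
  expect_identical(back2$images, stk$images)
  expect_equal(back2$pixel_size, 2, tolerance = 1e-6)
})

test_that("corrupt MRC input fails with a format error, not a crash", {
  f <- tempfile(fileext = ".mrc")
  writeBin(raw(100), f)                      # truncated header
  expect_error(read_map(f), "format error")

  vol <- gaussian_blob_volume(16, 3)
  write_map(vol, f)
  full <- readBin(f, "raw", n = file.size(f))
  writeBin(full[1:(1024 + 100)], f)          # truncated data
  expect_error(read_map(f), "truncated")

  expect_error(read_map(tempfile()), "not found")

  # non-square sections are rejected for stacks
  fns <- tempfile(fileext = ".mrcs")
  cryoval:::write_mrc_raw(array(1, c(16, 32, 2)), 1, fns)
  expect_error(read_stack(fns), "non-square")
})

test_that("STAR particle tables map angles, shifts and CTF columns", {
  f <- tempfile(fileext = ".star")
  writeLines(c("data_particles", "", "loop_",
               "_rlnAngleRot #1", "_rlnAngleTilt #2", "_rlnAnglePsi #3",
               "10 20 30", "40 50 60", "-70 80 90"), f)
  expect_warning(rec <- read_particles_star(f), "identity CTF")
  expect_identical(nrow(rec), 3L)
  expect_true(all(rec$has_orientation))
  expect_false(any(rec$has_ctf))
  expect_equal(rec$rot, c(10, 40, -70))
  expect_equal(rec$shift_x, c(0, 0, 0))

  # Angstrom shift dialect: 2.5 A at 1.25 A/px = 2 px
  f2 <- tempfile(fileext = ".star")
  writeLines(c("data_particles", "", "loop_",
               "_rlnAngleRot #1", "_rlnAngleTilt #2", "_rlnAnglePsi #3",
               "_rlnOriginXAngst #4", "_rlnOriginYAngst #5",
               "_rlnDefocusU #6", "_rlnDefocusV #7",
               "10 20 30 2.5 -2.5 12000 11000"), f2)
  rec2 <- read_particles_star(f2, pixel_size = 1.25)
  expect_equal(rec2$shift_x, 2)
  expect_equal(rec2$shift_y, -2)
  expect_true(rec2$has_ctf)
  expect_equal(rec2$defocus_u, 12000)

  # optics block supplies the pixel size and microscope constants
  f3 <- tempfile(fileext = ".star")
  writeLines(c("data_optics", "", "loop_",
               "_rlnOpticsGroup #1", "_rlnImagePixelSize #2", "_rlnVoltage #3",
               "1 2.0 200",
               "", "data_particles", "", "loop_",
               "_rlnOpticsGroup #1", "_rlnAngleRot #2", "_rlnAngleTilt #3",
               "_rlnAnglePsi #4", "_rlnOriginXAngst #5", "_rlnOriginYAngst #6",
               "_rlnDefocusU #7",
               "1 0 90 0 4.0 -6.0 9000"), f3)
  rec3 <- read_particles_star(f3)
  expect_equal(rec3$shift_x, 2)
  expect_equal(rec3$shift_y, -3)
  expect_equal(rec3$voltage, 200)
})

test_that("unknown STAR columns survive a round trip verbatim", {
  f <- tempfile(fileext = ".star")
  writeLines(c("data_particles", "", "loop_",
               "_rlnAngleRot #1", "_rlnAngleTilt #2", "_rlnAnglePsi #3",
               "_rlnDefocusU #4", "_rlnMicrographName #5", "_rlnRandomSubset #6",
               "10 20 30 9000 mic_001.mrc 1",
               "40 50 60 9500 mic_002.mrc 2"), f)
  rec <- read_particles_star(f)
  out <- tempfile(fileext = ".star")
  write_particles_star(rec, out)
  rec2 <- read_particles_star(out)
  expect_identical(attr(rec2, "extra")$rlnMicrographName,
                   c("mic_001.mrc", "mic_002.mrc"))
  expect_identical(attr(rec2, "extra")$rlnRandomSubset, c("1", "2"))
  expect_equal(rec2$rot, rec$rot)
  expect_equal(rec2$defocus_u, rec$defocus_u)
})

test_that("report files are internally consistent", {
  # small synthetic run
  vol <- make_phantom()
  ds <- simulate_dataset(vol, n = 6, snr = Inf, seed = 61)
  rep <- validate_particles(vol, ds$stack, ds$records, xi = 5, delta = 20,
                            M = 50, rot_step = 10, seed = 2)
  pre <- file.path(tempfile(), "run")
  files <- write_report(rep, pre, records = ds$records, prune_tau = 0.5)
  expect_true(all(file.exists(files)))

  sc <- read.csv(paste0(pre, "_scores.csv"))
  js <- jsonlite::read_json(paste0(pre, "_summary.json"))
  expect_equal(100 * mean(sc$q_p >= 0.5 & sc$q_a >= 0.5), js$Q)
  expect_equal(100 * mean(sc$q_p >= 0.5), js$percent_precise)
  expect_identical(js$parameters$xi, 5L)
  expect_identical(js$parameters$seed, 2L)

  pruned <- read_particles_star(paste0(pre, "_pruned.star"))
  expect_identical(nrow(pruned), length(prune(rep, 0.5)))
  expect_identical(nrow(pruned), as.integer(round(js$Q / 100 * nrow(sc))))

  starred <- read_particles_star(paste0(pre, "_scores.star"))
  expect_equal(as.numeric(attr(starred, "extra")$cvScorePrecision),
               sc$q_p, tolerance = 1e-6)
})
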