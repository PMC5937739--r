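test_that("native layout round-trips a recording bit-exactly", {
  rec <- small_sim()$recording
  dir <- withr::local_tempdir()
  manifest <- write_dataset(rec, dir, overwrite = TRUE)
  expect_setequal(names(manifest),
                  c("eeg.bin", "eog.bin", "nirs.bin", "events.tsv", "meta.json"))
  back <- read_dataset(dir)
  expect_identical(back$eeg, rec$eeg)
  expect_identical(back$eog, rec$eog)
  expect_identical(back$nirs_intensity, rec$nirs_intensity)
  expect_equal(back$events$onset_s, rec$events$onset_s)
  expect_equal(back$events$label, rec$events$label)
  expect_equal(back$eeg_rate_hz, rec$eeg_rate_hz)
  expect_equal(back$nirs_rate_hz, rec$nirs_rate_hz)
  expect_identical(back$frontal, rec$frontal)
  expect_equal(nrow(back$events), 12)
})

test_that("manifest checksums change iff samples change", {
  rec <- small_sim()$recording
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  m1 <- write_dataset(rec, d1, overwrite = TRUE)
  m2 <- write_dataset(rec, d2, overwrite = TRUE)
  expect_identical(unname(m1), unname(m2))

  rec2 <- rec
  rec2$eeg[1, 100] <- rec2$eeg[1, 100] + 1e-9
  d3 <- withr::local_tempdir()
  m3 <- write_dataset(rec2, d3, overwrite = TRUE)
  expect_false(m3[["eeg.bin"]] == m1[["eeg.bin"]])
  expect_identical(m3[["nirs.bin"]], m1[["nirs.bin"]])
})

test_that("refuses to clobber a non-empty directory without overwrite", {
  rec <- small_sim()$recording
  dir <- withr::local_tempdir()
  write_dataset(rec, dir, overwrite = TRUE)
  expect_error(write_dataset(rec, dir), "not empty")
  expect_silent(write_dataset(rec, dir, overwrite = TRUE))
})

test_that("corrupt datasets raise structured validation errors", {
  rec <- small_sim()$recording
  dir <- withr::local_tempdir()
  write_dataset(rec, dir, overwrite = TRUE)

  # missing metadata descriptor
  d2 <- withr::local_tempdir()
  write_dataset(rec, d2, overwrite = TRUE)
  unlink(file.path(d2, "meta.json"))
  expect_error(read_dataset(d2), "corrupt dataset")

  # tampered negative intensity, error names channel and sample
  d3 <- withr::local_tempdir()
  write_dataset(rec, d3, overwrite = TRUE)
  con <- file(file.path(d3, "nirs.bin"), "r+b")
  writeBin(-1.0, con, size = 8, endian = "little")
  close(con)
  expect_error(read_dataset(d3), "non-positive intensity at channel 1")

  # unknown event label, error carries the line number
  d4 <- withr::local_tempdir()
  write_dataset(rec, d4, overwrite = TRUE)
  ev <- readLines(file.path(d4, "events.tsv"))
  ev[3] <- sub("\t(MA|BL)$", "\tXX", ev[3])
  writeLines(ev, file.path(d4, "events.tsv"))
  expect_error(read_dataset(d4), "unknown event label 'XX'.*line 3")

  # rate inconsistent with the sample counts
  d5 <- withr::local_tempdir()
  write_dataset(rec, d5, overwrite = TRUE)
  meta <- jsonlite::read_json(file.path(d5, "meta.json"), simplifyVector = TRUE)
  meta$nirs_rate_hz <- 50
  jsonlite::write_json(meta, file.path(d5, "meta.json"), auto_unbox = TRUE)
  expect_error(read_dataset(d5), "rate mismatch")
})
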