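test_that("marker matrix files parse, validate and round-trip bit-exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,L1,L2", "s1,1,0", "s2,0,1", "s3,1,1"), path)
  m <- read_marker_matrix(path)
  expect_equal(dim(m), c(3L, 2L))
  expect_equal(unname(band_frequencies(m)), c(2 / 3, 2 / 3))
  expect_equal(rownames(m), c("s1", "s2", "s3"))

  out <- withr::local_tempfile(fileext = ".csv")
  write_marker_matrix(m, out)
  expect_identical(unclass(read_marker_matrix(out)), unclass(m))

  # tab-delimited variant
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tL1\tL2", "s1\t1\t0", "s2\t0\t1", "s3\t1\t1"), tsv)
  expect_identical(unclass(read_marker_matrix(tsv)), unclass(m))
})

test_that("marker parse errors name the offending line", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,L1,L2", "s1,1,0", "s2,2,1", "s3,1,1"), path)
  expect_error(read_marker_matrix(path), "line 3.*non-binary.*\"2\"")

  writeLines(c("sample_id,L1,L2", "s1,1,0", "s2,0", "s3,1,1"), path)
  expect_error(read_marker_matrix(path), "line 3.*expected 3 fields")

  writeLines(c("sample_id,L1,L2", "s1,1,0", "s1,0,1", "s3,1,1"), path)
  expect_error(read_marker_matrix(path), "duplicate sample_id: s1")

  writeLines(c("sample_id,L1,L1", "s1,1,0", "s2,0,1", "s3,1,1"), path)
  expect_error(read_marker_matrix(path), "duplicate locus_id: L1")
})

test_that("sample tables validate enums, coordinates and tray rules", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample_id,population,region,habitat,cohort,x,y,tray_id",
               "s1,RM1,R,meadow,AG,3,7,",
               "s2,RM1,r,Meadow,sb,1,2,T01"), path)
  s <- read_sample_table(path)
  expect_equal(s$habitat, c("meadow", "meadow"))  # case-insensitive enums
  expect_equal(s$x[1], 3)
  expect_equal(s$y[1], 7)
  expect_true(is.na(s$tray_id[1]))
  expect_equal(s$tray_id[2], "T01")

  writeLines(c("sample_id,population,region,habitat,cohort,x,y",
               "s1,RM1,R,forest,AG,3,7"), path)
  expect_error(read_sample_table(path), "habitat.*forest.*meadow, woodland")

  writeLines(c("sample_id,population,region,habitat,cohort,x,y",
               "s1,RM1,R,meadow,AG,3,7", "s1,RM1,R,meadow,AG,1,1"), path)
  expect_error(read_sample_table(path), "duplicate sample_id")

  # AG samples never carry a tray
  expect_error(sample_table(data.frame(
    sample_id = "a", population = "P", region = "R", habitat = "meadow",
    cohort = "AG", x = 0, y = 0, tray_id = "T1")), "tray_id")
})
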