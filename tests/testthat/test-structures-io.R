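test_that("fixture save/load round-trips a structure set exactly", {
  s <- toyStructureSet("rt1")
  f <- file.path(tempdir(), "rt1.txt")
  saveFixture(s, f)
  s2 <- loadFixture(f)
  expect_identical(caseId(s2), "rt1")
  expect_equal(structures(s2), structures(s), tolerance = 0)
  expect_equal(isocenter(s2), isocenter(s), tolerance = 0)
  # second round trip is byte-stable
  f2 <- file.path(tempdir(), "rt1b.txt")
  saveFixture(s2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("fixture without isocenter block falls back to the brain centroid", {
  s <- toyStructureSet("rt2")
  f <- file.path(tempdir(), "rt2.txt")
  saveFixture(s, f)
  lines <- readLines(f)
  isoAt <- which(lines == "isocenter")
  writeLines(lines[seq_len(isoAt - 1)], f)
  expect_warning(s2 <- loadFixture(f), "brain centroid")
  expect_equal(isocenter(s2), unname(colMeans(structurePoints(s, "BRAIN_CTV"))), tolerance = 1e-12)
})

test_that("malformed fixture lines are reported with their line number", {
  f <- file.path(tempdir(), "bad.txt")
  writeLines(c("case x", "structure BRAIN_CTV", "1 2 3", "1 2"), f)
  expect_error(loadFixture(f), "line 4")
  writeLines(c("case x", "1 2 3"), f)
  expect_error(loadFixture(f), "before any block header")
})

test_that("structureSet enforces its invariants", {
  expect_error(structureSet(list()), "empty")
  s <- toyStructureSet()
  broken <- structures(s)
  broken$LENS_R <- NULL
  expect_error(structureSet(broken, isocenter = c(0, 0, 0)), "LENS_R")
  # single-point structures are storable and writable
  one <- structures(s)
  one$LENS_L <- matrix(c(31, -83, -35), 1, 3)
  s1 <- structureSet(one, isocenter = c(0, 0, 0))
  f <- file.path(tempdir(), "one.txt")
  saveFixture(s1, f)
  expect_equal(nrow(structurePoints(loadFixture(f), "LENS_L")), 1)
  # swapped eyes violate lateral pairing
  swapped <- structures(s)
  names(swapped)[match(c("EYE_L", "EYE_R"), names(swapped))] <- c("EYE_R", "EYE_L")
  expect_error(structureSet(swapped, isocenter = c(0, 0, 0)), "lie left")
})

test_that("RTSTRUCT files load into canonical roles (explicit and implicit VR)", {
  f <- writeTestRTStruct(file.path(tempdir(), "rt_ok.dcm"), "ok")
  s <- loadRTStruct(f, isocenter = c(0, 0, 0), caseId = "dicom1")
  expect_setequal(names(structures(s)), structureRoles())
  expect_equal(nrow(structurePoints(s, "BRAIN_CTV")), 6) # two 3-point contours
  expect_equal(structurePoints(s, "EYE_L")[1, ], c(x = 40, y = 0, z = 5))

  fi <- writeTestRTStruct(file.path(tempdir(), "rt_impl.dcm"), "implicit")
  si <- loadRTStruct(fi, isocenter = c(0, 0, 0))
  expect_identical(structures(si), structures(s))

  # no isocenter supplied -> brain centroid, warned
  expect_warning(sb <- loadRTStruct(f), "brain centroid")
  expect_equal(isocenter(sb), unname(colMeans(structurePoints(s, "BRAIN_CTV"))), tolerance = 1e-12)
})

test_that("RTSTRUCT role resolution reports missing and ambiguous roles", {
  fm <- writeTestRTStruct(file.path(tempdir(), "rt_missing.dcm"), "missing")
  expect_error(loadRTStruct(fm, isocenter = c(0, 0, 0)), "LENS_R")

  fa <- writeTestRTStruct(file.path(tempdir(), "rt_amb.dcm"), "ambiguous")
  rm2 <- defaultRoleMap()
  rm2[["BRAIN_CTV"]] <- "brain"
  err <- tryCatch(loadRTStruct(fa, roleMap = rm2, isocenter = c(0, 0, 0)),
    error = conditionMessage
  )
  expect_match(err, "ambiguous")
  expect_match(err, "Brain")
  expect_match(err, "brain_stem")
})

test_that("rigid translation moves every centroid by the same vector", {
  s <- toyStructureSet()
  shift <- c(10, 10, 10)
  moved <- structureSet(
    lapply(structures(s), function(m) sweep(m, 2, -shift)),
    isocenter = isocenter(s) + shift
  )
  for (role in structureRoles()) {
    expect_equal(
      colMeans(structurePoints(moved, role)),
      colMeans(structurePoints(s, role)) + shift,
      tolerance = 1e-12
    )
  }
})
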