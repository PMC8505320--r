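test_that("long-format reading transcribes presences and orders units", {
  tf <- writeTempLong(c("individual_id,species_id,time_unit",
                        "i1,sp1,1", "i1,sp1,2", "i2,sp1,1"))
  cen <- readLongFormat(tf)
  expect_identical(censusUnits(cen), c("1", "2"))
  expect_identical(occupancy(cen),
                   matrix(c(1L, 1L, 1L, 0L), nrow = 2, byrow = TRUE,
                          dimnames = list(c("i1", "i2"), c("1", "2"))))
  expect_identical(unname(speciesIds(cen)), c("sp1", "sp1"))
})

test_that("species conflicts resolve to first appearance with a warning", {
  tf <- writeTempLong(c("individual_id,species_id,time_unit",
                        "i1,sp1,1", "i1,sp2,2"))
  expect_warning(cen <- readLongFormat(tf), "first appearance")
  expect_identical(unname(speciesIds(cen)), "sp1")
  # the first appearance is the earliest unit even if the file is unsorted
  tf2 <- writeTempLong(c("individual_id,species_id,time_unit",
                         "i1,sp2,2", "i1,sp1,1"))
  expect_warning(cen2 <- readLongFormat(tf2), "first appearance")
  expect_identical(unname(speciesIds(cen2)), "sp1")
})

test_that("degenerate and malformed inputs error clearly", {
  expect_error(readLongFormat(writeTempLong(character(0))), "no records")
  expect_error(readLongFormat(writeTempLong("individual_id,species_id,time_unit")),
               "no records")
  tf <- writeTempLong(c("id,sp,when", "i1,sp1,1"))
  expect_error(readLongFormat(tf), "missing column")
  tfBad <- writeTempLong(c("individual_id,species_id,time_unit",
                           "i1,sp1,spring", "i1,sp1,autumn"))
  expect_error(readLongFormat(tfBad), "neither numeric nor ISO dates")
  # ... unless an explicit order is declared
  cen <- readLongFormat(tfBad, unitOrder = c("spring", "autumn"))
  expect_identical(censusUnits(cen), c("spring", "autumn"))
})

test_that("duplicate (individual, unit) rows are deduplicated with a warning", {
  tf <- writeTempLong(c("individual_id,species_id,time_unit",
                        "i1,sp1,1", "i1,sp1,1", "i1,sp1,2"))
  expect_warning(cen <- readLongFormat(tf), "duplicate")
  expect_identical(occupancy(cen)["i1", ], c(`1` = 1L, `2` = 1L))
})

test_that("gap policies: strict errors naming offenders, fill repairs, events passes through", {
  z <- rbind(i1 = c(1, 0, 1), i2 = c(1, 1, 0))
  cen <- census(z, species = c("sp1", "sp2"))
  expect_error(applyGapPolicy(cen, "strict"), "i1")
  expect_message(filled <- applyGapPolicy(cen, "fill"), "filled 1")
  expect_identical(unname(occupancy(filled)["i1", ]), c(1L, 1L, 1L))
  expect_identical(occupancy(applyGapPolicy(cen, "events")), occupancy(cen))
  # contiguous censuses are unchanged under every policy
  ok <- census(rbind(i1 = c(1, 1, 0)), species = "sp1")
  for (p in c("strict", "fill", "events"))
    expect_identical(occupancy(applyGapPolicy(ok, p)), occupancy(ok))
})

test_that("abundance matrix counts individuals per species and unit", {
  am <- abundanceMatrix(fiveIndividualCensus())
  expect_identical(counts(am),
                   matrix(c(2L, 2L, 1L, 0L, 0L, 1L), nrow = 3, byrow = TRUE,
                          dimnames = list(c("sp1", "sp2", "sp3"),
                                          c("t1", "t2"))))
  expect_identical(unname(unitAbundance(am)), c(3, 3))
  expect_identical(nIndividuals(am), 5L)
  expect_identical(totalAbundance(am), 6L)
  expect_identical(unname(speciesRichness(am)), c(2, 2))
  expect_identical(pooledRichness(am), 3L)

  one <- census(rbind(i1 = c(1, 1)), species = "spA")
  expect_identical(unname(counts(abundanceMatrix(one))[1, ]), c(1L, 1L))
  expect_identical(nIndividuals(abundanceMatrix(one)), 1L)

  # conspecific individuals with disjoint occupancy still sum per column
  two <- census(rbind(i1 = c(1, 0), i2 = c(0, 1)), species = c("sp", "sp"))
  expect_identical(unname(counts(abundanceMatrix(two))[1, ]), c(1L, 1L))
})

test_that("abundance totals and permutation invariance hold on random censuses", {
  set.seed(42)
  for (rep in 1:25) {
    cen <- randomCensus()
    am <- abundanceMatrix(cen)
    expect_identical(sum(unitAbundance(am)), as.numeric(totalAbundance(am)))
    expect_identical(totalAbundance(am), sum(occupancy(cen)))
    expect_identical(nIndividuals(am), nIndividuals(cen))
    perm <- sample(nIndividuals(cen))
    permuted <- census(occupancy(cen)[perm, , drop = FALSE],
                       species = speciesIds(cen)[perm])
    amp <- abundanceMatrix(permuted)
    expect_identical(counts(amp)[rownames(counts(am)), , drop = FALSE],
                     counts(am))
  }
})

test_that("write/read round trip is the identity, including edge cases", {
  set.seed(7)
  for (rep in 1:15) {
    cen <- randomCensus()
    tf <- tempfile(fileext = ".csv")
    writeLongFormat(cen, tf)
    back <- readLongFormat(tf)
    expect_identical(occupancy(back), occupancy(cen))
    expect_identical(speciesIds(back), speciesIds(cen))
  }
  # a unit where nothing was recorded alive survives via the #units= header
  z <- rbind(i1 = c(1, 0, 0), i2 = c(1, 0, 1))
  empties <- applyGapPolicy(census(z, species = c("a", "b")), "events")
  tf <- tempfile(fileext = ".csv")
  writeLongFormat(empties, tf)
  expect_identical(censusUnits(readLongFormat(tf)), c("t1", "t2", "t3"))
  # species labels containing the delimiter are quoted
  weird <- census(rbind(i1 = c(1, 1)), species = "genus, species")
  tf2 <- tempfile(fileext = ".csv")
  writeLongFormat(weird, tf2)
  expect_identical(unname(speciesIds(readLongFormat(tf2))), "genus, species")
})

test_that("Census validity rejects malformed objects", {
  expect_error(census(rbind(i1 = c(1, 2)), species = "sp"), "0 or 1")
  expect_error(census(rbind(i1 = c(0, 0), i2 = c(1, 1)),
                      species = c("a", "b")), "at least one unit")
  z <- rbind(c(1, 1), c(1, 0)); rownames(z) <- c("i1", "i1")
  expect_error(census(z, species = c("a", "b")), "unique")
  expect_error(census(matrix(1L, 1, 1, dimnames = list("i1", "t1")),
                      species = "a"), "at least 2 time units")
})

test_that("wide export lists one row per individual with 0/1 unit columns", {
  tf <- tempfile(fileext = ".tsv")
  writeWideFormat(fiveIndividualCensus(), tf)
  wide <- read.delim(tf, check.names = FALSE)
  expect_identical(dim(wide), c(5L, 4L))
  expect_identical(wide$t1, c(1L, 1L, 1L, 0L, 0L))
})
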