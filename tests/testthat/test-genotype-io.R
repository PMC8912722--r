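test_that("dataset construction enforces the structural invariants", {
  ds <- toy_dataset(rbind(c("10/12", "14/14"),
                          c("10/10", "./.")),
                    pop = c("p1", "p1"))
  expect_s3_class(ds, "genotype_dataset")
  expect_equal(n_individuals(ds), 2)
  expect_equal(n_loci(ds), 2)
  expect_true(all(is.na(ds$alleles[2, 2, ])))

  # half-calls are rejected
  arr <- array(10L, dim = c(1, 1, 2))
  arr[1, 1, 2] <- NA_integer_
  expect_error(genotype_dataset(arr, pop = "p1"), "half-called")

  # non-positive allele sizes are rejected
  arr <- array(c(0L, 5L), dim = c(1, 1, 2))
  expect_error(genotype_dataset(arr, pop = "p1"), "positive")

  # every population needs a species
  arr <- array(5L, dim = c(1, 1, 2))
  expect_error(genotype_dataset(arr, pop = "p1",
                                species_of_pop = c(p9 = "s1")),
               "without species")
})

test_that("GenePop parsing handles the dialect and its error cases", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy file", "locA",
               "POP", "a1 , 010012", "a2 , 010010",
               "POP", "b1 , 012012", "b2 , 000000"), f)
  ds <- read_genepop(f)
  expect_equal(n_individuals(ds), 4)
  expect_equal(n_loci(ds), 1)
  expect_equal(length(unique(ds$pop)), 2)
  expect_equal(ds$alleles[1, 1, ], c(10L, 12L))
  # "000000" means both slots missing
  expect_true(all(is.na(ds$alleles[4, 1, ])))

  # wrong genotype count on a line is reported with its line number
  writeLines(c("t", "locA", "locB", "POP", "a1 , 010012"), f)
  expect_error(read_genepop(f), "line 5")

  # odd allele-code width
  writeLines(c("t", "locA", "POP", "a1 , 01012"), f)
  expect_error(read_genepop(f), "allele-code length")

  # empty population block
  writeLines(c("t", "locA", "POP", "POP", "b1 , 010010"), f)
  expect_error(read_genepop(f), "empty population")
})

test_that("GenePop writing applies the fixed-width coding rules", {
  ds <- toy_dataset(rbind(c("12/14")), pop = "p1", ids = "ind1")
  f <- withr::local_tempfile(fileext = ".gen")
  write_genepop(ds, f, digits = 3)
  lines <- readLines(f)
  expect_match(lines[4], "012014")

  # empty dataset: header and locus list only
  empty <- genotype_dataset(array(integer(0), dim = c(0, 2, 2)),
                            locus_names = c("locA", "locB"),
                            pop = character(0))
  write_genepop(empty, f)
  expect_equal(readLines(f)[2:3], c("locA", "locB"))

  # allele too large for the coding width
  big <- toy_dataset(rbind(c("1200/1200")), pop = "p1")
  expect_error(write_genepop(big, f), "does not fit")
})

test_that("STRUCTURE two-row tables round-trip and honor -9 as missing", {
  f <- withr::local_tempfile(fileext = ".str")
  writeLines(c("i1 p1 10 14", "i1 p1 12 -9"), f)
  ds <- read_structure_table(f)
  expect_equal(n_individuals(ds), 1)
  expect_equal(n_loci(ds), 2)
  expect_equal(ds$alleles[1, 1, ], c(10L, 12L))
  expect_true(all(is.na(ds$alleles[1, 2, ])))  # -9 masks the whole locus
})

test_that("read/write round trips preserve genotypes across both formats", {
  set.seed(41)
  for (rep in 1:5) {
    ds <- random_dataset(n = 7, L = 4, n_pop = 3, missing_rate = 0.15)
    g <- withr::local_tempfile(fileext = ".gen")
    s <- withr::local_tempfile(fileext = ".str")

    write_genepop(ds, g)
    back <- read_genepop(g)
    expect_identical(back$alleles, ds$alleles)
    expect_identical(back$individual_ids, ds$individual_ids)
    expect_identical(match(back$pop, unique(back$pop)),
                     match(ds$pop, unique(ds$pop)))

    # GenePop -> STRUCTURE -> GenePop
    write_structure_table(back, s)
    back2 <- read_structure_table(s, locus_names = back$locus_names)
    expect_identical(back2$alleles, ds$alleles)
    expect_identical(match(back2$pop, unique(back2$pop)),
                     match(ds$pop, unique(ds$pop)))
  }
})

test_that("metadata CSV joins by population and flags unknown populations", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("population,species,latitude,longitude,altitude",
               "p1,s1,23.5,121.0,1500",
               "p2,s2,24.0,121.2,2100"), f)
  meta <- read_metadata_csv(f)
  expect_equal(nrow(meta), 2)
  expect_type(meta$altitude, "double")
  expect_equal(meta$altitude, c(1500, 2100))

  ds <- random_dataset(n = 4, L = 2, n_pop = 2)
  ds <- attach_metadata(ds, meta)
  expect_equal(species_of_individual(ds)[1], "s1")

  ds3 <- random_dataset(n = 6, L = 2, n_pop = 3)
  expect_error(attach_metadata(ds3, meta), "p3")

  writeLines(c("population,latitude", "p1,23.5"), f)
  expect_error(read_metadata_csv(f), "missing columns")
})
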