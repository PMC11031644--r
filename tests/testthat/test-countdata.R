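test_that("read_counts validates schema, counts and keys", {
  path <- withr::local_tempfile(fileext = ".csv")

  write.csv(data.frame(species = "a", method = "HLC", location = "indoor",
                       site = "s", night = "n", count = 3),
            path, row.names = FALSE)
  tab <- read_counts(path)
  expect_s3_class(tab, "count_table")
  expect_identical(tab$count, 3L)

  # header-only file -> empty table with zero strata
  write.csv(data.frame(species = character(0), method = character(0),
                       location = character(0), site = character(0),
                       night = character(0), count = integer(0)),
            path, row.names = FALSE)
  empty <- read_counts(path)
  expect_identical(nrow(empty), 0L)
  expect_identical(nrow(strata(empty)), 0L)

  # missing column named in the error
  write.csv(data.frame(species = "a", method = "HLC", location = "indoor",
                       site = "s", night = "n"),
            path, row.names = FALSE)
  expect_error(read_counts(path), "count")

  # negative count rejected with its row number
  write.csv(data.frame(species = "a", method = "HLC", location = "indoor",
                       site = "s", night = "n", count = -3),
            path, row.names = FALSE)
  expect_error(read_counts(path), "non-negative integer.*1")

  # duplicate key rejected listing clashing rows
  write.csv(data.frame(species = "a", method = "HLC", location = "indoor",
                       site = "s", night = "n", count = c(1, 2)),
            path, row.names = FALSE)
  expect_error(read_counts(path), "duplicate.*1, 2")

  # remappable column names
  write.csv(data.frame(taxon = "a", method = "HLC", location = "indoor",
                       site = "s", night = "n", n = 5),
            path, row.names = FALSE)
  remapped <- read_counts(path, schema = c(species = "taxon", count = "n"))
  expect_identical(remapped$species, "a")
  expect_identical(remapped$count, 5L)
})

test_that("count tables round-trip through CSV unchanged", {
  tab <- tiny_table()
  path <- withr::local_tempfile(fileext = ".csv")
  write_counts(tab, path)
  back <- read_counts(path)
  expect_identical(as.data.frame(back), as.data.frame(tab))
})

test_that("species_arm_totals conserves counts", {
  tab <- tiny_table()
  tot <- species_arm_totals(tab)
  expect_identical(sum(tot), sum(tab$count))
  single <- count_table(data.frame(species = "sp A", method = "X",
                                   location = "indoor", site = "s",
                                   night = "n", count = 5))
  m <- species_arm_totals(single)
  expect_identical(dim(m), c(1L, 1L))
  expect_identical(m[1, 1], 5L)
})

test_that("genus composition sums to one and flags unmapped species", {
  tab <- tiny_table()
  p <- genus_composition(tab, "HLC")
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_named(p, c("Aedes", "Culex"))

  one_genus <- count_table(data.frame(species = "Culex only", method = "HLC",
                                      location = "indoor", site = "s",
                                      night = "n", count = 4))
  expect_equal(unname(genus_composition(one_genus, "HLC")), 1)

  expect_error(genus_composition(tab, "HLC",
                                 genus_map = c("Aedes demo" = "Aedes")),
               "Culex demo")
  expect_error(genus_composition(tab, "NOPE"), "zero total")
})

test_that("to_species_matrix keeps exactly the strata with a positive catch", {
  # species present in 12 of 35 strata: expected n_strata counted by brute
  # force over the records
  set.seed(11)
  present <- sort(sample(35, 12))
  recs <- do.call(rbind, lapply(1:35, function(i) {
    data.frame(species = "patchy", method = c("HLC", "SHK"),
               location = "indoor", site = "s1",
               night = sprintf("n%02d", i),
               count = if (i %in% present) c(2L, 1L) else c(0L, 0L))
  }))
  tab <- count_table(recs)
  m <- to_species_matrix(tab, "patchy")
  expect_identical(m$n_strata, length(present))
  expect_identical(sort(colnames(m$counts)), c("HLC indoor", "SHK indoor"))

  # permutation invariance to record order
  perm <- count_table(recs[sample(nrow(recs)), ])
  m2 <- to_species_matrix(perm, "patchy")
  expect_identical(m$counts, m2$counts)

  # single-stratum species
  one <- count_table(data.frame(species = "lone", method = "HLC",
                                location = "indoor", site = "s",
                                night = "n", count = 2))
  expect_identical(to_species_matrix(one, "lone")$n_strata, 1L)

  expect_error(to_species_matrix(tab, "missing species"), "not present")
  expect_error(to_species_matrix(tab, "patchy", arm_key("CDC", "indoor")),
               "reference arm")
})

test_that("zero-filling covers the full sampling frame within included strata", {
  # candidate arm has no record in stratum n2 but the stratum is sampled
  tab <- count_table(data.frame(
    species = "sp", method = c("HLC", "HLC", "SHK"),
    location = "indoor", site = "s",
    night = c("n1", "n2", "n1"), count = c(4L, 2L, 1L)))
  m <- to_species_matrix(tab, "sp")
  expect_identical(m$n_strata, 2L)
  expect_identical(m$counts["s | n2", "SHK indoor"], 0L)
})

test_that("minimum-strata filter mirrors model eligibility", {
  meta <- data.frame(species = c("often", "sometimes", "rare"),
                     n_strata = c(35, 10, 7))
  expect_identical(filter_by_strata(meta, 10)[1:2], c("often", "sometimes"))
  expect_identical(as.character(filter_by_strata(meta, 1)),
                   c("often", "sometimes", "rare"))
  expect_error(filter_by_strata(meta, 0), "min_strata")

  tab <- tiny_table()
  elig <- filter_by_strata(tab, 2)
  expect_setequal(as.character(elig), c("Aedes demo", "Culex demo"))
  expect_identical(as.character(filter_by_strata(tab, 3)), "Aedes demo")
})
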