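test_that("profile strings parse per the forensic conventions", {
  expect_length(parse_profile("rCRS")$positions, 0)
  expect_equal(parse_profile("16069 16126")$positions, c(16069L, 16126L))
  p <- parse_profile("T16126C C16292T C16294T A16399G",
                     range = c(16024, 16569))
  expect_equal(p$positions, c(16126L, 16292L, 16294L, 16399L))
  expect_equal(p$ref, c("T", "C", "C", "A"))
  expect_equal(p$alt, c("C", "T", "T", "G"))
  # bare positions imply the transition partner of the rCRS base
  q <- parse_profile("16093")
  expect_equal(q$ref, "T")
  expect_equal(q$alt, "C")
})

test_that("profile parsing rejects bad input", {
  expect_error(parse_profile("15900"), "range")
  expect_error(parse_profile("16093 16093"), "duplicate")
  expect_error(parse_profile("16093x16189"), "unparseable")
  expect_error(parse_profile("T16304T"), "identical")
  expect_warning(parse_profile("A16304C"), "rCRS base")
})

test_that("parse -> format -> parse round trips for generated profiles", {
  set.seed(41)
  for (i in 1:50) {
    p <- random_profile()
    expect_identical(parse_profile(format(p)), p)
  }
  # explicit transversion notation survives the round trip
  p <- parse_profile("C16232A", range = c(16024, 16569))
  expect_identical(format(p), "C16232A")
  expect_identical(parse_profile(format(p), range = c(16024, 16569))$alt,
                   "A")
})

test_that("IUPAC-coded stains parse to per-position statuses", {
  obs <- parse_mixture("16126Y 16292Y 16294Y 16304Y 16399R",
                       range = c(16024, 16569))
  expect_setequal(names(obs$status),
                  c("16126", "16292", "16294", "16304", "16399"))
  expect_true(all(obs$status == "MIXED"))
  expect_equal(mixture_status(obs, 16189), "REF_ONLY")

  obs2 <- parse_mixture("16189 16293", mixed = c(16189, 16293))
  expect_true(all(obs2$status == "MIXED"))

  empty <- parse_mixture("")
  expect_length(empty$status, 0)
  expect_equal(mixture_status(empty, 16093), "REF_ONLY")
})

test_that("IUPAC codes are validated against the reference base", {
  # 16093 has rCRS base T; 'R' decodes to A/G, which excludes T
  expect_warning(parse_mixture("16093R"), "does not include the rCRS base")
  expect_silent(parse_mixture("16093Y"))
  # >2-base codes are accepted but flagged
  obs <- parse_mixture("16093N")
  expect_equal(obs$flagged, 16093L)
  expect_error(parse_mixture("16093Q"), "unknown IUPAC")
})

test_that("databases collapse duplicate profiles into counts", {
  db <- table1_db()
  expect_equal(db$total, 9)
  expect_length(db$profiles, 8)  # H23 and H2136 share a profile
  expect_equal(as.integer(db$counts[[H23]]), 2)
  # duplicating every row doubles the total but not the frequencies
  db2 <- haplotype_db(rep(db$entries$profile, 2))
  expect_equal(db2$total, 18)
  expect_length(db2$profiles, 8)
  expect_equal(db_frequencies(db2)[names(db_frequencies(db))],
               db_frequencies(db))
})

test_that("database files load with row-level errors", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("region\tsample_id\tprofile", "X\t1\t20 rCRS"), f)
  # the profile field is the rest of the row; "20 rCRS" is not valid
  # ("rCRS" is only a profile on its own, and 20 is no HVS-I position)
  expect_error(load_database(f), "unparseable|outside range")
  writeLines(c("region\tsample_id\tprofile", "X\t1\trCRS"), f)
  db <- load_database(f)
  expect_equal(db$total, 1)
  expect_length(db$profiles, 1)
  writeLines(c("region\tsample_id\tprofile"), f)
  expect_error(load_database(f), "empty database file")
  writeLines(c("region\tsample_id\tprofile", "only-one-field"), f)
  expect_error(load_database(f), "line 2")
})

test_that("the casework fixture parses and the named pair explains it", {
  case <- mtmix_fixture("example3_case")
  expect_equal(case$victim$positions, 16304L)
  expect_equal(case$suspect$positions, c(16126L, 16292L, 16294L, 16399L))
  expect_true(all(case$stain$status == "MIXED"))
  expect_setequal(names(case$stain$status),
                  c("16126", "16292", "16294", "16304", "16399"))
  # victim + suspect lineages jointly explain every mixed call
  expect_true(is_consistent(list(case$victim, case$suspect), case$stain,
                            known = list(case$victim)))
  # but neither alone does
  expect_false(is_consistent(list(case$victim), case$stain))
  expect_false(is_consistent(list(case$suspect), case$stain))
})

test_that("frequency estimation follows counting with the add-one policy", {
  db <- table1_db()
  f <- haplotype_frequency(db, h(db, H23), "error")
  expect_equal(as.numeric(f), 2 / 9)
  unseen <- parse_profile("16224")
  expect_error(haplotype_frequency(db, unseen, "error"), "not found")
  fa <- haplotype_frequency(db, unseen, "add_one")
  expect_equal(as.numeric(fa), 1 / 10)
  expect_equal(attr(fa, "total"), 10)
  one <- haplotype_db("16093")
  expect_equal(as.numeric(haplotype_frequency(one, parse_profile("16093"),
                                              "error")), 1)
})

test_that("distinct-profile frequencies sum to one", {
  set.seed(42)
  for (i in 1:20) {
    db <- random_db(sample(3:20, 1), c(16093, 16189, 16224, 16293, 16311))
    expect_equal(sum(db_frequencies(db)), 1)
  }
})

test_that("design_matrix reproduces the tabulated 0/1 layout", {
  db <- table1_db()
  tab <- table2()
  cols <- c(H20 = "rCRS", H21 = H21, H22 = H22, H23 = H23,
            H1263 = H1263, H1264 = "16069 16126", H2135 = H2135,
            H2136 = H23, H2575 = "16126 16294 16296 16304")
  X <- design_matrix(lapply(unname(cols), function(k) db$profiles[[k]]),
                     sites = tab$sites, rcrs_row = TRUE)
  colnames(X) <- names(cols)
  expect_equal(X, tab$matrix)
  expect_equal(sum(X["16093", ]), 6)
  expect_equal(unname(design_matrix(list(parse_profile("rCRS")),
                                    sites = tab$sites)[, 1]),
               rep(0L, 10))
})

test_that("design_matrix agrees with set membership on random profiles", {
  set.seed(7)
  pool <- c(16069, 16093, 16126, 16189, 16224, 16293, 16311)
  for (rep in 1:20) {
    profs <- replicate(4, random_profile(pool), simplify = FALSE)
    sites <- sort(sample(pool, 5))
    X <- design_matrix(profs, sites = sites)
    for (i in seq_along(sites)) for (j in seq_along(profs))
      expect_identical(unname(X[i, j] == 1L),
                       sites[i] %in% profs[[j]]$positions)
  }
})
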