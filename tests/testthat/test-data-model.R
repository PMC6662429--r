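test_that("Genepop files round-trip through read and write", {
  g <- geno_tbl(
    id = rep(c("A", "B", "C"), each = 2),
    locus = rep(c("Loc1", "Loc2"), 3),
    a1 = c(101L, 204L, 102L, NA, 101L, 204L),
    a2 = c(101L, 206L, 102L, NA, 103L, 204L),
    population = rep(c("p1", "p1", "p2"), each = 2)
  )
  f <- withr::local_tempfile(fileext = ".gen")
  write_genepop(g, f)
  back <- read_genepop(f, pop_names = c("p1", "p2"))
  expect_equal(back[c("id", "population", "locus", "a1", "a2")],
               g[c("id", "population", "locus", "a1", "a2")],
               ignore_attr = TRUE)
  # missing-data count preserved
  expect_identical(sum(is.na(back$a1)), sum(is.na(g$a1)))
})

test_that("Genepop parsing maps all-zero codes to missing, not allele 0", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy", "LocA", "POP", "A , 101101", "B , 102102",
               "C , 000000"), f)
  g <- read_genepop(f)
  expect_equal(g$a1[g$id == "A"], 101L)
  expect_equal(g$a2[g$id == "B"], 102L)
  expect_true(is.na(g$a1[g$id == "C"]) && is.na(g$a2[g$id == "C"]))
})

test_that("a header-only Genepop file yields loci but zero individuals", {
  loci14 <- c("Ccste05", "CIDK135", "CIDK144", "CIDK184", "Z106", "Z148",
              "Z154", "Z494", "D1", "D11", "D101", "D110", "D111", "D140")
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("markers only", loci14), f)
  g <- read_genepop(f)
  expect_equal(nrow(g), 0)
  expect_equal(geno_loci(g), loci14)
})

test_that("malformed Genepop rows fail with the line number", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy", "LocA", "LocB", "POP", "A , 101101"), f)
  expect_error(read_genepop(f), "line 5")
  writeLines(c("toy", "LocA", "POP", "A , 000101"), f)
  expect_error(read_genepop(f), "half-missing")
})

test_that("the wide CSV genotype dialect is parsed, zeros meaning missing", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,population,site,nest,stage,LocA.a1,LocA.a2,LocB.a1,LocB.a2",
               "A,p1,s1,n1,hatchling,101,103,0,0",
               "B,p1,s1,n1,hatchling,101,101,202,204"), f)
  g <- read_genotypes_csv(f)
  expect_equal(nrow(g), 4)
  expect_true(is.na(g$a1[g$id == "A" & g$locus == "LocB"]))
  expect_equal(g$a2[g$id == "B" & g$locus == "LocB"], 204L)
  expect_equal(unique(g$nest), "n1")
})

test_that("coordinate reading defaults the window to the bounding box", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,x,y", "a,300000,2000000", "b,300010,2000000",
               "c,300000,2000010"), f)
  patt <- read_coordinates(f)
  expect_equal(pp_window(patt), c(300000, 300010, 2000000, 2000010))
})

test_that("lat/long-looking coordinates are rejected with projection advice", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("id,x,y", "a,-71.5,18.1", "b,-71.6,18.2"), f)
  expect_error(read_coordinates(f), "planar metres")
})

test_that("duplicate ids and out-of-window points are refused", {
  xy <- tibble::tibble(id = c("a", "a"), x = c(500, 600), y = c(0, 1))
  expect_error(pp(xy), "duplicated point id")
  xy2 <- tibble::tibble(id = c("a", "b"), x = c(500, 600), y = c(0, 1))
  expect_error(pp(xy2, window = c(0, 550, 0, 10)), "outside the window")
})

test_that("validate_study reports advisories and rejects non-tree designs", {
  s <- simulate_study(sim_config(missing_rate = 0), seed = 42)
  rep0 <- validate_study(s$panel, s$patterns$TIE, s$design)
  # MAL nests are orphans relative to the TIE pattern only
  expect_true(all(rep0$check %in% "orphan_nest"))
  all_patt <- pp(dplyr::bind_rows(lapply(s$patterns, pp_coords)))
  expect_equal(nrow(validate_study(s$panel, all_patt, s$design)), 0)
  bad <- s$design
  bad$cluster[bad$nest == bad$nest[1]][1] <- "elsewhere"
  expect_error(validate_study(s$panel, design = bad), "not a tree")
})

test_that("one hatchling per nest is selected reproducibly", {
  s <- simulate_study(sim_config(), seed = 5)
  sub <- one_per_nest(s$panel)
  expect_equal(sort(unique(sub$nest)), sort(unique(s$panel$nest)))
  per_nest <- dplyr::count(dplyr::distinct(sub, nest, id), nest)
  expect_true(all(per_nest$n == 1))
  # default rule: first id in sort order
  first_ids <- dplyr::summarise(
    dplyr::group_by(dplyr::distinct(s$panel, nest, id), nest),
    id = min(id), .groups = "drop")
  expect_setequal(unique(sub$id), first_ids$id)
  # seeded rule is deterministic under the same seed
  expect_identical(one_per_nest(s$panel, seed = 3), one_per_nest(s$panel, seed = 3))
})

test_that("half-called genotypes are rejected at construction", {
  expect_error(geno_tbl(id = "A", locus = "L1", a1 = 101L, a2 = NA),
               "half-called")
})
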