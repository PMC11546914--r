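# Exhaustive-enumeration oracle for the upper-tail hypergeometric p-value:
# count marker subsets of the universe with at least `hits` pathway members.
ora_enum_oracle <- function(n_universe, n_pathway, n_markers, hits) {
  subsets <- utils::combn(n_universe, n_markers)
  in_pathway <- function(s) sum(s <= n_pathway)  # wlog pathway = first ids
  mean(apply(subsets, 2, in_pathway) >= hits)
}

test_that("GMT round trip, deduplication and empty-line handling", {
  path <- toy_gmt_path()
  ann <- read_gmt(path)
  expect_identical(nrow(ann), 2L)
  expect_identical(ann$members[[1]], sprintf("m%d", 1:5))

  # duplicate member inside a line is dropped with a warning
  dir <- withr::local_tempdir()
  p2 <- file.path(dir, "dup.gmt")
  writeLines("PWX\tDup pathway\tm1\tm2\tm1", p2)
  expect_warning(annd <- read_gmt(p2), "duplicated")
  expect_identical(annd$members[[1]], c("m1", "m2"))

  # memberless line skipped with warning
  p3 <- file.path(dir, "empty.gmt")
  writeLines(c("PWY\tNo members", "PW2\tOk\tm1\tm2"), p3)
  expect_warning(ann3 <- read_gmt(p3), "no members")
  expect_identical(ann3$pathway_id, "PW2")

  # write/read round trip preserves the sets
  p4 <- file.path(dir, "out.gmt")
  write_gmt(ann, p4)
  expect_identical(read_gmt(p4), ann)
})

test_that("ora p-values match the hypergeometric tail and the enumeration oracle", {
  universe <- sprintf("u%02d", 1:20)
  ann <- tibble::tibble(
    pathway_id = "P1", pathway_name = "Toy",
    members = list(universe[1:5])
  )
  markers <- c(universe[1:3], universe[10:11])  # 3 of 5 drawn from the pathway
  res <- ora(markers, ann, universe)
  expect_equal(res$p_value, 1126 / 15504, tolerance = 1e-12)
  expect_identical(res$hits, 3L)
  expect_identical(res$total, 5L)
  expect_equal(res$p_value, ora_enum_oracle(20, 5, 5, 3))

  # a couple more points against the oracle
  expect_equal(
    ora(universe[1:2], ann, universe)$p_value, ora_enum_oracle(20, 5, 2, 2)
  )
  expect_equal(
    ora(universe[6:9], ann, universe)$p_value, ora_enum_oracle(20, 5, 4, 0)
  )

  # hits = 0 -> p = 1; markers = universe -> forced hits, p = 1
  expect_equal(ora(universe[6:9], ann, universe)$p_value, 1)
  full <- ora(universe, ann, universe)
  expect_identical(full$hits, 5L)
  expect_equal(full$p_value, 1)
})

test_that("ora respects the universe, ordering invariance and hit monotonicity", {
  universe <- sprintf("u%02d", 1:15)
  ann <- tibble::tibble(
    pathway_id = c("A", "B"),
    pathway_name = c("Path A", "Path B"),
    members = list(c(universe[1:4], "not_measured"), universe[5:10])
  )
  res <- ora(universe[c(1, 2, 5)], ann, universe)
  # unmeasured member does not count toward the pathway size
  expect_identical(res$total[res$pathway_id == "A"], 4L)
  # FDR dominates p
  expect_true(all(res$fdr >= res$p_value - 1e-12))

  # pathway file order does not change results
  res_flip <- ora(universe[c(1, 2, 5)], ann[2:1, ], universe)
  expect_identical(
    dplyr::arrange(tibble::as_tibble(res), .data$pathway_id),
    dplyr::arrange(tibble::as_tibble(res_flip), .data$pathway_id)
  )

  # adding a marker never decreases any hit count
  res_plus <- ora(universe[c(1, 2, 3, 5)], ann, universe)
  expect_true(all(res_plus$hits[order(res_plus$pathway_id)] >=
    res$hits[order(res$pathway_id)]))

  # marker outside the universe and empty universe are errors
  expect_error(ora("zzz", ann, universe), "outside the universe")
  expect_error(ora(character(0), ann, character(0)), "nonempty")
})

test_that("combine_marker_sets returns union, intersection and a tidy table", {
  a <- sprintf("p%02d", 1:37)
  b <- sprintf("s%02d", 1:54)
  disjoint <- combine_marker_sets(a, b)
  expect_identical(length(disjoint$union), 91L)
  expect_identical(length(disjoint$intersection), 0L)

  same <- combine_marker_sets(a, a)
  expect_identical(same$union, sort(a))
  expect_identical(same$intersection, sort(a))

  # overlap of exactly 8 ids, mirroring a dual-status marker set
  b2 <- c(a[1:8], b[1:20])
  both <- combine_marker_sets(a, b2)
  expect_identical(length(both$intersection), 8L)
  expect_identical(
    sum(both$table$in_primary & both$table$in_secondary), 8L
  )
})
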