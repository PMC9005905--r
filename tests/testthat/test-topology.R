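test_that("reference fixture has the expected structure", {
  tree <- fixture_tree()
  expect_s3_class(tree, "arterial_tree")
  expect_no_error(validate_tree(tree))
  # both renal arteries are terminal and carry their conventional ids
  expect_true(all(c(36, 38) %in% terminal_ids(tree)))
  expect_true(is_terminal(tree, 36))
  expect_true(is_terminal(tree, 44))
})

test_that("topology files round-trip losslessly", {
  tree <- fixture_tree()
  path <- withr::local_tempfile(fileext = ".json")
  save_tree(tree, path)
  back <- load_tree(path)
  expect_equal(back$segments, tree$segments)
  expect_equal(back$sites, tree$sites)
  expect_equal(back$root_id, tree$root_id)
  # and a second round trip is identical text
  path2 <- withr::local_tempfile(fileext = ".json")
  save_tree(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("malformed topologies are rejected with structural errors", {
  # no root: every segment has a parent
  expect_error(arterial_tree(list(
    artery_segment(1, "a", 10, 10, 9, 20, parent_id = 2),
    artery_segment(2, "b", 10, 10, 9, 20, parent_id = 1))),
    "root")
  # self-referencing parent creates an unreachable subgraph
  expect_error(arterial_tree(list(
    artery_segment(1, "a", 10, 10, 9, 20,
                   windkessel = windkessel_outlet(0.1, 5, 0.3)),
    artery_segment(2, "b", 10, 10, 9, 20, parent_id = 2))),
    "connected|cycle")
  # a hand-built cycle is caught by validate_tree
  tree <- fixture_tree()
  tree$segments[["1"]]$child_ids <- c(tree$segments[["1"]]$child_ids, 1L)
  expect_error(validate_tree(tree), "cycle|mismatch")
  # geometric invariants
  expect_error(artery_segment(9, "bad", -1, 10, 9, 20), "length")
  expect_error(artery_segment(9, "bad", 10, 9, 10, 20), "taper")
  # non-terminal with a Windkessel
  t2 <- fixture_tree()
  t2$segments[["1"]]$windkessel <- windkessel_outlet(0.1, 5, 0.3)
  expect_error(validate_tree(t2), "Windkessel")
})

test_that("terminal removal updates the tree and refuses unsafe removals", {
  tree <- fixture_tree()
  n0 <- length(terminal_ids(tree))
  t1 <- suppressWarnings(remove_segment(tree, 36))
  expect_equal(length(terminal_ids(t1)), n0 - 1)
  expect_null(t1$segments[["36"]])
  expect_false(36 %in% t1$segments[["10"]]$child_ids)
  # untouched segments are bit-identical
  untouched <- setdiff(names(tree$segments), c("36", "10"))
  expect_identical(t1$segments[untouched], tree$segments[untouched])
  # the removed segment's site is dropped with a warning
  expect_warning(remove_segment(tree, 36), "renal_left")
  # refusals
  expect_error(remove_segment(tree, 1), "root")
  expect_error(remove_segment(tree, 7), "non-terminal")
  expect_error(remove_segment(tree, 999), "no segment")
})

test_that("kidney configurations compose removals and transplant", {
  tree <- fixture_tree()
  expect_equal(apply_kidney_configuration(tree, "2KDN")$segments, tree$segments)
  t1 <- suppressWarnings(apply_kidney_configuration(tree, "1KDN"))
  expect_null(t1$segments[["36"]])
  expect_false(is.null(t1$segments[["38"]]))
  t0 <- suppressWarnings(apply_kidney_configuration(tree, "0KDN"))
  expect_null(t0$segments[["36"]])
  expect_null(t0$segments[["38"]])
  # removal order does not matter
  alt <- suppressWarnings(remove_segment(remove_segment(tree, 38), 36))
  expect_equal(t0$segments[sort(names(t0$segments))],
               alt$segments[sort(names(alt$segments))])
  # idempotence of the descriptor
  t0b <- suppressWarnings(apply_kidney_configuration(tree, "0KDN"))
  expect_equal(t0$segments, t0b$segments)
  expect_error(kidney_configuration("3KDN"))
})

test_that("transplant grafts the donor onto the terminal iliac", {
  tree <- fixture_tree()
  t0 <- suppressWarnings(apply_kidney_configuration(tree, "0KDN"))
  tx <- suppressWarnings(apply_kidney_configuration(tree, "TX"))
  # one extra terminal: graft + continuation replace the single outlet
  expect_equal(length(terminal_ids(tx)), length(terminal_ids(t0)) + 1)
  graft <- tx$segments[["38"]]
  expect_equal(graft$parent_id, 44L)
  expect_equal(graft$windkessel, tree$segments[["38"]]$windkessel)
  expect_equal(graft$distensibility, tree$segments[["38"]]$distensibility)
  expect_null(tx$segments[["44"]]$windkessel)
  # downstream leg measurement is unaffected
  expect_equal(arterial_path(tx, "carotid", "femoral")$distance_cm, 66)
  # donor must exist in the donor tree
  expect_error(transplant_segment(t0, 99, 44, donor_tree = tree), "not found")
  # target must be terminal
  expect_error(transplant_segment(tree, 38, 12, donor_tree = tree), "terminal")
})

test_that("arterial paths sum traversed lengths and are symmetric", {
  tree <- fixture_tree()
  expect_equal(arterial_path(tree, "carotid", "femoral")$distance_cm, 66)
  expect_equal(arterial_path(tree, "carotid", "radial")$distance_cm, 70)
  expect_equal(arterial_path(tree, "radial", "digital")$distance_cm, 19)
  expect_equal(arterial_path(tree, "carotid", "carotid")$distance_cm, 0)
  for (pr in list(c("carotid", "femoral"), c("radial", "digital"),
                  c("aorta", "renal_left"))) {
    expect_equal(arterial_path(tree, pr[1], pr[2])$distance_cm,
                 arterial_path(tree, pr[2], pr[1])$distance_cm)
  }
  # chain is contiguous and its lengths sum to the distance for
  # junction-crossing paths
  pm <- arterial_path(tree, "renal_left", "renal_right")
  expect_equal(pm$distance_cm, 3.5)  # 1.75 cm up each renal to the shared junction
  expect_error(arterial_path(tree, "carotid", "toe"), "unknown site")
})
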