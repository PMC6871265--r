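test_that("stem projection maps FADs by subtending-node depth", {
  topo <- read_tree_text("((A:1,B:1):1,C:2);")
  proj <- project_fads(topo, data.frame(lineage_id = "A", fad_ma = 3))
  # A's stem runs from the AB node at relative depth 0.5: implied root 3/0.5
  expect_equal(proj$attach_depth, 0.5)
  expect_equal(proj$implied_root_age, 6)
  # C subtends the root: implied root age equals its FAD
  projC <- project_fads(topo, data.frame(lineage_id = "C", fad_ma = 3))
  expect_equal(projC$implied_root_age, 3)
})

test_that("single-tip tree reduces to the lineage itself", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines("(A:3);", path)
  proj <- project_fads(read_newick(path),
                       data.frame(lineage_id = "A", fad_ma = 4))
  expect_equal(proj$implied_root_age, 4)
})

test_that("unmatched labels error and list the candidates", {
  topo <- read_tree_text("((A:1,B:1):1,C:2);")
  expect_error(project_fads(topo, data.frame(lineage_id = "Z", fad_ma = 1)),
               "unmatched.*Z.*candidates", ignore.case = TRUE)
})

test_that("equal implied ages sort deterministically by lineage label", {
  topo <- read_tree_text("(A:1,B:1,C:1);")  # star: all stems at the root
  proj <- project_fads(topo, data.frame(lineage_id = c("C", "A", "B"),
                                        fad_ma = c(2, 2, 2)))
  expect_equal(proj$lineage_id, c("A", "B", "C"))
  expect_equal(proj$attach_depth, rep(1, 3))
})

test_that("crown attachment uses the node's own depth, rejects tips", {
  topo <- read_tree_text("((A:1,B:1)ab:1,C:2)r;")
  proj <- project_fads(topo, data.frame(lineage_id = "ab", fad_ma = 3),
                       attach = "crown")
  expect_equal(proj$attach_depth, 0.5)
  expect_error(project_fads(topo, data.frame(lineage_id = "A", fad_ma = 3),
                            attach = "crown"), "crown")
})

test_that("supertaxon bracket treats implied positions as localities", {
  proj <- data.frame(lineage_id = letters[1:4], fad_ma = 1:4,
                     implied_root_age = c(10, 8, 6, 4))
  br <- supertaxon_bracket(proj, C = 0.95)
  expect_s3_class(br, "bracket_estimate")
  expect_equal(br$min_age, 10)
  expect_equal(round(br$soft_max_age, 1), 21.1)  # 10 * 20^(1/4)
  expect_equal(br$point_estimate, 10 * 5 / 4)
  # N = 1 reduces to ci_extant on that lineage
  br1 <- supertaxon_bracket(proj[1, , drop = FALSE], C = 0.95)
  expect_equal(br1$soft_max_age, ci_extant(10, 1, 0.95)$T_C)
  # named calibration lineage overrides the automatic choice
  br2 <- supertaxon_bracket(proj, C = 0.95, calibration_lineage = "b")
  expect_equal(br2$min_age, 8)
})

test_that("star tree reduces the bracket to ci_extant on raw FADs", {
  topo <- read_tree_text("(A:1,B:1,C:1,D:1);")
  fads <- data.frame(lineage_id = c("A", "B", "C", "D"),
                     fad_ma = c(9, 4, 7, 2))
  br <- supertaxon_bracket(project_fads(topo, fads), C = 0.95)
  expect_equal(br$soft_max_age, ci_extant(9, 4, 0.95)$T_C)
  expect_equal(br$min_age, 9)
})

test_that("the bracket is invariant to overall tree rescaling", {
  fads <- data.frame(lineage_id = c("A", "C"), fad_ma = c(3, 5))
  b1 <- supertaxon_bracket(project_fads(
    read_tree_text("((A:1,B:1):1,C:2);"), fads))
  b2 <- supertaxon_bracket(project_fads(
    read_tree_text("((A:10,B:10):10,C:20);"), fads))
  expect_equal(b1$soft_max_age, b2$soft_max_age)
})

test_that("dropping the youngest projection cannot shrink the soft max", {
  proj <- data.frame(lineage_id = letters[1:5],
                     implied_root_age = c(10, 9, 7, 5, 2))
  full <- supertaxon_bracket(proj)$soft_max_age
  dropped <- supertaxon_bracket(proj[-5, , drop = FALSE])$soft_max_age
  expect_gte(dropped, full)
})

test_that("leave-one-out flagging isolates wild implied ages", {
  even <- data.frame(lineage_id = letters[1:6],
                     implied_root_age = rep(8, 6))
  expect_equal(nrow(flag_inconsistent_fads(even)), 0L)

  skewed <- data.frame(lineage_id = letters[1:10],
                       implied_root_age = c(rep(5, 9), 50))
  flagged <- flag_inconsistent_fads(skewed)
  expect_equal(flagged$lineage_id, "j")

  # < 3 projections: warn, flag nothing
  expect_warning(two <- flag_inconsistent_fads(skewed[1:2, ]), ">= 3")
  expect_equal(nrow(two), 0L)
})

test_that("bracket recomputes cleanly after removing flagged FADs", {
  skewed <- data.frame(lineage_id = letters[1:10],
                       implied_root_age = c(rep(5, 9), 50))
  all_rows <- flag_inconsistent_fads(skewed, return = "all")
  keep <- all_rows[!all_rows$flagged, setdiff(names(all_rows), "flagged")]
  br <- supertaxon_bracket(keep, C = 0.95)
  expect_equal(br$min_age, 5)
  expect_equal(br$soft_max_age, ci_extant(5, 9, 0.95)$T_C)
})
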