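seg_label_thirds <- function(tree) label_segments(tree, overwrite = TRUE)

test_that("sub-branch counts at or below the reference stay active", {
  # two subs both attaching in the proximal third, reference 2 -> both active
  tr <- seg_label_thirds(forked_tree(main_len = 90, n_main = 10,
                                     attach_at = c(2, 3)))
  tr <- classify_subbranches(tr, reference_counts = c(proximal = 2, mid = 2,
                                                      distal = 1))
  expect_true(all(tr$branches$active[tr$branches$class == "sub"]))
})

test_that("excess sub-branches go inactive farthest-from-root first", {
  # three subs in the proximal third with reference 1
  tr <- seg_label_thirds(forked_tree(main_len = 120, n_main = 13,
                                     attach_at = c(2, 3, 4)))
  tr <- classify_subbranches(tr, reference_counts = c(proximal = 1, mid = 2,
                                                      distal = 1))
  act <- tr$branches$active[tr$branches$class == "sub"]
  expect_equal(sum(act), 1L)
  expect_equal(sum(!act), 2L)
  # the nearest-to-root sub survives
  expect_true(tr$branches$active[tr$branches$id == "S1"])
})

test_that("classification handles trees without sub-branches and rejects unlabeled mains", {
  tr <- straight_tree()
  expect_identical(classify_subbranches(tr), tr)
  tr2 <- forked_tree()
  expect_error(classify_subbranches(tr2), "segment labels")
})

test_that("main-branch importance interpolates linearly from 1.0 to 0.1", {
  # 3 equally spaced points: ends are the fixed anchors, midpoint is 0.55
  tr <- seg_label_thirds(straight_tree(length_mm = 100, n = 3))
  tr <- assign_importance(classify_subbranches(tr))
  expect_equal(tr$points$alpha, c(1.0, 0.55, 0.1))
})

test_that("active sub-branches decay linearly from the attach importance", {
  # attach at s = 1/3 of the main branch (alpha 0.7), 10 mm sub, 0.02/mm
  tr <- forked_tree(main_len = 90, n_main = 7, attach_at = 3, sub_len = 10,
                    n_sub_pts = 2)
  tr <- seg_label_thirds(tr)
  tr <- classify_subbranches(tr)
  tr <- assign_importance(tr, decay = 0.02)
  a_attach <- tr$points$alpha[3]
  expect_equal(a_attach, 1 - 0.9 * (2 / 6))
  sub_rows <- branch_rows(tr, "S1")
  expect_equal(tr$points$alpha[sub_rows[2]], a_attach - 0.02 * 10)
})

test_that("inactive sub-branches sit at the floor importance everywhere", {
  tr <- seg_label_thirds(forked_tree(main_len = 120, n_main = 13,
                                     attach_at = c(2, 3, 4)))
  tr <- classify_subbranches(tr, reference_counts = c(proximal = 1, mid = 2,
                                                      distal = 1))
  tr <- assign_importance(tr)
  for (bid in tr$branches$id[tr$branches$class == "sub" & !tr$branches$active]) {
    expect_true(all(tr$points$alpha[branch_rows(tr, bid)] == 0.1))
  }
})

test_that("importance is non-increasing along branches and spans [0.1, 1]", {
  for (seed in 1:5) {
    tr <- generate_vessel_tree(sample(c("LCA", "RCA"), 1), seed = seed)
    tr <- assign_importance(classify_subbranches(tr))
    expect_equal(max(tr$points$alpha), 1.0)
    expect_equal(min(tr$points$alpha), 0.1)
    for (bid in tr$branches$id) {
      a <- tr$points$alpha[branch_rows(tr, bid)]
      expect_true(all(diff(a) <= 1e-12))
    }
  }
})

test_that("importance assignment requires classified sub-branches", {
  tr <- seg_label_thirds(forked_tree())
  expect_error(assign_importance(tr), "unclassified")
})
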