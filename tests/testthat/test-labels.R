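# Label hierarchy, painting and parent constraints.

test_that("label hierarchies stay a forest with unique ids", {
  h <- label_hierarchy()
  h <- add_label(h, 0, "cell", "#00ff00")
  h <- add_label(h, 1, "nucleus", parent = 0)
  h <- add_label(h, 2, "nucleolus", parent = 1)
  h <- add_label(h, 3, "background")
  expect_equal(label_depth(h), c("0" = 0L, "1" = 1L, "2" = 2L, "3" = 0L))
  expect_error(add_label(h, 1, "dup"), "duplicate")
  expect_error(add_label(h, 4, "orphan", parent = 99), "not declared")
})

test_that("painting respects the chosen super-region level", {
  fx <- tiny_stack()
  d <- dim(fx$p$labels)
  h <- add_label(label_hierarchy(), 1, "a")
  ann <- annotation_volume(d)
  # voxel level: exactly one voxel
  ann1 <- paint(ann, cbind(2, 3, 4), "voxel", label = 1, hierarchy = h)
  expect_equal(sum(ann1$labels >= 0), 1L)
  expect_equal(ann1$labels[2, 3, 4], 1L)
  # supervoxel level: the whole region the coordinate lies in
  ann2 <- paint(ann, cbind(2, 3, 4), "supervoxel", label = 1,
                partition = fx$p, hierarchy = h)
  sv <- fx$p$labels[2, 3, 4]
  expect_equal(sum(ann2$labels == 1L), sum(fx$p$labels == sv))
  # idempotent repaint
  expect_identical(paint(ann2, cbind(2, 3, 4), "supervoxel", label = 1,
                         partition = fx$p), ann2)
  # megavoxel level covers at least the supervoxel
  desc <- supervoxel_mean(fx$fs, fx$p)
  mv <- megavoxels(fx$p, desc, similarity_threshold = 1e9)
  ann3 <- paint(ann, cbind(2, 3, 4), "megavoxel", label = 1,
                partition = fx$p, mv = mv)
  expect_true(all(ann3$labels[ann2$labels == 1L] == 1L))
  expect_error(paint(ann, cbind(2, 3, 4), "voxel", label = 7, hierarchy = h),
               "undeclared")
  expect_error(paint(ann, cbind(99, 1, 1), "voxel", label = 1), "out of bounds")
})

test_that("parent constraints use strict majority with ties excluded", {
  labs <- array(0L, c(4, 4, 4))
  labs[, , 3:4] <- 1L
  # full-volume parent: no restriction
  expect_true(all(constrain_to_parent(labs, array(TRUE, c(4, 4, 4)))))
  # half-volume parent aligned with region 1
  mask <- array(FALSE, c(4, 4, 4))
  mask[, , 3:4] <- TRUE
  expect_equal(constrain_to_parent(labs, mask), c(FALSE, TRUE))
  # exactly half of region 0 inside: tie -> excluded
  mask2 <- array(FALSE, c(4, 4, 4))
  mask2[, , 2:3] <- TRUE
  expect_equal(constrain_to_parent(labs, mask2), c(FALSE, FALSE))
  expect_error(constrain_to_parent(labs, array(FALSE, c(4, 4, 4))), "empty")
})

test_that("nested parent constraints compose", {
  fx <- small_phantom()
  p <- slic_supervoxels(gaussian_filter(fx$ph$volume$data, 1))
  cell <- fx$ph$labels >= 1L # inside the cell
  nucleus <- fx$ph$labels == 2L | fx$ph$labels == 3L
  in_cell <- constrain_to_parent(p, cell)
  in_nuc <- constrain_to_parent(p, nucleus)
  expect_true(all(which(in_nuc) %in% which(in_cell)))
})

test_that("child predictions outside the parent mask stay unchanged", {
  fx <- small_phantom()
  d <- dim(fx$ph$labels)
  # half-volume parent: training/prediction restricted to the lower x half
  parent_mask <- array(FALSE, d)
  parent_mask[, , 1:(d[3] %/% 2)] <- TRUE
  res <- segment_volume(fx$ph$volume, fx$ann, parent_mask = parent_mask,
                        seed = 3)
  inside <- constrain_to_parent(res$partition, parent_mask)
  outside_vox <- refine_to_voxels(ifelse(inside, 1L, 0L), res$partition) == 0L
  expect_true(all(res$labels[outside_vox] == -1L))
  expect_true(any(res$labels[!outside_vox] >= 0L))
  # whole-volume parent imposes no restriction
  res_all <- segment_volume(fx$ph$volume, fx$ann,
                            parent_mask = array(TRUE, d), seed = 3)
  res_plain <- segment_volume(fx$ph$volume, fx$ann, seed = 3)
  expect_identical(res_all$labels, res_plain$labels)
})

test_that("mask export and import round trip annotations exactly", {
  set.seed(60)
  grid <- array(sample(c(-1L, 0L, 1L, 2L), 4^3, replace = TRUE), c(4, 4, 4))
  masks <- export_masks(grid)
  expect_setequal(names(masks), c("0", "1", "2"))
  # union of masks + unlabelled = full grid
  covered <- Reduce(`|`, masks)
  expect_equal(covered, grid >= 0L, ignore_attr = TRUE)
  expect_identical(import_masks(masks), grid)
  # masked data equals pointwise product
  set.seed(61)
  datav <- array(rnorm(4^3), c(4, 4, 4))
  md <- export_masks(grid, label_ids = 1L, mode = "masked_data", data = datav)
  expect_equal(md[["1"]], datav * (grid == 1L))
  # empty label yields an all-zero mask
  em <- export_masks(grid, label_ids = 9L)
  expect_true(all(!em[["9"]]))
})
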