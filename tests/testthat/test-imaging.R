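# One rendered scene reused across segmentation tests.
seg_scene <- generate_tissue_scene("control", n_adipocytes = 6,
                                   n_macrophages = 12, frame = 384, seed = 13)
seg_stack <- render_multichannel_stack(seg_scene, optics_config(frame = 384),
                                       seed = 14)
seg_proj <- z_project(seg_stack, "sum")

test_that("z projection matches single planes, constants, and a loop oracle", {
  one <- array(runif(4 * 4 * 2), dim = c(4, 4, 2, 1))
  expect_equal(z_project(one, "sum")$data, one[, , , 1])
  expect_equal(z_project(one, "max")$data, one[, , , 1])
  ones <- array(1, dim = c(3, 3, 1, 2))
  expect_true(all(z_project(ones, "sum")$data == 2))
  expect_true(all(z_project(ones, "max")$data == 1))

  arr <- array(rpois(5 * 4 * 3 * 3, 7), dim = c(5, 4, 3, 3))
  ref_sum <- array(0, dim = c(5, 4, 3)); ref_max <- array(0, dim = c(5, 4, 3))
  for (y in 1:5) for (x in 1:4) for (ci in 1:3) {
    ref_sum[y, x, ci] <- sum(arr[y, x, ci, ])
    ref_max[y, x, ci] <- max(arr[y, x, ci, ])
  }
  expect_equal(z_project(arr, "sum")$data, ref_sum)
  expect_equal(z_project(arr, "max")$data, ref_max)
  expect_error(z_project(arr, "median"))
})

test_that("macrophage segmentation recovers the generator's cells", {
  seg <- segment_macrophages(seg_proj)
  expect_equal(max(seg$labels), 12)
  ids <- seg_scene$cells$id[seg_scene$cells$type == "macrophage"]
  ious <- sapply(ids, function(id) {
    tm <- seg_scene$macro_labels == id
    ov <- seg$labels[tm]; ov <- ov[ov > 0]
    if (length(ov) == 0) return(0)
    s <- as.integer(names(which.max(table(ov))))
    sum(seg$labels == s & tm) / sum(seg$labels == s | tm)
  })
  expect_true(all(ious >= 0.8))
})

test_that("degenerate lipofuscin inputs are handled explicitly", {
  p0 <- tiny_projection()
  p0$proj$data[, , 3] <- 0
  empty <- segment_macrophages(p0$proj)
  expect_equal(max(empty$labels), 0)
  p0$proj$data[, , 3] <- 5
  expect_error(segment_macrophages(p0$proj), "lipofuscin")
  # area filter above the largest object empties the mask
  seg <- segment_macrophages(seg_proj, min_area = 1e6)
  expect_equal(max(seg$labels), 0)
})

test_that("adipocyte rims are recovered and yield to macrophage claims", {
  segm <- segment_macrophages(seg_proj)
  sega <- segment_adipocyte_cytoplasm(seg_proj, segm$labels)
  expect_equal(max(sega$labels), 6)
  ids <- seg_scene$cells$id[seg_scene$cells$type == "adipocyte"]
  ious <- sapply(ids, function(id) {
    tm <- seg_scene$adipo_labels == id
    ov <- sega$labels[tm]; ov <- ov[ov > 0]
    if (length(ov) == 0) return(0)
    s <- as.integer(names(which.max(table(ov))))
    sum(sega$labels == s & tm) / sum(sega$labels == s | tm)
  })
  expect_true(all(ious >= 0.7))
  expect_false(any(sega$labels > 0 & segm$labels > 0))

  # pixels claimed by both masks are assigned macrophage-first
  fix <- tiny_projection()
  fake_macro <- matrix(0L, 48, 48)
  fake_macro[fix$rim] <- 1L            # macrophage mask covering the rim
  expect_warning(
    sub <- segment_adipocyte_cytoplasm(fix$proj, fake_macro, threshold = 10),
    "no adipocyte")
  expect_true(all(sub$labels[fix$rim] == 0))
})

test_that("an image without adipocytes gives empty rim labels with a warning", {
  sc0 <- generate_tissue_scene("control", n_adipocytes = 0, n_macrophages = 4,
                               frame = 128, seed = 21)
  st0 <- render_multichannel_stack(sc0, optics_config(frame = 128), seed = 22)
  p0 <- z_project(st0)
  segm <- segment_macrophages(p0)
  expect_warning(sega <- segment_adipocyte_cytoplasm(p0, segm$labels,
                                                     min_area = 200),
                 "no adipocyte")
  expect_equal(max(sega$labels), 0)
})

test_that("CLS detection counts crowns, not scattered singletons", {
  expect_equal(detect_cls(matrix(0L, 10, 10))$n_cls, 0L)
  sc <- generate_tissue_scene("diabetic", n_adipocytes = 8, n_macrophages = 4,
                              n_cls = 3, frame = 512, seed = 23)
  st <- render_multichannel_stack(sc, optics_config(frame = 512), seed = 24)
  p <- z_project(st)
  segm <- segment_macrophages(p)
  cls <- detect_cls(segm$labels)
  expect_equal(cls$n_cls, 3L)
  # scattered singletons beyond linking distance give no CLS
  scat <- generate_tissue_scene("control", n_adipocytes = 4, n_macrophages = 8,
                                frame = 384, seed = 25)
  stc <- render_multichannel_stack(scat, optics_config(frame = 384), seed = 26)
  segc <- segment_macrophages(z_project(stc))
  expect_equal(detect_cls(segc$labels)$n_cls, 0L)
})

test_that("cell records report exact means and one row per label", {
  fix <- tiny_projection()
  macro_lab <- matrix(0L, 48, 48); macro_lab[fix$macro] <- 1L
  adipo_lab <- matrix(0L, 48, 48); adipo_lab[fix$rim] <- 1L
  rec <- extract_cell_records(fix$proj, macro_lab, adipo_lab)
  expect_equal(nrow(rec), 2)
  m <- rec[rec$type == "macrophage", ]
  expect_identical(m$mean_nadh, 60)
  expect_identical(m$mean_lipofuscin, 300)
  expect_equal(m$redox_ratio, 40 / (60 + 40))

  # brute-force per-pixel loop oracle on a noisy image
  noisy <- fix$proj
  set.seed(2); noisy$data <- noisy$data + array(rpois(length(noisy$data), 3),
                                                dim = dim(noisy$data))
  rec2 <- extract_cell_records(noisy, macro_lab, adipo_lab)
  px <- which(macro_lab == 1L)
  expect_equal(rec2$mean_fad[rec2$type == "macrophage"],
               mean(noisy$data[, , 2][px]))
  expect_equal(nrow(extract_cell_records(fix$proj, NULL, NULL)), 0)
})

test_that("redox ratio follows its formula and stays in bounds", {
  expect_identical(redox_ratio(100, 100), 0.5)
  expect_identical(redox_ratio(0, 50), 0)
  expect_equal(redox_ratio(30, 70), 0.3)
  expect_error(redox_ratio(0, 0), "both")
  expect_error(redox_ratio(-1, 5), "non-negative")
  set.seed(3)
  fad <- runif(200, 0, 100); nadh <- runif(200, 0, 100)
  r <- redox_ratio(fad, nadh + 1e-9)
  expect_true(all(r >= 0 & r <= 1))
  # monotone increasing in i_fad at fixed i_nadh
  grid <- redox_ratio(seq(1, 100, by = 1), 40)
  expect_true(all(diff(grid) > 0))
})

test_that("relative lipofuscin intensity is a scale-invariant ratio", {
  rec <- data.frame(mean_lipofuscin = c(50, 100, 25))
  out <- relative_lipofuscin_intensity(rec, 50)
  expect_equal(out$lipofuscin_rel, c(1, 2, 0.5))
  out2 <- relative_lipofuscin_intensity(
    transform(rec, mean_lipofuscin = mean_lipofuscin * 2), 100)
  expect_equal(out2$lipofuscin_rel, out$lipofuscin_rel)
  expect_error(relative_lipofuscin_intensity(rec, 0), "> 0")
})

test_that("field aggregation averages at most ten cells and flags short fields", {
  rec <- data.frame(cell_id = 1:10, type = "adipocyte",
                    redox_ratio = rep(0.4, 10))
  pt <- fov_aggregate(rec)
  expect_equal(pt$redox_ratio, 0.4)
  expect_false(pt$short_count)
  vals <- c(5, 1, 4, 2, 8, 9, 3, 7, 6, 10)
  rec2 <- data.frame(cell_id = 1:12, type = "macrophage",
                     redox_ratio = c(vals, 100, 200))
  pt2 <- fov_aggregate(rec2)
  expect_equal(pt2$redox_ratio, mean(vals))   # only the first 10 cells
  rec3 <- data.frame(cell_id = 1:7, type = "adipocyte", redox_ratio = 1:7)
  pt3 <- fov_aggregate(rec3)
  expect_true(pt3$short_count)
  expect_equal(pt3$n_cells, 7)
  expect_error(fov_aggregate(rec3[0, ]), "no cell records")
})
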