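test_that("tile plans follow the grid formula and cover the padded frame", {
  p9 <- plan_tiles(c(2048, 2048), tile = 1024, stride = 512)
  expect_length(p9$tiles, 9)
  expect_equal(unname(p9$pad), c(0L, 0L, 0L, 0L))

  p1 <- plan_tiles(c(1024, 1024), tile = 1024, stride = 512)
  expect_length(p1$tiles, 1)
  expect_equal(unname(p1$pad), c(0L, 0L, 0L, 0L))

  p <- plan_tiles(c(2000, 2000), tile = 1024, stride = 512)
  expect_length(p$tiles, 9)
  expect_equal(p$padded, c(2048L, 2048L))
  expect_equal(unname(p$pad), c(24L, 24L, 24L, 24L))

  # union-cover by brute-force pixel counting, on a small analogue
  ps <- plan_tiles(c(200, 170), tile = 64, stride = 32)
  cover <- matrix(0L, ps$padded[1], ps$padded[2])
  for (sp in ps$tiles) {
    rr <- sp$row0:(sp$row0 + sp$size - 1L)
    cc <- sp$col0:(sp$col0 + sp$size - 1L)
    cover[rr, cc] <- cover[rr, cc] + 1L
  }
  expect_true(all(cover >= 1L))
  # interior pixels sit in at least 2 tiles when stride < tile
  interior <- cover[65:(ps$padded[1] - 64), 65:(ps$padded[2] - 64)]
  expect_true(all(interior >= 2L))
  expect_error(plan_tiles(c(100, 100), tile = 10, stride = 20), "stride")
})

test_that("tile extraction mirrors boundary pixels symmetrically", {
  one <- fluor_image(matrix(5, 1, 1))
  t1 <- extract_tiles(one, plan_tiles(c(1, 1), tile = 4, stride = 4))
  expect_equal(t1[[1]]$pixels, matrix(5, 4, 4))

  img <- fluor_image(matrix(runif(30 * 30), 30, 30))
  plan <- plan_tiles(c(30, 30), tile = 16, stride = 8)
  expect_equal(unname(plan$pad), c(1L, 1L, 1L, 1L))
  tiles <- extract_tiles(img, plan)
  # first padded row/col equal the mirrored interior (edge repeated)
  expect_equal(tiles[[1]]$pixels[1, 2:16], img$pixels[1, 1:15])
  expect_equal(tiles[[1]]$pixels[2:16, 1], img$pixels[1:15, 1])
  # zero-pad tiles are literal crops
  p0 <- plan_tiles(c(32, 32), tile = 16, stride = 8)
  img0 <- fluor_image(matrix(runif(32 * 32), 32, 32))
  t0 <- extract_tiles(img0, p0)
  expect_equal(t0[[1]]$pixels, img0$pixels[1:16, 1:16])
  expect_equal(t0[[length(t0)]]$pixels, img0$pixels[17:32, 17:32])
})

make_per_tile <- function(shape, tile, stride, put) {
  plan <- plan_tiles(shape, tile = tile, stride = stride)
  lapply(seq_along(plan$tiles), function(i) {
    list(spec = plan$tiles[[i]], instances = put(i, plan$tiles[[i]]))
  })
}

test_that("score threshold is strict: 0.65 dropped, 0.71 kept, 0.70 dropped", {
  shape <- c(64L, 64L)
  pt <- make_per_tile(shape, 64, 64, function(i, sp) {
    list(disc_instance(20, 20, 4, c(64L, 64L), score = 0.65, label_id = 1L),
         disc_instance(40, 40, 4, c(64L, 64L), score = 0.71, label_id = 2L),
         disc_instance(20, 40, 4, c(64L, 64L), score = 0.70, label_id = 3L))
  })
  res <- stitch_and_merge(pt, shape)
  expect_length(res$instances, 1)
  expect_equal(res$instances[[1]]$score, 0.71)
})

test_that("overlap suppression discards strictly above 30% of candidate area", {
  shape <- c(64L, 64L)
  # kept rectangle 10x10 = 100 px; candidates overlap by exactly 30 / 31 px
  kept <- rect_instance(1, 10, 1, 10, shape, score = 0.99, label_id = 1L)
  cand30 <- rect_instance(8, 17, 1, 10, shape, score = 0.9, label_id = 2L)   # 3 rows x 10
  cand31 <- rect_instance(26, 35, 1, 10, shape, score = 0.9, label_id = 3L)
  cand31$idx <- sort(c(rect_instance(28, 37, 1, 10, shape)$idx[1:69],
                       kept$idx[1:31]))
  cand31 <- instance_mask(cand31$idx, score = 0.9, label_id = 3L, shape = shape)
  expect_length(cand31$idx, 100)
  expect_length(intersect(cand31$idx, kept$idx), 31)
  pt <- make_per_tile(shape, 64, 64, function(i, sp) list(kept, cand30, cand31))
  res <- stitch_and_merge(pt, shape)
  expect_length(res$instances, 2)
  scores <- vapply(res$instances, `[[`, numeric(1), "score")
  areas <- vapply(res$instances, function(x) length(x$idx), integer(1))
  # the exactly-30% candidate survives, the 31% one does not
  expect_setequal(areas, c(100L, 100L))
  expect_equal(sort(scores), c(0.9, 0.99))
})

test_that("duplicate detections across overlapping tiles collapse to one instance", {
  shape <- c(96L, 96L)
  plan <- plan_tiles(c(96, 96), tile = 64, stride = 32)
  bead_src <- disc_instance(48, 48, 5, shape, score = 0.95, label_id = 1L)
  per_tile <- lapply(plan$tiles, function(sp) {
    r <- (bead_src$idx - 1L) %% 96L + 1L
    c <- (bead_src$idx - 1L) %/% 96L + 1L
    lr <- r - sp$row0 + 1L; lc <- c - sp$col0 + 1L
    ins <- if (all(lr >= 1 & lr <= 64 & lc >= 1 & lc <= 64))
      list(instance_mask((lc - 1L) * 64L + lr, score = 0.95, label_id = 1L,
                         shape = c(64L, 64L)))
    else list()
    list(spec = sp, instances = ins)
  })
  expect_gt(sum(lengths(lapply(per_tile, `[[`, "instances"))), 1)
  res <- stitch_and_merge(per_tile, shape)
  expect_length(res$instances, 1)
  expect_identical(res$instances[[1]]$idx, bead_src$idx)
})

test_that("disjoint beads split across tiles are each kept once", {
  shape <- c(96L, 96L)
  plan <- plan_tiles(c(96, 96), tile = 64, stride = 32)
  beads <- list(disc_instance(20, 20, 5, shape, score = 0.9, label_id = 1L),
                disc_instance(48, 70, 5, shape, score = 0.9, label_id = 2L),
                disc_instance(80, 40, 5, shape, score = 0.9, label_id = 3L))
  per_tile <- lapply(plan$tiles, function(sp) {
    ins <- list()
    for (b in beads) {
      r <- (b$idx - 1L) %% 96L + 1L; c <- (b$idx - 1L) %/% 96L + 1L
      lr <- r - sp$row0 + 1L; lc <- c - sp$col0 + 1L
      if (all(lr >= 1 & lr <= 64 & lc >= 1 & lc <= 64))
        ins[[length(ins) + 1L]] <- instance_mask((lc - 1L) * 64L + lr,
                                                 score = 0.9,
                                                 label_id = b$label_id,
                                                 shape = c(64L, 64L))
    }
    list(spec = sp, instances = ins)
  })
  res <- stitch_and_merge(per_tile, shape)
  expect_length(res$instances, 3)
  # idempotence: re-stitching the merged result changes nothing
  whole <- plan_tiles(c(96, 96), tile = 96, stride = 96)$tiles[[1]]
  again <- stitch_and_merge(list(list(spec = whole, instances = res$instances)),
                            shape)
  expect_equal(lapply(again$instances, `[[`, "idx"),
               lapply(res$instances, `[[`, "idx"))
})

test_that("a backend emitting wrong-shaped masks violates the contract loudly", {
  img <- fluor_image(matrix(0, 64, 64))
  bad <- function(pixels, spec)
    list(instance_mask(1:4, score = 0.9, label_id = 1L, shape = c(32L, 32L)))
  expect_error(segment_image(img, bad, tile = 64, stride = 64),
               "does not match tile size")
})
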