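test_that("extrusion satisfies the occupied-voxel counting formula", {
  pal <- default_palette()
  # uniform slab
  bp <- load_blueprint(array(255, dim = c(10, 10, 3)))
  g <- blueprint_to_grid(bp, pal, base_layers = 2L, scale = compute_scale(1, 1))
  expect_equal(occupied_voxels(g), 200)

  # single chamber pixel on a 3x3 white field
  img <- array(255, dim = c(3, 3, 3))
  img[2, 2, ] <- c(255, 0, 0)
  g <- blueprint_to_grid(load_blueprint(img), pal, base_layers = 1L,
                         scale = compute_scale(3, 3))
  expect_equal(occupied_voxels(g), 9 * 1 + 2)

  # fixture blueprint against the independent counting oracle
  fx <- generate_blueprint("growth_chip", 150, 100)
  bp <- load_blueprint(fx$image)
  b <- 2L
  g <- blueprint_to_grid(bp, pal, base_layers = b, scale = compute_scale(30, 150))
  rc <- fx$spec$recorded_role_counts
  hb <- pal$entries$height_blocks[match(names(rc), pal$entries$role)]
  expect_equal(occupied_voxels(g),
               150 * 100 * b + sum(hb * unlist(rc)))
  expect_equal(g$voxel_size_mm, 0.2)
})

test_that("columns are contiguous and occupancy matches heights", {
  set.seed(5)
  h <- rand_heights(4, 3, 5)
  g <- grid_from_heights(h)
  occ <- occupancy(g)
  # no floating voxels: occupied above implies occupied below
  for (z in 2:dim(occ)[3])
    expect_true(all(occ[, , z] <= occ[, , z - 1]))
  expect_equal(sum(occ), sum(h))
})

test_that("raising a role height never decreases occupancy", {
  fx <- generate_blueprint("multiwidth_channel", 80, 60)
  bp <- load_blueprint(fx$image)
  base <- default_palette()
  counts <- sapply(1:4, function(k) {
    e <- base$entries
    e$height_blocks[e$role == "chamber"] <- 2L + k
    occupied_voxels(blueprint_to_grid(bp, palette_spec(e),
                                      scale = compute_scale(1, 1)))
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("height budget and capacity limits are enforced", {
  expect_true(grid_capacity_check(1000, 1000, 120))
  expect_false(grid_capacity_check(1, 1, 257))
  expect_true(grid_capacity_check(150, 100, 7))
  expect_false(grid_capacity_check(1001, 10, 10))
  expect_true(grid_capacity_check(1500, 10, 10, k = 2))

  bp <- load_blueprint(array(255, dim = c(2, 2, 3)))
  expect_error(blueprint_to_grid(bp, base_layers = 255L,
                                 scale = compute_scale(1, 1)),
               "height budget")
})

test_that("grid container round-trips bit-exactly and rejects corruption", {
  set.seed(9)
  g <- grid_from_heights(rand_heights(7, 5, 6), voxel_size_mm = 0.35,
                         base_layers = 2L)
  f <- withr::local_tempfile(fileext = ".vxg")
  write_grid(g, f)
  back <- read_grid(f)
  expect_identical(back$heights, g$heights)
  expect_identical(back$voxel_size_mm, g$voxel_size_mm)
  expect_identical(back$base_layers, g$base_layers)
  expect_identical(back$max_height, g$max_height)
  expect_identical(back$nz, g$nz)

  # empty-occupancy grid round-trips too
  g0 <- grid_from_heights(matrix(0L, 3, 4), voxel_size_mm = 1)
  f0 <- withr::local_tempfile(fileext = ".vxg")
  write_grid(g0, f0)
  expect_identical(read_grid(f0)$heights, g0$heights)

  # truncated payload
  raw <- readBin(f, "raw", file.info(f)$size)
  f2 <- withr::local_tempfile(fileext = ".vxg")
  writeBin(raw[1:(length(raw) - 5)], f2)
  expect_error(read_grid(f2), "corrupt")
  # foreign file
  f3 <- withr::local_tempfile(fileext = ".vxg")
  writeBin(charToRaw("not a grid at all"), f3)
  expect_error(read_grid(f3), "not a chipmold grid")
})

test_that("CSV coordinate export lists each occupied voxel once", {
  g <- grid_from_heights(matrix(c(2L, 0L, 1L, 0L), 2, 2))
  f <- withr::local_tempfile(fileext = ".csv")
  grid_coords_csv(g, f)
  df <- utils::read.csv(f)
  expect_equal(nrow(df), 3)
  expect_false(any(duplicated(df)))
  expect_true(all(df$z >= 0))
})
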