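test_that("top-view mask marks exactly the above-base columns", {
  pal <- default_palette()
  # all-white blueprint: nothing rises above the slab
  bp <- load_blueprint(array(255, dim = c(5, 8, 3)))
  g <- blueprint_to_grid(bp, pal, base_layers = 2L, scale = compute_scale(1, 1))
  expect_false(any(topview_mask(g)$mask))

  # single chamber pixel
  img <- array(255, dim = c(4, 4, 3)); img[2, 3, ] <- c(255, 0, 0)
  g1 <- blueprint_to_grid(load_blueprint(img), pal, base_layers = 1L,
                          scale = compute_scale(1, 1))
  expect_equal(sum(topview_mask(g1)$mask), 1)
  expect_true(topview_mask(g1)$mask[2, 3])

  # fixture grid: mask equals the set of non-base blueprint cells
  fx <- generate_blueprint("growth_chip", 100, 80)
  bp <- load_blueprint(fx$image)
  g2 <- blueprint_to_grid(bp, pal, base_layers = 2L, scale = compute_scale(1, 1))
  expect_identical(topview_mask(g2)$mask, bp$roles != "base")
})

test_that("area accuracy follows the symmetric-difference definition", {
  # identity
  m <- mask_spec(matrix(c(TRUE, FALSE), 10, 10))
  r <- area_accuracy(m, m)
  expect_equal(r$area_accuracy, 1)
  expect_equal(r$error_region_px, 0)

  # one mask empty, the other true on exactly a quarter of the cells
  a <- mask_spec(matrix(FALSE, 10, 10))
  bm <- matrix(FALSE, 10, 10); bm[1:5, 1:5] <- TRUE
  r <- area_accuracy(a, mask_spec(bm))
  expect_equal(r$area_accuracy, 0.75)
  expect_equal(r$error_region_px, 25)

  # symmetry and bounds over random masks
  set.seed(8)
  for (k in 1:10) {
    x <- mask_spec(matrix(sample(c(TRUE, FALSE), 64, TRUE), 8, 8))
    y <- mask_spec(matrix(sample(c(TRUE, FALSE), 64, TRUE), 8, 8))
    rxy <- area_accuracy(x, y); ryx <- area_accuracy(y, x)
    expect_equal(rxy$area_accuracy, ryx$area_accuracy)
    expect_gte(rxy$area_accuracy, 0); expect_lte(rxy$area_accuracy, 1)
  }
  expect_error(area_accuracy(m, mask_spec(matrix(TRUE, 3, 3))), "dimensions differ")
})

test_that("flipping additional pixels never increases accuracy", {
  set.seed(4)
  base <- matrix(sample(c(TRUE, FALSE), 400, TRUE), 20, 20)
  ord <- sample(400)
  accs <- sapply(c(0, 5, 20, 80, 200), function(n) {
    b <- base; b[ord[seq_len(n)]] <- !b[ord[seq_len(n)]]
    area_accuracy(mask_spec(base), mask_spec(b))$area_accuracy
  })
  expect_true(all(diff(accs) <= 0))
})

test_that("length error uses the per-axis sqrt relation", {
  r <- overlap_report(2965, 21100, 15.52)
  # (1 - length_error_rate)^2 = area_accuracy by construction
  expect_equal((1 - r$length_error_rate)^2, r$area_accuracy)
  expect_equal(length_error(r, 15.52), r$length_error_mm)
  # endpoints
  expect_equal(length_error(overlap_report(0, 100), 10), 0)
  expect_equal(length_error(overlap_report(100, 100), 10), 10)
  expect_error(length_error(r, -1), "positive")
})

test_that("mesh comparison reduces to mask comparison on grid-born molds", {
  pal <- default_palette()
  sc <- compute_scale(30, 150)
  fx <- generate_blueprint("growth_chip", 150, 100)
  bp_a <- load_blueprint(fx$image)
  g_a <- blueprint_to_grid(bp_a, pal, scale = sc)
  m_a <- grid_to_mesh(g_a)

  # mesh vs itself
  r0 <- compare_meshes(m_a, m_a, sc$mm_per_pixel)
  expect_equal(r0$area_accuracy, 1)

  # perturbed fixture with n flipped flat-role pixels reports error exactly n
  n <- 37
  img_b <- perturb_blueprint(fx$image, n, seed = 12)
  g_b <- blueprint_to_grid(load_blueprint(img_b), pal, scale = sc)
  m_b <- grid_to_mesh(g_b)
  r <- compare_meshes(m_a, m_b, sc$mm_per_pixel)
  expect_equal(r$error_region_px, n)
  # agrees with the direct mask route
  rm <- area_accuracy(topview_mask(g_a), topview_mask(g_b))
  expect_equal(r$area_accuracy, rm$area_accuracy)

  # open meshes are refused
  open_mesh <- mesh_spec(m_a$vertices, m_a$triangles[-1, ])
  expect_error(compare_meshes(open_mesh, m_b, sc$mm_per_pixel), "open mesh")
})

test_that("mesh-vs-shifted-mesh error equals the brute-force mask XOR count", {
  h <- matrix(0L, 12, 12); h[4:8, 3:9] <- 2L; h <- h + 1L  # plateau on a slab
  g1 <- grid_from_heights(h, voxel_size_mm = 0.5, base_layers = 1L)
  hs <- matrix(0L, 12, 12); hs[4:8, 5:11] <- 2L; hs <- hs + 1L  # shift x by 2
  g2 <- grid_from_heights(hs, voxel_size_mm = 0.5, base_layers = 1L)
  r <- compare_meshes(grid_to_mesh(g1), grid_to_mesh(g2), 0.5)
  brute <- sum((h > 1) != (hs > 1))
  expect_equal(r$error_region_px, brute)
})

test_that("overlap reports serialize to JSON with all fields", {
  r <- overlap_report(10, 100, 5)
  f <- withr::local_tempfile(fileext = ".json")
  overlap_json(r, f)
  back <- jsonlite::read_json(f)
  expect_equal(back$error_region_px, 10)
  expect_equal(back$area_accuracy, 0.9)
  expect_equal(back$length_error_mm, r$length_error_mm)
})
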