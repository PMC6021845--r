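test_that("pixel classification picks the nearest palette color within tolerance", {
  pal <- default_palette()
  # exact palette colors map to their own roles at any tolerance
  for (i in seq_len(nrow(pal$entries))) {
    e <- pal$entries[i, ]
    expect_identical(classify_pixel(c(e$r, e$g, e$b), pal), e$role)
    expect_identical(classify_pixel(c(e$r, e$g, e$b), default_palette(tolerance = 0)),
                     e$role)
  }
  # near-red within tolerance
  expect_identical(classify_pixel(c(250, 5, 5), pal), "chamber")
  # mid-gray: brute-force distance to every default color exceeds 32
  cols <- as.matrix(pal$entries[, c("r", "g", "b")])
  dmin <- min(sqrt(rowSums(sweep(cols, 2, c(128, 128, 128))^2)))
  expect_gt(dmin, 32)
  expect_error(classify_pixel(c(128, 128, 128), pal), "tolerance")
  # lenient mode falls back to base with a warning
  lenient <- default_palette(strict = FALSE)
  expect_warning(role <- classify_pixel(c(128, 128, 128), lenient), "base")
  expect_identical(role, "base")
})

test_that("classification is order-stable for non-tied palettes", {
  pal <- default_palette()
  perm <- palette_spec(pal$entries[c(3, 1, 5, 2, 4), ],
                       tolerance = pal$tolerance)
  probe <- rbind(c(250, 5, 5), c(10, 10, 10), c(255, 250, 4), c(2, 3, 250),
                 c(245, 245, 245))
  for (k in seq_len(nrow(probe)))
    expect_identical(classify_pixel(probe[k, ], pal),
                     classify_pixel(probe[k, ], perm))
})

test_that("palette invariants are enforced", {
  e <- default_palette()$entries
  expect_error(palette_spec(e, tolerance = 200), "half the minimum")
  expect_error(palette_spec(e[e$role != "base", ]), "exactly one 'base'")
  e2 <- e; e2$height_blocks[1] <- 1L
  expect_error(palette_spec(e2), "base role must have height_blocks = 0")
  e3 <- e; e3$r[2] <- 255L; e3$g[2] <- 255L; e3$b[2] <- 255L
  expect_error(palette_spec(e3), "pairwise distinct")
})

test_that("palette YAML round-trips", {
  pal <- default_palette(tolerance = 20, strict = FALSE)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_palette(pal, f)
  back <- read_palette(f)
  expect_equal(back$entries$role, pal$entries$role)
  expect_equal(back$entries$height_blocks, pal$entries$height_blocks)
  expect_equal(back$tolerance, 20)
  expect_false(back$strict)
})

test_that("load_blueprint classifies whole images and reports offenders", {
  white <- array(255, dim = c(10, 10, 3))
  bp <- load_blueprint(white)
  expect_equal(unname(role_counts(bp)["base"]), 100L)
  expect_equal(dim(bp$roles), c(10L, 10L))

  # a stray green pixel is named in strict mode
  bad <- white; bad[3, 7, ] <- c(0, 255, 0)
  expect_error(load_blueprint(bad), "row 3, col 7")

  # fixture blueprint reproduces the generator's recorded counts
  fx <- generate_blueprint("growth_chip", 150, 100)
  bp <- load_blueprint(fx$image)
  rc <- role_counts(bp)
  expect_equal(as.list(rc), fx$spec$recorded_role_counts[names(rc)])
  expect_equal(sum(rc), 150L * 100L)
})

test_that("blueprint images survive a PNG round trip", {
  fx <- generate_blueprint("two_liquid_mixer", 80, 60)
  f <- withr::local_tempfile(fileext = ".png")
  write_image(fx$image, f)
  bp <- load_blueprint(f)
  expect_identical(bp$roles, load_blueprint(fx$image)$roles)
})

test_that("resize is nearest-neighbor, aspect-preserving and idempotent", {
  img <- array(0, dim = c(200, 300, 3))
  img[, , 1] <- 255  # all red
  img[1:50, 1:50, ] <- 255  # white corner block
  out <- resize_blueprint(img, 150)
  expect_equal(dim(out)[1:2], c(100L, 150L))
  # nearest-neighbor introduces no new colors
  cols <- unique(matrix(out, ncol = 3))
  expect_true(all(apply(cols, 1, function(cc)
    all(cc == c(255, 0, 0)) || all(cc == c(255, 255, 255)))))
  # already within bound: unchanged
  small <- array(128, dim = c(80, 100, 3))
  expect_identical(resize_blueprint(small, 150), small * 1.0)
  # idempotence at a fixed bound
  expect_identical(resize_blueprint(out, 150), out)
  expect_error(resize_blueprint(img, 0), "max_dim")
})

test_that("any palette-valid image still classifies cleanly after resizing", {
  for (design in c("growth_chip", "three_liquid_mixer")) {
    fx <- generate_blueprint(design, 150, 100)
    shrunk <- resize_blueprint(fx$image, 60)
    bp <- load_blueprint(shrunk)  # strict mode: would error on any new color
    expect_equal(bp$n_unmatched, 0L)
    expect_equal(dim(bp$roles), c(40L, 60L))
  }
})

test_that("scale arithmetic multiplies exactly and round-trips", {
  sc <- compute_scale(30, 150)
  expect_identical(sc$mm_per_pixel, 0.2)
  expect_identical(feature_size_mm(10, sc), 2)
  expect_identical(feature_size_mm(0, sc), 0)
  expect_identical(compute_scale(1, 1)$mm_per_pixel, 1)
  # randomized direct-multiplication oracle and full-width round trip
  set.seed(11)
  for (k in 1:20) {
    px <- sample(1:2000, 1); mm <- stats::runif(1, 0.5, 500)
    sc <- compute_scale(mm, px)
    n <- sample(0:px, 1)
    expect_equal(feature_size_mm(n, sc), n * mm / px)
    expect_equal(feature_size_mm(px, sc), mm)
  }
  expect_error(compute_scale(-1, 10), "positive")
  expect_error(compute_scale(10, 0), "positive")
  expect_error(feature_size_mm(-1, compute_scale(1, 1)), "non-negative")
})
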