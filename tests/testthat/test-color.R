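hex_to_lch <- function(hex) {
  lab <- farver::decode_colour(hex, to = "lab")
  h <- atan2(lab[, 3], lab[, 2]) * 180 / pi
  cbind(l = lab[, 1], c = sqrt(lab[, 2]^2 + lab[, 3]^2), h = h %% 360)
}

in_box <- function(hex, cons, tol = 1.5) {
  lch <- hex_to_lch(hex)
  hue_ok <- if (cons$hue_max - cons$hue_min >= 360) rep(TRUE, nrow(lch)) else {
    lo <- cons$hue_min %% 360; hi <- cons$hue_max %% 360
    if (lo <= hi) lch[, "h"] >= lo - tol & lch[, "h"] <= hi + tol
    else lch[, "h"] >= lo - tol | lch[, "h"] <= hi + tol
  }
  all(hue_ok) &&
    all(lch[, "l"] >= cons$l_min - tol & lch[, "l"] <= cons$l_max + tol) &&
    all(lch[, "c"] >= cons$chroma_min - tol & lch[, "c"] <= cons$chroma_max + tol)
}

test_that("exactly seven palette families are registered", {
  fam <- palette_families()
  expect_equal(nrow(fam), 7)
  expect_setequal(fam$family,
                  c("default", "light", "red", "yellow", "green", "blue", "purple"))
  expect_error(preset_palette("neon"), "valid families")
})

test_that("every family's colors satisfy its constraint box and are deterministic", {
  for (f in palette_families()$family) {
    cons <- pathcell:::family_constraints(f)
    pal <- preset_palette(f, 8)
    expect_length(pal, 8)
    expect_length(unique(pal), 8)
    expect_true(in_box(pal, cons), label = sprintf("family %s in box", f))
    expect_identical(pal, preset_palette(f, 8))
  }
  # regeneration path (unshipped n) also lands in the box
  expect_true(in_box(preset_palette("green", 13),
                     pathcell:::family_constraints("green")))
})

test_that("generate_palette is seed-deterministic and n=1 returns the box centroid", {
  cons <- pathcell:::family_constraints("blue")
  p1 <- generate_palette(5, cons, seed = 3)
  p2 <- generate_palette(5, cons, seed = 3)
  expect_identical(p1, p2)
  expect_false(identical(p1, generate_palette(5, cons, seed = 4)))

  one <- generate_palette(1, cons, seed = 0)
  expect_length(one, 1)
  expect_true(in_box(one, cons))

  impossible <- list(hue_min = 0, hue_max = 360, chroma_min = 120,
                     chroma_max = 140, l_min = 97, l_max = 99)
  expect_error(generate_palette(3, impossible), "unsatisfiable|empty")
})

test_that("k-means palettes are more separated than random draws from the box", {
  cons <- pathcell:::family_constraints("default")
  pal <- generate_palette(8, cons, seed = 0)
  ours <- palette_min_distance(pal)
  set.seed(1)
  base <- replicate(1000, {
    sam <- pathcell:::sample_gamut(cons, n_samples = 64)
    idx <- sample(length(sam$hex), 8)
    min(dist(sam$lab[idx, ]))
  })
  expect_gte(ours, quantile(base, 0.95))
})

test_that("RGB blending maps zero to black, single max to red, all max to white", {
  expect_equal(blend_rgb(list(c(0, 0, 0)), q_hi = 1), rep("#000000", 3))
  two <- blend_rgb(list(c(0, 1), c(0, 0), c(0, 0)), q_hi = 1)
  expect_equal(two[2], "#FF0000")
  all_max <- blend_rgb(list(c(0, 1), c(0, 1), c(0, 1)), q_hi = 1)
  expect_equal(all_max[2], "#FFFFFF")
  expect_error(blend_rgb(list(1:3, 1:2)), "equal length")
})

corner_hex <- function(corners) farver::encode_colour(unclass(corners) * 255)

test_that("RYB blending reproduces all 8 corners exactly", {
  corners <- ryb_corners()
  coords <- pathcell:::ryb_corner_coords()
  # feed coordinates through with an identity scaling (values already 0/1,
  # augmented with an explicit 0..1 range per channel)
  feats <- lapply(1:3, function(j) c(0, 1, coords[, j]))
  hex <- blend_ryb(feats, corners, q_hi = 1)[-(1:2)]
  expect_equal(hex, unname(corner_hex(corners)))
  # white at the origin
  expect_equal(hex[1], "#FFFFFF")
})

test_that("the RYB cube centre is the per-channel mean of all 8 corners", {
  corners <- ryb_corners()
  feats <- lapply(1:3, function(j) c(0, 1, 0.5))
  hex <- blend_ryb(feats, corners, q_hi = 1)[3]
  expected <- farver::encode_colour(rbind(colMeans(unclass(corners))) * 255)
  expect_equal(hex, unname(expected))
})

test_that("RYB blending is continuous on a dense grid (bounded steps)", {
  corners <- ryb_corners()
  g <- seq(0, 1, length.out = 21)
  grid <- as.matrix(expand.grid(g, g, g))
  rgb <- pathcell:::trilinear_ryb(grid, corners)
  arr <- array(rgb, dim = c(21, 21, 21, 3))
  step <- max(abs(arr[-1, , , ] - arr[-21, , , ]))
  corner_range <- max(unclass(corners)) - min(unclass(corners))
  expect_lte(step, corner_range / 20 + 1e-12)
})

test_that("increasing any RYB coordinate never increases CIELAB lightness", {
  corners <- ryb_corners()
  g <- seq(0, 1, length.out = 11)
  grid <- as.matrix(expand.grid(g, g, g))
  rgb <- pmin(pmax(pathcell:::trilinear_ryb(grid, corners), 0), 1)
  L <- farver::convert_colour(rgb * 255, from = "rgb", to = "lab")[, 1]
  arr <- array(L, dim = c(11, 11, 11))
  for (axis in 1:3) {
    d <- apply(arr, setdiff(1:3, axis), diff)
    expect_lte(max(d), 1e-6)
  }
  # a lightening corner table is rejected at construction
  bad <- list(white = c(1, 1, 1), red = c(0.2, 0, 0), yellow = c(0.9, 0.8, 0.1),
              blue = c(0.1, 0.2, 0.8), orange = c(1, 0.9, 0.8),
              green = c(0.1, 0.4, 0.2), purple = c(0.3, 0.1, 0.4),
              black = c(0, 0, 0))
  expect_error(ryb_corners(bad), "rejected")
  expect_error(ryb_corners(list(white = c(1, 1, 1))), "8 entries")
})

test_that("all blend outputs are valid 8-bit hex colors", {
  set.seed(6)
  feats <- lapply(1:3, function(i) rexp(200))
  expect_true(all(grepl("^#[0-9A-F]{6}$", blend_ryb(feats))))
  expect_true(all(grepl("^#[0-9A-F]{6}$", blend_rgb(feats))))
})

test_that("scale_feature clips at the quantile and min-max scales", {
  expect_equal(scale_feature(rep(3, 5)), rep(0, 5))
  v <- 0:10
  expect_equal(scale_feature(v, q_hi = 1), v / 10)
  with_outlier <- c(seq(0, 10, length.out = 199), 1000)
  s <- scale_feature(with_outlier, q_hi = 0.99)
  expect_equal(s[200], 1)                       # outlier clipped to the top
  expect_true(all(diff(s[1:199]) >= 0))          # order preserved below clip
  expect_error(scale_feature(1:5, q_hi = 0), "q_hi")
  expect_error(scale_feature(1:5, q_hi = 1.2), "q_hi")
})
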