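#' Palette family constraint boxes
#'
#' Seven professional discrete-palette families. `default` and `light` span
#' the whole hue circle; the five specialised families (`red`, `yellow`,
#' `green`, `blue`, `purple`) confine hues to one region. Constraints are
#' expressed in LCh (hue in degrees — ranges may wrap past 360 — chroma, and
#' CIELAB lightness L*).
#'
#' @return A tibble with one row per family: `family`, `hue_min`, `hue_max`,
#'   `chroma_min`, `chroma_max`, `l_min`, `l_max`, `seed`.
#' @export
palette_families <- function() {
  tibble(
    family = c("default", "light", "red", "yellow", "green", "blue", "purple"),
    hue_min = c(0, 0, 345, 40, 95, 200, 270),
    hue_max = c(360, 360, 410, 95, 165, 280, 330),
    chroma_min = c(20, 15, 25, 25, 25, 25, 25),
    chroma_max = c(60, 50, 70, 70, 70, 70, 70),
    l_min = c(35, 65, 35, 55, 35, 35, 35),
    l_max = c(75, 90, 70, 85, 75, 75, 75),
    seed = c(101L, 102L, 103L, 104L, 105L, 106L, 107L)
  )
}

family_constraints <- function(family) {
  fam <- palette_families()
  row <- fam[fam$family == family, ]
  if (nrow(row) != 1L)
    abort(sprintf("unknown palette family '%s'; valid families: %s",
                  family, paste(fam$family, collapse = ", ")))
  as.list(row)
}

# sample the LCh constraint box, keep sRGB-representable points, return both
# hex and Lab coordinates
sample_gamut <- function(constraints, n_samples = 4000L) {
  h <- runif(n_samples, constraints$hue_min, constraints$hue_max) %% 360
  c_ <- runif(n_samples, constraints$chroma_min, constraints$chroma_max)
  l <- runif(n_samples, constraints$l_min, constraints$l_max)
  lab <- cbind(l = l, a = c_ * cospi(h / 180), b = c_ * sinpi(h / 180))
  rgb <- farver::convert_colour(lab, from = "lab", to = "rgb")
  # farver clamps out-of-gamut values; detect them by round-trip error
  back <- farver::convert_colour(rgb, from = "rgb", to = "lab")
  ok <- sqrt(rowSums((lab - back)^2)) < 1
  if (!any(ok)) abort("unsatisfiable palette constraints: empty sRGB gamut sample")
  rgb <- rgb[ok, , drop = FALSE]
  list(lab = lab[ok, , drop = FALSE],
       hex = farver::encode_colour(rgb),
       hue = h[ok])
}

#' Generate a maximally distinct categorical palette
#'
#' Draws a dense seeded sample of the constraint box in CIELAB, runs k-means
#' with `n` centres, and snaps each centre to its nearest in-gamut sample, so
#' every returned color is guaranteed to satisfy the constraints. Output is
#' ordered by hue and fully determined by `seed`.
#'
#' @param n number of colors.
#' @param constraints a row of [palette_families()] as a list, or any list
#'   with `hue_min`, `hue_max`, `chroma_min`, `chroma_max`, `l_min`, `l_max`.
#' @param seed integer seed.
#' @return Character vector of `n` hex colors.
#' @export
generate_palette <- function(n, constraints = family_constraints("default"),
                             seed = 0L) {
  stopifnot_scalar_number(n, "n", lower = 1)
  with_stage_seed(seed, "palette", {
    sam <- sample_gamut(constraints)
    centers <- if (n == 1L) {
      matrix(colMeans(sam$lab), 1L)
    } else {
      if (nrow(sam$lab) <= n) abort("constraint box too small for n colors")
      kmeans(sam$lab, centers = n, nstart = 10L, iter.max = 100L)$centers
    }
    # snap each centre to the nearest in-gamut sample
    idx <- apply(centers, 1L, function(ctr) {
      which.min(colSums((t(sam$lab) - ctr)^2))
    })
    ord <- order(sam$hue[idx], sam$hex[idx])
    unname(sam$hex[idx][ord])
  })
}

palette_cache <- new.env(parent = emptyenv())

#' Preset palettes for the seven families
#'
#' Returns the family's palette for `n` colors, generated once per
#' `(family, n)` with the family's fixed seed and cached, so repeated calls
#' are identical.
#'
#' @param family one of the seven family names (see [palette_families()]).
#' @param n number of colors (default 8).
#' @return Character vector of `n` hex colors.
#' @export
preset_palette <- function(family, n = 8L) {
  constraints <- family_constraints(family)
  key <- sprintf("%s_%d", family, n)
  if (is.null(palette_cache[[key]]))
    palette_cache[[key]] <- generate_palette(n, constraints,
                                             seed = constraints$seed)
  palette_cache[[key]]
}

#' Minimum pairwise CIELAB distance of a palette
#' @param hex character vector of hex colors.
#' @return The smallest pairwise Euclidean distance in Lab space.
#' @export
palette_min_distance <- function(hex) {
  lab <- farver::decode_colour(hex, to = "lab")
  min(dist(lab))
}

# relative luminance of sRGB in [0,1] triplets (linear-light)
srgb_luminance <- function(rgb01) {
  lin <- ifelse(rgb01 <= 0.04045, rgb01 / 12.92, ((rgb01 + 0.055) / 1.055)^2.4)
  if (is.matrix(lin)) as.vector(lin %*% c(0.2126, 0.7152, 0.0722))
  else sum(lin * c(0.2126, 0.7152, 0.0722))
}

#' RYB blending corner table
#'
#' The RYB mixer maps a cell's scaled feature triple (red, yellow, blue
#' coordinates in `[0,1]^3`) to an RGB color by trilinear interpolation over
#' eight corner colors: white at the origin (no signal), the three tuned
#' primaries on the axes, three secondaries, and a near-black corner where
#' all channels saturate. The default primaries are tuned for visualisation —
#' yellow darkened toward gold, blue lightened toward azure — and every cube
#' edge strictly decreases in luminance, so deepening any coordinate never
#' lightens the color (checked on a dense grid at construction; a corner
#' table violating monotone deepening is rejected).
#'
#' @param corners named list of 8 RGB triplets in `[0,1]`: `white`, `red`,
#'   `yellow`, `blue`, `orange`, `green`, `purple`, `black`.
#' @param grid_n grid resolution per axis for the monotonicity check.
#' @return A validated corner table of class `ryb_corners` (8 x 3 matrix).
#' @export
ryb_corners <- function(corners = NULL, grid_n = 9L) {
  default <- list(
    white  = c(1.00, 1.00, 1.00),
    red    = c(0.90, 0.20, 0.22),
    yellow = c(0.93, 0.78, 0.12),
    blue   = c(0.20, 0.45, 0.85),
    orange = c(0.60, 0.30, 0.05),
    green  = c(0.13, 0.45, 0.25),
    purple = c(0.45, 0.20, 0.50),
    black  = c(0.13, 0.11, 0.12)
  )
  corners <- corners %||% default
  need <- c("white", "red", "yellow", "blue", "orange", "green", "purple", "black")
  if (!setequal(names(corners), need) || length(corners) != 8L)
    abort(sprintf("corner table must have exactly these 8 entries: %s",
                  paste(need, collapse = ", ")))
  m <- do.call(rbind, corners[need])
  if (!is.numeric(m) || any(m < 0) || any(m > 1) || ncol(m) != 3L)
    abort("corners must be RGB triplets in [0,1]")
  tab <- structure(m, class = c("ryb_corners", "matrix", "array"))
  check_monotone_deepening(tab, grid_n)
  tab
}

# corner order (white, red, yellow, blue, orange, green, purple, black)
# expressed as RYB cube coordinates
ryb_corner_coords <- function() {
  rbind(white = c(0, 0, 0), red = c(1, 0, 0), yellow = c(0, 1, 0),
        blue = c(0, 0, 1), orange = c(1, 1, 0), green = c(0, 1, 1),
        purple = c(1, 0, 1), black = c(1, 1, 1))
}

trilinear_ryb <- function(coords, corners) {
  cc <- ryb_corner_coords()
  r <- coords[, 1]; y <- coords[, 2]; b <- coords[, 3]
  out <- matrix(0, nrow(coords), 3L)
  for (i in seq_len(8L)) {
    w <- (r * cc[i, 1] + (1 - r) * (1 - cc[i, 1])) *
      (y * cc[i, 2] + (1 - y) * (1 - cc[i, 2])) *
      (b * cc[i, 3] + (1 - b) * (1 - cc[i, 3]))
    out <- out + outer(w, corners[i, ])
  }
  out
}

check_monotone_deepening <- function(corners, grid_n = 9L) {
  g <- seq(0, 1, length.out = grid_n)
  grid <- as.matrix(expand.grid(r = g, y = g, b = g))
  lum <- srgb_luminance(trilinear_ryb(grid, corners))
  arr <- array(lum, dim = c(grid_n, grid_n, grid_n))
  for (axis in 1:3) {
    d <- apply(arr, setdiff(1:3, axis), diff)
    if (any(d > 1e-9))
      abort("corner table rejected: increasing an RYB coordinate increases luminance")
  }
  invisible(TRUE)
}

#' Scale a feature vector to \[0, 1\] for blending
#'
#' Clips at the `q_hi` quantile (taming single-cell outliers), then min-max
#' scales; constant vectors map to all zeros.
#'
#' @param values numeric vector.
#' @param q_hi upper clipping quantile in (0, 1\]; default 0.99.
#' @return Numeric vector in `[0, 1]`.
#' @export
scale_feature <- function(values, q_hi = 0.99) {
  if (!is.numeric(q_hi) || length(q_hi) != 1L || q_hi <= 0 || q_hi > 1)
    abort("`q_hi` must be in (0, 1]")
  if (length(values) < 1L) abort("need at least one value")
  hi <- quantile(values, q_hi, names = FALSE)
  v <- pmin(values, hi)
  rng <- range(v)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  (v - rng[1]) / (rng[2] - rng[1])
}

prepare_channels <- function(features, q_hi) {
  if (is.numeric(features)) features <- list(features)
  if (length(features) < 1L || length(features) > 3L)
    abort("between 1 and 3 feature vectors required")
  n <- unique(lengths(features))
  if (length(n) != 1L) abort("feature vectors must have equal length")
  ch <- matrix(0, n, 3L)
  for (i in seq_along(features)) ch[, i] <- scale_feature(features[[i]], q_hi)
  ch
}

#' Blend features into per-cell colors (RGB system)
#'
#' Scaled features map directly onto the R, G and B channels (missing
#' channels are 0): black means no signal, brighter means more.
#'
#' @param features a numeric vector or list of up to 3 numeric vectors
#'   (equal length).
#' @param q_hi upper clipping quantile passed to [scale_feature()].
#' @return Character vector of hex colors, one per cell.
#' @export
blend_rgb <- function(features, q_hi = 0.99) {
  ch <- prepare_channels(features, q_hi)
  farver::encode_colour(ch * 255)
}

#' Blend features into per-cell colors (RYB system)
#'
#' Scaled features form a red/yellow/blue coordinate in `[0,1]^3`, mapped to
#' RGB by trilinear interpolation over the 8 configured corner colors
#' ([ryb_corners()]): white means no signal, deeper color means more.
#'
#' @inheritParams blend_rgb
#' @param corners a validated [ryb_corners()] table.
#' @return Character vector of hex colors, one per cell.
#' @export
blend_ryb <- function(features, corners = ryb_corners(), q_hi = 0.99) {
  if (!inherits(corners, "ryb_corners")) corners <- ryb_corners(corners)
  ch <- prepare_channels(features, q_hi)
  rgb01 <- trilinear_ryb(ch, corners)
  farver::encode_colour(pmin(pmax(rgb01, 0), 1) * 255)
}
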