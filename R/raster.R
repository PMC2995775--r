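# Pixel-grid rasterization.
#
# Grid convention: 0-based pixel coordinates, x rightward, y downward.
# Pixel (x, y) covers the half-open square [x, x+1) x [y, y+1) and is
# sampled at its centre (x+0.5, y+0.5). Masks are logical matrices indexed
# [y+1, x+1]. A pixel belongs to a shape iff its centre satisfies the
# shape test: even-odd rule for polygons, standard inequalities for
# rectangles (half-open) and ellipses. This makes pixel counts
# deterministic and directly comparable against analytic areas.

#' Reference rasterization resolution
#'
#' Pixel volumes and area fractions are computed on a grid whose longest
#' side is `long_side` pixels (default 512), aspect ratio taken from the
#' document background. Area *fractions*, not absolute counts, drive the
#' volume estimate, so any fixed resolution works; 512 balances
#' rasterization error (below 1% for slice-scale shapes) against speed.
#'
#' @param doc a [cmdx_document()] with a background image
#' @param long_side target length of the longest side in pixels
#' @return integer c(width, height)
#' @export
reference_grid_size <- function(doc, long_side = 512L) {
  img <- background_array(doc$background)
  d <- dim(img)
  h <- d[1]; w <- d[2]
  scale <- long_side / max(w, h)
  c(width = as.integer(round(w * scale)),
    height = as.integer(round(h * scale)))
}

#' Even-odd point-in-polygon test
#'
#' @param px,py numeric vectors of query coordinates
#' @param pts two-column vertex matrix (closed implicitly)
#' @return logical vector
#' @export
point_in_polygon <- function(px, py, pts) {
  n <- nrow(pts)
  inside <- rep(FALSE, length(px))
  if (n < 3) return(inside)
  j <- n
  for (i in seq_len(n)) {
    xi <- pts[i, 1]; yi <- pts[i, 2]
    xj <- pts[j, 1]; yj <- pts[j, 2]
    if (yi != yj) {
      cross <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, cross)
    }
    j <- i
  }
  inside
}

#' Shoelace area of a simple polygon
#' @param pts two-column vertex matrix
#' @return non-negative area in squared coordinate units
#' @export
polygon_area <- function(pts) {
  n <- nrow(pts)
  if (n < 3) return(0)
  x <- pts[, 1]; y <- pts[, 2]
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

empty_mask <- function(width, height) {
  matrix(FALSE, nrow = height, ncol = width)
}

# Rasterize an inside-test over the shape's bounding box only, then place
# into a full-grid mask. `test(px, py)` receives pixel-centre vectors.
rasterize_bbox <- function(test, xlim, ylim, width, height) {
  mask <- empty_mask(width, height)
  x0 <- max(0L, floor(xlim[1]))
  x1 <- min(width - 1L, ceiling(xlim[2]))
  y0 <- max(0L, floor(ylim[1]))
  y1 <- min(height - 1L, ceiling(ylim[2]))
  if (x0 > x1 || y0 > y1) return(mask)
  xs <- x0:x1
  ys <- y0:y1
  px <- rep(xs + 0.5, each = length(ys))
  py <- rep(ys + 0.5, times = length(xs))
  inside <- test(px, py)
  mask[cbind(rep(ys, times = length(xs)) + 1L,
             rep(xs, each = length(ys)) + 1L)] <- inside
  mask
}

#' Rasterize a polygon to a binary mask
#' @param pts two-column vertex matrix
#' @param width,height grid size in pixels
#' @return logical matrix \[height x width\]
#' @export
rasterize_polygon <- function(pts, width, height) {
  if (nrow(pts) < 3) stop("degenerate polygon: fewer than 3 vertices")
  if (polygon_area(pts) <= 0) stop("degenerate polygon: zero area")
  rasterize_bbox(function(px, py) point_in_polygon(px, py, pts),
                 range(pts[, 1]), range(pts[, 2]), width, height)
}

rasterize_rect <- function(rect, width, height) {
  if (rect[["width"]] <= 0 || rect[["height"]] <= 0) {
    stop("degenerate rectangle: non-positive size")
  }
  x0 <- rect[["x"]]; y0 <- rect[["y"]]
  x1 <- x0 + rect[["width"]]; y1 <- y0 + rect[["height"]]
  rasterize_bbox(function(px, py) px >= x0 & px < x1 & py >= y0 & py < y1,
                 c(x0, x1), c(y0, y1), width, height)
}

rasterize_ellipse <- function(rect, width, height) {
  if (rect[["width"]] <= 0 || rect[["height"]] <= 0) {
    stop("degenerate ellipse: non-positive size")
  }
  cx <- rect[["x"]] + rect[["width"]] / 2
  cy <- rect[["y"]] + rect[["height"]] / 2
  rx <- rect[["width"]] / 2
  ry <- rect[["height"]] / 2
  rasterize_bbox(function(px, py)
    ((px - cx) / rx)^2 + ((py - cy) / ry)^2 <= 1,
    c(cx - rx, cx + rx), c(cy - ry, cy + ry), width, height)
}

#' Rasterize a mask surface
#'
#' @param surface a [mask_surface()]
#' @param width,height grid size in pixels
#' @return list with `mask` (logical matrix) and `count` (its pixel
#'   volume, the number of TRUE pixels)
#' @export
rasterize_surface <- function(surface, width, height) {
  mask <- switch(surface$shape,
    polygon = rasterize_polygon(surface$points, width, height),
    rectangle = rasterize_rect(surface$rect, width, height),
    ellipse = rasterize_ellipse(surface$rect, width, height),
    stop("unknown shape '", surface$shape, "'")
  )
  list(mask = mask, count = sum(mask))
}

rasterize_geometry <- function(geom, width, height) {
  switch(geom$type,
    points = rasterize_polygon(geom$value, width, height),
    rect = rasterize_rect(geom$value, width, height),
    position = {
      m <- empty_mask(width, height)
      x <- floor(geom$value[["x"]]); y <- floor(geom$value[["y"]])
      if (x >= 0 && x < width && y >= 0 && y < height) m[y + 1, x + 1] <- TRUE
      m
    },
    stop("cannot rasterize geometry of type '", geom$type, "'")
  )
}

#' Find the topmost mask surface under a point
#'
#' The non-interactive analogue of the input layer: returns the id of the
#' topmost surface (last in document order) whose shape contains the
#' centre of the pixel under `point`, or NA when the point lies outside
#' every surface.
#'
#' @param doc a [cmdx_document()]
#' @param point numeric length-2 (x, y) in grid coordinates
#' @return surface id or NA_character_
#' @export
hit_test <- function(doc, point) {
  px <- floor(point[1]) + 0.5
  py <- floor(point[2]) + 0.5
  for (s in rev(doc$mask)) {
    hit <- switch(s$shape,
      polygon = point_in_polygon(px, py, s$points),
      rectangle = px >= s$rect[["x"]] & px < s$rect[["x"]] + s$rect[["width"]] &
        py >= s$rect[["y"]] & py < s$rect[["y"]] + s$rect[["height"]],
      ellipse = {
        cx <- s$rect[["x"]] + s$rect[["width"]] / 2
        cy <- s$rect[["y"]] + s$rect[["height"]] / 2
        ((px - cx) / (s$rect[["width"]] / 2))^2 +
          ((py - cy) / (s$rect[["height"]] / 2))^2 <= 1
      })
    if (isTRUE(hit)) return(s$id)
  }
  NA_character_
}
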