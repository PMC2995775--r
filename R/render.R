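# Four-layer renderer.
#
# Layers compose background -> mask -> draw. The input layer of the
# interactive editor is realized non-interactively as hit_test(). All
# blending is simple source-over with alpha = channel alpha/255 *
# opacity/255; colours arrive in the A;R;B;G wire order and are converted
# here.

erode4 <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  mask &
    pad[1:h, 2:(w + 1)] & pad[3:(h + 2), 2:(w + 1)] &
    pad[2:(h + 1), 1:w] & pad[2:(h + 1), 3:(w + 2)]
}

mask_outline <- function(mask) mask & !erode4(mask)

blend_mask <- function(canvas, mask, color_arbg, opacity = 255) {
  if (!any(mask)) return(canvas)
  rgba <- arbg_to_rgba(color_arbg)
  a <- rgba[["alpha"]] * opacity / 255
  if (a <= 0) return(canvas)
  idx <- which(mask)
  for (ch in 1:3) {
    plane <- canvas[, , ch]
    plane[idx] <- rgba[[ch]] * a + plane[idx] * (1 - a)
    canvas[, , ch] <- plane
  }
  alpha <- canvas[, , 4]
  alpha[idx] <- a + alpha[idx] * (1 - a)
  canvas[, , 4] <- alpha
  canvas
}

glyph_mask <- function(position, width, height, size = 7L) {
  m <- empty_mask(width, height)
  cx <- as.integer(floor(position[["x"]]))
  cy <- as.integer(floor(position[["y"]]))
  r <- size %/% 2
  for (d in -r:r) {
    for (pt in list(c(cx + d, cy), c(cx, cy + d))) {
      if (pt[1] >= 0 && pt[1] < width && pt[2] >= 0 && pt[2] < height) {
        m[pt[2] + 1, pt[1] + 1] <- TRUE
      }
    }
  }
  m
}

# Binary pixel mask of one map object (no clipping applied).
object_mask <- function(obj, width, height, filled = TRUE) {
  geom <- obj$geometry
  if (is.null(geom)) return(empty_mask(width, height))
  if (geom$type == "position") return(glyph_mask(geom$value, width, height))
  m <- rasterize_geometry(geom, width, height)
  if (!filled) m <- mask_outline(m)
  m
}

#' Render a cMDX document to an RGBA image
#'
#' Deterministic composition of the selected layers at the given grid
#' size: the background image, the mask layer (filled surfaces plus
#' border decorations where `border_paint` is set), and the draw layer
#' (map objects styled per their presentation attributes, clipped to
#' their surface when `set_clip` is set).
#'
#' @param doc a valid [cmdx_document()]
#' @param size integer c(width, height); default the reference grid
#' @param layers subset of c("background", "mask", "draw")
#' @return numeric array \[height x width x 4\], values in 0-1
#' @export
render_document <- function(doc, size = reference_grid_size(doc),
                            layers = c("background", "mask", "draw")) {
  w <- as.integer(size[[1]]); h <- as.integer(size[[2]])
  canvas <- array(1, dim = c(h, w, 4))
  if ("background" %in% layers && !is.null(doc$background)) {
    bg <- background_array(doc$background)
    bg <- resize_nearest(bg, w, h)
    if (length(dim(bg)) == 2) bg <- array(rep(bg, 3), dim = c(dim(bg), 3))
    for (ch in 1:3) canvas[, , ch] <- bg[, , ch]
  }
  surface_masks <- NULL
  get_surface_mask <- function(id) {
    if (is.null(surface_masks)) {
      surface_masks <<- lapply(doc$mask, function(s)
        rasterize_surface(s, w, h)$mask)
      names(surface_masks) <<- vapply(doc$mask, `[[`, character(1), "id")
    }
    surface_masks[[id]]
  }
  if ("mask" %in% layers) {
    for (s in doc$mask) {
      m <- get_surface_mask(s$id)
      if (s$style$is_filled) {
        canvas <- blend_mask(canvas, m, s$style$brush_color,
                             s$style$brush_opacity)
      }
      if (s$border_paint) {
        canvas <- blend_mask(canvas, mask_outline(m), s$border_stroke_color)
      }
    }
  }
  if ("draw" %in% layers) {
    for (o in doc$map_objects) {
      filled <- o$style$is_filled
      m <- object_mask(o, w, h, filled = filled)
      if (o$style$set_clip && !is.na(o$surface_id) &&
          nzchar(o$surface_id) && !is.null(get_surface_mask(o$surface_id))) {
        m <- m & get_surface_mask(o$surface_id)
      }
      if (filled || o$geometry$type == "position") {
        canvas <- blend_mask(canvas, m, o$style$brush_color,
                             o$style$brush_opacity)
      }
      if (!filled && o$geometry$type != "position") {
        canvas <- blend_mask(canvas, m, o$style$stroke_color,
                             o$style$stroke_opacity)
      }
    }
  }
  canvas
}

#' Render a document and write it as PNG
#' @param doc a [cmdx_document()]
#' @param path output file
#' @param ... passed to [render_document()]
#' @return `path`, invisibly
#' @export
render_to_png <- function(doc, path, ...) {
  img <- render_document(doc, ...)
  png::writePNG(img, path)
  invisible(path)
}
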