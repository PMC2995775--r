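# Magic-wand region extraction: 8-connected flood fill with per-channel
# tolerance, hole handling, and boundary tracing back to a map polygon.

# Expand a set of seed pixels to the full 8- or 4-connected component
# within `eligible`. Vectorized frontier dilation: each round grows the
# visited set by all eligible neighbours of the current frontier.
grow_component <- function(eligible, seeds, connectivity = 8) {
  h <- nrow(eligible); w <- ncol(eligible)
  visited <- matrix(FALSE, h, w)
  visited[seeds] <- eligible[seeds]
  frontier <- which(visited)
  offs <- if (connectivity == 8) {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  } else {
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  }
  while (length(frontier)) {
    r <- (frontier - 1L) %% h + 1L
    c_ <- (frontier - 1L) %/% h + 1L
    nxt <- integer(0)
    for (o in offs) {
      nr <- r + o[1]; nc <- c_ + o[2]
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      if (!any(ok)) next
      k <- (nc[ok] - 1L) * h + nr[ok]
      k <- k[eligible[k] & !visited[k]]
      if (length(k)) {
        k <- unique(k)
        visited[k] <- TRUE
        nxt <- c(nxt, k)
      }
    }
    frontier <- nxt
  }
  visited
}

image_channels <- function(image) {
  if (is.matrix(image)) {
    list(image)
  } else {
    d <- dim(image)
    nch <- min(d[3], 3)  # alpha is ignored for colour matching
    lapply(seq_len(nch), function(i) image[, , i])
  }
}

#' Magic-wand flood fill
#'
#' Selects the maximal 8-connected set of pixels whose colour lies within
#' `tolerance` of the seed pixel's colour (Chebyshev distance over the
#' RGB channels, on the 0-255 scale). With `outside_contour_only` the
#' selection keeps only the outside contour of the region: interior holes
#' are filled and the result is simply connected; otherwise holes remain
#' excluded.
#'
#' @param image numeric matrix (single channel) or array
#'   \[height x width x channels\] with values in 0-1
#' @param seed integer c(x, y), 0-based grid coordinates
#' @param tolerance per-channel tolerance, 0-255
#' @param outside_contour_only fill interior holes?
#' @return logical matrix \[height x width\]
#' @export
flood_fill <- function(image, seed, tolerance = 0,
                       outside_contour_only = FALSE) {
  chans <- image_channels(image)
  h <- nrow(chans[[1]]); w <- ncol(chans[[1]])
  x <- as.integer(seed[1]); y <- as.integer(seed[2])
  if (x < 0 || x >= w || y < 0 || y >= h) stop("seed out of bounds")
  eligible <- matrix(TRUE, h, w)
  for (ch in chans) {
    v0 <- ch[y + 1, x + 1]
    eligible <- eligible & (abs(ch - v0) * 255 <= tolerance + 1e-9)
  }
  region <- grow_component(eligible, cbind(y + 1, x + 1), connectivity = 8)
  if (outside_contour_only) region <- fill_holes(region)
  region
}

#' Fill interior holes of a binary mask
#'
#' A hole is any background component not 4-connected to the image
#' border (4-connectivity is the dual of the 8-connected foreground).
#'
#' @param mask logical matrix
#' @return logical matrix with holes set TRUE
#' @export
fill_holes <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- !mask
  border <- rbind(
    cbind(1L, seq_len(w)), cbind(h, seq_len(w)),
    cbind(seq_len(h), 1L), cbind(seq_len(h), w)
  )
  outside <- grow_component(bg, border, connectivity = 4)
  !outside
}

#' Label 8-connected components of a binary mask
#' @param mask logical matrix
#' @return integer matrix, 0 = background, 1..n component labels
#' @export
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  n <- 0L
  todo <- which(mask & lab == 0L)
  while (length(todo)) {
    n <- n + 1L
    k <- todo[1]
    r <- (k - 1L) %% nrow(mask) + 1L
    c_ <- (k - 1L) %/% nrow(mask) + 1L
    comp <- grow_component(mask, cbind(r, c_), connectivity = 8)
    lab[comp] <- n
    todo <- which(mask & lab == 0L)
  }
  lab
}

# Directed boundary cracks of a mask, oriented with the region on the
# right of the direction of travel (y axis points down). Returns a matrix
# of (x0, y0, x1, y1) in corner coordinates.
boundary_cracks <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(FALSE, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  idx <- which(mask, arr.ind = TRUE)
  r <- idx[, 1]; c_ <- idx[, 2]
  x <- c_ - 1L; y <- r - 1L  # 0-based pixel coords
  up    <- !pad[cbind(r,     c_ + 1L)]
  down  <- !pad[cbind(r + 2L, c_ + 1L)]
  left  <- !pad[cbind(r + 1L, c_)]
  right <- !pad[cbind(r + 1L, c_ + 2L)]
  rbind(
    cbind(x[up], y[up], x[up] + 1L, y[up]),               # top, +x
    cbind(x[right] + 1L, y[right], x[right] + 1L, y[right] + 1L),  # right, +y
    cbind(x[down] + 1L, y[down] + 1L, x[down], y[down] + 1L),      # bottom, -x
    cbind(x[left], y[left] + 1L, x[left], y[left])        # left, -y
  )
}

#' Trace the outer boundary of a mask as a closed polygon
#'
#' Converts a magic-wand selection into a map polygon, as the editor does
#' when a selection is accepted. The boundary follows pixel edges, so
#' re-rasterizing the polygon on the same grid reproduces the
#' (hole-filled) mask exactly; interior holes are not represented.
#'
#' @param mask non-empty logical matrix with a single 8-connected
#'   component
#' @return two-column vertex matrix (closed implicitly), collinear
#'   vertices removed
#' @export
trace_region_polygon <- function(mask) {
  if (!any(mask)) stop("mask is empty")
  lab <- label_components(mask)
  ncomp <- max(lab)
  if (ncomp > 1) {
    stop("mask has ", ncomp, " connected components; expected exactly 1")
  }
  filled <- fill_holes(mask)
  cr <- boundary_cracks(filled)
  # chain edges starting from the topmost-leftmost start vertex
  key <- function(x, y) paste(x, y)
  starts <- split(seq_len(nrow(cr)), key(cr[, 1], cr[, 2]))
  used <- rep(FALSE, nrow(cr))
  ord <- order(cr[, 2], cr[, 1])
  first <- ord[1]
  path_x <- cr[first, 1]; path_y <- cr[first, 2]
  cur <- first
  verts <- list(c(cr[first, 1], cr[first, 2]))
  repeat {
    used[cur] <- TRUE
    vx <- cr[cur, 3]; vy <- cr[cur, 4]
    if (vx == path_x && vy == path_y) break
    verts[[length(verts) + 1L]] <- c(vx, vy)
    cand <- starts[[key(vx, vy)]]
    cand <- cand[!used[cand]]
    if (!length(cand)) stop("boundary tracing failed: open contour")
    if (length(cand) > 1) {
      # pinch vertex (diagonal contact): prefer the left turn so the
      # walk wraps around the diagonally-connected pixel
      dx <- vx - cr[cur, 1]; dy <- vy - cr[cur, 2]
      lx <- dy; ly <- -dx
      turn <- (cr[cand, 3] - vx) == lx & (cr[cand, 4] - vy) == ly
      cand <- if (any(turn)) cand[turn][1] else cand[1]
    }
    cur <- cand[1]
  }
  v <- do.call(rbind, verts)
  drop_collinear(v)
}

drop_collinear <- function(v) {
  n <- nrow(v)
  if (n < 3) return(v)
  prev <- rbind(v[n, ], v[-n, ])
  nxt <- rbind(v[-1, ], v[1, ])
  d1 <- v - prev
  d2 <- nxt - v
  keep <- d1[, 1] * d2[, 2] - d1[, 2] * d2[, 1] != 0 |
    (d1[, 1] == 0 & d1[, 2] == 0)
  out <- v[keep, , drop = FALSE]
  colnames(out) <- c("x", "y")
  out
}
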