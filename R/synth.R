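# Synthetic template and specimen cohorts with recorded ground truth.
#
# The default template emulates the standard radical-prostatectomy
# schema: the prostate sectioned into eight slices (two per section
# level from base to apex), each with its slice factor, plus both
# seminal vesicles (factor 0). Each slice carries a dorsal
# peripheral-zone (PZ) sub-polygon. Specimens draw polygonal carcinoma
# foci as star-convex blobs; every generated quantity (focality, focus
# area fraction, slice, PZ membership) is recorded so analysis results
# can be checked against ground truth.

#' Cohort simulation parameters
#'
#' @param n_specimens number of specimens
#' @param seed base RNG seed; specimen i uses seed + i
#' @param multifocal_rate target fraction of specimens with >= 2
#'   spatially distinct foci
#' @param pz_bias probability that a focus is centred in the
#'   peripheral zone
#' @param adjacency_fraction fraction of multifocal specimens drawn as
#'   exactly two foci with overlapping bounding boxes but disjoint
#'   polygons (exercises the rectangularization false-merge: such
#'   specimens read as unifocal under bounding-box clustering)
#' @param foci_lambda Poisson mean of extra foci beyond the second in
#'   multifocal specimens
#' @param focus_frac_shape Beta shape parameters of the per-focus area
#'   fraction of its slice
#' @param focus_frac_range area fraction truncated to this range
#' @param volume_meanlog,volume_sdlog log-normal parameters of the
#'   prostate volume in cm^3 (default median 40 cm^3)
#' @return an object of class `cmdx_params`
#' @export
cohort_params <- function(n_specimens = 50L, seed = 1L,
                          multifocal_rate = 0.525, pz_bias = 0.75,
                          adjacency_fraction = 0.1, foci_lambda = 1.5,
                          focus_frac_shape = c(2, 14),
                          focus_frac_range = c(0.01, 0.2),
                          volume_meanlog = log(40), volume_sdlog = 0.3) {
  stopifnot(n_specimens >= 1,
            multifocal_rate >= 0, multifocal_rate <= 1,
            pz_bias >= 0, pz_bias <= 1,
            adjacency_fraction >= 0, adjacency_fraction <= 1,
            foci_lambda >= 0, all(focus_frac_shape > 0),
            focus_frac_range[1] > 0, focus_frac_range[2] <= 1)
  structure(list(
    n_specimens = as.integer(n_specimens), seed = as.integer(seed),
    multifocal_rate = multifocal_rate, pz_bias = pz_bias,
    adjacency_fraction = adjacency_fraction, foci_lambda = foci_lambda,
    focus_frac_shape = focus_frac_shape,
    focus_frac_range = focus_frac_range,
    volume_meanlog = volume_meanlog, volume_sdlog = volume_sdlog
  ), class = "cmdx_params")
}

# slice layout on a 512 x 512 canvas
SLICE_LAYOUT <- local({
  lev <- c("base", "middle1", "middle2", "apex")
  rows <- data.frame(
    level = rep(lev, each = 2),
    x = rep(c(70, 280), times = 4),
    y = rep(c(90, 192, 294, 396), each = 2),
    width = 150, height = 90,
    factor = rep(c(0.10, 0.15, 0.15, 0.10), each = 2)
  )
  rows$id <- paste0("S", seq_len(nrow(rows)))
  rows
})

# dorsal half of an ellipse as a polygon (the peripheral zone)
pz_polygon <- function(rect) {
  cx <- rect[["x"]] + rect[["width"]] / 2
  cy <- rect[["y"]] + rect[["height"]] / 2
  rx <- rect[["width"]] / 2 * 0.98
  ry <- rect[["height"]] / 2 * 0.98
  theta <- seq(0.12, pi - 0.12, length.out = 17)
  arc <- cbind(cx + rx * cos(theta), cy + ry * sin(theta))
  chord_y <- cy
  pts <- rbind(arc[order(-arc[, 1]), ],
               c(cx - rx * cos(0.12), chord_y),
               c(cx + rx * cos(0.12), chord_y))
  round(pts[nrow(pts):1, , drop = FALSE], 2)
}

default_background <- function(size = 512L) {
  img <- array(1, dim = c(size, size, 3))
  paint <- function(mask, value) {
    idx <- which(mask)
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[idx] <- value[ch]
      img[, , ch] <<- plane
    }
  }
  shapes <- c(
    lapply(seq_len(nrow(SLICE_LAYOUT)), function(i) {
      r <- SLICE_LAYOUT[i, ]
      c(x = r$x, y = r$y, width = r$width, height = r$height)
    }),
    list(c(x = 150, y = 20, width = 70, height = 45),
         c(x = 292, y = 20, width = 70, height = 45))
  )
  for (rect in shapes) {
    m <- rasterize_ellipse(rect, size, size)
    paint(m, c(0.93, 0.93, 0.95))
    paint(mask_outline(m), c(0.35, 0.35, 0.4))
  }
  img
}

default_tools <- function() {
  list(
    draw_tool("HGPIN", "High grade Prostatic Intraepithelial Neoplasia",
              "High grade Prostatic Intraepithelial Neoplasia",
              image_filename = "hgpin.png", type = "ImageWithoutSizing",
              style = presentation_style(
                brush_color = c(200, 0, 200, 0), set_clip = FALSE)),
    draw_tool("PCa", "Adenocarcinoma", "Adenocarcinoma of the prostate",
              type = "Polygon",
              style = presentation_style(
                brush_color = c(180, 255, 0, 0), brush_opacity = 200)),
    draw_tool("PCa-Wand", "Adenocarcinoma", "Adenocarcinoma of the prostate",
              type = "FloodFill",
              style = presentation_style(
                brush_color = c(180, 255, 0, 0), brush_opacity = 200)),
    draw_tool("CapInv", "Capsular invasion", "Capsular invasion",
              type = "Clip", type_of_clip = "Polygon",
              style = presentation_style(
                is_filled = FALSE, stroke_color = c(255, 0, 255, 0),
                stroke_width = 2)),
    draw_tool("ECE", "Extracapsular extension", "Extracapsular extension",
              type = "Clip", type_of_clip = "Polygon",
              style = presentation_style(
                is_filled = FALSE, stroke_color = c(255, 128, 255, 0),
                stroke_width = 2)),
    draw_tool("R1", "positive surgical margin", "Positive surgical margin",
              image_filename = "margin.png", type = "ImageWithoutSizing",
              style = presentation_style(
                brush_color = c(255, 0, 0, 0), set_clip = FALSE))
  )
}

#' Build the default prostate schema template
#'
#' Eight elliptical slice surfaces (two per section level, base to
#' apex) whose slice factors sum to 1, two seminal-vesicle surfaces
#' (factor 0), a dorsal PZ polygon per slice, the standard drawing-tool
#' palette and a programmatically drawn schematic background.
#'
#' @param size canvas size in pixels (square)
#' @return a valid [cmdx_document()] with an empty map
#' @export
make_default_template <- function(size = 512L) {
  surfaces <- lapply(seq_len(nrow(SLICE_LAYOUT)), function(i) {
    r <- SLICE_LAYOUT[i, ]
    rect <- c(x = r$x, y = r$y, width = r$width, height = r$height)
    mask_surface(
      id = r$id, name = paste("Slice", i), shape = "ellipse",
      rect = rect, percentage = r$factor,
      border_rect = rect,
      level = r$level,
      zone_labels = list(PZ = pz_polygon(rect)),
      style = presentation_style(is_filled = FALSE, set_clip = TRUE)
    )
  })
  vesicles <- list(
    mask_surface(id = "V1", name = "Seminal vesicle left",
                 shape = "ellipse",
                 rect = c(x = 150, y = 20, width = 70, height = 45),
                 percentage = 0, level = "vesicle",
                 style = presentation_style(is_filled = FALSE)),
    mask_surface(id = "V2", name = "Seminal vesicle right",
                 shape = "ellipse",
                 rect = c(x = 292, y = 20, width = 70, height = 45),
                 percentage = 0, level = "vesicle",
                 style = presentation_style(is_filled = FALSE))
  )
  cmdx_document(
    mask = c(surfaces, vesicles),
    tools = default_tools(),
    background = background_from_array(default_background(size)),
    map_objects = list(),
    form = form_record(),
    complete = TRUE
  )
}

# -- focus geometry --------------------------------------------------------

# Star-convex blob: smoothed random radii around a centre. Guaranteed
# simple, so the shoelace area is exact.
star_blob <- function(center, radius, k = 14, wobble = 0.3) {
  theta <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  noise <- stats::runif(k, -wobble, wobble)
  noise <- (noise + c(noise[-1], noise[1]) + c(noise[k], noise[-k])) / 3
  r <- radius * (1 + noise)
  cbind(center[1] + r * cos(theta), center[2] + r * sin(theta))
}

scale_about <- function(center, pts, f) {
  cbind(center[1] + (pts[, 1] - center[1]) * f,
        center[2] + (pts[, 2] - center[2]) * f)
}

# Thin blob elongated along a 45-degree diagonal.
diagonal_blob <- function(center, half_len, half_thick, k = 14) {
  theta <- seq(0, 2 * pi, length.out = k + 1)[-(k + 1)]
  noise <- 1 + stats::runif(k, -0.08, 0.08)
  ex <- half_len * cos(theta) * noise
  ey <- half_thick * sin(theta) * noise
  ang <- pi / 4
  cbind(center[1] + ex * cos(ang) - ey * sin(ang),
        center[2] + ex * sin(ang) + ey * cos(ang))
}

# Largest scale factor keeping center + t * (v - center) inside the
# ellipse shrunk by `margin`.
max_scale_in_ellipse <- function(pts, center, rect, margin = 0.96) {
  cx <- rect[["x"]] + rect[["width"]] / 2
  cy <- rect[["y"]] + rect[["height"]] / 2
  rx <- rect[["width"]] / 2 * margin
  ry <- rect[["height"]] / 2 * margin
  dx <- (center[1] - cx) / rx; dy <- (center[2] - cy) / ry
  vx <- (pts[, 1] - center[1]) / rx; vy <- (pts[, 2] - center[2]) / ry
  # ((dx + t vx)^2 + (dy + t vy)^2) = 1
  a <- vx^2 + vy^2
  b <- 2 * (dx * vx + dy * vy)
  cc <- dx^2 + dy^2 - 1
  disc <- pmax(b^2 - 4 * a * cc, 0)
  t <- (-b + sqrt(disc)) / (2 * a)
  min(t)
}

# Sample a focus centre inside the requested zone, keeping a margin of
# `clearance` pixels from the PZ chord so a focus of that radius stays
# wholly on its side of the zone boundary.
sample_point_in <- function(rect, pz, want_pz, clearance = 0,
                            max_tries = 400) {
  chord_y <- min(pz[, 2])
  for (i in seq_len(max_tries)) {
    p <- c(stats::runif(1, rect[["x"]], rect[["x"]] + rect[["width"]]),
           stats::runif(1, rect[["y"]], rect[["y"]] + rect[["height"]]))
    cx <- rect[["x"]] + rect[["width"]] / 2
    cy <- rect[["y"]] + rect[["height"]] / 2
    inside <- ((p[1] - cx) / (rect[["width"]] / 2 * 0.85))^2 +
      ((p[2] - cy) / (rect[["height"]] / 2 * 0.85))^2 <= 1
    if (!inside) next
    in_pz <- as.logical(point_in_polygon(p[1], p[2], pz))
    if (in_pz != want_pz) next
    ok <- if (want_pz) p[2] - chord_y >= clearance
          else chord_y - p[2] >= clearance
    if (ok) return(p)
    if (i > max_tries / 2) return(p)  # relax clearance rather than fail
  }
  stop("could not place a focus centre (pz constraint infeasible)")
}

slice_rect <- function(surface) surface$rect

# -- specimen simulation ---------------------------------------------------

#' Simulate one specimen document
#'
#' Draws the focality label, focus count, sizes and placements from
#' `params`; multifocal specimens get foci with padded disjoint bounding
#' boxes (>= 5 reference pixels apart) except for the adjacency
#' fraction, which places thin diagonal foci with overlapping bounding
#' boxes but disjoint polygons. Reproducible given `seed`.
#'
#' @param template a template document, e.g. [make_default_template()]
#' @param params a [cohort_params()]
#' @param seed integer RNG seed
#' @return list with `doc` (a valid [cmdx_document()]) and `truth`
#'   (focality label, prostate volume, per-focus slice, area fraction
#'   of its slice, PZ membership, and the specimen's true relative
#'   tumour volume)
#' @export
simulate_specimen <- function(template, params, seed) {
  set.seed(seed)
  slices <- Filter(function(s) !identical(s$level, "vesicle"),
                   template$mask)
  slice_ids <- vapply(slices, `[[`, character(1), "id")
  gs <- reference_grid_size(template)
  slice_area <- vapply(slices, function(s)
    pi * s$rect[["width"]] * s$rect[["height"]] / 4, numeric(1))
  names(slice_area) <- slice_ids

  multifocal <- stats::runif(1) < params$multifocal_rate
  n_foci <- if (multifocal) 2L + stats::rpois(1, params$foci_lambda) else 1L
  adjacent <- multifocal && stats::runif(1) < params$adjacency_fraction

  draw_frac <- function() {
    f <- stats::rbeta(1, params$focus_frac_shape[1],
                      params$focus_frac_shape[2])
    min(max(f, params$focus_frac_range[1]), params$focus_frac_range[2])
  }

  foci <- list()
  truth_rows <- list()
  boxes <- list()
  pad <- 5

  slice_pixels <- vapply(slices, function(s)
    rasterize_surface(s, gs[["width"]], gs[["height"]])$count, numeric(1))
  names(slice_pixels) <- slice_ids

  add_focus <- function(pts, sid, in_pz, rel = "") {
    id <- paste0("F", length(foci) + 1L)
    pts <- round(pts, 2)
    area <- polygon_area(pts)
    spx <- slice_pixels[[sid]]
    g1 <- sample(3:5, 1); g2 <- sample(3:5, 1)
    foci[[length(foci) + 1L]] <<- map_object(
      id = id, tool_name = "PCa", kind = "pca_focus",
      geometry = pts,
      style = presentation_style(brush_color = c(180, 255, 0, 0),
                                 brush_opacity = 200),
      relation = rel,
      befund = befund_record(id = id, show_gleason = TRUE,
                             gleason1 = g1, gleason2 = g2),
      surface_id = sid)
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      focus_id = id, slice_id = sid,
      area_fraction = area / spx, in_pz = in_pz,
      stringsAsFactors = FALSE)
    boxes[[length(boxes) + 1L]] <<- bbox_of(pts)
  }

  place_separated <- function() {
    # the zone assignment and target size are drawn once per focus, so
    # placement retries cannot correlate focus size with zone
    want_pz <- stats::runif(1) < params$pz_bias
    frac <- draw_frac()
    for (try in seq_len(200)) {
      si <- sample(seq_along(slices), 1)
      s <- slices[[si]]
      target_area <- frac * slice_area[[s$id]]
      r_est <- sqrt(target_area / pi) * 1.15
      ctr <- sample_point_in(s$rect, s$zone_labels$PZ, want_pz,
                             clearance = r_est)
      blob <- star_blob(ctr, radius = 10)
      blob <- scale_about(ctr, blob, sqrt(target_area / polygon_area(blob)))
      cap <- max_scale_in_ellipse(blob, ctr, s$rect)
      if (cap < 1) blob <- scale_about(ctr, blob, cap)
      # keep the focus wholly inside (or outside) the PZ band so the
      # realized pixel share reflects the placement bias
      zone_ok <- function(pts) {
        inz <- point_in_polygon(pts[, 1], pts[, 2], s$zone_labels$PZ)
        if (want_pz) all(inz) else !any(inz)
      }
      fits <- cap >= 0.95 && zone_ok(blob)
      if (!fits && try <= 120) next  # prefer a new centre over shrinking
      t <- 1
      while (!fits && t > 0.25) {
        t <- t * 0.8
        cand <- scale_about(ctr, blob, t)
        if (zone_ok(cand)) {
          blob <- cand
          fits <- TRUE
        }
      }
      if (!fits) next
      if (sqrt(polygon_area(blob) / pi) < 3) next
      bb <- bbox_of(blob)
      bb_pad <- bb + c(-pad, pad, -pad, pad)
      clash <- any(vapply(boxes, function(b)
        bboxes_overlap(bb_pad, b), logical(1)))
      if (!clash) {
        return(list(pts = blob, sid = s$id,
                    in_pz = as.logical(point_in_polygon(
                      ctr[1], ctr[2], s$zone_labels$PZ))))
      }
    }
    stop("could not place focus with disjoint padded bounding box ",
         "after 200 tries")
  }

  if (adjacent) {
    # two thin diagonal foci: overlapping axis-aligned bounding boxes,
    # disjoint polygons
    si <- sample(seq_along(slices), 1)
    s <- slices[[si]]
    cx <- s$rect[["x"]] + s$rect[["width"]] / 2
    cy <- s$rect[["y"]] + s$rect[["height"]] / 2
    ry <- s$rect[["height"]] / 2
    want_pz <- stats::runif(1) < params$pz_bias
    base_y <- if (want_pz) cy + 0.45 * ry else cy - 0.55 * ry
    off <- 11
    d1 <- diagonal_blob(c(cx - off, base_y + off / 2), 26, 3.5)
    d2 <- diagonal_blob(c(cx + off, base_y - off / 2), 26, 3.5)
    add_focus(d1, s$id, want_pz)
    add_focus(d2, s$id, want_pz)
  } else {
    for (i in seq_len(n_foci)) {
      p <- place_separated()
      add_focus(p$pts, p$sid, p$in_pz)
    }
  }

  truth_foci <- do.call(rbind, truth_rows)
  vol <- round(stats::rlnorm(1, params$volume_meanlog,
                             params$volume_sdlog), 1)
  factors <- stats::setNames(
    vapply(slices, `[[`, numeric(1), "percentage"), slice_ids)
  true_rel <- sum(truth_foci$area_fraction *
                    factors[truth_foci$slice_id])
  doc <- template
  doc$map_objects <- foci
  b1 <- foci[[1]]$befund
  doc$form <- form_record(
    pT = sample(c("pT2a", "pT2c", "pT3a", "pT3b"), 1,
                prob = c(0.15, 0.45, 0.3, 0.1)),
    pN = "pN0", pM = "pMX",
    datum = "2010-06-15",
    gls1 = b1$gleason1, gls2 = b1$gleason2, gls_total = b1$gleason_score,
    L = "L0", V = "V0", R = sample(c("R0", "R1"), 1, prob = c(.8, .2)),
    lk_b = 0L, lk_g = sample(5:15, 1),
    prostat_volumen = vol,
    patient_fields = list(
      list(name = "PatientName",
           value = paste0("Patient-", seed), sensitive = TRUE),
      list(name = "PatientId",
           value = sprintf("%06d", seed %% 1000000L), sensitive = TRUE)
    )
  )
  truth <- list(
    focality = if (multifocal) "multifocal" else "unifocal",
    adjacent = adjacent,
    prostate_volume = vol,
    relative_volume = true_rel,
    foci = truth_foci
  )
  list(doc = doc, truth = truth)
}

#' Simulate a specimen cohort
#'
#' @param params a [cohort_params()]
#' @param template template document; default [make_default_template()]
#' @param dir optional directory: packages are written as
#'   `<id>.cmdx` plus a `manifest.csv` of ground truth
#' @param passphrase optional; encrypts sensitive fields in written
#'   packages
#' @return list with `docs` (named list of documents), `truth` (list of
#'   per-specimen ground truth) and `manifest` (data frame)
#' @export
simulate_cohort <- function(params, template = make_default_template(),
                            dir = NULL, passphrase = NULL) {
  n <- params$n_specimens
  docs <- vector("list", n)
  truth <- vector("list", n)
  ids <- sprintf("spec%03d", seq_len(n))
  for (i in seq_len(n)) {
    sim <- simulate_specimen(template, params, seed = params$seed + i)
    docs[[i]] <- sim$doc
    truth[[i]] <- sim$truth
  }
  names(docs) <- ids
  names(truth) <- ids
  manifest <- do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(id = ids[i], seed = params$seed + i,
               focality = truth[[i]]$focality,
               adjacent = truth[[i]]$adjacent,
               n_foci = nrow(truth[[i]]$foci),
               prostate_volume_cm3 = truth[[i]]$prostate_volume,
               true_relative_volume = truth[[i]]$relative_volume,
               stringsAsFactors = FALSE)
  }))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_len(n)) {
      write_cmdx(docs[[i]], file.path(dir, paste0(ids[i], ".cmdx")),
                 passphrase = passphrase)
    }
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(docs = docs, truth = truth, manifest = manifest)
}
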