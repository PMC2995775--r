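# Cohort analysis engine: slice-factor-weighted tumour volume,
# multifocality clustering, focality concordance, per-slice incidence,
# peripheral-zone localization, cumulative frequency maps, CSV export.

# Rasterize the template of a document once: slice masks, pixel counts,
# factors, levels and PZ zone masks at the reference resolution. Reused
# across every specimen of a cohort sharing the template.
template_raster <- function(doc, long_side = 512L) {
  gs <- reference_grid_size(doc, long_side)
  w <- gs[["width"]]; h <- gs[["height"]]
  slices <- lapply(doc$mask, function(s) {
    r <- rasterize_surface(s, w, h)
    pz <- NULL
    if (length(s$zone_labels)) {
      pz <- empty_mask(w, h)
      for (z in s$zone_labels) pz <- pz | rasterize_polygon(z, w, h)
      pz <- pz & r$mask
    }
    list(id = s$id, level = s$level, factor = s$percentage,
         vesicle = identical(s$level, "vesicle"),
         mask = r$mask, count = r$count, pz = pz)
  })
  names(slices) <- vapply(doc$mask, `[[`, character(1), "id")
  list(width = w, height = h, slices = slices)
}

pca_foci <- function(doc) {
  Filter(function(o) identical(o$kind, "pca_focus"), doc$map_objects)
}

# Surface a focus belongs to; falls back to a centroid hit test when the
# object does not name one.
focus_surface_id <- function(obj, doc) {
  if (!is.na(obj$surface_id) && nzchar(obj$surface_id)) return(obj$surface_id)
  ctr <- colMeans(obj$geometry$value)
  hit_test(doc, ctr)
}

# Per-slice binary cancer masks (union over foci, clipped to the slice).
# A pixel contains PCa iff it is covered by >= 1 focus; overlapping foci
# are counted once.
cancer_masks <- function(doc, tr) {
  out <- lapply(tr$slices, function(s) NULL)
  for (obj in pca_foci(doc)) {
    sid <- focus_surface_id(obj, doc)
    if (is.na(sid) || is.null(tr$slices[[sid]])) next
    m <- rasterize_polygon(obj$geometry$value, tr$width, tr$height)
    m <- m & tr$slices[[sid]]$mask
    out[[sid]] <- if (is.null(out[[sid]])) m else out[[sid]] | m
  }
  out
}

#' Estimate tumour volume from the drawn map
#'
#' For each prostate slice, the cancer area in pixels (union of the
#' clipped carcinoma foci) is divided by the slice area in pixels and
#' multiplied by the slice factor; the sum of these relative
#' contributions is the relative cancer volume, which multiplied by the
#' prostate volume gives the tumour volume in cubic centimetres.
#' Seminal-vesicle surfaces carry no slice factor and are excluded.
#'
#' @param doc a valid [cmdx_document()]
#' @param long_side reference rasterization resolution
#' @return an object of class `cmdx_volume`: `per_slice` data frame
#'   (slice_id, cancer_pixels, slice_pixels, slice_factor,
#'   relative_contribution), `relative_volume`, and `volume_cm3` (NA when
#'   the form records no prostate volume)
#' @export
estimate_volume <- function(doc, long_side = 512L) {
  tr <- template_raster(doc, long_side)
  estimate_volume_tr(doc, tr)
}

estimate_volume_tr <- function(doc, tr) {
  cm <- cancer_masks(doc, tr)
  keep <- !vapply(tr$slices, `[[`, logical(1), "vesicle")
  rows <- lapply(tr$slices[keep], function(s) {
    cancer <- if (is.null(cm[[s$id]])) 0L else sum(cm[[s$id]])
    data.frame(slice_id = s$id, cancer_pixels = cancer,
               slice_pixels = s$count, slice_factor = s$factor,
               relative_contribution = cancer / s$count * s$factor,
               stringsAsFactors = FALSE)
  })
  per_slice <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  rel <- sum(per_slice$relative_contribution)
  vol <- doc$form$prostat_volumen
  structure(list(
    per_slice = per_slice,
    relative_volume = rel,
    volume_cm3 = if (is.na(vol)) NA_real_ else rel * vol
  ), class = "cmdx_volume")
}

#' @export
print.cmdx_volume <- function(x, ...) {
  cat(sprintf("<cmdx_volume relative %.4f%s>\n", x$relative_volume,
              if (is.na(x$volume_cm3)) ""
              else sprintf(", %.2f cm^3", x$volume_cm3)))
  print(x$per_slice)
  invisible(x)
}

# -- multifocality ---------------------------------------------------------

union_find <- function(n) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  list(
    union = function(i, j) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <<- rj
    },
    roots = function() vapply(seq_len(n), find, integer(1))
  )
}

bbox_of <- function(pts) {
  c(xmin = min(pts[, 1]), xmax = max(pts[, 1]),
    ymin = min(pts[, 2]), ymax = max(pts[, 2]))
}

bboxes_overlap <- function(a, b) {
  a[["xmin"]] <= b[["xmax"]] && b[["xmin"]] <= a[["xmax"]] &&
    a[["ymin"]] <= b[["ymax"]] && b[["ymin"]] <= a[["ymax"]]
}

parse_relation_ids <- function(relation) {
  if (is.na(relation) || !nzchar(relation)) return(character(0))
  trimws(strsplit(relation, "[;,]")[[1]])
}

#' Classify a specimen as unifocal or multifocal
#'
#' Each carcinoma focus is replaced by its axis-aligned bounding
#' rectangle ("bbox" mode, the default) and foci on the same slice whose
#' rectangles intersect are merged; the transitive closure of this
#' overlap relation partitions the foci into clusters. A specimen with
#' two or more clusters is multifocal. Rectangularization enlarges the
#' tumour area, so adjacent but distinct foci can be falsely merged —
#' "polygon" mode instead tests rasterized polygon overlap at the
#' reference resolution for sensitivity analysis of that behaviour.
#' Foci on different slices are linked only when their `relation`
#' attribute names the other focus.
#'
#' @param doc a valid [cmdx_document()]
#' @param mode "bbox" or "polygon"
#' @param long_side reference resolution (polygon mode)
#' @return an object of class `cmdx_focality`: `n_drawn_foci`,
#'   `n_clusters`, `label` ("unifocal"/"multifocal"), `cluster_members`
#'   (list of focus-id vectors)
#' @export
cluster_foci <- function(doc, mode = c("bbox", "polygon"),
                         long_side = 512L) {
  mode <- match.arg(mode)
  foci <- pca_foci(doc)
  n <- length(foci)
  if (n == 0) {
    return(structure(list(n_drawn_foci = 0L, n_clusters = 0L,
                          label = "unifocal",
                          cluster_members = list()),
                     class = "cmdx_focality"))
  }
  ids <- vapply(foci, `[[`, character(1), "id")
  sids <- vapply(foci, function(o) focus_surface_id(o, doc), character(1))
  uf <- union_find(n)
  if (mode == "bbox") {
    boxes <- lapply(foci, function(o) bbox_of(o$geometry$value))
  } else {
    gs <- reference_grid_size(doc, long_side)
    pixsets <- lapply(foci, function(o)
      which(rasterize_polygon(o$geometry$value, gs[["width"]],
                              gs[["height"]])))
  }
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (!identical(sids[i], sids[j])) next
        hit <- if (mode == "bbox") {
          bboxes_overlap(boxes[[i]], boxes[[j]])
        } else {
          length(intersect(pixsets[[i]], pixsets[[j]])) > 0
        }
        if (hit) uf$union(i, j)
      }
    }
  }
  # cross-slice linkage via Relation metadata
  for (i in seq_len(n)) {
    for (rid in parse_relation_ids(foci[[i]]$relation)) {
      j <- match(rid, ids)
      if (!is.na(j)) uf$union(i, j)
    }
  }
  roots <- uf$roots()
  members <- split(ids, roots)
  names(members) <- NULL
  k <- length(members)
  structure(list(
    n_drawn_foci = n, n_clusters = k,
    label = if (k >= 2) "multifocal" else "unifocal",
    cluster_members = members
  ), class = "cmdx_focality")
}

#' @export
print.cmdx_focality <- function(x, ...) {
  cat(sprintf("<cmdx_focality %s: %d foci in %d cluster(s)>\n",
              x$label, x$n_drawn_foci, x$n_clusters))
  invisible(x)
}

#' Concordance between tool and reference focality calls
#'
#' @param pairs data frame with columns `tool` and `reference`, each
#'   "unifocal" or "multifocal" (one row per specimen)
#' @return an object of class `cmdx_concordance`: the 2x2 `counts`
#'   matrix (tool x reference), marginal `totals`, and percentages
#'   `sensitivity_multifocal` (detected multifocal / reference
#'   multifocal), `specificity`, `reference_multifocal_rate`,
#'   `tool_multifocal_rate`
#' @export
focality_concordance <- function(pairs) {
  if (NROW(pairs) == 0) stop("no specimen pairs supplied")
  lv <- c("unifocal", "multifocal")
  tool <- factor(pairs$tool, levels = lv)
  ref <- factor(pairs$reference, levels = lv)
  if (anyNA(tool) || anyNA(ref)) {
    stop("labels must be 'unifocal' or 'multifocal'")
  }
  counts <- table(tool = tool, reference = ref)
  n <- sum(counts)
  structure(list(
    counts = unclass(counts),
    totals = list(tool = rowSums(counts), reference = colSums(counts),
                  n = n),
    sensitivity_multifocal =
      100 * counts["multifocal", "multifocal"] /
      sum(counts[, "multifocal"]),
    specificity =
      100 * counts["unifocal", "unifocal"] / sum(counts[, "unifocal"]),
    reference_multifocal_rate = 100 * sum(counts[, "multifocal"]) / n,
    tool_multifocal_rate = 100 * sum(counts["multifocal", ]) / n
  ), class = "cmdx_concordance")
}

#' @export
print.cmdx_concordance <- function(x, ...) {
  cat("<cmdx_concordance>\n")
  print(x$counts)
  cat(sprintf("  sensitivity (multifocal) : %.1f%%\n",
              x$sensitivity_multifocal))
  cat(sprintf("  specificity              : %.1f%%\n", x$specificity))
  cat(sprintf("  reference multifocal rate: %.1f%%\n",
              x$reference_multifocal_rate))
  cat(sprintf("  tool multifocal rate     : %.1f%%\n",
              x$tool_multifocal_rate))
  invisible(x)
}

# -- cohort-level operations -----------------------------------------------

same_template <- function(a, b, tolerance = 1e-6) {
  sa <- lapply(a$mask, function(s) s[c("id", "shape", "points", "rect")])
  sb <- lapply(b$mask, function(s) s[c("id", "shape", "points", "rect")])
  isTRUE(all.equal(sa, sb, tolerance = tolerance))
}

check_shared_template <- function(docs, ids) {
  if (length(docs) < 2) return(invisible(TRUE))
  for (i in 2:length(docs)) {
    if (!same_template(docs[[1]], docs[[i]])) {
      stop("documents '", ids[1], "' and '", ids[i],
           "' do not share the same template mask")
    }
  }
  invisible(TRUE)
}

doc_ids <- function(docs) {
  nm <- names(docs)
  if (is.null(nm)) nm <- rep("", length(docs))
  ifelse(nzchar(nm), nm, paste0("doc", seq_along(docs)))
}

#' Cumulative focus-frequency map over a cohort
#'
#' Accumulates, per pixel of the shared template grid, the number of
#' carcinoma foci covering that pixel across all documents (each focus
#' clipped to its slice and counted individually). The companion heatmap
#' colour-codes frequency from blue (low) to red (high) over the
#' template background.
#'
#' @param docs list of [cmdx_document()]s sharing one template
#' @param long_side reference resolution
#' @return an object of class `cmdx_cummap`: integer `grid`
#'   \[height x width\], `n_foci`, `n_specimens`, and `heatmap` (RGBA
#'   array)
#' @export
cumulative_map <- function(docs, long_side = 512L) {
  stopifnot(length(docs) >= 1)
  ids <- doc_ids(docs)
  check_shared_template(docs, ids)
  tr <- template_raster(docs[[1]], long_side)
  grid <- matrix(0L, tr$height, tr$width)
  n_foci <- 0L
  for (doc in docs) {
    for (obj in pca_foci(doc)) {
      sid <- focus_surface_id(obj, doc)
      if (is.na(sid) || is.null(tr$slices[[sid]])) next
      m <- rasterize_polygon(obj$geometry$value, tr$width, tr$height)
      m <- m & tr$slices[[sid]]$mask
      grid <- grid + m
      n_foci <- n_foci + 1L
    }
  }
  heat <- heatmap_image(grid, docs[[1]], tr)
  structure(list(grid = grid, n_foci = n_foci,
                 n_specimens = length(docs), heatmap = heat),
            class = "cmdx_cummap")
}

heatmap_image <- function(grid, doc, tr) {
  canvas <- render_document(doc, size = c(tr$width, tr$height),
                            layers = c("background", "mask"))
  mx <- max(grid)
  if (mx == 0) return(canvas)
  ramp <- grDevices::colorRamp(c("blue", "cyan", "yellow", "red"))
  idx <- which(grid > 0)
  cols <- ramp(grid[idx] / mx) / 255
  for (ch in 1:3) {
    plane <- canvas[, , ch]
    plane[idx] <- cols[, ch] * 0.8 + plane[idx] * 0.2
    canvas[, , ch] <- plane
  }
  canvas
}

#' @export
print.cmdx_cummap <- function(x, ...) {
  cat(sprintf("<cmdx_cummap %d foci over %d specimens, max overlap %d>\n",
              x$n_foci, x$n_specimens, max(x$grid)))
  invisible(x)
}

#' Summary statistics over per-level zone percentages
#'
#' @param values numeric vector of per-level percentages
#' @return list with `mean`, `sd` (sample standard deviation) and
#'   `median`
#' @export
zone_percentage_summary <- function(values) {
  list(mean = mean(values), sd = stats::sd(values),
       median = stats::median(values))
}

#' Peripheral-zone localization of carcinoma per section level
#'
#' For each section level (base, middle1, middle2, apex) the percentage
#' of cancer pixels lying inside the template's peripheral-zone (PZ)
#' polygons, pooled over the whole cohort:
#' 100 * (cancer pixels in PZ of that level) / (all cancer pixels in that
#' level). `per_specimen` mode instead averages the per-specimen
#' percentages. Levels with no cancer pixels are excluded from the
#' summary with a warning.
#'
#' @param docs list of [cmdx_document()]s sharing one template with PZ
#'   zones and slice levels
#' @param mode "pooled" (pixel-weighted, default) or "per_specimen"
#' @param long_side reference resolution
#' @return an object of class `cmdx_zones`: `per_level` data frame
#'   (level, pz_percent, cancer_pixels), and `summary` with mean, sd,
#'   median over the per-level percentages
#' @export
zone_localization <- function(docs, mode = c("pooled", "per_specimen"),
                              long_side = 512L) {
  mode <- match.arg(mode)
  ids <- doc_ids(docs)
  check_shared_template(docs, ids)
  tr <- template_raster(docs[[1]], long_side)
  levels_here <- setdiff(unique(vapply(tr$slices, `[[`, character(1),
                                       "level")), c(NA, "vesicle"))
  if (!length(levels_here)) {
    stop("template declares no slice levels; zone localization needs them")
  }
  slice_level <- vapply(tr$slices, `[[`, character(1), "level")
  acc <- matrix(0, nrow = length(levels_here), ncol = 2,
                dimnames = list(levels_here, c("pz", "all")))
  per_spec <- matrix(NA_real_, nrow = length(docs),
                     ncol = length(levels_here),
                     dimnames = list(NULL, levels_here))
  for (d in seq_along(docs)) {
    cm <- cancer_masks(docs[[d]], tr)
    for (lev in levels_here) {
      pz <- 0; all_ <- 0
      for (sid in names(tr$slices)[slice_level == lev & !is.na(slice_level)]) {
        m <- cm[[sid]]
        if (is.null(m)) next
        all_ <- all_ + sum(m)
        if (!is.null(tr$slices[[sid]]$pz)) {
          pz <- pz + sum(m & tr$slices[[sid]]$pz)
        }
      }
      acc[lev, "pz"] <- acc[lev, "pz"] + pz
      acc[lev, "all"] <- acc[lev, "all"] + all_
      if (all_ > 0) per_spec[d, lev] <- 100 * pz / all_
    }
  }
  pct <- if (mode == "pooled") {
    ifelse(acc[, "all"] > 0, 100 * acc[, "pz"] / acc[, "all"], NA_real_)
  } else {
    colMeans(per_spec, na.rm = TRUE)
  }
  per_level <- data.frame(level = levels_here, pz_percent = as.numeric(pct),
                          cancer_pixels = as.numeric(acc[, "all"]),
                          stringsAsFactors = FALSE)
  usable <- !is.na(per_level$pz_percent)
  if (any(!usable)) {
    warning("levels with no cancer pixels excluded from summary: ",
            paste(per_level$level[!usable], collapse = ", "))
  }
  structure(list(
    per_level = per_level,
    mode = mode,
    summary = zone_percentage_summary(per_level$pz_percent[usable])
  ), class = "cmdx_zones")
}

#' @export
print.cmdx_zones <- function(x, ...) {
  cat("<cmdx_zones>\n")
  print(x$per_level)
  cat(sprintf("  mean %.1f%% +/- %.1f, median %.1f%% (%s)\n",
              x$summary$mean, x$summary$sd, x$summary$median, x$mode))
  invisible(x)
}

#' Per-slice incidence of carcinoma across a cohort
#'
#' @param docs list of [cmdx_document()]s sharing one template
#' @param long_side reference resolution
#' @return data frame with `slice_id`, `n_with_cancer`, `fraction`
#'   (specimens with >= 1 cancer pixel in the slice / all specimens)
#' @export
slice_incidence <- function(docs, long_side = 512L) {
  ids <- doc_ids(docs)
  check_shared_template(docs, ids)
  tr <- template_raster(docs[[1]], long_side)
  keep <- names(tr$slices)[!vapply(tr$slices, `[[`, logical(1), "vesicle")]
  hits <- stats::setNames(integer(length(keep)), keep)
  for (doc in docs) {
    cm <- cancer_masks(doc, tr)
    for (sid in keep) {
      if (!is.null(cm[[sid]]) && any(cm[[sid]])) {
        hits[[sid]] <- hits[[sid]] + 1L
      }
    }
  }
  data.frame(slice_id = keep, n_with_cancer = as.integer(hits),
             fraction = as.numeric(hits) / length(docs),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Analyse a cohort of cMDX documents
#'
#' Runs volume estimation, multifocality classification, per-slice
#' incidence, peripheral-zone localization and the cumulative map over a
#' list of documents (or a directory of .cmdx packages) sharing one
#' template.
#'
#' @param docs list of [cmdx_document()]s, or a directory containing
#'   `.cmdx` packages
#' @param mode clustering mode, see [cluster_foci()]
#' @param zone_mode see [zone_localization()]
#' @param long_side reference resolution
#' @param passphrase optional, for encrypted packages
#' @return an object of class `cmdx_cohort`: `rows` (per-specimen data
#'   frame), `slice_incidence`, `zones`, `cumulative`, `n_specimens`,
#'   `n_foci`
#' @export
analyze_cohort <- function(docs, mode = "bbox", zone_mode = "pooled",
                           long_side = 512L, passphrase = NULL) {
  if (is.character(docs) && length(docs) == 1) {
    paths <- list.files(docs, pattern = "\\.cmdx$", full.names = TRUE)
    if (!length(paths)) stop("no .cmdx packages found in ", docs)
    docs <- lapply(paths, read_cmdx, passphrase = passphrase)
    names(docs) <- sub("\\.cmdx$", "", basename(paths))
  }
  ids <- doc_ids(docs)
  check_shared_template(docs, ids)
  tr <- template_raster(docs[[1]], long_side)
  rows <- vector("list", length(docs))
  for (i in seq_along(docs)) {
    doc <- docs[[i]]
    vol <- estimate_volume_tr(doc, tr)
    foc <- cluster_foci(doc, mode = mode, long_side = long_side)
    slice_flags <- as.list(stats::setNames(
      vol$per_slice$cancer_pixels > 0,
      paste0("cancer_in_", vol$per_slice$slice_id)))
    rows[[i]] <- data.frame(
      id = ids[i], n_foci = foc$n_drawn_foci,
      n_clusters = foc$n_clusters, focality = foc$label,
      relative_volume = vol$relative_volume,
      volume_cm3 = vol$volume_cm3,
      slice_flags, stringsAsFactors = FALSE)
  }
  rows <- do.call(rbind, rows)
  structure(list(
    rows = rows,
    slice_incidence = slice_incidence(docs, long_side),
    zones = tryCatch(zone_localization(docs, mode = zone_mode,
                                       long_side = long_side),
                     error = function(e) NULL),
    cumulative = cumulative_map(docs, long_side),
    n_specimens = length(docs),
    n_foci = sum(rows$n_foci)
  ), class = "cmdx_cohort")
}

#' @export
print.cmdx_cohort <- function(x, ...) {
  cat(sprintf("<cmdx_cohort %d specimens, %d foci, %.1f%% multifocal>\n",
              x$n_specimens, x$n_foci,
              100 * mean(x$rows$focality == "multifocal")))
  invisible(x)
}

#' Export cohort analysis results as CSV files
#'
#' Writes `specimens.csv` (one row per specimen: focality, volumes,
#' per-slice cancer flags), `slice_incidence.csv` and, when zone data is
#' present, `zone_summary.csv`. RFC-4180 CSV with a header row, '.'
#' decimal separator, UTF-8.
#'
#' @param result a `cmdx_cohort` from [analyze_cohort()]
#' @param destination directory (created if needed)
#' @return character vector of files written, invisibly
#' @export
export_csv <- function(result, destination) {
  stopifnot(inherits(result, "cmdx_cohort"))
  dir.create(destination, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  f <- file.path(destination, "specimens.csv")
  utils::write.csv(result$rows, f, row.names = FALSE, fileEncoding = "UTF-8")
  written <- c(written, f)
  f <- file.path(destination, "slice_incidence.csv")
  utils::write.csv(result$slice_incidence, f, row.names = FALSE,
                   fileEncoding = "UTF-8")
  written <- c(written, f)
  if (!is.null(result$zones)) {
    z <- result$zones$per_level
    z$summary_mean <- result$zones$summary$mean
    z$summary_sd <- result$zones$summary$sd
    z$summary_median <- result$zones$summary$median
    f <- file.path(destination, "zone_summary.csv")
    utils::write.csv(z, f, row.names = FALSE, fileEncoding = "UTF-8")
    written <- c(written, f)
  }
  invisible(written)
}
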