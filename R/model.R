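# Domain model for cMDX documents.
#
# A cMDX document bundles reusable Template Data (mask surfaces describing
# the sliced prostate schema, drawing tools, a background image) with
# per-patient Patient Data (drawn map objects and a textual form record).
# Constructors here are permissive; validate_document() reports every
# violated constraint without raising.

CMDX_SHAPES <- c("polygon", "rectangle", "ellipse")
CMDX_TOOL_TYPES <- c("Polygon", "FloodFill", "Clip", "ImageWithoutSizing")
CMDX_KINDS <- c("pca_focus", "hgpin", "capsular_invasion",
                "extracapsular_extension", "positive_margin")
CMDX_LEVELS <- c("base", "middle1", "middle2", "apex", "vesicle")

#' Presentation style attributes
#'
#' Styling shared by mask surfaces and drawn map objects: fill and stroke
#' colours (four 0-255 channels in Alpha;Red;Blue;Green order, the cMDX
#' wire order), opacities, stroke geometry. Note the channel order A;R;B;G
#' follows the cMDX attribute format and differs from the conventional
#' A;R;G;B.
#'
#' @param is_filled fill the shape interior?
#' @param set_clip clip the drawn object to its mask surface?
#' @param brush_type "solid" or "hatch"
#' @param brush_color,stroke_color numeric length-4, channels
#'   alpha, red, blue, green in 0-255
#' @param brush_opacity,stroke_opacity 0-255
#' @param stroke_width non-negative line width in pixels
#' @param stroke_dash_style,stroke_start_cap,stroke_end_cap,stroke_line_join,stroke_pen_type,stroke_alignment
#'   presentation enum strings, preserved verbatim
#' @return an object of class `cmdx_style`
#' @export
presentation_style <- function(is_filled = TRUE, set_clip = TRUE,
                               brush_type = "solid",
                               brush_color = c(alpha = 180, red = 255,
                                               blue = 0, green = 0),
                               brush_opacity = 255,
                               stroke_color = c(alpha = 255, red = 0,
                                                blue = 0, green = 0),
                               stroke_opacity = 255,
                               stroke_width = 1,
                               stroke_dash_style = "Solid",
                               stroke_start_cap = "Flat",
                               stroke_end_cap = "Flat",
                               stroke_line_join = "Miter",
                               stroke_pen_type = "SolidColor",
                               stroke_alignment = "Center") {
  nm <- c("alpha", "red", "blue", "green")
  brush_color <- stats::setNames(as.numeric(brush_color), nm)
  stroke_color <- stats::setNames(as.numeric(stroke_color), nm)
  structure(list(
    is_filled = isTRUE(is_filled), set_clip = isTRUE(set_clip),
    brush_type = brush_type, brush_color = brush_color,
    brush_opacity = as.numeric(brush_opacity),
    stroke_color = stroke_color,
    stroke_opacity = as.numeric(stroke_opacity),
    stroke_width = as.numeric(stroke_width),
    stroke_dash_style = stroke_dash_style,
    stroke_start_cap = stroke_start_cap,
    stroke_end_cap = stroke_end_cap,
    stroke_line_join = stroke_line_join,
    stroke_pen_type = stroke_pen_type,
    stroke_alignment = stroke_alignment
  ), class = "cmdx_style")
}

#' Mask surface (drawing surface)
#'
#' One surface of the schematic template: a prostate slice or seminal
#' vesicle, drawn as polygon, rectangle or ellipse. `percentage` is the
#' slice factor: the fraction of whole-prostate volume attributed to this
#' slice, used to weight pixel-count area fractions into a volume estimate.
#' `zone_labels` are named sub-region polygons (e.g. the peripheral zone
#' "PZ") and `level` the section level; both are serialized in an extension
#' namespace so readers unaware of them can ignore them.
#'
#' @param id surface identifier (unique within the mask)
#' @param name display name
#' @param shape "polygon", "rectangle" or "ellipse"
#' @param points two-column vertex matrix (polygon only)
#' @param rect numeric (x, y, width, height) (rectangle/ellipse only)
#' @param percentage slice factor in \[0, 1\]
#' @param pixel_volume pixel count of the surface at the reference
#'   resolution; derived, rewritten on save
#' @param size_of_slice optional real dimensions in mm, length 2
#' @param border_points,border_rect,border_stroke_color,border_paint
#'   border decoration of the surface outline
#' @param style a [presentation_style()]
#' @param zone_labels named list of two-column polygon matrices
#' @param level one of base, middle1, middle2, apex, vesicle, or NA
#' @param extras named character vector of unknown attributes preserved
#'   for forward compatibility
#' @return an object of class `cmdx_surface`
#' @export
mask_surface <- function(id, name = id, shape = c("ellipse", "polygon",
                                                  "rectangle"),
                         points = NULL, rect = NULL,
                         percentage = 0, pixel_volume = NA_integer_,
                         size_of_slice = NULL,
                         border_points = NULL, border_rect = NULL,
                         border_stroke_color = c(alpha = 255, red = 255,
                                                 blue = 0, green = 0),
                         border_paint = TRUE,
                         style = presentation_style(is_filled = FALSE),
                         zone_labels = list(), level = NA_character_,
                         extras = character(0)) {
  shape <- match.arg(shape)
  if (!is.null(points)) points <- as_vertex_matrix(points)
  if (!is.null(rect)) {
    rect <- stats::setNames(as.numeric(rect[1:4]),
                            c("x", "y", "width", "height"))
  }
  zone_labels <- lapply(zone_labels, as_vertex_matrix)
  structure(list(
    id = as.character(id), name = as.character(name), shape = shape,
    points = points, rect = rect,
    percentage = as.numeric(percentage),
    pixel_volume = pixel_volume,
    size_of_slice = size_of_slice,
    border_points = if (!is.null(border_points))
      as_vertex_matrix(border_points) else NULL,
    border_rect = border_rect,
    border_stroke_color = stats::setNames(
      as.numeric(border_stroke_color[1:4]),
      c("alpha", "red", "blue", "green")),
    border_paint = isTRUE(border_paint),
    style = style, zone_labels = zone_labels,
    level = level, extras = extras
  ), class = "cmdx_surface")
}

as_vertex_matrix <- function(p) {
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  dimnames(p) <- list(NULL, c("x", "y"))
  p
}

#' Drawing tool definition
#'
#' One entry of the tool palette: the disease it documents and the style
#' used to draw it. `type` governs how the tool acquires geometry:
#' "Polygon" (freehand boundary), "FloodFill" (magic wand), "Clip"
#' (clipped overlay such as capsular invasion) or "ImageWithoutSizing"
#' (anchored symbol).
#'
#' @param name short disease code (referenced by map objects)
#' @param description free text
#' @param text full disease name
#' @param image_filename symbol image reference (may be "")
#' @param type one of Polygon, FloodFill, Clip, ImageWithoutSizing
#' @param type_of_clip clip geometry for Clip tools
#' @param style a [presentation_style()]
#' @param properties optional named character vector
#' @param extras unknown attributes, preserved
#' @return an object of class `cmdx_tool`
#' @export
draw_tool <- function(name, description = name, text = description,
                      image_filename = "", type = "Polygon",
                      type_of_clip = NULL,
                      style = presentation_style(),
                      properties = character(0),
                      extras = character(0)) {
  structure(list(
    name = as.character(name), description = as.character(description),
    text = as.character(text), image_filename = as.character(image_filename),
    type = as.character(type), type_of_clip = type_of_clip,
    style = style, properties = properties, extras = extras
  ), class = "cmdx_tool")
}

#' Histological findings of one carcinoma focus
#'
#' The Befund record attached to a drawn PCa focus: primary and secondary
#' Gleason patterns (1-5 each), their sum as the Gleason score, textual
#' grading, and optional real dimensions in mm.
#'
#' @param id focus identifier
#' @param show_gleason display the score on the report?
#' @param gleason1,gleason2 primary/secondary pattern, integer 1-5
#' @param gleason_score sum of the two patterns (2-10); defaults to their
#'   sum when both patterns are given
#' @param grading non-numeric grading text
#' @param length,width,slice_thick optional mm
#' @return an object of class `cmdx_befund`
#' @export
befund_record <- function(id = NA_character_, show_gleason = FALSE,
                          gleason1 = NA_integer_, gleason2 = NA_integer_,
                          gleason_score = NA_integer_, grading = "",
                          length = NA_real_, width = NA_real_,
                          slice_thick = NA_real_) {
  g1 <- suppressWarnings(as.integer(gleason1))
  g2 <- suppressWarnings(as.integer(gleason2))
  gs <- suppressWarnings(as.integer(gleason_score))
  if (is.na(gs) && !is.na(g1) && !is.na(g2)) gs <- g1 + g2
  structure(list(
    id = as.character(id), show_gleason = isTRUE(show_gleason),
    gleason1 = g1, gleason2 = g2, gleason_score = gs,
    grading = as.character(grading),
    length = as.numeric(length), width = as.numeric(width),
    slice_thick = as.numeric(slice_thick)
  ), class = "cmdx_befund")
}

is_empty_befund <- function(b) {
  is.na(b$gleason1) && is.na(b$gleason2) && is.na(b$gleason_score) &&
    !b$show_gleason && !nzchar(b$grading)
}

#' Drawn pathology element
#'
#' One object on the map layer: a polygonal PCa focus, an HGPIN or
#' positive-margin symbol, or a capsular invasion / extracapsular
#' extension polyline. `relation` and `relation_slide` are opaque
#' topographical linkage attributes preserved verbatim; when `relation`
#' holds a semicolon-separated list of focus ids, clustering treats the
#' listed foci as parts of the same tumour.
#'
#' @param id object identifier (unique within the map)
#' @param tool_name name of the [draw_tool()] used
#' @param kind one of pca_focus, hgpin, capsular_invasion,
#'   extracapsular_extension, positive_margin
#' @param geometry for foci/invasions a two-column vertex matrix; for
#'   symbols a length-2 anchor position; a length-4 vector is treated as
#'   a rectangle
#' @param style a [presentation_style()]
#' @param relation,relation_slide opaque linkage text
#' @param befund optional [befund_record()] (pca_focus only)
#' @param surface_id id of the mask surface the object belongs to
#' @param extras unknown attributes, preserved
#' @return an object of class `cmdx_mapobject`
#' @export
map_object <- function(id, tool_name, kind = "pca_focus", geometry = NULL,
                       style = presentation_style(),
                       relation = "", relation_slide = "",
                       befund = NULL, surface_id = NA_character_,
                       extras = character(0)) {
  geom <- normalize_geometry(geometry)
  structure(list(
    id = as.character(id), tool_name = as.character(tool_name),
    kind = as.character(kind), geometry = geom, style = style,
    relation = as.character(relation),
    relation_slide = as.character(relation_slide),
    befund = befund, surface_id = as.character(surface_id),
    extras = extras
  ), class = "cmdx_mapobject")
}

normalize_geometry <- function(geometry) {
  if (is.null(geometry)) return(NULL)
  if (is.matrix(geometry)) {
    return(list(type = "points", value = as_vertex_matrix(geometry)))
  }
  if (is.list(geometry) && !is.null(geometry$type)) return(geometry)
  v <- as.numeric(geometry)
  if (length(v) == 2) {
    return(list(type = "position", value = stats::setNames(v, c("x", "y"))))
  }
  if (length(v) == 4) {
    return(list(type = "rect",
                value = stats::setNames(v, c("x", "y", "width", "height"))))
  }
  stop("cannot interpret geometry of length ", length(v))
}

#' Textual form record of the pathology report
#'
#' Clinical and personal fields of the report form: TNM codes, grading,
#' invasion and margin status, lymph node counts, prostate dimensions and
#' volume, plus free patient identity fields. Patient fields flagged
#' sensitive are encrypted on save when a passphrase is supplied.
#'
#' @param pT,pN,pM TNM classification codes
#' @param datum report date (ISO-8601 text)
#' @param kernatypie,diff_muster,klassifizierung_adeno histology text
#' @param gls1,gls2,gls_total,g_grading,helpap grading fields
#' @param L,V,R lymph/venous invasion and resection margin codes
#' @param lk_b,lk_g positive / total extirpated lymph node counts
#' @param prostat_length,prostat_width optional mm
#' @param prostat_volumen prostate volume in cubic centimetres; the fixed
#'   specimen's weight in grams is taken as numerically equivalent
#' @param patient_fields list of entries `list(name=, value=, sensitive=)`;
#'   a read-back encrypted entry carries an `envelope` instead of `value`
#' @param encrypted whether sensitive fields are currently envelopes
#' @param extras unknown attributes, preserved
#' @return an object of class `cmdx_form`
#' @export
form_record <- function(pT = "", pN = "", pM = "", datum = "",
                        kernatypie = "", diff_muster = "",
                        klassifizierung_adeno = "",
                        gls1 = NA_integer_, gls2 = NA_integer_,
                        gls_total = NA_integer_, g_grading = "",
                        helpap = "", L = "", V = "", R = "",
                        lk_b = NA_integer_, lk_g = NA_integer_,
                        prostat_length = NA_real_, prostat_width = NA_real_,
                        prostat_volumen = NA_real_,
                        patient_fields = list(), encrypted = FALSE,
                        extras = character(0)) {
  structure(list(
    pT = pT, pN = pN, pM = pM, datum = datum,
    kernatypie = kernatypie, diff_muster = diff_muster,
    klassifizierung_adeno = klassifizierung_adeno,
    gls1 = suppressWarnings(as.integer(gls1)),
    gls2 = suppressWarnings(as.integer(gls2)),
    gls_total = suppressWarnings(as.integer(gls_total)),
    g_grading = g_grading, helpap = helpap,
    L = L, V = V, R = R,
    lk_b = suppressWarnings(as.integer(lk_b)),
    lk_g = suppressWarnings(as.integer(lk_g)),
    prostat_length = as.numeric(prostat_length),
    prostat_width = as.numeric(prostat_width),
    prostat_volumen = as.numeric(prostat_volumen),
    patient_fields = patient_fields, encrypted = isTRUE(encrypted),
    extras = extras
  ), class = "cmdx_form")
}

#' Assemble a cMDX document
#'
#' @param mask list of [mask_surface()]s (the template schema)
#' @param tools list of [draw_tool()]s
#' @param background list with `bytes` (raw image data), `format`
#'   ("png", "jpeg", "tiff", "bmp") and `filename`; see
#'   [background_from_array()]
#' @param map_objects list of [map_object()]s (the patient drawing)
#' @param form a [form_record()]
#' @param complete whether the template declares its slice factors
#'   complete (their sum is then required to be 1 within 1%)
#' @param extras unknown attributes, preserved
#' @return an object of class `cmdx_document`
#' @export
cmdx_document <- function(mask = list(), tools = list(),
                          background = NULL, map_objects = list(),
                          form = form_record(), complete = TRUE,
                          extras = character(0)) {
  structure(list(
    mask = mask, tools = tools, background = background,
    map_objects = map_objects, form = form,
    complete = isTRUE(complete), extras = extras
  ), class = "cmdx_document")
}

#' Wrap a numeric image array as a document background
#'
#' Encodes the array as PNG bytes so the background round-trips through
#' the package byte-identically.
#'
#' @param img numeric array (height x width x channels, values in 0-1)
#' @param filename name of the image part inside the package
#' @return background list for [cmdx_document()]
#' @export
background_from_array <- function(img, filename = "BGImage.png") {
  list(bytes = png::writePNG(img), format = "png", filename = filename)
}

#' Decode a document background to a numeric array
#' @param background the `background` slot of a [cmdx_document()]
#' @return numeric array, height x width x channels, values in 0-1
#' @export
background_array <- function(background) {
  if (is.null(background)) stop("document has no background image")
  decode_image_bytes(background$bytes, background$format)
}

# -- validation ------------------------------------------------------------

violation <- function(element, rule, message) {
  data.frame(element = element, rule = rule, message = message,
             stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(element = character(0), rule = character(0),
             message = character(0), stringsAsFactors = FALSE)
}

check_arbg <- function(col, what, id) {
  v <- no_violations()
  if (any(is.na(col)) || any(col < 0) || any(col > 255)) {
    v <- rbind(v, violation(id, "channel_range",
                            paste0(what, " channels must lie in [0, 255]")))
  }
  v
}

validate_style <- function(style, id) {
  v <- rbind(
    check_arbg(style$brush_color, "brush colour", id),
    check_arbg(style$stroke_color, "stroke colour", id)
  )
  for (f in c("brush_opacity", "stroke_opacity")) {
    x <- style[[f]]
    if (is.na(x) || x < 0 || x > 255) {
      v <- rbind(v, violation(id, "opacity_range",
                              paste0(f, " must lie in [0, 255]")))
    }
  }
  if (is.na(style$stroke_width) || style$stroke_width < 0) {
    v <- rbind(v, violation(id, "stroke_width_nonnegative",
                            "stroke_width must be >= 0"))
  }
  if (!style$brush_type %in% c("solid", "hatch")) {
    v <- rbind(v, violation(id, "brush_type_enum",
                            "brush_type must be 'solid' or 'hatch'"))
  }
  v
}

validate_surface <- function(s) {
  v <- validate_style(s$style, s$id)
  has_pts <- !is.null(s$points)
  has_rect <- !is.null(s$rect)
  if (has_pts == has_rect) {
    v <- rbind(v, violation(s$id, "geometry_exclusive",
                            "exactly one of points/rect must be populated"))
  }
  if (s$shape == "polygon" && !has_pts) {
    v <- rbind(v, violation(s$id, "shape_geometry_match",
                            "polygon surfaces need points"))
  }
  if (s$shape %in% c("rectangle", "ellipse") && !has_rect) {
    v <- rbind(v, violation(s$id, "shape_geometry_match",
                            paste0(s$shape, " surfaces need rect")))
  }
  if (has_pts && nrow(s$points) < 3) {
    v <- rbind(v, violation(s$id, "polygon_min_vertices",
                            "polygon must have >= 3 vertices"))
  }
  if (has_rect && (s$rect[["width"]] <= 0 || s$rect[["height"]] <= 0)) {
    v <- rbind(v, violation(s$id, "rect_positive",
                            "rect width and height must be > 0"))
  }
  if (is.na(s$percentage) || s$percentage < 0 || s$percentage > 1) {
    v <- rbind(v, violation(s$id, "percentage_range",
                            "slice factor must lie in [0, 1]"))
  }
  if (!is.na(s$pixel_volume) && s$pixel_volume <= 0) {
    v <- rbind(v, violation(s$id, "pixel_volume_positive",
                            "pixel_volume must be > 0"))
  }
  if (!is.na(s$level) && !s$level %in% CMDX_LEVELS) {
    v <- rbind(v, violation(s$id, "level_enum",
                            paste0("unknown level '", s$level, "'")))
  }
  v
}

validate_tool <- function(t) {
  v <- validate_style(t$style, t$name)
  if (!t$type %in% CMDX_TOOL_TYPES) {
    v <- rbind(v, violation(t$name, "tool_type_enum",
                            paste0("unknown tool type '", t$type, "'")))
  }
  if (identical(t$type, "Clip") && is.null(t$type_of_clip)) {
    v <- rbind(v, violation(t$name, "clip_needs_type_of_clip",
                            "Clip tools must declare type_of_clip"))
  }
  v
}

validate_befund <- function(b, id) {
  v <- no_violations()
  for (f in c("gleason1", "gleason2")) {
    g <- b[[f]]
    if (!is.na(g) && (g < 1 || g > 5)) {
      v <- rbind(v, violation(id, "gleason_pattern_range",
                              paste0(f, " must lie in 1-5")))
    }
  }
  if (!is.na(b$gleason_score) &&
      (b$gleason_score < 2 || b$gleason_score > 10)) {
    v <- rbind(v, violation(id, "gleason_score_range",
                            "gleason_score must lie in 2-10"))
  }
  if (!is.na(b$gleason1) && !is.na(b$gleason2) && !is.na(b$gleason_score) &&
      b$gleason_score != b$gleason1 + b$gleason2) {
    v <- rbind(v, violation(id, "gleason_score_sum",
                            "gleason_score must equal gleason1 + gleason2"))
  }
  v
}

validate_mapobject <- function(o, surface_ids, tool_names) {
  v <- validate_style(o$style, o$id)
  if (!o$kind %in% CMDX_KINDS) {
    v <- rbind(v, violation(o$id, "kind_enum",
                            paste0("unknown kind '", o$kind, "'")))
  }
  if (!o$tool_name %in% tool_names) {
    v <- rbind(v, violation(o$id, "tool_resolves",
                            paste0("tool '", o$tool_name, "' not defined")))
  }
  if (!is.na(o$surface_id) && nzchar(o$surface_id) &&
      !o$surface_id %in% surface_ids) {
    v <- rbind(v, violation(o$id, "surface_resolves",
                            paste0("surface '", o$surface_id,
                                   "' not defined")))
  }
  if (identical(o$kind, "pca_focus")) {
    ok <- !is.null(o$geometry) && identical(o$geometry$type, "points") &&
      nrow(o$geometry$value) >= 3
    if (!ok) {
      v <- rbind(v, violation(o$id, "focus_polygon",
                              "pca_focus needs a polygon with >= 3 vertices"))
    }
  } else if (!is.null(o$befund) && !is_empty_befund(o$befund)) {
    v <- rbind(v, violation(o$id, "befund_only_on_focus",
                            "befund is only permitted on pca_focus objects"))
  }
  if (!is.null(o$befund)) v <- rbind(v, validate_befund(o$befund, o$id))
  v
}

validate_form <- function(form) {
  v <- no_violations()
  if (!is.na(form$lk_b) && !is.na(form$lk_g) && form$lk_b > form$lk_g) {
    v <- rbind(v, violation("Formular", "lymph_node_counts",
                            "positive nodes (LK-B) cannot exceed extirpated nodes (LK-G)"))
  }
  if (!is.na(form$prostat_volumen) && form$prostat_volumen <= 0) {
    v <- rbind(v, violation("Formular", "prostate_volume_positive",
                            "Prostatvolumen must be > 0 when present"))
  }
  v
}

#' Validate a cMDX document
#'
#' Checks every structural constraint of the document model: style channel
#' ranges, geometry/shape consistency, Gleason arithmetic, reference
#' resolution of tool and surface ids, lymph node counts, and (when the
#' template declares itself complete) that the prostate-slice factors sum
#' to 1 within 1%. Validation never raises; it reports.
#'
#' @param doc a [cmdx_document()]
#' @return a data frame with columns `element`, `rule`, `message`; zero
#'   rows means the document is valid
#' @export
validate_document <- function(doc) {
  v <- no_violations()
  for (s in doc$mask) v <- rbind(v, validate_surface(s))
  for (t in doc$tools) v <- rbind(v, validate_tool(t))
  surface_ids <- vapply(doc$mask, `[[`, character(1), "id")
  tool_names <- vapply(doc$tools, `[[`, character(1), "name")
  if (anyDuplicated(surface_ids)) {
    v <- rbind(v, violation(surface_ids[duplicated(surface_ids)][1],
                            "surface_id_unique", "duplicate surface id"))
  }
  object_ids <- vapply(doc$map_objects, `[[`, character(1), "id")
  if (anyDuplicated(object_ids)) {
    v <- rbind(v, violation(object_ids[duplicated(object_ids)][1],
                            "object_id_unique", "duplicate map object id"))
  }
  for (o in doc$map_objects) {
    v <- rbind(v, validate_mapobject(o, surface_ids, tool_names))
  }
  v <- rbind(v, validate_form(doc$form))
  if (doc$complete && length(doc$mask)) {
    slice <- !vapply(doc$mask, function(s)
      identical(s$level, "vesicle"), logical(1))
    total <- sum(vapply(doc$mask[slice], `[[`, numeric(1), "percentage"))
    if (total < 0.99 || total > 1.01) {
      v <- rbind(v, violation("Mask", "slice_factor_sum",
                              sprintf("slice factors sum to %.4f, expected 1 within 1%%",
                                      total)))
    }
  }
  v
}

#' Pair each carcinoma focus with its histology record
#'
#' @param doc a valid [cmdx_document()]
#' @return list of `list(object=, befund=)`; foci without a stored Befund
#'   get an empty record (show_gleason FALSE)
#' @export
resolve_focus_records <- function(doc) {
  foci <- Filter(function(o) identical(o$kind, "pca_focus"), doc$map_objects)
  ids <- vapply(foci, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("duplicate focus id '", dup, "' (objects ",
         paste(which(ids == dup), collapse = " and "), ")")
  }
  lapply(foci, function(o) {
    b <- o$befund %||% befund_record(id = o$id)
    list(object = o, befund = b)
  })
}

#' @export
print.cmdx_document <- function(x, ...) {
  nfoci <- sum(vapply(x$map_objects, function(o)
    identical(o$kind, "pca_focus"), logical(1)))
  cat("<cmdx_document>\n")
  cat("  mask surfaces :", length(x$mask), "\n")
  cat("  drawing tools :", length(x$tools), "\n")
  cat("  map objects   :", length(x$map_objects),
      sprintf("(%d PCa foci)", nfoci), "\n")
  cat("  prostate vol. :",
      if (is.na(x$form$prostat_volumen)) "unknown"
      else paste0(x$form$prostat_volumen, " cm^3"), "\n")
  invisible(x)
}

#' @export
print.cmdx_surface <- function(x, ...) {
  cat(sprintf("<cmdx_surface %s '%s' %s, slice factor %.3f>\n",
              x$id, x$name, x$shape, x$percentage))
  invisible(x)
}
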