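# cMDX package reading and writing.
#
# A cMDX package is a zip archive laid out after the Open Packaging
# Conventions: Resource/ holds the Template Data (Mask.xml, Tools.xml and
# the background image), Content/ holds the Patient Data (Map.xml,
# Form.xml), plus [Content_Types].xml. Befund records are serialized as an
# XML fragment inside a CDATA section of their map object. Vertex lists
# serialize as "X1;Y1 X2;Y2 ...", rectangles as "X;Y;Width;Height",
# colours as "A;R;B;G". Unknown attributes are preserved in an extras bag
# and re-emitted on save.

CMDX_NS <- "urn:cmdx:document:1"
CMDX_EXT_NS <- "urn:cmdx:extensions:1"
OPC_CT_NS <- "http://schemas.openxmlformats.org/package/2006/content-types"

STYLE_ATTRS <- c("IsFilled", "SetClip", "BrushType", "BrushOpacity",
                 "BrushColor", "Stroke-Alignment", "StrokeOpacity",
                 "StrokeColor", "StrokeDashstyle", "StrokeStartCap",
                 "StrokeEndCap", "StrokeLineJoin", "StrokePentype",
                 "StrokeWidth")

style_to_attrs <- function(style) {
  c(
    IsFilled = format_bool(style$is_filled),
    SetClip = format_bool(style$set_clip),
    BrushType = if (identical(style$brush_type, "hatch")) "HatchBrush"
                else "SolidBrush",
    BrushOpacity = fmt_num(style$brush_opacity),
    BrushColor = format_arbg(style$brush_color),
    `Stroke-Alignment` = style$stroke_alignment,
    StrokeOpacity = fmt_num(style$stroke_opacity),
    StrokeColor = format_arbg(style$stroke_color),
    StrokeDashstyle = style$stroke_dash_style,
    StrokeStartCap = style$stroke_start_cap,
    StrokeEndCap = style$stroke_end_cap,
    StrokeLineJoin = style$stroke_line_join,
    StrokePentype = style$stroke_pen_type,
    StrokeWidth = fmt_num(style$stroke_width)
  )
}

style_from_attrs <- function(a) {
  get <- function(nm, default) if (nm %in% names(a)) a[[nm]] else default
  presentation_style(
    is_filled = parse_bool(get("IsFilled", "True")),
    set_clip = parse_bool(get("SetClip", "True")),
    brush_type = if (identical(get("BrushType", "SolidBrush"), "HatchBrush"))
      "hatch" else "solid",
    brush_color = parse_arbg(get("BrushColor", "255;0;0;0")),
    brush_opacity = parse_num(get("BrushOpacity", "255")),
    stroke_color = parse_arbg(get("StrokeColor", "255;0;0;0")),
    stroke_opacity = parse_num(get("StrokeOpacity", "255")),
    stroke_width = parse_num(get("StrokeWidth", "1")),
    stroke_dash_style = get("StrokeDashstyle", "Solid"),
    stroke_start_cap = get("StrokeStartCap", "Flat"),
    stroke_end_cap = get("StrokeEndCap", "Flat"),
    stroke_line_join = get("StrokeLineJoin", "Miter"),
    stroke_pen_type = get("StrokePentype", "SolidColor"),
    stroke_alignment = get("Stroke-Alignment", "Center")
  )
}

local_name <- function(nm) sub("^.*:", "", nm)

node_attrs <- function(node) {
  a <- xml2::xml_attrs(node)
  a[!grepl("^xmlns", names(a))]
}

set_attrs <- function(node, attrs) {
  for (nm in names(attrs)) {
    if (!is.na(attrs[[nm]])) xml2::xml_set_attr(node, nm, attrs[[nm]])
  }
  node
}

drop_known <- function(attrs, known) {
  r <- attrs[!local_name(names(attrs)) %in% local_name(known)]
  if (!length(r)) character(0) else r
}

# -- Mask.xml --------------------------------------------------------------

SURFACE_ATTRS <- c("Id", "Name", "Percentage", "PixelVolume", "SizeOfSlice",
                   "Points", "Rectangle", "Border-Points",
                   "Border-Rectangle", "Border-StrokeColor", "BorderPaint",
                   "Level", STYLE_ATTRS)

serialize_mask_part <- function(surfaces, complete = TRUE,
                                image_filename = "BGImage.png",
                                extras = character(0)) {
  root <- xml2::xml_new_root("Mask", xmlns = CMDX_NS,
                             `xmlns:cx` = CMDX_EXT_NS)
  xml2::xml_set_attr(root, "Complete", format_bool(complete))
  xml2::xml_set_attr(root, "ImageFilename", image_filename)
  set_attrs(root, extras)
  for (s in surfaces) {
    tag <- c(polygon = "Polygon", rectangle = "Rectangle",
             ellipse = "Ellipse")[[s$shape]]
    node <- xml2::xml_add_child(root, tag)
    attrs <- c(Id = s$id, Name = s$name,
               Percentage = fmt_num(s$percentage),
               PixelVolume = if (is.na(s$pixel_volume)) NA_character_
                             else fmt_num(s$pixel_volume))
    if (!is.null(s$size_of_slice)) {
      attrs <- c(attrs, SizeOfSlice = paste(fmt_num(s$size_of_slice),
                                            collapse = ";"))
    }
    if (!is.null(s$points)) attrs <- c(attrs, Points = format_points(s$points))
    if (!is.null(s$rect)) attrs <- c(attrs, Rectangle = format_rect(s$rect))
    if (!is.null(s$border_points)) {
      attrs <- c(attrs, `Border-Points` = format_points(s$border_points))
    }
    if (!is.null(s$border_rect)) {
      attrs <- c(attrs, `Border-Rectangle` = format_rect(s$border_rect))
    }
    attrs <- c(attrs,
               `Border-StrokeColor` = format_arbg(s$border_stroke_color),
               BorderPaint = format_bool(s$border_paint),
               style_to_attrs(s$style))
    if (!is.na(s$level)) attrs <- c(attrs, `cx:Level` = s$level)
    set_attrs(node, attrs)
    set_attrs(node, s$extras)
    for (zn in names(s$zone_labels)) {
      z <- xml2::xml_add_child(node, "cx:Zone")
      xml2::xml_set_attr(z, "Name", zn)
      xml2::xml_set_attr(z, "Points", format_points(s$zone_labels[[zn]]))
    }
  }
  as.character(root)
}

#' Parse a Mask.xml part
#' @param xml_text XML text of the part
#' @return list with `surfaces` (list of [mask_surface()]), `complete`,
#'   `image_filename` and `extras`
#' @export
parse_mask_part <- function(xml_text) {
  root <- xml2::read_xml(xml_text)
  ra <- node_attrs(root)
  surfaces <- lapply(xml2::xml_children(root), function(node) {
    tag <- local_name(xml2::xml_name(node))
    if (!tag %in% c("Polygon", "Rectangle", "Ellipse")) return(NULL)
    a <- node_attrs(node)
    lv <- a[local_name(names(a)) == "Level"]
    zones <- list()
    for (child in xml2::xml_children(node)) {
      if (local_name(xml2::xml_name(child)) == "Zone") {
        za <- node_attrs(child)
        zones[[za[["Name"]]]] <- parse_points(za[["Points"]])
      }
    }
    mask_surface(
      id = a[["Id"]],
      name = if ("Name" %in% names(a)) a[["Name"]] else a[["Id"]],
      shape = tolower(tag),
      points = if ("Points" %in% names(a)) parse_points(a[["Points"]]),
      rect = if ("Rectangle" %in% names(a)) parse_rect(a[["Rectangle"]]),
      percentage = if ("Percentage" %in% names(a))
        parse_num(a[["Percentage"]]) else 0,
      pixel_volume = if ("PixelVolume" %in% names(a))
        as.integer(parse_num(a[["PixelVolume"]])) else NA_integer_,
      size_of_slice = if ("SizeOfSlice" %in% names(a))
        parse_num(strsplit(a[["SizeOfSlice"]], ";")[[1]]),
      border_points = if ("Border-Points" %in% names(a))
        parse_points(a[["Border-Points"]]),
      border_rect = if ("Border-Rectangle" %in% names(a))
        parse_rect(a[["Border-Rectangle"]]),
      border_stroke_color = if ("Border-StrokeColor" %in% names(a))
        parse_arbg(a[["Border-StrokeColor"]]) else c(255, 255, 0, 0),
      border_paint = parse_bool(if ("BorderPaint" %in% names(a))
        a[["BorderPaint"]] else "True"),
      style = style_from_attrs(a),
      zone_labels = zones,
      level = if (length(lv)) lv[[1]] else NA_character_,
      extras = drop_known(a, SURFACE_ATTRS)
    )
  })
  list(
    surfaces = Filter(Negate(is.null), surfaces),
    complete = parse_bool(if ("Complete" %in% names(ra)) ra[["Complete"]]
                          else "True"),
    image_filename = if ("ImageFilename" %in% names(ra))
      ra[["ImageFilename"]] else NA_character_,
    extras = drop_known(ra, c("Complete", "ImageFilename"))
  )
}

# -- Tools.xml -------------------------------------------------------------

TOOL_ATTRS <- c("Name", "Description", "Text", "Image-Filename", "Type",
                "TypeOfClip", STYLE_ATTRS)

serialize_tools_part <- function(tools) {
  root <- xml2::xml_new_root("Tools", xmlns = CMDX_NS)
  for (t in tools) {
    node <- xml2::xml_add_child(root, "DrawTool")
    attrs <- c(Name = t$name, Description = t$description, Text = t$text,
               `Image-Filename` = t$image_filename, Type = t$type)
    if (!is.null(t$type_of_clip)) attrs <- c(attrs, TypeOfClip = t$type_of_clip)
    set_attrs(node, c(attrs, style_to_attrs(t$style)))
    set_attrs(node, t$extras)
    if (length(t$properties)) {
      props <- xml2::xml_add_child(node, "Properties")
      for (k in names(t$properties)) {
        p <- xml2::xml_add_child(props, "Property")
        xml2::xml_set_attr(p, "Key", k)
        xml2::xml_set_attr(p, "Value", t$properties[[k]])
      }
    }
  }
  as.character(root)
}

#' Parse a Tools.xml part
#' @param xml_text XML text of the part
#' @return list of [draw_tool()]s
#' @export
parse_tools_part <- function(xml_text) {
  root <- xml2::read_xml(xml_text)
  out <- lapply(xml2::xml_children(root), function(node) {
    if (local_name(xml2::xml_name(node)) != "DrawTool") return(NULL)
    a <- node_attrs(node)
    props <- character(0)
    for (child in xml2::xml_children(node)) {
      if (local_name(xml2::xml_name(child)) == "Properties") {
        for (p in xml2::xml_children(child)) {
          pa <- node_attrs(p)
          props[[pa[["Key"]]]] <- pa[["Value"]]
        }
      }
    }
    draw_tool(
      name = a[["Name"]],
      description = if ("Description" %in% names(a)) a[["Description"]]
                    else a[["Name"]],
      text = if ("Text" %in% names(a)) a[["Text"]] else "",
      image_filename = if ("Image-Filename" %in% names(a))
        a[["Image-Filename"]] else "",
      type = a[["Type"]],
      type_of_clip = if ("TypeOfClip" %in% names(a)) a[["TypeOfClip"]],
      style = style_from_attrs(a),
      properties = props,
      extras = drop_known(a, TOOL_ATTRS)
    )
  })
  Filter(Negate(is.null), out)
}

# -- Map.xml ---------------------------------------------------------------

MAPOBJ_ATTRS <- c("Id", "ToolName", "Kind", "SurfaceId", "Relation",
                  "RelationSlide", "Points", "Rectangle", "Position",
                  STYLE_ATTRS)

serialize_befund <- function(b) {
  node <- xml2::xml_new_root("Befund")
  attrs <- c(
    ID = b$id,
    ShowGleason = format_bool(b$show_gleason),
    Gleason1 = if (is.na(b$gleason1)) NA_character_ else fmt_num(b$gleason1),
    Gleason2 = if (is.na(b$gleason2)) NA_character_ else fmt_num(b$gleason2),
    GleasonScore = if (is.na(b$gleason_score)) NA_character_
                   else fmt_num(b$gleason_score),
    Grading = if (nzchar(b$grading)) b$grading else NA_character_,
    Length = if (is.na(b$length)) NA_character_ else fmt_num(b$length),
    Width = if (is.na(b$width)) NA_character_ else fmt_num(b$width),
    SliceThick = if (is.na(b$slice_thick)) NA_character_
                 else fmt_num(b$slice_thick)
  )
  set_attrs(node, attrs)
  # single-element fragment without XML declaration
  sub("^<\\?xml[^>]*\\?>\\s*", "", as.character(node))
}

parse_befund_fragment <- function(txt, object_id) {
  txt <- trimws(txt)
  if (!nzchar(txt)) return(NULL)
  node <- tryCatch(xml2::read_xml(txt), error = function(e) NULL)
  if (is.null(node) || local_name(xml2::xml_name(node)) != "Befund") {
    warning("map object '", object_id,
            "': CDATA content is not a Befund element; kept empty",
            call. = FALSE)
    return(befund_record(id = object_id))
  }
  a <- xml2::xml_attrs(node)
  get <- function(nm, default = NA_character_) {
    if (nm %in% names(a)) a[[nm]] else default
  }
  befund_record(
    id = get("ID", object_id),
    show_gleason = parse_bool(get("ShowGleason", "False")),
    gleason1 = parse_num(get("Gleason1")),
    gleason2 = parse_num(get("Gleason2")),
    gleason_score = parse_num(get("GleasonScore")),
    grading = {g <- get("Grading"); if (is.na(g)) "" else g},
    length = parse_num(get("Length")),
    width = parse_num(get("Width")),
    slice_thick = parse_num(get("SliceThick"))
  )
}

serialize_map_part <- function(map_objects) {
  root <- xml2::xml_new_root("Map", xmlns = CMDX_NS)
  for (o in map_objects) {
    node <- xml2::xml_add_child(root, "MapObject")
    attrs <- c(Id = o$id, ToolName = o$tool_name, Kind = o$kind,
               SurfaceId = if (is.na(o$surface_id)) NA_character_
                           else o$surface_id)
    if (nzchar(o$relation)) attrs <- c(attrs, Relation = o$relation)
    if (nzchar(o$relation_slide)) {
      attrs <- c(attrs, RelationSlide = o$relation_slide)
    }
    if (!is.null(o$geometry)) {
      attrs <- c(attrs, switch(o$geometry$type,
        points = c(Points = format_points(o$geometry$value)),
        rect = c(Rectangle = format_rect(o$geometry$value)),
        position = c(Position = paste(fmt_num(o$geometry$value),
                                      collapse = ";"))
      ))
    }
    set_attrs(node, c(attrs, style_to_attrs(o$style)))
    set_attrs(node, o$extras)
    if (!is.null(o$befund)) {
      xml2::xml_add_child(node, xml2::xml_cdata(serialize_befund(o$befund)))
    }
  }
  as.character(root)
}

#' Parse a Map.xml part
#' @param xml_text XML text of the part
#' @return list of [map_object()]s, Befund records extracted from their
#'   CDATA sections
#' @export
parse_map_part <- function(xml_text) {
  root <- xml2::read_xml(xml_text)
  out <- lapply(xml2::xml_children(root), function(node) {
    if (local_name(xml2::xml_name(node)) != "MapObject") return(NULL)
    a <- node_attrs(node)
    geometry <- NULL
    if ("Points" %in% names(a)) {
      geometry <- list(type = "points", value = parse_points(a[["Points"]]))
    } else if ("Rectangle" %in% names(a)) {
      geometry <- list(type = "rect", value = parse_rect(a[["Rectangle"]]))
    } else if ("Position" %in% names(a)) {
      v <- parse_num(strsplit(a[["Position"]], ";")[[1]])
      geometry <- list(type = "position",
                       value = stats::setNames(v[1:2], c("x", "y")))
    }
    befund <- parse_befund_fragment(xml2::xml_text(node), a[["Id"]])
    map_object(
      id = a[["Id"]], tool_name = a[["ToolName"]],
      kind = if ("Kind" %in% names(a)) a[["Kind"]] else "pca_focus",
      geometry = geometry,
      style = style_from_attrs(a),
      relation = if ("Relation" %in% names(a)) a[["Relation"]] else "",
      relation_slide = if ("RelationSlide" %in% names(a))
        a[["RelationSlide"]] else "",
      befund = befund,
      surface_id = if ("SurfaceId" %in% names(a)) a[["SurfaceId"]]
                   else NA_character_,
      extras = drop_known(a, MAPOBJ_ATTRS)
    )
  })
  Filter(Negate(is.null), out)
}

# -- Form.xml --------------------------------------------------------------

FORM_FIELD_MAP <- c(
  pT = "pT", pN = "pN", pM = "pM", datum = "Datum",
  kernatypie = "Kernatypie", diff_muster = "DiffMuster",
  klassifizierung_adeno = "KlassifizierungAdeno",
  gls1 = "GLS1", gls2 = "GLS2", gls_total = "GLSTotal",
  g_grading = "GGrading", helpap = "HELPAP",
  L = "L", V = "V", R = "R", lk_b = "LK-B", lk_g = "LK-G",
  prostat_length = "ProstatLength", prostat_width = "ProstatWidth",
  prostat_volumen = "Prostatvolumen"
)

serialize_form_part <- function(form, passphrase = NULL) {
  root <- xml2::xml_new_root("Form", xmlns = CMDX_NS)
  node <- xml2::xml_add_child(root, "Formular")
  attrs <- character(0)
  for (fld in names(FORM_FIELD_MAP)) {
    v <- form[[fld]]
    xml_name <- FORM_FIELD_MAP[[fld]]
    if (is.character(v)) {
      if (nzchar(v)) attrs[[xml_name]] <- v
    } else if (!is.na(v)) {
      attrs[[xml_name]] <- fmt_num(v)
    }
  }
  encrypting <- !is.null(passphrase)
  attrs[["Encrypted"]] <- format_bool(encrypting)
  set_attrs(node, attrs)
  set_attrs(node, form$extras)
  for (pf in form$patient_fields) {
    p <- xml2::xml_add_child(node, "PatientField")
    xml2::xml_set_attr(p, "Name", pf$name)
    xml2::xml_set_attr(p, "Sensitive", format_bool(isTRUE(pf$sensitive)))
    env <- pf$envelope
    if (encrypting && isTRUE(pf$sensitive) && !is.null(pf$value)) {
      env <- encrypt_field(pf$value, passphrase)
    }
    if (!is.null(env) && (encrypting || is.null(pf$value))) {
      set_attrs(p, c(Ciphertext = env$ciphertext, Salt = env$salt,
                     IV = env$iv, MAC = env$mac,
                     KdfRounds = fmt_num(env$kdf_iterations),
                     SchemeTag = env$scheme_tag))
    } else {
      xml2::xml_set_attr(p, "Value", pf$value %||% "")
    }
  }
  as.character(root)
}

#' Parse a Form.xml part
#'
#' @param xml_text XML text of the part
#' @param passphrase optional; when given, sensitive envelope fields are
#'   decrypted (a wrong passphrase raises an authentication error), else
#'   they are returned as opaque envelopes with the `encrypted` flag set
#' @return a [form_record()]
#' @export
parse_form_part <- function(xml_text, passphrase = NULL) {
  root <- xml2::read_xml(xml_text)
  node <- NULL
  for (child in xml2::xml_children(root)) {
    if (local_name(xml2::xml_name(child)) == "Formular") node <- child
  }
  if (is.null(node)) stop("Form part has no Formular element")
  a <- node_attrs(node)
  args <- list()
  for (fld in names(FORM_FIELD_MAP)) {
    xml_name <- FORM_FIELD_MAP[[fld]]
    if (xml_name %in% names(a)) args[[fld]] <- a[[xml_name]]
  }
  patient_fields <- list()
  any_encrypted <- FALSE
  for (p in xml2::xml_children(node)) {
    if (local_name(xml2::xml_name(p)) != "PatientField") next
    pa <- node_attrs(p)
    value <- NULL
    envelope <- NULL
    if ("Ciphertext" %in% names(pa)) {
      env <- structure(list(
        ciphertext = pa[["Ciphertext"]], salt = pa[["Salt"]],
        iv = pa[["IV"]], mac = pa[["MAC"]],
        kdf_iterations = as.integer(parse_num(pa[["KdfRounds"]])),
        scheme_tag = pa[["SchemeTag"]]
      ), class = "cmdx_envelope")
      if (!is.null(passphrase)) {
        value <- decrypt_field(env, passphrase)
      } else {
        envelope <- env
        any_encrypted <- TRUE
      }
    } else {
      value <- pa[["Value"]]
    }
    entry <- c(list(name = pa[["Name"]]),
               if (!is.null(value)) list(value = value),
               list(sensitive = parse_bool(pa["Sensitive"])),
               if (!is.null(envelope)) list(envelope = envelope))
    patient_fields[[length(patient_fields) + 1L]] <- entry
  }
  args$patient_fields <- patient_fields
  args$encrypted <- any_encrypted
  args$extras <- drop_known(a, c(FORM_FIELD_MAP, "Encrypted"))
  do.call(form_record, args)
}

# -- package assembly ------------------------------------------------------

content_types_xml <- function(image_ext) {
  root <- xml2::xml_new_root("Types", xmlns = OPC_CT_NS)
  for (ct in list(c("xml", "application/xml"),
                  c(image_ext, paste0("image/", image_ext)))) {
    d <- xml2::xml_add_child(root, "Default")
    xml2::xml_set_attr(d, "Extension", ct[1])
    xml2::xml_set_attr(d, "ContentType", ct[2])
  }
  as.character(root)
}

#' Write a cMDX package
#'
#' Validates the document, recomputes each surface's PixelVolume at the
#' reference resolution, serializes the four XML parts plus the
#' background image into the Resource/Content zip layout, and encrypts
#' sensitive patient fields when a passphrase is given.
#'
#' @param doc a [cmdx_document()]
#' @param destination path of the package file to create
#' @param passphrase optional; encrypts sensitive patient fields
#' @return invisibly, a data frame of part names and byte sizes
#' @export
write_cmdx <- function(doc, destination, passphrase = NULL) {
  v <- validate_document(doc)
  if (nrow(v)) {
    stop("document is not valid:\n",
         paste0("  [", v$element, "] ", v$rule, ": ", v$message,
                collapse = "\n"))
  }
  gs <- reference_grid_size(doc)
  doc$mask <- lapply(doc$mask, function(s) {
    s$pixel_volume <- rasterize_surface(s, gs[["width"]],
                                        gs[["height"]])$count
    s
  })
  stage <- tempfile("cmdx_stage_")
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  dir.create(file.path(stage, "Resource"), recursive = TRUE)
  dir.create(file.path(stage, "Content"), recursive = TRUE)
  img_name <- doc$background$filename %||% "BGImage.png"
  writeLines(serialize_mask_part(doc$mask, complete = doc$complete,
                                 image_filename = img_name,
                                 extras = doc$extras),
             file.path(stage, "Resource", "Mask.xml"))
  writeLines(serialize_tools_part(doc$tools),
             file.path(stage, "Resource", "Tools.xml"))
  writeBin(doc$background$bytes, file.path(stage, "Resource", img_name))
  writeLines(serialize_map_part(doc$map_objects),
             file.path(stage, "Content", "Map.xml"))
  writeLines(serialize_form_part(doc$form, passphrase = passphrase),
             file.path(stage, "Content", "Form.xml"))
  writeLines(content_types_xml(tolower(tools::file_ext(img_name))),
             file.path(stage, "[Content_Types].xml"))
  if (file.exists(destination)) unlink(destination)
  zip::zip(normalizePath(destination, mustWork = FALSE),
           files = c("[Content_Types].xml", "Resource", "Content"),
           root = stage, mode = "mirror")
  files <- list.files(stage, recursive = TRUE, all.files = TRUE)
  summary <- data.frame(
    part = files,
    bytes = vapply(file.path(stage, files), function(f)
      as.numeric(file.size(f)), numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  invisible(summary)
}

read_part <- function(dir, part) {
  path <- file.path(dir, part)
  if (!file.exists(path)) {
    stop("structural error: part '", part, "' missing from package",
         call. = FALSE)
  }
  txt <- paste(readLines(path, warn = FALSE, encoding = "UTF-8"),
               collapse = "\n")
  txt
}

with_part_context <- function(part, expr) {
  tryCatch(expr, error = function(e) {
    stop("while parsing '", part, "': ", conditionMessage(e), call. = FALSE)
  })
}

#' Read a cMDX package
#'
#' @param source path to a cMDX zip package
#' @param passphrase optional; decrypts sensitive patient fields. Without
#'   it, encrypted fields stay opaque envelopes and the form's
#'   `encrypted` flag is set.
#' @return a [cmdx_document()]
#' @export
read_cmdx <- function(source, passphrase = NULL) {
  if (!file.exists(source)) stop("no such package: ", source)
  exdir <- tempfile("cmdx_read_")
  on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
  tryCatch(zip::unzip(source, exdir = exdir),
           error = function(e) stop("not a readable zip package: ", source,
                                    call. = FALSE))
  mask_info <- with_part_context("Resource/Mask.xml",
    parse_mask_part(read_part(exdir, file.path("Resource", "Mask.xml"))))
  tools <- with_part_context("Resource/Tools.xml",
    parse_tools_part(read_part(exdir, file.path("Resource", "Tools.xml"))))
  map_objects <- with_part_context("Content/Map.xml",
    parse_map_part(read_part(exdir, file.path("Content", "Map.xml"))))
  form <- with_part_context("Content/Form.xml",
    parse_form_part(read_part(exdir, file.path("Content", "Form.xml")),
                    passphrase = passphrase))
  res_files <- list.files(file.path(exdir, "Resource"))
  img_candidates <- setdiff(res_files, c("Mask.xml", "Tools.xml"))
  img_name <- if (!is.na(mask_info$image_filename) &&
                  mask_info$image_filename %in% res_files) {
    mask_info$image_filename
  } else if (length(img_candidates) == 1) {
    img_candidates
  } else {
    stop("structural error: background image missing from Resource/")
  }
  img_path <- file.path(exdir, "Resource", img_name)
  background <- list(
    bytes = readBin(img_path, "raw", n = file.size(img_path)),
    format = image_format_from_name(img_name),
    filename = img_name
  )
  cmdx_document(
    mask = mask_info$surfaces, tools = tools, background = background,
    map_objects = map_objects, form = form,
    complete = mask_info$complete, extras = mask_info$extras
  )
}

#' Compare two documents on all modelled fields
#'
#' @param a,b [cmdx_document()]s
#' @param tolerance numeric tolerance for coordinate comparison
#' @param ignore_pixel_volume drop surface pixel volumes before comparing
#'   (they are derived and rewritten on save)
#' @return TRUE, or a character vector describing the differences
#' @export
documents_equivalent <- function(a, b, tolerance = 1e-8,
                                 ignore_pixel_volume = TRUE) {
  strip <- function(doc) {
    if (ignore_pixel_volume) {
      doc$mask <- lapply(doc$mask, function(s) {
        s$pixel_volume <- NA_integer_
        s
      })
    }
    doc
  }
  res <- all.equal(strip(a), strip(b), tolerance = tolerance,
                   check.attributes = TRUE)
  if (isTRUE(res)) TRUE else res
}
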