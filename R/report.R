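# Single-document PDF report: rendered schema, textual findings,
# tumour-volume table. Deterministic output: fixed timestamp metadata so
# identical documents produce byte-identical files.

REPORT_FIELD_LABELS <- c(
  pT = "pT", pN = "pN", pM = "pM", datum = "Date",
  gls_total = "Gleason score", g_grading = "Grading", helpap = "Helpap",
  L = "L", V = "V", R = "R",
  lk_b = "Lymph nodes positive", lk_g = "Lymph nodes examined",
  prostat_volumen = "Prostate volume (cm^3)"
)

form_display_lines <- function(form) {
  lines <- character(0)
  for (fld in names(REPORT_FIELD_LABELS)) {
    v <- form[[fld]]
    txt <- if (is.character(v)) v else if (is.na(v)) "" else fmt_num(v)
    if (nzchar(txt)) {
      lines <- c(lines, paste0(REPORT_FIELD_LABELS[[fld]], ": ", txt))
    }
  }
  for (pf in form$patient_fields) {
    val <- if (!is.null(pf$value)) pf$value else "[encrypted]"
    lines <- c(lines, paste0(pf$name, ": ", val))
  }
  lines
}

# Overwrite the 14-digit timestamps of the PDF info dictionary in place
# (same byte length, so cross-reference offsets stay valid).
scrub_pdf_dates <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  fixed <- charToRaw("20100101000000")
  for (pat in c("/CreationDate (D:", "/ModDate (D:")) {
    offs <- grepRaw(pat, bytes, fixed = TRUE, all = TRUE)
    for (o in offs) {
      start <- o + nchar(pat)
      bytes[start:(start + 13)] <- fixed
    }
  }
  writeBin(bytes, path)
  invisible(path)
}

#' Generate a one-page PDF report for a document
#'
#' The page shows the rendered schematic map, the textual form findings
#' (encrypted patient fields display as "\[encrypted\]" when no
#' passphrase was used at read time) and the per-slice tumour-volume
#' table. Output is deterministic: the same document yields a
#' byte-identical file.
#'
#' @param doc a valid [cmdx_document()]
#' @param path output PDF path
#' @return `path`, invisibly
#' @export
export_report <- function(doc, path) {
  v <- validate_document(doc)
  if (nrow(v)) stop("document is not valid; run validate_document()")
  vol <- estimate_volume(doc)
  img <- render_document(doc)
  grDevices::pdf(path, width = 8.27, height = 11.69,
                 useDingbats = FALSE, compress = TRUE)
  on.exit(grDevices::dev.off(), add = TRUE)
  grid::grid.newpage()
  grid::grid.text("Radical prostatectomy specimen report",
                  y = grid::unit(0.97, "npc"),
                  gp = grid::gpar(fontsize = 16, fontface = "bold"))
  grid::grid.raster(img, x = grid::unit(0.30, "npc"),
                    y = grid::unit(0.62, "npc"),
                    width = grid::unit(0.52, "npc"))
  lines <- form_display_lines(doc$form)
  if (length(lines)) {
    grid::grid.text(paste(lines, collapse = "\n"),
                    x = grid::unit(0.62, "npc"),
                    y = grid::unit(0.88, "npc"),
                    just = c("left", "top"),
                    gp = grid::gpar(fontsize = 9))
  }
  tab <- vol$per_slice
  hdr <- sprintf("%-8s %14s %13s %13s %13s", "Slice", "Cancer px",
                 "Slice px", "Factor", "Contribution")
  body <- sprintf("%-8s %14d %13d %13.3f %13.5f",
                  tab$slice_id, tab$cancer_pixels, tab$slice_pixels,
                  tab$slice_factor, tab$relative_contribution)
  total <- sprintf("Relative tumour volume: %.4f%s", vol$relative_volume,
                   if (is.na(vol$volume_cm3)) ""
                   else sprintf("   Tumour volume: %.2f cm^3",
                                vol$volume_cm3))
  grid::grid.text(paste(c(hdr, body, "", total), collapse = "\n"),
                  x = grid::unit(0.08, "npc"),
                  y = grid::unit(0.30, "npc"),
                  just = c("left", "top"),
                  gp = grid::gpar(fontsize = 9, fontfamily = "mono"))
  grDevices::dev.off()
  on.exit(NULL)
  scrub_pdf_dates(path)
  invisible(path)
}
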