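`%||%` <- function(a, b) if (is.null(a)) b else a

#' Format a number for XML serialization
#'
#' Locale-independent: '.' decimal separator, no scientific notation,
#' trailing zeros trimmed.
#' @param x numeric vector
#' @return character vector
#' @keywords internal
fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("")
    s <- format(v, scientific = FALSE, trim = TRUE, digits = 15,
                decimal.mark = ".", nsmall = 0)
    s
  }, character(1))
  out
}

parse_num <- function(s) {
  suppressWarnings(as.numeric(s))
}

#' Serialize a vertex matrix as "X1;Y1 X2;Y2 ..."
#' @param pts two-column numeric matrix
#' @keywords internal
format_points <- function(pts) {
  stopifnot(is.matrix(pts), ncol(pts) == 2)
  paste(paste(fmt_num(pts[, 1]), fmt_num(pts[, 2]), sep = ";"),
        collapse = " ")
}

#' Parse "X1;Y1 X2;Y2 ..." into a vertex matrix
#' @keywords internal
parse_points <- function(s) {
  s <- trimws(s)
  if (!nzchar(s)) return(matrix(numeric(0), ncol = 2))
  toks <- strsplit(s, "[[:space:]]+")[[1]]
  xy <- vapply(strsplit(toks, ";"), function(p) parse_num(p[1:2]), numeric(2))
  matrix(t(xy), ncol = 2, dimnames = list(NULL, c("x", "y")))
}

#' Serialize a rectangle as "X;Y;Width;Height"
#' @keywords internal
format_rect <- function(r) {
  paste(fmt_num(as.numeric(r[1:4])), collapse = ";")
}

parse_rect <- function(s) {
  v <- parse_num(strsplit(trimws(s), ";")[[1]])
  if (length(v) != 4) stop("rectangle must have 4 components: ", s)
  names(v) <- c("x", "y", "width", "height")
  v
}

# Colours carry four 0-255 channels in the order Alpha;Red;Blue;Green.
# That channel order (A;R;B;G rather than the conventional A;R;G;B) is the
# cMDX wire format; conversion to R colour space happens only in the
# renderer.
format_arbg <- function(col) {
  paste(fmt_num(round(as.numeric(col[1:4]))), collapse = ";")
}

parse_arbg <- function(s) {
  v <- parse_num(strsplit(trimws(s), ";")[[1]])
  if (length(v) != 4) stop("colour must have 4 channels (A;R;B;G): ", s)
  names(v) <- c("alpha", "red", "blue", "green")
  v
}

#' Convert an A;R;B;G channel vector to an RGBA fraction vector
#' @keywords internal
arbg_to_rgba <- function(col) {
  c(red = col[["red"]], green = col[["green"]], blue = col[["blue"]],
    alpha = col[["alpha"]]) / 255
}

format_bool <- function(x) if (isTRUE(x)) "True" else "False"

parse_bool <- function(s) {
  if (is.null(s) || is.na(s)) return(FALSE)
  tolower(trimws(s)) %in% c("true", "1", "yes")
}

new_id_counter <- function(prefix) {
  i <- 0L
  function() {
    i <<- i + 1L
    paste0(prefix, i)
  }
}
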