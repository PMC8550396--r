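#' The 9 x 13 RGB reference color matrix
#'
#' Color labels for orchid flowers (CF) and labella (CL) are defined over a
#' two-dimensional arrangement of the RGB color space: a matrix of 9 rows by
#' 13 columns whose columns sweep hue from red through yellow, green, blue and
#' purple, and whose rows run from dark, saturated shades at the top to pale,
#' near-white tints at the bottom. White sits in the bottom-right cell (9, 13).
#' Columns 7--9 hold the blues, which do not occur in orchid flowers or
#' labella and are excluded from every color scheme.
#'
#' The exact per-cell RGB values carry no semantics beyond the column/row
#' partition, so the default palette is generated procedurally (hue by column,
#' value and saturation by row) and can be overridden cell-by-cell with
#' [read_palette()].
#'
#' @param palette optional 9 x 13 x 3 numeric array of RGB values in
#'   `[0, 255]` overriding the procedural palette, e.g. from [read_palette()].
#' @param whiteness minimum channel value for a cell to count as white; cell
#'   (9, 13) must satisfy it.
#' @return an object of class `color_matrix`: a list with elements `rgb`
#'   (9 x 13 x 3 array, values in 0--255), `whiteness`, and `blue_cols`
#'   (the excluded blue columns, 7:9).
#' @examples
#' m <- color_matrix()
#' m$rgb[9, 13, ]  # white
#' @export
color_matrix <- function(palette = NULL, whiteness = 240) {
  if (is.null(palette)) palette <- default_palette()
  stopifnot(is.numeric(palette), identical(dim(palette), c(9L, 13L, 3L)))
  if (any(palette < 0) || any(palette > 255)) {
    stop("palette values must lie in [0, 255]")
  }
  if (any(palette[9, 13, ] < whiteness)) {
    stop("cell (9, 13) must be white: all channels >= ", whiteness)
  }
  structure(
    list(rgb = palette, whiteness = whiteness, blue_cols = 7:9),
    class = "color_matrix"
  )
}

# Procedural palette: hue varies across columns (red -> yellow -> green ->
# blue -> purple/pink), value increases and saturation decreases down the
# rows, so the bottom row is close to white and cell (9, 13) is forced white.
# Brightness changes (illumination) move a color within its column, never
# across the label boundary between columns.
default_palette <- function() {
  hues <- c(0, 30, 52, 85, 115, 145, 195, 220, 240, 268, 288, 308, 330) / 360
  rows <- seq_len(9)
  val <- 0.35 + 0.65 * (rows - 1) / 8
  sat <- 0.95 - 0.75 * (rows - 1) / 8
  pal <- array(0, dim = c(9, 13, 3))
  for (j in seq_len(13)) {
    hex <- grDevices::hsv(hues[j], sat, val)
    rgb <- t(grDevices::col2rgb(hex))
    pal[, j, ] <- rgb
  }
  pal[9, 13, ] <- c(255, 255, 255)
  pal
}

#' @export
print.color_matrix <- function(x, ...) {
  cat("Color reference matrix: 9 x 13 cells,",
      "blue columns", paste(range(x$blue_cols), collapse = "-"),
      "excluded\n")
  cat("White cell (9,13):", paste(x$rgb[9, 13, ], collapse = ","), "\n")
  invisible(x)
}

#' Read a palette override file
#'
#' Reads a YAML file mapping `"row,col"` keys to `[R, G, B]` triples and
#' applies the overrides on top of the procedural default palette.
#'
#' @param path path to a YAML file.
#' @return a 9 x 13 x 3 array suitable for [color_matrix()].
#' @export
read_palette <- function(path) {
  spec <- yaml::read_yaml(path)
  pal <- default_palette()
  for (key in names(spec)) {
    rc <- as.integer(strsplit(key, ",", fixed = TRUE)[[1]])
    if (length(rc) != 2 || anyNA(rc) || rc[1] < 1 || rc[1] > 9 ||
        rc[2] < 1 || rc[2] > 13) {
      stop("invalid palette cell key: ", key)
    }
    val <- as.numeric(spec[[key]])
    if (length(val) != 3) stop("palette entry ", key, " is not an RGB triple")
    pal[rc[1], rc[2], ] <- val
  }
  pal
}

# linearized non-blue cell table for nearest-cell lookups: data.frame with
# row, col, r, g, b
cell_table <- function(m) {
  keep <- setdiff(seq_len(13), m$blue_cols)
  grid <- expand.grid(row = seq_len(9), col = keep)
  rgb <- t(apply(grid, 1, function(x) m$rgb[x[1], x[2], ]))
  cbind(grid, r = rgb[, 1], g = rgb[, 2], b = rgb[, 3])
}
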