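#' Color schemes for flower and labellum labels
#'
#' A color scheme partitions the non-blue cells of the reference
#' [color_matrix()] into named primary colors and fixes which primary/
#' secondary combinations are allowed. Two schemes are supported:
#'
#' * **Scheme 1** (4 colors): Red (columns 1--2), Yellow (column 3),
#'   Green (columns 4--6), Purple (columns 10--13). Cell (9, 13) -- white --
#'   is mapped to Yellow, whose pale column end it resembles.
#' * **Scheme 2** (5 colors): Red (column 1 plus the four darkest cells of
#'   column 2), Yellow (the rest of columns 2--3), Green (columns 4--6),
#'   Purple (columns 10--13), White (the single cell (9, 13)).
#'
#' Rows 1--8 of column 13 sit on the purple-to-white edge of the matrix and
#' are assigned to Purple in both schemes so that every non-blue cell carries
#' exactly one label.
#'
#' Each scheme also carries, per target (`CF` = color of flower, `CL` = color
#' of labellum), the combinations that do not occur in nature and are
#' excluded from the combination label space, plus the directed exclusion
#' list used when commutativity of the combination is switched off (the
#' ablation label space).
#'
#' @param scheme_id 1 or 2.
#' @param target `"CF"` (flower) or `"CL"` (labellum).
#' @param matrix a [color_matrix()]; defaults to the procedural palette.
#' @return an object of class `color_scheme` with fields `scheme_id`,
#'   `target`, `primaries`, `column_map` (label -> matrix of (row, col)
#'   cells), `excluded_combinations` (canonical names),
#'   `excluded_directed` (ordered `Primary|Secondary` pairs for the
#'   non-commutative ablation) and `matrix`.
#' @examples
#' sch <- color_scheme(1, "CF")
#' scheme_labels(sch)
#' scheme_labels(sch, use_secondary = TRUE)
#' @export
color_scheme <- function(scheme_id, target = c("CF", "CL"),
                         matrix = color_matrix()) {
  target <- match.arg(target)
  if (!scheme_id %in% c(1, 2)) stop("scheme_id must be 1 or 2")
  scheme_id <- as.integer(scheme_id)

  all_rows <- seq_len(9)
  cells <- function(rows, cols) {
    g <- expand.grid(row = rows, col = cols)
    as.matrix(g[order(g$col, g$row), , drop = FALSE])
  }
  drop_cell <- function(m, row, col) {
    m[!(m[, 1] == row & m[, 2] == col), , drop = FALSE]
  }

  if (scheme_id == 1L) {
    primaries <- c("Red", "Yellow", "Green", "Purple")
    column_map <- list(
      Red    = cells(all_rows, 1:2),
      Yellow = rbind(cells(all_rows, 3), c(9, 13)),
      Green  = cells(all_rows, 4:6),
      Purple = drop_cell(cells(all_rows, 10:13), 9, 13)
    )
    excl <- list(c("Red", "Purple"), c("Green", "Purple"))
    excl_directed <- c("Red|Purple", "Purple|Red",
                       "Green|Purple", "Purple|Green")
  } else {
    primaries <- c("Red", "Yellow", "Green", "Purple", "White")
    yellow <- rbind(cells(5:9, 2), cells(all_rows, 3))
    column_map <- list(
      Red    = rbind(cells(all_rows, 1), cells(1:4, 2)),
      Yellow = yellow,
      Green  = cells(all_rows, 4:6),
      Purple = drop_cell(cells(all_rows, 10:13), 9, 13),
      White  = cells(9, 13)
    )
    if (target == "CL") {
      excl <- list(c("Red", "Red"), c("Red", "Purple"), c("Red", "White"),
                   c("Yellow", "Green"), c("Green", "Purple"))
      excl_directed <- c("Red|Red",
                         "Red|Purple", "Purple|Red",
                         "Red|White", "White|Red",
                         "Yellow|Green", "Green|Yellow",
                         "Green|Purple", "Purple|Green")
    } else {
      excl <- list(c("Red", "Purple"), c("Red", "White"),
                   c("Yellow", "White"), c("Green", "Purple"))
      # directed ablation list; additionally drops the White-as-secondary
      # orderings of the two surviving White pairs, giving the 15-label
      # ablation space for CF2
      excl_directed <- c("Red|Purple", "Purple|Red",
                         "Red|White", "White|Red",
                         "Yellow|White", "White|Yellow",
                         "Green|Purple", "Purple|Green",
                         "Green|White", "Purple|White")
    }
  }

  sch <- structure(
    list(scheme_id = scheme_id, target = target, primaries = primaries,
         column_map = column_map,
         excluded_combinations = character(0),
         excluded_directed = excl_directed,
         matrix = matrix),
    class = "color_scheme"
  )
  sch$excluded_combinations <- vapply(
    excl, function(p) canonical_name(p[1], p[2]), character(1)
  )
  validate_scheme(sch)
  sch
}

validate_scheme <- function(sch) {
  all_cells <- do.call(rbind, sch$column_map)
  key <- paste(all_cells[, 1], all_cells[, 2])
  if (anyDuplicated(key)) stop("scheme cell sets overlap")
  n_nonblue <- 9 * (13 - length(sch$matrix$blue_cols))
  if (length(key) != n_nonblue) {
    stop("scheme cell sets do not cover the ", n_nonblue, " non-blue cells")
  }
  if (any(all_cells[, 2] %in% sch$matrix$blue_cols)) {
    stop("scheme assigns labels to blue columns")
  }
  invisible(sch)
}

#' @export
print.color_scheme <- function(x, ...) {
  cat(sprintf("Color scheme %d for %s: %d primaries (%s)\n",
              x$scheme_id, x$target, length(x$primaries),
              paste(x$primaries, collapse = ", ")))
  cat("Excluded combinations:",
      paste(x$excluded_combinations, collapse = ", "), "\n")
  invisible(x)
}

#' Count color combinations with repetition
#'
#' Number of unordered selections of `k` colors from `n` with repetition
#' allowed (a primary may equal its secondary, which is the same as having
#' no secondary color): `choose(n + k - 1, k)`.
#'
#' @param n number of colors, positive integer.
#' @param k selection size, positive integer.
#' @return the multichoose count, as a number.
#' @examples
#' count_multichoose(4, 2)  # 10 for the 4-color scheme
#' count_multichoose(5, 2)  # 15 for the 5-color scheme
#' @export
count_multichoose <- function(n, k) {
  if (length(n) != 1 || length(k) != 1 || !is.numeric(n) || !is.numeric(k) ||
      n < 1 || k < 1 || n != round(n) || k != round(k)) {
    stop("n and k must be positive integers")
  }
  choose(n + k - 1, k)
}

# order-independent name: equal colors collapse to the single color,
# otherwise the two names are concatenated in alphabetical order
canonical_name <- function(primary, secondary) {
  if (primary == secondary) return(primary)
  paste(sort(c(primary, secondary)), collapse = "")
}

#' Canonicalize a primary/secondary color combination
#'
#' The combination of a primary and a secondary color is commutative
#' (`AB = BA`), and a combination whose two colors coincide is just the
#' single color. The canonical name concatenates the two color names in
#' alphabetical order, so `canonicalize` of (Red, Yellow) and (Yellow, Red)
#' agree.
#'
#' @param primary,secondary color names, both in `scheme$primaries`.
#' @param scheme a [color_scheme()].
#' @return an object of class `color_combination` with fields `primary`,
#'   `secondary` and `canonical_name`.
#' @examples
#' sch <- color_scheme(1, "CF")
#' canonicalize("Red", "Red", sch)$canonical_name      # "Red"
#' canonicalize("Yellow", "Red", sch)$canonical_name   # same as (Red, Yellow)
#' @export
canonicalize <- function(primary, secondary, scheme) {
  for (lab in c(primary, secondary)) {
    if (!lab %in% scheme$primaries) {
      stop("unknown label for scheme ", scheme$scheme_id, ": ", lab)
    }
  }
  structure(
    list(primary = primary, secondary = secondary,
         canonical_name = canonical_name(primary, secondary)),
    class = "color_combination"
  )
}

#' @export
print.color_combination <- function(x, ...) {
  cat(sprintf("Color combination %s (primary %s, secondary %s)\n",
              x$canonical_name, x$primary, x$secondary))
  invisible(x)
}

#' Enumerate the label space of a scheme
#'
#' With `use_secondary = FALSE` the label space is the scheme's primaries
#' (4 colors for scheme 1, 5 for scheme 2). With `use_secondary = TRUE` it is
#' all canonical primary/secondary combinations minus the combinations that
#' do not occur in nature for the scheme's target: 8 labels for CF1/CL1,
#' 11 for CF2 and 10 for CL2.
#'
#' Setting `commutative = FALSE` switches to the ablation label space in
#' which the order of primary and secondary is kept (label names are the
#' ordered concatenation, single colors keep their plain name), of sizes
#' 12/15/12/16 for CF1/CF2/CL1/CL2.
#'
#' @param scheme a [color_scheme()].
#' @param use_secondary include secondary-color combinations?
#' @param commutative treat `AB` and `BA` as the same label? Only consulted
#'   when `use_secondary` is `TRUE`.
#' @return character vector of labels in a fixed, deterministic order.
#' @export
scheme_labels <- function(scheme, use_secondary = FALSE, commutative = TRUE) {
  prim <- scheme$primaries
  if (!use_secondary) return(prim)
  n <- length(prim)
  if (commutative) {
    out <- character(0)
    for (i in seq_len(n)) for (j in i:n) {
      out <- c(out, canonical_name(prim[i], prim[j]))
    }
    setdiff(out, scheme$excluded_combinations)
  } else {
    out <- character(0)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      key <- paste(prim[i], prim[j], sep = "|")
      if (key %in% scheme$excluded_directed) next
      out <- c(out, if (i == j) prim[i] else paste0(prim[i], prim[j]))
    }
    out
  }
}

#' Label of a matrix cell under a scheme
#'
#' @param scheme a [color_scheme()].
#' @param row,col 1-based cell indices, `1 <= row <= 9`, `1 <= col <= 13`.
#' @return the primary-color label owning the cell.
#' @examples
#' label_for_cell(color_scheme(2, "CF"), 9, 13)  # "White"
#' @export
label_for_cell <- function(scheme, row, col) {
  if (row < 1 || row > 9 || col < 1 || col > 13) stop("cell out of range")
  if (col %in% scheme$matrix$blue_cols) {
    stop("unsupported color: columns ",
         paste(range(scheme$matrix$blue_cols), collapse = "-"),
         " are blue, which does not occur in orchids")
  }
  for (lab in names(scheme$column_map)) {
    m <- scheme$column_map[[lab]]
    if (any(m[, 1] == row & m[, 2] == col)) return(lab)
  }
  stop("cell (", row, ",", col, ") not covered by scheme")  # unreachable
}

#' Sample a palette RGB for a label
#'
#' Draws one of the label's matrix cells uniformly at random (using R's RNG,
#' so deterministic under `set.seed`) and returns its RGB triple.
#'
#' @param scheme a [color_scheme()].
#' @param label a primary-color label of the scheme.
#' @return numeric RGB triple in 0--255.
#' @export
palette_color <- function(scheme, label) {
  m <- scheme$column_map[[label]]
  if (is.null(m)) stop("unknown label for scheme ", scheme$scheme_id, ": ", label)
  if (nrow(m) == 0) stop("label ", label, " has an empty cell set")
  i <- sample.int(nrow(m), 1)
  scheme$matrix$rgb[m[i, 1], m[i, 2], ]
}

#' Map pixels to primary-color labels
#'
#' Assigns each pixel the label of the non-blue reference-matrix cell whose
#' RGB direction is closest (smallest angle in RGB space, `metric =
#' "angular"`, insensitive to multiplicative illumination changes) or
#' closest in plain Euclidean RGB distance (`metric = "euclidean"`). Used by
#' the pixel-vote oracle that checks synthetic images are labeled
#' recoverably.
#'
#' @param scheme a [color_scheme()].
#' @param pixels an N x 3 matrix of RGB values, in `[0, 1]` or 0--255.
#' @param metric `"angular"` (default) or `"euclidean"`.
#' @return character vector of N labels.
#' @export
classify_pixels <- function(scheme, pixels,
                            metric = c("angular", "euclidean")) {
  metric <- match.arg(metric)
  pixels <- as.matrix(pixels)
  if (ncol(pixels) != 3) stop("pixels must be an N x 3 RGB matrix")
  if (max(pixels) <= 1) pixels <- pixels * 255
  tab <- cell_table(scheme$matrix)
  ref <- as.matrix(tab[, c("r", "g", "b")])
  if (metric == "angular") {
    pn <- sqrt(pmax(rowSums(pixels^2), 1e-9))
    rn <- sqrt(rowSums(ref^2))
    cosang <- (pixels %*% t(ref)) / outer(pn, rn)
    d <- 1 - cosang^2
  } else {
    d <- outer(rowSums(pixels^2), rep(1, nrow(ref))) -
      2 * pixels %*% t(ref) + outer(rep(1, nrow(pixels)), rowSums(ref^2))
  }
  idx <- max.col(-d, ties.method = "first")
  cell_labels <- cell_label_lookup(scheme)
  unname(cell_labels[paste(tab$row[idx], tab$col[idx])])
}

# named lookup "row col" -> label over all assigned cells
cell_label_lookup <- function(scheme) {
  out <- character(0)
  for (lab in names(scheme$column_map)) {
    m <- scheme$column_map[[lab]]
    v <- rep(lab, nrow(m))
    names(v) <- paste(m[, 1], m[, 2])
    out <- c(out, v)
  }
  out
}

#' Export a scheme definition to JSON
#'
#' @param scheme a [color_scheme()].
#' @param path file to write; if `NULL`, the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
scheme_to_json <- function(scheme, path = NULL) {
  obj <- list(
    scheme_id = scheme$scheme_id,
    target = scheme$target,
    primaries = scheme$primaries,
    column_map = lapply(scheme$column_map, function(m) {
      unname(apply(m, 1, function(x) list(row = x[1], col = x[2])))
    }),
    excluded_combinations = scheme$excluded_combinations,
    excluded_directed = scheme$excluded_directed
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
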