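# Synthetic orchid-like images: a multi-lobed "flower" (sepals + petals)
# dominated by a primary color with an optional secondary rim, a smaller
# labellum lobe with its own colors, textured background clutter including
# green foliage tones, illumination jitter and pixel noise. The generator
# emulates the statistical structure color-label classifiers rely on --
# region sizes, primary/secondary split, clutter, imbalance -- at cartoon
# fidelity; it makes no attempt at photorealism.

#' Synthetic dataset configuration
#'
#' @param image_size square image size in pixels.
#' @param n_per_class images per class: a single integer, or a named vector
#'   over class labels to emulate imbalance.
#' @param use_secondary generate classes over the combination label space
#'   (primary + secondary) instead of primaries only.
#' @param secondary_fraction probability that a primary-only sample carries
#'   a (distinct) secondary rim color anyway.
#' @param labellum_scale labellum size as a fraction of the flower size;
#'   must be < 1 (the labellum is the smaller region).
#' @param clutter_level background clutter intensity in `[0, 1]`
#'   (0 = plain background).
#' @param illumination_jitter multiplicative brightness range applied to
#'   the whole image.
#' @param noise_sd standard deviation of additive Gaussian pixel noise.
#' @param seed integer seed governing the whole dataset.
#' @export
synth_config <- function(image_size = 224, n_per_class = 100,
                         use_secondary = FALSE, secondary_fraction = 0.5,
                         labellum_scale = 0.3, clutter_level = 0.5,
                         illumination_jitter = c(0.75, 1.25),
                         noise_sd = 0.02, seed = 1L) {
  stopifnot(secondary_fraction >= 0, secondary_fraction <= 1,
            clutter_level >= 0, clutter_level <= 1,
            labellum_scale > 0, labellum_scale < 1,
            length(illumination_jitter) == 2)
  structure(
    list(image_size = as.integer(image_size), n_per_class = n_per_class,
         use_secondary = use_secondary,
         secondary_fraction = secondary_fraction,
         labellum_scale = labellum_scale, clutter_level = clutter_level,
         illumination_jitter = illumination_jitter, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

ellipse_mask <- function(S, cx, cy, a, b, theta) {
  gx <- matrix(seq_len(S), S, S, byrow = TRUE)  # column coordinate
  gy <- matrix(seq_len(S), S, S)                # row coordinate
  dx <- gx - cx
  dy <- gy - cy
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  u^2 + v^2 <= 1
}

fill_mask <- function(img, mask, rgb01, shade = NULL) {
  for (ch in 1:3) {
    plane <- img[, , ch]
    val <- rgb01[ch]
    plane[mask] <- if (is.null(shade)) val else val * shade[mask]
    img[, , ch] <- plane
  }
  img
}

# fill a region with a per-pixel mixture of several same-label colors
# (rows of cols01) under mild multiplicative shading
fill_mask_multi <- function(img, mask, cols01, shade) {
  npix <- sum(mask)
  if (npix == 0) return(img)
  pick <- sample.int(nrow(cols01), npix, replace = TRUE)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[mask] <- cols01[pick, ch] * shade[mask]
    img[, , ch] <- plane
  }
  img
}

# sample a few palette cells of one label (petal regions are not one flat
# RGB; mixing cells of the same label gives within-region texture)
sample_label_colors <- function(scheme, label, k = 3) {
  t(replicate(k, palette_color(scheme, label) / 255))
}

# paint a region: primary fill with mild per-pixel shading, optional
# secondary rim occupying `rim_frac` of the region (by center distance)
paint_region <- function(img, mask, cx, cy, cols_primary, cols_secondary,
                         rim_frac) {
  S <- dim(img)[1]
  shade <- matrix(stats::runif(S * S, 0.92, 1.0), S, S)
  img <- fill_mask_multi(img, mask, cols_primary, shade)
  if (!is.null(cols_secondary) && rim_frac > 0) {
    gx <- matrix(seq_len(S), S, S, byrow = TRUE)
    gy <- matrix(seq_len(S), S, S)
    d <- sqrt((gx - cx)^2 + (gy - cy)^2)
    dm <- d[mask]
    cut <- stats::quantile(dm, 1 - rim_frac)
    rim <- mask & (d > cut)
    img <- fill_mask_multi(img, rim, cols_secondary, shade)
  }
  img
}

check_combination <- function(comb, scheme) {
  nm <- canonical_name(comb$primary, comb$secondary)
  if (nm %in% scheme$excluded_combinations) {
    stop("combination ", nm, " is excluded for scheme ", scheme$scheme_id,
         " ", scheme$target)
  }
  invisible(nm)
}

#' Generate one synthetic orchid image
#'
#' Renders background clutter, a flower of 5--6 overlapping elliptical
#' lobes colored by the CF combination (secondary color as an outer rim
#' covering 15--35% of the region), and a smaller offset labellum lobe
#' colored by the CL combination, then applies illumination jitter and
#' Gaussian noise. Deterministic for a fixed `seed`.
#'
#' @param cf,cl [canonicalize()]d color combinations for the flower and
#'   labellum (a combination whose secondary equals its primary has no rim).
#' @param cfg a [synth_config()].
#' @param scheme_cf,scheme_cl the [color_scheme()]s the combinations refer
#'   to (same `scheme_id`, targets CF and CL).
#' @param seed optional integer; when given, `set.seed` is called first.
#' @return an object of class `annotated_image`: list with `image`
#'   (S x S x 3 array in `[0, 1]`), the four label fields, `scheme_id` and
#'   region masks (`flower_mask`, `labellum_mask`).
#' @export
generate_sample <- function(cf, cl, cfg, scheme_cf, scheme_cl,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_combination(cf, scheme_cf)
  check_combination(cl, scheme_cl)
  S <- cfg$image_size

  # background: muted foliage/soil tone plus clutter blobs and texture
  base_hue <- sample(c(stats::runif(1, 0.22, 0.40),   # greens
                       stats::runif(1, 0.05, 0.12),   # browns
                       stats::runif(1, 0.55, 0.65)), 1)  # dull blue-gray
  base <- grDevices::col2rgb(
    grDevices::hsv(base_hue, stats::runif(1, 0.2, 0.5),
                   stats::runif(1, 0.25, 0.55))
  )[, 1] / 255
  img <- array(rep(base, each = S * S), dim = c(S, S, 3))
  n_blobs <- round(cfg$clutter_level * 8)
  for (i in seq_len(n_blobs)) {
    hue <- sample(c(stats::runif(1, 0.2, 0.42), stats::runif(1, 0.04, 0.13)), 1)
    col <- grDevices::col2rgb(
      grDevices::hsv(hue, stats::runif(1, 0.3, 0.8), stats::runif(1, 0.2, 0.7))
    )[, 1] / 255
    m <- ellipse_mask(S, stats::runif(1, 1, S), stats::runif(1, 1, S),
                      stats::runif(1, 0.05, 0.25) * S,
                      stats::runif(1, 0.05, 0.25) * S,
                      stats::runif(1, 0, pi))
    img <- fill_mask(img, m, col)
  }
  if (cfg$clutter_level > 0) {
    img <- img + array(stats::rnorm(S * S * 3, 0, 0.04 * cfg$clutter_level),
                       dim = dim(img))
    img[img < 0] <- 0
    img[img > 1] <- 1
  }

  # flower: 5-6 petal/sepal ellipses around a jittered center
  cx <- S / 2 + stats::runif(1, -0.06, 0.06) * S
  cy <- S / 2 + stats::runif(1, -0.06, 0.06) * S
  rf <- 0.30 * S * stats::runif(1, 0.85, 1.1)
  np <- sample(5:6, 1)
  angles <- seq(0, 2 * pi, length.out = np + 1)[-(np + 1)] +
    stats::runif(1, 0, 2 * pi / np)
  flower <- matrix(FALSE, S, S)
  for (a in angles) {
    pcx <- cx + 0.55 * rf * cos(a)
    pcy <- cy + 0.55 * rf * sin(a)
    flower <- flower | ellipse_mask(S, pcx, pcy, 0.62 * rf, 0.38 * rf, a)
  }

  cf_rgb <- sample_label_colors(scheme_cf, cf$primary)
  cf_sec_rgb <- NULL
  rim_frac <- 0
  if (cf$secondary != cf$primary) {
    cf_sec_rgb <- sample_label_colors(scheme_cf, cf$secondary)
    rim_frac <- stats::runif(1, 0.15, 0.35)
  }
  img <- paint_region(img, flower, cx, cy, cf_rgb, cf_sec_rgb, rim_frac)

  # labellum: one smaller lobe offset below the flower center
  lcx <- cx + stats::runif(1, -0.1, 0.1) * rf
  lcy <- cy + 0.5 * rf
  la <- cfg$labellum_scale * rf * 1.25
  lb <- cfg$labellum_scale * rf * 0.85
  labellum <- ellipse_mask(S, lcx, lcy, la, lb,
                           pi / 2 + stats::runif(1, -0.3, 0.3))
  cl_rgb <- sample_label_colors(scheme_cl, cl$primary)
  cl_sec_rgb <- NULL
  lrim <- 0
  if (cl$secondary != cl$primary) {
    cl_sec_rgb <- sample_label_colors(scheme_cl, cl$secondary)
    lrim <- stats::runif(1, 0.15, 0.35)
  }
  img <- paint_region(img, labellum, lcx, lcy, cl_rgb, cl_sec_rgb, lrim)

  # illumination jitter (gamma-style brightness transform: keeps channels
  # in [0,1] without clipping, which would wash bright colors to white)
  f <- stats::runif(1, cfg$illumination_jitter[1],
                    cfg$illumination_jitter[2])
  img <- img^(1 / f)
  if (cfg$noise_sd > 0) {
    img <- img + array(stats::rnorm(S * S * 3, 0, cfg$noise_sd),
                       dim = dim(img))
  }
  img[img < 0] <- 0
  img[img > 1] <- 1

  structure(
    list(image = img,
         cf_primary = cf$primary,
         cf_secondary = if (cf$secondary == cf$primary) NA_character_ else cf$secondary,
         cl_primary = cl$primary,
         cl_secondary = if (cl$secondary == cl$primary) NA_character_ else cl$secondary,
         scheme_id = scheme_cf$scheme_id,
         split = NA_character_,
         flower_mask = flower & !labellum,
         labellum_mask = labellum),
    class = "annotated_image"
  )
}

#' @export
print.annotated_image <- function(x, ...) {
  cat(sprintf("Annotated image %dx%d, scheme %d: CF %s%s, CL %s%s (%s)\n",
              dim(x$image)[1], dim(x$image)[2], x$scheme_id,
              x$cf_primary,
              if (is.na(x$cf_secondary)) "" else paste0("+", x$cf_secondary),
              x$cl_primary,
              if (is.na(x$cl_secondary)) "" else paste0("+", x$cl_secondary),
              x$split))
  invisible(x)
}

# draw a (primary, secondary) pair for a class label of the given scheme:
# for a combination label the order of the two colors is randomized; for a
# single-color label a secondary may still be attached with probability
# `sec_frac` when allowed (it does not change the class)
draw_combination <- function(label, scheme, use_secondary, sec_frac) {
  prim <- scheme$primaries
  if (use_secondary) {
    parts <- prim[vapply(prim, function(p) startsWith(label, p) &&
                           (label == p || substring(label, nchar(p) + 1) %in% prim),
                         logical(1))]
    if (label %in% prim) {
      return(canonicalize(label, label, scheme))
    }
    a <- parts[1]
    b <- substring(label, nchar(a) + 1)
    if (stats::runif(1) < 0.5) canonicalize(a, b, scheme) else canonicalize(b, a, scheme)
  } else {
    partners <- setdiff(prim, label)
    ok <- partners[vapply(partners, function(s) {
      !canonical_name(label, s) %in% scheme$excluded_combinations
    }, logical(1))]
    single_ok <- !canonical_name(label, label) %in% scheme$excluded_combinations
    # a color whose pure form is excluded (e.g. a labellum that is never
    # entirely red) always carries a secondary rim
    if (length(ok) && (!single_ok || stats::runif(1) < sec_frac)) {
      return(canonicalize(label, sample(ok, 1), scheme))
    }
    if (!single_ok) {
      stop("label ", label, " admits no allowed combination for scheme ",
           scheme$scheme_id, " ", scheme$target)
    }
    canonicalize(label, label, scheme)
  }
}

#' Generate a labeled synthetic dataset
#'
#' Generates `n_per_class` images for every class of the chosen target's
#' label space, assigns stratified train/validation/test splits in 70/20/10
#' proportions, and builds a manifest. The class variable is the label of
#' `scheme` (the CF label space when `scheme$target == "CF"`, CL
#' otherwise); the other target's colors are drawn at random from its
#' allowed combinations.
#'
#' @param cfg a [synth_config()].
#' @param scheme a [color_scheme()] defining the class variable.
#' @param class_labels optional explicit class labels (defaults to
#'   [scheme_labels()] of `scheme` with `cfg$use_secondary`).
#' @return object of class `synth_dataset`: list with `images` (list of
#'   arrays), `manifest` (data.frame: filename, species_id, cf_primary,
#'   cf_secondary, cl_primary, cl_secondary, scheme_id, split, class_label),
#'   `class_labels` and `config`.
#' @export
generate_dataset <- function(cfg, scheme, class_labels = NULL) {
  set.seed(cfg$seed)
  if (is.null(class_labels)) {
    class_labels <- scheme_labels(scheme, use_secondary = cfg$use_secondary)
  }
  other_target <- if (scheme$target == "CF") "CL" else "CF"
  other <- color_scheme(scheme$scheme_id, other_target, scheme$matrix)

  n_map <- cfg$n_per_class
  if (length(n_map) == 1 && is.null(names(n_map))) {
    n_map <- stats::setNames(rep(n_map, length(class_labels)), class_labels)
  }
  if (!all(class_labels %in% names(n_map))) {
    stop("n_per_class must name every class label")
  }
  if (any(n_map[class_labels] < 10)) {
    warning("classes with fewer than 10 images cannot be stratified cleanly")
  }

  images <- list()
  rows <- list()
  k <- 0
  for (lb in class_labels) {
    n <- n_map[[lb]]
    splits <- split_assignments(n)
    for (i in seq_len(n)) {
      k <- k + 1
      class_comb <- draw_combination(lb, scheme, cfg$use_secondary,
                                     cfg$secondary_fraction)
      other_lab <- sample(other$primaries, 1)
      other_comb <- draw_combination(other_lab, other, FALSE,
                                     cfg$secondary_fraction)
      if (scheme$target == "CF") {
        smp <- generate_sample(class_comb, other_comb, cfg, scheme, other)
      } else {
        smp <- generate_sample(other_comb, class_comb, cfg, other, scheme)
      }
      smp$split <- splits[i]
      images[[k]] <- smp
      rows[[k]] <- data.frame(
        filename = sprintf("img_%05d.png", k),
        species_id = sprintf("synthsp_%02d", sample.int(20, 1)),
        cf_primary = smp$cf_primary, cf_secondary = smp$cf_secondary,
        cl_primary = smp$cl_primary, cl_secondary = smp$cl_secondary,
        scheme_id = smp$scheme_id, split = smp$split,
        class_label = lb, stringsAsFactors = FALSE
      )
    }
  }
  manifest <- do.call(rbind, rows)
  structure(
    list(images = lapply(images, `[[`, "image"),
         samples = images,
         manifest = manifest, class_labels = class_labels, config = cfg,
         scheme = scheme),
    class = "synth_dataset"
  )
}

# stratified 70/20/10 split labels for one class of size n, shuffled
split_assignments <- function(n) {
  n_tr <- round(0.7 * n)
  n_va <- round(0.2 * n)
  n_te <- n - n_tr - n_va
  sample(c(rep("train", n_tr), rep("validation", n_va), rep("test", n_te)))
}

#' @export
print.synth_dataset <- function(x, ...) {
  cat(sprintf("Synthetic dataset: %d images, %d classes (%s), scheme %d %s\n",
              length(x$images), length(x$class_labels),
              paste(x$class_labels, collapse = ", "),
              x$scheme$scheme_id, x$scheme$target))
  print(table(x$manifest$class_label, x$manifest$split))
  invisible(x)
}

#' Pixel-vote oracle label
#'
#' Majority primary-color label over a region's pixels, mapped through the
#' reference matrix with [classify_pixels()]. Serves as an independent check
#' that synthetic images are labeled recoverably.
#'
#' @param image S x S x 3 array in `[0, 1]`.
#' @param mask logical S x S region mask.
#' @param scheme a [color_scheme()].
#' @return the majority label over the region.
#' @export
pixel_vote <- function(image, mask, scheme) {
  px <- cbind(image[, , 1][mask], image[, , 2][mask], image[, , 3][mask])
  labs <- classify_pixels(scheme, px)
  names(which.max(table(labs)))
}

#' Write a synthetic dataset to disk
#'
#' Writes each image as PNG plus a `manifest.csv` in `dir`.
#'
#' @param ds a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(ds$images)) {
    png::writePNG(ds$images[[i]], file.path(dir, ds$manifest$filename[i]))
  }
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(ds$manifest, path, row.names = FALSE)
  invisible(path)
}
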