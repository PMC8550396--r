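# Experiment orchestration: dataset reading, label-space derivation from
# (scheme, target, use_secondary, commutativity), training of the required
# classifier(s), fusion, validation TPR tables for the ensembles, and test
# evaluation.

#' Experiment configuration
#'
#' @param scheme_id color scheme, 1 or 2.
#' @param target `"CF"` (flower) or `"CL"` (labellum).
#' @param use_secondary classify primary+secondary combinations instead of
#'   primaries only.
#' @param commutativity treat `AB` and `BA` as one label (the standard
#'   label space); `FALSE` switches to the ordered ablation label space.
#' @param classifier one of `"multiclass"`, `"binary_m1"` (one-vs-rest
#'   logical merge), `"binary_m2"` (max probability),
#'   `"ensemble_mltc"`, `"ensemble_mlcr"`.
#' @param backbone registered backbone name.
#' @param train a [train_config()].
#' @param synth a [synth_config()] used when no dataset is supplied.
#' @param data optional dataset: a [generate_dataset()] result or a
#'   manifest CSV path readable by [read_dataset()].
#' @export
experiment_config <- function(scheme_id = 1, target = c("CF", "CL"),
                              use_secondary = FALSE, commutativity = TRUE,
                              classifier = c("multiclass", "binary_m1",
                                             "binary_m2", "ensemble_mltc",
                                             "ensemble_mlcr"),
                              backbone = "tinycnn",
                              train = train_config(),
                              synth = synth_config(),
                              data = NULL) {
  structure(
    list(scheme_id = scheme_id, target = match.arg(target),
         use_secondary = use_secondary, commutativity = commutativity,
         classifier = match.arg(classifier), backbone = backbone,
         train = train, synth = synth, data = data),
    class = "experiment_config"
  )
}

#' Read an experiment configuration from YAML
#'
#' Top-level keys mirror the [experiment_config()] arguments; `train` and
#' `synth` are nested maps passed to [train_config()] / [synth_config()].
#'
#' @param path YAML file.
#' @export
read_experiment_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[setdiff(names(y), c("train", "synth"))]
  if (!is.null(y$train)) args$train <- do.call(train_config, y$train)
  if (!is.null(y$synth)) args$synth <- do.call(synth_config, y$synth)
  do.call(experiment_config, args)
}

#' Read a dataset from a manifest
#'
#' Reads `manifest.csv` (columns filename, species_id, cf_primary,
#' cf_secondary, cl_primary, cl_secondary, scheme_id, split, ...) and the
#' referenced PNG/JPEG images. Labels are validated against the configured
#' scheme; offending rows are reported by line number.
#'
#' @param manifest_path path to the manifest CSV.
#' @param scheme a [color_scheme()] to validate CF labels against (its
#'   CL counterpart validates the CL labels); `NULL` skips validation.
#' @param images_dir directory of the image files; defaults to the
#'   manifest's directory.
#' @return list with `images` (list of arrays) and `manifest`.
#' @export
read_dataset <- function(manifest_path, scheme = NULL,
                         images_dir = dirname(manifest_path)) {
  manifest <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  req <- c("filename", "cf_primary", "cl_primary", "split")
  if (length(miss <- setdiff(req, names(manifest)))) {
    stop("manifest lacks column(s): ", paste(miss, collapse = ", "))
  }
  if (!is.null(scheme)) {
    sch_cf <- if (scheme$target == "CF") scheme else
      color_scheme(scheme$scheme_id, "CF", scheme$matrix)
    sch_cl <- if (scheme$target == "CL") scheme else
      color_scheme(scheme$scheme_id, "CL", scheme$matrix)
    errs <- character(0)
    for (i in seq_len(nrow(manifest))) {
      for (side in c("cf", "cl")) {
        sch <- if (side == "cf") sch_cf else sch_cl
        p <- manifest[[paste0(side, "_primary")]][i]
        s <- manifest[[paste0(side, "_secondary")]][i]
        if (is.null(s) || is.na(s) || s == "") s <- p
        if (!p %in% sch$primaries || !s %in% sch$primaries) {
          errs <- c(errs, sprintf("row %d: unknown %s label '%s'",
                                  i, toupper(side),
                                  if (p %in% sch$primaries) s else p))
        } else if (canonical_name(p, s) %in% sch$excluded_combinations) {
          errs <- c(errs, sprintf("row %d: excluded %s combination %s",
                                  i, toupper(side), canonical_name(p, s)))
        }
      }
    }
    if (length(errs)) {
      stop("invalid manifest rows:\n", paste(errs, collapse = "\n"))
    }
  }
  paths <- file.path(images_dir, manifest$filename)
  missing <- !file.exists(paths)
  if (any(missing)) {
    stop("missing image file(s): ",
         paste(utils::head(manifest$filename[missing], 5), collapse = ", "))
  }
  images <- lapply(paths, function(p) {
    img <- png::readPNG(p)
    if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
    img[, , 1:3, drop = FALSE]
  })
  list(images = images, manifest = manifest)
}

# class label of each manifest row under the experiment's label space
record_labels <- function(manifest, target, use_secondary, commutative) {
  p <- manifest[[paste0(tolower(target), "_primary")]]
  s <- manifest[[paste0(tolower(target), "_secondary")]]
  s[is.na(s) | s == ""] <- p[is.na(s) | s == ""]
  if (!use_secondary) return(p)
  if (commutative) {
    mapply(canonical_name, p, s, USE.NAMES = FALSE)
  } else {
    ifelse(p == s, p, paste0(p, s))
  }
}

#' Run a full color-classification experiment
#'
#' Derives the label space from the configuration, obtains a dataset
#' (supplied, read from a manifest, or generated synthetically), trains the
#' classifier(s) the requested fusion strategy needs -- one multi-class
#' model and/or one binary head per label -- computes validation-split TPR
#' tables when an ensemble is requested, evaluates on the test split and
#' returns a metrics report. Fully seeded via the training configuration.
#'
#' @param cfg an [experiment_config()].
#' @return object of class `experiment_report`.
#' @export
run_experiment <- function(cfg) {
  scheme <- color_scheme(cfg$scheme_id, cfg$target)
  labels <- scheme_labels(scheme, use_secondary = cfg$use_secondary,
                          commutative = cfg$commutativity)
  m <- length(labels)

  ds <- cfg$data
  if (is.null(ds)) {
    synth <- cfg$synth
    synth$use_secondary <- cfg$use_secondary
    if (!cfg$commutativity) {
      stop("synthetic generation for the non-commutative ablation label ",
           "space is not supported; supply a dataset")
    }
    ds <- generate_dataset(synth, scheme)
  } else if (is.character(ds)) {
    ds <- read_dataset(ds, scheme)
  }
  manifest <- ds$manifest
  y <- record_labels(manifest, cfg$target, cfg$use_secondary,
                     cfg$commutativity)
  if (length(bad <- setdiff(unique(y), labels))) {
    stop("dataset contains labels outside the label space: ",
         paste(bad, collapse = ", "))
  }
  idx_tr <- manifest$split == "train"
  idx_va <- manifest$split == "validation"
  idx_te <- manifest$split == "test"

  need_multi <- cfg$classifier %in% c("multiclass", "ensemble_mltc",
                                      "ensemble_mlcr")
  need_bin <- cfg$classifier %in% c("binary_m1", "binary_m2",
                                    "ensemble_mltc", "ensemble_mlcr")
  bin_labels <- if (cfg$classifier == "binary_m1") labels[-m] else labels

  models <- list()
  if (need_multi) {
    conf <- cfg$train
    models$multiclass <- color_classifier(
      ds$images[idx_tr], y[idx_tr], backbone = cfg$backbone,
      labels = labels,
      validation = list(images = ds$images[idx_va], y = y[idx_va]),
      config = conf
    )
  }
  if (need_bin) {
    models$binary <- list()
    for (i in seq_along(bin_labels)) {
      conf <- cfg$train
      conf$seed <- conf$seed + i
      models$binary[[bin_labels[i]]] <- color_classifier(
        ds$images[idx_tr], as.integer(y[idx_tr] == bin_labels[i]),
        backbone = cfg$backbone, activation = "sigmoid", config = conf
      )
    }
  }

  bin_probs <- function(idx) {
    vapply(bin_labels,
           function(lb) predict_proba(models$binary[[lb]], ds$images[idx]),
           numeric(sum(idx)))
  }
  multi_labels <- function(idx) {
    P <- predict_proba(models$multiclass, ds$images[idx])
    labels[max.col(P, ties.method = "first")]
  }
  m2_labels <- function(idx) {
    P <- bin_probs(idx)
    apply(P, 1, function(p) merge_max_probability(p, labels = labels))
  }

  report <- list(
    classifier = cfg$classifier, scheme_id = cfg$scheme_id,
    target = cfg$target, use_secondary = cfg$use_secondary,
    commutativity = cfg$commutativity,
    label_space = labels,
    n = c(train = sum(idx_tr), validation = sum(idx_va), test = sum(idx_te))
  )
  truths <- y[idx_te]

  preds <- switch(cfg$classifier,
    multiclass = multi_labels(idx_te),
    binary_m1 = {
      P <- bin_probs(idx_te)
      apply(P, 1, function(p) {
        merge_one_vs_rest(as.integer(p > 0.5), labels)$label
      })
    },
    binary_m2 = m2_labels(idx_te),
    ensemble_mltc = ,
    ensemble_mlcr = {
      t1 <- compute_tpr_table(multi_labels(idx_va), y[idx_va], "C1",
                              labels = labels)
      t2 <- compute_tpr_table(m2_labels(idx_va), y[idx_va], "C2",
                              labels = labels)
      l1 <- multi_labels(idx_te)
      l2 <- m2_labels(idx_te)
      report$tpr_tables <- list(C1 = t1, C2 = t2)
      report$disagreements <- sum(l1 != l2)
      fun <- if (cfg$classifier == "ensemble_mltc") ensemble_mltc else ensemble_mlcr
      mapply(function(a, b) fun(a, b, t1, t2), l1, l2, USE.NAMES = FALSE)
    }
  )

  cm <- confusion(truths, preds, labels = labels)
  report$confusion <- cm
  report$accuracy <- accuracy(cm)
  report$macro_f1 <- macro_f1(cm)
  if (cfg$classifier == "binary_m1") {
    report$accuracy_incl_excl <-
      accuracy_with_without_inconsistent(truths, preds)
  }
  report$predictions <- preds
  report$truths <- truths
  report$models <- models
  structure(report, class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("Experiment: %s, scheme %d %s, %s%s\n", x$classifier,
              x$scheme_id, x$target,
              if (x$use_secondary) "primary+secondary" else "primary only",
              if (x$commutativity) "" else " (non-commutative ablation)"))
  cat(sprintf("  label space (%d): %s\n", length(x$label_space),
              paste(x$label_space, collapse = ", ")))
  cat(sprintf("  split sizes: train %d / validation %d / test %d\n",
              x$n["train"], x$n["validation"], x$n["test"]))
  cat(sprintf("  test accuracy %.4f, macro-F1 %.4f\n",
              x$accuracy, x$macro_f1))
  if (!is.null(x$accuracy_incl_excl)) {
    cat(sprintf("  accuracy incl. inconsistent %.4f / without %.4f\n",
                x$accuracy_incl_excl["include"],
                x$accuracy_incl_excl["without"]))
  }
  if (!is.null(x$disagreements)) {
    cat(sprintf("  base-classifier disagreements on test set: %d\n",
                x$disagreements))
  }
  invisible(x)
}

#' Write an experiment report
#'
#' Writes `report.json` (metrics, label space, TPR tables, disagreements)
#' and `confusion.csv` into `dir`.
#'
#' @param report an [run_experiment()] result.
#' @param dir output directory.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  obj <- list(
    classifier = report$classifier, scheme_id = report$scheme_id,
    target = report$target, use_secondary = report$use_secondary,
    commutativity = report$commutativity,
    label_space = report$label_space, n = as.list(report$n),
    accuracy = report$accuracy, macro_f1 = report$macro_f1
  )
  if (!is.null(report$accuracy_incl_excl)) {
    obj$accuracy_include_inconsistent <- report$accuracy_incl_excl[["include"]]
    obj$accuracy_without_inconsistent <- report$accuracy_incl_excl[["without"]]
  }
  if (!is.null(report$disagreements)) obj$disagreements <- report$disagreements
  if (!is.null(report$tpr_tables)) {
    obj$tpr_tables <- lapply(report$tpr_tables, function(t) as.list(t$tpr))
  }
  jsonlite::write_json(obj, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_confusion_csv(report$confusion, file.path(dir, "confusion.csv"))
  invisible(file.path(dir, "report.json"))
}
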