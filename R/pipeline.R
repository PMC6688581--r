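#' The feature registry
#'
#' Canonical ordered catalogue of every feature the extraction modules emit,
#' with its family (protein vs RNA, sequence vs structure) and units.
#' Registry order fixes all tie-breaking in ranking and selection, and the
#' family column drives the ablation masks.
#'
#' @return A data.frame with columns `name`, `family` (one of `protein_seq`,
#'   `protein_struct`, `rna_seq`, `rna_struct`), `units`, `description`.
#' @export
feature_registry <- function() {
  reg <- rbind(
    c("protein_molecular_mass", "protein_seq", "Da", "summed residue molecular weights"),
    c("hbond_total", "protein_seq", "count", "total hydrogen-bonding capacity"),
    c("n_hydrophilic", "protein_seq", "count", "hydrophilic residues"),
    c("n_hydrophobic", "protein_seq", "count", "hydrophobic residues"),
    c("n_aromatic_positive", "protein_seq", "count", "aromatic or positively charged residues"),
    c("n_charged", "protein_seq", "count", "charged residues"),
    c("n_polar", "protein_seq", "count", "polar residues"),
    c("pct_hydrophilic", "protein_seq", "%", "hydrophilic residue percentage"),
    c("pct_hydrophobic", "protein_seq", "%", "hydrophobic residue percentage"),
    c("pct_aromatic_positive", "protein_seq", "%", "aromatic/positive residue percentage"),
    c("pct_charged", "protein_seq", "%", "charged residue percentage"),
    c("pct_polar", "protein_seq", "%", "polar residue percentage"),
    c("helix_count", "protein_struct", "count", "alpha-helix residues (DSSP H/G/I)"),
    c("sheet_count", "protein_struct", "count", "beta-sheet residues (DSSP E/B)"),
    c("helix_mass", "protein_struct", "Da", "summed masses of helix residues"),
    c("sheet_mass", "protein_struct", "Da", "summed masses of sheet residues"),
    c("helix_pct", "protein_struct", "%", "helix residue percentage"),
    c("sheet_pct", "protein_struct", "%", "sheet residue percentage"),
    c("helix_segments", "protein_struct", "count", "contiguous helix segments (auxiliary)"),
    c("sheet_segments", "protein_struct", "count", "contiguous sheet segments (auxiliary)"),
    c("total_rasa", "protein_struct", "A^2", "summed solvent-accessible surface area"),
    c("rna_molecular_mass", "rna_seq", "Da", "RNA mass from base composition"),
    c("mfe_frequency", "rna_struct", "probability", "Boltzmann frequency of the MFE structure"),
    c("ensemble_diversity", "rna_struct", "dimensionless", "expected base-pair distance"),
    c("cww_count", "rna_struct", "count", "cis Watson-Crick base pairs"),
    c("cww_relative_frequency", "rna_struct", "fraction", "cWW pairs / annotated pairs"),
    c("bph0_count", "rna_struct", "count", "0BPh base-phosphate interactions"),
    c("bph0_relative_frequency", "rna_struct", "fraction", "0BPh / annotated base-phosphate")
  )
  out <- as.data.frame(reg, stringsAsFactors = FALSE)
  names(out) <- c("name", "family", "units", "description")
  out
}

#' Pipeline run configuration
#'
#' @param gbrt A [gbrt_config()].
#' @param class_mode `"per_class"` trains one model per RNA class;
#'   `"pooled"` trains a single model on all complexes.
#' @param feature_mask `"all"`, `"protein_only"`, `"rna_only"`,
#'   `"sequence_only"`, `"structure_only"`, or an explicit character vector
#'   of feature names.
#' @param top_n Size of the ranked candidate pool for greedy selection.
#' @param tol Improvement tolerance for greedy selection.
#' @param min_class_n Classes with fewer usable complexes are skipped.
#' @param seed Master seed recorded for the run.
#' @return A `run_config` list.
#' @export
run_config <- function(gbrt = gbrt_config(), class_mode = c("per_class", "pooled"),
                       feature_mask = "all", top_n = 10, tol = 1e-4,
                       min_class_n = 3, seed = 1L) {
  class_mode <- match.arg(class_mode)
  structure(list(gbrt = gbrt, class_mode = class_mode,
                 feature_mask = feature_mask, top_n = top_n, tol = tol,
                 min_class_n = min_class_n, seed = as.integer(seed)),
            class = "run_config")
}

resolve_feature_mask <- function(mask, feature_names, families = NULL) {
  if (length(mask) > 1 || !mask %in% c("all", "protein_only", "rna_only",
                                       "sequence_only", "structure_only")) {
    sel <- intersect(mask, feature_names)
    if (!length(sel)) stop("feature mask resolves to an empty set")
    return(sel)
  }
  if (is.null(families)) {
    reg <- feature_registry()
    families <- setNames(reg$family, reg$name)
  }
  fam <- families[feature_names]
  keep <- switch(mask,
    all = rep(TRUE, length(feature_names)),
    protein_only = fam %in% c("protein_seq", "protein_struct"),
    rna_only = fam %in% c("rna_seq", "rna_struct"),
    sequence_only = fam %in% c("protein_seq", "rna_seq"),
    structure_only = fam %in% c("protein_struct", "rna_struct")
  )
  keep[is.na(keep)] <- FALSE
  sel <- feature_names[keep]
  if (!length(sel)) stop("feature mask '", mask, "' resolves to an empty set")
  sel
}

#' Extract the feature table for a manifest of complexes
#'
#' The manifest is the single entry point of the pipeline: one row per
#' complex with columns `complex_id`, `pdb` (path), and optionally `dssp`,
#' `rnafold`, `rnaview` (paths to tool outputs), plus any affinity/class
#' columns which are carried through untouched elsewhere.  Missing or
#' unreadable tool outputs degrade gracefully: the corresponding
#' structure-derived columns become `NA` with a warning.
#'
#' @param manifest Data.frame as above, or path to a manifest TSV.
#' @param base_dir Directory that relative paths are resolved against.
#' @return A data.frame with `complex_id` followed by all registry features,
#'   one row per manifest row.
#' @export
extract_features <- function(manifest, base_dir = ".") {
  if (is.character(manifest)) manifest <- utils::read.delim(manifest, stringsAsFactors = FALSE)
  if (!all(c("complex_id", "pdb") %in% names(manifest))) {
    stop("manifest needs complex_id and pdb columns")
  }
  reg <- feature_registry()
  rows <- lapply(seq_len(nrow(manifest)), function(r) {
    row <- manifest[r, ]
    path <- function(col) {
      if (!col %in% names(row) || is.na(row[[col]]) || !nzchar(row[[col]])) return(NULL)
      p <- row[[col]]
      if (!file.exists(p)) p <- file.path(base_dir, row[[col]])
      if (!file.exists(p)) return(NULL)
      p
    }
    pdb_path <- path("pdb")
    if (is.null(pdb_path)) stop("manifest row ", r, " (", row$complex_id,
                                "): PDB file not found")
    cs <- validate_complex(parse_complex(readLines(pdb_path), row$complex_id))
    seqs <- extract_sequences(cs)
    protein_seq <- paste(seqs$protein, collapse = "")

    dssp_path <- path("dssp")
    ssr <- NULL
    if (!is.null(dssp_path)) {
      ssr <- parse_dssp(readLines(dssp_path))
    } else {
      warning(row$complex_id, ": no DSSP output; protein structure features are NA")
    }
    prot <- protein_feature_block(protein_seq, ssr)

    ensemble <- NULL
    rf_path <- path("rnafold")
    if (!is.null(rf_path)) {
      ensemble <- parse_rnafold_output(readLines(rf_path))
    } else {
      warning(row$complex_id, ": no RNAfold output; ensemble features are NA")
    }
    bpr <- NULL
    rv_path <- path("rnaview")
    if (!is.null(rv_path)) {
      bpr <- parse_rnaview_output(readLines(rv_path), sum(nchar(seqs$rna)))
    } else {
      warning(row$complex_id, ": no RNAVIEW output; base-pair features are NA")
    }
    rna <- rna_feature_block(seqs$rna, ensemble, bpr)
    c(prot, rna)
  })
  mat <- do.call(rbind, rows)
  out <- data.frame(complex_id = manifest$complex_id, mat,
                    stringsAsFactors = FALSE, row.names = NULL)
  stopifnot(all(reg$name %in% names(out)))
  out[, c("complex_id", reg$name)]
}

#' Train per-class affinity models with feature selection
#'
#' For each RNA class (or for the pooled set): ranks candidate features by
#' single-feature LOOCV correlation, runs greedy forward selection over the
#' top-ranked pool, fits the final GBRT model on the selected features, and
#' reports LOOCV metrics.  Rows with missing values in candidate features
#' are dropped with a logged count; classes with fewer than `min_class_n`
#' usable complexes are skipped with a warning.
#'
#' @param features Feature table (`complex_id` + feature columns).
#' @param affinity Affinity table with `complex_id` and `delta_g_kcal_mol`
#'   (see [read_affinity_table()]).
#' @param classes Class labels: a data.frame with `complex_id` and
#'   `rna_class`, or a named vector.  Ignored in pooled mode.
#' @param config A [run_config()].
#' @param families Optional named family vector for non-registry features
#'   (e.g. synthetic benchmarks); defaults to the registry.
#' @return A `prbind_training` object: list of per-class results, each with
#'   `class`, `n`, `complex_ids`, `ranked`, `selected`, `trajectory`,
#'   `model` (a `gbrt_model`), and `report` (predictions and metrics).
#' @export
run_training <- function(features, affinity, classes = NULL,
                         config = run_config(), families = NULL) {
  stopifnot(inherits(config, "run_config"))
  dat <- merge(features, affinity[, c("complex_id", "delta_g_kcal_mol")],
               by = "complex_id", sort = FALSE)
  feat_names <- setdiff(names(features), "complex_id")
  feat_names <- resolve_feature_mask(config$feature_mask, feat_names, families)

  if (config$class_mode == "pooled") {
    groups <- list(pooled = seq_len(nrow(dat)))
  } else {
    cls <- class_vector(classes, dat$complex_id)
    groups <- split(seq_len(nrow(dat)), cls)
  }

  results <- list()
  for (g in names(groups)) {
    ix <- groups[[g]]
    sub <- dat[ix, , drop = FALSE]
    keep <- stats::complete.cases(sub[, feat_names, drop = FALSE]) &
      !is.na(sub$delta_g_kcal_mol)
    if (any(!keep)) {
      warning("class ", g, ": dropping ", sum(!keep), " row(s) with missing values")
      sub <- sub[keep, , drop = FALSE]
    }
    if (nrow(sub) < config$min_class_n) {
      warning("class ", g, ": only ", nrow(sub),
              " usable complexes; skipping (need >= ", config$min_class_n, ")")
      next
    }
    X <- as.matrix(sub[, feat_names, drop = FALSE])
    y <- sub$delta_g_kcal_mol
    ranked <- rank_features(X, y, config = config$gbrt, top_n = config$top_n)
    sel <- greedy_select(X, y, ranked, config = config$gbrt, tol = config$tol)
    model <- fit_gbrt(X[, sel$selected, drop = FALSE], y, config$gbrt)
    metrics <- tryCatch(evaluation_metrics(sel$predictions, y),
                        error = function(e) list(pearson_r = NA_real_,
                                                 mae = mae(sel$predictions, y),
                                                 r2 = NA_real_, n = length(y)))
    results[[g]] <- list(
      class = g, n = nrow(sub), complex_ids = sub$complex_id,
      ranked = ranked, selected = sel$selected, trajectory = sel$trajectory,
      model = model,
      report = c(list(predictions = data.frame(
        complex_id = sub$complex_id, actual = y, predicted = sel$predictions,
        stringsAsFactors = FALSE)), metrics)
    )
  }
  if (!length(results)) stop("no class had enough usable complexes to train")
  structure(list(results = results, config = config), class = "prbind_training")
}

class_vector <- function(classes, complex_ids) {
  if (is.null(classes)) stop("per-class training needs class labels")
  if (is.data.frame(classes)) {
    cls <- setNames(as.character(classes$rna_class), classes$complex_id)
  } else {
    cls <- classes
  }
  out <- cls[complex_ids]
  if (anyNA(out)) {
    stop("missing class label for: ",
         paste(complex_ids[is.na(out)], collapse = ", "))
  }
  out
}

#' Predict affinities with trained per-class models
#'
#' @param training A `prbind_training` from [run_training()].
#' @param features Feature table with the selected features (no missing
#'   values among them).
#' @param classes Class labels (as in [run_training()]); ignored when the
#'   training was pooled.
#' @return A data.frame `complex_id`, `rna_class`, `predicted_delta_g`.
#' @export
run_predict <- function(training, features, classes = NULL) {
  stopifnot(inherits(training, "prbind_training"))
  pooled <- training$config$class_mode == "pooled"
  cls <- if (pooled) rep("pooled", nrow(features)) else class_vector(classes, features$complex_id)
  preds <- numeric(nrow(features))
  for (r in seq_len(nrow(features))) {
    res <- training$results[[cls[r]]]
    if (is.null(res)) stop("no trained model for class '", cls[r], "' (row ",
                           features$complex_id[r], ")")
    x <- features[r, res$selected, drop = FALSE]
    if (anyNA(x)) stop("missing selected feature value(s) for ", features$complex_id[r])
    preds[r] <- predict(res$model, x)
  }
  data.frame(complex_id = features$complex_id, rna_class = cls,
             predicted_delta_g = preds, stringsAsFactors = FALSE)
}

#' Feature-mask ablation study
#'
#' Re-runs training under each feature mask (`all`, `protein_only`,
#' `rna_only`, `sequence_only`, `structure_only`) and tabulates the LOOCV
#' metrics per class and mask, reproducing the protein-vs-RNA and
#' sequence-vs-structure contrast experiments.
#'
#' @inheritParams run_training
#' @param masks Masks to compare.
#' @return A data.frame `class`, `mask`, `n`, `n_selected`, `pearson_r`,
#'   `mae`, `r2`.
#' @export
run_ablation <- function(features, affinity, classes = NULL,
                         config = run_config(), families = NULL,
                         masks = c("all", "protein_only", "rna_only",
                                   "sequence_only", "structure_only")) {
  out <- list()
  for (mk in masks) {
    cfg <- config
    cfg$feature_mask <- mk
    tr <- run_training(features, affinity, classes, cfg, families = families)
    for (res in tr$results) {
      out[[length(out) + 1L]] <- data.frame(
        class = res$class, mask = mk, n = res$n,
        n_selected = length(res$selected),
        pearson_r = res$report$pearson_r, mae = res$report$mae,
        r2 = res$report$r2, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Summarise a training run
#'
#' @param training A `prbind_training`.
#' @return A data.frame with one row per class: `class`, `n`, `n_selected`,
#'   `selected` (comma-joined), `pearson_r`, `mae`, `r2`.
#' @export
training_summary <- function(training) {
  stopifnot(inherits(training, "prbind_training"))
  do.call(rbind, lapply(training$results, function(res) {
    data.frame(class = res$class, n = res$n, n_selected = length(res$selected),
               selected = paste(res$selected, collapse = ","),
               pearson_r = res$report$pearson_r, mae = res$report$mae,
               r2 = res$report$r2, stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Write a training report to disk
#'
#' Writes per-complex LOOCV predictions as TSV and a JSON summary (metrics,
#' selected features, selection trajectory, configuration) per class.
#'
#' @param training A `prbind_training`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_training_report <- function(training, dir) {
  stopifnot(inherits(training, "prbind_training"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  preds <- do.call(rbind, lapply(training$results, function(res) {
    cbind(class = res$class, res$report$predictions)
  }))
  tsv <- file.path(dir, "loocv_predictions.tsv")
  utils::write.table(preds, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  summary_doc <- lapply(training$results, function(res) {
    list(class = res$class, n = res$n, selected = res$selected,
         trajectory = res$trajectory,
         metrics = list(pearson_r = res$report$pearson_r,
                        mae = res$report$mae, r2 = res$report$r2))
  })
  js <- file.path(dir, "training_summary.json")
  jsonlite::write_json(list(config = unclass(training$config)[c("class_mode",
                                                                "feature_mask",
                                                                "top_n", "tol",
                                                                "seed")],
                            gbrt = unclass(training$config$gbrt),
                            classes = summary_doc),
                       js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}
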