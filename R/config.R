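#' Full pipeline configuration
#'
#' Nested configuration covering every stage, with the reference
#' hyperparameters as defaults: learning rate 0.0001 with exponential
#' decay (253 steps, rate 0.96), dropout 0.6, patience 10, max 100
#' epochs, 5 folds, probability threshold 0.5, IoU gate 0.5, 7
#' self-training rounds with erosion in the first 4, augmentation
#' multipliers 7.0 (big) / 1.3 (small) and the stated transform
#' probabilities. Round-trips losslessly through YAML.
#'
#' @param phantom a [phantom_spec()].
#' @param model a [resunet_config()].
#' @param train a [train_config()].
#' @param selftrain a [selftrain_config()].
#' @param augment an [augmentation_policy()].
#' @param run_dir run output directory.
#' @param master_seed master seed for the whole pipeline.
#' @param log_level one of `"quiet"`, `"info"`.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(phantom = phantom_spec(),
                            model = resunet_config(),
                            train = train_config(),
                            selftrain = selftrain_config(),
                            augment = augmentation_policy(),
                            run_dir = "runs/default",
                            master_seed = 1L,
                            log_level = "info") {
  structure(list(phantom = phantom, model = model, train = train,
                 selftrain = selftrain, augment = augment,
                 run_dir = run_dir, master_seed = as.integer(master_seed),
                 log_level = match.arg(log_level, c("quiet", "info"))),
            class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config a [pipeline_config()].
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  plain <- lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML path written by [write_config()].
#' @return a [pipeline_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  rebuild <- function(vals, ctor) do.call(ctor, vals[names(vals) %in% names(formals(ctor))])
  cfg <- pipeline_config(
    phantom = rebuild(y$phantom, phantom_spec),
    model = rebuild(y$model, resunet_config),
    train = rebuild(y$train, train_config),
    selftrain = rebuild(y$selftrain, selftrain_config),
    augment = rebuild(y$augment, augmentation_policy),
    run_dir = y$run_dir %||% "runs/default",
    master_seed = y$master_seed %||% 1L,
    log_level = y$log_level %||% "info")
  cfg
}

#' Generate and write a phantom dataset (CLI backend)
#'
#' @param config a [pipeline_config()]; `config$phantom` is the
#'   template and `config$master_seed` the master seed.
#' @param out_dir output directory.
#' @param n_volumes number of volumes.
#' @param contrast_range per-volume tube-intensity range.
#' @return the manifest path, invisibly.
#' @export
cmd_phantom <- function(config, out_dir, n_volumes = 4L,
                        contrast_range = c(0.15, 0.35)) {
  samples <- generate_dataset(n_volumes, config$phantom, contrast_range,
                              seed = config$master_seed)
  write_phantom_dataset(samples, out_dir)
}

#' Preprocess volumes and weak masks into a slice dataset (CLI backend)
#'
#' Reads aligned NIfTI volume/mask files, applies the preprocessing
#' chain (isotropic resampling, 8-bit quantization, unit
#' normalization), builds pseudo-RGB slice pairs for every slice with
#' a non-empty weak mask, and persists them with a JSON index.
#'
#' @param config a [pipeline_config()].
#' @param volume_paths,mask_paths equal-length vectors of NIfTI paths.
#' @param out_dir output directory.
#' @return the index path, invisibly.
#' @export
cmd_prepare <- function(config, volume_paths, mask_paths, out_dir) {
  if (length(volume_paths) != length(mask_paths)) {
    stopf("cmd_prepare: %d volumes but %d masks", length(volume_paths), length(mask_paths))
  }
  missing <- !file.exists(mask_paths)
  if (any(missing)) {
    stopf("cmd_prepare: missing mask file(s) for volume(s): %s",
          paste(basename(volume_paths[missing]), collapse = ", "))
  }
  samples <- lapply(seq_along(volume_paths), function(i) {
    v <- read_volume(volume_paths[i])
    m <- read_volume(mask_paths[i], mask = TRUE)
    v <- resample_isotropic(v, 1.0, kind = "image")
    m <- resample_isotropic(m, 1.0, kind = "mask")
    if (!identical(dim(v$data), dim(m$data))) {
      stopf("cmd_prepare: volume %s and mask %s disagree after resampling (%s vs %s)",
            basename(volume_paths[i]), basename(mask_paths[i]),
            paste(dim(v$data), collapse = "x"), paste(dim(m$data), collapse = "x"))
    }
    v <- normalize_unit(quantize_to_8bit(v))
    list(volume = v, mask = m, volume_id = tools::file_path_sans_ext(
      basename(volume_paths[i]), compression = TRUE))
  })
  pairs <- build_slice_dataset(samples)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  index <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    f <- sprintf("pair_%05d.csv", i)  # flat text payload, see below
    save_pair_text(p, file.path(out_dir, f))
    list(file = f, volume_id = p$volume_id, slice_index = p$slice_index,
         provenance = p$provenance)
  })
  ip <- file.path(out_dir, "index.json")
  jsonlite::write_json(index, ip, auto_unbox = TRUE, digits = NA)
  invisible(ip)
}

# Pairs are persisted as plain-text CSV (header row of dims, then the
# image channels and mask flattened column-major), keeping every
# artifact greppable and platform-neutral.
save_pair_text <- function(pair, path) {
  d <- dim(pair$image)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# H=%d W=%d", d[1], d[2]), con)
  utils::write.table(
    data.frame(image = as.vector(pair$image), mask_rep = rep(as.vector(pair$mask), 3L)),
    con, row.names = FALSE, sep = ",")
  invisible(path)
}

load_pair_text <- function(path, volume_id, slice_index, provenance = "bbox") {
  hdr <- readLines(path, n = 1L)
  dims <- as.integer(regmatches(hdr, gregexpr("[0-9]+", hdr))[[1]])
  tab <- utils::read.csv(path, skip = 1L)
  img <- array(tab$image, c(dims[1], dims[2], 3L))
  msk <- matrix(tab$mask_rep[seq_len(dims[1] * dims[2])], dims[1], dims[2])
  slice_pair(img, msk, volume_id, slice_index, provenance)
}

#' Run the self-training pipeline from a phantom directory (CLI backend)
#'
#' Loads a [cmd_phantom()] dataset, runs [run_pipeline()], and writes
#' round directories and the consolidated metrics CSV under
#' `config$run_dir`.
#'
#' @param config a [pipeline_config()].
#' @param data_dir directory written by [cmd_phantom()].
#' @return the [run_pipeline()] round states, invisibly.
#' @export
cmd_selftrain <- function(config, data_dir) {
  manifest <- jsonlite::read_json(file.path(data_dir, "manifest.json"))
  samples <- lapply(seq_along(manifest), function(i) {
    list(volume = read_volume(file.path(data_dir, sprintf("vol_%03d.nii.gz", i))),
         weak = read_volume(file.path(data_dir, sprintf("weak_%03d.nii.gz", i)),
                            mask = TRUE, provenance = "weak-bbox"),
         gt = read_volume(file.path(data_dir, sprintf("gt_%03d.nii.gz", i)),
                          mask = TRUE, provenance = "ground-truth"),
         volume_id = i)
  })
  rounds <- run_pipeline(samples, config$selftrain, config$train, config$model,
                         policy = config$augment, seed = config$master_seed,
                         run_dir = config$run_dir,
                         verbose = config$log_level == "info")
  invisible(rounds)
}

#' Evaluate predicted masks against ground-truth masks (CLI backend)
#'
#' Matches NIfTI files by name between the two directories, scores
#' every slice, and writes CSV and JSON reports.
#'
#' @param pred_dir,gt_dir directories of binary NIfTI masks with
#'   matching file names.
#' @param out_prefix path prefix for `<prefix>.csv` / `<prefix>.json`.
#' @return the [evaluate_masks()] report, invisibly.
#' @export
cmd_evaluate <- function(pred_dir, gt_dir, out_prefix) {
  pf <- sort(list.files(pred_dir, pattern = "\\.nii(\\.gz)?$"))
  gf <- sort(list.files(gt_dir, pattern = "\\.nii(\\.gz)?$"))
  orphans <- c(setdiff(pf, gf), setdiff(gf, pf))
  if (length(orphans) > 0) {
    stopf("cmd_evaluate: unmatched files: %s", paste(orphans, collapse = ", "))
  }
  preds <- list(); gts <- list(); ids <- character(0)
  for (f in pf) {
    pv <- read_volume(file.path(pred_dir, f), mask = TRUE)
    gv <- read_volume(file.path(gt_dir, f), mask = TRUE)
    for (k in seq_len(dim(pv$data)[1])) {
      preds[[length(preds) + 1L]] <- pv$data[k, , ]
      gts[[length(gts) + 1L]] <- gv$data[k, , ]
      ids <- c(ids, sprintf("%s_s%03d", f, k))
    }
  }
  report <- evaluate_masks(preds, gts, ids = ids)
  write_eval_report(report, paste0(out_prefix, ".csv"), paste0(out_prefix, ".json"))
  invisible(report)
}
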