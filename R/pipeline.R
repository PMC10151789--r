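#' Detect keypoints for a batch of annotation files
#'
#' The full pipeline over one file or a directory of files: load each
#' scene, match fruits to stems, estimate keypoints, and write
#' `<id>_pairs.json` plus `<id>_keypoints.json` into `out_dir`. A file that
#' fails to parse is reported with a warning and skipped; the batch
#' continues.
#'
#' @param input Path to one annotation file or a directory of `.json`
#'   files.
#' @param out_dir Output directory (created if needed).
#' @param dialect `"labelme"` or `"coco"`.
#' @param config A [match_config()].
#' @param label_map Passed to the loader.
#' @return Tibble summary: one row per input file with pair/keypoint
#'   counts and an `ok` flag.
#' @export
run_detect <- function(input, out_dir, dialect = c("labelme", "coco"),
                       config = match_config(), label_map = NULL) {
  dialect <- match.arg(dialect)
  files <- if (dir.exists(input)) {
    f <- list.files(input, pattern = "\\.json$", full.names = TRUE)
    f[basename(f) != "manifest.json"]
  } else input
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(files, function(fn) {
    res <- tryCatch({
      scene <- if (dialect == "labelme") load_labelme(fn, label_map)
               else load_coco(fn, image_id = coco_first_image_id(fn),
                              label_map = label_map)
      pairs <- match_scene(scene, config)
      kps <- keypoints_for_scene(scene, pairs)
      stub <- sub("\\.json$", "", basename(fn))
      jsonlite::write_json(pairs, file.path(out_dir, paste0(stub, "_pairs.json")),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      jsonlite::write_json(kps, file.path(out_dir, paste0(stub, "_keypoints.json")),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      tibble::tibble(file = basename(fn), n_pairs = nrow(pairs),
                     n_keypoints = nrow(kps), ok = TRUE)
    }, error = function(e) {
      warning(sprintf("skipping '%s': %s", fn, conditionMessage(e)),
              call. = FALSE)
      tibble::tibble(file = basename(fn), n_pairs = NA_integer_,
                     n_keypoints = NA_integer_, ok = FALSE)
    })
    res
  })
  dplyr::bind_rows(rows)
}

coco_first_image_id <- function(path) {
  js <- jsonlite::read_json(path)
  if (length(js$images) == 0) stop("COCO file lists no images", call. = FALSE)
  as.character(js$images[[1]]$id)
}

#' Evaluate predicted pairs against a ground-truth manifest
#'
#' Reads the `*_pairs.json` files written by [run_detect()] and the
#' `manifest.json` written by [generate_dataset()], compares them with
#' [match_confusion()], and returns precision/recall.
#'
#' @param pred_dir Directory holding `*_pairs.json` files.
#' @param manifest_path Path to the dataset `manifest.json`.
#' @return One-row tibble: tp, fp, fn, precision, recall.
#' @export
run_eval <- function(pred_dir, manifest_path) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  truth <- tibble::as_tibble(man$truth_pairs)
  pf <- list.files(pred_dir, pattern = "_pairs\\.json$", full.names = TRUE)
  pred <- dplyr::bind_rows(lapply(pf, function(f)
    tibble::as_tibble(jsonlite::read_json(f, simplifyVector = TRUE))))
  if (nrow(pred) == 0)
    pred <- tibble::tibble(image_id = character(), fruit_index = integer(),
                           stem_index = integer())
  if (is.null(truth) || length(truth) == 0 || nrow(truth) == 0)
    truth <- tibble::tibble(image_id = character(), fruit_index = integer(),
                            stem_index = integer())
  precision_recall(match_confusion(pred, truth))
}

#' Simulate a dataset of synthetic scenes
#'
#' Convenience wrapper around [scene_spec()] + [generate_dataset()]:
#' `n_scenes` scenes with per-scene seeds derived deterministically from
#' `seed`.
#'
#' @param out_dir Output directory.
#' @param n_scenes Number of scenes.
#' @param seed Base seed; scene `k` uses `seed * 1000 + k`.
#' @param dialect Annotation dialect to write.
#' @param ... Further arguments to [scene_spec()].
#' @return Manifest tibble, invisibly.
#' @export
run_simulate <- function(out_dir, n_scenes = 10, seed = 1L,
                         dialect = c("labelme", "coco"), ...) {
  dialect <- match.arg(dialect)
  specs <- lapply(seq_len(n_scenes), function(k)
    scene_spec(seed = seed * 1000L + k, ...))
  generate_dataset(specs, out_dir, dialect = dialect)
}

#' Refine a probability map stored as NPY
#'
#' Reads a coarse map, runs [refine()] with the given predictor (the
#' identity predictor by default, i.e. pure iterative upsampling), writes
#' the refined map as NPY, and optionally a 0.5-thresholded PNG mask.
#'
#' @param npy_in,npy_out Input and output NPY paths.
#' @param schedule A [refine_schedule()].
#' @param predictor Point predictor; see [refine()].
#' @param png_out Optional path for the thresholded binary PNG.
#' @return The refined matrix, invisibly.
#' @export
run_refine <- function(npy_in, npy_out, schedule = refine_schedule(),
                       predictor = identity_predictor, png_out = NULL) {
  coarse <- read_npy(npy_in)
  out <- refine(coarse, predictor, schedule)
  write_npy(out, npy_out)
  if (!is.null(png_out))
    png::writePNG((out >= 0.5) * 1, png_out)
  invisible(out)
}
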