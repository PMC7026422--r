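#' Read a per-frame detection submission file
#'
#' Submission files are whitespace-separated text, one box per line:
#' `<class_name> <confidence> <x1> <y1> <x2> <y2>`. Ground-truth annotation
#' files use the same dialect without the confidence column (set
#' `with_confidence = FALSE`). Empty files yield zero boxes.
#'
#' @param path Path to the text file.
#' @param catalog An [ead_catalog()]; class names outside the catalog are
#'   rejected with the offending line number.
#' @param with_confidence Whether the file carries a confidence column
#'   (`TRUE` for predictions, `FALSE` for references).
#' @return A box table (see [boxes_df()]), rows in reading order.
#' @export
read_detection_file <- function(path, catalog = ead_catalog(),
                                with_confidence = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  keep <- nzchar(lines)
  if (!any(keep)) return(empty_boxes())
  nfield <- if (with_confidence) 6L else 5L
  rows <- vector("list", sum(keep))
  j <- 0
  for (i in which(keep)) {
    parts <- strsplit(lines[i], "[[:space:]]+")[[1]]
    if (length(parts) != nfield)
      stop(path, " line ", i, ": expected ", nfield, " fields, got ",
           length(parts))
    cl <- parts[1]
    if (!cl %in% catalog$names)
      stop(path, " line ", i, ": unknown class '", cl, "'")
    num <- suppressWarnings(as.numeric(parts[-1]))
    if (any(is.na(num)))
      stop(path, " line ", i, ": non-numeric field")
    if (with_confidence) {
      conf <- num[1]; xy <- num[2:5]
      if (conf < 0 || conf > 1)
        stop(path, " line ", i, ": confidence ", conf, " outside [0, 1]")
    } else {
      conf <- NA_real_; xy <- num[1:4]
    }
    if (xy[3] <= xy[1] || xy[4] <= xy[2])
      stop(path, " line ", i, ": degenerate box")
    j <- j + 1
    rows[[j]] <- data.frame(class = cl, confidence = conf,
                            x1 = xy[1], y1 = xy[2], x2 = xy[3], y2 = xy[4],
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  validate_boxes(df, where = path)
  df
}

#' Write a box table to the canonical submission dialect
#'
#' Inverse of [read_detection_file()] on canonical-form files.
#'
#' @param boxes Box table from [boxes_df()].
#' @param path Output file path.
#' @param with_confidence Include the confidence column.
#' @return `path`, invisibly.
#' @export
write_detection_file <- function(boxes, path, with_confidence = TRUE) {
  fmt_num <- function(x) formatC(x, format = "g", digits = 15)
  lines <- if (nrow(boxes) == 0) character() else {
    if (with_confidence)
      paste(boxes$class, fmt_num(boxes$confidence), fmt_num(boxes$x1),
            fmt_num(boxes$y1), fmt_num(boxes$x2), fmt_num(boxes$y2))
    else
      paste(boxes$class, fmt_num(boxes$x1), fmt_num(boxes$y1),
            fmt_num(boxes$x2), fmt_num(boxes$y2))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a frame's per-class binary masks
#'
#' Expects one single-channel PNG per segmentation class, named
#' `<frame_id>_<class>.png`. Any pixel value > 0 is foreground, tolerating
#' both `{0, 1}` and `{0, 255}` dialects. A missing class file is imputed
#' as an all-zero mask of the common shape (logged via `message()`), so the
#' result always contains exactly the catalog's segmentation classes.
#'
#' @param dir Directory holding the mask images.
#' @param frame_id Frame identifier used in filenames.
#' @param catalog An [ead_catalog()].
#' @return Named list of 0/1 matrices, one per segmentation class.
#' @export
read_mask_set <- function(dir, frame_id, catalog = ead_catalog()) {
  classes <- catalog$segmentation_classes
  masks <- stats::setNames(vector("list", length(classes)), classes)
  shape <- NULL
  for (cl in classes) {
    f <- file.path(dir, paste0(frame_id, "_", cl, ".png"))
    if (!file.exists(f)) next
    img <- png::readPNG(f)
    if (length(dim(img)) == 3) img <- img[, , 1]
    m <- matrix(as.integer(img > 0), nrow(img), ncol(img))
    if (is.null(shape)) shape <- dim(m)
    else if (!identical(shape, dim(m)))
      stop("frame ", frame_id, ": mask '", cl, "' is ",
           paste(dim(m), collapse = "x"), ", expected ",
           paste(shape, collapse = "x"))
    masks[[cl]] <- m
  }
  if (is.null(shape))
    stop("frame ", frame_id, ": no mask files found in ", dir)
  missing <- classes[vapply(masks, is.null, logical(1))]
  if (length(missing)) {
    message("frame ", frame_id, ": no mask for ",
            paste(missing, collapse = ", "), "; scored as all-zero")
    for (cl in missing) masks[[cl]] <- matrix(0L, shape[1], shape[2])
  }
  masks
}

#' Write a frame's per-class masks as PNGs
#'
#' @param masks Named list of 0/1 matrices.
#' @param dir Output directory (created if needed).
#' @param frame_id Frame identifier used in filenames.
#' @return `dir`, invisibly.
#' @export
write_mask_set <- function(masks, dir, frame_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (cl in names(masks)) {
    m <- masks[[cl]]
    png::writePNG(matrix(as.numeric(m > 0), nrow(m), ncol(m)),
                  file.path(dir, paste0(frame_id, "_", cl, ".png")))
  }
  invisible(dir)
}

#' Read a directory of per-frame box files
#'
#' One file per frame named `<frame_id>.txt`. With `masks = TRUE`, each
#' frame's per-class mask PNGs are read from the same directory.
#'
#' @param dir Directory of `.txt` files (and mask PNGs).
#' @param catalog An [ead_catalog()].
#' @param with_confidence Passed to [read_detection_file()].
#' @param masks Also read segmentation masks.
#' @return Named list of [ead_frame()] objects keyed by frame id.
#' @export
read_frame_dir <- function(dir, catalog = ead_catalog(),
                           with_confidence = TRUE, masks = FALSE) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  frames <- list()
  for (f in files) {
    id <- sub("\\.txt$", "", basename(f))
    bx <- read_detection_file(f, catalog, with_confidence = with_confidence)
    mk <- NULL; sz <- NULL
    if (masks) {
      mk <- read_mask_set(dir, id, catalog)
      sz <- dim(mk[[1]])
    }
    frames[[id]] <- ead_frame(id, bx, masks = mk, image_size = sz)
  }
  frames
}

#' Align a submission against ground truth
#'
#' Report-only check: ground-truth frames missing from the submission are
#' scored as empty predictions (the challenge scored non-submission as
#' failure, keeping denominators fixed); submission frames absent from the
#' ground truth are ignored with a warning entry.
#'
#' @param sub Named list of submission frames.
#' @param gt Named list of ground-truth frames.
#' @return A list with character vectors `missing` (in gt, not in sub;
#'   scored empty), `ignored` (in sub, not in gt) and `ok` (scored frames).
#' @export
validate_submission <- function(sub, gt) {
  gt_ids <- names(gt); sub_ids <- names(sub)
  list(missing = setdiff(gt_ids, sub_ids),
       ignored = setdiff(sub_ids, gt_ids),
       ok = intersect(gt_ids, sub_ids))
}

# Align sub to gt: missing frames become empty predictions, extras dropped.
align_submission <- function(sub, gt, catalog = ead_catalog(),
                             masks = FALSE) {
  out <- list()
  for (id in names(gt)) {
    if (!is.null(sub[[id]])) {
      out[[id]] <- sub[[id]]
    } else {
      mk <- NULL; sz <- gt[[id]]$image_size
      if (masks && !is.null(sz)) {
        mk <- lapply(stats::setNames(catalog$segmentation_classes,
                                     catalog$segmentation_classes),
                     function(cl) matrix(0L, sz[1], sz[2]))
      }
      out[[id]] <- ead_frame(id, empty_boxes(), masks = mk, image_size = sz)
    }
  }
  out
}

#' Default evaluation configuration
#'
#' @return A list with the class catalog, the IoU match threshold (0.25),
#'   detection score weights (0.6 mAP, 0.4 IoU), segmentation score
#'   weights (0.75 on the F1/Jaccard mean, 0.25 on F2), the generalization
#'   deviation tolerance (0.1), consensus settings (strict majority,
#'   IoU 0.25) and the random seed.
#' @export
default_config <- function() {
  list(classes = ead_catalog()$names,
       segmentation_classes = ead_catalog()$segmentation_classes,
       iou_thresh = 0.25,
       detection_weights = list(map = 0.6, iou = 0.4),
       segmentation_weights = list(overlap = 0.75, f2 = 0.25),
       generalization_tol = 0.1,
       consensus = list(min_fraction = 0.5, iou_thresh = 0.25),
       empty_value = 1,
       seed = 1L)
}

#' Read a YAML configuration file
#'
#' Fields present in the file override [default_config()]; all others keep
#' their defaults.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_config <- function(path) {
  cfg <- default_config()
  user <- yaml::read_yaml(path)
  utils::modifyList(cfg, user)
}
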