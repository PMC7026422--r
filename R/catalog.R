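#' Class catalog for artefact evaluation
#'
#' A catalog fixes the set of artefact class labels in scope: the full
#' detection set and the subset that carries pixel-level masks for the
#' segmentation task. The number of detection classes is the `N` used when
#' averaging per-class generalization deviations.
#'
#' @param names Character vector of unique class identifiers, in catalog
#'   order.
#' @param detection_classes Subset of `names` scored for detection.
#'   Defaults to all of `names`.
#' @param segmentation_classes Subset of `detection_classes` scored for
#'   segmentation (classes with binary mask annotations).
#' @return An object of class `ead_catalog` with elements `names`,
#'   `detection_classes`, `segmentation_classes` and `N` (number of
#'   detection classes).
#' @examples
#' cat7 <- ead_catalog()
#' cat7$N                       # 7
#' cat7$segmentation_classes    # 5 classes, blur and contrast excluded
#' @export
ead_catalog <- function(names = c("specularity", "saturation", "artefact",
                                  "blur", "contrast", "bubbles", "instrument"),
                        detection_classes = names,
                        segmentation_classes = setdiff(names, c("blur", "contrast"))) {
  names <- as.character(names)
  if (anyDuplicated(names))
    stop("class names must be unique")
  if (!all(detection_classes %in% names))
    stop("detection_classes must be a subset of names")
  if (!all(segmentation_classes %in% detection_classes))
    stop("segmentation_classes must be a subset of detection_classes")
  structure(
    list(names = names,
         detection_classes = as.character(detection_classes),
         segmentation_classes = as.character(segmentation_classes),
         N = length(detection_classes)),
    class = "ead_catalog")
}

#' @export
print.ead_catalog <- function(x, ...) {
  cat("<ead_catalog> ", length(x$names), " classes\n", sep = "")
  cat("  detection (", x$N, "): ",
      paste(x$detection_classes, collapse = ", "), "\n", sep = "")
  cat("  segmentation (", length(x$segmentation_classes), "): ",
      paste(x$segmentation_classes, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Construct a bounding-box table
#'
#' Boxes use 0-based pixel coordinates with half-open extent
#' `[x1, x2) x [y1, y2)`, so `area = (x2 - x1) * (y2 - y1)` and a box is
#' degenerate when `x2 <= x1` or `y2 <= y1`. Reference (ground-truth) boxes
#' carry `NA` confidence.
#'
#' @param class Character vector of class labels.
#' @param x1,y1,x2,y2 Numeric vectors of corner coordinates (pixels);
#'   `(x1, y1)` top-left, `(x2, y2)` bottom-right.
#' @param confidence Numeric vector in `[0, 1]`, or `NA` for references.
#' @return A `data.frame` with columns `class`, `confidence`, `x1`, `y1`,
#'   `x2`, `y2`.
#' @examples
#' boxes_df("specularity", 10, 10, 20, 20, confidence = 0.9)
#' @export
boxes_df <- function(class = character(), x1 = numeric(), y1 = numeric(),
                     x2 = numeric(), y2 = numeric(), confidence = NA_real_) {
  df <- data.frame(class = as.character(class),
                   confidence = as.numeric(confidence),
                   x1 = as.numeric(x1), y1 = as.numeric(y1),
                   x2 = as.numeric(x2), y2 = as.numeric(y2),
                   stringsAsFactors = FALSE)
  validate_boxes(df)
  df
}

validate_boxes <- function(df, where = "boxes") {
  if (nrow(df) == 0) return(invisible(df))
  if (any(!is.finite(df$x1) | !is.finite(df$y1) |
          !is.finite(df$x2) | !is.finite(df$y2)))
    stop(where, ": box coordinates must be finite")
  if (any(df$x1 < 0 | df$y1 < 0))
    stop(where, ": box coordinates must be >= 0")
  bad <- df$x2 <= df$x1 | df$y2 <= df$y1
  if (any(bad))
    stop(where, ": degenerate box (x2 <= x1 or y2 <= y1) at row ",
         which(bad)[1])
  conf <- df$confidence[!is.na(df$confidence)]
  if (length(conf) && any(conf < 0 | conf > 1))
    stop(where, ": confidence outside [0, 1]")
  invisible(df)
}

empty_boxes <- function() {
  data.frame(class = character(), confidence = numeric(),
             x1 = numeric(), y1 = numeric(),
             x2 = numeric(), y2 = numeric(), stringsAsFactors = FALSE)
}

#' Bundle one frame's annotations or predictions
#'
#' A frame holds a box table and, for segmentation, one binary mask per
#' class. The same spatial location may carry several class labels
#' (multi-label regions are the norm in endoscopy artefacts), so masks of
#' different classes may overlap freely.
#'
#' @param frame_id Frame identifier (string).
#' @param boxes Box table from [boxes_df()].
#' @param masks Named list of 0/1 matrices (`height x width`), one per
#'   segmentation class, or `NULL` when masks are not used.
#' @param image_size Integer `c(height, width)` in pixels; required when
#'   masks are present or boxes must be bounds-checked.
#' @return An object of class `ead_frame`.
#' @export
ead_frame <- function(frame_id, boxes = empty_boxes(), masks = NULL,
                      image_size = NULL) {
  if (!is.null(image_size)) {
    image_size <- as.integer(image_size)
    if (length(image_size) != 2 || any(image_size <= 0))
      stop("image_size must be positive c(height, width)")
    if (nrow(boxes) &&
        any(boxes$x2 > image_size[2] | boxes$y2 > image_size[1]))
      stop("frame ", frame_id, ": box exceeds image bounds")
  }
  if (!is.null(masks)) {
    if (is.null(image_size))
      stop("image_size required when masks are given")
    for (cl in names(masks)) {
      m <- masks[[cl]]
      if (!identical(dim(m), as.integer(image_size)))
        stop("frame ", frame_id, ": mask '", cl,
             "' shape differs from image_size")
      if (!all(m %in% c(0, 1)))
        stop("frame ", frame_id, ": mask '", cl, "' has values outside {0,1}")
    }
  }
  structure(list(frame_id = as.character(frame_id), boxes = boxes,
                 masks = masks, image_size = image_size),
            class = "ead_frame")
}

#' @export
print.ead_frame <- function(x, ...) {
  cat("<ead_frame> ", x$frame_id, ": ", nrow(x$boxes), " boxes",
      if (!is.null(x$masks)) paste0(", ", length(x$masks), " masks"),
      if (!is.null(x$image_size))
        paste0(", ", x$image_size[1], "x", x$image_size[2]),
      "\n", sep = "")
  invisible(x)
}
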