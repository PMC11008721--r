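#' YOLO-format label file reading and writing
#'
#' One box per line: `class cx cy w h [conf]`, whitespace separated, all box
#' fields normalized to [0, 1] relative to the image size. The single-class
#' setting uses class id 0 throughout. Corner boxes use the package's
#' continuous pixel frame: x1 = (cx - w/2) * W, etc.
#'
#' @name yolo_io
NULL

#' Read a YOLO label file into pixel-corner detections
#'
#' Malformed lines (wrong field count, non-numeric values, normalized values
#' outside [0, 1]) are rejected with their line number.
#'
#' @param path label file path
#' @param image_w,image_h image size in pixels used to denormalize
#' @return data.frame with columns class, x1, y1, x2, y2, conf (1 when the
#'   file has no confidence column); empty file gives an empty frame
#' @export
read_yolo_labels <- function(path, image_w, image_h) {
  stopifnot(image_w > 0, image_h > 0)
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  out <- data.frame(class = integer(0), x1 = numeric(0), y1 = numeric(0),
                    x2 = numeric(0), y2 = numeric(0), conf = numeric(0))
  for (i in which(keep)) {
    fields <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (!length(fields) %in% c(5L, 6L))
      stop("line ", i, ": expected 5 or 6 fields, got ", length(fields))
    vals <- suppressWarnings(as.numeric(fields))
    if (any(is.na(vals)))
      stop("line ", i, ": non-numeric field")
    if (any(vals[2:5] < 0 | vals[2:5] > 1))
      stop("line ", i, ": normalized value outside [0, 1]")
    cx <- vals[2] * image_w; cy <- vals[3] * image_h
    w <- vals[4] * image_w; h <- vals[5] * image_h
    out <- rbind(out, data.frame(
      class = as.integer(vals[1]),
      x1 = cx - w / 2, y1 = cy - h / 2, x2 = cx + w / 2, y2 = cy + h / 2,
      conf = if (length(vals) == 6L) vals[6] else 1))
  }
  out
}

#' Write detections to a YOLO label file
#'
#' Coordinates are normalized by the image size and written with 6 decimals,
#' so a read-back round trip agrees within 1e-6 of the normalized value. A
#' confidence column is emitted when `dets$conf` is present and not all 1.
#'
#' @param dets data.frame with x1, y1, x2, y2 and optional conf, class
#' @param image_w,image_h image size in pixels
#' @param path output path
#' @param clip clip boxes to the image instead of erroring when they extend
#'   outside it
#' @return `path`, invisibly
#' @export
write_yolo_labels <- function(dets, image_w, image_h, path, clip = FALSE) {
  dets <- as.data.frame(dets)
  if (nrow(dets) == 0L) { writeLines(character(0), path); return(invisible(path)) }
  if (clip) {
    dets$x1 <- pmax(dets$x1, 0); dets$y1 <- pmax(dets$y1, 0)
    dets$x2 <- pmin(dets$x2, image_w); dets$y2 <- pmin(dets$y2, image_h)
  } else if (any(dets$x1 < 0 | dets$y1 < 0 |
                 dets$x2 > image_w | dets$y2 > image_h)) {
    stop("box outside image; use clip = TRUE to clip")
  }
  cls <- if (!is.null(dets$class)) dets$class else rep(0L, nrow(dets))
  cx <- (dets$x1 + dets$x2) / 2 / image_w
  cy <- (dets$y1 + dets$y2) / 2 / image_h
  w <- (dets$x2 - dets$x1) / image_w
  h <- (dets$y2 - dets$y1) / image_h
  with_conf <- !is.null(dets$conf) && !all(dets$conf == 1)
  lines <- if (with_conf)
    sprintf("%d %.6f %.6f %.6f %.6f %.6f", cls, cx, cy, w, h, dets$conf)
  else sprintf("%d %.6f %.6f %.6f %.6f", cls, cx, cy, w, h)
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a crop-row fit to the report JSON dialect
#'
#' @param fit a [fit_crop_rows()] object
#' @param image image identifier echoed into the report
#' @param path output JSON path; NULL returns the list without writing
#' @return the report list, invisibly when written
#' @export
write_fit_json <- function(fit, image = "", path = NULL) {
  line_rec <- function(l, gaps) list(m = l$m, b = l$b, form = l$form,
                                     n_points = l$n_points,
                                     flagged = gaps$flagged)
  rep_list <- list(
    image = image,
    rows = list(line_rec(fit$lines$left, fit$gaps$left),
                line_rec(fit$lines$right, fit$gaps$right)),
    nav = list(mc = fit$nav$mc, bc = fit$nav$bc, xi = fit$nav$xi,
               yi = fit$nav$yi, parallel = fit$nav$parallel),
    config = fit$config)
  if (is.null(path)) return(rep_list)
  jsonlite::write_json(rep_list, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(rep_list)
}
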