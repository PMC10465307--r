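# COCO-format dataset I/O: PNG images plus a single JSON with images /
# annotations / categories, one category "berry". Masks are stored as
# uncompressed column-major run-length encodings (the COCO RLE convention:
# counts alternate runs of 0s and 1s, starting with the 0 run).

#' Run-length encode a binary mask (COCO uncompressed RLE)
#'
#' @param mask logical or 0/1 matrix (H x W); runs are taken down columns.
#' @return list with `size = c(H, W)` and integer `counts`.
#' @export
rle_encode <- function(mask) {
  v <- as.integer(mask)
  r <- rle(v)
  counts <- r$lengths
  if (length(v) && r$values[1] == 1L) counts <- c(0L, counts)
  if (!length(v)) counts <- integer()
  list(size = dim(mask), counts = as.integer(counts))
}

#' Decode a COCO uncompressed RLE to a logical mask
#'
#' @param rle list with `size` and `counts` as produced by [rle_encode()].
#' @return H x W logical matrix.
#' @export
rle_decode <- function(rle) {
  counts <- as.integer(rle$counts)
  vals <- rep(c(0L, 1L), length.out = length(counts))
  v <- rep(vals, counts)
  size <- as.integer(rle$size)
  if (length(v) != prod(size))
    stop("rle_decode: counts do not cover the mask size")
  matrix(as.logical(v), size[1], size[2])
}

rle_area <- function(rle) {
  counts <- as.integer(rle$counts)
  if (!length(counts)) return(0L)
  sum(counts[seq(2L, length(counts), by = 2L)])
}

#' Write scenes as a COCO dataset
#'
#' Images are written as PNG files and annotations as a single COCO JSON
#' (0-based `[x, y, width, height]` boxes, visible-pixel areas, uncompressed
#' RLE masks). The round trip through [read_coco_dataset()] reproduces counts
#' and areas exactly.
#'
#' @param scenes non-empty list of `synthetic_scene` objects.
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list (paths plus the COCO structure).
#' @export
write_coco_dataset <- function(scenes, out_dir) {
  if (!length(scenes)) stop("write_coco_dataset: empty scene list")
  if (inherits(scenes, "synthetic_scene")) scenes <- list(scenes)
  dir.create(file.path(out_dir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("write_coco_dataset: cannot create ", out_dir)
  images <- list()
  annotations <- list()
  ann_id <- 0L
  for (k in seq_along(scenes)) {
    sc <- scenes[[k]]
    fn <- sprintf("img_%05d.png", k)
    png::writePNG(sc$image / 255, file.path(out_dir, "images", fn))
    images[[k]] <- list(id = k, file_name = fn,
                        height = nrow(sc$owner), width = ncol(sc$owner))
    inst <- sc$instances
    for (j in seq_len(nrow(inst))) {
      ann_id <- ann_id + 1L
      seg <- rle_encode(instance_mask(sc, j))
      annotations[[ann_id]] <- list(
        id = ann_id, image_id = k, category_id = 1L,
        bbox = c(inst$x[j], inst$y[j], inst$w[j], inst$h[j]),
        area = inst$area[j],
        segmentation = list(size = as.integer(seg$size), counts = seg$counts),
        iscrowd = 0L)
    }
  }
  coco <- list(images = images, annotations = annotations,
               categories = list(list(id = 1L, name = "berry")))
  json_path <- file.path(out_dir, "annotations.json")
  jsonlite::write_json(coco, json_path, auto_unbox = TRUE, digits = NA)
  invisible(list(dir = out_dir, json = json_path, coco = coco))
}

#' Read a COCO dataset written by this package
#'
#' @param path dataset directory (containing `annotations.json`) or a path to
#'   the JSON itself.
#' @return list with `images`, `annotations`, `categories` (lists of records)
#'   and `dir` (the dataset directory, for locating image files).
#' @export
read_coco_dataset <- function(path) {
  json <- if (dir.exists(path)) file.path(path, "annotations.json") else path
  if (!file.exists(json)) stop("read_coco_dataset: no annotations at ", path)
  coco <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  coco$dir <- dirname(json)
  coco
}

#' Load one dataset image as an array
#'
#' @param coco value of [read_coco_dataset()].
#' @param image_id image record id.
#' @return H x W x 3 array in 0-255.
#' @export
coco_load_image <- function(coco, image_id) {
  rec <- Find(function(im) im$id == image_id, coco$images)
  if (is.null(rec)) stop("coco_load_image: no image with id ", image_id)
  img <- png::readPNG(file.path(coco$dir, "images", rec$file_name))
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}

# Per-image ground-truth lists (corner boxes, areas, masks) from a COCO read.
coco_ground_truth <- function(coco, image_id, masks = TRUE) {
  anns <- Filter(function(a) a$image_id == image_id, coco$annotations)
  if (!length(anns))
    return(list(boxes = matrix(numeric(), 0, 4), areas = numeric(),
                masks = list()))
  bb <- do.call(rbind, lapply(anns, function(a) unlist(a$bbox)))
  boxes <- cbind(x1 = bb[, 1], y1 = bb[, 2],
                 x2 = bb[, 1] + bb[, 3], y2 = bb[, 2] + bb[, 4])
  list(boxes = boxes,
       areas = vapply(anns, function(a) as.numeric(a$area), numeric(1)),
       masks = if (masks) lapply(anns, function(a) rle_decode(a$segmentation))
               else NULL)
}
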