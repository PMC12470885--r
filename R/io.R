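# Dataset readers / writers.

#' Describe an on-disk dataset
#'
#' The expected layout is `root/<split>/images/` and `root/<split>/masks/`
#' with image/mask pairs sharing a file stem.  PNG is read natively; TIFF
#' and JPEG are read through the tiff / EBImage packages when present.
#'
#' @param root dataset root directory.
#' @return object of class `"dataset_layout"`.
#' @export
dataset_layout <- function(root) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  splits <- intersect(c("train", "val", "test"), list.dirs(root,
                                                           full.names = FALSE,
                                                           recursive = FALSE))
  if (!length(splits)) stop("no train/val/test subdirectories under ", root)
  structure(list(root = root, splits = splits), class = "dataset_layout")
}

img_exts <- c("png", "jpg", "jpeg", "tif", "tiff")

read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    jpg = ,
    jpeg = {
      if (!requireNamespace("EBImage", quietly = TRUE))
        stop("reading JPEG requires the 'EBImage' package")
      img <- EBImage::readImage(path)
      a <- EBImage::imageData(img)
      # EBImage stores (x, y[, c]); transpose to (row, col[, c])
      if (length(dim(a)) == 2) t(a) else aperm(a, c(2, 1, 3))
    },
    stop("unsupported image format: ", ext)
  )
  if (is.matrix(x)) x <- array(rep(x, 3), c(dim(x), 3))
  if (dim(x)[3] > 3) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3] == 1) x <- array(rep(x[, , 1], 3), c(dim(x)[1:2], 3))
  x
}

read_mask <- function(path) {
  x <- read_image(path)
  m <- x[, , 1]
  # 8-bit masks are binarised at 128 (0.5 on the unit scale)
  (m >= 0.5) * 1
}

#' Load image/mask pairs for one split
#'
#' Pairs are matched by shared file stem; a missing or surplus mask is an
#' error naming the offending stem.  Masks are binarised at 128 (8-bit
#' scale).
#'
#' @param layout a [dataset_layout()].
#' @param split one of `"train"`, `"val"`, `"test"`.
#' @return list of `list(image, mask, stem)` entries.
#' @export
load_pairs <- function(layout, split) {
  stopifnot(inherits(layout, "dataset_layout"))
  if (!split %in% layout$splits)
    stop("split '", split, "' not present in dataset")
  img_dir <- file.path(layout$root, split, "images")
  msk_dir <- file.path(layout$root, split, "masks")
  imgs <- list.files(img_dir, pattern = paste0("\\.(",
                                               paste(img_exts,
                                                     collapse = "|"),
                                               ")$"),
                     ignore.case = TRUE)
  if (!length(imgs)) stop("no images found under ", img_dir)
  msks <- list.files(msk_dir)
  msk_stems <- tools::file_path_sans_ext(msks)
  lapply(imgs, function(f) {
    stem <- tools::file_path_sans_ext(f)
    j <- match(stem, msk_stems)
    if (is.na(j))
      stop("no mask found for image stem '", stem, "'")
    list(image = read_image(file.path(img_dir, f)),
         mask = read_mask(file.path(msk_dir, msks[j])),
         stem = stem)
  })
}

#' Write a binary mask as an 8-bit PNG (foreground = 255)
#' @param mask binary matrix.
#' @param path output file.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(as.matrix(mask) * 1, path)
  invisible(path)
}
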