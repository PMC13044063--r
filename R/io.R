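#' Read an image file into an H x W x 3 array
#'
#' Decodes PNG/JPEG/TIFF via EBImage into row-major H x W x 3 with values in
#' \[0, 1\] (8-bit files are divided by 255 on read). Grayscale files are
#' replicated across channels; alpha channels are dropped.
#'
#' @param path Image file path.
#' @return H x W x 3 numeric array in \[0, 1\].
#' @export
read_image <- function(path) {
  img <- EBImage::readImage(path)
  dat <- EBImage::imageData(img)
  if (length(dim(dat)) == 2) {
    dat <- array(rep(dat, 3L), dim = c(dim(dat), 3L))
  }
  if (dim(dat)[3] > 3) dat <- dat[, , 1:3, drop = FALSE]
  # EBImage stores x (width) first; internal convention is rows first
  out <- aperm(dat, c(2, 1, 3))
  pmin(pmax(out, 0), 1)
}

#' Write an H x W x 3 array (or H x W mask) to an image file
#'
#' RGB arrays are written as colour PNG/JPEG; binary masks as single-channel
#' images with foreground 1 mapped to white (255).
#'
#' @param image H x W x 3 array in \[0, 1\], or an H x W matrix (e.g. a mask).
#' @param path Output path; format inferred from the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  if (length(dim(image)) == 3) {
    out <- EBImage::Image(aperm(image, c(2, 1, 3)), colormode = "Color")
  } else {
    out <- EBImage::Image(t(image))
  }
  EBImage::writeImage(out, path)
  invisible(path)
}

#' Load a class-folder image tree as a dataset tibble
#'
#' Expects `root/<class>/<image files>`; folder names become class labels,
#' files are decoded to \[0, 1\] arrays in deterministic (sorted) order.
#' Unreadable files are skipped with a warning, mirroring the curation step
#' that drops corrupted captures.
#'
#' @param root Directory with one subdirectory per class.
#' @return A tibble with `sample_id`, `class` (factor over the folder names),
#'   `image` (list-column), `path`.
#' @export
load_image_folder <- function(root) {
  if (!dir.exists(root)) {
    abort(paste0("Directory not found: ", root), class = "garlicnet_error_io")
  }
  classes <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  classes <- classes[classes != ""]
  if (length(classes) == 0) {
    abort("`root` contains no class subdirectories.",
          class = "garlicnet_error_io")
  }
  rows <- purrr::map(classes, function(cl) {
    files <- sort(list.files(file.path(root, cl),
                             pattern = "\\.(png|jpg|jpeg|tif|tiff)$",
                             ignore.case = TRUE, full.names = TRUE))
    imgs <- purrr::map(files, function(f) {
      tryCatch(read_image(f), error = function(e) {
        warn(paste0("Skipping unreadable image: ", f))
        NULL
      })
    })
    ok <- !purrr::map_lgl(imgs, is.null)
    tibble::tibble(
      sample_id = tools::file_path_sans_ext(basename(files[ok])),
      class = cl,
      image = imgs[ok],
      path = files[ok]
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    abort("No readable images found under `root`.",
          class = "garlicnet_error_io")
  }
  out$class <- factor(out$class, levels = classes)
  out
}
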