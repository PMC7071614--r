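# Readers/writers for images, labels, displacement fields, affine
# parameters and dataset manifests. Intensities are normalized to [0, 1]
# at load so the loss weights keep their stated meaning; labels are never
# rescaled.

img_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") return("png")
  if (ext %in% c("tif", "tiff")) return("tiff")
  stop("unsupported image format: ", path)
}

to_gray <- function(x) {
  if (length(dim(x)) == 2) return(x)
  if (length(dim(x)) == 3) {
    nc <- dim(x)[3]
    if (nc == 1) return(x[, , 1])
    # luminance reduction; an alpha channel, if present, is ignored
    return(0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3])
  }
  stop("unsupported image array")
}

#' Read an intensity image
#'
#' Reads a PNG or TIFF image as a numeric matrix scaled to \[0, 1\] from
#' its native bit depth; multi-channel images are reduced by luminance.
#'
#' @param path File path.
#' @return Numeric H x W matrix in \[0, 1\].
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("read_image: no such file: ", path)
  x <- switch(img_format(path),
    png = png::readPNG(path),
    tiff = suppressWarnings(tiff::readTIFF(path)))
  to_gray(x)
}

#' Write an intensity image
#'
#' PNG is written at 8 bits; TIFF at the requested bit depth (8, 16, or
#' 32-bit float). Values must lie in \[0, 1\].
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param path Destination (.png, .tif/.tiff).
#' @param bits Bit depth for TIFF output.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, bits = 8) {
  image <- pmin(pmax(as.matrix(image), 0), 1)
  switch(img_format(path),
    png = png::writePNG(image, path),
    tiff = tiff::writeTIFF(image, path, bits.per.sample = as.integer(bits)))
  invisible(path)
}

#' Read an integer label image
#'
#' Label values are preserved exactly (never rescaled). TIFF labels are
#' read with their raw integer codes; 8-bit PNG labels are decoded back to
#' 0..255. Floating-point label files are rejected.
#'
#' @param path File path.
#' @return Integer H x W matrix.
#' @export
read_label <- function(path) {
  if (!file.exists(path)) stop("read_label: no such file: ", path)
  fmt <- img_format(path)
  if (fmt == "tiff") {
    x <- suppressWarnings(tiff::readTIFF(path, as.is = TRUE, info = TRUE))
    bps <- attr(x, "bits.per.sample")
    if (isTRUE(bps == 32) || (is.double(x) && any(x != round(x)))) {
      stop("read_label: floating-point label file: ", path)
    }
  } else {
    x <- round(png::readPNG(path) * 255)
  }
  storage.mode(x) <- "integer"
  to_int_matrix(x)
}

to_int_matrix <- function(x) {
  if (length(dim(x)) == 3) x <- x[, , 1]
  matrix(as.integer(x), nrow(x), ncol(x)) # plain matrix, no file metadata
}

#' Write an integer label image
#'
#' Stored losslessly as 16-bit TIFF (labels up to 65535) or 8-bit PNG
#' (labels up to 255).
#'
#' @param label Non-negative integer matrix.
#' @param path Destination (.tif/.tiff preferred, .png for labels < 256).
#' @return `path`, invisibly.
#' @export
write_label <- function(label, path) {
  label <- as.matrix(label)
  if (any(label < 0) || any(label != round(label))) {
    stop("write_label: labels must be non-negative integers")
  }
  if (img_format(path) == "tiff") {
    if (max(label) > 65535) stop("write_label: label value > 65535")
    tiff::writeTIFF(label / 65535, path, bits.per.sample = 16L)
  } else {
    if (max(label) > 255) stop("write_label: PNG labels limited to 255")
    png::writePNG(label / 255, path)
  }
  invisible(path)
}

#' Serialize a displacement field
#'
#' The two displacement channels are written as a 32-bit float TIFF
#' (affinely encoded into \[0, 1\]) with a JSON sidecar recording the
#' encoding range and the coordinate convention (normalized \[-1, 1\]
#' align-corners grid, channels (dx, dy), backward warping).
#'
#' @param field A [dense_field()].
#' @param path Destination TIFF; the sidecar is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  field <- as_dense_field(field)
  lo <- min(field); hi <- max(field)
  if (hi == lo) hi <- lo + 1
  enc <- (unclass(field) - lo) / (hi - lo)
  tiff::writeTIFF(enc, path, bits.per.sample = 32L)
  jsonlite::write_json(list(
    format = "dualreg-field-1",
    height = nrow(field), width = ncol(field),
    channels = c("dx", "dy"),
    encoding = list(lo = lo, hi = hi),
    coordinates = "normalized [-1,1], align-corners, backward warping"),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$format, "dualreg-field-1")) {
    stop("read_field: unrecognized field file")
  }
  enc <- suppressWarnings(tiff::readTIFF(path))
  d <- enc * (meta$encoding$hi - meta$encoding$lo) + meta$encoding$lo
  dense_field(d[, , 1], d[, , 2])
}

#' Serialize affine parameters as JSON
#'
#' @param p An [affine_params()].
#' @param path Destination JSON file.
#' @return `path` / the read `affine_params`.
#' @export
write_affine_json <- function(p, path) {
  p <- as_affine_params(p)
  jsonlite::write_json(as.list(stats::setNames(as.numeric(p), names(p))),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_affine_json
#' @export
read_affine_json <- function(path) {
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_affine_params(unlist(v[c("a11", "a12", "a21", "a22", "tx", "ty")]))
}

#' Write a simulated dataset to disk
#'
#' Writes each pair's source/reference images (PNG), labels (TIFF),
#' ground-truth field (float TIFF) and affine (JSON) under `dir`, plus a
#' `manifest.json` listing every record with its split tag and the
#' generating deformation spec.
#'
#' @param dataset A `synthetic_dataset` from [make_dataset()].
#' @param dir Output directory (created if missing).
#' @param spec The [deformation_spec()] used (stored in the manifest).
#' @param seed The master seed used (stored in the manifest).
#' @return The manifest path, invisibly.
#' @export
write_dataset <- function(dataset, dir, spec = deformation_spec(),
                          seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  records <- lapply(seq_along(dataset$pairs), function(i) {
    p <- dataset$pairs[[i]]
    stem <- sprintf("pair_%04d", i)
    rec <- list(
      source_path = file.path(dir, paste0(stem, "_source.png")),
      reference_path = file.path(dir, paste0(stem, "_reference.png")),
      split = as.character(dataset$split[i]))
    write_image(p$source, rec$source_path)
    write_image(p$reference, rec$reference_path)
    if (!is.null(p$source_label)) {
      rec$source_label_path <- file.path(dir, paste0(stem, "_source_label.tif"))
      rec$reference_label_path <-
        file.path(dir, paste0(stem, "_reference_label.tif"))
      write_label(p$source_label, rec$source_label_path)
      write_label(p$reference_label, rec$reference_label_path)
    }
    if (!is.null(p$gt_field)) {
      rec$gt_field_path <- file.path(dir, paste0(stem, "_gt_field.tif"))
      write_field(p$gt_field, rec$gt_field_path)
      rec$gt_affine_path <- file.path(dir, paste0(stem, "_gt_affine.json"))
      write_affine_json(p$gt_affine, rec$gt_affine_path)
    }
    rec
  })
  manifest <- list(format = "dualreg-manifest-1", seed = seed,
                   spec = unclass(spec), records = records)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a dataset manifest
#'
#' Validates that every referenced file exists and that split tags are
#' train/val/test, then loads the pairs.
#'
#' @param path Path to a `manifest.json` written by [write_dataset()].
#' @return A `synthetic_dataset` (ground-truth fields are reloaded when
#'   present).
#' @export
read_dataset <- function(path) {
  man <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(man$format, "dualreg-manifest-1")) {
    stop("read_dataset: unrecognized manifest")
  }
  pairs <- lapply(man$records, function(rec) {
    for (f in grep("_path$", names(rec), value = TRUE)) {
      if (!file.exists(rec[[f]])) {
        stop("read_dataset: missing file: ", rec[[f]])
      }
    }
    if (!rec$split %in% c("train", "val", "test")) {
      stop("read_dataset: bad split tag: ", rec$split)
    }
    pr <- image_pair(
      read_image(rec$source_path), read_image(rec$reference_path),
      source_label = if (!is.null(rec$source_label_path)) {
        read_label(rec$source_label_path)
      },
      reference_label = if (!is.null(rec$reference_label_path)) {
        read_label(rec$reference_label_path)
      })
    if (!is.null(rec$gt_field_path)) {
      pr <- structure(c(pr, list(
        gt_field = read_field(rec$gt_field_path),
        gt_affine = read_affine_json(rec$gt_affine_path))),
        class = c("synthetic_pair", "image_pair"))
    }
    pr
  })
  split <- factor(vapply(man$records, `[[`, character(1), "split"),
                  levels = c("train", "val", "test"))
  structure(list(pairs = pairs, split = split),
            class = "synthetic_dataset")
}
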