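# Dataset I/O in YOLO text-label layout, stratified splitting, augmentation
# and letterbox preprocessing.
#
# Layout: <root>/images/*.png (or .jpg) with sibling <root>/labels/*.txt,
# one "class cx cy w h" line per box, all coordinates normalized to [0,1].

#' Construct a normalized annotation
#' @param class_id zero-based class index
#' @param cx,cy,w,h normalized center-format box
#' @return one-row data.frame
#' @export
annotation <- function(class_id, cx, cy, w, h) {
  if (w <= 0 || h <= 0) stop("annotation: box must have positive size")
  if (any(c(cx, cy, w, h) < 0) || any(c(cx, cy, w, h) > 1))
    stop("annotation: coordinates must lie in [0,1]")
  data.frame(class_id = as.integer(class_id), cx = cx, cy = cy, w = w, h = h)
}

empty_annotations <- function() {
  data.frame(class_id = integer(0), cx = numeric(0), cy = numeric(0),
             w = numeric(0), h = numeric(0))
}

#' Read one YOLO label file
#' @param path label text file
#' @return annotations data.frame; malformed lines collected in attribute
#'   `problems` with file and line numbers
#' @export
read_yolo_label <- function(path) {
  if (!file.exists(path)) return(empty_annotations())
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  anns <- empty_annotations()
  problems <- character(0)
  for (i in seq_along(lines)) {
    parts <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (length(parts) != 5L || any(is.na(parts))) {
      problems <- c(problems, sprintf("%s:%d: malformed line", path, i))
      next
    }
    anns <- rbind(anns, data.frame(class_id = as.integer(parts[1]),
                                   cx = parts[2], cy = parts[3],
                                   w = parts[4], h = parts[5]))
  }
  attr(anns, "problems") <- problems
  anns
}

#' Write annotations as a YOLO label file
#' @param anns annotations data.frame
#' @param path output file
#' @export
write_yolo_label <- function(anns, path) {
  lines <- sprintf("%d %.6f %.6f %.6f %.6f",
                   anns$class_id, anns$cx, anns$cy, anns$w, anns$h)
  writeLines(lines, path)
}

#' Read a YOLO-layout dataset into a manifest
#'
#' @param root dataset directory containing `images/` and `labels/`
#' @return a `dataset_manifest`: list of records (image path, size,
#'   annotations, split tag); unreadable images become record-level error
#'   entries rather than aborting
#' @export
read_yolo_dataset <- function(root) {
  img_dir <- file.path(root, "images")
  lbl_dir <- file.path(root, "labels")
  imgs <- sort(list.files(img_dir, pattern = "\\.(png|jpg|jpeg)$",
                          ignore.case = TRUE))
  records <- lapply(imgs, function(f) {
    p <- file.path(img_dir, f)
    stem <- tools::file_path_sans_ext(f)
    sz <- tryCatch(dim(read_image(p))[1:2], error = function(e) NULL)
    if (is.null(sz)) {
      return(list(image = p, error = "unreadable image",
                  annotations = empty_annotations(), split = NA_character_))
    }
    anns <- read_yolo_label(file.path(lbl_dir, paste0(stem, ".txt")))
    list(image = p, height = sz[1], width = sz[2], annotations = anns,
         split = NA_character_)
  })
  new_manifest(records)
}

new_manifest <- function(records) {
  structure(list(records = records), class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  tags <- manifest_splits(x)
  cat(sprintf("dataset_manifest: %d records (%s)\n", length(x$records),
              paste(sprintf("%s=%d", names(table(tags)), table(tags)),
                    collapse = ", ")))
  invisible(x)
}

manifest_splits <- function(m) {
  vapply(m$records, function(r) r$split %||% NA_character_, character(1))
}

# dominant (most frequent, ties to smallest id) class of a record
dominant_class <- function(r) {
  cls <- r$annotations$class_id
  if (!length(cls)) return(NA_integer_)
  tab <- table(cls)
  as.integer(names(tab)[which.max(tab)])
}

#' Stratified 7:2:1-style split
#'
#' Shuffles deterministically under the seed, stratifies by each record's
#' dominant class, and assigns per class `floor(ratio * n)` records to the
#' validation and test splits with all remainders going to train.
#'
#' @param m a `dataset_manifest`
#' @param ratios length-3 numeric (train, val, test) summing to 1
#' @param seed integer RNG seed
#' @return the manifest with populated split tags
#' @export
split_dataset <- function(m, ratios = c(0.7, 0.2, 0.1), seed = 0L) {
  if (abs(sum(ratios) - 1) > 1e-9) stop("split_dataset: ratios must sum to 1")
  cls <- vapply(m$records, dominant_class, integer(1))
  cls[is.na(cls)] <- -1L
  n <- length(m$records)
  tags <- rep("train", n)
  rng <- local_rng(seed)
  on.exit(restore_rng(rng))
  # global quotas floor(ratio * n), remainders to train; each quota is then
  # apportioned over the class strata by largest remainder, keeping every
  # stratum within one image of its proportional share
  classes <- sort(unique(cls))
  sizes <- vapply(classes, function(cl) sum(cls == cl), integer(1))
  if (any(sizes < 3L))
    warning("split_dataset: some class has fewer records than splits")
  nv <- largest_remainder(floor(ratios[2] * n), sizes)
  nt <- largest_remainder(floor(ratios[3] * n), sizes)
  for (k in seq_along(classes)) {
    idx <- which(cls == classes[k])
    idx <- idx[sample.int(length(idx))]
    if (nv[k] > 0L) tags[idx[seq_len(nv[k])]] <- "val"
    if (nt[k] > 0L) tags[idx[nv[k] + seq_len(nt[k])]] <- "test"
  }
  for (i in seq_along(m$records)) m$records[[i]]$split <- tags[i]
  m
}

# seed the RNG locally, restoring the caller's state afterwards
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

# ---- augmentation -----------------------------------------------------------

#' Augment an image and its boxes
#'
#' Geometric ops transform boxes consistently; photometric ops leave them
#' untouched.
#'
#' @param image H x W x 3 array in `[0,1]`
#' @param anns annotations data.frame
#' @param op one of `"hflip"`, `"vflip"`, `"contrast"`, `"gaussian_blur"`
#' @param params list: `factor` for contrast, `sigma` for blur
#' @param seed optional RNG seed for stochastic parameters
#' @return list(image, annotations)
#' @export
augment <- function(image, anns, op, params = list(), seed = NULL) {
  if (!is.null(seed)) { rng <- local_rng(seed); on.exit(restore_rng(rng)) }
  switch(op,
    hflip = {
      image <- image[, rev(seq_len(dim(image)[2])), , drop = FALSE]
      if (nrow(anns)) anns$cx <- 1 - anns$cx
    },
    vflip = {
      image <- image[rev(seq_len(dim(image)[1])), , , drop = FALSE]
      if (nrow(anns)) anns$cy <- 1 - anns$cy
    },
    contrast = {
      f <- params$factor %||% stats::runif(1, 0.6, 1.4)
      mu <- mean(image)
      image <- pmin(pmax((image - mu) * f + mu, 0), 1)
    },
    gaussian_blur = {
      image <- gaussian_blur(image, params$sigma %||% 1.5)
    },
    stop("augment: unknown op ", op))
  list(image = image, annotations = anns)
}

#' Edge-renormalized Gaussian blur
#' @param image H x W x C array
#' @param sigma standard deviation in pixels
#' @return blurred image, same shape; a constant image is preserved exactly
#' @export
gaussian_blur <- function(image, sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  d <- dim(image)
  kh <- array(k, c(2L * r + 1L, 1L, 1L, 1L))
  kv <- array(k, c(1L, 2L * r + 1L, 1L, 1L))
  blur1 <- function(x) {
    C <- dim(x)[3]
    xt <- array(x, c(d[1], d[2], C, 1L))
    wh <- array(rep(kh, C), c(2L * r + 1L, 1L, 1L, C))
    wv <- array(rep(kv, C), c(1L, 2L * r + 1L, 1L, C))
    y <- .conv2d_fwd(xt, wh, numeric(1), 1L, 1L, r, r, 0L, 0L, C, FALSE)
    y <- .conv2d_fwd(y, wv, numeric(1), 1L, 1L, 0L, 0L, r, r, C, FALSE)
    array(y, dim(x))
  }
  num <- blur1(image)
  den <- blur1(array(1, d))   # kernel mass inside the frame
  num / den
}

# ---- preprocessing ----------------------------------------------------------

#' Letterbox an image to a square network input
#'
#' Aspect-preserving bilinear resize with symmetric gray padding; pixel
#' values stay in `[0,1]`. The returned transform maps detections back to
#' source coordinates.
#'
#' @param image H x W x 3 array in `[0,1]`
#' @param size target side length (default 640)
#' @param pad_value padding intensity (default 114/255, the YOLO gray)
#' @return list(image, transform = list(scale, pad_x, pad_y, width, height))
#' @export
preprocess <- function(image, size = 640L, pad_value = 114 / 255) {
  d <- dim(image)
  s <- min(size / d[1], size / d[2])
  nh <- round(d[1] * s); nw <- round(d[2] * s)
  resized <- bilinear_resize(image, nh, nw)
  py <- (size - nh) %/% 2L
  px <- (size - nw) %/% 2L
  out <- array(pad_value, c(size, size, d[3]))
  out[py + seq_len(nh), px + seq_len(nw), ] <- resized
  list(image = out,
       transform = list(scale = s, pad_x = px, pad_y = py,
                        width = d[2], height = d[1], size = size))
}

#' Map a normalized source-image box into letterbox coordinates
#' @param box numeric (cx, cy, w, h) normalized to the source image
#' @param tf transform returned by [preprocess()]
#' @return (cx, cy, w, h) normalized to the letterboxed square
#' @export
box_to_letterbox <- function(box, tf) {
  c(cx = (box[[1]] * tf$width * tf$scale + tf$pad_x) / tf$size,
    cy = (box[[2]] * tf$height * tf$scale + tf$pad_y) / tf$size,
    w = box[[3]] * tf$width * tf$scale / tf$size,
    h = box[[4]] * tf$height * tf$scale / tf$size)
}

#' Inverse of [box_to_letterbox()]
#' @param box (cx, cy, w, h) normalized to the letterboxed square
#' @param tf transform returned by [preprocess()]
#' @return (cx, cy, w, h) normalized to the source image
#' @export
box_from_letterbox <- function(box, tf) {
  c(cx = (box[[1]] * tf$size - tf$pad_x) / (tf$width * tf$scale),
    cy = (box[[2]] * tf$size - tf$pad_y) / (tf$height * tf$scale),
    w = box[[3]] * tf$size / (tf$width * tf$scale),
    h = box[[4]] * tf$size / (tf$height * tf$scale))
}

#' Bilinear resize
#' @param image H x W x C array
#' @param nh,nw target size
#' @return resized array
#' @export
bilinear_resize <- function(image, nh, nw) {
  d <- dim(image)
  if (nh == d[1] && nw == d[2]) return(image)
  # sample centers mapped into source pixel coordinates
  ys <- (seq_len(nh) - 0.5) * d[1] / nh + 0.5
  xs <- (seq_len(nw) - 0.5) * d[2] / nw + 0.5
  y0 <- pmin(pmax(floor(ys), 1), d[1]); y1 <- pmin(y0 + 1, d[1])
  x0 <- pmin(pmax(floor(xs), 1), d[2]); x1 <- pmin(x0 + 1, d[2])
  fy <- pmin(pmax(ys - y0, 0), 1); fx <- pmin(pmax(xs - x0, 0), 1)
  out <- array(0, c(nh, nw, d[3]))
  for (c in seq_len(d[3])) {
    ch <- image[, , c]
    a <- ch[y0, x0]; b <- ch[y0, x1]; cc <- ch[y1, x0]; dd <- ch[y1, x1]
    top <- a * outer(rep(1, nh), 1 - fx) + b * outer(rep(1, nh), fx)
    bot <- cc * outer(rep(1, nh), 1 - fx) + dd * outer(rep(1, nh), fx)
    out[, , c] <- top * outer(1 - fy, rep(1, nw)) + bot * outer(fy, rep(1, nw))
  }
  out
}

#' Read an image file as an H x W x 3 array in `[0,1]`
#' @param path PNG or JPEG file
#' @return numeric array
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") png::readPNG(path)
  else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("jpeg", quietly = TRUE))
      stop("read_image: jpeg package not available")
    jpeg::readJPEG(path)
  } else stop("read_image: unsupported format ", ext)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Write an image array to PNG
#' @param image H x W x 3 array in `[0,1]`
#' @param path output path
#' @export
write_image <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
}
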