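# Deterministic procedural generator for paddy-leaf scenes with three
# foliar-disease lesion classes:
#   0 Brown Spot       - small near-round dark-brown spots with a pale halo
#   1 Rice Blast       - spindle/diamond lesions, pale gray center, brown rim
#   2 Bacterial Blight - long yellow-brown marginal stripes
# Scenarios modulate illumination and crowding: "sunny" (bright, high
# contrast), "cloudy" (flat, dim), "dense" (more blades, clustered lesions,
# frequent box overlap). Rendering is parametric (no trained weights), so a
# seed fixes images and labels bit-for-bit.

#' Scene configuration
#' @param scenario `"sunny"`, `"cloudy"` or `"dense"`
#' @param lesions_per_image integer range (min, max)
#' @param occlusion_rate fraction of lesions deliberately placed to overlap
#'   an earlier lesion (dense scenes raise the effective rate)
#' @param image_size square side in pixels (>= 64)
#' @param seed integer seed
#' @return a `scene_config`
#' @export
scene_config <- function(scenario = c("sunny", "cloudy", "dense"),
                         lesions_per_image = c(3L, 8L),
                         occlusion_rate = 0.1, image_size = 640L, seed = 0L) {
  scenario <- match.arg(scenario)
  if (occlusion_rate < 0 || occlusion_rate > 1)
    stop("scene_config: occlusion_rate must lie in [0,1]")
  if (image_size < 64L) stop("scene_config: image_size must be >= 64")
  if (scenario == "dense") occlusion_rate <- max(occlusion_rate, 0.5)
  structure(list(scenario = scenario,
                 lesions_per_image = as.integer(lesions_per_image),
                 occlusion_rate = occlusion_rate,
                 image_size = as.integer(image_size),
                 seed = as.integer(seed)),
            class = "scene_config")
}

# scenario-dependent leaf background
.render_background <- function(S, scenario) {
  base <- switch(scenario,
    sunny = c(0.30, 0.55, 0.18), cloudy = c(0.22, 0.40, 0.16),
    dense = c(0.24, 0.46, 0.15))
  n_blades <- switch(scenario, sunny = 6L, cloudy = 6L, dense = 12L)
  img <- array(0, c(S, S, 3L))
  gy <- outer(seq(0, 1, length.out = S), rep(1, S))
  for (c in 1:3) img[, , c] <- base[c] * (0.85 + 0.3 * gy)
  xg <- outer(rep(1, S), seq_len(S))
  yg <- outer(seq_len(S), rep(1, S))
  for (b in seq_len(n_blades)) {
    x0 <- stats::runif(1, -0.2, 1.2) * S
    slope <- stats::runif(1, -0.35, 0.35)
    hw <- stats::runif(1, 0.02, 0.05) * S
    dist <- abs(xg - (x0 + slope * yg))
    mask <- pmax(0, 1 - dist / hw)
    tint <- stats::runif(1, -0.08, 0.10)
    for (c in 1:3) img[, , c] <- img[, , c] + mask * tint
  }
  img <- img + array(stats::rnorm(S * S * 3, 0, 0.012), c(S, S, 3L))
  light <- switch(scenario, sunny = 1.18, cloudy = 0.82, dense = 0.95)
  pmin(pmax(img * light, 0), 1)
}

# render one lesion; returns modified image + normalized tight box
.render_lesion <- function(img, class_id, cx, cy, S) {
  xg <- outer(rep(1, S), seq_len(S)) - cx * S
  yg <- outer(seq_len(S), rep(1, S)) - cy * S
  theta <- switch(as.character(class_id),
    "0" = stats::runif(1, 0, pi),
    "1" = stats::runif(1, -0.5, 0.5) + pi / 2,     # blades run near-vertical
    "2" = stats::runif(1, -0.18, 0.18) + pi / 2)
  u <- cos(theta) * xg + sin(theta) * yg
  v <- -sin(theta) * xg + cos(theta) * yg
  if (class_id == 0L) {            # small dark near-round spot + halo
    a <- stats::runif(1, 0.018, 0.035) * S
    b <- a * stats::runif(1, 0.75, 1.0)
    r2 <- (u / a)^2 + (v / b)^2
    core <- r2 <= 1
    halo <- r2 > 1 & r2 <= 2.1
    col <- c(0.33, 0.16, 0.05)
    halo_col <- c(0.65, 0.62, 0.28)
  } else if (class_id == 1L) {     # spindle with pale center
    a <- stats::runif(1, 0.055, 0.095) * S
    b <- a * stats::runif(1, 0.28, 0.4)
    # diamond (L1) profile gives the spindle taper
    r2 <- (abs(u) / a + abs(v) / b)
    core <- r2 <= 1
    halo <- r2 > 1 & r2 <= 1.35
    col <- c(0.78, 0.76, 0.68)     # pale center
    halo_col <- c(0.42, 0.22, 0.08)
  } else {                         # long marginal stripe
    a <- stats::runif(1, 0.16, 0.28) * S
    b <- a * stats::runif(1, 0.07, 0.11)
    wav <- 0.3 * b * sin(v / max(1, 0.12 * a))
    r2 <- pmax(abs(v) / a, abs(u - wav) / b)
    core <- r2 <= 1
    halo <- r2 > 1 & r2 <= 1.25
    col <- c(0.62, 0.5, 0.16)
    halo_col <- c(0.72, 0.66, 0.3)
  }
  blend <- function(im, mask, colr, alpha) {
    for (c in 1:3) {
      ch <- im[, , c]
      ch[mask] <- (1 - alpha) * ch[mask] + alpha * colr[c]
      im[, , c] <- ch
    }
    im
  }
  img <- blend(img, halo, halo_col, 0.55)
  img <- blend(img, core, col, 0.92)
  idx <- which(core, arr.ind = TRUE)
  if (!nrow(idx)) return(NULL)
  y1 <- min(idx[, 1]); y2 <- max(idx[, 1])
  x1 <- min(idx[, 2]); x2 <- max(idx[, 2])
  # pixel p spans ((p-1)/S, p/S]; the tight box runs (x1-1)/S .. x2/S
  box <- annotation(class_id,
                    cx = (x1 - 1 + x2) / 2 / S, cy = (y1 - 1 + y2) / 2 / S,
                    w = max(x2 - x1 + 1, 2) / S, h = max(y2 - y1 + 1, 2) / S)
  list(image = img, box = box)
}

#' Generate one synthetic paddy scene
#'
#' @param cfg a [scene_config()]
#' @param class_mix sampling weights for classes 0..2 (default equal)
#' @param n_lesions override the lesion count (default drawn from the
#'   config's range)
#' @return list(image = H x W x 3 array, annotations = data.frame);
#'   deterministic given `cfg$seed`
#' @export
generate_scene <- function(cfg, class_mix = c(1, 1, 1), n_lesions = NULL) {
  stopifnot(inherits(cfg, "scene_config"))
  rng <- local_rng(cfg$seed)
  on.exit(restore_rng(rng))
  S <- cfg$image_size
  img <- .render_background(S, cfg$scenario)
  lo <- cfg$lesions_per_image[1]; hi <- cfg$lesions_per_image[2]
  n <- n_lesions %||% sample(lo:hi, 1L)
  anns <- empty_annotations()
  margin <- 0.12
  placed <- list()
  for (i in seq_len(n)) {
    cls <- sample(0:2, 1L, prob = class_mix)
    overlap_wanted <- length(placed) > 0 && stats::runif(1) < cfg$occlusion_rate
    if (overlap_wanted) {
      ref <- placed[[sample.int(length(placed), 1L)]]
      cx <- min(1 - margin, max(margin, ref[1] + stats::runif(1, -0.04, 0.04)))
      cy <- min(1 - margin, max(margin, ref[2] + stats::runif(1, -0.04, 0.04)))
    } else {
      ok <- FALSE
      for (try in 1:20) {
        cx <- stats::runif(1, margin, 1 - margin)
        cy <- stats::runif(1, margin, 1 - margin)
        ok <- !length(placed) ||
          all(vapply(placed, function(p)
            (p[1] - cx)^2 + (p[2] - cy)^2 > 0.03, logical(1)))
        if (ok) break
      }
      if (!ok) warning("generate_scene: crowded placement is best-effort")
    }
    r <- .render_lesion(img, cls, cx, cy, S)
    if (is.null(r)) next
    img <- r$image
    anns <- rbind(anns, r$box)
    placed[[length(placed) + 1L]] <- c(cx, cy)
  }
  list(image = img, annotations = anns)
}

#' Classify a rendered lesion from its geometry and colors
#'
#' Rule-based inverse of the renderer, used as a self-consistency check that
#' the three classes are visually separable: very elongated boxes are
#' Bacterial Blight; otherwise a pale center relative to the rim indicates
#' Rice Blast, a dark center Brown Spot.
#'
#' @param image scene image
#' @param box one annotation row (normalized)
#' @return predicted class id
#' @export
classify_lesion <- function(image, box) {
  S <- dim(image)[1]
  aspect <- max(box$w, box$h) / max(1e-6, min(box$w, box$h))
  long_px <- max(box$w, box$h) * S
  if (aspect > 4 || long_px > 0.24 * S) return(2L)
  x1 <- max(1, round((box$cx - box$w / 2) * S)); x2 <- min(S, round((box$cx + box$w / 2) * S))
  y1 <- max(1, round((box$cy - box$h / 2) * S)); y2 <- min(S, round((box$cy + box$h / 2) * S))
  patch <- image[y1:y2, x1:x2, , drop = FALSE]
  ph <- dim(patch)[1]; pw <- dim(patch)[2]
  cyi <- max(1, round(ph * 0.35)):min(ph, round(ph * 0.65))
  cxi <- max(1, round(pw * 0.35)):min(pw, round(pw * 0.65))
  center <- mean(patch[cyi, cxi, ])
  if (center > 0.5) 1L else 0L
}

#' Generate a synthetic dataset manifest (and optionally rendered files)
#'
#' Dominant-class image counts follow `class_ratio` by largest remainder;
#' each image draws most lesions from its dominant class plus minority-class
#' lesions, mirroring field imagery where one disease dominates a view.
#'
#' @param n number of images
#' @param class_ratio length-3 weights, default `c(4, 3, 3)`
#' @param out_root output directory (`images/`, `labels/`); `NULL` for a
#'   manifest-only run without rendering
#' @param seed integer seed
#' @param image_size square image side
#' @param scenario scene scenario for all images, or `"mix"` to cycle
#' @return a `dataset_manifest`; records carry `dominant` and, for
#'   manifest-only runs, the scene config needed to render on demand
#' @export
generate_dataset <- function(n, class_ratio = c(4, 3, 3), out_root = NULL,
                             seed = 0L, image_size = 640L, scenario = "mix") {
  if (n < length(class_ratio)) stop("generate_dataset: n below class count")
  counts <- largest_remainder(n, class_ratio)
  doms <- rep(seq_along(counts) - 1L, counts)
  rng <- local_rng(seed)
  doms <- doms[sample.int(length(doms))]
  restore_rng(rng)
  scenarios <- c("sunny", "cloudy", "dense")
  if (!is.null(out_root)) {
    dir.create(file.path(out_root, "images"), recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_root, "labels"), recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(file.path(out_root, "images")))
      stop("generate_dataset: cannot create output directory")
  }
  records <- vector("list", n)
  for (i in seq_len(n)) {
    sc <- if (identical(scenario, "mix")) scenarios[1L + (i - 1L) %% 3L] else scenario
    cfg <- scene_config(sc, image_size = image_size,
                        seed = seed + 1000L + i)
    mix <- c(1, 1, 1) * 0.15
    mix[doms[i] + 1L] <- 1
    scene <- generate_scene(cfg, class_mix = mix)
    rec <- list(height = image_size, width = image_size,
                annotations = scene$annotations, split = NA_character_,
                dominant = doms[i], config = cfg, class_mix = mix)
    if (!is.null(out_root)) {
      stem <- sprintf("%05d", i)
      rec$image <- file.path(out_root, "images", paste0(stem, ".png"))
      write_image(scene$image, rec$image)
      write_yolo_label(scene$annotations,
                       file.path(out_root, "labels", paste0(stem, ".txt")))
    } else {
      rec$image <- sprintf("synthetic://%05d", i)
    }
    records[[i]] <- rec
  }
  new_manifest(records)
}

#' Largest-remainder apportionment of n into integer counts
#' @param n total
#' @param weights numeric weights
#' @return integer vector summing to n
#' @export
largest_remainder <- function(n, weights) {
  q <- n * weights / sum(weights)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

# re-render the image for a manifest-only record
render_record <- function(rec) {
  if (!is.null(rec$config)) {
    generate_scene(rec$config, class_mix = rec$class_mix)$image
  } else read_image(rec$image)
}
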