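# Synthetic single-bunch scene generator.
#
# Renders dense clusters of mutually occluding, near-circular elliptical
# berries over a leaf-green textured background, with exact per-instance
# visibility bookkeeping. The geometry defaults emulate the box statistics of
# a single-bunch grape dataset at network input scale: box widths/heights of
# 5-100 px, aspect ratios 0.5-2 and visible areas of 60-10,000 px^2.

#' Specify a synthetic bunch scene
#'
#' @param image_height,image_width canvas size in pixels.
#' @param berry_count number of berries placed (before visibility filtering).
#' @param radius_range min/max equivalent radius in pixels; must lie within
#'   \[2.5, 50\] so berry diameters stay in the 5-100 px band. Radii are drawn
#'   log-uniformly, giving the small-berry-heavy size distribution typical of
#'   bunches before thinning while still spanning the emulated 60-10,000 px^2
#'   area band.
#' @param aspect_range min/max width/height ratio of the ellipse (unitless),
#'   within \[0.5, 2\]; berries are near-circular by default.
#' @param overlap_level fraction in \[0, 1\] controlling centre spacing:
#'   0 forces pairwise-disjoint berries, larger values allow centres as close
#'   as `(1 - overlap_level)` times the sum of radii.
#' @param berry_color,background_color RGB triples in 0-255.
#' @param color_jitter per-berry uniform colour jitter amplitude.
#' @param min_visible_fraction berries whose visible (un-occluded) pixel
#'   fraction falls below this are left unannotated and uncounted.
#' @param min_area annotation floor on visible pixel area, mirroring the
#'   emulated dataset's observed 60 px^2 minimum.
#' @param drop_outside_bands drop annotations whose visible box falls outside
#'   the emulated statistical bands (width/height 5-100, aspect 0.5-2, area
#'   60-10,000)? Occlusion can leave rare extreme fragments; the bands keep
#'   the generated annotations within the distribution the generator emulates.
#' @param seed integer RNG seed; scenes are bit-reproducible given the spec.
#' @return an object of class `scene_spec`.
#' @export
scene_spec <- function(image_height = 320L, image_width = 320L,
                       berry_count = 60L,
                       radius_range = c(5, 44),
                       aspect_range = c(0.8, 1.25),
                       overlap_level = 0.4,
                       berry_color = c(105, 150, 80),
                       background_color = c(90, 135, 70),
                       color_jitter = 18,
                       min_visible_fraction = 0.15,
                       min_area = 60,
                       drop_outside_bands = TRUE,
                       seed = 1L) {
  spec <- list(image_height = as.integer(image_height),
               image_width = as.integer(image_width),
               berry_count = as.integer(berry_count),
               radius_range = as.numeric(radius_range),
               aspect_range = as.numeric(aspect_range),
               overlap_level = overlap_level,
               berry_color = berry_color,
               background_color = background_color,
               color_jitter = color_jitter,
               min_visible_fraction = min_visible_fraction,
               min_area = min_area,
               drop_outside_bands = isTRUE(drop_outside_bands),
               seed = as.integer(seed))
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
  spec
}

validate_scene_spec <- function(spec) {
  if (spec$image_height < 32L || spec$image_width < 32L)
    stop("scene_spec: image must be at least 32x32 pixels")
  if (spec$berry_count < 1L)
    stop("scene_spec: berry_count must be >= 1")
  rr <- spec$radius_range
  if (length(rr) != 2L || rr[1] > rr[2] || rr[1] < 2.5 || rr[2] > 50)
    stop("scene_spec: radius_range must be increasing and within [2.5, 50]")
  ar <- spec$aspect_range
  if (length(ar) != 2L || ar[1] > ar[2] || ar[1] < 0.5 || ar[2] > 2)
    stop("scene_spec: aspect_range must be increasing and within [0.5, 2]")
  if (spec$overlap_level < 0 || spec$overlap_level > 1)
    stop("scene_spec: overlap_level must be in [0, 1]")
  if (spec$min_visible_fraction <= 0 || spec$min_visible_fraction > 1)
    stop("scene_spec: min_visible_fraction must be in (0, 1]")
  margin <- max(rr) * sqrt(max(ar)) + 1
  if (spec$image_height < 2 * margin || spec$image_width < 2 * margin)
    stop("scene_spec: image too small to contain the largest berry")
  invisible(spec)
}

#' An easy scene preset for smoke experiments
#'
#' A few large, well-separated, high-contrast berries: the configuration used
#' for desk-scale training and detection smoke runs.
#'
#' @param berry_count number of berries.
#' @param image_size square canvas side in pixels.
#' @param seed RNG seed.
#' @return a `scene_spec`.
#' @export
easy_scene_spec <- function(berry_count = 5L, image_size = 128L, seed = 1L) {
  scene_spec(image_height = image_size, image_width = image_size,
             berry_count = berry_count,
             radius_range = c(13, 18), aspect_range = c(0.9, 1.12),
             overlap_level = 0, min_visible_fraction = 1,
             berry_color = c(70, 45, 110), background_color = c(150, 180, 130),
             color_jitter = 10, seed = seed)
}

# Place berry centres around the cluster centre by rejection sampling under
# the centre-spacing constraint; the scatter widens if placement stalls so
# the procedure always terminates.
place_berries <- function(spec, radii) {
  n <- length(radii)
  H <- spec$image_height; W <- spec$image_width
  margin <- radii * sqrt(spec$aspect_range[2]) + 1
  cx0 <- W / 2; cy0 <- H / 2
  sd0 <- 0.22 * min(H, W) + 0.55 * sqrt(n) * mean(radii)
  sd_cap <- 2 * max(H, W)
  xs <- numeric(n); ys <- numeric(n)
  for (i in seq_len(n)) {
    sdi <- sd0
    cycles <- 0L
    x <- NA_real_; y <- NA_real_
    repeat {
      ok <- FALSE
      for (try in seq_len(80L)) {
        x <- stats::rnorm(1, cx0, min(sdi, sd_cap))
        y <- stats::rnorm(1, cy0, min(sdi, sd_cap))
        if (x < margin[i] || x > W - margin[i] ||
            y < margin[i] || y > H - margin[i]) next
        if (i > 1L) {
          d <- sqrt((xs[seq_len(i - 1L)] - x)^2 + (ys[seq_len(i - 1L)] - y)^2)
          mind <- (1 - spec$overlap_level) * (radii[seq_len(i - 1L)] + radii[i])
          if (any(d < mind)) next
        }
        ok <- TRUE
        break
      }
      if (ok) break
      cycles <- cycles + 1L
      # dense specs: once the widened scatter fails repeatedly, fall back to
      # a uniform in-bounds draw; the spacing constraint is best-effort for
      # overlapping bunches but remains a hard guarantee for overlap 0
      if (cycles >= 8L && spec$overlap_level > 0) {
        x <- stats::runif(1, margin[i], W - margin[i])
        y <- stats::runif(1, margin[i], H - margin[i])
        break
      }
      if (cycles >= 200L)
        stop("place_berries: cannot place berries disjointly; reduce ",
             "berry_count or radius_range, or allow overlap")
      sdi <- sdi * 1.3
    }
    xs[i] <- x; ys[i] <- y
  }
  cbind(x = xs, y = ys)
}

#' Generate a synthetic bunch scene
#'
#' Berries are rendered as shaded filled ellipses in painter's order (later
#' berries occlude earlier ones); only visible pixels are annotated.
#' Deterministic given the spec's seed.
#'
#' @param spec a [scene_spec()].
#' @return an object of class `synthetic_scene` with fields `image`
#'   (H x W x 3 array, 0-255), `owner` (H x W integer matrix, 0 = background),
#'   `instances` (data.frame of the annotated berries: COCO `x, y, w, h`
#'   0-based box, visible `area`, `visible_fraction`), and `true_count`.
#' @export
generate_bunch_scene <- function(spec) {
  validate_scene_spec(spec)
  with_seed(spec$seed, {
    H <- spec$image_height; W <- spec$image_width
    n <- spec$berry_count

    lr <- log(spec$radius_range)
    radii <- exp(stats::runif(n, lr[1], lr[2]))
    aspect <- stats::runif(n, spec$aspect_range[1], spec$aspect_range[2])
    a <- radii * sqrt(aspect)   # semi-axis along x
    b <- radii / sqrt(aspect)   # semi-axis along y
    centers <- place_berries(spec, radii)

    # Background: low-frequency leafy texture plus pixel noise.
    xg <- matrix(seq_len(W), H, W, byrow = TRUE)
    yg <- matrix(seq_len(H), H, W)
    img <- array(0, c(H, W, 3))
    for (ch in 1:3) {
      f1 <- stats::runif(2, 0.004, 0.02); ph <- stats::runif(2, 0, 2 * pi)
      tex <- 9 * sin(2 * pi * f1[1] * xg + ph[1]) +
             9 * sin(2 * pi * f1[2] * yg + ph[2])
      img[, , ch] <- spec$background_color[ch] + tex +
        matrix(stats::rnorm(H * W, sd = 6), H, W)
    }

    owner <- matrix(0L, H, W)
    full_area <- integer(n)
    jit <- matrix(stats::runif(3 * n, -spec$color_jitter, spec$color_jitter),
                  n, 3)
    for (i in seq_len(n)) {
      cx <- centers[i, 1]; cy <- centers[i, 2]
      i0 <- max(1L, floor(cy - b[i])); i1 <- min(H, ceiling(cy + b[i]))
      j0 <- max(1L, floor(cx - a[i])); j1 <- min(W, ceiling(cx + a[i]))
      ii <- i0:i1; jj <- j0:j1
      dx <- (matrix(jj, length(ii), length(jj), byrow = TRUE) - cx) / a[i]
      dy <- (matrix(ii, length(ii), length(jj)) - cy) / b[i]
      d2 <- dx * dx + dy * dy
      inside <- d2 <= 1
      full_area[i] <- sum(inside)
      if (!any(inside)) next
      shade <- 0.55 + 0.45 * sqrt(pmax(0, 1 - d2))
      sel <- which(inside, arr.ind = TRUE)
      rsel <- ii[sel[, 1]]; csel <- jj[sel[, 2]]
      lin <- rsel + (csel - 1L) * H
      for (ch in 1:3) {
        col <- (spec$berry_color[ch] + jit[i, ch]) * shade[inside] +
          stats::rnorm(length(lin), sd = 4)
        img[lin + (ch - 1L) * H * W] <- col
      }
      owner[lin] <- i
    }
    img <- pmin(pmax(img, 0), 255)

    inst <- annotate_owner_map(owner, full_area, spec)
    structure(list(image = img, owner = owner, instances = inst,
                   true_count = nrow(inst), spec = spec),
              class = "synthetic_scene")
  })
}

# Visibility bookkeeping: tight boxes over visible pixels, annotation drop
# rules (visible fraction, area floor, statistical bands).
annotate_owner_map <- function(owner, full_area, spec) {
  H <- nrow(owner); W <- ncol(owner)
  ids <- seq_along(full_area)
  vis <- tabulate(owner[owner > 0L], nbins = length(full_area))
  rows <- list()
  for (i in ids) {
    if (vis[i] == 0L || full_area[i] == 0L) next
    vf <- vis[i] / full_area[i]
    if (vf < spec$min_visible_fraction) next
    if (vis[i] < spec$min_area) next
    lin <- which(owner == i)
    r <- (lin - 1L) %% H + 1L
    cc <- (lin - 1L) %/% H + 1L
    x0 <- min(cc) - 1L; x1 <- max(cc)       # 0-based, exclusive right edge
    y0 <- min(r) - 1L; y1 <- max(r)
    w <- x1 - x0; h <- y1 - y0
    if (spec$drop_outside_bands) {
      asp <- w / h
      if (w < 5 || w > 100 || h < 5 || h > 100) next
      if (asp < 0.5 || asp > 2) next
      if (vis[i] < 60 || vis[i] > 10000) next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(instance = i, x = x0, y = y0, w = w, h = h,
                 area = vis[i], visible_fraction = vf)
  }
  if (!length(rows))
    return(data.frame(instance = integer(), x = numeric(), y = numeric(),
                      w = numeric(), h = numeric(), area = numeric(),
                      visible_fraction = numeric()))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract the visible binary mask of one annotated instance
#'
#' @param scene a `synthetic_scene`.
#' @param k row index into `scene$instances`.
#' @return H x W logical matrix of visible pixels.
#' @export
instance_mask <- function(scene, k) {
  scene$owner == scene$instances$instance[k]
}

#' Ground truth of a scene in detector coordinates
#'
#' @param scene a `synthetic_scene`.
#' @return list with `boxes` (n x 4 matrix of corner boxes x1, y1, x2, y2),
#'   `areas` (visible pixel counts) and `masks` (list of logical matrices).
#' @export
scene_ground_truth <- function(scene) {
  inst <- scene$instances
  boxes <- cbind(x1 = inst$x, y1 = inst$y,
                 x2 = inst$x + inst$w, y2 = inst$y + inst$h)
  masks <- lapply(seq_len(nrow(inst)), function(k) instance_mask(scene, k))
  list(boxes = boxes, areas = inst$area, masks = masks)
}

#' Random scored-box fixture
#'
#' Seeded valid boxes with confidence scores, used as small inputs for
#' suppression and matching tests.
#'
#' @param n number of boxes (may be 0).
#' @param seed RNG seed.
#' @param score_range score bounds.
#' @param canvas c(width, height) bounds the boxes.
#' @param size_range box side bounds in pixels.
#' @return data.frame with columns x1, y1, x2, y2, score.
#' @export
random_box_fixture <- function(n, seed = 1L, score_range = c(0.05, 1),
                               canvas = c(100, 100), size_range = c(4, 40)) {
  stopifnot(n >= 0)
  with_seed(seed, {
    if (n == 0L)
      return(data.frame(x1 = numeric(), y1 = numeric(), x2 = numeric(),
                        y2 = numeric(), score = numeric()))
    w <- stats::runif(n, size_range[1], min(size_range[2], canvas[1]))
    h <- stats::runif(n, size_range[1], min(size_range[2], canvas[2]))
    x1 <- stats::runif(n, 0, canvas[1] - w)
    y1 <- stats::runif(n, 0, canvas[2] - h)
    data.frame(x1 = x1, y1 = y1, x2 = x1 + w, y2 = y1 + h,
               score = stats::runif(n, score_range[1], score_range[2]))
  })
}
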