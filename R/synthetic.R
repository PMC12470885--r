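# Synthetic fundus-like images with branching vessel trees.
#
# The generator emulates the two properties of retinal data that the rest
# of the package depends on: severe class imbalance (thin curvilinear
# foreground on a large background) and capillary thinness (segments of
# width 1-2 px), composited over a vignetted, noisy, fundus-toned
# background.  It makes every other module testable without downloads.

#' Parameters of the synthetic vessel-tree generator
#'
#' @param image_size integer vector (H, W).
#' @param n_roots number of primary vessels entering the fundus disc.
#' @param branch_prob probability that a segment spawns two children.
#' @param depth_max maximum branching depth.
#' @param width_root stroke radius (pixels) of a primary vessel.
#' @param width_min minimum stroke radius; must be >= 0.5 px so that the
#'   thinnest segments rasterise to 1-px-wide curves.
#' @param curvature standard deviation (radians) of the random heading
#'   change per step; larger values give more tortuous vessels.
#' @param foreground_target desired vessel-pixel fraction of the image.
#'   Trees are added until at least 3/4 of the target is covered, and
#'   generation stops early past 3/2 of it, keeping the realised fraction
#'   within +-50% of the target.
#' @param noise_sigma standard deviation of the additive pixel noise.
#' @param seed integer seed; the (image, mask) pair is a pure function of
#'   `(seed, params)`.
#' @return object of class `"vessel_tree_params"`.
#' @export
vessel_tree_params <- function(image_size = c(256, 256), n_roots = 3,
                               branch_prob = 0.35, depth_max = 4,
                               width_root = NULL, width_min = 0.5,
                               curvature = 0.25, foreground_target = 0.10,
                               noise_sigma = 0.02, seed = 1) {
  if (length(image_size) == 1) image_size <- rep(image_size, 2)
  if (any(image_size < 16)) stop("image too small to draw vessels")
  if (is.null(width_root)) width_root <- max(1.5, min(image_size) / 60)
  if (width_min < 0.5) stop("width_min must be at least 0.5 px")
  if (foreground_target <= 0 || foreground_target >= 1)
    stop("foreground_target must be in (0, 1)")
  structure(list(image_size = as.integer(image_size), n_roots = n_roots,
                 branch_prob = branch_prob, depth_max = depth_max,
                 width_root = width_root, width_min = width_min,
                 curvature = curvature,
                 foreground_target = foreground_target,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "vessel_tree_params")
}

# Trace one vessel from (y, x) with heading ang; returns updated canvas.
# Recursive midpoint-free random walk: constant step, Gaussian heading
# noise, linear width taper, binomial branching.
trace_vessel <- function(canvas, y, x, ang, width, depth, p) {
  H <- nrow(canvas); W <- ncol(canvas)
  len <- stats::runif(1, 0.25, 0.55) * min(H, W) / depth
  steps <- max(4L, ceiling(len / 0.5))
  ys <- numeric(steps); xs <- numeric(steps); rs <- numeric(steps)
  w_end <- max(p$width_min, width * stats::runif(1, 0.6, 0.85))
  for (i in seq_len(steps)) {
    ang <- ang + stats::rnorm(1, 0, p$curvature / sqrt(steps))
    y <- y + 0.5 * sin(ang)
    x <- x + 0.5 * cos(ang)
    ys[i] <- y; xs[i] <- x
    rs[i] <- width + (w_end - width) * (i - 1) / max(1, steps - 1)
    if (y < 2 || y > H - 1 || x < 2 || x > W - 1) {
      ys <- ys[seq_len(i)]; xs <- xs[seq_len(i)]; rs <- rs[seq_len(i)]
      break
    }
  }
  canvas <- stamp_disks(canvas, ys, xs, rs)
  at_edge <- y < 2 || y > H - 1 || x < 2 || x > W - 1
  if (!at_edge && depth < p$depth_max) {
    if (stats::runif(1) < p$branch_prob) {
      split <- stats::runif(1, 0.3, 0.6)
      canvas <- trace_vessel(canvas, y, x, ang + split, w_end, depth + 1, p)
      canvas <- trace_vessel(canvas, y, x, ang - split, w_end, depth + 1, p)
    } else {
      canvas <- trace_vessel(canvas, y, x, ang, w_end, depth + 1, p)
    }
  }
  canvas
}

# Smooth low-frequency field in [-1, 1] from a coarse Gaussian grid.
lowfreq_noise <- function(H, W, cells = 6) {
  g <- matrix(stats::rnorm(cells * cells), cells, cells)
  a <- array(g, c(cells, cells, 1, 1))
  up <- resize_bilinear_fw(a, H, W)
  m <- matrix(up, H, W)
  m / max(abs(m), 1e-8)
}

#' Generate one synthetic fundus image with vessel ground truth
#'
#' Random recursive branching vessels are rasterised with tapering
#' anti-aliased strokes (root width down to capillary width) into a
#' coverage layer.  The binary mask is the coverage thresholded at 0.5.
#' The RGB image composites the vessels (strongest contrast in the green
#' channel, as in real fundus photographs) over a radially vignetted
#' background with low-frequency illumination drift and additive Gaussian
#' noise.  Fully reproducible from `(seed, params)`.
#'
#' @param params a [vessel_tree_params()] object.
#' @return list with `image` (H x W x 3 array in \[0, 1\]), `mask`
#'   (binary H x W matrix) and `params`.
#' @export
generate_vessel_tree <- function(params = vessel_tree_params()) {
  stopifnot(inherits(params, "vessel_tree_params"))
  p <- params
  H <- p$image_size[1]; W <- p$image_size[2]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(p$seed)

  canvas <- matrix(0, H, W)
  cy <- H / 2; cx <- W / 2
  fov_r <- 0.48 * min(H, W)
  target <- p$foreground_target
  n_spawned <- 0L
  repeat {
    # root on the fundus disc rim, heading inward
    phi <- stats::runif(1, 0, 2 * pi)
    y0 <- cy + 0.9 * fov_r * sin(phi)
    x0 <- cx + 0.9 * fov_r * cos(phi)
    ang <- atan2(cy - y0, cx - x0) + stats::rnorm(1, 0, 0.3)
    canvas <- trace_vessel(canvas, y0, x0, ang, p$width_root, 1L, p)
    n_spawned <- n_spawned + 1L
    frac <- mean(canvas >= 0.5)
    if (n_spawned >= p$n_roots && frac >= 0.75 * target) break
    if (frac >= 1.5 * target) break
    if (n_spawned >= 8L * p$n_roots) break   # give up on bad draws
  }
  mask <- (canvas >= 0.5) * 1

  # background: fundus-toned vignette + illumination drift
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  r2 <- ((yy - cy) / (0.7 * H))^2 + ((xx - cx) / (0.7 * W))^2
  vign <- 1 - 0.45 * r2
  drift <- lowfreq_noise(H, W)
  base <- c(0.82, 0.52, 0.25)         # R, G, B fundus tones
  depthc <- c(0.25, 0.45, 0.10)       # vessel contrast per channel
  img <- array(0, c(H, W, 3))
  soft <- pmin(canvas, 1)
  for (ch in 1:3) {
    bg <- base[ch] * vign * (1 + 0.06 * drift)
    v <- bg - depthc[ch] * soft * bg
    v <- v + stats::rnorm(H * W, 0, p$noise_sigma)
    img[, , ch] <- pmin(pmax(v, 0), 1)
  }
  list(image = img, mask = mask, params = params)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Write a synthetic dataset to disk
#'
#' Generates `n` image/mask pairs and writes them in the standard layout
#' `root/<split>/images/*.png`, `root/<split>/masks/*.png` together with a
#' JSON manifest recording the per-image seeds and parameters, so that the
#' dataset can be regenerated bit-identically.
#'
#' @param n total number of image/mask pairs.
#' @param params a [vessel_tree_params()]; its `seed` seeds the whole
#'   dataset and per-image seeds are derived from it.
#' @param out_dir output directory (created if missing).
#' @param split named integer vector assigning pairs to splits, e.g.
#'   `c(train = 15, val = 5, test = 20)`; must sum to `n`.
#' @return the dataset root directory, invisibly.
#' @export
make_dataset <- function(n, params = vessel_tree_params(), out_dir,
                         split = NULL) {
  if (is.null(split)) split <- c(train = n, val = 0L, test = 0L)
  if (sum(split) != n) stop("split sizes must sum to n")
  seeds <- params$seed + seq_len(n) - 1L
  assign_split <- rep(names(split), times = split)
  manifest <- list(params = unclass(params)[setdiff(names(params), "seed")],
                   images = list())
  idx <- 0L
  for (i in seq_len(n)) {
    idx <- idx + 1L
    sp <- assign_split[i]
    pi <- params; pi$seed <- seeds[i]
    gen <- generate_vessel_tree(pi)
    stem <- sprintf("%s_%03d", sp, i)
    img_dir <- file.path(out_dir, sp, "images")
    msk_dir <- file.path(out_dir, sp, "masks")
    dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(msk_dir, recursive = TRUE, showWarnings = FALSE)
    png::writePNG(gen$image, file.path(img_dir, paste0(stem, ".png")))
    png::writePNG(gen$mask, file.path(msk_dir, paste0(stem, ".png")))
    manifest$images[[stem]] <- list(seed = seeds[i], split = sp)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
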