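# Shared fixture builders.

# brute-force Euclidean distance to the nearest nonzero pixel
brute_edt <- function(feature) {
  H <- nrow(feature); W <- ncol(feature)
  pts <- which(feature == 1, arr.ind = TRUE)
  D <- matrix(Inf, H, W)
  if (!nrow(pts)) return(D)
  for (h in seq_len(H))
    for (w in seq_len(W))
      D[h, w] <- sqrt(min((pts[, 1] - h)^2 + (pts[, 2] - w)^2))
  D
}

random_mask <- function(H, W, p = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  (matrix(stats::runif(H * W), H, W) < p) * 1
}

# a filled square mask centred in a larger domain
square_mask <- function(n, side) {
  m <- matrix(0, n, n)
  lo <- (n - side) %/% 2 + 1
  m[lo:(lo + side - 1), lo:(lo + side - 1)] <- 1
  m
}

tiny_pairs <- function(n, size = 48, seed0 = 900) {
  lapply(seq_len(n), function(i) {
    g <- generate_vessel_tree(vessel_tree_params(image_size = c(size, size),
                                                 seed = seed0 + i))
    list(image = g$image, mask = g$mask)
  })
}
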