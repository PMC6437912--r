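# Per-pixel feature channels feeding the structured contour forest.

CHANNEL_NAMES <- c(
  "L", "a", "b",
  "gradmag_s0", "gradmag_s1.5",
  "orient_000_full", "orient_045_full", "orient_090_full", "orient_135_full",
  "orient_000_half", "orient_045_half", "orient_090_half", "orient_135_half"
)

#' Compute the 13 per-pixel feature channels of an RGB image
#'
#' The channel stack used throughout contour detection: the three CIE-Lab
#' colour channels, gradient magnitude of luminance at Gaussian blur
#' \eqn{\sigma = 0} and \eqn{\sigma = 1.5}, and oriented gradient energy
#' (absolute directional derivative at 0, 45, 90 and 135 degrees) at full
#' resolution and at half resolution upsampled back, for 13 channels total.
#'
#' @param rgb H x W x 3 array with values in `[0, 1]` (sRGB).
#' @return object of class `channel_stack`: a list with `values`
#'   (H x W x 13 array) and `channel_names`.
#' @examples
#' img <- array(runif(64 * 64 * 3), c(64, 64, 3))
#' ch <- compute_channels(img)
#' dim(ch$values)
#' @export
compute_channels <- function(rgb) {
  assert_rgb(rgb)
  H <- dim(rgb)[1]; W <- dim(rgb)[2]
  if (min(H, W) < 16) stop("image must be at least 16 pixels on a side")
  lab <- convertColor(matrix(rgb, ncol = 3L), from = "sRGB", to = "Lab")
  Lc <- matrix(lab[, 1], H, W)
  ac <- matrix(lab[, 2], H, W)
  bc <- matrix(lab[, 3], H, W)

  grad_pair <- function(m) list(gy = finite_diff(m, "y"), gx = finite_diff(m, "x"))
  g0 <- grad_pair(Lc)
  g1 <- grad_pair(gaussian_blur(Lc, 1.5))
  gm0 <- sqrt(g0$gy^2 + g0$gx^2)
  gm1 <- sqrt(g1$gy^2 + g1$gx^2)

  orient_bank <- function(m) {
    g <- grad_pair(m)
    th <- c(0, 45, 90, 135) * pi / 180
    lapply(th, function(t) abs(cos(t) * g$gx + sin(t) * g$gy))
  }
  ob_full <- orient_bank(Lc)

  # half scale: 2x2 block mean, oriented energy, nearest upsample
  H2 <- floor(H / 2); W2 <- floor(W / 2)
  blk <- (Lc[seq_len(2 * H2), seq_len(2 * W2)])
  half <- (blk[seq(1, 2 * H2, 2), seq(1, 2 * W2, 2)] +
           blk[seq(2, 2 * H2, 2), seq(1, 2 * W2, 2)] +
           blk[seq(1, 2 * H2, 2), seq(2, 2 * W2, 2)] +
           blk[seq(2, 2 * H2, 2), seq(2, 2 * W2, 2)]) / 4
  ob_half <- lapply(orient_bank(half), function(m) {
    up <- m[rep(seq_len(H2), each = 2), rep(seq_len(W2), each = 2), drop = FALSE]
    # pad odd trailing row/col by replication
    out <- matrix(0, H, W)
    out[seq_len(2 * H2), seq_len(2 * W2)] <- up
    if (H > 2 * H2) out[H, ] <- out[2 * H2, ]
    if (W > 2 * W2) out[, W] <- out[, 2 * W2]
    out
  })

  vals <- array(0, c(H, W, 13L))
  chans <- c(list(Lc, ac, bc, gm0, gm1), ob_full, ob_half)
  for (i in seq_along(chans)) vals[, , i] <- chans[[i]]
  structure(list(values = vals, channel_names = CHANNEL_NAMES),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<channel_stack %d x %d, %d channels>\n", d[1], d[2], d[3]))
  invisible(x)
}
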