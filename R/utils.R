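# Shared low-level helpers. Image rasters are numeric matrices (H x W) or
# H x W x 3 arrays in [0, 1]; label rasters are integer matrices with 0
# reserved for boundary/background.

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library internals never perturb user-level randomness.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# deterministic 32-bit mix of small integers, for deriving stream seeds
mix_seed <- function(...) {
  v <- c(...)
  h <- 5381
  for (x in v) h <- (h * 33 + as.numeric(x)) %% 2147483647
  as.integer(h)
}

mirror_index <- function(i, n) {
  # 0-based reflection without border duplication collapse
  i <- i %% (2L * n)
  ifelse(i >= n, 2L * n - i - 1L, i)
}

#' Separable Gaussian blur with mirrored borders
#'
#' Direct (non-FFT) separable convolution; the result at a pixel depends only
#' on pixels within `radius` of it, so blurring a crop agrees with blurring
#' the full image away from the crop border.
#'
#' @param x numeric matrix.
#' @param sigma Gaussian standard deviation in pixels; `0` returns `x`.
#' @return blurred matrix of the same shape.
#' @export
gaussian_blur <- function(x, sigma) {
  stopifnot(is.matrix(x), sigma >= 0)
  if (sigma == 0) return(x)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  w <- w / sum(w)
  H <- nrow(x); W <- ncol(x)
  conv1 <- function(m, n_along, by_row) {
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq(-r, r)) {
      idx <- mirror_index(seq_len(n_along) - 1 + j, n_along) + 1L
      out <- out + w[j + r + 1] * (if (by_row) m[idx, , drop = FALSE]
                                   else m[, idx, drop = FALSE])
    }
    out
  }
  conv1(conv1(x, H, TRUE), W, FALSE)
}

# centred finite differences with replicated borders
finite_diff <- function(x, along = c("y", "x")) {
  along <- match.arg(along)
  H <- nrow(x); W <- ncol(x)
  if (along == "y") {
    up <- x[c(1L, seq_len(H - 1L)), , drop = FALSE]
    dn <- x[c(seq_len(H)[-1L], H), , drop = FALSE]
  } else {
    up <- x[, c(1L, seq_len(W - 1L)), drop = FALSE]
    dn <- x[, c(seq_len(W)[-1L], W), drop = FALSE]
  }
  (dn - up) / 2
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_rgb_image <- function(x) is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L

assert_rgb <- function(x) {
  if (!is_rgb_image(x))
    stop("expected an H x W x 3 RGB array; convert grayscale input by ",
         "replicating the channel, e.g. array(rep(g, 3), c(dim(g), 3))",
         call. = FALSE)
  invisible(x)
}
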