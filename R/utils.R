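# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Saves the caller's `.Random.seed`, seeds the RNG with `seed`, evaluates
#' `expr`, and restores the previous state, so that seeded generators are
#' bit-reproducible without perturbing the session RNG.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# FWHM of a Gaussian = 2*sqrt(2 ln 2) * sigma
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

# Normalized 1-D Gaussian kernel truncated at 3 sigma (always odd length).
gauss_kernel <- function(sigma_px) {
  if (sigma_px <= 0) return(1)
  r <- max(1L, ceiling(3 * sigma_px))
  k <- stats::dnorm(seq(-r, r), sd = sigma_px)
  k / sum(k)
}

# Shift an array along one dimension with replicate (clamped) boundaries.
shift_dim <- function(arr, dim_index, by) {
  d <- dim(arr)
  if (is.null(d)) d <- length(arr)
  n <- d[dim_index]
  idx <- pmin(pmax(seq_len(n) - by, 1L), n)
  args <- rep(list(quote(expr = )), length(d))
  args[[dim_index]] <- idx
  do.call(`[`, c(list(arr), args, list(drop = FALSE)))
}

# Separable Gaussian blur along one array dimension (replicate boundary).
blur_dim <- function(arr, dim_index, sigma_px) {
  k <- gauss_kernel(sigma_px)
  if (length(k) == 1L) return(arr)
  r <- (length(k) - 1L) / 2L
  out <- array(0, dim(arr))
  for (j in seq_along(k)) {
    out <- out + k[j] * shift_dim(arr, dim_index, j - r - 1L)
  }
  out
}

# Gaussian blur of a matrix (image) given FWHM in pixels.
blur_image_fwhm <- function(img, fwhm_px) {
  if (fwhm_px <= 0) return(img)
  s <- fwhm_to_sigma(fwhm_px)
  blur_dim(blur_dim(img, 1L, s), 2L, s)
}

# Bilinear sampling of matrix img (rows = y, cols = x) at fractional pixel
# coordinates; pixel centers sit at integer coordinates 1..n. Coordinates
# outside the grid are clamped to the border.
bilinear_sample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  i00 <- cbind(y0, x0); i01 <- cbind(y0, x0 + 1)
  i10 <- cbind(y0 + 1, x0); i11 <- cbind(y0 + 1, x0 + 1)
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}

# Rayleigh speckle amplitude with unit mean (sigma = sqrt(2/pi)).
rrayleigh_unit <- function(n) {
  sqrt(-2 * log(stats::runif(n))) / sqrt(pi / 2)
}

# Distance from points (px, py) to segment (ax,ay)-(bx,by); vectorized over
# points. Used by the tube rasterizer and by geometric test oracles.
point_segment_distance <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax; dy <- by - ay
  len2 <- dx * dx + dy * dy
  if (len2 == 0) return(sqrt((px - ax)^2 + (py - ay)^2))
  t <- ((px - ax) * dx + (py - ay) * dy) / len2
  t <- pmin(pmax(t, 0), 1)
  sqrt((px - (ax + t * dx))^2 + (py - (ay + t * dy))^2)
}

stopifnot_positive <- function(...) {
  vals <- list(...)
  nms <- sapply(substitute(list(...))[-1], deparse)
  for (i in seq_along(vals)) {
    v <- vals[[i]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v <= 0))
      stop(sprintf("'%s' must be positive and finite", nms[i]), call. = FALSE)
  }
  invisible(TRUE)
}
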