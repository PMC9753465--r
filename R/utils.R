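## internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_amis <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "amisquant_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

check_number <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_amis("amisquant_config_error", "'%s' must be a single finite number", name)
  if (x < min || (strict_min && x <= min) || x > max)
    stop_amis("amisquant_config_error", "'%s' = %g out of range [%g, %g]%s",
              name, x, min, max, if (strict_min) " (exclusive lower bound)" else "")
  x
}

check_count <- function(x, name, min = 0L) {
  check_number(x, name, min = min)
  if (x != as.integer(x))
    stop_amis("amisquant_config_error", "'%s' must be an integer count", name)
  as.integer(x)
}

## Partition `n` consecutive items into `k` contiguous near-equal runs,
## any remainder going to the earliest runs. Returns a factor of length n.
partition_index <- function(n, k) {
  if (k < 1L || n < k)
    stop_amis("amisquant_precondition_error",
              "cannot partition %d samples into %d sections", n, k)
  base <- n %/% k
  rem <- n %% k
  sizes <- rep(base, k)
  if (rem > 0L) sizes[seq_len(rem)] <- base + 1L
  rep.int(seq_len(k), sizes)
}

## Bilinear interpolation of a matrix img[y, x] at physical coords (x_um, y_um)
## under the voxel-centre convention: centre of pixel (row r, col c) is at
## ((c - 0.5) * px, (r - 0.5) * px). Coordinates outside the image raise a
## geometry error.
bilinear_sample <- function(img, x_um, y_um, pixel_size_um) {
  nx <- ncol(img); ny <- nrow(img)
  cx <- x_um / pixel_size_um - 0.5  # 0-based fractional column
  cy <- y_um / pixel_size_um - 0.5
  if (any(cx < -0.5 - 1e-9 | cx > nx - 0.5 + 1e-9 |
          cy < -0.5 - 1e-9 | cy > ny - 0.5 + 1e-9))
    stop_amis("amisquant_geometry_error",
              "sample position outside image bounds")
  ## clamp to the centre grid so edge samples use nearest-pixel values
  cx <- pmin(pmax(cx, 0), nx - 1)
  cy <- pmin(pmax(cy, 0), ny - 1)
  x0 <- floor(cx); y0 <- floor(cy)
  x1 <- pmin(x0 + 1, nx - 1); y1 <- pmin(y0 + 1, ny - 1)
  fx <- cx - x0; fy <- cy - y0
  i00 <- cbind(y0 + 1, x0 + 1); i01 <- cbind(y0 + 1, x1 + 1)
  i10 <- cbind(y1 + 1, x0 + 1); i11 <- cbind(y1 + 1, x1 + 1)
  img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
}

## deterministic RNG scope: run expr with seed, restore caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
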