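#' Segment a grayscale image into a binary marker mask
#'
#' Thresholds a grayscale matrix, either with Otsu's method (maximise
#' between-class variance over candidate cuts between consecutive observed
#' intensities) or a fixed intensity cut. Foreground is strictly above the
#' threshold. Already-binary input (logical, or exactly the values 0/1)
#' passes through unchanged under either method.
#'
#' @param image numeric or logical matrix of pixel intensities.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold intensity cut, required for `method = "fixed"`.
#' @param provenance source label forwarded to the result.
#' @return a [binary_image()].
#' @export
segment_image <- function(image, method = c("otsu", "fixed"),
                          threshold = NULL, provenance = "segmented") {
  method <- match.arg(method)
  if (!is.matrix(image) || length(image) == 0L)
    stop("image must be a non-empty matrix", call. = FALSE)
  if (is.logical(image))
    return(binary_image(image, provenance))
  vals <- sort(unique(as.vector(image)))
  if (method == "fixed") {
    if (is.null(threshold))
      stop("fixed segmentation requires a threshold", call. = FALSE)
  } else {
    if (length(vals) < 2L)
      stop("Otsu threshold is degenerate on a constant image", call. = FALSE)
    threshold <- otsu_threshold(as.vector(image))
  }
  binary_image(image > threshold, provenance)
}

# Otsu: pick the cut maximising w0*w1*(mu0-mu1)^2 over midpoints between
# consecutive distinct intensities (works for non-integer images too).
otsu_threshold <- function(v) {
  vals <- sort(unique(v))
  cuts <- (vals[-length(vals)] + vals[-1L]) / 2
  best <- -Inf
  thr <- cuts[1L]
  for (ct in cuts) {
    lo <- v <= ct
    w0 <- mean(lo)
    w1 <- 1 - w0
    s <- w0 * w1 * (mean(v[lo]) - mean(v[!lo]))^2
    if (s > best) {
      best <- s
      thr <- ct
    }
  }
  thr
}

#' Box-counting scan of a binary image
#'
#' Tiles the image with a non-overlapping grid of `eps` x `eps` boxes
#' anchored at the origin (top-left, 0-based) for every box size in the
#' ladder, and records the number of occupied boxes \eqn{N(\epsilon)} plus
#' the population mean and variance of per-box foreground mass. Partial
#' edge boxes are included. The default ladder is powers of 2 from 1 to
#' `floor(min_side / 2)`; pass `base = 3` (or explicit `box_sizes`) for
#' power-of-3 fixtures such as the Sierpinski carpet.
#'
#' @param img a [binary_image()] with at least one foreground pixel.
#' @param box_sizes optional strictly increasing integer box sides; each
#'   must be >= 1 and <= the smaller image side.
#' @param base ladder base used when `box_sizes` is `NULL` (2 or 3).
#' @return an object of class `box_count_curve`: a data frame with columns
#'   `box_size`, `occupied`, `mass_mean`, `mass_var` (one row per scale)
#'   and attribute `n_foreground`.
#' @export
#' @examples
#' img <- generate_spatial_image(c(64, 64), "solid")
#' box_count(img)
box_count <- function(img, box_sizes = NULL, base = 2L) {
  stopifnot(inherits(img, "binary_image"))
  px <- img$pixels
  if (!any(px))
    stop("box_count requires at least one foreground pixel", call. = FALSE)
  min_side <- min(dim(px))
  if (is.null(box_sizes)) {
    k <- floor(log(min_side / 2) / log(base) + 1e-9)
    if (k < 0) stop("image too small for a box-size ladder", call. = FALSE)
    box_sizes <- as.integer(base^(0:k))
  }
  box_sizes <- as.integer(box_sizes)
  if (any(box_sizes < 1L) || any(box_sizes > min_side) ||
      any(diff(box_sizes) <= 0))
    stop("box_sizes must be strictly increasing, within [1, min side]",
         call. = FALSE)
  m <- matrix(as.numeric(px), nrow(px), ncol(px))
  res <- lapply(box_sizes, function(eps) {
    gr <- (seq_len(nrow(m)) - 1L) %/% eps
    gc <- (seq_len(ncol(m)) - 1L) %/% eps
    mass <- as.vector(rowsum(t(rowsum(m, gr, reorder = TRUE)), gc,
                             reorder = TRUE))
    mm <- mean(mass)
    c(occupied = sum(mass > 0), mass_mean = mm,
      mass_var = mean(mass^2) - mm^2)  # population variance
  })
  out <- data.frame(box_size = box_sizes, do.call(rbind, res))
  out$occupied <- as.integer(out$occupied)
  attr(out, "n_foreground") <- sum(px)
  class(out) <- c("box_count_curve", "data.frame")
  out
}

#' Box-counting fractal dimension
#'
#' Ordinary least-squares slope of \eqn{\ln N(\epsilon)} against
#' \eqn{\ln \epsilon}: `fd = -slope`, clamped to \[0, 2\] (grid-edge
#' effects can push the raw slope marginally outside the admissible range
#' for 2-D images). For a constant curve (e.g. a single pixel) the slope is
#' 0 and the constant fit is exact, so `r2 = 1`.
#'
#' @param curve a [box_count()] result with at least 3 scales.
#' @return a list of class `fractal_metrics` with elements `fd`, `r2` (and
#'   `lacunarity = NA`; see [lacunarity()]).
#' @export
#' @examples
#' img <- generate_spatial_image(c(81, 81), "sierpinski_carpet")
#' fractal_dimension(box_count(img, base = 3))$fd  # ~ log(8)/log(3)
fractal_dimension <- function(curve) {
  stopifnot(inherits(curve, "box_count_curve"))
  use <- curve$occupied >= 1
  if (sum(use) < 3L)
    stop("fractal dimension needs at least 3 usable scales", call. = FALSE)
  lx <- log(curve$box_size[use])
  ly <- log(curve$occupied[use])
  slope <- stats::cov(lx, ly) / stats::var(lx)
  fitted <- mean(ly) + slope * (lx - mean(lx))
  ss_res <- sum((ly - fitted)^2)
  ss_tot <- sum((ly - mean(ly))^2)
  r2 <- if (ss_tot == 0) 1 else max(0, min(1, 1 - ss_res / ss_tot))
  structure(list(fd = max(0, min(2, -slope)), lacunarity = NA_real_,
                 r2 = r2),
            class = "fractal_metrics")
}

#' Fixed-grid lacunarity
#'
#' Per scale, \eqn{\lambda(\epsilon) = \mathrm{var}(m)/\mathrm{mean}(m)^2 +
#' 1} over the per-box foreground masses \eqn{m} of the origin-anchored
#' fixed grid (population moments, empty boxes included; no gliding box).
#' The summary lacunarity is the unweighted mean of \eqn{\lambda(\epsilon)}
#' over scales. A translation-invariant fill gives exactly 1; patchy, gappy
#' patterns give larger values. Scales with zero mean mass are skipped with
#' a warning.
#'
#' @param curve a [box_count()] result.
#' @return a list of class `fractal_metrics` with `lacunarity` populated
#'   and the per-scale values in `lambda_per_scale`.
#' @export
lacunarity <- function(curve) {
  stopifnot(inherits(curve, "box_count_curve"))
  ok <- curve$mass_mean > 0
  if (!any(ok))
    stop("lacunarity undefined: zero mean mass at every scale",
         call. = FALSE)
  if (any(!ok))
    warning(sum(!ok), " scale(s) with zero mean mass skipped")
  lam <- curve$mass_var[ok] / curve$mass_mean[ok]^2 + 1
  structure(list(fd = NA_real_, lacunarity = mean(lam), r2 = NA_real_,
                 lambda_per_scale = stats::setNames(lam,
                                                    curve$box_size[ok])),
            class = "fractal_metrics")
}

#' Fractal dimension and lacunarity of one image
#'
#' Convenience wrapper running [box_count()], [fractal_dimension()] and
#' [lacunarity()] on a single binary image.
#'
#' @inheritParams box_count
#' @return a `fractal_metrics` list with `fd`, `lacunarity` and `r2`.
#' @export
fractal_metrics <- function(img, box_sizes = NULL, base = 2L) {
  curve <- box_count(img, box_sizes = box_sizes, base = base)
  fd <- fractal_dimension(curve)
  lc <- lacunarity(curve)
  structure(list(fd = fd$fd, lacunarity = lc$lacunarity, r2 = fd$r2,
                 lambda_per_scale = lc$lambda_per_scale),
            class = "fractal_metrics")
}

#' @export
print.fractal_metrics <- function(x, ...) {
  cat("<fractal_metrics> fd:", format(x$fd, digits = 4),
      " lacunarity:", format(x$lacunarity, digits = 4),
      " r2:", format(x$r2, digits = 4), "\n")
  invisible(x)
}

#' Intersect marker masks into a Treg mask
#'
#' Cells positive for both CD4 and FOXP3 define the Treg-like population;
#' the metric core operates on one binary image, so channel merging is this
#' thin intersection.
#'
#' @param cd4_mask,foxp3_mask [binary_image()]s of identical shape.
#' @return a [binary_image()] of the pixelwise conjunction.
#' @export
treg_mask <- function(cd4_mask, foxp3_mask) {
  stopifnot(inherits(cd4_mask, "binary_image"),
            inherits(foxp3_mask, "binary_image"))
  if (!identical(dim(cd4_mask$pixels), dim(foxp3_mask$pixels)))
    stop("masks must have identical shape", call. = FALSE)
  binary_image(cd4_mask$pixels & foxp3_mask$pixels,
               provenance = paste0("treg(", cd4_mask$provenance, "&",
                                   foxp3_mask$provenance, ")"))
}

#' Compare a spatial metric between two image groups
#'
#' Extracts `fd` or `lacunarity` from per-image [fractal_metrics()] lists
#' and applies the two-sided [mann_whitney_u()] test, the standard
#' nonparametric comparison for per-slide spatial metrics between patient
#' groups (e.g. KRAS-mutant vs wild-type tissue).
#'
#' @param metrics_a,metrics_b lists of `fractal_metrics`, each of length
#'   >= 2.
#' @param measure `"fd"` or `"lacunarity"`.
#' @return a list with `measure`, `mean_a`, `mean_b`, `U`, `p.value`, and
#'   group sizes.
#' @export
compare_groups <- function(metrics_a, metrics_b,
                           measure = c("fd", "lacunarity")) {
  measure <- match.arg(measure)
  pull <- function(ms) vapply(ms, `[[`, numeric(1), measure)
  a <- pull(metrics_a)
  b <- pull(metrics_b)
  if (length(a) < 2L || length(b) < 2L)
    stop("each group needs at least 2 images", call. = FALSE)
  tst <- mann_whitney_u(a, b)
  list(measure = measure, mean_a = mean(a), mean_b = mean(b),
       U = tst$statistic, p.value = tst$p.value,
       n_a = length(a), n_b = length(b))
}
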