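# Age-adjusted, location-specific normative model and z-score
# standardization of en-face thickness maps.

# Mirror an en-face map horizontally (nasal/temporal flip). Left and right
# eyes are mirrored to a common orientation before normative fitting because
# retinal topography is nasal/temporal-asymmetric.
mirror_horizontal <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]

#' Fit the age-adjusted normative thickness model
#'
#' Fits, independently at every pixel and for every layer, the linear model
#' thickness ~ age across a reference set of non-atrophic eyes. The model
#' stores per-layer intercept and age-slope maps (um, um/year) and a
#' location-specific residual standard deviation map (um), floored at
#' `sd_floor` to keep the subsequent division numerically safe. Left eyes
#' are mirrored to the right-eye orientation before fitting.
#'
#' @param maps Either a `normative_set` (from [generate_normative_set()]) or
#'   a list, one element per eye, of named lists of layer matrices (um).
#' @param ages Ages in years (ignored when `maps` is a `normative_set`).
#' @param lateralities `"R"`/`"L"` per eye; defaults to all `"R"`.
#' @param pixel_pitch_deg Pixel pitch in degrees.
#' @param sd_floor Lower bound for the SD map, um.
#' @return An object of class `normative_model`: per-layer `intercept`,
#'   `age_slope` and `sd` matrices, `age_range`, `sd_floor`,
#'   `pixel_pitch_deg`, `n_reference`.
#' @export
fit_normative <- function(maps, ages = NULL, lateralities = NULL,
                          pixel_pitch_deg = NULL, sd_floor = 1) {
  if (inherits(maps, "normative_set")) {
    ages <- maps$ages
    lateralities <- maps$lateralities
    pixel_pitch_deg <- maps$pixel_pitch_deg
    maps <- maps$maps
  }
  n_eyes <- length(maps)
  if (n_eyes < 3) stop("need at least 3 reference maps", call. = FALSE)
  if (length(ages) != n_eyes) {
    stop("`ages` must have one value per reference eye", call. = FALSE)
  }
  if (var(ages) == 0) {
    stop("ages are constant; the age slope is not identifiable",
         call. = FALSE)
  }
  if (sd_floor <= 0) stop("sd_floor must be positive", call. = FALSE)
  lateralities <- lateralities %||% rep("R", n_eyes)
  layers <- names(maps[[1]])
  dims <- dim(maps[[1]][[1]])
  ok <- vapply(maps, function(m) {
    identical(sort(names(m)), sort(layers)) &&
      all(vapply(m, function(g) identical(dim(g), dims), logical(1)))
  }, logical(1))
  if (!all(ok)) stop("reference maps disagree in layers or geometry",
                     call. = FALSE)

  # Per-pixel least squares thickness ~ age, vectorized over pixels:
  # stack maps as an n_eyes x n_pixels matrix and solve the shared 2x2
  # normal equations.
  X <- cbind(1, ages)
  XtX_inv <- solve(crossprod(X))
  fit_layer <- function(ly) {
    Y <- do.call(rbind, lapply(seq_len(n_eyes), function(i) {
      g <- maps[[i]][[ly]]
      if (lateralities[i] == "L") g <- mirror_horizontal(g)
      as.vector(g)
    }))
    beta <- XtX_inv %*% crossprod(X, Y)     # 2 x n_pixels
    resid <- Y - X %*% beta
    sd_hat <- sqrt(colSums(resid^2) / (n_eyes - 2))
    list(intercept = matrix(beta[1, ], dims[1], dims[2]),
         age_slope = matrix(beta[2, ], dims[1], dims[2]),
         sd = matrix(pmax(sd_hat, sd_floor), dims[1], dims[2]))
  }
  layer_fits <- lapply(layers, fit_layer)
  names(layer_fits) <- layers
  structure(list(layers = layer_fits, age_range = range(ages),
                 sd_floor = sd_floor, pixel_pitch_deg = pixel_pitch_deg,
                 n_reference = n_eyes, orientation = "R"),
            class = "normative_model")
}

#' @export
print.normative_model <- function(x, ...) {
  d <- dim(x$layers[[1]]$intercept)
  cat(sprintf(
    "Normative model: %d reference eyes, layers %s, %d x %d grid\n",
    x$n_reference, paste(names(x$layers), collapse = "/"), d[1], d[2]))
  cat(sprintf("  age range %.1f-%.1f y, SD floor %g um\n",
              x$age_range[1], x$age_range[2], x$sd_floor))
  invisible(x)
}

#' Standardize a thickness map to z-scores
#'
#' Transforms a thickness map to z-score units pixel by pixel: the
#' age-adjusted normative mean is subtracted and the difference divided by
#' the location-specific normative SD,
#' `z(x) = (t(x) - (intercept(x) + slope(x) * age)) / sd(x)`.
#' Left-eye maps are standardized against the mirrored model so the
#' returned z-map stays in the eye's native orientation.
#'
#' @param map Thickness matrix, um.
#' @param age Age in years at acquisition.
#' @param model A [fit_normative()] model.
#' @param layer Layer name present in the model.
#' @param laterality `"R"` or `"L"`.
#' @return Matrix of z-scores with the same dimensions as `map`.
#' @export
standardize <- function(map, age, model, layer, laterality = "R") {
  stopifnot(inherits(model, "normative_model"))
  if (!layer %in% names(model$layers)) {
    stop("layer '", layer, "' not present in the normative model",
         call. = FALSE)
  }
  lf <- model$layers[[layer]]
  if (!identical(dim(map), dim(lf$intercept))) {
    stop("map geometry does not match the normative model", call. = FALSE)
  }
  if (age < model$age_range[1] || age > model$age_range[2]) {
    warning(sprintf(
      "age %.1f outside the normative reference range [%.1f, %.1f]; %s",
      age, model$age_range[1], model$age_range[2],
      "z-scores are extrapolated"), call. = FALSE)
  }
  mu <- lf$intercept + lf$age_slope * age
  sdm <- lf$sd
  if (laterality == "L") {
    mu <- mirror_horizontal(mu)
    sdm <- mirror_horizontal(sdm)
  }
  (map - mu) / sdm
}
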