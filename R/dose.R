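## Linear-quadratic dose-response: F(D) = alpha D^2 + beta D + gamma,
## fitted to (dose, cells, dicentrics) calibration points and inverted to
## estimate an absorbed dose from an observed dicentric frequency.

#' Dicentric frequency per cell
#'
#' Total number of class-1 (dicentric) boxes across an image set divided
#' by the number of images (one metaphase = one cell).
#'
#' @param detections list of per-image detection/box data.frames, or a
#'   single data.frame.
#' @param nImages number of cells (defaults to the list length).
#' @return dicentrics per cell.
#' @export
dicentricFrequency <- function(detections, nImages = NULL) {
  if (is.data.frame(detections)) detections <- list(detections)
  if (is.null(nImages)) nImages <- length(detections)
  stopifnot(nImages >= 1)
  sum(vapply(detections, function(d) sum(d$class_id == 1L), 0L)) / nImages
}

#' Fit the linear-quadratic dose-response curve
#'
#' Weighted least-squares fit of F = alpha D^2 + beta D + gamma to
#' calibration points `(dose, n_cells, n_dicentrics)`. The default weights
#' are `n_cells`, reflecting that the variance of a Poisson-count
#' frequency scales as 1/n_cells. Three noise-free points at distinct
#' doses are interpolated exactly. A negative fitted background `gamma`
#' is clipped to 0 with a warning.
#'
#' @param points data.frame with columns `dose` (Gy), `n_cells`,
#'   `n_dicentrics` — or `dose` and `frequency`.
#' @param weighting `"cells"` (default) or `"none"`.
#' @return A [DoseResponseModel-class] with the coefficient covariance.
#' @examples
#' pts <- data.frame(dose = c(0, 1, 2, 4), n_cells = 1000,
#'                   n_dicentrics = c(1, 85, 270, 890))
#' fitDoseResponse(pts)
#' @export
fitDoseResponse <- function(points, weighting = c("cells", "none")) {
  weighting <- match.arg(weighting)
  if (!"frequency" %in% names(points)) {
    stopifnot(all(c("dose", "n_cells", "n_dicentrics") %in% names(points)),
              all(points$n_cells >= 1))
    points$frequency <- points$n_dicentrics / points$n_cells
  }
  if (length(unique(points$dose)) < 3)
    stop("underdetermined: need at least 3 distinct doses", call. = FALSE)
  w <- if (weighting == "cells" && "n_cells" %in% names(points))
    points$n_cells else rep(1, nrow(points))
  fit <- lm(frequency ~ I(dose^2) + dose, data = points, weights = w)
  cf <- coef(fit)
  gamma <- cf[["(Intercept)"]]
  if (gamma < 0) {
    warning("fitted background gamma was negative (", signif(gamma, 3),
            "); clipped to 0")
    gamma <- 0
  }
  V <- tryCatch(vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  doseResponseModel(alpha = cf[["I(dose^2)"]], beta = cf[["dose"]],
                    gamma = gamma, cov = V)
}

#' Estimate absorbed dose from a dicentric frequency
#'
#' Inverts the linear-quadratic model: for alpha > 0 the non-negative root
#' \deqn{D = \frac{-\beta + \sqrt{\beta^2 + 4\alpha(F - \gamma)}}{2\alpha},}
#' for alpha = 0 the linear solution (F - gamma)/beta. Frequencies at or
#' below the background gamma give 0 Gy; a negative discriminant (possible
#' only when F < gamma) gives 0 Gy with a warning.
#'
#' @param model a [DoseResponseModel-class].
#' @param frequency observed dicentrics per cell (>= 0, vectorized).
#' @return estimated dose(s) in Gy.
#' @examples
#' m <- doseResponseModel(0.05, 0.03, 0.001)
#' estimateDose(m, doseResponse(m, 2))  # 2 Gy
#' @export
estimateDose <- function(model, frequency) {
  stopifnot(all(frequency >= 0))
  a <- model@alpha; b <- model@beta; g <- model@gamma
  vapply(frequency, function(f) {
    if (f <= g) return(0)
    if (a == 0) {
      if (b == 0) stop("degenerate model: alpha = beta = 0", call. = FALSE)
      return((f - g) / b)
    }
    disc <- b^2 + 4 * a * (f - g)
    if (disc < 0) {
      warning("no non-negative real root; returning 0 Gy")
      return(0)
    }
    (-b + sqrt(disc)) / (2 * a)
  }, numeric(1))
}
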