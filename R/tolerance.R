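#' Control parameters for Monte Carlo tolerance calibration
#'
#' Bivariate (ellipsoidal) tolerance factors have no closed form and are
#' calibrated by simulation over the sampling distribution of the sample mean
#' and covariance. These settings control that calibration.
#'
#' @param n_rep Number of outer Monte Carlo replicates, i.e. simulated
#'   `(mean, covariance)` draws. More replicates sharpen the confidence-level
#'   quantile.
#' @param n_inner Number of inner draws per replicate used to trace the
#'   empirical content-vs-radius curve of each simulated ellipsoid. Also sets
#'   the resolution of the content grid (`1 / n_inner`).
#' @param seed Base seed. The actual stream for each calibration is derived
#'   deterministically from this seed together with `n` and `gamma`, so
#'   results are reproducible and independent of call order.
#'
#' @return A list of class `tol_control`.
#' @export
#' @examples
#' tol_control(n_rep = 2000)
tol_control <- function(n_rep = 4000L, n_inner = 1000L, seed = 1234L) {
  stopifnot(n_rep >= 100, n_inner >= 100)
  structure(
    list(n_rep = as.integer(n_rep), n_inner = as.integer(n_inner),
         seed = as.integer(seed)),
    class = "tol_control"
  )
}

#' One-sided normal tolerance factor
#'
#' Factor `k1` such that the one-sided limit `mean + k1 * sd` (or
#' `mean - k1 * sd`) bounds at least a proportion `beta` of a normal
#' population with confidence `gamma`. Computed exactly from the noncentral-t
#' quantile, `k1 = qt(gamma, n - 1, ncp = qnorm(beta) * sqrt(n)) / sqrt(n)`.
#'
#' @param n Sample size (>= 2).
#' @param beta Content: population proportion to be bounded, in (0, 1).
#' @param gamma Confidence level, in (0, 1).
#'
#' @return The tolerance factor (vectorised over its arguments).
#' @export
#' @examples
#' tol_factor_one_sided(6, beta = 0.85, gamma = 0.90)
#' # converges to the normal quantile as n grows:
#' tol_factor_one_sided(1e6, 0.85, 0.90)
#' qnorm(0.85)
tol_factor_one_sided <- function(n, beta = 0.85, gamma = 0.90) {
  check_prob(beta, "beta")
  check_prob(gamma, "gamma")
  if (any(n < 2)) {
    abort("`n` must be at least 2 for a one-sided tolerance factor (no variance estimate otherwise).")
  }
  qt(gamma, df = n - 1, ncp = qnorm(beta) * sqrt(n)) / sqrt(n)
}

#' Monte Carlo calibration of bivariate ellipsoidal tolerance radii
#'
#' Simulates the sampling distribution of the squared Mahalanobis radius
#' needed for the data ellipsoid `(x - xbar)' S^-1 (x - xbar) <= k` to cover
#' a proportion `beta` of a bivariate normal population, at every content
#' level at once. Both [tol_factor_bivariate()] and [tol_content_bivariate()]
#' read from this table, which makes the two exact inverses of each other up
#' to interpolation.
#'
#' The calibration is carried out in canonical form (`mu = 0`, `Sigma = I`),
#' which is sufficient because the Mahalanobis radius is invariant under
#' affine transformation. Each replicate draws `xbar ~ N(0, I/n)` and
#' `S ~ Wishart(n - 1, I) / (n - 1)`, then traces the empirical quantile
#' curve of the form value `(X - xbar)' S^-1 (X - xbar)` over `n_inner`
#' population draws `X`. The stored radius at content `beta` is the `gamma`
#' quantile of the per-replicate `beta` quantiles.
#'
#' @param n Sample size the region will be built from (>= 3).
#' @param gamma Confidence level in (0, 1).
#' @param control A [tol_control()] list.
#'
#' @return An object of class `bivariate_calibration`: a list with the
#'   content grid `beta`, calibrated radii `k`, and the generating settings.
#' @export
#' @examples
#' cal <- bivariate_calibration(10, 0.90, tol_control(n_rep = 500))
#' approx(cal$beta, cal$k, xout = 0.85)$y
bivariate_calibration <- function(n, gamma = 0.90, control = tol_control()) {
  check_prob(gamma, "gamma")
  if (n < 3) abort("`n` must be at least 3 for a bivariate tolerance region.")
  n <- as.integer(n)
  key <- paste(n, format(gamma, digits = 12), control$n_rep, control$n_inner,
               control$seed, sep = "|")
  hit <- the$calibrations[[key]]
  if (!is.null(hit)) return(hit)

  R <- control$n_rep
  M <- control$n_inner
  # derived stream seed, kept within 32-bit integer range
  stream <- (control$seed + 7919 * n + round(1e5 * gamma)) %% .Machine$integer.max

  cal <- withr::with_seed(as.integer(stream), {
    xbar <- matrix(rnorm(2 * R, sd = 1 / sqrt(n)), ncol = 2)
    S <- rWishart(R, df = n - 1, Sigma = diag(2)) / (n - 1)
    # closed-form eigendecomposition of each 2x2 covariance
    a <- S[1, 1, ]; b <- S[1, 2, ]; d <- S[2, 2, ]
    disc <- sqrt(pmax((a - d)^2 / 4 + b^2, 0))
    l1 <- (a + d) / 2 + disc
    l2 <- pmax((a + d) / 2 - disc, .Machine$double.eps)
    off <- abs(b) > 1e-14
    v1x <- ifelse(off, b, 1); v1y <- ifelse(off, l1 - a, 0)
    nv <- sqrt(v1x^2 + v1y^2)
    v1x <- v1x / nv; v1y <- v1y / nv
    # coordinates of xbar in the eigenbasis
    b1 <- v1x * xbar[, 1] + v1y * xbar[, 2]
    b2 <- -v1y * xbar[, 1] + v1x * xbar[, 2]
    # inner population draws: quadratic form values, one row per replicate
    V <- (matrix(rnorm(R * M), R, M) - b1)^2 / l1 +
         (matrix(rnorm(R * M), R, M) - b2)^2 / l2
    V <- t(apply(V, 1L, sort, method = "quick"))
    # gamma quantile of each order statistic = radius at content j / M
    k <- apply(V, 2L, quantile, probs = gamma, names = FALSE)
    list(beta = seq_len(M) / M, k = cummax(k))
  })

  cal$n <- n
  cal$gamma <- gamma
  cal$control <- control
  class(cal) <- "bivariate_calibration"
  the$calibrations[[key]] <- cal
  cal
}

#' Bivariate ellipsoidal tolerance factor
#'
#' Squared Mahalanobis radius `k` such that the ellipsoid
#' `(x - xbar)' S^-1 (x - xbar) <= k` around the sample mean contains at
#' least a proportion `beta` of the bivariate normal population with
#' confidence `gamma`. As `n` grows (and for `gamma = 0.5`) the factor
#' approaches the chi-squared quantile `qchisq(beta, 2)`.
#'
#' @inheritParams bivariate_calibration
#' @param beta Content in (0, 1).
#'
#' @return The calibrated factor (vectorised over `beta`).
#' @export
#' @examples
#' tol_factor_bivariate(10, 0.85, 0.90, tol_control(n_rep = 500))
tol_factor_bivariate <- function(n, beta = 0.85, gamma = 0.90,
                                 control = tol_control()) {
  check_prob(beta, "beta")
  cal <- bivariate_calibration(n, gamma, control)
  approx(cal$beta, cal$k, xout = beta, rule = 2)$y
}

#' Largest content covered at a given squared Mahalanobis radius
#'
#' The inverse of [tol_factor_bivariate()]: the largest proportion `beta`
#' such that a tolerance region of squared Mahalanobis radius `d2` still
#' covers `beta` of the population with confidence `gamma`. Along a ridgeline
#' profile this is the coverage a species' tolerance region attains when
#' forced to extend exactly to a shared point. Returns 0 at `d2 = 0` (a
#' point covers nothing) and approaches 1 as `d2` grows.
#'
#' @inheritParams bivariate_calibration
#' @param d2 Squared Mahalanobis radius (>= 0); vectorised.
#'
#' @return Content values in `[0, 1)`, monotone nondecreasing in `d2`.
#' @export
#' @examples
#' ctl <- tol_control(n_rep = 500)
#' k <- tol_factor_bivariate(12, 0.85, 0.90, ctl)
#' tol_content_bivariate(k, 12, 0.90, ctl) # ~ 0.85
tol_content_bivariate <- function(d2, n, gamma = 0.90, control = tol_control()) {
  if (any(d2 < 0)) abort("`d2` must be nonnegative.")
  cal <- bivariate_calibration(n, gamma, control)
  # invert the monotone table k(beta); below the smallest radius content is ~0
  out <- approx(c(0, cal$k), c(0, cal$beta), xout = d2, rule = 2, ties = max)$y
  pmin(out, max(cal$beta) - 1e-12)
}

#' Per-species bivariate normal estimates of leaf traits
#'
#' Fits a bivariate normal to each species' per-specimen mean leaf length and
#' width (optionally log-transformed), producing the mean vector, unbiased
#' covariance matrix and sample size used by the ridgeline and tolerance
#' machinery. Species whose covariance is singular or near-singular (e.g.
#' a zero-variance trait) are flagged degenerate rather than dropped.
#'
#' @param means A specimen-means table as returned by [specimen_means()]
#'   (columns `species`, `leaf_length`, `leaf_width`).
#' @param transform `"log"` (default) to work on natural-log scale, or
#'   `"none"`. Size traits are positive and right-skewed, so the log scale is
#'   where the normal model is plausible.
#'
#' @return A tibble with one row per species: `species`, `n`, list-columns
#'   `mu` (length-2 mean vector) and `sigma` (2x2 covariance), and a logical
#'   `degenerate` flag. The transform used is stored as an attribute.
#' @export
#' @examples
#' panel <- generate_species("sp", n = 10, leaf_log_mean = c(3, 2),
#'                           leaf_log_cov = diag(0.02, 2),
#'                           flower_log_mean = 2, flower_log_sd = 0.3,
#'                           seed = 1)
#' estimate_bivariate(specimen_means(panel))
estimate_bivariate <- function(means, transform = c("log", "none")) {
  transform <- rlang::arg_match(transform)
  need <- c("species", "leaf_length", "leaf_width")
  missing_cols <- setdiff(need, names(means))
  if (length(missing_cols) > 0) {
    abort(paste0("`means` lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  small <- dplyr::count(means, .data$species) |> dplyr::filter(.data$n < 3)
  if (nrow(small) > 0) {
    abort(paste0("Bivariate estimation needs n >= 3 per species; too small: ",
                 paste(small$species, collapse = ", "),
                 ". Apply `filter_min_n()` first."))
  }
  f <- if (transform == "log") log else identity
  out <- means |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(
      n = dplyr::n(),
      mu = list(c(mean(f(.data$leaf_length)), mean(f(.data$leaf_width)))),
      sigma = list(cov(cbind(f(.data$leaf_length), f(.data$leaf_width)))),
      .groups = "drop"
    ) |>
    dplyr::mutate(degenerate = purrr::map_lgl(.data$sigma, is_degenerate_cov))
  attr(out, "transform") <- transform
  out
}

is_degenerate_cov <- function(sigma, tol = 1e-12) {
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  any(!is.finite(ev)) || min(ev) <= tol * max(abs(ev), 1)
}

check_prob <- function(x, name) {
  if (any(x <= 0 | x >= 1)) {
    abort(paste0("`", name, "` must lie strictly between 0 and 1."))
  }
  invisible(x)
}
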