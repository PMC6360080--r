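#' Tolerance-coverage profile along the ridgeline of a species pair
#'
#' For each point `x*(alpha)` of the ridgeline between two species' bivariate
#' normal estimates, computes the squared Mahalanobis distance from each
#' species' mean and converts it into `beta_i(alpha)`: the largest population
#' proportion of species *i* whose tolerance region (at confidence `gamma`,
#' sample size `n_i`) just reaches `x*(alpha)`. Where both profiles exceed
#' `1 - threshold`, tolerance regions each covering that much of their
#' species meet in at most a single point — the operational signature of a
#' morphological discontinuity.
#'
#' By construction `beta1(0) = 0` and `beta2(1) = 0`: at a species' own mean
#' the touching region degenerates to a point.
#'
#' @inheritParams ridgeline_manifold
#' @param gamma Confidence level for the tolerance regions (default 0.90).
#' @param control Monte Carlo settings, see [tol_control()].
#'
#' @return A tibble of class `beta_profile` with columns `alpha`, `x`, `y`,
#'   `d2_1`, `d2_2`, `beta1`, `beta2`.
#' @export
#' @examples
#' e1 <- list(mu = c(0, 0), sigma = diag(2), n = 10, species = "a")
#' e2 <- list(mu = c(6, 0), sigma = diag(2), n = 12, species = "b")
#' pr <- beta_profile(e1, e2, grid_size = 65, control = tol_control(n_rep = 500))
#' detect_gap_bivariate(pr)
beta_profile <- function(est1, est2, gamma = 0.90, grid_size = 513,
                         control = tol_control()) {
  e1 <- as_biv_estimate(est1, "est1")
  e2 <- as_biv_estimate(est2, "est2")
  if (is.na(e1$n) || is.na(e2$n)) abort("Estimates must carry sample sizes `n`.")
  curve <- ridgeline_manifold(e1, e2, grid_size = grid_size)
  pts <- cbind(curve$x, curve$y)
  d2_1 <- mahalanobis2(pts, e1$mu, e1$sigma)
  d2_2 <- mahalanobis2(pts, e2$mu, e2$sigma)
  out <- tibble(
    alpha = curve$alpha, x = curve$x, y = curve$y,
    d2_1 = d2_1, d2_2 = d2_2,
    beta1 = tol_content_bivariate(d2_1, e1$n, gamma, control),
    beta2 = tol_content_bivariate(d2_2, e2$n, gamma, control)
  )
  class(out) <- c("beta_profile", class(out))
  attr(out, "est1") <- e1
  attr(out, "est2") <- e2
  attr(out, "gamma") <- gamma
  attr(out, "control") <- control
  out
}

# continuous min(beta1, beta2)(alpha), shared by the decision and its
# grid-refinement step
profile_objective <- function(profile) {
  e1 <- attr(profile, "est1"); e2 <- attr(profile, "est2")
  gamma <- attr(profile, "gamma"); control <- attr(profile, "control")
  function(a) {
    p <- ridgeline_points(a, e1$mu, e1$sigma, e2$mu, e2$sigma)
    b1 <- tol_content_bivariate(mahalanobis2(p, e1$mu, e1$sigma), e1$n, gamma, control)
    b2 <- tol_content_bivariate(mahalanobis2(p, e2$mu, e2$sigma), e2$n, gamma, control)
    pmin(b1, b2)
  }
}

#' Bivariate morphological-gap decision for one species pair
#'
#' A discontinuity in the bivariate trait space is supported when some point
#' of the ridgeline is reached only by tolerance regions covering at least
#' `1 - threshold` of *each* species, i.e. when
#' `max_alpha min(beta1, beta2) >= 1 - threshold`. The grid maximum is
#' refined by continuous optimisation in the bracketing interval.
#'
#' @param profile A [beta_profile()] tibble.
#' @param threshold Overlap threshold (default 0.15, so content 0.85).
#'
#' @return A one-row tibble: `species_1`, `species_2`, `trait = "leaf"`,
#'   `supported`, `criterion_value` (the refined profile maximum),
#'   `alpha_max`, `threshold`, `gamma`.
#' @export
detect_gap_bivariate <- function(profile, threshold = 0.15) {
  check_prob(threshold, "threshold")
  if (!inherits(profile, "beta_profile")) {
    abort("`profile` must come from beta_profile().")
  }
  f <- profile_objective(profile)
  m <- pmin(profile$beta1, profile$beta2)
  i <- which.max(m)
  lo <- profile$alpha[max(i - 1, 1)]
  hi <- profile$alpha[min(i + 1, nrow(profile))]
  crit <- m[i]; a_max <- profile$alpha[i]
  if (hi > lo) {
    opt <- optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-6)
    if (opt$objective >= crit) {
      crit <- opt$objective
      a_max <- opt$maximum
    }
  }
  tibble(
    species_1 = attr(profile, "est1")$species,
    species_2 = attr(profile, "est2")$species,
    trait = "leaf",
    supported = crit >= 1 - threshold,
    criterion_value = crit,
    alpha_max = a_max,
    threshold = threshold,
    gamma = attr(profile, "gamma")
  )
}

#' Univariate one-tailed morphological-gap decision
#'
#' Compares a count trait (flower number per inflorescence) between two
#' species with one-sided normal tolerance limits on the (by default) log
#' scale: the species with the smaller transformed mean receives an upper
#' limit `xbar + k1 * s`, the other a lower limit `xbar - k1 * s`, with
#' `k1 = tol_factor_one_sided(n, 1 - threshold, gamma)`. A discontinuity is
#' supported when the upper limit falls below the lower limit; the criterion
#' value is the signed gap `L - U` on the transformed scale. A zero-variance
#' sample (e.g. a species whose every inflorescence carries one flower)
#' degenerates naturally to a limit at its mean.
#'
#' Direction assignment ties (equal transformed means) are broken by species
#' name order, making the decision deterministic and symmetric in its
#' arguments.
#'
#' @param counts1,counts2 Integer vectors of per-specimen flower counts.
#' @param species Character vector of the two species names.
#' @param gamma Confidence level (default 0.90).
#' @param threshold Overlap threshold; content is `1 - threshold`.
#' @param transform `"log"` (default) or `"none"`.
#'
#' @return A one-row tibble: `species_1`, `species_2`, `trait = "flower"`,
#'   `supported`, `criterion_value`, the natural-scale `upper_limit` of the
#'   low species and `lower_limit` of the high species, `species_low`,
#'   `species_high`, `threshold`, `gamma`.
#' @export
#' @examples
#' detect_gap_univariate(c(1, 1, 2, 1, 3, 2), c(800, 950, 881, 900, 850),
#'                       species = c("new", "known"))
detect_gap_univariate <- function(counts1, counts2,
                                  species = c("species_1", "species_2"),
                                  gamma = 0.90, threshold = 0.15,
                                  transform = c("log", "none")) {
  transform <- rlang::arg_match(transform)
  check_prob(gamma, "gamma")
  check_prob(threshold, "threshold")
  if (length(counts1) < 2 || length(counts2) < 2) {
    abort("Each species needs at least 2 flower counts.")
  }
  if (any(c(counts1, counts2) < 1)) abort("Flower counts must be >= 1.")
  f <- if (transform == "log") log else identity
  inv <- if (transform == "log") exp else identity
  x1 <- f(counts1); x2 <- f(counts2)
  beta <- 1 - threshold
  k1 <- tol_factor_one_sided(length(x1), beta, gamma)
  k2 <- tol_factor_one_sided(length(x2), beta, gamma)
  m1 <- mean(x1); m2 <- mean(x2)
  low_first <- if (m1 == m2) order(species)[1] == 1L else m1 < m2
  if (low_first) {
    upper <- m1 + k1 * sd(x1)
    lower <- m2 - k2 * sd(x2)
    lo_sp <- species[1]; hi_sp <- species[2]
  } else {
    upper <- m2 + k2 * sd(x2)
    lower <- m1 - k1 * sd(x1)
    lo_sp <- species[2]; hi_sp <- species[1]
  }
  tibble(
    species_1 = species[1],
    species_2 = species[2],
    trait = "flower",
    supported = upper < lower,
    criterion_value = lower - upper,
    upper_limit = inv(upper),
    lower_limit = inv(lower),
    species_low = lo_sp,
    species_high = hi_sp,
    threshold = threshold,
    gamma = gamma
  )
}

#' Pairwise gap scan of a focal species against a panel
#'
#' Runs the full decision procedure for the focal species against every
#' other species in a specimen-means table: the bivariate leaf-shape
#' decision along each pair's ridgeline and the univariate one-tailed
#' flower-number decision. Species below the minimum sample size are
#' excluded first; pairs whose leaf covariance is degenerate get a flower
#' decision only, with the event recorded.
#'
#' @param means A specimen-means tibble ([specimen_means()]).
#' @param focal Name of the focal (putative new) species.
#' @param config A [morphogap_config()] list.
#'
#' @return An object of class `morphogap_scan`: a list with `decisions`
#'   (long tibble, one row per pair and trait), `summary` (counts of pairs
#'   separated by leaf only, flower only, both, either, neither), `profiles`
#'   (named list of [beta_profile()] tibbles), `excluded`, `events`,
#'   `focal`, and `config`. Supports [tidy()], [glance()] and [autoplot()].
#' @export
run_all_pairs <- function(means, focal, config = morphogap_config()) {
  kept <- filter_min_n(means, config$min_n)
  excluded <- attr(kept, "excluded")
  if (!focal %in% kept$species) {
    abort(paste0("Focal species `", focal,
                 "` absent after the minimum-sample-size filter."))
  }
  ests <- estimate_bivariate(kept, transform = config$transform_leaf)
  counts <- split(kept$flower_count, kept$species)
  others <- sort(setdiff(ests$species, focal))
  focal_est <- dplyr::filter(ests, .data$species == focal)
  control <- tol_control(config$n_rep, config$n_inner, config$seed)

  events <- character()
  profiles <- list()
  decisions <- purrr::map(others, function(sp) {
    other_est <- dplyr::filter(ests, .data$species == sp)
    leaf <- NULL
    if (focal_est$degenerate[[1]] || other_est$degenerate[[1]]) {
      bad <- c(focal, sp)[c(focal_est$degenerate[[1]], other_est$degenerate[[1]])]
      events <<- c(events, paste0("degenerate leaf covariance for ",
                                  paste(bad, collapse = ", "),
                                  "; leaf decision skipped for pair ", sp))
      leaf <- tibble(species_1 = focal, species_2 = sp, trait = "leaf",
                     supported = NA, criterion_value = NA_real_,
                     alpha_max = NA_real_, threshold = config$threshold,
                     gamma = config$gamma)
    } else {
      pr <- beta_profile(focal_est, other_est, gamma = config$gamma,
                         grid_size = config$grid_size, control = control)
      profiles[[sp]] <<- pr
      leaf <- detect_gap_bivariate(pr, threshold = config$threshold)
    }
    flower <- detect_gap_univariate(
      counts[[focal]], counts[[sp]], species = c(focal, sp),
      gamma = config$gamma, threshold = config$threshold,
      transform = config$transform_flower
    )
    dplyr::bind_rows(leaf, flower)
  }) |>
    dplyr::bind_rows()

  summary <- summarise_decisions(decisions)
  structure(
    list(decisions = decisions, summary = summary, profiles = profiles,
         excluded = excluded, events = events, focal = focal, config = config),
    class = "morphogap_scan"
  )
}

summarise_decisions <- function(decisions) {
  wide <- decisions |>
    dplyr::select("species_1", "species_2", "trait", "supported") |>
    tidyr::pivot_wider(names_from = "trait", values_from = "supported")
  if (!"leaf" %in% names(wide)) wide$leaf <- NA
  if (!"flower" %in% names(wide)) wide$flower <- NA
  leaf <- wide$leaf %in% TRUE
  flower <- wide$flower %in% TRUE
  tibble(
    n_pairs = nrow(wide),
    leaf_gap = sum(leaf),
    flower_gap = sum(flower),
    both = sum(leaf & flower),
    leaf_only = sum(leaf & !flower),
    flower_only = sum(!leaf & flower),
    either = sum(leaf | flower),
    neither = sum(!leaf & !flower)
  )
}

#' @export
print.morphogap_scan <- function(x, ...) {
  cat("Morphological gap scan: `", x$focal, "` vs ",
      x$summary$n_pairs, " species\n", sep = "")
  cat("  gamma = ", x$config$gamma, ", threshold = ", x$config$threshold,
      " (content ", 1 - x$config$threshold, ")\n", sep = "")
  cat("  separated by leaf shape: ", x$summary$leaf_gap,
      "; by flower number: ", x$summary$flower_gap,
      "; both: ", x$summary$both,
      "; either: ", x$summary$either,
      "; neither: ", x$summary$neither, "\n", sep = "")
  if (nrow(x$excluded) > 0) {
    cat("  excluded (n too small): ",
        paste(x$excluded$species, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname run_all_pairs
#' @param x A `morphogap_scan` object.
#' @param ... Unused.
#' @method tidy morphogap_scan
#' @export
tidy.morphogap_scan <- function(x, ...) x$decisions

#' @rdname run_all_pairs
#' @method glance morphogap_scan
#' @export
glance.morphogap_scan <- function(x, ...) {
  dplyr::bind_cols(
    tibble(focal = x$focal),
    x$summary,
    tibble(gamma = x$config$gamma, threshold = x$config$threshold,
           n_excluded = nrow(x$excluded))
  )
}
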