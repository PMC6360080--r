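#' Plot a ridgeline tolerance-coverage profile
#'
#' Shows, for one species pair, the proportion of each species covered with
#' confidence `gamma` by the tolerance region reaching each point of the
#' ridgeline (x-axis: `alpha`, 0 at the first species' bivariate mean, 1 at
#' the second's), with a dashed reference line at content `1 - threshold`.
#' Two curves both crossing the reference line signal a discontinuity.
#'
#' @param object A [beta_profile()] tibble.
#' @param threshold Reference overlap threshold (default 0.15).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot beta_profile
#' @export
autoplot.beta_profile <- function(object, threshold = 0.15, ...) {
  e1 <- attr(object, "est1"); e2 <- attr(object, "est2")
  long <- tidyr::pivot_longer(
    as_tibble(object)[c("alpha", "beta1", "beta2")],
    cols = c("beta1", "beta2"), names_to = "side", values_to = "beta"
  ) |>
    dplyr::mutate(species = ifelse(.data$side == "beta1",
                                   as.character(e1$species),
                                   as.character(e2$species)))
  ggplot2::ggplot(long, ggplot2::aes(.data$alpha, .data$beta,
                                     colour = .data$species)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::geom_hline(yintercept = 1 - threshold, linetype = "dashed") +
    ggplot2::labs(
      x = "ridgeline position α",
      y = sprintf("proportion covered with confidence γ = %.2f",
                  attr(object, "gamma")),
      colour = NULL
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot the one-tailed flower-number tolerance limits of a scan
#'
#' For every pair in a gap scan, shows the focal species' and the other
#' species' flower-count ranges with the one-sided tolerance limits: the
#' upper limit of the low-count species (dashed) and the lower limit of the
#' high-count species (dotted), on a log axis. Non-overlap of the limits
#' supports a discontinuity.
#'
#' @param scan A `morphogap_scan` from [run_all_pairs()].
#' @return A ggplot object.
#' @export
plot_flower_gaps <- function(scan) {
  fl <- dplyr::filter(scan$decisions, .data$trait == "flower")
  if (nrow(fl) == 0) abort("Scan holds no flower decisions.")
  df <- fl |>
    dplyr::mutate(pair = .data$species_2) |>
    dplyr::arrange(.data$criterion_value)
  df$pair <- factor(df$pair, levels = df$pair)
  ggplot2::ggplot(df, ggplot2::aes(y = .data$pair)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$upper_limit,
                                       xend = .data$lower_limit,
                                       yend = .data$pair,
                                       colour = .data$supported)) +
    ggplot2::geom_point(ggplot2::aes(x = .data$upper_limit), shape = 4) +
    ggplot2::geom_point(ggplot2::aes(x = .data$lower_limit), shape = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "flowers per inflorescence (tolerance limits)",
                  y = NULL, colour = "gap supported") +
    ggplot2::theme_minimal()
}

#' @rdname run_all_pairs
#' @param object A `morphogap_scan`.
#' @param type `"leaf"` for a faceted grid of coverage profiles,
#'   `"flower"` for the one-tailed limit chart.
#' @method autoplot morphogap_scan
#' @export
autoplot.morphogap_scan <- function(object, type = c("leaf", "flower"), ...) {
  type <- rlang::arg_match(type)
  if (type == "flower") return(plot_flower_gaps(object))
  if (length(object$profiles) == 0) abort("Scan holds no leaf profiles.")
  long <- purrr::imap(object$profiles, function(pr, sp) {
    as_tibble(pr)[c("alpha", "beta1", "beta2")] |>
      dplyr::mutate(pair = sp)
  }) |>
    dplyr::bind_rows() |>
    tidyr::pivot_longer(c("beta1", "beta2"), names_to = "side",
                        values_to = "beta") |>
    dplyr::mutate(side = ifelse(.data$side == "beta1", "focal", "other"))
  ggplot2::ggplot(long, ggplot2::aes(.data$alpha, .data$beta,
                                     colour = .data$side)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(yintercept = 1 - object$config$threshold,
                        linetype = "dashed") +
    ggplot2::facet_wrap(~pair) +
    ggplot2::labs(x = "ridgeline position α", y = "proportion covered",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write per-pair coverage-profile figures
#'
#' Renders one PNG per stored ridgeline profile of a scan into `out_dir`.
#' An empty scan writes nothing and succeeds.
#'
#' @param scan A `morphogap_scan`.
#' @param out_dir Output directory (created if needed).
#' @param width,height,dpi Device settings passed to [ggplot2::ggsave()].
#' @return Invisibly, the written file paths.
#' @export
plot_profiles <- function(scan, out_dir, width = 5, height = 4, dpi = 120) {
  if (length(scan$profiles) == 0) return(invisible(character()))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- purrr::imap_chr(scan$profiles, function(pr, sp) {
    slug <- gsub("[^A-Za-z0-9]+", "_", sp)
    path <- file.path(out_dir, paste0(slug, ".png"))
    ggplot2::ggsave(path, autoplot(pr, threshold = scan$config$threshold),
                    width = width, height = height, dpi = dpi)
    path
  })
  invisible(unname(paths))
}
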