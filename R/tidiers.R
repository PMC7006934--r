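#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
tidy.cv_result <- function(x, ...) x$reps

#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(method = x$method, mean_pa = x$mean_pa, sd_pa = x$sd_pa,
                 n_reps = x$n_reps, p_value = x$p_value,
                 zero_pa = is.na(x$p_value) | x$p_value > 0.05)
}

#' @export
tidy.gp_fit <- function(x, ...) {
  eff <- c(x$f, x$b)
  if (is.null(eff)) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(term = names(eff), estimate = unname(eff))
}

#' @export
glance.gp_fit <- function(x, ...) {
  tibble::tibble(method = x$method, mu = x$mu, sigma2_g = x$sigma2_g,
                 sigma2_e = x$sigma2_e, n = length(x$gebv))
}

#' @export
tidy.gwas_scan <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.gwas_scan <- function(x, ...) {
  cf <- attr(x, "config")
  tibble::tibble(coding = cf$coding, kinship = cf$kinship, n_pc = cf$n_pc,
                 lambda = attr(x, "lambda"),
                 n_markers = dplyr::n_distinct(x$marker_id))
}

#' Manhattan plot of an association scan
#'
#' @param object a [gwas_scan()] result.
#' @param threshold optional p-value threshold drawn as a horizontal line.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.gwas_scan <- function(object, threshold = NULL, ...) {
  df <- tibble::as_tibble(object) |>
    dplyr::filter(is.finite(.data$p)) |>
    dplyr::arrange(.data$chrom, .data$pos) |>
    dplyr::mutate(index = dplyr::row_number(),
                  chrom = factor(.data$chrom))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$index, -log10(.data$p),
                                        colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.8) +
    ggplot2::facet_wrap(~effect, ncol = 1) +
    ggplot2::labs(x = "marker index", y = expression(-log[10](p)),
                  colour = "chromosome") +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = -log10(threshold),
                                 linetype = "dashed")
  }
  p
}

#' QQ plot of observed against expected scan p-values
#'
#' @inheritParams autoplot.gwas_scan
#' @return A ggplot annotated with the genomic inflation factor.
#' @export
plot_qq <- function(object, ...) {
  pv <- sort(object$p[is.finite(object$p)])
  df <- tibble::tibble(
    expected = -log10(stats::ppoints(length(pv))),
    observed = -log10(pv)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(
      x = expression(Expected ~ -log[10](p)),
      y = expression(Observed ~ -log[10](p)),
      subtitle = sprintf("lambda = %.3f", attr(object, "lambda"))
    ) +
    ggplot2::theme_minimal()
}

#' Boxplot of cross-validated predictive abilities
#'
#' @param object a `cv_result` or a list of them.
#' @param ... unused.
#' @return A ggplot of per-replicate Pearson correlations by method.
#' @export
autoplot.cv_result <- function(object, ...) {
  objs <- if (inherits(object, "cv_result")) list(object) else object
  df <- purrr::map_dfr(objs, function(o) {
    dplyr::mutate(o$reps, method = o$method)
  })
  means <- df |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(m = mean(.data$r, na.rm = TRUE))
  ggplot2::ggplot(df, ggplot2::aes(.data$method, .data$r)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::geom_text(data = means,
                       ggplot2::aes(.data$method, .data$m,
                                    label = sprintf("%.3f", .data$m)),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(x = NULL, y = "predictive ability (Pearson r)") +
    ggplot2::theme_minimal()
}

#' Plot adjusted yields and LNTI distributions
#'
#' @param adjusted the tibble from [adjusted_means()].
#' @return A ggplot with the per-regime adjusted-yield densities and the
#'   LNTI histogram.
#' @export
plot_adjusted_means <- function(adjusted) {
  long <- adjusted |>
    tidyr::pivot_longer(c("gy_ln", "gy_in"), names_to = "regime",
                        values_to = "yield")
  ggplot2::ggplot(long, ggplot2::aes(.data$yield, fill = .data$regime)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::labs(x = "adjusted grain yield (Mg/ha)", y = "density") +
    ggplot2::theme_minimal()
}
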