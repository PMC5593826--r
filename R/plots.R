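# ggplot2 helpers for the main result types.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Bar chart of the substitution spectrum
#'
#' @param calls tibble of calls (or a precomputed [spectrum_summary()])
#' @return a ggplot
#' @export
plot_spectrum <- function(calls) {
  tab <- if (all(c("class", "n", "fraction") %in% names(calls))) calls
         else spectrum_summary(calls)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$class, y = .data$fraction)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::scale_y_continuous(labels = function(x) sprintf("%.0f%%", 100 * x)) +
    ggplot2::labs(x = NULL, y = "fraction of variants",
                  title = "Substitution spectrum") +
    ggplot2::theme_minimal()
}

#' Coverage along the mitochondrial genome
#'
#' @param depth tibble with `position` and `depth` (from
#'   [assign_and_pileup()])
#' @param min_depth horizontal reference line
#' @return a ggplot
#' @export
plot_depth <- function(depth, min_depth = 30) {
  ggplot2::ggplot(depth, ggplot2::aes(x = .data$position, y = .data$depth)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_hline(yintercept = min_depth, linetype = 2,
                        colour = "firebrick") +
    ggplot2::labs(x = "mt-genome position (bp)", y = "read depth") +
    ggplot2::theme_minimal()
}

#' Per-lesion VAF profile of a patient's somatic variants
#'
#' One tile per (variant, lesion) coloured by VAF; trunk variants fill all
#' rows, private variants a single one.
#'
#' @param assignment a `clonal_assignment`
#' @return a ggplot
#' @export
plot_clonality <- function(assignment) {
  long <- assignment$variants |>
    mutate(vafs = purrr::map(.data$vafs, function(v) {
      tibble(lesion = names(v), vaf = unname(v))
    })) |>
    tidyr::unnest("vafs")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$lesion, y = .data$label,
                                     fill = .data$vaf)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$category),
                        scales = "free_y", space = "free_y") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "lesion", y = NULL, fill = "VAF") +
    ggplot2::theme_minimal()
}
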