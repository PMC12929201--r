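#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_tile geom_point
#'   facet_wrap labs scale_fill_viridis_c scale_fill_manual theme_minimal
#'   geom_hline scale_y_log10
#' @export
ggplot2::autoplot

#' Plot a knowledge-gap summary
#'
#' Bar chart of the relative frequency of no/weak-evidence drugs per
#' subpopulation, faceted by study type.
#'
#' @param object A [gap_summary()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gap_summary <- function(object, ...) {
  ggplot(object, aes(x = .data$subpopulation, y = .data$relative_frequency,
                     fill = .data$subpopulation)) +
    geom_col(show.legend = FALSE) +
    facet_wrap(~ study_type) +
    labs(x = NULL, y = "share of drugs with no or weak evidence",
         title = "Pharmacotherapy knowledge gap by subpopulation") +
    theme_minimal()
}

#' Plot a disproportionality screen
#'
#' EBGM against IC for every pair, signal decisions highlighted; the
#' dashed lines mark the decision thresholds on each axis.
#'
#' @param object A `signal_screen` tibble from [screen_signals()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.signal_screen <- function(object, ...) {
  ggplot(object, aes(x = .data$ic, y = .data$ebgm,
                     colour = .data$is_signal)) +
    geom_point(alpha = 0.6) +
    scale_y_log10() +
    labs(x = "information component (IC)", y = "EBGM (log scale)",
         colour = "signal",
         title = "Drug-event disproportionality screen") +
    theme_minimal()
}

#' Publication-evidence heatmap
#'
#' Tile plot of per-drug paper counts by study type for one subpopulation,
#' drugs ordered by descending overall publication frequency.
#'
#' @param evidence Output of [drug_evidence()].
#' @param subpopulation Subpopulation to display.
#' @return A ggplot.
#' @export
plot_evidence_heatmap <- function(evidence, subpopulation) {
  df <- filter(evidence, .data$subpopulation == !!subpopulation)
  ord <- df |>
    summarise(total = sum(.data$paper_count), .by = "drug") |>
    arrange(desc(.data$total), .data$drug)
  df <- mutate(df, drug = factor(.data$drug, levels = rev(ord$drug)))
  ggplot(df, aes(x = .data$study_type, y = .data$drug,
                 fill = log10(.data$paper_count + 1))) +
    geom_tile() +
    scale_fill_viridis_c(name = "log10(papers + 1)") +
    labs(x = NULL, y = NULL,
         title = paste("Publication evidence:", subpopulation)) +
    theme_minimal()
}
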