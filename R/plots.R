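write_figure <- function(plot, out_path, width = 9, height = 7) {
  base <- sub("\\.(png|svg)$", "", out_path)
  ggplot2::ggsave(paste0(base, ".png"), plot, width = width, height = height,
                  dpi = 150)
  ggplot2::ggsave(paste0(base, ".svg"), plot, width = width, height = height,
                  device = grDevices::svg)
  invisible(c(png = paste0(base, ".png"), svg = paste0(base, ".svg")))
}

# Axis labels for one radar panel: flagged metabolites get a trailing "*".
radar_labels <- function(flags, individual, level, timepoint, metabolites) {
  fl <- flags[flags$individual == individual &
                abs(flags$level - level) < 1e-12 &
                flags$timepoint == timepoint & !is.na(flags$flagged) &
                flags$flagged, "metabolite"]
  ifelse(metabolites %in% fl, paste0(metabolites, "*"), metabolites)
}

#' Radar plot of an individual's metabolite profile
#'
#' One polar panel per time point. Metabolite levels are min-max scaled per
#' metabolite across the cohort for display only (flags are always computed
#' on the raw scale). Light grey traces show the cohort, the highlighted
#' trace the chosen individual, and the shaded band their HPD prediction
#' interval; metabolites flagged at a time point carry an asterisk in that
#' panel's axis labels.
#'
#' @param dataset The observed [metabo_dataset()].
#' @param flags A [flag_individuals()] result.
#' @param individual Individual identifier to highlight.
#' @param level HPD level of the displayed band (must be in `flags`).
#' @param out_path Optional path; the figure is written as both PNG and
#'   SVG.
#' @return The assembled plot (patchwork), invisibly if written to file.
#' @export
radar_plot <- function(dataset, flags, individual, level = 0.975,
                       out_path = NULL) {
  stopifnot(inherits(dataset, "metabo_dataset"),
            inherits(flags, "flag_table"))
  if (!individual %in% dataset$individuals)
    stop(sprintf("unknown individual '%s'", individual), call. = FALSE)
  if (!any(abs(flags$level - level) < 1e-12))
    stop(sprintf("level %g not present in the flag table", level),
         call. = FALSE)
  sc <- dataset$schema
  mets <- sc$metabolites
  d <- dataset$data

  rng <- lapply(mets, function(m) range(d[[m]], na.rm = TRUE))
  names(rng) <- mets
  scale01 <- function(v, m)
    (v - rng[[m]][1L]) / max(rng[[m]][2L] - rng[[m]][1L], .Machine$double.eps)

  panels <- lapply(seq_len(dataset$T_max), function(t) {
    dt <- d[d[[sc$time]] == t, , drop = FALSE]
    long <- do.call(rbind, lapply(mets, function(m) data.frame(
      individual = as.character(dt[[sc$id]]), metabolite = m,
      value = scale01(dt[[m]], m), stringsAsFactors = FALSE)))
    long$axis <- match(long$metabolite, mets)
    band <- flags[flags$individual == individual &
                    abs(flags$level - level) < 1e-12 &
                    flags$timepoint == t, , drop = FALSE]
    band <- band[match(mets, band$metabolite), , drop = FALSE]
    band_df <- data.frame(axis = seq_along(mets),
                          lower = vapply(seq_along(mets), function(k)
                            scale01(band$lower[k], mets[k]), 0),
                          upper = vapply(seq_along(mets), function(k)
                            scale01(band$upper[k], mets[k]), 0))
    close_loop <- function(df) rbind(df, transform(df[1L, , drop = FALSE],
                                                   axis = length(mets) + 1L))
    band_df <- close_loop(band_df)
    cohort <- long[long$individual != individual, , drop = FALSE]
    self <- long[long$individual == individual, , drop = FALSE]
    cohort <- do.call(rbind, lapply(split(cohort, cohort$individual),
                                    close_loop))
    if (nrow(self)) self <- close_loop(self[order(self$axis), , drop = FALSE])

    ggplot2::ggplot() +
      ggplot2::geom_ribbon(data = band_df,
                           ggplot2::aes(x = .data$axis, ymin = .data$lower,
                                        ymax = .data$upper),
                           fill = "steelblue", alpha = 0.3) +
      ggplot2::geom_path(data = cohort,
                         ggplot2::aes(x = .data$axis, y = .data$value,
                                      group = .data$individual),
                         colour = "grey80", linewidth = 0.3) +
      ggplot2::geom_path(data = self,
                         ggplot2::aes(x = .data$axis, y = .data$value),
                         colour = "firebrick", linewidth = 0.8) +
      ggplot2::geom_point(data = self,
                          ggplot2::aes(x = .data$axis, y = .data$value),
                          colour = "firebrick", size = 1.2) +
      ggplot2::scale_x_continuous(
        breaks = seq_along(mets), limits = c(1, length(mets) + 1L),
        labels = radar_labels(flags, individual, level, t, mets)) +
      ggplot2::coord_polar() +
      ggplot2::labs(title = sprintf("Time point %d", t), x = NULL,
                    y = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.y = ggplot2::element_blank())
  })
  p <- patchwork::wrap_plots(panels) +
    patchwork::plot_annotation(
      title = sprintf("Individual %s (%.1f%% HPD)", individual, 100 * level))
  if (!is.null(out_path)) {
    write_figure(p, out_path)
    return(invisible(p))
  }
  p
}

#' Heatmap of metabolite-pair co-flagging counts
#'
#' Sequential red scale — darker cells mean more flagged individuals —
#' with the counts annotated.
#'
#' @param counts A symmetric count matrix from [pair_flag_counts()].
#' @param out_path Optional path; written as both PNG and SVG.
#' @return The ggplot, invisibly if written to file.
#' @export
pair_heatmap <- function(counts, out_path = NULL) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts))
  if (!isTRUE(all.equal(counts, t(counts))))
    stop("pair-count matrix must be symmetric", call. = FALSE)
  mets <- rownames(counts) %||% sprintf("m%d", seq_len(nrow(counts)))
  long <- expand.grid(row = mets, col = mets, stringsAsFactors = FALSE)
  long$count <- as.vector(counts)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$col, y = .data$row,
                                          fill = .data$count)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), size = 3) +
    ggplot2::scale_fill_gradient(low = "#fff5f0", high = "#99000d",
                                 limits = c(0, max(counts, 1))) +
    ggplot2::scale_x_discrete(limits = mets) +
    ggplot2::scale_y_discrete(limits = rev(mets)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "individuals") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
  if (!is.null(out_path)) {
    write_figure(p, out_path, width = 7, height = 6)
    return(invisible(p))
  }
  p
}

#' Boxplots of MAD values by model and time point
#'
#' @param result A [run_study()] result (or any data.frame with columns
#'   `model`, `timepoint`, `mad`).
#' @param out_path Optional path; written as both PNG and SVG.
#' @return The ggplot, invisibly if written to file.
#' @export
mad_boxplot <- function(result, out_path = NULL) {
  tab <- if (inherits(result, "simulation_result")) result$table else result
  stopifnot(is.data.frame(tab), nrow(tab) > 0L,
            all(c("model", "timepoint", "mad") %in% names(tab)))
  p <- ggplot2::ggplot(tab, ggplot2::aes(x = factor(.data$timepoint),
                                         y = .data$mad,
                                         fill = .data$model)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::scale_fill_manual(values = c(independent = "#fdae61",
                                          multivariate = "#2c7bb6")) +
    ggplot2::labs(x = "time point",
                  y = "MAD between correlation matrices",
                  fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(out_path)) {
    write_figure(p, out_path, width = 7, height = 5)
    return(invisible(p))
  }
  p
}
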