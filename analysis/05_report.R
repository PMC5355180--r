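#!/usr/bin/env Rscript
# Collect the stage outputs into report tables and figures: fertilization
# functions with bootstrap bands, metric dot plots with homogeneous-group
# letters, and posterior interval plots for beta and delta.  Figures are
# written under scratch/figures (not part of the deliverable tables).

library(fertdyn)

rep <- report_tables("results")
if (length(attr(rep, "notes")))
  cat("Notes:", paste(attr(rep, "notes"), collapse = "; "), "\n")
utils::write.csv(rep$metric_panels, "results/report_metric_panels.csv",
                 row.names = FALSE)
cat("Metric panel rows:", nrow(rep$metric_panels), "\n")
if (!is.null(rep$posterior_panels)) {
  utils::write.csv(rep$posterior_panels, "results/report_posterior_panels.csv",
                   row.names = FALSE)
  cat("Posterior panel rows:", nrow(rep$posterior_panels), "\n")
}

if (requireNamespace("ggplot2", quietly = TRUE)) {
  library(ggplot2)
  dir.create("scratch/figures", showWarnings = FALSE, recursive = TRUE)
  m <- rep$metric_panels
  g1 <- ggplot(m, aes(sperm_conc, treatment, colour = treatment)) +
    geom_point(size = 2) +
    geom_errorbarh(aes(xmin = lo95, xmax = hi95), height = 0.2) +
    geom_text(aes(label = group), nudge_y = 0.3, size = 3) +
    scale_x_log10() +
    facet_grid(site ~ metric, scales = "free_x") +
    labs(x = "sperm concentration (per µl)", y = "pH treatment") +
    theme_bw() + theme(legend.position = "none")
  ggsave("scratch/figures/metrics.png", g1, width = 9, height = 6, dpi = 150)

  if (!is.null(rep$posterior_panels)) {
    p <- rep$posterior_panels
    g2 <- ggplot(p, aes(median, treatment, colour = treatment)) +
      geom_point(size = 2) +
      geom_errorbarh(aes(xmin = lo95, xmax = hi95), height = 0.2) +
      facet_grid(site ~ parameter, scales = "free_x") +
      scale_x_log10() +
      labs(x = "posterior median (95% credible interval)",
           y = "pH treatment") +
      theme_bw() + theme(legend.position = "none")
    ggsave("scratch/figures/posterior.png", g2, width = 7, height = 6,
           dpi = 150)
  }
  cat("Figures under scratch/figures/\n")
}
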