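#!/usr/bin/env Rscript
# Two-week evening-reading protocol (eBook vs paper book) over the retained
# sleep-phenotype ensemble, both condition orders, at 90 and 500 lux daytime
# baselines. Produces per-night sleep onset latencies, the mean eBook-minus-
# Book latency difference (delta), and per-order phase-shift summaries.
suppressPackageStartupMessages(library(circalux))
dir.create("results", showWarnings = FALSE)

filter_file <- "results/sleep_grid_filter.csv"
pts <- if (file.exists(filter_file)) {
  p <- read.csv(filter_file)
  p[p$pass, ]
} else {
  message("no filter output found; rerunning the grid search")
  f <- sweep_sleep_filter()
  f$points[f$points$pass, ]
}
message(sprintf("running %d retained sets x 2 orders x 2 baselines", nrow(pts)))

summaries <- list()
for (baseline in c(90, 500)) {
  m <- run_chang_ensemble(pts, baseline_lux = baseline)
  write.csv(m, sprintf("results/ebook_sol_metrics_%dlux.csv", baseline),
            row.names = FALSE)
  s <- summarize_ensemble(m)
  message(sprintf("%d lux: mean SOL eBook %.1f min, Book %.1f min, delta %.2f min",
                  baseline,
                  s$sol_by_condition$mean[s$sol_by_condition$condition == "ebook"],
                  s$sol_by_condition$mean[s$sol_by_condition$condition == "book"],
                  s$delta_sol_min))
  summaries[[as.character(baseline)]] <-
    cbind(baseline_lux = baseline, delta_sol_min = s$delta_sol_min,
          s$shift_by_order)
}
write.csv(do.call(rbind, summaries), "results/ebook_sol_summary.csv",
          row.names = FALSE)
message("wrote results/ebook_sol_metrics_{90,500}lux.csv and results/ebook_sol_summary.csv")
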