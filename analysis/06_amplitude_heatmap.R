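#!/usr/bin/env Rscript
# Average circadian amplitude over the last day of 20-day baseline-plus-pulse
# runs, on an 11 x 15 grid of baseline level (0-1000 lux) by pulse offset
# (0-14 h after waking). Bright baselines with midday pulses maximize
# amplitude; dim baselines with day-edge pulses minimize it.
suppressPackageStartupMessages(library(circalux))
dir.create("results", showWarnings = FALSE)

hm <- amplitude_heatmap(seq(0, 1000, by = 100), 0:14)
write.csv(hm, "results/amplitude_heatmap.csv", row.names = FALSE)

best <- hm[which.max(hm$amplitude), ]
worst <- hm[which.min(hm$amplitude), ]
message(sprintf("max amplitude %.3f at baseline %d lux, pulse %d h after waking",
                best$amplitude, best$baseline_lux, best$pulse_offset_h))
message(sprintf("min amplitude %.3f at baseline %d lux, pulse %d h after waking",
                worst$amplitude, worst$baseline_lux, worst$pulse_offset_h))

fig <- ggplot2::ggplot(hm, ggplot2::aes(pulse_offset_h, baseline_lux,
                                        fill = amplitude)) +
  ggplot2::geom_tile() +
  ggplot2::scale_fill_viridis_c(name = "avg amplitude") +
  ggplot2::labs(x = "pulse offset (h after waking)", y = "baseline lux") +
  ggplot2::theme_minimal()
ggplot2::ggsave("results/amplitude_heatmap.png", fig, width = 6, height = 4,
                dpi = 150)
message("wrote results/amplitude_heatmap.{csv,png}")
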