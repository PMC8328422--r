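#!/usr/bin/env Rscript
# Stage 2: validate scale measurements as growth proxies.
#
# Before using increment widths as a somatic-growth proxy, checks that the
# scale tracks the body: ordinary least squares of fork length on scale
# radius (and on circulus count), with a group offset and slope interaction
# to confirm the relationship is shared by wild and hatchery-reared fish.

library(scalechron)

ds <- read_increment_csv("results/data/fish.csv",
                         "results/data/increments.csv")
ds <- prepare_dataset(ds)

cal_r <- fit_calibration(ds$fish, "radius")
cal_c <- fit_calibration(ds$fish, "circuli")

print(cal_r)
cat("\n")
print(cal_c)

tab <- compare_calibrations(ds$fish)
cat("\nPreferred proxy:", tab$predictor[tab$preferred], "\n")
cat("(radius explains", round(100 * cal_r$r_squared), "% of fork-length",
    "variance; circuli", round(100 * cal_c$r_squared), "%)\n")

dir.create("results", showWarnings = FALSE)
out <- dplyr::bind_rows(
  dplyr::mutate(cal_r$coefficients, predictor = "radius",
                r_squared = cal_r$r_squared, .before = 1),
  dplyr::mutate(cal_c$coefficients, predictor = "circuli",
                r_squared = cal_c$r_squared, .before = 1))
readr::write_csv(out, "results/calibration.csv")
cat("Wrote results/calibration.csv\n")
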