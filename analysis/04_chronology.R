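#!/usr/bin/env Rscript
# Stage 4: growth biochronologies, variance partition, plasticity test.
#
# Turns the posterior draws from stage 3 into per-stratum growth
# chronologies (posterior of the year effects), partitions the growth
# variance among observation, fish and year sources, and compares the
# spread of individual growth levels between wild and hatchery-reared fish
# with the variance-ratio test.

library(scalechron)

sigma <- as.matrix(readr::read_csv("results/posterior/sigma_draws.csv",
                                   show_col_types = FALSE))
u_year <- as.matrix(
  readr::read_csv("results/posterior/year_effect_draws.csv",
                  show_col_types = FALSE))
fish <- readr::read_csv("results/posterior/fish_intercepts.csv",
                        show_col_types = FALSE)

chron <- extract_chronology(u_year)
readr::write_csv(tibble::as_tibble(chron), "results/chronology.csv")
cat("Chronology cells per stratum:\n")
print(table(paste(chron$group, chron$environment, sep = ":")))

vp <- variance_partition(c(obs = mean(sigma[, "obs"]),
                           fish = mean(sigma[, "fish"]),
                           year = mean(sigma[, "year"])))
cat("\nVariance partition (posterior-mean SDs):\n")
print(as.data.frame(vp), digits = 3)
readr::write_csv(vp, "results/variance_partition.csv")

pt <- fish_plasticity_test(fish$intercept_mean, fish$group)
cat("\n")
print(pt)
readr::write_csv(tibble::tibble(f = pt$f, df1 = pt$df[1], df2 = pt$df[2],
                                p_value = pt$p_value,
                                var_hatchery = pt$variance[["hatchery"]],
                                var_wild = pt$variance[["wild"]]),
                 "results/plasticity_test.csv")
cat("Wrote results/chronology.csv, variance_partition.csv,",
    "plasticity_test.csv\n")
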