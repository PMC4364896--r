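#!/usr/bin/env Rscript
# Step 5: mast frequency under synthetic warming scenarios.
#
# Three synthetic 129-year scenario temperature series (2 lead-in years +
# 1972-2098) stand in for downscaled climate-model output: each is cooler
# and damped relative to the station-like fixture record (the typical bias
# of grid-interpolated scenarios) and carries a linear warming trend whose
# steepness differs by scenario. Each is bias-adjusted to the fixture
# record's overlap moments, then mast years are predicted by the climate
# thresholds (T_{y} >= T_thres, dT_y >= dT_thres) and their frequency
# statistics tabulated. Run 01 and 03 first.

library(pulsepop)

temps <- read_annual("results/fixture/temperature.csv", units = "degC")
sfm <- readRDS("results/seedfall_models.rds")
masts <- sfm$masts
cat(sprintf("thresholds from the historical record: T_thres = %.2f degC, dT_thres = %.2f degC\n\n",
            masts$t_thres, masts$dt_thres))

# historical (observed-seedfall) mast statistics for the comparison column
hist_st <- mast_interval_stats(masts$flags)

scenario_defs <- list(  # trend in degC per decade, synthetic stand-ins
  high_warming = 0.30, mid_warming = 0.20, low_warming = 0.12)

rows <- list()
rows[["historical/seedfall"]] <- c(model = "seedfall", scenario = "historical",
                                   hist_st[c("prop_single", "prop_double", "mean_gap")])
for (nm in names(scenario_defs)) {
  raw <- gen_temperatures(129, mean = 15.3, sd = 0.45,
                          seed = 100 + match(nm, names(scenario_defs)),
                          start_year = 1970)
  raw$value <- raw$value + scenario_defs[[nm]] / 10 * (seq_len(129) - 1)
  adj <- adjust_scenario(raw, temps)
  dts <- compute_delta_t(adj)
  # scenario century: the final 100 years of the series
  cent_years <- utils::tail(adj$year, 100)
  t_flags <- adj$value[adj$year %in% cent_years] >= masts$t_thres
  dt_flags <- dts$value[dts$year %in% cent_years] >= masts$dt_thres
  for (model in c("T", "dT")) {
    fl <- if (model == "T") t_flags else dt_flags
    st <- mast_interval_stats(fl)
    rows[[paste(nm, model)]] <- c(model = model, scenario = nm,
                                  st[c("prop_single", "prop_double", "mean_gap")])
  }
}
tab <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
rownames(tab) <- NULL
print(tab, digits = 3)
dir.create("results", showWarnings = FALSE)
write.csv(tab, "results/scenario_mast_frequency.csv", row.names = FALSE)

cat("\nUnder warming trends the absolute-T threshold is crossed in most\n")
cat("years (mast 'predicted' almost every year), while the delta-T\n")
cat("threshold depends on year-to-year change and keeps mast frequency\n")
cat("near its historical rate - the qualitative contrast between the two\n")
cat("climate drivers.\n")
cat("\nwrote results/scenario_mast_frequency.csv\n")
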