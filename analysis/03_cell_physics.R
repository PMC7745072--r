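#!/usr/bin/env Rscript
# Stage 3: physical cell parameters and biomass composition.
#
# Intersects the four mean cell-mass curves (buoyant mass; dry mass over
# dry-mass fraction; two water-balance forms) to find the most probable cell
# diameter and mass window, derives volume / surface / SA:V, and accounts the
# measured biomass masses as dry-mass fractions.

suppressPackageStartupMessages(library(mincell))
dir.create("results", showWarnings = FALSE)

win <- most_probable_window(cell_phys_params())
print(win)

panel <- biomass_panel()
fr <- biomass_fractions(panel)
cat("\nbiomass fractions (% of dry mass):\n")
print(transform(fr, fraction_pct = round(fraction_pct, 1)), row.names = FALSE)
carbs <- carb_composition(panel)
cat("\ncarbohydrate composition (% of carbohydrate mass):\n")
print(transform(carbs, fraction_pct = round(fraction_pct, 1)), row.names = FALSE)

write.table(fr, "results/biomass_fractions.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(carbs, "results/carb_composition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_budget_json(list(
  diameter_nm = win$d_range_nm, mass_fg = win$mass_range,
  volume_um3 = win$volume_range, area_um2 = win$area_range,
  sav_per_um = win$sav_range), "results/phys_window.json")
cat("\nwrote results/phys_window.json, biomass_fractions.tsv, carb_composition.tsv\n")
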