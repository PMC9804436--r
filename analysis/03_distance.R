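#!/usr/bin/env Rscript
# Build the along-shelf distance field (shortest paths over shelf cells with
# coastline and shelf break as barriers) and assign each cleaned stranding
# its poleward distance from the southern origin.

source("analysis/_common.R")

world <- study_world()
records <- utils::read.csv("results/records_clean.csv")

grid <- synthetic_shelf_grid(world)
field <- build_distance_field(grid, origin = world$origin)
print(field)

records <- poleward_distance(records, field, snap_km = 25)
n_ok <- sum(!is.na(records$poleward_distance_km))
message(sprintf("Assigned poleward distance to %d/%d records (%d unsnappable)",
                n_ok, nrow(records), nrow(records) - n_ok))
message(sprintf("Distance range: %.0f - %.0f km",
                min(records$poleward_distance_km, na.rm = TRUE),
                max(records$poleward_distance_km, na.rm = TRUE)))
save_table(records, "records_distance")
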