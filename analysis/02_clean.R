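#!/usr/bin/env Rscript
# Parse the raw stranding CSVs through the Level-A reader, normalize
# coordinate notation, cross-check locations against the county gazetteer,
# and split the coast at Cape Hatteras. No row is dropped silently.

source("analysis/_common.R")
library(dplyr)

files <- list.files("results/synthetic", pattern = "\\.csv$", full.names = TRUE)
files <- files[!basename(files) %in% c("sst_cube.csv", "census.csv")]
stopifnot(length(files) > 0)

census <- utils::read.csv("results/synthetic/census.csv")
gaz <- gazetteer_from_census(census)

all_records <- list(); all_rejects <- list()
for (f in files) {
  parsed <- read_level_a(f)
  recs <- parsed$records |>
    normalize_coordinates() |>
    validate_locations(gaz, max_km = 50) |>
    assign_region(split_latitude = 35.25)
  all_records[[f]] <- recs
  all_rejects[[f]] <- parsed$rejects
  message(sprintf("  %-28s %5d records, %d rejects", basename(f),
                  nrow(recs), nrow(parsed$rejects)))
}
records <- bind_rows(all_records)
rejects <- bind_rows(all_rejects)

message(sprintf("Cleaned %d records (%d rejects); %d NEUS / %d SEUS; %d flagged",
                nrow(records), nrow(rejects),
                sum(records$region == "NEUS"), sum(records$region == "SEUS"),
                sum(records$qc_flags != "")))
save_table(records, "records_clean")
if (nrow(rejects) > 0) save_table(rejects, "records_rejects")
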