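# Shared fixtures built in code.

# a minimal two-event survey: one day, one location, 8 water + 8 sediment
# replicates, detections placed by hand
tiny_survey <- function() {
  samples <- do.call(rbind, lapply(c("water", "sediment"), function(sub) {
    data.frame(sample_id = paste0(sub, "_r", 1:8),
               location = "L1", substrate = sub, season = "wet",
               date = "2023-03-10", replicate_index = 1:8,
               volume_ml = if (sub == "water") 450 else NA_real_,
               stringsAsFactors = FALSE)
  }))
  detections <- data.frame(
    sample_id = c("water_r1", "water_r2", "water_r3",  # sp A in 3 water reps
                  "water_r1",                          # sp B, 12SV5 only
                  "sediment_r5"),                      # sp A in 1 sediment rep
    primer = c("12SV5", "MiMammal", "12SV5", "12SV5", "MiMammal"),
    taxon_name = c("Aardvark one", "Aardvark one", "Aardvark one",
                   "Bushpig two", "Aardvark one"),
    rank = "species",
    read_count = c(10L, 20L, 5L, 7L, 3L), stringsAsFactors = FALSE)
  list(samples = samples, detections = detections)
}

write_tsv_tmp <- function(df, name) {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()), name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
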