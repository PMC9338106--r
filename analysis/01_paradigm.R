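#!/usr/bin/env Rscript
# Paradigm sanity checks and the trial schedule.
#
# Verifies the task geometry against its printed values (the target's 667-ms
# transit to the zone center, the square's 2-cm displacement per 100-ms
# motion epoch, the initial edge distances of 3.5/18.5/33.5 cm), builds the
# 600-trial randomized schedule and the background disc scene, and writes
# both under results/.

library(mfresponse)

dir.create("results", showWarnings = FALSE)

geom <- mfr_geometry()
checks <- data.frame(
  quantity = c("target_transit_time_ms", "square_displacement_cm",
               "nearest_edge_small_cm", "nearest_edge_medium_cm",
               "nearest_edge_large_cm"),
  value = c(1000 * geom$target_start_offset / geom$target_speed,
            square_position(0.45, list(square_onset = 0.35,
                                       direction = "right"), geom),
            nearest_edge_distance(7), nearest_edge_distance(37),
            nearest_edge_distance(67)))
print(checks)
write.csv(checks, "results/paradigm_checks.csv", row.names = FALSE,
          quote = FALSE)

sched <- build_schedule(25, 2, seed = 1)
counts <- schedule_counts(sched)
cat(sprintf("schedule: %d trials, cell counts per block all %d: %s\n",
            nrow(sched), max(counts), all(counts == 25)))
write_schedule(sched, "results/schedule.csv")

scene <- generate_scene(1, geom)
write.csv(round(scene, 3), "results/scene_discs.csv", row.names = FALSE,
          quote = FALSE)
cat(sprintf("scene: %d background discs written\n", nrow(scene)))
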