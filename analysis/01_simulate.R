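#!/usr/bin/env Rscript
# Simulate one scene of each kind (IHC row, supporting-cell epithelium,
# SGN terminals) with known ground truth. Movies go to scratch/ (large,
# binary); ground truth and scene configurations go to results/scenes/.

suppressPackageStartupMessages(library(cochleaCa))

out <- "results/scenes"
movies <- "scratch/scenes"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
dir.create(movies, recursive = TRUE, showWarnings = FALSE)

scenes <- list(
  ihc = scene_config("ihc", n_frames = 9000, frame_rate = 30, px_size = 2,
                     height = 32, width = 224, n_ihc = 20, seed = 101),
  supporting = scene_config("supporting", n_frames = 1500, frame_rate = 10,
                            px_size = 1, height = 176, width = 224,
                            seed = 102, wave_rate_per_min = 8,
                            wave_min_separation_s = 8, wave_offset_um = 40),
  sgn = scene_config("sgn", n_frames = 9000, frame_rate = 30, px_size = 1,
                     height = 48, width = 200, n_ihc = 6, seed = 103))

for (kind in names(scenes)) {
  cfg <- scenes[[kind]]
  sc <- switch(kind,
               ihc = generate_ihc_scene(cfg),
               supporting = generate_supporting_scene(cfg),
               sgn = generate_sgn_scene(cfg))
  write_movie(sc$movie, file.path(movies, paste0(kind, ".tif")))
  truth <- sc$truth
  truth$signal <- NULL     # frame-by-frame signal matrix: too big for JSON
  write_ground_truth(truth, file.path(out, paste0(kind, "_truth.json")))
  n_items <- switch(kind,
                    ihc = nrow(sc$truth$participants),
                    supporting = nrow(sc$truth$waves),
                    sgn = nrow(sc$truth$participants))
  cat(sprintf("%-10s %d x %d px, %d frames @ %g Hz -> %d ground-truth %s\n",
              kind, cfg$height, cfg$width, cfg$n_frames, cfg$frame_rate,
              n_items,
              if (kind == "supporting") "waves" else "peaks"))
}
cat("movies in", movies, "; ground truth in", out, "\n")
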