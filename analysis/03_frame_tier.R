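#!/usr/bin/env Rscript
# Frame-tier demonstration: renders near-IR camera-frame triplets for a
# small simulated session, tracks pupil and head marker, and compares the
# tracked displacements with the generating ground truth. Uses a compact
# camera geometry so the whole session renders in seconds; the tracker's
# accuracy contract (sub-0.05 px) is unchanged by frame size.
# Writes results/tracking_accuracy.csv.

library(ofrkit)

cam <- camera_model(frame_size_px = c(320, 280), pupil_radius_px = 18,
                    iris_radius_px = 45, marker_radius_px = 7,
                    px_per_deg = 40, pupil_center = c(200, 150),
                    marker_center = c(70, 70))
tracker <- list(pupil_min_area = 400, pupil_max_area = 1e4,
                marker_min_area = 40, marker_max_area = 600,
                exclude_radius = 80)

model <- subject_model(n_trials_per_cell = 5, seed = 301,
                       movement_noise_sd_deg = 0.1,
                       fixation_noise_sd_deg = 0.03,
                       head_noise_sd_px = 0.4,
                       saccade_rate = 0, head_jump_rate = 0,
                       blink_rate = 0.1)
session <- simulate_trial_table(model)
triplets <- render_session_frames(session, cam)
tracked <- track_session(triplets, tracker)

ok <- !session$trials$blink_flag
cols <- grep("^d[xy]_", names(tracked), value = TRUE)
err <- abs(as.matrix(tracked[ok, cols]) -
             as.matrix(session$trials[ok, cols]))
acc <- data.frame(metric = c("n_trials", "n_blinks_true",
                             "n_blinks_detected", "max_abs_err_px",
                             "rmse_px"),
                  value = c(nrow(tracked), sum(session$trials$blink_flag),
                            sum(tracked$blink_flag), max(err),
                            sqrt(mean(err^2))))

dir.create("results", showWarnings = FALSE)
write.csv(acc, "results/tracking_accuracy.csv", row.names = FALSE)
cat("Tracked", nrow(tracked), "trials;", sum(tracked$blink_flag),
    "blink discards (", sum(session$trials$blink_flag), "generated).\n")
cat(sprintf("Displacement recovery: max |err| = %.4f px, RMSE = %.4f px\n",
            max(err), sqrt(mean(err^2))))
cat("Both are expected to sit well below the 0.05 px contract.\n")
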