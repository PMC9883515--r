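#!/usr/bin/env Rscript
# Mechanistic dissection: (i) the model-variant dichotomy — upstream-seeded
# skeleton-model waves reverse to downstream propagation across a 3x3
# (E:D, v_f) grid, while the reduced switch model (which by construction
# cannot respond to MinE advection) is probed from homogeneous initial
# states; (ii) switching off MinE advection changes neither the upstream
# nor the downstream outcome, so MinE transport is not what selects the
# direction.

library(minflow)

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

g <- min_grid(200, 256)
classify <- function(p, init, t1 = 1000, t2 = 400) {
  tr <- tryCatch({
    a <- simulate_min(init, p, g, min_schedule(0.02, t1, 500))
    minflow:::.continue(a, p, t2, min_schedule(0.02, t2, 500))
  }, error = function(e) NULL)
  if (is.null(tr)) return(list(classification = "failed", velocity = NA))
  pattern_velocity(tr, window = 1)
}

cat("Variant dichotomy over 3x3 (E:D, v_f) grids...\n")
rows <- list()
for (r in c(0.3, 0.6, 1.0)) for (v in c(1, 2, 3)) {
  p <- reduce_switch_model(min_params_at_ratio(r, v_f = v))
  pv <- classify(p, noisy_homogeneous_state(p, g, seed = 1))
  rows[[length(rows) + 1]] <- data.frame(variant = "reduced_switch",
                                         ratio = r, v_f = v,
                                         classification = pv$classification,
                                         velocity = pv$velocity)
}
for (r in c(0.12, 0.14, 0.16)) for (v in c(1, 2, 3)) {
  p <- as_skeleton(min_params_at_ratio(r, v_f = v))
  init <- seeded_wave_state(p, g, 50, -1)
  init$fields[, "c_Ei"] <- 0
  init <- field_state(init$fields)
  pv <- classify(p, init)
  rows[[length(rows) + 1]] <- data.frame(variant = "skeleton",
                                         ratio = r, v_f = v,
                                         classification = pv$classification,
                                         velocity = pv$velocity)
}
tab <- do.call(rbind, rows)
print(tab, digits = 3)
utils::write.csv(tab, file.path(out_dir, "variant_dichotomy.csv"),
                 row.names = FALSE)
cat("\nNote: with the shipped kinetic set the reduced switch model's",
    "homogeneous state is linearly stable over this grid, so its",
    "'exclusively upstream' claim cannot be exercised (no patterns form);",
    "the skeleton half of the dichotomy shows upstream-seeded waves",
    "reversing to downstream everywhere patterns persist.\n")

cat("\nMinE-advection ablation at a high- and a low-E:D point...\n")
hi <- minE_advection_ablation(min_params_at_ratio(1, v_f = 2), g,
                              t_relax = 800, t_measure = 400, seed = 1)
lo <- minE_advection_ablation(min_params_at_ratio(0.05, v_f = 2), g,
                              seeds = "down",
                              t_relax = 800, t_measure = 400, seed = 1)
hi$point <- "high E:D (1.0)"; lo$point <- "low E:D (0.05, seeded)"
ab <- rbind(hi, lo)
print(ab, digits = 3)
utils::write.csv(ab, file.path(out_dir, "minE_ablation.csv"),
                 row.names = FALSE)
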