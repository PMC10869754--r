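#!/usr/bin/env Rscript
# Stage 1: build the five-basin voltage-sensor surrogate and sample the
# short-trajectory ensemble from a non-equilibrium spread of start points
# along the transition path. Writes the featurized ensemble and the
# enumerated landscape minima under results/.

library(vsdga)

seed <- 1L
dir.create("results", showWarnings = FALSE)

model <- make_vsd_surrogate(n_features = 20, seed = seed)
mins <- surrogate_grid_minima(model)
cat(sprintf("surrogate landscape: %d local minima on a 200x200 grid\n", nrow(mins)))
print(mins, row.names = FALSE)
write.csv(mins, "results/surrogate_minima.csv", row.names = FALSE)

ens <- sample_surrogate_ensemble(model, n_traj = 400, n_frames = 120, seed = seed)
print(ens)
write_ensemble_csv(ens, "results/ensemble.csv")
qc <- model$charge_map(model$basin_centers[c(1, 5), ])
cat(sprintf("constructed charge gap between end basins: %.3f e\n", diff(qc)))
cat("wrote results/ensemble.csv and results/surrogate_minima.csv\n")
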