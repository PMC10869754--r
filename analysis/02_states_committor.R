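#!/usr/bin/env Rscript
# Stage 2: assign down/up state labels from the translocation-rotation
# ellipses, build the boundary-conforming distance basis from the
# distance-like features, and solve the Galerkin committor system. Writes
# per-frame labels and committor values.

library(vsdga)

lag <- 5L
ens <- read_ensemble_csv("results/ensemble.csv")
fl <- flatten_ensemble(ens)
X <- fl$values

labels <- assign_states(X[, c("d", "theta")])
cat(sprintf("state labels: %d down (A), %d up (B), %d unassigned\n",
            sum(labels == "A"), sum(labels == "B"), sum(labels == "none")))

feat_cols <- grep("^dist", colnames(X), value = TRUE)
basis <- build_distance_basis(X[, feat_cols], labels)
cat(sprintf("distance basis: %d whitened functions (%d dropped)\n",
            ncol(basis$values), basis$n_dropped))

stopped <- stop_times(ens, labels, lag)
system <- assemble_system(basis$values, basis$guess, stopped)
committor <- solve_committor(system, basis$values, basis$guess)
cat(sprintf("committor solved at lag %d: %d pairs, condition number %.2f\n",
            lag, system$n_pairs, committor$condition_number))
cat(sprintf("committor quartiles: %s\n",
            paste(round(quantile(committor$q_plus), 3), collapse = " ")))

write.csv(data.frame(traj_id = fl$traj, frame_id = fl$frame, label = labels,
                     q_plus = committor$q_plus, raw = committor$raw_values),
          "results/committor.csv", row.names = FALSE)
cat("wrote results/committor.csv\n")
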