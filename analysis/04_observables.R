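#!/usr/bin/env Rscript
# Stage 4: transition-path-theory observables. Free-energy profiles along
# the displacement charge (with voltage tilts) and on the committor-charge
# and translocation-rotation planes, reactive currents, the equilibrium
# time-correlation function of the charge with its biexponential fit,
# committor-conditioned CV distributions, and the sensing charge.

library(vsdga)

lag <- 5L
kT <- 1
ens <- read_ensemble_csv("results/ensemble.csv")
fl <- flatten_ensemble(ens)
X <- fl$values
cm <- read.csv("results/committor.csv")
wm <- read.csv("results/weights_mfpt.csv")
q <- cm$q_plus
w <- wm$weight
labels <- cm$label

pmf_qd <- weighted_pmf(X[, "Qd"], w, bins = 48, kT = kT)
m1 <- pmf_minima(pmf_qd, prominence = 0.3)
cat(sprintf("1D charge PMF: %d minima at Qd = %s e\n", nrow(m1),
            paste(round(m1$center, 2), collapse = ", ")))

pmf_q_qd <- weighted_pmf(cbind(q, X[, "Qd"]), w, bins = c(24, 24), kT = kT)
m2 <- pmf_minima(pmf_q_qd, max_free_energy = 5, smooth_width = 1)
interior <- m2$center1 > 0.1 & m2$center1 < 0.9
cat(sprintf("2D committor-charge PMF: %d minima, %d interior (q+ = %s)\n",
            nrow(m2), sum(interior),
            paste(round(m2$center1[interior], 2), collapse = ", ")))

for (V in c(-50, 50)) {
  tl <- tilt_pmf(pmf_qd, V, e_mV_per_energy = 0.0230605 / 0.5961 * kT)
  lowest <- tl$centers[[1]][which.min(tl$free_energy)]
  cat(sprintf("tilt %+d mV-equivalent: global minimum at Qd = %.2f e\n", V, lowest))
}

stopped <- stop_times(ens, labels, lag)
cur <- reactive_current(X[, c("d", "theta")], q, w, stopped, bins = c(24, 24),
                        lag_time = lag * ens$save_interval)
mag <- sqrt(cur$current[, , 1]^2 + cur$current[, , 2]^2)
imax <- which(mag == max(mag), arr.ind = TRUE)[1, ]
cat(sprintf("reactive current peaks at (d, theta) = (%.2f, %.1f)\n",
            cur$centers[[1]][imax[1]], cur$centers[[2]][imax[2]]))

qd_c <- X[, "Qd"] - weighted.mean(X[, "Qd"], w)
tcf <- equilibrium_tcf(qd_c, w, ens, lags = c(1:5, 8, 12, 16, 24, 32, 48, 64, 96))
fit <- try(fit_biexponential(tcf), silent = TRUE)
if (!inherits(fit, "try-error")) {
  cat(sprintf("charge TCF biexponential fit: tau_slow = %.2f, tau_fast = %.3f time units (a1 = %.2f)\n",
              fit$tau1, fit$tau2, fit$a1))
} else {
  cat("charge TCF: biexponential fit did not converge on this series\n")
}

dQ <- sensing_charge(X[, "Qd"], w, labels)
cat(sprintf("sensing charge (up minus down): %.3f e\n", dQ))

viol_d <- committor_binned_distributions(X[, "d"], q, w)
viol_th <- committor_binned_distributions(X[, "theta"], q, w)

dir.create("results", showWarnings = FALSE)
write.csv(data.frame(Qd = pmf_qd$centers[[1]], F = pmf_qd$free_energy),
          "results/pmf_charge.csv", row.names = FALSE)
g2 <- expand.grid(q = pmf_q_qd$centers[[1]], Qd = pmf_q_qd$centers[[2]])
g2$F <- as.vector(pmf_q_qd$free_energy)
write.csv(g2, "results/pmf_committor_charge.csv", row.names = FALSE)
write.csv(rbind(cbind(cv = "d", viol_d), cbind(cv = "theta", viol_th)),
          "results/violins.csv", row.names = FALSE)
write.csv(data.frame(lag = tcf$lags, C = tcf$values), "results/tcf_charge.csv",
          row.names = FALSE)
cat("wrote results/pmf_charge.csv, pmf_committor_charge.csv, violins.csv, tcf_charge.csv\n")
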