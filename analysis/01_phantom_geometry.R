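#!/usr/bin/env Rscript
## Phantom combinatorics and geometry: enumerate all sphere permutations,
## tabulate the mirror-equivalence classes, and compute the adjacent-sphere
## surface gaps that later contextualize the recovery extremes.

library(spectrc)
dir.create("results", showWarnings = FALSE)

perms <- enumerate_permutations(nema_diameters("NEMA_SPECT"))
write.csv(perms, "results/permutations_spect.csv", row.names = FALSE)
cat(sprintf("enumerated %d permutations (%d sagittal mirror classes)\n",
            nrow(perms), length(unique(perms$mirror_class))))

cfg <- phantom_config("NEMA_SPECT")
## gaps for the arrangement that puts the two largest spheres side by side
tight <- c(37, 60, 13, 17, 22, 28)
gaps <- neighbor_surface_gaps(cfg, tight)
write.csv(gaps, "results/neighbor_gaps_tightest.csv", row.names = FALSE)
cat(sprintf("37/60 mm adjacent surface gap on the %.1f mm ring: %.1f mm\n",
            cfg$ring_radius, gaps$gap_mm[1]))
cat(sprintf("13/60 mm gap: %.1f mm\n",
            neighbor_surface_gaps(cfg, c(13, 60, 17, 22, 28, 37))$gap_mm[1]))

vols <- data.frame(diameter_mm = nema_diameters("NEMA_SPECT"))
vols$volume_ml <- sphere_volume(vols$diameter_mm)
write.csv(vols, "results/sphere_volumes.csv", row.names = FALSE)
print(vols)
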