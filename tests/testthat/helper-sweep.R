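# The structured desk sweep is the study's core numerical experiment and is
# reused by several test files; it is computed once per session and cached.

.sweep_cache <- new.env(parent = emptyenv())

desk_sweep_cached <- function() {
  if (is.null(.sweep_cache$spect))
    .sweep_cache$spect <- run_sweep("NEMA_SPECT", master_seed = 42L)
  .sweep_cache$spect
}

# companion PET-phantom run over the six rotations of the standard ordering
# (balanced: every diameter visits every position once)
pet_rotations_cached <- function() {
  if (is.null(.sweep_cache$pet)) {
    perms <- desk_permutations(nema_diameters("NEMA_PET"))[1:6, ]
    .sweep_cache$pet <- run_sweep("NEMA_PET", permutations = perms,
                                  master_seed = 42L)
  }
  .sweep_cache$pet
}

# RC table filtered to the analysis update counts: noRR at 50 updates,
# RR at the maximum performed (200)
analysis_rc <- function(sweep) {
  rc <- sweep$rc_table
  rbind(rc[rc$arm == "noRR" & rc$updates == 50, ],
        rc[rc$arm == "RR" & rc$updates == max(rc$updates[rc$arm == "RR"]), ])
}
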