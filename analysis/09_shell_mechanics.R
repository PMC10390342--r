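#!/usr/bin/env Rscript
# Core-plus-shell mechanics: which shell load case reproduces the observed
# phase-1 shape change (length down, width and height up)? Runs the three
# load cases and the stripe tension-reduction sweep showing the long-range
# effect of a local surface-tension defect.

library(vncmorph)
dir.create("results", showWarnings = FALSE)

model <- build_shell_model(stripe = list(center_um = 100, width_um = 20,
                                         scale = 0.2))
rows <- lapply(c("normal_pressure", "isotropic_tension",
                 "anisotropic_tension"), function(lc) {
  r <- simulate_shell(model, lc, use_stripe = FALSE)
  message(sprintf("%-20s dL=%7.3f  dW=%7.3f  dH=%7.3f  dV/V=%+.3f%%  ecc %.3f->%.3f",
                  lc, r$dL_um, r$dW_um, r$dH_um, 100 * r$volume_change_rel,
                  r$eccentricity_before, r$eccentricity_after))
  data.frame(load_case = lc, dL_um = r$dL_um, dW_um = r$dW_um,
             dH_um = r$dH_um, volume_change_rel = r$volume_change_rel,
             ecc_before = r$eccentricity_before,
             ecc_after = r$eccentricity_after)
})
write.csv(do.call(rbind, rows), "results/shell_load_cases.csv",
          row.names = FALSE)
message("only anisotropic (axial) tension gives dL<0 with dW>0 and dH>0,")
message("the isovolumetric phase-1 signature")

sweep <- lapply(c(0, 0.25, 0.5, 0.75, 1), function(s) {
  sp <- stripe_perturbation(model, scale = s)
  data.frame(stripe_scale = s,
             tail_displacement_um = sp$perturbed$tail_displacement_um,
             base_tail_um = sp$base$tail_displacement_um,
             ratio = sp$tail_ratio)
})
sweep <- do.call(rbind, sweep)
write.csv(sweep, "results/shell_stripe_sweep.csv", row.names = FALSE)
print(sweep, row.names = FALSE)
message("tail motion weakens monotonically as tension is reduced in a",
        " central stripe >100 um away: a long-range network effect")
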