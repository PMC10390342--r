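#!/usr/bin/env Rscript
# AFM stiffness recovery: simulate force-spectroscopy curves for a softer
# early stage and a stiffer late stage, fit the spherical Hertz model at
# the 230 nm target depth, and summarise the recovered effective moduli.

library(vncmorph)
dir.create("results", showWarnings = FALSE)

cm <- contact_model()
stages <- c(stage15 = 300, stage17 = 900)   # Pa, soft -> stiff
rows <- list()
for (nm in names(stages)) {
  E <- stages[[nm]]
  noise <- 0.05 * hertz_force(cm$target_depth_nm, E, cm) / cm$k_nm
  fits <- vapply(1:50, function(i)
    fit_hertz(generate_force_curve(E, cm, noise_sd = noise,
                                   seed = i))$E_pa, numeric(1))
  rows[[nm]] <- data.frame(stage = nm, E_true_pa = E,
                           median_E_pa = median(fits),
                           mean_E_pa = mean(fits), sd_E_pa = sd(fits))
  message(sprintf("%s: true %d Pa, recovered %.0f +/- %.0f Pa (n = 50)",
                  nm, E, mean(fits), sd(fits)))
}
write.csv(do.call(rbind, rows), "results/afm_recovery.csv", row.names = FALSE)
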