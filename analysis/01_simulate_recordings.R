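#!/usr/bin/env Rscript
# Simulate the study's recording conditions: per genotype (WT, TG) and
# region (CA3, CA1), spontaneous slices with sharp wave-ripples and
# carbachol recordings with ~40 Hz gamma. Traces are written to
# results/traces/ in the package's binary container together with the
# generator ground truth, for the downstream drivers to consume.

suppressMessages(library(slicephys))

out_dir <- "results/traces"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

design <- expand.grid(genotype = c("WT", "TG"), region = c("CA3", "CA1"),
                      slice = 1:4, stringsAsFactors = FALSE)

# TG slices carry slightly larger, more frequent events -- an arbitrary but
# fixed synthetic contrast so the comparison layer has signal to find.
manifest <- list()
for (i in seq_len(nrow(design))) {
  d <- design[i, ]
  seed <- 1000L * i
  bump <- if (d$genotype == "TG") 1.25 else 1
  sp <- generate_spwr_trace(spwr_gen_params(
    60, event_rate_hz = 2 * bump, sw_amplitude_mv = 0.1 * bump,
    ripple_freq_hz = 180, noise_sd_mv = 0.01, seed = seed))
  sp$trace$meta$genotype <- d$genotype
  sp$trace$meta$region <- d$region
  sp$trace$meta$slice_id <- sprintf("%s_%s_s%d", d$genotype, d$region, d$slice)
  ga <- generate_gamma_trace(gamma_gen_params(
    90, osc_freq_hz = 40, osc_amp_mv = 0.05 * bump, phase_diffusion = 5,
    noise_sd_mv = 0.02, seed = seed + 1L))
  ga$trace$meta <- sp$trace$meta
  ga$trace$meta$condition <- "carbachol"

  stem <- file.path(out_dir, sp$trace$meta$slice_id)
  write_trace(sp$trace, paste0(stem, "_spont.lfp"))
  write_trace(ga$trace, paste0(stem, "_cch.lfp"))
  manifest[[i]] <- data.frame(
    slice_id = sp$trace$meta$slice_id, genotype = d$genotype,
    region = d$region, seed = seed,
    n_planted_events = length(sp$truth$event_times_s),
    planted_gamma_hz = ga$truth$osc_freq_hz,
    planted_tau_ms = ga$truth$coherence_tau_ms)
}
manifest <- do.call(rbind, manifest)
write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("Simulated", nrow(manifest), "slices ->", out_dir, "\n")
print(head(manifest, 4))
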