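#!/usr/bin/env Rscript
# Simulate triple-immunolabelled confocal fields per genotype, segment the
# three channels on maximum-intensity projections and count triple-positive
# puncta; normalize densities to the WT mean.

suppressMessages(library(slicephys))

dir.create("results", showWarnings = FALSE)
animals <- expand.grid(genotype = c("WT", "TG"), animal = 1:4,
                       stringsAsFactors = FALSE)
rows <- list()
for (i in seq_len(nrow(animals))) {
  a <- animals[i, ]
  # TG carries more triple-colocalized sites, with between-animal
  # variability around each genotype mean -- fixed synthetic contrast
  set.seed(7000L + i)
  tf <- (if (a$genotype == "TG") 0.45 else 0.3) + runif(1, -0.05, 0.05)
  g <- generate_puncta_stack(puncta_gen_params(
    shape_px = 256L, n_sites = sample(90:110, 1), triple_fraction = tf,
    singles_per_channel = 10L, noise_sd = 0.02, blur_sigma_px = 1,
    seed = 7000L + i))
  masks <- lapply(1:3, function(ch) {
    segment_channel(max_projection(g$stack, ch), segmentation_params("otsu"))
  })
  res <- colocalize_triple(masks[[1]], masks[[2]], masks[[3]],
                           pixel_size_um = g$stack$pixel_size_um)
  rows[[i]] <- data.frame(
    genotype = a$genotype, animal_id = paste0(a$genotype, a$animal),
    planted_triples = sum(g$truth$site_table$triple),
    triple_count = res$triple_count,
    triple_density_per_100um2 = res$triple_density_per_100um2,
    pv_count = res$per_channel_counts[["A"]])
}
tab <- do.call(rbind, rows)
norm <- normalize_to_reference(
  split(tab$triple_density_per_100um2, tab$genotype), "WT")
tab$density_vs_wt <- NA_real_
for (gt in names(norm)) tab$density_vs_wt[tab$genotype == gt] <- norm[[gt]]
write.table(tab, "results/coloc_summaries.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)

cat("Colocalization for", nrow(tab), "fields -> results/coloc_summaries.tsv\n")
cat(sprintf("  recovered/planted triples: %d/%d; TG density vs WT: %.2f\n",
            sum(tab$triple_count), sum(tab$planted_triples),
            mean(tab$density_vs_wt[tab$genotype == "TG"])))
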