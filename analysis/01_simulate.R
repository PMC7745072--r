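#!/usr/bin/env Rscript
# Stage 1: build the synthetic study system.
#
# Generates a 30-kb circular genome with ~30 genes organised into operons,
# each with a planted sigma-70-style promoter and an intrinsic terminator,
# then simulates every measurement the downstream stages consume: 5'-RACE
# read starts, RNA-seq fragment counts, spectral counts, growth curves and
# OD dilution series. All ground truth is serialised alongside.

suppressPackageStartupMessages(library(mincell))
seed <- as.integer(commandArgs(TRUE)[1]); if (is.na(seed)) seed <- 1L
out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

truth <- generate_genome(n_genes = 30, genome_length = 30000, seed = seed)
write_sim_truth(truth, out)
cat(sprintf("genome: %d bp, %d genes, %d promoters (%d with motif), %d terminators, %d TUs\n",
            truth$genome$length_bp, nrow(truth$genome$genes),
            nrow(truth$promoters), sum(truth$promoters$has_motif),
            nrow(truth$terminators), nrow(truth$tus)))

race <- simulate_race(truth, depth = 500, background_rate = 0.02, seed = seed)
write_strand_signal(race, file.path(out, "race_plus.bedgraph"),
                    file.path(out, "race_minus.bedgraph"))
cat(sprintf("5'-RACE: %.0f read starts simulated\n", race$total_mapped))

rnaseq <- simulate_rnaseq(truth, total_fragments = 5e5, dispersion = 0.1,
                          n_reps = 3, seed = seed)
write.table(rnaseq, file.path(out, "rnaseq_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

prot <- simulate_proteome(truth, total_spectra = 40000, seed = seed)
write.table(prot, file.path(out, "spectral_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

growth <- simulate_growth(dt_minutes = 32, n_timepoints = 8, noise_sd = 0.05,
                          seed = seed)
write.table(data.frame(time_min = growth$times, count = growth$values),
            file.path(out, "growth_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

ods <- simulate_od_dilutions(dt_minutes = 38, noise_sd = 0.002, seed = seed)
od_tab <- do.call(rbind, lapply(ods, function(cu)
  data.frame(dilution = cu$dilution, time_min = cu$times, od = cu$values)))
write.table(od_tab, file.path(out, "od_dilutions.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("wrote simulated measurements and truth to", out, "\n")
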