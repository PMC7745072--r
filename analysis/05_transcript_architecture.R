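#!/usr/bin/env Rscript
# Stage 5: terminators, term-to-term scaffolds and transcription units.
#
# Predicts Rho-independent terminators (stem-loop + poly-T tail scoring),
# partitions each strand of the circle into term-to-term scaffolds, builds
# TUs from every motif-associated TSS to its scaffold TTS with the 500-bp
# 5'UTR gene-attribution rule, rescues orphan genes, and summarises TU
# statistics. A TU-anchored aggregate read profile is also written.

suppressPackageStartupMessages(library(mincell))
sim <- "results/sim"
genome <- read_genome(file.path(sim, "genome.fasta"), file.path(sim, "genes.gff3"))

terms <- predict_terminators(genome)
cat(sprintf("%d terminators (score > 0, stable folds); mean T-tract %.1f nt\n",
            nrow(terms), mean(terms$t_tract_len)))
truth_terms <- read.delim(file.path(sim, "terminators.tsv"))
cat(sprintf("TTS recall %.3f / precision %.3f\n",
            mean(paste(truth_terms$tts, truth_terms$strand) %in%
                   paste(terms$tts, terms$strand)),
            mean(paste(terms$tts, terms$strand) %in%
                   paste(truth_terms$tts, truth_terms$strand))))

scaffolds <- build_scaffolds(terms, genome)
race <- read_strand_signal(file.path(sim, "race_plus.bedgraph"),
                           file.path(sim, "race_minus.bedgraph"), genome)
tss <- annotate_tss(race, genome)$tss
tus <- reconstruct_tus(scaffolds, tss, genome)
rnaseq <- read.delim(file.path(sim, "rnaseq_counts.tsv"))
expr <- tapply(rnaseq$count, rnaseq$gene_id, sum)
res <- rescue_orphans(tus, tss, scaffolds, genome, expression = expr)
tus <- res$tus
cat(sprintf("%d TUs reconstructed (%d coding, %d rescued); %d orphan genes\n",
            nrow(tus), sum(tus$category == "coding"),
            sum(startsWith(tus$category, "rescue")), length(res$orphans)))

st <- tu_statistics(tus, genome)
cat(sprintf("genes/TU: mean %.2f, max %d; mean TU length %.0f bp; mean UTRs 5'/3': %.0f/%.0f bp; genes covered: %d\n",
            st$mean_genes_per_tu, st$max_genes_per_tu, st$mean_length_bp,
            st$mean_utr5, st$mean_utr3, st$genes_covered))

truth_tus <- read.delim(file.path(sim, "tus.tsv"))
key <- function(d) paste(d$tss, d$tts, d$strand, d$gene_ids)
coding <- tus[tus$gene_ids != "", ]
cat(sprintf("TU recall %.3f / precision %.3f against planted TUs\n",
            mean(key(truth_tus) %in% key(coding)),
            mean(key(coding) %in% key(truth_tus))))

write.table(terms, "results/terminators.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write_tus_gff(tus[names(tus) != "leaderless"], "results/tus.gff3")
prof <- meta_profile(race, data.frame(start = tus$start, end = tus$end,
                                      strand = tus$strand),
                     genome, flank = 100, n_bins = 100)
write.table(prof, "results/tu_meta_profile.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat("wrote results/terminators.tsv, tus.gff3, tu_meta_profile.tsv\n")
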