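# Shared fixtures. Simulated truths are cached per seed so that test files
# exercising different stages of the pipeline do not regenerate them.

.sim_cache <- new.env(parent = emptyenv())

cached_truth <- function(seed, ...) {
  key <- paste0("truth_", seed, "_", paste(c(...), collapse = "_"))
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- generate_genome(seed = seed, ...)
  }
  .sim_cache[[key]]
}

# A hand-built genome: explicit sequence plus gene table.
toy_genome <- function(sequence, genes = empty_gene_table(), circular = TRUE) {
  genome_annotation(sequence, genes, circular)
}

gene_row <- function(id, start, end, strand = "+", kind = "CDS") {
  data.frame(id = id, start = start, end = end, strand = strand, kind = kind,
             product = "", stringsAsFactors = FALSE)
}

random_dna <- function(n, gc = 0.27, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

# Minimal truth object for the count simulators: each gene is its own TU.
toy_truth <- function(gene_lengths, abundances, genome_length = NULL,
                      protein_lengths = NULL, copies = NULL) {
  n <- length(gene_lengths)
  gap <- 50L
  starts <- cumsum(c(gap, utils::head(gene_lengths, -1) + gap))
  ends <- starts + gene_lengths - 1L
  if (is.null(genome_length)) genome_length <- max(ends) + gap
  genes <- do.call(rbind, lapply(seq_len(n), function(i)
    gene_row(sprintf("g%02d", i), starts[i], ends[i])))
  genome <- genome_annotation(random_dna(genome_length, seed = 123), genes)
  tus <- data.frame(tu_id = sprintf("TU%02d", seq_len(n)),
                    tss = pmax(starts - 30L, 1L), tts = ends + 20L,
                    strand = "+", gene_ids = genes$id,
                    abundance = abundances, tss_type = "main",
                    stringsAsFactors = FALSE)
  if (is.null(protein_lengths)) protein_lengths <- gene_lengths %/% 3L
  proteins <- stats::setNames(
    vapply(protein_lengths, function(k) paste(rep("A", k), collapse = ""),
           character(1)), genes$id)
  if (is.null(copies)) copies <- rep(1000, n)
  structure(list(genome = genome,
                 promoters = data.frame(),
                 terminators = data.frame(),
                 tus = tus,
                 proteins = proteins,
                 protein_abundance = stats::setNames(copies, genes$id),
                 biomass_truth = list(protein = 10.3, rna = 4.9, lipid = 4.0,
                                      dna = 1.7, carbohydrate = 0.9,
                                      dry_mass = 22.1),
                 growth_truth = list(dt_minutes = 32)),
            class = "sim_truth")
}

pos_key <- function(pos, strand) paste(pos, strand)

tu_key <- function(tus) paste(tus$tss, tus$tts, tus$strand, tus$gene_ids)

empty_tu_with_flag <- function() {
  out <- empty_tu_table()
  out$leaderless <- logical(0)
  out
}
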