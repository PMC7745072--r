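# Synthetic study system: a miniature circular genome with planted regulatory
# architecture (sigma-70-style promoters with a TAWAAT -10 box and degenerate
# TG extension, stem-loop intrinsic terminators with poly-T tails, operons of
# 1-5 genes), plus simulators for every measurement the pipeline consumes:
# 5'-RACE read starts, RNA-seq fragment counts, spectral counts, growth
# curves, and OD dilution series. All truth quantities are machine-readable so
# that pipeline output can be scored against a known answer.
#
# Genes are built from sense codons of translation table 4 (TGA = Trp, the
# Mollicute convention), so every planted CDS translates cleanly.

# Codons that are stops under translation table 4.
STOPS_TT4 <- c("TAA", "TAG")

sample_bases <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(BASES, n, replace = TRUE, prob = p)
}

GENETIC_CODE_TT4 <- local({
  gc <- Biostrings::GENETIC_CODE
  gc[["TGA"]] <- "W"
  gc
})

codon_pool <- local({
  all <- names(GENETIC_CODE_TT4)
  setdiff(all, STOPS_TT4)
})

sample_codons <- function(n, gc) {
  w <- vapply(strsplit(codon_pool, ""), function(b) {
    prod(ifelse(b %in% c("A", "T"), (1 - gc) / 2, gc / 2))
  }, numeric(1))
  sample(codon_pool, n, replace = TRUE, prob = w / sum(w))
}

translate_tt4 <- function(dna) {
  codons <- substring(dna, seq(1, nchar(dna) - 2, 3), seq(3, nchar(dna), 3))
  aa <- unname(GENETIC_CODE_TT4[codons])
  paste(aa[aa != "*"], collapse = "")
}

has_box_match <- function(seq) grepl("TA[AT]AAT", seq)

#' Generate a synthetic circular genome with planted architecture
#'
#' Builds operons of 1-5 genes, each headed by a planted promoter (TAWAAT -10
#' box; TG-extended with probability `tg_ext_prob`; spacer to the +1 drawn
#' from 6-7 with probability `spacer_mode_prob`, otherwise uniform on 4-9; +1
#' purine with `P(A) = plus_one_a_prob`, else G) and tailed by a stem-loop
#' terminator (stem 8-12 bp, loop 4-8 nt, poly-T tail of 4-8 nt; the
#' transcription termination site is the last stem base). A fraction of
#' multi-gene operons additionally carries an internal promoter (iTSS) near
#' the 3' end of a gene, and a fraction of operon promoters can be planted
#' without any motif (their upstream window is resampled until it contains no
#' TAWAAT-like site, so motif-assignment truth is unambiguous). Operon strand
#' is random. Every planted feature is recorded in the returned truth object.
#'
#' @param n_genes total number of genes to place (>= 1).
#' @param genome_length circular genome size in bp.
#' @param gc_fraction genome G+C fraction in (0, 1).
#' @param operon_size_probs probabilities for operon sizes 1..5.
#' @param itss_frac fraction of multi-gene operons with an internal promoter.
#' @param no_motif_frac fraction of operon promoters planted without a motif.
#' @param tg_ext_prob,spacer_mode_prob,plus_one_a_prob promoter composition
#'   probabilities (see description).
#' @param seed RNG seed (deterministic output per seed).
#' @param certify check the finished genome with the default terminator
#'   predictor and regenerate (derived sub-seed) if background sequence
#'   happens to contain an extraneous detectable terminator, so that planted
#'   structure is the only terminator-like structure present.
#' @return object of class `sim_truth`: list with `genome`
#'   (a [genome_annotation()]), `promoters`, `terminators`, `tus` (data
#'   frames in genome coordinates), `proteins` (per-gene amino-acid
#'   sequences), `protein_abundance` (copies/cell), `biomass_truth` (fg/cell),
#'   `growth_truth` (doubling time, min).
#' @export
generate_genome <- function(n_genes = 30, genome_length = 30000,
                            gc_fraction = 0.27,
                            operon_size_probs = c(0.45, 0.25, 0.15, 0.10, 0.05),
                            itss_frac = 0.2, no_motif_frac = 0,
                            tg_ext_prob = 0.7, spacer_mode_prob = 0.8,
                            plus_one_a_prob = 0.7, seed = 1, certify = TRUE) {
  for (attempt in 0:24) {
    truth <- generate_genome_once(
      n_genes = n_genes, genome_length = genome_length,
      gc_fraction = gc_fraction, operon_size_probs = operon_size_probs,
      itss_frac = itss_frac, no_motif_frac = no_motif_frac,
      tg_ext_prob = tg_ext_prob, spacer_mode_prob = spacer_mode_prob,
      plus_one_a_prob = plus_one_a_prob,
      seed = (seed + attempt * 100003L) %% .Machine$integer.max)
    if (!certify) return(truth)
    tm <- predict_terminators(truth$genome)
    if (setequal(paste(tm$tts, tm$strand),
                 paste(truth$terminators$tts, truth$terminators$strand))) {
      return(truth)
    }
  }
  stop("background sequence kept producing extraneous terminators; ",
       "try another seed or a larger genome")
}

generate_genome_once <- function(n_genes, genome_length, gc_fraction,
                                 operon_size_probs, itss_frac, no_motif_frac,
                                 tg_ext_prob, spacer_mode_prob,
                                 plus_one_a_prob, seed) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (gc_fraction <= 0 || gc_fraction >= 1) stop("gc_fraction must be in (0, 1)")
  set.seed(seed)

  # draw operon sizes until genes are exhausted
  sizes <- integer()
  left <- n_genes
  while (left > 0) {
    k <- sample(seq_along(operon_size_probs), 1, prob = operon_size_probs)
    k <- min(k, left)
    sizes <- c(sizes, k)
    left <- left - k
  }

  blocks <- vector("list", length(sizes))
  no_motif_flags <- stats::runif(length(sizes)) < no_motif_frac
  for (i in seq_along(sizes)) {
    blocks[[i]] <- build_operon_block(
      sizes[i], gc = gc_fraction, itss_frac = itss_frac,
      no_motif = no_motif_flags[i], tg_ext_prob = tg_ext_prob,
      spacer_mode_prob = spacer_mode_prob, plus_one_a_prob = plus_one_a_prob)
  }

  strands <- sample(c("+", "-"), length(blocks), replace = TRUE)

  seq_parts <- character()
  offset <- 0L
  gene_rows <- list(); prom_rows <- list(); term_rows <- list(); tu_rows <- list()
  proteins <- list()
  gene_counter <- 0L; tu_counter <- 0L; prom_counter <- 0L; term_counter <- 0L

  for (i in seq_along(blocks)) {
    blk <- blocks[[i]]
    gap <- sample(80:150, 1)
    seq_parts <- c(seq_parts, paste(sample_bases(gap, gc_fraction), collapse = ""))
    offset <- offset + gap
    B <- blk$length
    sigma <- strands[i]
    map_pos <- function(p) if (sigma == "+") offset + p else offset + B - p + 1L
    map_iv <- function(a, b) {
      if (sigma == "+") c(offset + a, offset + b) else c(offset + B - b + 1L, offset + B - a + 1L)
    }
    blkseq <- blk$seq
    if (sigma == "-") blkseq <- revcomp(blkseq)
    seq_parts <- c(seq_parts, blkseq)

    gid_map <- character(length(blk$genes$local_start))
    for (g in seq_along(gid_map)) {
      gene_counter <- gene_counter + 1L
      gid <- sprintf("g%03d", gene_counter)
      gid_map[g] <- gid
      iv <- map_iv(blk$genes$local_start[g], blk$genes$local_end[g])
      gene_rows[[length(gene_rows) + 1L]] <- data.frame(
        id = gid, start = iv[1], end = iv[2], strand = sigma, kind = "CDS",
        product = "hypothetical protein", stringsAsFactors = FALSE)
      proteins[[gid]] <- blk$genes$aa[g]
    }
    for (p in seq_len(nrow(blk$promoters))) {
      pr <- blk$promoters[p, ]
      prom_counter <- prom_counter + 1L
      tu_counter <- tu_counter + 1L
      gene_idx <- seq.int(pr$first_gene, nrow(blk$genes))
      prom_rows[[length(prom_rows) + 1L]] <- data.frame(
        tss_id = sprintf("P%03d", prom_counter),
        tss = map_pos(pr$tss), strand = sigma,
        minus10_start = if (pr$has_motif) map_pos(pr$minus10_start) else NA_integer_,
        spacer_len = if (pr$has_motif) pr$spacer else NA_integer_,
        strength = pr$strength, has_motif = pr$has_motif,
        type = pr$type, stringsAsFactors = FALSE)
      tu_rows[[length(tu_rows) + 1L]] <- data.frame(
        tu_id = sprintf("TU%03d", tu_counter),
        tss = map_pos(pr$tss), tts = map_pos(blk$term$tts), strand = sigma,
        gene_ids = paste(gid_map[gene_idx], collapse = ","),
        abundance = stats::rlnorm(1, meanlog = log(0.5), sdlog = 0.8),
        tss_type = pr$type, stringsAsFactors = FALSE)
    }
    term_counter <- term_counter + 1L
    s5 <- map_iv(blk$term$stem5[1], blk$term$stem5[2])
    lp <- map_iv(blk$term$loop[1], blk$term$loop[2])
    s3 <- map_iv(blk$term$stem3[1], blk$term$stem3[2])
    term_rows[[length(term_rows) + 1L]] <- data.frame(
      term_id = sprintf("T%03d", term_counter), strand = sigma,
      stem5_start = s5[1], stem5_end = s5[2],
      loop_start = lp[1], loop_end = lp[2],
      stem3_start = s3[1], stem3_end = s3[2],
      tts = map_pos(blk$term$tts), t_tract_len = blk$term$t_tract,
      stringsAsFactors = FALSE)
    offset <- offset + B
  }

  if (offset > genome_length) {
    stop(sprintf(paste0("placed architecture needs %d bp but genome_length is %d; ",
                        "increase genome_length or reduce n_genes"),
                 offset, genome_length))
  }
  tail_len <- genome_length - offset
  if (tail_len > 0) {
    seq_parts <- c(seq_parts, paste(sample_bases(tail_len, gc_fraction), collapse = ""))
  }
  sequence <- paste(seq_parts, collapse = "")

  genes <- do.call(rbind, gene_rows)
  genome <- genome_annotation(sequence, genes, circular = TRUE)
  copies <- stats::setNames(
    stats::rlnorm(nrow(genes), meanlog = log(5000), sdlog = 0.9), genes$id)

  structure(list(
    genome = genome,
    promoters = do.call(rbind, prom_rows),
    terminators = do.call(rbind, term_rows),
    tus = do.call(rbind, tu_rows),
    proteins = unlist(proteins),
    protein_abundance = copies,
    biomass_truth = list(protein = 10.3, rna = 4.9, lipid = 4.0, dna = 1.7,
                         carbohydrate = 0.9, dry_mass = 22.1),
    growth_truth = list(dt_minutes = 32)
  ), class = "sim_truth")
}

# One operon on its local coding strand. Local coordinates 1..length.
build_operon_block <- function(n_genes, gc, itss_frac, no_motif,
                               tg_ext_prob, spacer_mode_prob, plus_one_a_prob) {
  U <- 30L  # upstream pad containing the promoter
  pad <- sample_bases(U, gc)
  tss_local <- U + 1L

  spacer <- if (stats::runif(1) < spacer_mode_prob) sample(6:7, 1) else sample(4:9, 1)
  bstart <- tss_local - spacer - 6L
  minus10_start <- bstart
  has_motif <- !no_motif
  scan_zone <- function(p) paste(p[12:U], collapse = "")  # covers box starts for spacer 4..9
  if (has_motif) {
    box <- c("T", "A", sample(c("A", "T"), 1), "A", "A", "T")
    repeat {
      pad2 <- pad
      pad2[bstart:(bstart + 5L)] <- box
      if (stats::runif(1) < tg_ext_prob) {
        pad2[(bstart - 3L):(bstart - 1L)] <- c("T", "G", sample(BASES, 1))
      }
      # exactly one box-like site in the scannable zone keeps truth unambiguous
      zone <- scan_zone(pad2)
      if (length(gregexpr("TA[AT]AAT", zone)[[1]]) == 1L &&
          gregexpr("TA[AT]AAT", zone)[[1]][1] != -1L) { pad <- pad2; break }
      pad[seq_len(U)] <- sample_bases(U, gc)  # resample background and retry
    }
  } else {
    while (has_box_match(scan_zone(pad))) pad <- sample_bases(U, gc)
  }

  plus_one <- if (stats::runif(1) < plus_one_a_prob) "A" else "G"
  utr5 <- sample(20:80, 1)

  chars <- c(pad, plus_one, sample_bases(utr5 - 1L, gc))
  gene_local <- data.frame(local_start = integer(), local_end = integer(),
                           aa = character(), stringsAsFactors = FALSE)
  for (g in seq_len(n_genes)) {
    len_codons <- sample(100:300, 1)
    codons <- c("ATG", sample_codons(len_codons - 2L, gc), "TAA")
    gene_seq <- paste(codons, collapse = "")
    gstart <- length(chars) + 1L
    chars <- c(chars, strsplit(gene_seq, "")[[1]])
    gene_local <- rbind(gene_local, data.frame(
      local_start = gstart, local_end = length(chars),
      aa = translate_tt4(paste(codons[-length(codons)], collapse = "")),
      stringsAsFactors = FALSE))
    if (g < n_genes) chars <- c(chars, sample_bases(sample(10:40, 1), gc))
  }

  promoters <- data.frame(
    tss = tss_local, minus10_start = minus10_start, spacer = spacer,
    strength = stats::runif(1, 0.5, 2), has_motif = has_motif,
    type = "main", first_gene = 1L, stringsAsFactors = FALSE)

  # optional internal promoter near the 3' end of a non-terminal gene
  if (n_genes >= 2 && stats::runif(1) < itss_frac) {
    host <- sample(seq_len(n_genes - 1L), 1)
    hstart <- gene_local$local_start[host]; hend <- gene_local$local_end[host]
    max_off <- min(120L, hend - hstart - 25L)
    if (max_off >= 45L) {
      off <- sample(45:max_off, 1)
      itss <- hend - off
      ispacer <- if (stats::runif(1) < spacer_mode_prob) sample(6:7, 1) else sample(4:9, 1)
      ibstart <- itss - ispacer - 6L
      chars[ibstart:(ibstart + 5L)] <- c("T", "A", sample(c("A", "T"), 1), "A", "A", "T")
      if (stats::runif(1) < tg_ext_prob) {
        chars[(ibstart - 3L):(ibstart - 1L)] <- c("T", "G", sample(BASES, 1))
      }
      chars[itss] <- if (stats::runif(1) < plus_one_a_prob) "A" else "G"
      promoters <- rbind(promoters, data.frame(
        tss = itss, minus10_start = ibstart, spacer = ispacer,
        strength = stats::runif(1, 0.5, 2), has_motif = TRUE,
        type = "itss", first_gene = host + 1L, stringsAsFactors = FALSE))
    }
  }

  # terminator: C guard base, stem, loop, mirrored stem, poly-T tail, C guard.
  # Stems are resampled until the hairpin is canonically stable (dG <= -10
  # kcal/mol), as real intrinsic terminators are strong folds.
  chars <- c(chars, sample_bases(sample(15:45, 1) - 1L, gc), "C")
  stem_len <- sample(8:12, 1)
  loop_len <- sample(4:8, 1)
  repeat {
    stem5 <- sample(BASES, stem_len, replace = TRUE, prob = c(0.2, 0.3, 0.3, 0.2))
    dg <- hairpin_dg_stack(paste(stem5, collapse = ""),
                           revcomp(paste(stem5, collapse = "")), loop_len)
    # canonical terminators close the stem with a strong G:C pair; this also
    # keeps the stem/T-tract boundary unambiguous
    if (dg <= -10 && stem5[1] %in% c("G", "C")) break
  }
  loop <- sample_bases(loop_len, 0.1)  # A/T-rich loop, unlikely to pair with the stem
  stem3 <- strsplit(revcomp(paste(stem5, collapse = "")), "")[[1]]
  s5_start <- length(chars) + 1L
  chars <- c(chars, stem5)
  loop_start <- length(chars) + 1L
  chars <- c(chars, loop)
  s3_start <- length(chars) + 1L
  chars <- c(chars, stem3)
  tts_local <- length(chars)
  t_tract <- sample(4:8, 1)
  chars <- c(chars, rep("T", t_tract), "C", sample_bases(14L, gc))

  list(seq = paste(chars, collapse = ""), length = length(chars),
       genes = gene_local, promoters = promoters,
       term = list(stem5 = c(s5_start, s5_start + stem_len - 1L),
                   loop = c(loop_start, loop_start + loop_len - 1L),
                   stem3 = c(s3_start, s3_start + stem_len - 1L),
                   tts = tts_local, t_tract = t_tract))
}

#' Simulate a strand-specific 5'-RACE read-start track
#'
#' Per-base counts are Poisson background everywhere, plus peaks at each
#' planted TSS: total peak intensity `strength * depth` split 80/10/10 over
#' the exact +1 and its two neighbours (independent Poisson draws).
#'
#' @param truth a `sim_truth`.
#' @param depth expected reads per unit promoter strength.
#' @param background_rate Poisson background per base per strand.
#' @param seed RNG seed.
#' @return a [strand_signal()] in raw read-start counts.
#' @export
simulate_race <- function(truth, depth = 500, background_rate = 0.02, seed = 1) {
  if (depth <= 0) stop("depth must be > 0")
  if (background_rate < 0) stop("background_rate must be >= 0")
  set.seed(seed)
  L <- truth$genome$length_bp
  plus <- stats::rpois(L, background_rate)
  minus <- stats::rpois(L, background_rate)
  pr <- truth$promoters
  for (i in seq_len(nrow(pr))) {
    pos <- pr$tss[i]
    lambda <- pr$strength[i] * depth * c(0.1, 0.8, 0.1)
    at <- wrap_pos(c(pos - 1L, pos, pos + 1L), L)
    draws <- stats::rpois(3, lambda)
    if (pr$strand[i] == "+") plus[at] <- plus[at] + draws
    else minus[at] <- minus[at] + draws
  }
  strand_signal(plus, minus, unit = "read_starts")
}

#' Simulate per-gene RNA-seq fragment counts
#'
#' Expected fragments are proportional to (sum of abundances of the planted
#' TUs containing the gene) times gene length, scaled to `total_fragments`.
#' Counts are negative binomial with the given dispersion; `dispersion = 0`
#' returns the rounded expectation (deterministic).
#'
#' @param truth a `sim_truth`.
#' @param total_fragments expected total mapped fragments per replicate.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param n_reps number of replicates.
#' @param seed RNG seed.
#' @return data.frame with columns `gene_id`, `length_nt`, `rep`, `count`.
#' @export
simulate_rnaseq <- function(truth, total_fragments = 5e5, dispersion = 0.1,
                            n_reps = 3, seed = 1) {
  set.seed(seed)
  genes <- truth$genome$genes
  expr <- gene_expression_truth(truth)
  len <- genes$end - genes$start + 1L
  w <- expr[genes$id] * len
  mu <- total_fragments * w / sum(w)
  out <- list()
  for (r in seq_len(n_reps)) {
    counts <- if (dispersion <= 0) round(mu) else
      stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    out[[r]] <- data.frame(gene_id = genes$id, length_nt = len, rep = r,
                           count = as.numeric(counts), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Planted per-gene mRNA expression (sum of containing-TU abundances)
#' @param truth a `sim_truth`.
#' @return named numeric vector over gene ids.
#' @export
gene_expression_truth <- function(truth) {
  genes <- truth$genome$genes
  expr <- stats::setNames(numeric(nrow(genes)), genes$id)
  for (i in seq_len(nrow(truth$tus))) {
    for (g in tu_gene_vector(truth$tus$gene_ids[i])) {
      expr[g] <- expr[g] + truth$tus$abundance[i]
    }
  }
  expr
}

#' Simulate spectral counts for the planted proteome
#'
#' Spectra are multinomial over proteins with probability proportional to
#' copies-per-cell times protein length.
#'
#' @param truth a `sim_truth`.
#' @param total_spectra total validated spectra.
#' @param seed RNG seed.
#' @return data.frame with columns `gene_id`, `length_aa`, `spc`.
#' @export
simulate_proteome <- function(truth, total_spectra = 40000, seed = 1) {
  set.seed(seed)
  ids <- names(truth$protein_abundance)
  len_aa <- nchar(truth$proteins[ids])
  p <- truth$protein_abundance * len_aa
  spc <- as.vector(stats::rmultinom(1, total_spectra, p / sum(p)))
  data.frame(gene_id = ids, length_aa = as.integer(len_aa), spc = spc,
             stringsAsFactors = FALSE)
}

#' Simulate an exponential growth-count table
#'
#' Counts follow `N0 * 2^(t/dt) * exp(e)` with `e ~ N(0, noise_sd)`.
#'
#' @param dt_minutes doubling time.
#' @param n_timepoints number of samples.
#' @param t_step sampling interval (min).
#' @param noise_sd lognormal noise sd.
#' @param n0 initial count.
#' @param seed RNG seed.
#' @return a [growth_curve()] of kind `"count"`.
#' @export
simulate_growth <- function(dt_minutes = 32, n_timepoints = 8, t_step = 15,
                            noise_sd = 0.05, n0 = 1e5, seed = 1) {
  set.seed(seed)
  t <- seq(0, by = t_step, length.out = n_timepoints)
  v <- n0 * 2^(t / dt_minutes) * exp(stats::rnorm(n_timepoints, 0, noise_sd))
  growth_curve(t, v, kind = "count")
}

#' Simulate colorimetric OD dilution curves
#'
#' A monotone declining template (acidification of the phenol-red medium
#' lowers OD560 as the culture grows): an initial plateau, a long linear
#' decline, and a final plateau, sampled on a common time grid. Each dilution
#' is time-shifted by `log2(dilution) * dt_minutes`. The genuinely linear
#' decline is what makes the regression-based offset method (linearity
#' threshold R^2 > 0.999) applicable, as in the real assay.
#'
#' @param dt_minutes doubling time.
#' @param dilutions dilution factors (1 = undiluted).
#' @param noise_sd additive OD noise sd.
#' @param t_step,t_max sampling grid (min).
#' @param od_max,od_min,decline_dur,t_mid template parameters: start OD, end
#'   OD, duration of the linear decline (min), and mid-decline time of the
#'   undiluted culture.
#' @param seed RNG seed.
#' @return list of [growth_curve()] objects of kind `"od"` with `dilution` set.
#' @export
simulate_od_dilutions <- function(dt_minutes = 38, dilutions = c(1, 2, 4, 8),
                                  noise_sd = 0, t_step = 10, t_max = 960,
                                  od_max = 0.50, od_min = 0.12,
                                  decline_dur = 240, t_mid = 300, seed = 1) {
  set.seed(seed)
  t <- seq(0, t_max, by = t_step)
  lapply(dilutions, function(f) {
    mid <- t_mid + log2(f) * dt_minutes
    frac <- pmin(1, pmax(0, (t - (mid - decline_dur / 2)) / decline_dur))
    od <- od_max - (od_max - od_min) * frac
    od <- od + stats::rnorm(length(t), 0, noise_sd)
    growth_curve(t, od, kind = "od", dilution = f)
  })
}

#' Serialize a truth object to YAML + TSV
#'
#' Writes `truth.yaml` (scalars), `promoters.tsv`, `terminators.tsv`,
#' `tus.tsv`, `protein_abundance.tsv`, `genome.fasta` and `genes.gff3` into a
#' directory.
#'
#' @param truth a `sim_truth`.
#' @param dir output directory (created if needed).
#' @return invisibly, `dir`.
#' @export
write_sim_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome(truth$genome, file.path(dir, "genome.fasta"),
               file.path(dir, "genes.gff3"))
  tsv <- function(df, name) utils::write.table(
    df, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  tsv(truth$promoters, "promoters.tsv")
  tsv(truth$terminators, "terminators.tsv")
  tsv(truth$tus, "tus.tsv")
  tsv(data.frame(gene_id = names(truth$protein_abundance),
                 copies = unname(truth$protein_abundance)),
      "protein_abundance.tsv")
  tsv(data.frame(gene_id = names(truth$proteins),
                 aa_sequence = unname(truth$proteins)), "proteins.tsv")
  yaml::write_yaml(list(biomass_truth = truth$biomass_truth,
                        growth_truth = truth$growth_truth,
                        length_bp = truth$genome$length_bp),
                   file.path(dir, "truth.yaml"))
  invisible(dir)
}
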