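# Transcription start site calling from 5'-RACE read-start tracks.
#
# Significance rule: the background rate is estimated as the trimmed mean of
# non-null per-base counts (top 1% excluded, both strands pooled); a position
# is significant when its Poisson upper-tail p-value clears a Bonferroni
# correction over 2 x genome-length sites. Significant positions on the same
# strand within a small window are merged into one candidate TSS represented
# by the maximal-count position (ties -> smallest coordinate). Promoter
# motifs are assigned by position-weight-matrix scan upstream of the +1.

#' Read starts per million mapped reads
#'
#' `rspm[i] = raw[i] * 1e6 / total_mapped`, per strand.
#'
#' @param signal a [strand_signal()] with `total_mapped > 0`.
#' @return a `strand_signal` with unit `rspm`.
#' @export
compute_rspm <- function(signal) {
  stopifnot(inherits(signal, "strand_signal"))
  if (signal$total_mapped <= 0) stop("total_mapped must be > 0")
  strand_signal(signal$plus * 1e6 / signal$total_mapped,
                signal$minus * 1e6 / signal$total_mapped,
                total_mapped = signal$total_mapped, unit = "rspm")
}

# Merge sorted significant positions on one strand into clusters
# (chain rule: successive gap <= window), circular-aware.
cluster_positions <- function(pos, counts, window, L, circular = TRUE) {
  if (!length(pos)) return(integer())
  ord <- order(pos)
  pos <- pos[ord]; counts <- counts[ord]
  grp <- cumsum(c(1L, as.integer(diff(pos) > window)))
  if (circular && max(grp) > 1L) {
    # wrap: last cluster adjacent to first across the origin
    gap <- (pos[1] + L) - pos[length(pos)]
    if (gap <= window) grp[grp == max(grp)] <- 1L
  }
  reps <- integer(0)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    best <- idx[counts[idx] == max(counts[idx])]
    reps <- c(reps, pos[min(best)])
  }
  sort(reps)
}

#' Call candidate TSS positions from a raw read-start track
#'
#' @param signal a [strand_signal()] in raw counts.
#' @param alpha family-wise error rate for the Bonferroni-corrected Poisson
#'   test (default 0.05).
#' @param cluster_window merge distance in bp for significant positions on the
#'   same strand (default 5).
#' @param trim fraction of the highest-count sites (over all 2L sites)
#'   excluded from the background mean before averaging (default 0.001,
#'   mirroring the observation that true start sites occupy well under 0.1%
#'   of all sites). The mean is taken over the remaining sites including
#'   zeros, so the estimate is the (peak-censored) background rate.
#' @return data.frame with columns `position`, `strand`, `raw_count`, `rspm`,
#'   sorted by position; zero rows if nothing is significant.
#' @export
call_tss <- function(signal, alpha = 0.05, cluster_window = 5L, trim = 0.001) {
  stopifnot(inherits(signal, "strand_signal"))
  L <- length(signal$plus)
  allv <- c(signal$plus, signal$minus)
  empty <- data.frame(position = integer(), strand = character(),
                      raw_count = numeric(), rspm = numeric(),
                      stringsAsFactors = FALSE)
  if (all(allv == 0)) return(empty)
  srt <- sort(allv)
  n_keep <- length(srt) - ceiling(trim * length(srt))
  lambda <- mean(srt[seq_len(max(n_keep, 1L))])
  lambda <- max(lambda, 1e-12)
  threshold_p <- alpha / (2 * L)
  is_sig <- function(x) {
    x > 0 & stats::ppois(x - 1, lambda, lower.tail = FALSE) < threshold_p
  }
  rows <- list()
  for (s in c("+", "-")) {
    v <- if (s == "+") signal$plus else signal$minus
    sig <- which(is_sig(v))
    reps <- cluster_positions(sig, v[sig], cluster_window, L)
    if (length(reps)) {
      rows[[s]] <- data.frame(position = reps, strand = s,
                              raw_count = v[reps],
                              rspm = v[reps] * 1e6 / signal$total_mapped,
                              stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a promoter position-weight matrix from labelled sites
#'
#' The PWM covers a window of `ext_width + box_width` columns: the degenerate
#' TG-extension element followed by the -10 box. Sites supply the genomic
#' coordinate of the box base that is 5'-most in transcription direction
#' (`minus10_start`) and the strand; the window starts `ext_width` bases
#' upstream of it.
#'
#' @param sites data.frame with columns `minus10_start`, `strand`.
#' @param genome a [genome_annotation()].
#' @param box_width,ext_width motif geometry (defaults 6 and 3).
#' @param pseudocount added per base per column before normalising.
#' @param background base frequencies; defaults to the genome composition.
#' @return object of class `promoter_pwm`: probability matrix (rows ACGT),
#'   box column indices, background, and log-odds consensus scores.
#' @export
build_pwm <- function(sites, genome, box_width = 6L, ext_width = 3L,
                      pseudocount = 0.5, background = NULL) {
  if (!nrow(sites)) stop("no labelled sites")
  width <- box_width + ext_width
  seqs <- vapply(seq_len(nrow(sites)), function(i) {
    p <- sites$minus10_start[i]; s <- sites$strand[i]
    start <- if (s == "+") p - ext_width else p + ext_width
    subseq_oriented(genome, start, width, s)
  }, character(1))
  if (is.null(background)) {
    comp <- table(factor(strsplit(genome$sequence, "")[[1]], levels = BASES))
    background <- as.numeric(comp) / sum(comp)
    names(background) <- BASES
  }
  counts <- matrix(pseudocount, nrow = 4, ncol = width,
                   dimnames = list(BASES, NULL))
  for (sq in seqs) {
    b <- strsplit(sq, "")[[1]]
    for (j in seq_len(width)) counts[b[j], j] <- counts[b[j], j] + 1
  }
  probs <- sweep(counts, 2, colSums(counts), "/")
  structure(list(probs = probs, width = width,
                 box_cols = (ext_width + 1L):width, ext_width = ext_width,
                 background = background, n_sites = length(seqs)),
            class = "promoter_pwm")
}

#' Log-odds score of a sequence under a promoter PWM
#' @param pwm a `promoter_pwm`.
#' @param seq string of length `pwm$width`.
#' @param cols optional column subset (default: all).
#' @return log2-odds score (sum over columns of `log2(p / background)`).
#' @export
pwm_score <- function(pwm, seq, cols = seq_len(pwm$width)) {
  b <- strsplit(seq, "")[[1]]
  sum(vapply(cols, function(j) log2(pwm$probs[b[j], j] / pwm$background[b[j]]),
             numeric(1)))
}

# score of the consensus sequence (per-column maximum-probability base)
pwm_consensus_score <- function(pwm, cols) {
  sum(vapply(cols, function(j) {
    b <- which.max(pwm$probs[, j])
    log2(pwm$probs[b, j] / pwm$background[b])
  }, numeric(1)))
}

#' Consensus sequence of a promoter PWM
#' @param pwm a `promoter_pwm`.
#' @return string of the per-column maximum-probability bases.
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Scan for a promoter motif upstream of a TSS
#'
#' Tries every -10 box placement with spacer (bases strictly between the box
#' and the +1) in `spacer_range`. A placement is admissible when its -10 box
#' log-odds reaches `score_threshold` times the box consensus score; among
#' admissible placements the best full-window (EXT + box) score wins.
#'
#' @param tss +1 position (1-based genomic coordinate).
#' @param strand TSS strand.
#' @param genome a [genome_annotation()].
#' @param pwm a [build_pwm()] result.
#' @param spacer_range integer range of spacers to scan (default 4-9).
#' @param score_threshold fraction of the box consensus score required
#'   (default 0.6).
#' @return list with `minus10_start` (coordinate of the box base 5'-most in
#'   transcription direction), `minus10_seq`, `spacer_len`, `pwm_score`, or
#'   `NULL` when no placement passes.
#' @export
scan_promoter <- function(tss, strand, genome, pwm, spacer_range = c(4L, 9L),
                          score_threshold = 0.6) {
  box_w <- length(pwm$box_cols)
  need <- pwm_consensus_score(pwm, pwm$box_cols) * score_threshold
  best <- NULL
  for (s in seq(spacer_range[1], spacer_range[2])) {
    # window start: ext_width bases upstream of the box 5' end
    offset <- s + box_w + pwm$ext_width   # from +1 back to window start
    start <- if (strand == "+") tss - offset else tss + offset
    sq <- subseq_oriented(genome, start, pwm$width, strand)
    box_score <- pwm_score(pwm, sq, pwm$box_cols)
    if (box_score < need) next
    full <- pwm_score(pwm, sq)
    if (is.null(best) || full > best$pwm_score) {
      m10 <- if (strand == "+") tss - s - box_w else tss + s + box_w
      best <- list(minus10_start = m10,
                   minus10_seq = substring(sq, pwm$ext_width + 1L, pwm$width),
                   spacer_len = s, pwm_score = full)
    }
  }
  best
}

#' Seed-consensus promoter labelling
#'
#' Finds candidate -10 boxes by exact match to the degenerate consensus
#' `TAWAAT` within the scanned spacer range, for PWM bootstrapping (the
#' discover step that replaces de novo motif search).
#'
#' @param tss_df TSS table (`position`, `strand`).
#' @param genome a [genome_annotation()].
#' @param spacer_range spacers to try.
#' @return data.frame of labelled sites (`position`, `strand`,
#'   `minus10_start`, `spacer_len`), one row per TSS with a consensus match
#'   (smallest spacer wins on ties).
#' @export
label_consensus_sites <- function(tss_df, genome, spacer_range = c(4L, 9L)) {
  rows <- list()
  for (i in seq_len(nrow(tss_df))) {
    pos <- tss_df$position[i]; s <- tss_df$strand[i]
    for (sp in seq(spacer_range[1], spacer_range[2])) {
      start <- if (s == "+") pos - sp - 6L else pos + sp + 6L
      box <- subseq_oriented(genome, start, 6L, s)
      if (grepl("^TA[AT]AAT$", box)) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = pos, strand = s, minus10_start = start, spacer_len = sp,
          stringsAsFactors = FALSE)
        break
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(position = integer(), strand = character(),
                      minus10_start = integer(), spacer_len = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Classify TSSs by genomic context
#'
#' A TSS inside any gene span is internal (iTSS; parallel or antiparallel by
#' the overlapping gene's strand). Otherwise it is intergenic (gTSS) and
#' oriented by the strand of the closest downstream gene in the TSS's
#' transcription direction (circular distance, capped at half the genome).
#' The +1 base is read from the genome (reverse-complemented on the minus
#' strand).
#'
#' @param tss_df TSS table with `position`, `strand`.
#' @param genome a [genome_annotation()].
#' @return the table with added columns `context_class` (`p-gTSS`, `a-gTSS`,
#'   `p-iTSS`, `a-iTSS` or `unassigned`), `downstream_gene`,
#'   `overlapping_gene`, `plus_one_base`.
#' @export
classify_tss <- function(tss_df, genome) {
  g <- genome$genes
  L <- genome$length_bp
  n <- nrow(tss_df)
  cls <- character(n); down <- rep(NA_character_, n); over <- rep(NA_character_, n)
  p1 <- character(n)
  for (i in seq_len(n)) {
    pos <- tss_df$position[i]; s <- tss_df$strand[i]
    p1[i] <- subseq_oriented(genome, pos, 1L, s)
    hit <- which(g$start <= pos & g$end >= pos)
    if (length(hit)) {
      hit <- hit[1]
      over[i] <- g$id[hit]
      cls[i] <- if (g$strand[hit] == s) "p-iTSS" else "a-iTSS"
      # downstream gene still recorded for iTSS-derived TU building
    }
    if (nrow(g)) {
      edges <- pmin(
        vapply(seq_len(nrow(g)), function(j)
          circ_downstream_dist(pos, g$start[j], s, L), numeric(1)),
        vapply(seq_len(nrow(g)), function(j)
          circ_downstream_dist(pos, g$end[j], s, L), numeric(1)))
      cand <- setdiff(order(edges), if (length(hit)) hit else integer())
      cand <- cand[edges[cand] <= L / 2]
      if (length(cand)) down[i] <- g$id[cand[1]]
    }
    if (!length(hit)) {
      cls[i] <- if (is.na(down[i])) "unassigned" else
        if (g$strand[g$id == down[i]] == s) "p-gTSS" else "a-gTSS"
    }
  }
  tss_df$context_class <- cls
  tss_df$downstream_gene <- down
  tss_df$overlapping_gene <- over
  tss_df$plus_one_base <- p1
  tss_df
}

#' Call, motif-annotate and classify TSSs in one pass
#'
#' Chains [call_tss()], [label_consensus_sites()], [build_pwm()],
#' [scan_promoter()] and [classify_tss()]. When fewer than `min_sites`
#' consensus-labelled sites exist, no PWM is built and all TSSs are reported
#' motif-less.
#'
#' @param signal raw read-start [strand_signal()].
#' @param genome a [genome_annotation()].
#' @param alpha,cluster_window passed to [call_tss()].
#' @param score_threshold passed to [scan_promoter()].
#' @param min_sites minimal labelled sites to fit a PWM.
#' @return list with `tss` (annotated table incl. `has_motif`, `minus10_start`,
#'   `minus10_seq`, `spacer_len`, `pwm_score`) and `pwm` (or NULL).
#' @export
annotate_tss <- function(signal, genome, alpha = 0.05, cluster_window = 5L,
                         score_threshold = 0.6, min_sites = 3L) {
  tss <- call_tss(signal, alpha = alpha, cluster_window = cluster_window)
  tss$has_motif <- logical(nrow(tss))
  tss$minus10_start <- rep(NA_integer_, nrow(tss))
  tss$minus10_seq <- rep(NA_character_, nrow(tss))
  tss$spacer_len <- rep(NA_integer_, nrow(tss))
  tss$pwm_score <- rep(NA_real_, nrow(tss))
  pwm <- NULL
  if (nrow(tss)) {
    seeds <- label_consensus_sites(tss, genome)
    if (nrow(seeds) >= min_sites) {
      pwm <- build_pwm(seeds, genome)
      for (i in seq_len(nrow(tss))) {
        hit <- scan_promoter(tss$position[i], tss$strand[i], genome, pwm,
                             score_threshold = score_threshold)
        if (!is.null(hit)) {
          tss$has_motif[i] <- TRUE
          tss$minus10_start[i] <- hit$minus10_start
          tss$minus10_seq[i] <- hit$minus10_seq
          tss$spacer_len[i] <- hit$spacer_len
          tss$pwm_score[i] <- hit$pwm_score
        }
      }
    }
    tss <- classify_tss(tss, genome)
  }
  list(tss = tss, pwm = pwm)
}

#' Summarise TSS classes
#' @param tss_df annotated TSS table from [annotate_tss()] / [classify_tss()].
#' @return data.frame of counts and percentages per context class.
#' @export
tss_class_summary <- function(tss_df) {
  tab <- table(factor(tss_df$context_class,
                      levels = c("p-gTSS", "a-gTSS", "p-iTSS", "a-iTSS", "unassigned")))
  data.frame(context_class = names(tab), n = as.integer(tab),
             pct = if (sum(tab) > 0) 100 * as.integer(tab) / sum(tab) else
               rep(0, length(tab)),
             stringsAsFactors = FALSE)
}
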