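# I/O and coordinate conventions.
#
# Internal convention everywhere in the package: 1-based inclusive coordinates,
# strand in {+,-}. The only places where another dialect exists are the readers
# and writers in this file (bedGraph is 0-based half-open; GFF3 is 1-based
# inclusive). Wrap-around (origin-spanning) gene records are rejected at load;
# circular topology is handled downstream (scaffolds, distances).

BASES <- c("A", "C", "G", "T")

#' Construct a genome annotation
#'
#' Container for a (usually circular) bacterial genome sequence plus its typed,
#' stranded gene records. This is the coordinate frame for every downstream
#' stage of the pipeline.
#'
#' @param sequence single uppercase A/C/G/T string.
#' @param genes data.frame with columns `id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `kind` (`CDS`, `rRNA`, `tRNA` or `other`), `product`.
#'   Coordinates are 1-based inclusive and must lie within the sequence.
#' @param circular logical; is the chromosome circular?
#' @return object of class `genome_annotation` with fields `sequence`,
#'   `length_bp`, `circular`, `genes` (sorted by start).
#' @export
genome_annotation <- function(sequence, genes = empty_gene_table(), circular = TRUE) {
  sequence <- toupper(as.character(sequence))
  if (length(sequence) != 1L || nchar(sequence) < 1L) {
    stop("sequence must be a single non-empty string")
  }
  if (grepl("[^ACGT]", sequence)) {
    stop("sequence contains non-ACGT characters")
  }
  len <- nchar(sequence)
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  needed <- c("id", "start", "end", "strand", "kind", "product")
  missing_cols <- setdiff(needed, names(genes))
  if (length(missing_cols)) {
    stop("genes table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  genes <- genes[needed]
  if (nrow(genes)) {
    genes$start <- as.integer(genes$start)
    genes$end <- as.integer(genes$end)
    bad <- genes$start > genes$end
    if (any(bad)) stop("gene with start > end (wrap-around genes are rejected): ",
                       paste(genes$id[bad], collapse = ", "))
    out <- genes$start < 1L | genes$end > len
    if (any(out)) stop("gene outside sequence bounds: ",
                       paste(genes$id[out], collapse = ", "))
    if (anyDuplicated(genes$id)) stop("duplicate gene ids")
    if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
    genes <- genes[order(genes$start, genes$end), , drop = FALSE]
    rownames(genes) <- NULL
  }
  structure(
    list(sequence = sequence, length_bp = len, circular = isTRUE(circular),
         genes = genes),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat(sprintf("<genome_annotation> %s bp, %s, %d genes\n",
              format(x$length_bp, big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$genes)))
  invisible(x)
}

#' @rdname genome_annotation
#' @export
empty_gene_table <- function() {
  data.frame(id = character(), start = integer(), end = integer(),
             strand = character(), kind = character(), product = character(),
             stringsAsFactors = FALSE)
}

# --- circular coordinate helpers ------------------------------------------

#' Wrap a position onto a circular genome
#' @param pos integer vector (may be outside 1..len).
#' @param len genome length.
#' @return positions wrapped into 1..len.
#' @export
wrap_pos <- function(pos, len) ((pos - 1L) %% len) + 1L

# Downstream distance from `from` to `to` in transcription direction.
circ_downstream_dist <- function(from, to, strand, len) {
  if (strand == "+") (to - from) %% len else (from - to) %% len
}

#' Extract a subsequence in transcription direction
#'
#' Reads `len_out` bases starting at `pos` (inclusive) in the direction of
#' transcription, wrapping on circular genomes; the minus-strand result is
#' reverse-complemented so it reads 5' to 3'.
#'
#' @param genome a [genome_annotation()].
#' @param pos 1-based start (the transcript's 5'-most base).
#' @param len_out number of bases.
#' @param strand `"+"` or `"-"`.
#' @return character string of length `len_out`.
#' @export
subseq_oriented <- function(genome, pos, len_out, strand) {
  L <- genome$length_bp
  raw <- if (strand == "+") seq.int(pos, pos + len_out - 1L) else
    seq.int(pos - len_out + 1L, pos)
  if (any(raw < 1L | raw > L)) {
    if (!genome$circular) stop("window extends past the end of a linear contig")
    raw <- wrap_pos(raw, L)
  }
  s <- paste(substring(genome$sequence, raw, raw), collapse = "")
  if (strand == "-") s <- revcomp(s)
  s
}

#' Reverse-complement a DNA string
#' @param x character vector of DNA strings.
#' @return reverse-complemented strings.
#' @export
revcomp <- function(x) {
  vapply(chartr("ACGTacgt", "TGCAtgca", x), function(s)
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = ""),
    character(1), USE.NAMES = FALSE)
}

#' Reverse-complement a whole genome annotation
#'
#' Maps every gene interval `[s, e]` to `[L + 1 - e, L + 1 - s]` with flipped
#' strand. Used by the strand-symmetry property tests.
#' @param genome a `genome_annotation`.
#' @return the mirrored `genome_annotation`.
#' @export
revcomp_genome <- function(genome) {
  L <- genome$length_bp
  genes <- genome$genes
  if (nrow(genes)) {
    new_start <- L + 1L - genes$end
    new_end <- L + 1L - genes$start
    genes$start <- new_start
    genes$end <- new_end
    genes$strand <- ifelse(genes$strand == "+", "-", "+")
  }
  genome_annotation(revcomp(genome$sequence), genes, genome$circular)
}

# --- FASTA / GFF3 ----------------------------------------------------------

#' Read a genome from FASTA + GFF3
#'
#' @param fasta_path FASTA file with exactly one record.
#' @param gff_path GFF3 file (1-based inclusive). May contain only headers.
#' @param circular logical flag for chromosome topology.
#' @return a `genome_annotation`.
#' @export
read_genome <- function(fasta_path, gff_path = NULL, circular = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  if (length(seqs) != 1L) {
    stop("FASTA must contain exactly one record, found ", length(seqs))
  }
  genes <- empty_gene_table()
  if (!is.null(gff_path)) {
    n_data <- length(grep("^[^#]", readLines(gff_path, warn = FALSE), value = TRUE))
    if (n_data > 0) {
      gr <- rtracklayer::import(gff_path, format = "gff3")
      if (length(gr)) {
        md <- S4Vectors::mcols(gr)
        ids <- if ("ID" %in% names(md)) as.character(md$ID) else
          paste0("gene_", seq_along(gr))
        kind <- if ("type" %in% names(md)) as.character(md$type) else
          rep("other", length(gr))
        kind[!kind %in% c("CDS", "rRNA", "tRNA")] <- "other"
        product <- if ("product" %in% names(md)) as.character(md$product) else
          rep("", length(gr))
        product[is.na(product)] <- ""
        genes <- data.frame(
          id = ids,
          start = GenomicRanges::start(gr),
          end = GenomicRanges::end(gr),
          strand = as.character(GenomicRanges::strand(gr)),
          kind = kind, product = product, stringsAsFactors = FALSE)
        genes$strand[!genes$strand %in% c("+", "-")] <- "+"
      }
    }
  }
  genome_annotation(as.character(seqs[[1]]), genes, circular)
}

#' Write a genome annotation to FASTA + GFF3
#' @param genome a `genome_annotation`.
#' @param fasta_path,gff_path output paths.
#' @param name sequence name used in both files.
#' @return invisibly, the input genome.
#' @export
write_genome <- function(genome, fasta_path, gff_path, name = "chr") {
  dna <- Biostrings::DNAStringSet(genome$sequence)
  names(dna) <- name
  Biostrings::writeXStringSet(dna, fasta_path)
  lines <- c("##gff-version 3",
             sprintf("##sequence-region %s 1 %d", name, genome$length_bp))
  g <- genome$genes
  if (nrow(g)) {
    lines <- c(lines, sprintf(
      "%s\tmincell\t%s\t%d\t%d\t.\t%s\t.\tID=%s;product=%s",
      name, g$kind, g$start, g$end, g$strand, g$id,
      gsub("[;=\t]", "_", g$product)))
  }
  writeLines(lines, gff_path)
  invisible(genome)
}

# --- strand signals (bedGraph) --------------------------------------------

#' Construct a per-base stranded signal track
#'
#' @param plus,minus non-negative numeric vectors of genome length (per-base
#'   read starts or coverage).
#' @param total_mapped positive number; defaults to the sum of both tracks.
#' @param unit one of `read_starts`, `coverage`, `rspm`, `fpkm_density`.
#' @return object of class `strand_signal`.
#' @export
strand_signal <- function(plus, minus, total_mapped = NULL,
                          unit = c("read_starts", "coverage", "rspm", "fpkm_density")) {
  unit <- match.arg(unit)
  if (length(plus) != length(minus)) stop("plus and minus tracks differ in length")
  if (any(plus < 0) || any(minus < 0)) stop("signal values must be non-negative")
  if (is.null(total_mapped)) total_mapped <- sum(plus) + sum(minus)
  if (total_mapped < 0) stop("total_mapped must be non-negative")
  structure(list(plus = as.numeric(plus), minus = as.numeric(minus),
                 total_mapped = total_mapped, unit = unit),
            class = "strand_signal")
}

#' @export
print.strand_signal <- function(x, ...) {
  cat(sprintf("<strand_signal> %d bp, unit=%s, total_mapped=%.4g\n",
              length(x$plus), x$unit, x$total_mapped))
  invisible(x)
}

bedgraph_to_vector <- function(path, len) {
  v <- numeric(len)
  lns <- readLines(path, warn = FALSE)
  lns <- lns[!grepl("^(#|track|browser)", lns) & nzchar(lns)]
  if (!length(lns)) return(v)
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (!length(gr)) return(v)
  s <- GenomicRanges::start(gr)   # rtracklayer converts to 1-based inclusive
  e <- GenomicRanges::end(gr)
  if (any(e > len) || any(s < 1)) stop("bedGraph interval beyond genome length")
  val <- as.numeric(S4Vectors::mcols(gr)$score)
  for (i in seq_along(gr)) v[s[i]:e[i]] <- val[i]
  v
}

#' Read strand-specific bedGraph tracks into a dense signal
#'
#' bedGraph intervals are the standard 0-based half-open dialect; positions not
#' covered by any interval get 0.
#'
#' @param bedgraph_plus,bedgraph_minus paths (one file per strand).
#' @param genome a `genome_annotation` giving the length.
#' @param total_mapped optional override; defaults to the sum of all values.
#' @param unit signal unit, see [strand_signal()].
#' @return a `strand_signal`.
#' @export
read_strand_signal <- function(bedgraph_plus, bedgraph_minus, genome,
                               total_mapped = NULL, unit = "read_starts") {
  p <- bedgraph_to_vector(bedgraph_plus, genome$length_bp)
  m <- bedgraph_to_vector(bedgraph_minus, genome$length_bp)
  strand_signal(p, m, total_mapped = total_mapped, unit = unit)
}

vector_to_bedgraph <- function(v, path, name = "chr") {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts0 <- ends - r$lengths       # 0-based starts
  keep <- r$values != 0
  lines <- sprintf("%s\t%d\t%d\t%s", name, starts0[keep], ends[keep],
                   format(r$values[keep], trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}

#' Write a strand signal as two bedGraph files
#' @param signal a `strand_signal`.
#' @param path_plus,path_minus output paths.
#' @param name sequence name.
#' @return invisibly, the signal.
#' @export
write_strand_signal <- function(signal, path_plus, path_minus, name = "chr") {
  vector_to_bedgraph(signal$plus, path_plus, name)
  vector_to_bedgraph(signal$minus, path_minus, name)
  invisible(signal)
}

# --- TU tables (GFF3) ------------------------------------------------------

#' Write transcription units as GFF3
#'
#' One `transcription_unit` feature per TU with `ID`, TSS/TTS coordinates, UTR
#' lengths and category as attributes, followed by one child `gene` line per
#' attributed gene (`Parent=` link).
#'
#' @param tus TU table as returned by [reconstruct_tus()].
#' @param path output path.
#' @param name sequence name.
#' @return invisibly, the path.
#' @export
write_tus_gff <- function(tus, path, name = "chr") {
  if (nrow(tus) && anyDuplicated(tus$tu_id)) stop("duplicate TU ids")
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(tus))) {
    tu <- tus[i, ]
    lo <- min(tu$start, tu$end); hi <- max(tu$start, tu$end)
    lines <- c(lines, sprintf(
      "%s\tmincell\ttranscription_unit\t%d\t%d\t.\t%s\t.\tID=%s;tss=%d;tts=%d;utr5=%d;utr3=%d;category=%s;tss_class=%s",
      name, lo, hi, tu$strand, tu$tu_id, tu$tss, tu$tts,
      tu$utr5_len, tu$utr3_len, tu$category, tu$tss_class))
    gids <- tu_gene_vector(tu$gene_ids)
    for (g in gids) {
      lines <- c(lines, sprintf(
        "%s\tmincell\tgene\t%d\t%d\t.\t%s\t.\tID=%s.%s;Parent=%s",
        name, lo, hi, tu$strand, tu$tu_id, g, tu$tu_id))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a TU GFF3 written by [write_tus_gff()]
#' @param path GFF3 path.
#' @return TU table (one row per TU).
#' @export
read_tus_gff <- function(path) {
  lns <- readLines(path, warn = FALSE)
  lns <- lns[!grepl("^#", lns) & nzchar(lns)]
  fields <- strsplit(lns, "\t", fixed = TRUE)
  attr_of <- function(a, key) {
    m <- regmatches(a, regexec(paste0("(?:^|;)", key, "=([^;]*)"), a))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  tu_rows <- list(); genes_by_parent <- list()
  for (f in fields) {
    a <- f[9]
    if (f[3] == "transcription_unit") {
      tu_rows[[attr_of(a, "ID")]] <- data.frame(
        tu_id = attr_of(a, "ID"),
        tss = as.integer(attr_of(a, "tss")), tts = as.integer(attr_of(a, "tts")),
        start = as.integer(f[4]), end = as.integer(f[5]), strand = f[7],
        gene_ids = "", utr5_len = as.integer(attr_of(a, "utr5")),
        utr3_len = as.integer(attr_of(a, "utr3")),
        category = attr_of(a, "category"), tss_class = attr_of(a, "tss_class"),
        stringsAsFactors = FALSE)
    } else if (f[3] == "gene") {
      parent <- attr_of(a, "Parent")
      gid <- sub(paste0("^", parent, "\\."), "", attr_of(a, "ID"))
      genes_by_parent[[parent]] <- c(genes_by_parent[[parent]], gid)
    }
  }
  if (!length(tu_rows)) return(empty_tu_table())
  out <- do.call(rbind, tu_rows)
  for (id in names(genes_by_parent)) {
    out$gene_ids[out$tu_id == id] <- paste(genes_by_parent[[id]], collapse = ",")
  }
  # TU span as stored internally (start = TSS side in transcription direction)
  flip <- out$strand == "-"
  s <- ifelse(flip, out$end, out$start)
  e <- ifelse(flip, out$start, out$end)
  out$start <- as.integer(s); out$end <- as.integer(e)
  rownames(out) <- NULL
  out
}

tu_gene_vector <- function(gene_ids) {
  if (is.na(gene_ids) || !nzchar(gene_ids)) character() else
    strsplit(gene_ids, ",", fixed = TRUE)[[1]]
}

empty_tu_table <- function() {
  data.frame(tu_id = character(), tss = integer(), tts = integer(),
             start = integer(), end = integer(), strand = character(),
             gene_ids = character(), utr5_len = integer(), utr3_len = integer(),
             category = character(), tss_class = character(),
             stringsAsFactors = FALSE)
}
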