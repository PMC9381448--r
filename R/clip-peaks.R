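#' @title CLIP peak sets: thresholding, sharing, annotation, k-mers
#' @description Readers and writers for the BED6+2 peak dialect (name =
#'   RBP, two extra columns carrying log2 fold-enrichment of IP over
#'   size-matched input and -log10 P), significance thresholding, peak- and
#'   transcript-level sharing between datasets, a simplified priority-based
#'   gene-region annotator, and k-mer Z-score motif enrichment.
#'
#'   Overlap semantics everywhere: same strand, at least one shared base,
#'   half-open coordinate arithmetic (BED convention).
#' @name clip_peaks
NULL

#' Read peaks from a BED6+2 file
#'
#' Columns: chrom, start, end, name (RBP), score (ignored), strand,
#' log2_fc, neg_log10_p. No header.
#'
#' @param path BED6+2 file.
#' @return tibble of peaks.
#' @export
read_peaks <- function(path) {
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "rbp", "score", "strand",
                  "log2_fc", "neg_log10_p"),
    col_types = "ciicdcdd", progress = FALSE
  )
  if (nrow(raw) == 0) return(empty_peaks())
  validate_peaks(raw)
  raw
}

#' @keywords internal
validate_peaks <- function(peaks) {
  if (any(peaks$start < 0))
    stop("peak with negative start coordinate")
  if (any(peaks$start >= peaks$end))
    stop("peak with start >= end (intervals are half-open, need start < end)")
  if (any(!peaks$strand %in% c("+", "-")))
    stop("peak strand must be '+' or '-'")
  if (any(peaks$neg_log10_p < 0))
    stop("neg_log10_p must be non-negative")
  invisible(peaks)
}

#' @export
empty_peaks <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 rbp = character(), score = numeric(), strand = character(),
                 log2_fc = numeric(), neg_log10_p = numeric())
}

#' Write peaks as BED6+2
#' @param peaks peak tibble.
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  readr::write_tsv(peaks, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Peak significance thresholds
#'
#' The published cutoffs: log2(FC) > 5 and -log10(P) > 5 for TDP-43;
#' log2(FC) > 3 and -log10(P) > 3 for NOVA1, NOVA2 and RBFOX2. Both
#' comparisons are strict.
#'
#' @param rbp RBP name (case-insensitive match on "TDP43"/"TDP-43").
#' @return list with `min_log2_fc`, `min_neg_log10_p`.
#' @export
default_peak_threshold <- function(rbp) {
  cut <- if (toupper(gsub("-", "", rbp)) == "TDP43") 5 else 3
  list(min_log2_fc = cut, min_neg_log10_p = cut)
}

#' Keep significantly enriched peaks
#'
#' @param peaks peak tibble.
#' @param threshold list with `min_log2_fc` and `min_neg_log10_p`
#'   (strict ">" on both).
#' @export
threshold_peaks <- function(peaks, threshold) {
  keep <- peaks$log2_fc > threshold$min_log2_fc &
    peaks$neg_log10_p > threshold$min_neg_log10_p
  peaks[keep, , drop = FALSE]
}

#' @keywords internal
peaks_to_granges <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    strand = peaks$strand
  )
}

#' Fraction of peaks in `a` overlapping any same-strand peak in `b`
#'
#' Asymmetric by design: the denominator is |a|.
#'
#' @param a,b peak tibbles (already thresholded).
#' @export
peak_share_fraction <- function(a, b) {
  if (nrow(a) == 0) stop("peak_share_fraction: empty query peak set")
  if (nrow(b) == 0) return(0)
  ga <- peaks_to_granges(a); gb <- peaks_to_granges(b)
  hit <- IRanges::overlapsAny(ga, gb, minoverlap = 1L, ignore.strand = FALSE)
  mean(hit)
}

#' Fraction of `a`-bound genes also bound by `b`
#'
#' A gene counts as bound when >= 1 peak overlaps its span on the same
#' strand. The denominator is the number of genes hit by `a`.
#'
#' @param a,b peak tibbles.
#' @param gene_model tibble with columns chrom, start, end, strand, name.
#' @export
transcript_share_fraction <- function(a, b, gene_model) {
  if (nrow(gene_model) == 0) stop("transcript_share_fraction: empty gene model")
  gm <- GenomicRanges::GRanges(
    seqnames = gene_model$chrom,
    ranges = IRanges::IRanges(start = gene_model$start + 1L,
                              end = gene_model$end),
    strand = gene_model$strand, name = gene_model$name
  )
  hit_genes <- function(p) {
    if (nrow(p) == 0) return(character())
    unique(gm$name[IRanges::overlapsAny(gm, peaks_to_granges(p),
                                        minoverlap = 1L,
                                        ignore.strand = FALSE)])
  }
  ga <- hit_genes(a)
  if (length(ga) == 0) stop("transcript_share_fraction: no genes hit by a")
  mean(ga %in% hit_genes(b))
}

.region_priority <- c("CDS", "3'UTR", "5'UTR", "noncoding_exon", "intron")

#' Assign each peak to one gene-region class
#'
#' Simplified priority annotator: every peak gets exactly one class by the
#' fixed priority CDS > 3'UTR > 5'UTR > noncoding exon > intron >
#' intergenic (no overlap); ties within a class go to the interval with the
#' longest overlap. Same-strand overlap only.
#'
#' @param peaks peak tibble.
#' @param gene_model tibble with chrom, start, end, strand and a `class`
#'   column drawn from CDS, 5'UTR, 3'UTR, noncoding_exon, intron.
#' @param priority character vector ordering the classes (most to least
#'   dominant).
#' @return list with `assignment` (per-peak class), `counts`, `fractions`.
#' @export
annotate_regions <- function(peaks, gene_model,
                             priority = .region_priority) {
  if (nrow(peaks) == 0)
    return(list(assignment = character(),
                counts = stats::setNames(integer(length(priority) + 1),
                                         c(priority, "intergenic")),
                fractions = stats::setNames(numeric(length(priority) + 1),
                                            c(priority, "intergenic"))))
  unknown <- setdiff(unique(gene_model$class), priority)
  if (length(unknown) > 0)
    stop("annotate_regions: unknown region class(es): ",
         paste(unknown, collapse = ", "))
  gp <- peaks_to_granges(peaks)
  gm <- GenomicRanges::GRanges(
    seqnames = gene_model$chrom,
    ranges = IRanges::IRanges(start = gene_model$start + 1L,
                              end = gene_model$end),
    strand = gene_model$strand
  )
  ov <- GenomicRanges::findOverlaps(gp, gm, minoverlap = 1L,
                                    ignore.strand = FALSE)
  assignment <- rep("intergenic", nrow(peaks))
  if (length(ov) > 0) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    width <- IRanges::width(IRanges::pintersect(
      IRanges::ranges(gp)[qh], IRanges::ranges(gm)[sh]))
    rank <- match(gene_model$class[sh], priority)
    # best hit per peak: lowest priority rank, then longest overlap
    ord <- order(qh, rank, -width)
    best <- !duplicated(qh[ord])
    assignment[qh[ord][best]] <- gene_model$class[sh[ord][best]]
  }
  classes <- c(priority, "intergenic")
  counts <- stats::setNames(
    vapply(classes, function(cl) sum(assignment == cl), integer(1)), classes)
  list(assignment = assignment, counts = counts,
       fractions = counts / sum(counts))
}

#' @keywords internal
.kmer_freqs <- function(seqs, k) {
  if (length(seqs) == 0) stop("kmer: empty sequence set")
  ss <- Biostrings::DNAStringSet(chartr("uU", "tT", toupper(seqs)))
  counts <- colSums(Biostrings::oligonucleotideFrequency(ss, width = k))
  total <- sum(counts)                   # windows containing N match nothing
  if (total == 0) stop("kmer: no valid k-mer positions (sequences too short or all-N)")
  list(counts = counts, total = total)
}

#' k-mer Z-score enrichment of foreground over background sequences
#'
#' For every k-mer w: freq_fg(w) = count_fg(w) / N_fg where N_fg is the
#' total number of valid foreground k-mer windows (windows containing N are
#' skipped), likewise for the background, and
#' z(w) = (freq_fg - freq_bg) / sqrt(freq_bg (1 - freq_bg) / N_fg)
#' (one-sample binomial approximation against the empirical background
#' frequency). k-mers absent from the background get pseudo-frequency
#' 1 / (N_bg + 4^k). T and U are treated as identical; sequences are
#' uppercased on read.
#'
#' @param fg_seqs,bg_seqs character vectors of sequences over A,C,G,T/U,N.
#' @param k k-mer length (4 or 6).
#' @return tibble (kmer, count_fg, freq_fg, freq_bg, z) sorted by
#'   descending z.
#' @export
kmer_enrichment <- function(fg_seqs, bg_seqs, k = 4) {
  stopifnot(k %in% c(4, 6))
  fg <- .kmer_freqs(fg_seqs, k)
  bg <- .kmer_freqs(bg_seqs, k)
  freq_fg <- fg$counts / fg$total
  freq_bg <- bg$counts / bg$total
  freq_bg[bg$counts == 0] <- 1 / (bg$total + 4^k)
  z <- (freq_fg - freq_bg) / sqrt(freq_bg * (1 - freq_bg) / fg$total)
  out <- tibble::tibble(kmer = names(fg$counts),
                        count_fg = unname(fg$counts),
                        freq_fg = unname(freq_fg),
                        freq_bg = unname(freq_bg),
                        z = unname(z))
  out[order(-out$z), , drop = FALSE]
}

#' Read sequences from a FASTA file as a character vector
#' @param path FASTA file.
#' @export
read_fasta_seqs <- function(path) {
  as.character(Biostrings::readDNAStringSet(path))
}
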