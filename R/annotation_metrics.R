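## Gene-table arithmetic: lengths, codons, overlaps, spacers, strand tallies.

VERT_MITO_STOPS <- c("TAA", "TAG", "AGA", "AGG")

#' Per-gene metric table
#'
#' Computes, for every feature, its circular-aware length from the
#' coordinates (never trusting an annotated size column) and, when a genome
#' sequence is attached, the start codon and a stop-codon classification
#' for protein-coding genes.  The stop classification is frame-based: the
#' trailing \code{length mod 3} nucleotides (or the final codon when the
#' length is divisible by 3) are compared against the vertebrate
#' mitochondrial stop set TAA/TAG/AGA/AGG, giving \code{complete(XYZ)},
#' \code{incomplete(T)}, \code{incomplete(TA)} or, for a trailing fragment
#' that is not a stop prefix, \code{trailing(...)} with the observed bases.
#'
#' @param record a [mito_genome]
#' @return data frame with columns name, category, strand, length,
#'   start_codon, stop_codon_class, anticodon
#' @export
build_gene_table <- function(record) {
  f <- record$features
  f <- f[order(f$start), , drop = FALSE]
  n <- nrow(f)
  len <- integer(n)
  for (i in seq_len(n)) len[i] <- feature_length(f[i, ])
  start_codon <- rep(NA_character_, n)
  stop_class <- rep(NA_character_, n)
  if (!is.null(record$sequence)) {
    for (i in seq_len(n)) {
      if (f$category[i] != "PCG") next
      cds <- extract_feature_sequence(record, f$name[i])
      start_codon[i] <- substr(cds, 1, 3)
      tail_n <- len[i] %% 3L
      if (tail_n == 0L) tail_n <- 3L
      tail_s <- substr(cds, len[i] - tail_n + 1L, len[i])
      stop_class[i] <-
        if (tail_n == 3L) {
          if (tail_s %in% VERT_MITO_STOPS) paste0("complete(", tail_s, ")")
          else paste0("trailing(", tail_s, ")")
        } else if (tail_s %in% c("T", "TA")) {
          paste0("incomplete(", tail_s, ")")
        } else {
          paste0("trailing(", tail_s, ")")
        }
    }
  }
  out <- data.frame(name = f$name, category = f$category, strand = f$strand,
                    length = len, start_codon = start_codon,
                    stop_codon_class = stop_class,
                    anticodon = f$anticodon, stringsAsFactors = FALSE)
  ## flag disagreement with any annotated start codon carried in the input
  if ("start_codon" %in% names(record$features) && !is.null(record$sequence)) {
    ann <- record$features$start_codon[order(record$features$start)]
    bad <- which(!is.na(ann) & !is.na(start_codon) & ann != start_codon)
    if (length(bad) > 0)
      warning("computed start codon disagrees with annotation for: ",
              paste(out$name[bad], collapse = ", "))
  }
  out
}

#' Adjacency analysis: intergenic spacers and gene overlaps
#'
#' Walks adjacent feature pairs around the circle (including the junction
#' from the last, possibly origin-wrapping, feature back to the first) and
#' reports the signed gap \code{start(downstream) - end(upstream) - 1};
#' negative gaps are overlaps.  The summary counts overlaps (gap < 0,
#' magnitudes summed), spacers (gap > 0) and ignores abutting pairs
#' (gap == 0).
#'
#' @param record a [mito_genome] with at least 2 features
#' @return list with \code{pairs} (data frame upstream, downstream, gap) and
#'   \code{summary} (n_overlaps, total_overlap_bp, n_spacers,
#'   total_spacer_bp, longest_spacer)
#' @export
adjacency_analysis <- function(record) {
  f <- record$features[order(record$features$start), , drop = FALSE]
  n <- nrow(f)
  if (n < 2) stop("adjacency analysis needs at least 2 features")
  ## linearized end: an origin-wrapping feature effectively ends at end2
  lin_end <- ifelse(is.na(f$end2), f$end, f$end2 + record$genome_length)
  ups <- f$name
  downs <- c(f$name[-1], f$name[1])
  next_start <- c(f$start[-1], f$start[1] + record$genome_length)
  gap <- as.integer(next_start - lin_end - 1L)
  ## the wrap junction: if last feature spans the origin its end2 already
  ## sits past genome_length, handled by the linearization above
  pairs <- data.frame(upstream = ups, downstream = downs, gap = gap,
                      stringsAsFactors = FALSE)
  summary <- list(
    n_overlaps = sum(gap < 0),
    total_overlap_bp = sum(-gap[gap < 0]),
    n_spacers = sum(gap > 0),
    total_spacer_bp = sum(gap[gap > 0]),
    longest_spacer = if (any(gap > 0)) max(gap) else 0L)
  list(pairs = pairs, summary = summary)
}

#' Gene counts per category and strand
#'
#' @param record a [mito_genome]
#' @return contingency table (category x strand) of feature counts
#' @export
strand_tally <- function(record) {
  f <- record$features
  table(factor(f$category, levels = c("PCG", "tRNA", "rRNA", "CR")),
        factor(f$strand, levels = c("H", "L")))
}

#' Circular coverage identity check
#'
#' On a fully annotated circular genome, feature lengths plus spacers minus
#' overlaps must tile the circle exactly:
#' \code{sum(lengths) + total_spacer_bp - total_overlap_bp == genome_length}.
#'
#' @param record a [mito_genome]
#' @return list with the three components and \code{holds} (logical)
#' @export
coverage_identity <- function(record) {
  gt <- build_gene_table(record)
  adj <- adjacency_analysis(record)
  total <- sum(gt$length) + adj$summary$total_spacer_bp -
    adj$summary$total_overlap_bp
  list(feature_bp = sum(gt$length),
       spacer_bp = adj$summary$total_spacer_bp,
       overlap_bp = adj$summary$total_overlap_bp,
       reconstructed_length = total,
       genome_length = record$genome_length,
       holds = total == record$genome_length)
}
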