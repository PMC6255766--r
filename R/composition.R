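## Base composition, A+T content and AT/GC strand skew.

#' Nucleotide composition and strand skew of a sequence
#'
#' Counts A, C, G, T and ambiguous ("other") bases and computes
#' \code{AT skew = (A - T) / (A + T)} and \code{GC skew = (G - C) / (G + C)}.
#' The A+T percentage is taken over unambiguous bases only.  A zero
#' denominator yields an NA skew.
#'
#' @param seq upper-case DNA string
#' @return object of class \code{composition_stats}: list with counts
#'   (a, c, g, t, other), length, at_percent, gc_percent, at_skew, gc_skew
#' @export
#' @examples
#' compute_composition("GGGC")$gc_skew  # 0.5
compute_composition <- function(seq) {
  if (is.null(seq) || nchar(seq) == 0) stop("empty sequence")
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAString(seq))
  a <- freq[["A"]]; c_ <- freq[["C"]]; g <- freq[["G"]]; t <- freq[["T"]]
  other <- nchar(seq) - (a + c_ + g + t)
  unambig <- a + c_ + g + t
  structure(list(
    a = a, c = c_, g = g, t = t, other = other, length = nchar(seq),
    at_percent = if (unambig > 0) 100 * (a + t) / unambig else NA_real_,
    gc_percent = if (unambig > 0) 100 * (g + c_) / unambig else NA_real_,
    at_skew = if (a + t > 0) (a - t) / (a + t) else NA_real_,
    gc_skew = if (g + c_ > 0) (g - c_) / (g + c_) else NA_real_),
    class = "composition_stats")
}

#' @export
print.composition_stats <- function(x, ...) {
  cat(sprintf(
    "<composition> %d bp  A+T %.2f%%  AT skew %s  GC skew %s\n",
    x$length, x$at_percent,
    formatC(x$at_skew, digits = 3, format = "f"),
    formatC(x$gc_skew, digits = 3, format = "f")))
  invisible(x)
}

#' Composition by genome partition
#'
#' Pools feature sequences into the partitions genome / PCG / tRNA / rRNA /
#' CR and computes [compute_composition] on each pool.  Following the usual
#' strand convention, protein-coding genes on the light strand are
#' reverse-complemented before pooling (reading orientation), while tRNA and
#' rRNA genes are pooled in their native genome (H-strand) register; the
#' control region is taken as annotated.
#'
#' @param record a [mito_genome] with sequence attached
#' @return named list of \code{composition_stats}, one per partition present
#' @export
partition_composition <- function(record) {
  if (is.null(record$sequence))
    stop("cannot compute partition composition: record has no sequence")
  f <- record$features
  pools <- list(genome = record$sequence)
  for (part in c("PCG", "tRNA", "rRNA", "CR")) {
    names_in <- f$name[f$category == part]
    if (length(names_in) == 0) next
    seqs <- vapply(names_in, function(nm) {
      extract_feature_sequence(record, nm, orient = (part == "PCG"))
    }, character(1))
    pools[[part]] <- paste(seqs, collapse = "")
  }
  lapply(pools, compute_composition)
}

#' Composition table across species
#'
#' @param records list of [mito_genome] (with sequences)
#' @return data frame, one row per (species x partition)
#' @export
composition_table <- function(records) {
  if (length(records) == 0)
    stop("no genome records with sequence available")
  rows <- lapply(records, function(rec) {
    parts <- partition_composition(rec)
    do.call(rbind, lapply(names(parts), function(p) {
      s <- parts[[p]]
      data.frame(species = rec$species, partition = p, length = s$length,
                 at_percent = round(s$at_percent, 2),
                 at_skew = round(s$at_skew, 3),
                 gc_skew = round(s$gc_skew, 3), stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
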