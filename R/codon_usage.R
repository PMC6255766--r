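## Codon counting and relative synonymous codon usage (RSCU) under the
## vertebrate mitochondrial genetic code (transl_table 2).

#' The vertebrate mitochondrial genetic code
#'
#' Named character vector mapping the 64 DNA codons to one-letter amino
#' acids, with "*" for stops.  Differs from the standard code at AGA/AGG
#' (stop), ATA (Met) and TGA (Trp).
#'
#' @return named character vector of length 64
#' @export
vertebrate_mito_code <- function() {
  Biostrings::getGeneticCode("2")
}

ALL_CODONS <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

#' Count codons over a set of oriented CDS
#'
#' Each CDS is read 5'->3' in frame from its first base; a trailing 1-2 nt
#' (incomplete stop codon) is dropped.  Stop codons are tallied separately
#' and excluded from the main count.  Codons containing ambiguity codes are
#' skipped and tallied.
#'
#' @param cds_list character vector of CDS sequences already in reading
#'   orientation (light-strand genes reverse-complemented)
#' @param code genetic code, default [vertebrate_mito_code()]
#' @return list with \code{counts} (named integer vector over non-stop
#'   codons), \code{stop_counts}, \code{n_ambiguous}
#' @export
count_codons <- function(cds_list, code = vertebrate_mito_code()) {
  codons_all <- ALL_CODONS()
  stops <- names(code)[code == "*"]
  counts <- stats::setNames(integer(length(codons_all)), codons_all)
  n_amb <- 0L
  for (cds in cds_list) {
    cds <- toupper(cds)
    if (grepl("[^ACGTRYSWKMBDHVN]", cds))
      stop("CDS contains non-IUPAC characters")
    n_cod <- nchar(cds) %/% 3L
    if (n_cod == 0) next
    cods <- substring(cds, 3L * seq_len(n_cod) - 2L, 3L * seq_len(n_cod))
    ok <- cods %in% codons_all
    n_amb <- n_amb + sum(!ok)
    tab <- table(cods[ok])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  list(counts = counts[!(codons_all %in% stops)],
       stop_counts = counts[codons_all %in% stops],
       n_ambiguous = n_amb,
       code_id = "vertebrate mitochondrial")
}

#' Relative synonymous codon usage
#'
#' For amino acid i with n_i synonymous codons, RSCU of codon j is the
#' observed count x_ij divided by the mean count over the family,
#' \code{x_ij / ((1/n_i) * sum_j x_ij)}.  Stop codons are excluded;
#' families with zero total get NA.  Within each family the RSCU values
#' sum to the family size.
#'
#' @param codon_counts result of [count_codons]
#' @param code genetic code, default [vertebrate_mito_code()]
#' @return data frame with columns codon, amino_acid, count, rscu
#' @export
compute_rscu <- function(codon_counts, code = vertebrate_mito_code()) {
  counts <- codon_counts$counts
  aa <- code[names(counts)]
  out <- data.frame(codon = names(counts), amino_acid = unname(aa),
                    count = as.integer(counts), rscu = NA_real_,
                    stringsAsFactors = FALSE)
  for (a in unique(aa)) {
    idx <- which(out$amino_acid == a)
    total <- sum(out$count[idx])
    if (total > 0)
      out$rscu[idx] <- out$count[idx] / (total / length(idx))
  }
  out[order(out$amino_acid, out$codon), ]
}

#' RSCU for the protein-coding genes of one genome
#'
#' Convenience wrapper: extracts all PCG sequences in reading orientation
#' and runs [count_codons] + [compute_rscu].
#'
#' @param record a [mito_genome] with sequence
#' @return data frame as [compute_rscu]
#' @export
genome_rscu <- function(record) {
  pcg <- record$features$name[record$features$category == "PCG"]
  if (length(pcg) == 0) stop("no protein-coding genes annotated")
  cds <- vapply(pcg, function(nm) extract_feature_sequence(record, nm),
                character(1))
  compute_rscu(count_codons(cds))
}
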