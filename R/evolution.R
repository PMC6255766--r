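## Codon-aware pairwise alignment, Nei-Gojobori (1986) Ka/Ks with
## Jukes-Cantor correction, K2P distances, supermatrix concatenation and
## neighbor joining.

.ng86_env <- new.env(parent = emptyenv())

codon_split <- function(x) {
  n <- nchar(x) %/% 3L
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Translate a CDS
#'
#' Trailing 1-2 nt (incomplete stop) are dropped; codons with ambiguity
#' translate to "X".
#'
#' @param cds nucleotide string in reading orientation
#' @param code genetic code, default [vertebrate_mito_code()]
#' @return character vector of one-letter amino acids ("*" = stop)
#' @export
translate_cds <- function(cds, code = vertebrate_mito_code()) {
  cods <- codon_split(toupper(cds))
  aa <- unname(code[cods])
  aa[is.na(aa)] <- "X"
  aa
}

## Per-codon synonymous site count: at each position the fraction of
## non-stop single-base changes that preserve the amino acid.  Changes to
## stop codons are excluded from the denominator.
ng86_site_table <- function(code) {
  key <- paste(code, collapse = "")
  if (!is.null(.ng86_env[[paste0("sites_", key)]]))
    return(.ng86_env[[paste0("sites_", key)]])
  bases <- c("A", "C", "G", "T")
  codons <- names(code)
  s <- stats::setNames(numeric(length(codons)), codons)
  for (cod in codons) {
    if (code[[cod]] == "*") { s[cod] <- NA_real_; next }
    ch <- strsplit(cod, "")[[1]]
    tot <- 0
    for (pos in 1:3) {
      alts <- bases[bases != ch[pos]]
      alt_codons <- vapply(alts, function(b) {
        x <- ch; x[pos] <- b; paste(x, collapse = "")
      }, character(1))
      valid <- alt_codons[code[alt_codons] != "*"]
      if (length(valid) > 0)
        tot <- tot + sum(code[valid] == code[[cod]]) / length(valid)
    }
    s[cod] <- tot
  }
  .ng86_env[[paste0("sites_", key)]] <- s
  s
}

## Observed synonymous/nonsynonymous differences for one codon pair,
## averaged over all substitution orderings whose intermediates avoid
## stop codons.  If every ordering passes through a stop, all orderings
## are used (steps to or from a stop count as nonsynonymous).
ng86_pair_diff <- function(c1, c2, code) {
  if (c1 == c2) return(c(sd = 0, nd = 0))
  p1 <- strsplit(c1, "")[[1]]
  p2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(p1 != p2)
  k <- length(diff_pos)
  orders <- switch(as.character(k),
                   "1" = list(diff_pos),
                   "2" = list(diff_pos, rev(diff_pos)),
                   "3" = {
                     perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                                   c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
                     lapply(perms, function(p) diff_pos[p])
                   })
  path_counts <- function(ord, allow_stop) {
    cur <- p1
    sd <- 0; nd <- 0
    for (pos in ord) {
      nxt <- cur
      nxt[pos] <- p2[pos]
      a1 <- code[[paste(cur, collapse = "")]]
      a2 <- code[[paste(nxt, collapse = "")]]
      if (a2 == "*" && !allow_stop) return(NULL)
      if (a1 == a2 && a1 != "*") sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(orders, path_counts,
                                        allow_stop = FALSE))
  if (length(res) == 0)
    res <- lapply(orders, path_counts, allow_stop = TRUE)
  counts <- do.call(rbind, res)
  c(sd = mean(counts[, "sd"]), nd = mean(counts[, "nd"]))
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) return(NA_real_)
  if (p == 0) return(0)      # avoid IEEE negative zero from -0.75 * log(1)
  -0.75 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori (1986) Ka/Ks from a codon alignment
#'
#' Counts synonymous (S) and nonsynonymous (N) sites per codon (averaged
#' over the two sequences; single-base changes to stop codons are excluded
#' from the site denominators) and observed synonymous/nonsynonymous
#' differences (Sd, Nd) averaged over all mutational paths that avoid stop
#' intermediates.  Proportions pS = Sd/S and pN = Nd/N are Jukes-Cantor
#' corrected, \code{d = -3/4 log(1 - 4p/3)}; p >= 3/4 gives a saturated
#' (NA) rate.  Codon columns containing a gap, an ambiguity code or a stop
#' codon are excluded pairwise.
#'
#' @param alignment list with elements \code{a} and \code{b}: equal-length
#'   gapped CDS strings (gaps in whole-codon units), e.g. from
#'   [align_codons_pairwise]
#' @param code genetic code, default [vertebrate_mito_code()]
#' @return object of class \code{kaks_record}: S, N, Sd, Nd, pS, pN, Ks,
#'   Ka, ratio, n_codons (compared), n_excluded
#' @export
ng86 <- function(alignment, code = vertebrate_mito_code()) {
  a <- toupper(alignment$a); b <- toupper(alignment$b)
  if (nchar(a) != nchar(b)) stop("aligned rows differ in length")
  if (nchar(a) %% 3L != 0L) stop("alignment length not divisible by 3")
  ca <- codon_split(a); cb <- codon_split(b)
  sites <- ng86_site_table(code)
  clean <- function(x) x %in% names(code) & code[x] != "*"
  use <- clean(ca) & clean(cb)
  S <- 0; Sd <- 0; Nd <- 0
  for (i in which(use)) {
    S <- S + (sites[[ca[i]]] + sites[[cb[i]]]) / 2
    d <- ng86_pair_diff(ca[i], cb[i], code)
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  n_codons <- sum(use)
  N <- 3 * n_codons - S
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jc_correct(pS)
  Ka <- jc_correct(pN)
  ratio <- if (!is.na(Ks) && !is.na(Ka) && Ks > 0) Ka / Ks else NA_real_
  structure(list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 Ks = Ks, Ka = Ka, ratio = ratio,
                 n_codons = n_codons, n_excluded = length(ca) - n_codons),
            class = "kaks_record")
}

#' @export
print.kaks_record <- function(x, ...) {
  cat(sprintf(
    "<kaks> S=%.2f N=%.2f Sd=%.2f Nd=%.2f Ks=%s Ka=%s Ka/Ks=%s (%d codons)\n",
    x$S, x$N, x$Sd, x$Nd,
    formatC(x$Ks, digits = 4, format = "f"),
    formatC(x$Ka, digits = 4, format = "f"),
    formatC(x$ratio, digits = 4, format = "f"), x$n_codons))
  invisible(x)
}

#' Protein-guided pairwise codon alignment
#'
#' Translates both CDS (incomplete trailing codons dropped; internal stops
#' trigger a warning and align as an ordinary residue), aligns the protein
#' sequences globally (match +1, mismatch 0, gap -1) and back-maps the
#' alignment to codons, so gaps occur only in whole-codon units.
#'
#' @param cds_a,cds_b CDS nucleotide strings in reading orientation
#' @param code genetic code, default [vertebrate_mito_code()]
#' @return list: a, b (gapped codon strings), protein_a, protein_b
#' @export
align_codons_pairwise <- function(cds_a, cds_b,
                                  code = vertebrate_mito_code()) {
  aa_a <- translate_cds(cds_a, code)
  aa_b <- translate_cds(cds_b, code)
  if (length(aa_a) == 0 || length(aa_b) == 0)
    stop("CDS shorter than one codon")
  n_int_a <- sum(aa_a[-length(aa_a)] == "*")
  n_int_b <- sum(aa_b[-length(aa_b)] == "*")
  if (n_int_a + n_int_b > 0)
    warning("internal stop codon(s) in CDS; aligned as mismatch state")
  alphabet <- sort(unique(c(aa_a, aa_b, "X", "*")))
  submat <- matrix(0, length(alphabet), length(alphabet),
                   dimnames = list(alphabet, alphabet))
  diag(submat) <- 1
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(paste(gsub("\\*", "U", aa_a), collapse = "")),
    Biostrings::AAString(paste(gsub("\\*", "U", aa_b), collapse = "")),
    substitutionMatrix = {
      rownames(submat) <- colnames(submat) <- gsub("\\*", "U", alphabet)
      submat
    },
    gapOpening = 0, gapExtension = 1, type = "global")
  row_a <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  row_b <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  cod_a <- codon_split(toupper(cds_a))
  cod_b <- codon_split(toupper(cds_b))
  ia <- 0L; ib <- 0L
  out_a <- character(length(row_a)); out_b <- character(length(row_b))
  for (k in seq_along(row_a)) {
    if (row_a[k] == "-") out_a[k] <- "---"
    else { ia <- ia + 1L; out_a[k] <- cod_a[ia] }
    if (row_b[k] == "-") out_b[k] <- "---"
    else { ib <- ib + 1L; out_b[k] <- cod_b[ib] }
  }
  list(a = paste(out_a, collapse = ""), b = paste(out_b, collapse = ""),
       protein_a = paste(row_a, collapse = ""),
       protein_b = paste(row_b, collapse = ""))
}

#' Per-gene Ka/Ks summary over pairwise comparisons
#'
#' Averages the Ka/Ks ratio per gene over pairwise records; NA (saturated
#' or Ks = 0) ratios are excluded with a count.  Genes are returned in
#' ascending order of the mean ratio.
#'
#' @param records data frame with columns \code{gene} and \code{ratio}
#'   (one row per pairwise comparison), e.g. from [kaks_table]
#' @return data frame: gene, mean_ratio, sd_ratio, n_pairs, n_excluded
#' @export
summarize_kaks <- function(records) {
  genes <- unique(records$gene)
  rows <- lapply(genes, function(g) {
    r <- records$ratio[records$gene == g]
    ok <- !is.na(r)
    data.frame(gene = g,
               mean_ratio = if (any(ok)) mean(r[ok]) else NA_real_,
               sd_ratio = if (sum(ok) >= 2) stats::sd(r[ok]) else NA_real_,
               n_pairs = sum(ok), n_excluded = sum(!ok),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_ratio), ]
  rownames(out) <- NULL
  out
}

#' Pairwise Ka/Ks across genomes, per gene
#'
#' For every protein-coding gene shared by the genome records, aligns and
#' runs [ng86] either for every pair against one reference species
#' (\code{mode = "vs_reference"}) or for all species pairs
#' (\code{mode = "all_pairs"}).
#'
#' @param records list of [mito_genome] with sequences
#' @param reference species label of the reference (default: first record)
#' @param mode "vs_reference" or "all_pairs"
#' @return data frame: gene, species_a, species_b, Ka, Ks, ratio
#' @export
kaks_table <- function(records, reference = NULL,
                       mode = c("vs_reference", "all_pairs")) {
  mode <- match.arg(mode)
  species <- vapply(records, `[[`, character(1), "species")
  names(records) <- species
  if (is.null(reference)) reference <- species[1]
  genes <- Reduce(intersect, lapply(records, function(r)
    r$features$name[r$features$category == "PCG"]))
  pairs <- if (mode == "vs_reference") {
    others <- setdiff(species, reference)
    cbind(rep(reference, length(others)), others)
  } else {
    t(utils::combn(species, 2))
  }
  rows <- list()
  for (g in genes) {
    for (i in seq_len(nrow(pairs))) {
      a <- extract_feature_sequence(records[[pairs[i, 1]]], g)
      b <- extract_feature_sequence(records[[pairs[i, 2]]], g)
      rec <- ng86(align_codons_pairwise(a, b))
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, species_a = pairs[i, 1], species_b = pairs[i, 2],
        Ka = rec$Ka, Ks = rec$Ks, ratio = rec$ratio,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Distances and trees -------------------------------------------------------

#' Kimura two-parameter distance between two aligned rows
#'
#' Columns with a gap or ambiguity in either row are excluded.  With
#' transition proportion P and transversion proportion Q,
#' \code{d = 1/2 log(1 / (1 - 2P - Q)) + 1/4 log(1 / (1 - 2Q))}.
#' A non-positive logarithm argument returns NA (saturated).
#'
#' @param row_a,row_b equal-length aligned nucleotide strings
#' @return distance (substitutions/site) or NA
#' @export
k2p_distance <- function(row_a, row_b) {
  a <- strsplit(toupper(row_a), "")[[1]]
  b <- strsplit(toupper(row_b), "")[[1]]
  if (length(a) != length(b)) stop("rows differ in length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n == 0) stop("no comparable sites")
  diff <- a != b
  transitions <- diff & ((a %in% c("A", "G") & b %in% c("A", "G")) |
                           (a %in% c("C", "T") & b %in% c("C", "T")))
  P <- sum(transitions) / n
  Q <- sum(diff & !transitions) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
  0.5 * log(1 / arg1) + 0.25 * log(1 / arg2)
}

#' K2P distance matrix over a set of aligned sequences
#'
#' @param seqs named character vector of equal-length aligned sequences
#' @return symmetric matrix with zero diagonal (NA where saturated)
#' @export
k2p_matrix <- function(seqs) {
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- k2p_distance(seqs[[i]], seqs[[j]])
    m[i, j] <- m[j, i] <- d
  }
  m
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Genes are concatenated in list order; a taxon missing from a gene gets
#' an all-gap block of that gene's width.  The partition map records the
#' 1-based column span of each gene.
#'
#' @param alignments named list (gene -> named character vector of aligned
#'   sequences, equal length within each gene)
#' @return list: supermatrix (named character vector), partitions (data
#'   frame gene, start, end)
#' @export
concatenate_pcgs <- function(alignments) {
  if (is.null(names(alignments)) || any(names(alignments) == ""))
    stop("alignments must be a named list (gene names)")
  for (g in names(alignments)) {
    taxa <- names(alignments[[g]])
    if (anyDuplicated(taxa)) stop("duplicate taxon labels in gene ", g)
    if (length(unique(nchar(alignments[[g]]))) > 1)
      stop("unequal aligned lengths within gene ", g)
  }
  all_taxa <- unique(unlist(lapply(alignments, names)))
  widths <- vapply(alignments, function(x) nchar(x[[1]]), integer(1))
  ends <- cumsum(widths)
  partitions <- data.frame(gene = names(alignments),
                           start = c(1L, utils::head(ends, -1) + 1L),
                           end = ends, stringsAsFactors = FALSE)
  super <- stats::setNames(rep("", length(all_taxa)), all_taxa)
  for (g in names(alignments)) {
    block <- alignments[[g]]
    gap <- strrep("-", widths[[g]])
    for (tx in all_taxa)
      super[[tx]] <- paste0(super[[tx]],
                            if (tx %in% names(block)) block[[tx]] else gap)
  }
  list(supermatrix = super, partitions = partitions)
}

#' Extract one gene's alignment back out of a supermatrix
#'
#' @param concat result of [concatenate_pcgs]
#' @param gene gene name in the partition map
#' @return named character vector
#' @export
supermatrix_partition <- function(concat, gene) {
  p <- concat$partitions[concat$partitions$gene == gene, ]
  if (nrow(p) == 0) stop("unknown gene: ", gene)
  vapply(concat$supermatrix, substr, character(1), p$start, p$end)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via \pkg{ape}); the matrix must be
#' symmetric with a zero diagonal.  Negative branch lengths are clamped to
#' zero with a warning.
#'
#' @param m symmetric distance matrix with taxon dimnames
#' @return an \code{ape::phylo} tree
#' @export
nj_tree <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("not a square matrix")
  if (nrow(m) < 3) stop("need at least 3 taxa")
  if (any(is.na(m))) stop("distance matrix contains NA (saturated pairs)")
  if (!isTRUE(all.equal(m, t(m)))) stop("asymmetric distance matrix")
  tree <- ape::nj(as.dist(m))
  if (any(tree$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}
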