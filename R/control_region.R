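## Tandem repeats (VNTR/STR), conserved motifs and candidate stem-loops in
## control-region sequences.

## minimal period of a string via the KMP failure function
minimal_period <- function(motif) {
  n <- nchar(motif)
  ch <- strsplit(motif, "")[[1]]
  fail <- integer(n)
  k <- 0L
  for (i in 2:max(2L, n)) {
    if (n < 2) break
    while (k > 0 && ch[k + 1] != ch[i]) k <- fail[k]
    if (ch[k + 1] == ch[i]) k <- k + 1L
    fail[i] <- k
  }
  p <- n - fail[n]
  if (n %% p == 0L) p else n
}

#' Find exact tandem repeats
#'
#' Exhaustive scan over periods with greedy maximal extension: a locus is
#' reported where the motif \code{seq[start..start+period-1]} tiles forward
#' for at least \code{min_copies} copies (a fractional final copy is
#' allowed and reflected in \code{copies}).  The motif's smallest period
#' wins (a run of (AT)xN is never reported with period 4), and overlapping
#' candidate loci are collapsed to the leftmost-longest.
#'
#' @param seq nucleotide string
#' @param min_period,max_period period bounds in bp (default 1-60)
#' @param min_copies minimum (possibly fractional) copy number, default 2
#' @param min_length minimum total run length in bp, default 8; suppresses
#'   the ubiquitous chance di- and mononucleotide doublets of random
#'   sequence
#' @return data frame: motif, period, copies, start, end (1-based inclusive)
#' @export
find_tandem_repeats <- function(seq, min_period = 1L, max_period = 60L,
                                min_copies = 2, min_length = 8L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0) stop("empty sequence")
  ch <- strsplit(seq, "")[[1]]
  cand <- list()
  for (p in min_period:min(max_period, n %/% 2)) {
    eq <- ch[seq_len(n - p)] == ch[(p + 1):n]   # eq[i]: s[i] == s[i+p]
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    for (j in which(r$values)) {
      run_start <- pos[j]
      match_len <- r$lengths[j]
      total_len <- match_len + p          # run of periodicity p
      if (total_len < p * min_copies || total_len < min_length) next
      motif <- substr(seq, run_start, run_start + p - 1L)
      if (minimal_period(motif) != p) next
      cand[[length(cand) + 1L]] <- data.frame(
        motif = motif, period = p, copies = total_len / p,
        start = run_start, end = run_start + total_len - 1L,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0)
    return(data.frame(motif = character(), period = integer(),
                      copies = numeric(), start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, cand)
  ## collapse overlaps: leftmost-longest wins, shorter overlapped loci drop
  out <- out[order(out$start, -(out$end - out$start), out$period), ]
  keep <- logical(nrow(out))
  last_end <- 0L
  occupied <- rep(FALSE, n)
  for (i in seq_len(nrow(out))) {
    span <- out$start[i]:out$end[i]
    if (!any(occupied[span])) {
      keep[i] <- TRUE
      occupied[span] <- TRUE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan for an IUPAC motif
#'
#' All exact matches of an IUPAC-ambiguity-aware pattern, 1-based start
#' positions; optionally also searches the reverse complement strand.
#'
#' @param seq nucleotide string
#' @param motif IUPAC pattern, length >= 4
#' @param search_revcomp also report matches of the reverse-complemented
#'   motif (positions still on the forward sequence)
#' @return data frame: start, end, strand ("+" or "-"), match
#' @export
scan_motif <- function(seq, motif, search_revcomp = FALSE) {
  if (nchar(motif) < 4) stop("motif must be at least 4 nt")
  subject <- Biostrings::DNAString(toupper(seq))
  hit_df <- function(pat, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pat), subject,
                                  fixed = FALSE)
    if (length(m) == 0)
      return(data.frame(start = integer(), end = integer(),
                        strand = character(), match = character(),
                        stringsAsFactors = FALSE))
    data.frame(start = Biostrings::start(m), end = Biostrings::end(m),
               strand = strand, match = as.character(m),
               stringsAsFactors = FALSE)
  }
  out <- hit_df(toupper(motif), "+")
  if (search_revcomp)
    out <- rbind(out, hit_df(revcomp(toupper(motif)), "-"))
  out[order(out$start), , drop = FALSE]
}

#' Find candidate stem-loop (hairpin) structures
#'
#' Max-pairing heuristic: every window where a contiguous stem of
#' Watson-Crick or wobble (G:T) pairs within \code{stem_bounds} encloses a
#' loop within \code{loop_bounds}.  Each reported stem is locally maximal
#' (not extendable on either side within the bounds).  Results are ranked
#' by stem length, then by fewest wobble pairs.
#'
#' @param seq nucleotide string
#' @param stem_bounds integer pair (min, max) stem pairs, default c(2, 7)
#' @param loop_bounds integer pair (min, max) loop nt, default c(4, 23)
#' @return data frame: start, end (hairpin span), stem_len, loop_len,
#'   n_wc, n_wobble, pair_classes (comma string, outermost first)
#' @export
find_stem_loops <- function(seq, stem_bounds = c(2L, 7L),
                            loop_bounds = c(4L, 23L)) {
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n == 0) stop("empty sequence")
  ch <- strsplit(seq, "")[[1]]
  paired <- function(i, j) {
    i >= 1 && j <= n && paste0(ch[i], ch[j]) %in% c(WC_PAIRS, WOBBLE_PAIRS)
  }
  rows <- list()
  for (loop_len in loop_bounds[1]:loop_bounds[2]) {
    if (n - loop_len < 2) break
    for (loop_start in 2:(n - loop_len)) {
      i <- loop_start - 1L            # innermost stem positions
      j <- loop_start + loop_len
      if (!paired(i, j)) next
      s <- 1L
      while (s < stem_bounds[2] && paired(i - s, j + s)) s <- s + 1L
      if (s < stem_bounds[1]) next
      ## locally maximal: cannot extend further (checked by loop exit) --
      ## also require the innermost flank not to shrink into a longer stem
      ## reported at another loop window; dedup below
      outer_i <- i - s + 1L
      outer_j <- j + s - 1L
      cls <- pair_class(ch[outer_i:i], ch[outer_j:j])
      rows[[length(rows) + 1L]] <- data.frame(
        start = outer_i, end = outer_j, stem_len = s, loop_len = loop_len,
        n_wc = sum(cls == "watson_crick"), n_wobble = sum(cls == "wobble"),
        pair_classes = paste(cls, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(start = integer(), end = integer(),
                      stem_len = integer(), loop_len = integer(),
                      n_wc = integer(), n_wobble = integer(),
                      pair_classes = character(), stringsAsFactors = FALSE))
  out <- unique(do.call(rbind, rows))
  out <- out[order(-out$stem_len, out$n_wobble, out$start), ]
  rownames(out) <- NULL
  out
}

#' Control-region report for one genome
#'
#' Runs repeat, motif and stem-loop detection on the annotated control
#' region; coordinates are relative to the CR start.
#'
#' @param record a [mito_genome] with sequence
#' @param csb1_motif conserved CSB-1 motif to scan for (default GACATA)
#' @return list with cr_length, composition, repeats, motif_hits, stem_loops
#' @export
control_region_report <- function(record, csb1_motif = "GACATA") {
  crs <- record$features$name[record$features$category == "CR"]
  if (length(crs) == 0) stop("no control region annotated")
  cr <- extract_feature_sequence(record, crs[1])
  list(cr_length = nchar(cr),
       composition = compute_composition(cr),
       repeats = find_tandem_repeats(cr),
       motif_hits = scan_motif(cr, csb1_motif),
       stem_loops = find_stem_loops(cr))
}
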