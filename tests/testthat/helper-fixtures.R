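# Shared fixtures and independent oracles.

# minimal annotated record on a small circular genome
tiny_record <- function(sequence = NULL, genome_length = 40L) {
  feats <- data.frame(
    name = c("geneA", "trnX", "wrap"),
    category = c("PCG", "tRNA", "CR"),
    strand = c("H", "L", "H"),
    start = c(3L, 13L, 35L), end = c(11L, 20L, 40L),
    start2 = c(NA, NA, 1L), end2 = c(NA, NA, 2L),
    anticodon = c(NA, "GAA", NA), stringsAsFactors = FALSE)
  mito_genome(feats, genome_length, sequence = sequence, species = "tiny")
}

random_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# --- independent Nei-Gojobori oracle: plain brute-force enumeration ------

oracle_syn_sites <- function(codon, code) {
  bases <- c("A", "C", "G", "T")
  total <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (b in bases) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (code[[mut]] == "*") next
      valid <- valid + 1
      if (code[[mut]] == code[[codon]]) syn <- syn + 1
    }
    if (valid > 0) total <- total + syn / valid
  }
  total
}

# sd/nd for a codon pair: enumerate all orderings of the differing
# positions explicitly; orderings whose intermediates hit a stop are
# dropped (all orderings used if every one is blocked)
oracle_pair_diff <- function(c1, c2, code) {
  diffs <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (length(diffs) == 0) return(c(0, 0))
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  walk <- function(order, allow_stop) {
    cur <- c1; sd <- 0; nd <- 0
    for (pos in order) {
      nxt <- cur
      substr(nxt, pos, pos) <- substr(c2, pos, pos)
      if (!allow_stop && code[[nxt]] == "*") return(NULL)
      if (code[[cur]] == code[[nxt]] && code[[cur]] != "*") sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  res <- Filter(Negate(is.null), lapply(perms(diffs), walk, allow_stop = FALSE))
  if (length(res) == 0) res <- lapply(perms(diffs), walk, allow_stop = TRUE)
  colMeans(do.call(rbind, res))
}
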