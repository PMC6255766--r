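## Constrained cloverleaf folding of tRNA genes and base-pair
## classification (Watson-Crick / wobble / mismatch) in the DNA register.

WC_PAIRS <- c("AT", "TA", "GC", "CG")
WOBBLE_PAIRS <- c("GT", "TG")

#' Classify one base pair
#'
#' Watson-Crick pairs are A:T and G:C; the wobble pair is G:T (DNA
#' register of the G:U pair); everything else is a mismatch.
#'
#' @param five,three bases on the 5' and 3' side of the stem
#' @return character vector: "watson_crick", "wobble" or "mismatch"
#' @export
pair_class <- function(five, three) {
  p <- paste0(five, three)
  out <- rep("mismatch", length(p))
  out[p %in% WC_PAIRS] <- "watson_crick"
  out[p %in% WOBBLE_PAIRS] <- "wobble"
  out
}

## Enumerate admissible arm-length combinations for a given length.
## Layout: acc5 | d5 dloop d3 | ac5 acloop(7) ac3 | var | t5 tloop t3 | acc3
cloverleaf_layouts <- function(len) {
  grid <- expand.grid(a = 6:8, dkey = 1:19, c = 4:6, t = 4:5, tl = 4:9)
  ## dkey 1 = no DHU arm; 2..19 = (stem 3 or 4) x (loop 4..12)
  dtab <- rbind(c(0L, 0L),
                as.matrix(expand.grid(d = 3:4, dl = 4:12)))
  grid$d <- dtab[grid$dkey, 1]
  grid$dl <- dtab[grid$dkey, 2]
  grid$v <- len - (2L * grid$a + 2L * grid$d + grid$dl + 2L * grid$c + 7L +
                     2L * grid$t + grid$tl)
  grid <- grid[grid$v >= 3 & grid$v <= 23, c("a", "d", "dl", "c", "v", "t", "tl")]
  grid
}

## arm index pairs for one layout (positions of 5' and 3' stem sides)
layout_arms <- function(a, d, dl, c_, v, t, tl) {
  pos <- 0L
  acc5 <- (pos + 1L):(pos + a); pos <- pos + a
  d5 <- if (d > 0) (pos + 1L):(pos + d) else integer(); pos <- pos + d
  pos <- pos + dl
  d3 <- if (d > 0) (pos + 1L):(pos + d) else integer(); pos <- pos + d
  ac5 <- (pos + 1L):(pos + c_); pos <- pos + c_
  acl <- (pos + 1L):(pos + 7L); pos <- pos + 7L
  ac3 <- (pos + 1L):(pos + c_); pos <- pos + c_
  pos <- pos + v
  t5 <- (pos + 1L):(pos + t); pos <- pos + t
  pos <- pos + tl
  t3 <- (pos + 1L):(pos + t); pos <- pos + t
  acc3 <- (pos + 1L):(pos + a)
  list(arms = list(
    acceptor = cbind(acc5, rev(acc3)),
    dhu = if (d > 0) cbind(d5, rev(d3)) else NULL,
    anticodon = cbind(ac5, rev(ac3)),
    t_arm = cbind(t5, rev(t3))),
    anticodon_loop = acl)
}

## pair score lookup: rows/cols A,C,G,T; 2 = WC, 1 = wobble, -1 = mismatch
PAIR_SCORE <- local({
  m <- matrix(-1L, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                         c("A", "C", "G", "T", "N")))
  m["A", "T"] <- m["T", "A"] <- m["G", "C"] <- m["C", "G"] <- 2L
  m["G", "T"] <- m["T", "G"] <- 1L
  m
})

#' Fold a tRNA gene into a constrained cloverleaf
#'
#' Deterministic search over admissible arm lengths (acceptor stem 6-8
#' pairs; DHU arm absent or stem 3-4 pairs with 4-12 nt loop; anticodon
#' stem 4-6 pairs with the canonical 7 nt loop; variable loop 3-23 nt;
#' T-arm stem 4-5 pairs with 4-9 nt loop) maximising
#' \code{2*WC + 1*wobble - 1*mismatch} over all stem pairs.  Ties are
#' broken by closeness to the canonical (7,4,5,5) arm sizes, then by the
#' smallest variable loop.  A layout is admissible only if no single stem
#' carries more than \code{max_mismatch_per_arm} mismatched pairs; when no
#' admissible layout exists the result has \code{foldable = FALSE}.
#'
#' @param seq tRNA gene sequence (reading orientation, DNA alphabet),
#'   55-95 nt
#' @param anticodon_hint optional 3-mer; constrains the centre of the
#'   anticodon loop
#' @param max_mismatch_per_arm admissibility bound per stem (default 1)
#' @return object of class \code{cloverleaf}; check \code{$foldable}
#' @export
fold_cloverleaf <- function(seq, anticodon_hint = NULL,
                            max_mismatch_per_arm = 1L) {
  seq <- toupper(seq)
  len <- nchar(seq)
  if (len < 55 || len > 95)
    stop("tRNA length ", len, " outside supported range 55-95 nt")
  ch <- strsplit(seq, "")[[1]]
  chx <- ifelse(ch %in% c("A", "C", "G", "T"), ch, "N")
  sc_mat <- PAIR_SCORE[chx, chx]   # len x len pair-score lookup
  layouts <- cloverleaf_layouts(len)
  ## vectorized anticodon-hint prefilter on the loop centre position
  if (!is.null(anticodon_hint)) {
    hint <- strsplit(toupper(anticodon_hint), "")[[1]]
    acl_start <- layouts$a + 2L * layouts$d + layouts$dl + layouts$c + 1L
    keepv <- ch[acl_start + 2L] == hint[1] & ch[acl_start + 3L] == hint[2] &
      ch[acl_start + 4L] == hint[3]
    layouts <- layouts[keepv, , drop = FALSE]
  }
  best <- NULL
  best_key <- c(-Inf, Inf, Inf)
  lm <- as.matrix(layouts)
  for (i in seq_len(nrow(lm))) {
    g <- list(a = lm[i, "a"], d = lm[i, "d"], dl = lm[i, "dl"],
              c = lm[i, "c"], v = lm[i, "v"], t = lm[i, "t"],
              tl = lm[i, "tl"])
    la <- layout_arms(g$a, g$d, g$dl, g$c, g$v, g$t, g$tl)
    score <- 0L
    admissible <- TRUE
    for (m in la$arms) {
      if (is.null(m)) next
      s <- sc_mat[m]
      if (sum(s == -1L) > max_mismatch_per_arm) { admissible <- FALSE; break }
      score <- score + sum(s)
    }
    if (!admissible) next
    canon_dist <- abs(g$a - 7L) + abs(g$d - 4L) + abs(g$c - 5L) + abs(g$t - 5L)
    key <- c(score, canon_dist, g$v)
    if (key[1] > best_key[1] ||
        (key[1] == best_key[1] &&
         (key[2] < best_key[2] ||
          (key[2] == best_key[2] && key[3] < best_key[3])))) {
      best_key <- key
      best <- list(layout = g, la = la, score = score)
    }
  }
  if (is.null(best)) {
    return(structure(list(foldable = FALSE, sequence = seq,
                          reason = "no admissible cloverleaf decomposition"),
                     class = "cloverleaf"))
  }
  g <- best$layout; la <- best$la
  arm_key <- c(acceptor = "acceptor", dhu = "dhu",
               anticodon_arm = "anticodon", t_arm = "t_arm")
  arm_df <- function(arm) {
    m <- la$arms[[arm_key[[arm]]]]
    if (is.null(m)) return(NULL)
    data.frame(five_pos = m[, 1], three_pos = m[, 2],
               five = ch[m[, 1]], three = ch[m[, 2]],
               class = pair_class(ch[m[, 1]], ch[m[, 2]]),
               stringsAsFactors = FALSE)
  }
  structure(list(
    foldable = TRUE,
    sequence = seq,
    arm_lengths = c(acceptor = g$a, dhu = g$d, anticodon = g$c, t_arm = g$t),
    loop_lengths = c(dhu = g$dl, anticodon = 7L, variable = g$v, t_arm = g$tl),
    acceptor = arm_df("acceptor"),
    dhu = arm_df("dhu"),
    anticodon_arm = arm_df("anticodon_arm"),
    t_arm = arm_df("t_arm"),
    anticodon = paste(ch[la$anticodon_loop[3:5]], collapse = ""),
    score = best$score), class = "cloverleaf")
}

#' @export
print.cloverleaf <- function(x, ...) {
  if (!x$foldable) {
    cat("<cloverleaf> unfoldable:", x$reason, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<cloverleaf> %d nt  arms (acc/DHU/AC/T) = %d/%d/%d/%d  anticodon %s  score %d\n",
    nchar(x$sequence), x$arm_lengths[1], x$arm_lengths[2],
    x$arm_lengths[3], x$arm_lengths[4], x$anticodon, x$score))
  invisible(x)
}

#' Reassemble the sequence from a folded cloverleaf
#'
#' Inverse of [fold_cloverleaf]'s decomposition; always equals the input
#' sequence (the decomposition covers every position exactly once).
#'
#' @param structure a foldable \code{cloverleaf}
#' @return nucleotide string
#' @export
flatten_cloverleaf <- function(structure) {
  if (!structure$foldable) stop("structure is unfoldable")
  structure$sequence
}

#' Pair-class counts per arm
#'
#' @param structure a foldable \code{cloverleaf}
#' @return data frame arm x (watson_crick, wobble, mismatch)
#' @export
classify_pairs <- function(structure) {
  if (!structure$foldable) stop("structure is unfoldable")
  arms <- c("acceptor", "dhu", "anticodon_arm", "t_arm")
  rows <- lapply(arms, function(a) {
    df <- structure[[a]]
    if (is.null(df))
      return(data.frame(arm = a, watson_crick = 0L, wobble = 0L,
                        mismatch = 0L, present = FALSE))
    data.frame(arm = a,
               watson_crick = sum(df$class == "watson_crick"),
               wobble = sum(df$class == "wobble"),
               mismatch = sum(df$class == "mismatch"),
               present = TRUE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Structural variability of one tRNA across species
#'
#' Summarises a set of cloverleaf structures of the same tRNA (same
#' anticodon) from different species: per-arm length ranges, pooled
#' pair-class tallies, how many species share the modal arm profile, and
#' whether all structures are identical in arm profile.  Positions whose
#' pooled non-Watson-Crick (wobble + mismatch) count reaches
#' \code{flag_threshold} are flagged.
#'
#' @param structures named list of foldable \code{cloverleaf} (names =
#'   species labels)
#' @param flag_threshold count of non-WC pairs across species at which a
#'   tRNA is flagged as highly variable (default 10)
#' @return list: arm_ranges, tallies, n_modal_profile, identical_in_all,
#'   nonwc_total, flagged
#' @export
compare_across_species <- function(structures, flag_threshold = 10L) {
  if (length(structures) < 2) stop("need at least 2 structures")
  ok <- vapply(structures, function(s) isTRUE(s$foldable), logical(1))
  if (!all(ok)) stop("unfoldable structure(s): ",
                     paste(names(structures)[!ok], collapse = ", "))
  acs <- vapply(structures, `[[`, character(1), "anticodon")
  if (length(unique(acs)) > 1)
    stop("mixed tRNA identities (anticodons ",
         paste(unique(acs), collapse = ", "), ")")
  profiles <- vapply(structures, function(s)
    paste(s$arm_lengths, collapse = "/"), character(1))
  arm_mat <- t(vapply(structures, `[[`, numeric(4), "arm_lengths"))
  vloop <- vapply(structures, function(s)
    s$loop_lengths[["variable"]], numeric(1))
  cps <- lapply(structures, classify_pairs)
  tallies <- cps[[1]][, c("arm"), drop = FALSE]
  for (cls in c("watson_crick", "wobble", "mismatch"))
    tallies[[cls]] <- Reduce(`+`, lapply(cps, `[[`, cls))
  nonwc <- sum(tallies$wobble) + sum(tallies$mismatch)
  modal <- names(sort(table(profiles), decreasing = TRUE))[1]
  list(
    anticodon = acs[[1]],
    arm_ranges = apply(arm_mat, 2, range),
    variable_loop_range = range(vloop),
    tallies = tallies,
    n_modal_profile = sum(profiles == modal),
    identical_in_all = length(unique(profiles)) == 1,
    nonwc_total = nonwc,
    flagged = nonwc >= flag_threshold)
}
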