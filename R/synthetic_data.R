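## Synthetic circular mitogenomes with the statistical structure the
## analyses assume, plus divergent CDS pairs for Ka/Ks recovery tests.
## Every generated object carries a truth record re-validated at
## generation time.

## run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Per-base sampling probabilities from composition targets
#'
#' @param at target A+T fraction (0-1)
#' @param at_skew,gc_skew target strand skews
#' @return named numeric vector over A, C, G, T summing to 1
#' @export
base_probs <- function(at, at_skew = 0, gc_skew = 0) {
  stopifnot(at > 0, at < 1)
  gc <- 1 - at
  c(A = at * (1 + at_skew) / 2, C = gc * (1 - gc_skew) / 2,
    G = gc * (1 + gc_skew) / 2, T = at * (1 - at_skew) / 2)
}

sample_bases <- function(n, probs) {
  if (n <= 0) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

## Codon sampling weights over the 60 non-stop codons whose *expected*
## base composition equals the target despite stop exclusion (fixed-point
## correction of the independent-base product weights).
nonstop_codon_probs <- function(probs, code = vertebrate_mito_code()) {
  codons <- names(code)[code != "*"]
  mat <- do.call(rbind, strsplit(codons, ""))
  q <- probs
  for (iter in 1:60) {
    w <- q[mat[, 1]] * q[mat[, 2]] * q[mat[, 3]]
    w <- w / sum(w)
    e <- vapply(c("A", "C", "G", "T"), function(b)
      sum(w * rowSums(mat == b)) / 3, numeric(1))
    q <- q * probs / e
    q <- q / sum(q)
  }
  w <- q[mat[, 1]] * q[mat[, 2]] * q[mat[, 3]]
  stats::setNames(w / sum(w), codons)
}

## Oriented CDS of a given length: templated start codon, non-stop body
## codons, frame-determined ending (complete stop for length %% 3 == 0,
## else an incomplete T / TA stop).
build_cds <- function(len, start_codon, stop_codon, codon_probs) {
  tail_n <- len %% 3L
  n_cod <- len %/% 3L
  stop_s <- if (tail_n == 1L) "T" else if (tail_n == 2L) "TA"
  else if (!is.na(stop_codon) && stop_codon %in% VERT_MITO_STOPS) stop_codon
  else "TAA"
  n_body <- n_cod - 1L - (tail_n == 0L)  # minus start, minus complete stop
  body <- sample(names(codon_probs), n_body, replace = TRUE,
                 prob = codon_probs)
  paste0(start_codon, paste(body, collapse = ""), stop_s)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

## choose DHU/variable/T loop lengths for a given tRNA length under the
## canonical arm sizes; preference close to the canonical loop sizes
solve_trna_loops <- function(len, dhu_absent = FALSE) {
  a <- 7L; d <- if (dhu_absent) 0L else 4L; c_ <- 5L; t <- 5L
  need <- len - (2L * a + 2L * d + 2L * c_ + 7L + 2L * t)
  grid <- expand.grid(dl = if (dhu_absent) 0L else 4:12, v = 3:23, tl = 4:9)
  grid <- grid[grid$dl + grid$v + grid$tl == need, , drop = FALSE]
  if (nrow(grid) == 0)
    stop("no canonical cloverleaf layout for length ", len)
  pen <- abs(grid$dl - ifelse(dhu_absent, 0L, 8L)) + abs(grid$v - 4L) +
    abs(grid$tl - 7L)
  g <- grid[order(pen, grid$v), ][1, ]
  list(a = a, d = d, dl = g$dl, c = c_, v = g$v, t = t, tl = g$tl)
}

## Build a tRNA sequence realising a cloverleaf plan; planted is an
## optional data frame (arm, index, class) of non-Watson-Crick pairs.
build_trna <- function(len, anticodon, probs, dhu_absent = FALSE,
                       planted = NULL) {
  plan <- solve_trna_loops(len, dhu_absent)
  stem <- function(n) sample_bases(n, probs)
  mk_pair3 <- function(five, arm) {
    three <- unname(COMPLEMENT[five])          # 3' side, innermost first
    if (!is.null(planted)) {
      sel <- planted[planted$arm == arm, , drop = FALSE]
      for (r in seq_len(nrow(sel))) {
        i <- sel$index[r]
        if (sel$class[r] == "wobble" && !(five[i] %in% c("G", "T")))
          five[i] <- "G"
        three[i] <- if (sel$class[r] == "wobble") {
          if (five[i] == "G") "T" else "G"
        } else {
          setdiff(c("A", "C", "G", "T"),
                  c(COMPLEMENT[five[i]],
                    if (five[i] %in% c("G", "T")) setdiff(c("G", "T"), five[i])))[1]
        }
      }
    }
    list(five = five, three = rev(three))
  }
  acc <- mk_pair3(stem(plan$a), "acceptor")
  dhu <- if (plan$d > 0) mk_pair3(stem(plan$d), "dhu") else NULL
  ac <- mk_pair3(stem(plan$c), "anticodon_arm")
  tarm <- mk_pair3(stem(plan$t), "t_arm")
  dloop <- sample_bases(plan$dl, probs)
  acloop <- c(sample_bases(2, probs), strsplit(anticodon, "")[[1]],
              sample_bases(2, probs))
  vloop <- sample_bases(plan$v, probs)
  tloop <- sample_bases(plan$tl, probs)
  seq <- paste(c(acc$five, if (!is.null(dhu)) dhu$five, dloop,
                 if (!is.null(dhu)) dhu$three,
                 ac$five, acloop, ac$three, vloop,
                 tarm$five, tloop, tarm$three, acc$three), collapse = "")
  list(seq = seq, plan = plan)
}

## ---------------------------------------------------------------------------

#' Default synthetic genome specification
#'
#' Emulates the annotated black softshell turtle mitogenome: the 37-gene
#' vertebrate layout with its control region spanning the origin
#' (16796 bp), per-partition A+T and skew targets matching that genome
#' (genome 62.16% A+T, AT skew 0.197, GC skew -0.400; PCG 61.26%, tRNA
#' 63.82%, rRNA 61.47%, CR 68.52%), four planted control-region tandem
#' repeats -- (ATTAT)x8, a 49 bp duplication, (AT)x7 and (TATTA)x20,
#' separated by 151 / 781 / 87 bp spacers -- and a planted GACATA motif.
#' The trnS1 gene is built without a DHU arm; all other tRNAs follow the
#' canonical 7/4/5/5 cloverleaf.
#'
#' @param at_target optional single A+T fraction applied to every
#'   partition (overrides the per-partition defaults)
#' @return a \code{genome_spec} list
#' @export
default_genome_spec <- function(at_target = NULL) {
  layout <- nilssonia_feature_table()$features
  comp <- list(
    genome = list(at = 0.6216, at_skew = 0.197, gc_skew = -0.400),
    PCG = list(at = 0.6126, at_skew = 0.136, gc_skew = -0.414),
    tRNA = list(at = 0.6382, at_skew = 0.143, gc_skew = -0.215),
    rRNA = list(at = 0.6147, at_skew = 0.307, gc_skew = -0.180),
    CR = list(at = 0.6852, at_skew = 0.07, gc_skew = -0.374))
  if (!is.null(at_target))
    comp <- lapply(comp, function(x) { x$at <- at_target; x })
  structure(list(
    genome_length = 16796L,
    layout = layout,
    composition = comp,
    cr_repeats = list(
      list(motif = "ATTAT", copies = 8L),
      list(motif = NA, period = 49L, copies = 2L),  # random 49-mer
      list(motif = "AT", copies = 7L),
      list(motif = "TATTA", copies = 20L)),
    cr_spacers = c(151L, 781L, 87L),
    csb1_motif = "GACATA",
    dhu_absent = "trnS1"), class = "genome_spec")
}

## Assemble the control region: flank, repeats with spacers, motif.
build_control_region <- function(len, spec, probs) {
  reps <- spec$cr_repeats
  motifs <- lapply(reps, function(r) {
    if (!is.na(r$motif)) r$motif
    else {  # random aperiodic motif of the requested period
      repeat {
        m <- paste(sample_bases(r$period, probs), collapse = "")
        if (minimal_period(m) == r$period) break
      }
      m
    }
  })
  runs <- vapply(seq_along(reps), function(i)
    strrep(motifs[[i]], reps[[i]]$copies), character(1))
  total_rep <- sum(nchar(runs))
  total_sp <- sum(spec$cr_spacers)
  flank <- len - total_rep - total_sp
  if (flank < 2) stop("control region too short for the repeat layout")
  lead <- flank %/% 2L
  tail_len <- flank - lead
  ## sampling probability for unconstrained CR positions, adjusted so the
  ## whole CR hits its A+T target despite the A/T-only planted repeats
  rep_at <- sum(vapply(seq_along(runs), function(i) {
    ch <- strsplit(runs[[i]], "")[[1]]
    sum(ch %in% c("A", "T"))
  }, numeric(1)))
  n_free <- len - total_rep
  at_free <- (probs[["A"]] + probs[["T"]]) * len - rep_at
  at_free <- min(max(at_free / n_free, 0.05), 0.95)
  scale_at <- at_free / (probs[["A"]] + probs[["T"]])
  scale_gc <- (1 - at_free) / (probs[["C"]] + probs[["G"]])
  q <- probs * c(A = scale_at, C = scale_gc, G = scale_gc, T = scale_at)
  guard <- function(bases, left_of = NULL, right_of = NULL) {
    ## keep spacer/flank ends from extending an adjacent repeat run
    if (!is.null(left_of) && length(bases) > 0) {     # bases precede run
      motif <- left_of
      bad <- substr(motif, nchar(motif), nchar(motif))
      while (bases[length(bases)] == bad)
        bases[length(bases)] <- sample_bases(1, q)
    }
    if (!is.null(right_of) && length(bases) > 0) {    # bases follow run
      bad <- substr(right_of, 1, 1)
      while (bases[1] == bad) bases[1] <- sample_bases(1, q)
    }
    bases
  }
  spacers <- lapply(seq_along(spec$cr_spacers), function(i)
    guard(sample_bases(spec$cr_spacers[i], q),
          left_of = motifs[[i + 1]], right_of = motifs[[i]]))
  ## plant the conserved motif midway through the longest spacer
  longest <- which.max(spec$cr_spacers)
  sp <- spacers[[longest]]
  mpos <- length(sp) %/% 2L
  sp[mpos:(mpos + nchar(spec$csb1_motif) - 1L)] <-
    strsplit(spec$csb1_motif, "")[[1]]
  spacers[[longest]] <- sp
  lead_b <- guard(sample_bases(lead, q), left_of = motifs[[1]])
  tail_b <- guard(sample_bases(tail_len, q), right_of = motifs[[length(runs)]])
  parts <- character(0)
  pos <- length(lead_b)
  truth_rep <- data.frame(motif = vapply(motifs, identity, character(1)),
                          period = nchar(vapply(motifs, identity, character(1))),
                          copies = vapply(reps, function(r) as.numeric(r$copies),
                                          numeric(1)),
                          start = NA_integer_, end = NA_integer_,
                          stringsAsFactors = FALSE)
  parts <- c(parts, paste(lead_b, collapse = ""))
  for (i in seq_along(runs)) {
    truth_rep$start[i] <- pos + 1L
    truth_rep$end[i] <- pos + nchar(runs[i])
    pos <- pos + nchar(runs[i])
    parts <- c(parts, runs[i])
    if (i <= length(spacers)) {
      parts <- c(parts, paste(spacers[[i]], collapse = ""))
      pos <- pos + length(spacers[[i]])
    }
  }
  parts <- c(parts, paste(tail_b, collapse = ""))
  cr <- paste(parts, collapse = "")
  stopifnot(nchar(cr) == len)
  motif_start <- nchar(paste(parts[seq_len(longest * 2)], collapse = "")) +
    mpos
  list(seq = cr, repeats = truth_rep, motif_start = motif_start)
}

#' Generate a synthetic annotated mitogenome with a truth record
#'
#' Deterministic given (spec, seed).  Features are written onto the circle
#' in the order tRNA, PCG, rRNA, CR (first writer wins inside annotated
#' overlaps), intergenic positions are sampled from the genome-wide base
#' probabilities, and the truth record stores planted control-region
#' repeats, per-tRNA cloverleaf plans and realized per-partition
#' composition.  tRNA plans and planted repeats are re-validated against
#' the emitted sequence before returning.
#'
#' @param spec a \code{genome_spec}, default [default_genome_spec()]
#' @param seed integer seed governing all randomness
#' @param species label for the record
#' @return list with \code{record} (a [mito_genome]) and \code{truth}
#' @export
generate_genome <- function(spec = default_genome_spec(), seed = 1L,
                            species = "synthetic") {
  with_seed(seed, {
    layout <- spec$layout
    L <- spec$genome_length
    lin_max <- max(ifelse(is.na(layout$end2), layout$end, layout$end2 +
                            0L), layout$end)
    if (max(layout$end) > L) stop("layout exceeds genome length")
    probs <- list(
      genome = do.call(base_probs, spec$composition$genome),
      PCG = do.call(base_probs, spec$composition$PCG),
      tRNA = do.call(base_probs, spec$composition$tRNA),
      rRNA = do.call(base_probs, spec$composition$rRNA),
      CR = do.call(base_probs, spec$composition$CR))
    codon_probs <- nonstop_codon_probs(probs$PCG)
    genome <- rep(NA_character_, L)

    positions_of <- function(f) {
      p <- f$start:f$end
      if (!is.na(f$start2)) p <- c(p, f$start2:f$end2)
      p
    }
    write_feature <- function(pos, oriented, strand) {
      txt <- if (strand == "L") revcomp(oriented) else oriented
      ch <- strsplit(txt, "")[[1]]
      free <- is.na(genome[pos])
      genome[pos[free]] <<- ch[free]
    }

    truth_trna <- list()
    attempts_limit <- 25L

    ## --- tRNAs first (their structure is the most constrained) ---
    trna_rows <- which(layout$category == "tRNA")
    for (i in trna_rows[order(layout$start[trna_rows])]) {
      f <- layout[i, ]
      len <- feature_length(f)
      dhu_absent <- f$name %in% spec$dhu_absent
      pos <- positions_of(f)
      pre_filled <- !is.na(genome[pos])
      built <- NULL
      for (att in seq_len(attempts_limit)) {
        cand <- build_trna(len, f$anticodon, probs$tRNA, dhu_absent)
        ## validate against what will actually land in the genome
        txt <- if (f$strand == "L") revcomp(cand$seq) else cand$seq
        ch <- strsplit(txt, "")[[1]]
        ch[pre_filled] <- genome[pos[pre_filled]]
        realized <- paste(ch, collapse = "")
        oriented <- if (f$strand == "L") revcomp(realized) else realized
        fold <- fold_cloverleaf(oriented, anticodon_hint = f$anticodon)
        plan_arm <- c(cand$plan$a, cand$plan$d, cand$plan$c, cand$plan$t)
        if (fold$foldable && all(fold$arm_lengths == plan_arm)) {
          built <- list(cand = cand, oriented = oriented)
          break
        }
      }
      if (is.null(built))
        stop("could not realise a foldable plan for ", f$name)
      write_feature(pos, built$cand$seq, f$strand)
      truth_trna[[f$name]] <- list(plan = built$cand$plan,
                                   anticodon = f$anticodon,
                                   dhu_absent = dhu_absent)
    }

    ## --- protein-coding genes ---
    truth_pcg <- list()
    pcg_rows <- which(layout$category == "PCG")
    for (i in pcg_rows[order(layout$start[pcg_rows])]) {
      f <- layout[i, ]
      len <- feature_length(f)
      start_codon <- if ("start_codon" %in% names(layout) &&
                         !is.na(f$start_codon)) f$start_codon else "ATG"
      stop_codon <- if ("stop_codon" %in% names(layout)) f$stop_codon
      else NA_character_
      cds <- build_cds(len, start_codon, stop_codon, codon_probs)
      write_feature(positions_of(f), cds, f$strand)
      truth_pcg[[f$name]] <- list(start_codon = start_codon, length = len)
    }

    ## --- rRNAs ---
    for (i in which(layout$category == "rRNA")) {
      f <- layout[i, ]
      write_feature(positions_of(f),
                    paste(sample_bases(feature_length(f), probs$rRNA),
                          collapse = ""), f$strand)
    }

    ## --- control region (planted repeats + motif) ---
    cr_row <- which(layout$category == "CR")
    truth_cr <- NULL
    if (length(cr_row) == 1) {
      f <- layout[cr_row, ]
      len <- feature_length(f)
      pos <- positions_of(f)
      for (att in seq_len(attempts_limit)) {
        cr <- build_control_region(len, spec, probs$CR)
        found <- find_tandem_repeats(cr$seq)
        ok <- all(vapply(seq_len(nrow(cr$repeats)), function(k) {
          any(found$start == cr$repeats$start[k] &
                found$period == cr$repeats$period[k] &
                found$copies == cr$repeats$copies[k])
        }, logical(1)))
        if (ok) break
      }
      if (!ok) stop("could not realise the planted control-region repeats")
      write_feature(pos, cr$seq, f$strand)
      truth_cr <- cr[c("repeats", "motif_start")]
    }

    ## --- intergenic fill ---
    free <- is.na(genome)
    genome[free] <- sample_bases(sum(free), probs$genome)
    seq <- paste(genome, collapse = "")

    record <- mito_genome(layout, L, sequence = seq, species = species,
                          accession = NA_character_)
    comp <- partition_composition(record)
    truth <- list(
      seed = seed,
      targets = spec$composition,
      realized_at = lapply(comp, function(x) x$at_percent / 100),
      trna = truth_trna,
      pcg = truth_pcg,
      cr = truth_cr)
    list(record = record, truth = truth)
  })
}

#' Generate a pair of divergent CDS with known substitution truth
#'
#' Builds an ancestral CDS of \code{n_codons} random non-stop codons and
#' derives a second sequence by applying at most one substitution per
#' codon: each site mutates synonymously with probability
#' \code{syn_rate} (picking uniformly among its synonymous non-stop
#' alternatives) and nonsynonymously with probability \code{nonsyn_rate}.
#' Because no codon carries more than one change, the realized synonymous
#' and nonsynonymous substitution counts in the truth record coincide
#' exactly with Nei-Gojobori observed differences.
#'
#' @param n_codons CDS length in codons
#' @param syn_rate,nonsyn_rate per-site substitution probabilities (< 0.5)
#' @param code genetic code, default [vertebrate_mito_code()]
#' @param seed integer seed
#' @return list: cds_a, cds_b, truth (n_syn, n_nonsyn, changed_codons)
#' @export
generate_divergent_pair <- function(n_codons, syn_rate, nonsyn_rate,
                                    code = vertebrate_mito_code(),
                                    seed = 1L) {
  if (syn_rate < 0 || nonsyn_rate < 0 || syn_rate >= 0.5 ||
      nonsyn_rate >= 0.5)
    stop("rates must lie in [0, 0.5) to stay clear of saturation")
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    nonstop <- names(code)[code != "*"]
    anc <- sample(nonstop, n_codons, replace = TRUE)
    der <- anc
    n_syn <- 0L; n_nonsyn <- 0L
    changed <- integer(0)
    for (ci in seq_len(n_codons)) {
      ch <- strsplit(anc[ci], "")[[1]]
      events <- list()
      for (pos in 1:3) {
        alts <- bases[bases != ch[pos]]
        alt_cod <- vapply(alts, function(b) {
          x <- ch; x[pos] <- b; paste(x, collapse = "")
        }, character(1))
        alt_cod <- alt_cod[code[alt_cod] != "*"]
        syn_alt <- alt_cod[code[alt_cod] == code[[anc[ci]]]]
        non_alt <- setdiff(alt_cod, syn_alt)
        if (length(syn_alt) > 0 && stats::runif(1) < syn_rate)
          events[[length(events) + 1L]] <-
            list(type = "syn", to = sample(syn_alt, 1))
        if (length(non_alt) > 0 && stats::runif(1) < nonsyn_rate)
          events[[length(events) + 1L]] <-
            list(type = "nonsyn", to = sample(non_alt, 1))
      }
      if (length(events) == 0) next
      ev <- events[[sample.int(length(events), 1)]]
      der[ci] <- ev$to
      if (ev$type == "syn") n_syn <- n_syn + 1L else n_nonsyn <- n_nonsyn + 1L
      changed <- c(changed, ci)
    }
    list(cds_a = paste(anc, collapse = ""),
         cds_b = paste(der, collapse = ""),
         truth = list(n_syn = n_syn, n_nonsyn = n_nonsyn,
                      changed_codons = changed,
                      syn_rate = syn_rate, nonsyn_rate = nonsyn_rate))
  })
}

#' Export a generated genome as GenBank + FASTA + truth JSON
#'
#' @param generated result of [generate_genome]
#' @param dir output directory (created if needed)
#' @param basename file stem
#' @return named character vector of written paths
#' @export
export_synthetic_genome <- function(generated, dir, basename = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gb <- file.path(dir, paste0(basename, ".gb"))
  fa <- file.path(dir, paste0(basename, ".fasta"))
  js <- file.path(dir, paste0(basename, ".truth.json"))
  write_genbank(generated$record, gb)
  write_fasta_genome(generated$record, fa)
  jsonlite::write_json(generated$truth, js, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  c(genbank = gb, fasta = fa, truth = js)
}
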