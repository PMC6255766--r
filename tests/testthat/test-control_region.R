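test_that("a planted repeat in random flanks is found exactly", {
  set.seed(61)
  flank <- function(n) random_dna(n, alphabet = c("G", "C"))
  s <- paste0(flank(50), strrep("ATTAT", 8), flank(50))
  reps <- find_tandem_repeats(s)
  hit <- reps[reps$motif == "ATTAT", ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$copies, 8)
  expect_equal(hit$start, 51L)
  expect_equal(hit$end, 90L)
})

test_that("the smallest period wins for multi-period runs", {
  reps <- find_tandem_repeats("ATATATATATATAT", min_length = 4L)
  expect_equal(nrow(reps), 1L)
  expect_equal(reps$period, 2L)
  expect_equal(reps$copies, 7)
  expect_identical(reps$motif, "AT")
})

test_that("two planted repeats separated by a spacer are both reported", {
  set.seed(62)
  spacer <- random_dna(87, alphabet = c("G", "C"))
  s <- paste0(strrep("AT", 7), spacer, strrep("TATTA", 20))
  reps <- find_tandem_repeats(s)
  reps <- reps[reps$motif %in% c("AT", "TATTA"), ]
  expect_equal(nrow(reps), 2L)
  expect_equal(reps$start, c(1L, 14L + 87L + 1L))
  expect_equal(reps$copies, c(7, 20))
  # observed spacer between the two loci
  expect_equal(reps$start[2] - reps$end[1] - 1L, 87L)
})

test_that("repeat finder is exact on motif^k for random aperiodic motifs", {
  set.seed(63)
  for (rep_i in 1:40) {
    p <- sample(1:60, 1)
    k <- sample(2:25, 1)
    repeat {
      motif <- random_dna(p)
      if (mitocomp:::minimal_period(motif) == p) break
    }
    s <- strrep(motif, k)
    reps <- find_tandem_repeats(s, min_length = 2L)
    expect_equal(nrow(reps), 1L, info = paste(motif, k))
    expect_equal(reps$period, p)
    expect_equal(reps$copies, k)
    # reported locus re-validates: the span is the motif tiled k times
    expect_identical(substr(s, reps$start, reps$end), strrep(motif, k))
  }
})

test_that("IUPAC motif scanning reports 1-based exact matches", {
  hits <- scan_motif("AAGACATAAA", "GACATA")
  expect_equal(hits$start, 3L)
  expect_equal(nrow(scan_motif("AAAAAAA", "GACATA")), 0L)
  # IUPAC Y matches C and T
  hits_y <- scan_motif("GACATAGGGGATATA", "GAYATA")
  expect_equal(hits_y$start, c(1L, 10L))
  # reverse-complement search reports forward coordinates
  hits_rc <- scan_motif(paste0("TT", revcomp("GACATA"), "TT"), "GACATA",
                        search_revcomp = TRUE)
  expect_equal(hits_rc$strand, "-")
  expect_equal(hits_rc$start, 3L)
  expect_error(scan_motif("ACGT", "ACG"), "at least 4")
})

test_that("stem-loop detection finds hairpins and honours pair classes", {
  sl <- find_stem_loops("GCGCAAAAGCGC")
  expect_gte(nrow(sl), 1L)
  expect_equal(sl$stem_len[1], 4L)
  expect_equal(sl$loop_len[1], 4L)
  expect_equal(sl$n_wobble[1], 0L)

  expect_equal(nrow(find_stem_loops(strrep("A", 60))), 0L)

  # planted hairpin with one wobble pair in the stem
  sl2 <- find_stem_loops("GCTGAAAACGGC")
  top <- sl2[1, ]
  expect_equal(top$stem_len, 4L)
  expect_equal(top$n_wobble, 1L)
  cls <- strsplit(top$pair_classes, ",")[[1]]
  expect_equal(sum(cls == "wobble"), 1L)
  # every reported pair is complementary under its declared class:
  # stems contain only watson_crick/wobble by construction
  expect_true(all(cls %in% c("watson_crick", "wobble")))
})

test_that("the control-region report recovers every planted truth field", {
  gen <- generate_genome(seed = 64L)
  rep_ <- control_region_report(gen$record)
  expect_equal(rep_$cr_length, 1290L)
  truth <- gen$truth$cr$repeats
  for (k in seq_len(nrow(truth))) {
    m <- rep_$repeats[rep_$repeats$start == truth$start[k], ]
    expect_equal(nrow(m), 1L)
    expect_identical(m$motif, truth$motif[k])
    expect_equal(m$copies, truth$copies[k])
    expect_equal(m$end, truth$end[k])
  }
  # conserved motif present at the planted position
  expect_true(gen$truth$cr$motif_start %in% rep_$motif_hits$start)
  # stem-loops exist within the documented bounds
  expect_gte(nrow(rep_$stem_loops), 1L)
  expect_true(all(rep_$stem_loops$stem_len >= 2 &
                    rep_$stem_loops$stem_len <= 7))
  expect_true(all(rep_$stem_loops$loop_len >= 4 &
                    rep_$stem_loops$loop_len <= 23))
})
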