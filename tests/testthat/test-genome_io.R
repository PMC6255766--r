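test_that("the bundled feature table parses into the full 37-gene annotation", {
  rec <- nilssonia_feature_table()
  expect_s3_class(rec, "mito_genome")
  expect_equal(as.integer(table(rec$features$category)[c("PCG", "tRNA", "rRNA", "CR")]),
               c(13L, 22L, 2L, 1L))
  expect_equal(rec$genome_length, 16796L)
  # features come back sorted by first start and stay stable
  expect_equal(rec$features$start, sort(rec$features$start))
  expect_identical(rec$features$name[1], "trnF")
  # origin-spanning CR kept as two segments, never end < start
  cr <- rec$features[rec$features$name == "CR", ]
  expect_equal(c(cr$start, cr$end, cr$start2, cr$end2),
               c(15565L, 16796L, 1L, 58L))
})

test_that("feature-table edge cases: empty file, bad coordinates, duplicates", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines("name\tcategory\tstrand\tstart\tend", tmp)
  empty <- read_feature_table(tmp, genome_length = 1000L)
  expect_equal(nrow(empty$features), 0L)

  writeLines(c("name\tcategory\tstrand\tstart\tend",
               "bad\tPCG\tH\t50\t10"), tmp)
  expect_error(read_feature_table(tmp, 1000L), "end < start")

  writeLines(c("name\tcategory\tstrand\tstart\tend",
               "g1\tPCG\tH\t1\t30", "g1\tPCG\tH\t40\t60"), tmp)
  expect_error(read_feature_table(tmp, 1000L), "duplicate")

  writeLines(c("name\tcategory\tstrand\tstart\tend",
               "g1\tPCG\tH\t1\txyz"), tmp)
  expect_error(read_feature_table(tmp, 1000L), "malformed")
})

test_that("feature extraction orients, wraps the origin and reverse-complements", {
  s <- paste(rep("ACGTAACCGGTTACGTAACC", 2), collapse = "")  # 40 bp
  rec <- tiny_record(sequence = s)
  # H-strand: plain substring
  expect_identical(extract_feature_sequence(rec, "geneA"), substr(s, 3, 11))
  # L-strand tRNA: reverse complement of the genome text
  expect_identical(extract_feature_sequence(rec, "trnX"),
                   revcomp(substr(s, 13, 20)))
  expect_identical(extract_feature_sequence(rec, "trnX", orient = FALSE),
                   substr(s, 13, 20))
  # origin-spanning feature concatenates its segments in order
  expect_identical(extract_feature_sequence(rec, "wrap"),
                   paste0(substr(s, 35, 40), substr(s, 1, 2)))
  expect_error(extract_feature_sequence(rec, "nope"), "unknown feature")
  expect_identical(revcomp("AACC"), "GGTT")
})

test_that("extracted length equals the circular feature length for every feature", {
  gen <- generate_genome(seed = 301L)
  rec <- gen$record
  for (i in seq_len(nrow(rec$features))) {
    f <- rec$features[i, ]
    expect_equal(nchar(extract_feature_sequence(rec, f$name)),
                 mitocomp:::feature_length(f), info = f$name)
  }
})

test_that("GenBank write/read round-trips generator output exactly", {
  rec <- generate_genome(seed = 302L, species = "roundtrip")$record
  gb <- tempfile(fileext = ".gb")
  write_genbank(rec, gb)
  back <- read_genbank(gb)
  expect_identical(back$sequence, rec$sequence)
  cols <- c("name", "category", "strand", "start", "end", "start2", "end2",
            "anticodon")
  expect_identical(back$features[, cols], rec$features[, cols])
  # complement() mapped to strand L, join() to two segments
  expect_identical(back$features$strand[back$features$name == "nad6"], "L")
  expect_false(is.na(back$features$start2[back$features$name == "CR"]))
})

test_that("a GenBank file without ORIGIN yields a sequence-free record, not a crash", {
  rec <- generate_genome(seed = 303L)$record
  gb <- tempfile(fileext = ".gb")
  write_genbank(rec, gb)
  lines <- readLines(gb)
  o <- grep("^ORIGIN", lines)
  writeLines(c(lines[seq_len(o - 1)], "//"), gb)
  back <- read_genbank(gb)
  expect_null(back$sequence)
  expect_equal(nrow(back$features), 38L)
  expect_error(extract_feature_sequence(back, "nad1"), "no sequence")
})
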