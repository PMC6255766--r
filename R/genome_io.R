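## Circular-coordinate arithmetic -------------------------------------------

#' Length of a (possibly origin-spanning) feature on a circular genome
#'
#' Features are stored as one or two 1-based inclusive segments; a second
#' segment is only used for features wrapping the origin (e.g. a control
#' region annotated as 15565..16796 joined to 1..58).
#'
#' @param feature one row of a feature table (list or single-row data frame)
#' @return integer length in bp
#' @keywords internal
feature_length <- function(feature) {
  len <- feature$end - feature$start + 1L
  if (!is.na(feature$start2)) {
    len <- len + feature$end2 - feature$start2 + 1L
  }
  as.integer(len)
}

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented correctly (e.g. R <-> Y).
#'
#' @param x upper-case DNA string
#' @return reverse-complemented string
#' @export
#' @examples
#' revcomp("AACC")  # "GGTT"
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

## Record constructor --------------------------------------------------------

#' Construct an annotated mitogenome record
#'
#' The central container of the package: an ordered circular feature
#' annotation plus an optional genome sequence.  Features are sorted by the
#' start of their first segment; names must be unique.
#'
#' @param features data frame with columns \code{name}, \code{category}
#'   (one of PCG, tRNA, rRNA, CR), \code{strand} (H or L), \code{start},
#'   \code{end}, and optionally \code{start2}, \code{end2} (origin-spanning
#'   features) and \code{anticodon} (tRNA only)
#' @param genome_length declared genome length in bp
#' @param sequence optional upper-case genome sequence (H-strand text);
#'   when given, its length must equal \code{genome_length}
#' @param species,accession labels carried through reports
#' @return object of class \code{mito_genome}
#' @export
mito_genome <- function(features, genome_length, sequence = NULL,
                        species = "unknown", accession = NA_character_) {
  stopifnot(is.data.frame(features))
  needed <- c("name", "category", "strand", "start", "end")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols) > 0)
    stop("feature table lacks columns: ", paste(missing_cols, collapse = ", "))
  n_feat <- nrow(features)
  if (!"start2" %in% names(features))
    features$start2 <- rep(NA_integer_, n_feat)
  if (!"end2" %in% names(features))
    features$end2 <- rep(NA_integer_, n_feat)
  if (!"anticodon" %in% names(features))
    features$anticodon <- rep(NA_character_, n_feat)
  for (col in c("start", "end", "start2", "end2"))
    features[[col]] <- as.integer(features[[col]])

  if (anyDuplicated(features$name))
    stop("duplicate feature names: ",
         paste(unique(features$name[duplicated(features$name)]), collapse = ", "))
  bad <- which(features$end < features$start)
  if (length(bad) > 0)
    stop("feature '", features$name[bad[1]], "': end < start (",
         features$end[bad[1]], " < ", features$start[bad[1]],
         "); origin-spanning features must use a second segment")
  bad <- which(features$end > genome_length | features$start < 1L |
                 (!is.na(features$end2) & features$end2 > genome_length))
  if (length(bad) > 0)
    stop("feature '", features$name[bad[1]], "' exceeds genome length ",
         genome_length)
  bad <- which(features$category == "tRNA" & is.na(features$anticodon))
  if (length(bad) > 0)
    warning("tRNA feature(s) without anticodon: ",
            paste(features$name[bad], collapse = ", "))

  if (!is.null(sequence)) {
    sequence <- toupper(sequence)
    if (nchar(sequence) != genome_length)
      stop("sequence length ", nchar(sequence),
           " != declared genome length ", genome_length)
    if (grepl("[^ACGTRYSWKMBDHVN]", sequence))
      stop("sequence contains non-IUPAC characters")
  }

  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  structure(
    list(species = species, accession = accession,
         genome_length = as.integer(genome_length),
         sequence = sequence, features = features),
    class = "mito_genome")
}

#' @export
print.mito_genome <- function(x, ...) {
  cat("<mito_genome> ", x$species,
      if (!is.na(x$accession)) paste0(" (", x$accession, ")"), "\n", sep = "")
  cat("  circular genome: ", x$genome_length, " bp",
      if (is.null(x$sequence)) " (annotation only)" else " (sequence attached)",
      "\n", sep = "")
  tab <- table(x$features$category)
  cat("  features: ", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

## Feature-table TSV ---------------------------------------------------------

#' Read a feature-coordinate table
#'
#' The TSV dialect has columns \code{name}, \code{category}, \code{strand},
#' \code{start}, \code{end} and optionally \code{start2}, \code{end2},
#' \code{anticodon} (plus any annotation columns such as \code{start_codon},
#' which are carried along).  Coordinates are 1-based inclusive;
#' origin-spanning features carry a second segment.
#'
#' @param path TSV file with a header row
#' @param genome_length declared circular genome length in bp
#' @param species,accession labels for the record
#' @return a [mito_genome] record (without sequence)
#' @export
read_feature_table <- function(path, genome_length, species = "unknown",
                               accession = NA_character_) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, fill = TRUE,
                           na.strings = c("NA", ""))
  if (nrow(tab) == 0) {
    empty <- data.frame(name = character(), category = character(),
                        strand = character(), start = integer(),
                        end = integer(), stringsAsFactors = FALSE)
    return(mito_genome(empty, genome_length, species = species,
                       accession = accession))
  }
  for (col in c("start", "end")) {
    v <- suppressWarnings(as.integer(tab[[col]]))
    if (anyNA(v))
      stop("malformed ", col, " in row ", which(is.na(v))[1],
           " (", tab$name[which(is.na(v))[1]], ")")
    tab[[col]] <- v
  }
  mito_genome(tab, genome_length, species = species, accession = accession)
}

#' Write a feature-coordinate table
#'
#' @param record a [mito_genome]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_feature_table <- function(record, path) {
  utils::write.table(record$features, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Bundled feature table of the Nilssonia nigricans mitogenome
#'
#' The 37-gene annotation (13 protein-coding genes, 22 tRNAs, 2 rRNAs) plus
#' control region of the black softshell turtle mitogenome (16796 bp,
#' GenBank accession MG383833), as a ready-made [mito_genome] record
#' without sequence.  The control region spans the origin
#' (15565..16796 + 1..58).
#'
#' @return a [mito_genome] record with 38 features
#' @export
nilssonia_feature_table <- function() {
  path <- system.file("extdata", "nilssonia_nigricans_mtgenes.tsv",
                      package = "mitocomp", mustWork = TRUE)
  read_feature_table(path, genome_length = 16796L,
                     species = "Nilssonia nigricans", accession = "MG383833")
}

## GenBank flat file ---------------------------------------------------------

#' Read an annotated mitogenome from a GenBank flat file
#'
#' Parses LOCUS, ORIGIN and the feature keys CDS, tRNA, rRNA and D-loop.
#' \code{complement(a..b)} locations map to strand L; \code{join(a..b,c..d)}
#' maps to a two-segment (origin-spanning) feature.  A file without an
#' ORIGIN block yields a record whose \code{sequence} is \code{NULL}.
#'
#' @param path GenBank flat file
#' @return a [mito_genome]
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) stop("not a GenBank flat file: no LOCUS line")
  genome_length <- as.integer(sub(".*?(\\d+)\\s+bp.*", "\\1", locus[1]))
  species <- "unknown"
  org <- grep("^\\s+ORGANISM", lines, value = TRUE)
  if (length(org) > 0) species <- trimws(sub("^\\s+ORGANISM\\s+", "", org[1]))
  accession <- NA_character_
  acc <- grep("^ACCESSION", lines, value = TRUE)
  if (length(acc) > 0) {
    accession <- trimws(sub("^ACCESSION\\s*", "", acc[1]))
    if (accession == "" || accession == "unknown") accession <- NA_character_
  }

  ## feature block
  fstart <- grep("^FEATURES", lines)
  fend <- grep("^(ORIGIN|//)", lines)
  fend <- fend[fend > fstart][1]
  feat_lines <- if (length(fstart) > 0 && !is.na(fend) && fend > fstart + 1)
    lines[(fstart + 1):(fend - 1)] else character()

  keys <- c(CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA", D_loop = "CR")
  is_key <- grepl("^\\s{1,10}(CDS|tRNA|rRNA|D-loop)\\s", feat_lines)
  idx <- which(is_key)
  rows <- list()
  for (k in seq_along(idx)) {
    i <- idx[k]
    block_end <- if (k < length(idx)) idx[k + 1] - 1 else length(feat_lines)
    block <- feat_lines[i:block_end]
    key <- sub("^\\s+(\\S+).*", "\\1", block[1])
    category <- keys[[gsub("-", "_", key)]]
    loc <- sub("^\\s+\\S+\\s+", "", block[1])
    strand <- if (grepl("complement", loc)) "L" else "H"
    segs <- regmatches(loc, gregexpr("\\d+\\.\\.\\d+", loc))[[1]]
    if (length(segs) < 1 || length(segs) > 2)
      stop("unsupported location '", loc, "'")
    coords <- do.call(rbind, lapply(strsplit(segs, "\\.\\."), as.integer))
    qual <- paste(block[-1], collapse = " ")
    gname <- if (grepl("/gene=", qual))
      sub('.*?/gene="([^"]+)".*', "\\1", qual) else paste0(key, "_", k)
    anticodon <- NA_character_
    if (grepl("/note=\"anticodon:", qual))
      anticodon <- sub('.*?/note="anticodon:([A-Z]{3})".*', "\\1", qual)
    rows[[k]] <- data.frame(
      name = gname, category = category, strand = strand,
      start = coords[1, 1], end = coords[1, 2],
      start2 = if (nrow(coords) == 2) coords[2, 1] else NA_integer_,
      end2 = if (nrow(coords) == 2) coords[2, 2] else NA_integer_,
      anticodon = anticodon, stringsAsFactors = FALSE)
  }
  features <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(name = character(), category = character(),
               strand = character(), start = integer(), end = integer(),
               stringsAsFactors = FALSE)

  ## sequence
  ostart <- grep("^ORIGIN", lines)
  sequence <- NULL
  if (length(ostart) > 0) {
    oend <- grep("^//", lines)
    oend <- oend[oend > ostart[1]][1]
    if (is.na(oend)) oend <- length(lines) + 1
    seq_lines <- lines[(ostart[1] + 1):(oend - 1)]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
    if (nchar(sequence) == 0) sequence <- NULL
  }
  mito_genome(features, genome_length, sequence = sequence,
              species = species, accession = accession)
}

#' Write a mitogenome record as a GenBank flat file
#'
#' Emits LOCUS, ACCESSION, ORGANISM, a FEATURES table (CDS/tRNA/rRNA/D-loop
#' keys, complement() for L-strand features, join() for origin-spanning
#' segments) and the ORIGIN block when a sequence is attached.
#'
#' @param record a [mito_genome]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_genbank <- function(record, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl(sprintf("LOCUS       %-16s %d bp    DNA     circular     %s",
             ifelse(is.na(record$accession), "synthetic", record$accession),
             record$genome_length, format(Sys.Date(), "%d-%b-%Y")))
  wl("DEFINITION  ", record$species, " mitochondrion, complete genome.")
  wl("ACCESSION   ",
     ifelse(is.na(record$accession), "unknown", record$accession))
  wl("  ORGANISM  ", record$species)
  wl("FEATURES             Location/Qualifiers")
  keys <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", CR = "D-loop")
  for (i in seq_len(nrow(record$features))) {
    f <- record$features[i, ]
    loc <- paste0(f$start, "..", f$end)
    if (!is.na(f$start2))
      loc <- paste0("join(", loc, ",", f$start2, "..", f$end2, ")")
    if (f$strand == "L") loc <- paste0("complement(", loc, ")")
    wl(sprintf("     %-16s%s", keys[[f$category]], loc))
    wl(sprintf("                     /gene=\"%s\"", f$name))
    if (!is.na(f$anticodon))
      wl(sprintf("                     /note=\"anticodon:%s\"", f$anticodon))
  }
  if (!is.null(record$sequence)) {
    wl("ORIGIN")
    s <- tolower(record$sequence)
    pos <- seq(1, nchar(s), by = 60)
    for (p in pos) {
      chunk <- substr(s, p, min(p + 59, nchar(s)))
      groups <- regmatches(chunk, gregexpr(".{1,10}", chunk))[[1]]
      wl(sprintf("%9d %s", p, paste(groups, collapse = " ")))
    }
  }
  wl("//")
  invisible(path)
}

#' Write the genome sequence as FASTA
#'
#' @param record a [mito_genome] with sequence
#' @param path output file
#' @return `path`, invisibly
#' @export
write_fasta_genome <- function(record, path) {
  if (is.null(record$sequence)) stop("record has no sequence")
  x <- Biostrings::DNAStringSet(record$sequence)
  names(x) <- paste0(ifelse(is.na(record$accession), "synthetic",
                            record$accession), " ", record$species)
  Biostrings::writeXStringSet(x, path, width = 70)
  invisible(path)
}

## Sequence extraction -------------------------------------------------------

#' Extract the oriented sequence of one annotated feature
#'
#' Segments are concatenated in annotation order (wrapping the origin for
#' two-segment features) and the result is reverse-complemented when the
#' feature lies on the light (L) strand, so PCG/tRNA sequences come back in
#' their reading orientation.
#'
#' @param record a [mito_genome] with sequence attached
#' @param name feature name
#' @param orient if FALSE, return the H-strand (genome register) text even
#'   for L-strand features
#' @return upper-case nucleotide string
#' @export
extract_feature_sequence <- function(record, name, orient = TRUE) {
  if (is.null(record$sequence)) stop("record has no sequence")
  i <- match(name, record$features$name)
  if (is.na(i)) stop("unknown feature: ", name)
  f <- record$features[i, ]
  if (f$end > record$genome_length) stop("segment beyond declared length")
  s <- substr(record$sequence, f$start, f$end)
  if (!is.na(f$start2)) {
    if (f$end2 > record$genome_length) stop("segment beyond declared length")
    s <- paste0(s, substr(record$sequence, f$start2, f$end2))
  }
  if (orient && f$strand == "L") s <- revcomp(s)
  s
}
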