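## Cross-species comparative pipeline joining all stages, with artifact
## files, manifest and log.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  path
}

#' Run the comparative mitogenome pipeline
#'
#' Executes the enabled stages over one or more genome records and writes
#' per-stage TSV/JSON/newick artifacts plus a manifest and log to
#' \code{out_dir}.  Stages: \code{metrics} (gene table, adjacency,
#' strand tally), \code{composition}, \code{rscu}, \code{trna}
#' (cloverleaf folds), \code{cr} (repeats, motif, stem-loops),
#' \code{kaks} (pairwise Nei-Gojobori vs the reference), \code{tree}
#' (K2P + neighbor joining on the concatenated PCGs; genes whose lengths
#' differ across species are skipped with a note).  A failing stage is
#' isolated: its error is logged and the other stages still run.
#'
#' @param genomes list of [mito_genome] records (or paths to GenBank
#'   files, which are read first)
#' @param stages character vector of stage names (default: all)
#' @param out_dir output directory
#' @param reference species used as the Ka/Ks reference (default: first)
#' @return invisibly, a list with \code{report} (one row per species),
#'   \code{artifacts} (paths), \code{errors} (named list, empty on success)
#' @export
run_pipeline <- function(genomes,
                         stages = c("metrics", "composition", "rscu",
                                    "trna", "cr", "kaks", "tree"),
                         out_dir = tempfile("mitocomp_run_"),
                         reference = NULL) {
  if (length(genomes) == 0) stop("no genome inputs given")
  known <- c("metrics", "composition", "rscu", "trna", "cr", "kaks", "tree")
  bad <- setdiff(stages, known)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  genomes <- lapply(genomes, function(g) {
    if (is.character(g)) {
      if (!file.exists(g)) stop("unreadable input: ", g)
      read_genbank(g)
    } else g
  })
  species <- vapply(genomes, `[[`, character(1), "species")
  names(genomes) <- species
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(format(Sys.time(), "%H:%M:%S "), ...,
                            "\n", sep = "", file = log_path, append = TRUE)
  artifacts <- character(0)
  errors <- list()
  report <- data.frame(species = species, genome_length =
                         vapply(genomes, `[[`, integer(1), "genome_length"),
                       stringsAsFactors = FALSE)
  run_stage <- function(name, fn) {
    logf("stage ", name, " start")
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      logf("stage ", name, " FAILED: ", conditionMessage(res))
      errors[[name]] <<- conditionMessage(res)
    } else {
      logf("stage ", name, " done")
    }
  }

  if ("metrics" %in% stages) run_stage("metrics", function() {
    for (sp in species) {
      gt <- build_gene_table(genomes[[sp]])
      adj <- adjacency_analysis(genomes[[sp]])
      p1 <- write_tsv(gt, file.path(out_dir, paste0(sp, "_gene_table.tsv")))
      p2 <- write_tsv(adj$pairs,
                      file.path(out_dir, paste0(sp, "_adjacency.tsv")))
      artifacts <<- c(artifacts, p1, p2)
      for (k in names(adj$summary))
        report[report$species == sp, k] <<- adj$summary[[k]]
    }
  })

  have_seq <- vapply(genomes, function(g) !is.null(g$sequence), logical(1))

  if ("composition" %in% stages) run_stage("composition", function() {
    tab <- composition_table(genomes[have_seq])
    artifacts <<- c(artifacts,
                    write_tsv(tab, file.path(out_dir, "composition.tsv")))
    gen <- tab[tab$partition == "genome", ]
    for (col in c("at_percent", "at_skew", "gc_skew"))
      report[[col]] <<- gen[[col]][match(report$species, gen$species)]
  })

  if ("rscu" %in% stages) run_stage("rscu", function() {
    for (sp in species[have_seq]) {
      tab <- genome_rscu(genomes[[sp]])
      artifacts <<- c(artifacts,
                      write_tsv(tab, file.path(out_dir,
                                               paste0(sp, "_rscu.tsv"))))
    }
  })

  if ("trna" %in% stages) run_stage("trna", function() {
    for (sp in species[have_seq]) {
      rec <- genomes[[sp]]
      trnas <- rec$features[rec$features$category == "tRNA", ]
      folds <- lapply(seq_len(nrow(trnas)), function(i) {
        s <- extract_feature_sequence(rec, trnas$name[i])
        f <- fold_cloverleaf(s, anticodon_hint = trnas$anticodon[i])
        if (!f$foldable) f <- fold_cloverleaf(s)  # retry unconstrained
        if (!f$foldable) return(list(foldable = FALSE))
        list(foldable = TRUE,
             arm_lengths = as.list(f$arm_lengths),
             anticodon = f$anticodon, score = f$score,
             pair_classes = classify_pairs(f))
      })
      names(folds) <- trnas$name
      p <- file.path(out_dir, paste0(sp, "_trna_structures.json"))
      jsonlite::write_json(folds, p, auto_unbox = TRUE, digits = NA,
                           force = TRUE, pretty = TRUE)
      artifacts <<- c(artifacts, p)
    }
  })

  if ("cr" %in% stages) run_stage("cr", function() {
    for (sp in species[have_seq]) {
      rep_ <- control_region_report(genomes[[sp]])
      p1 <- write_tsv(rep_$repeats,
                      file.path(out_dir, paste0(sp, "_cr_repeats.tsv")))
      p2 <- write_tsv(rep_$stem_loops,
                      file.path(out_dir, paste0(sp, "_cr_stemloops.tsv")))
      artifacts <<- c(artifacts, p1, p2)
      report[report$species == sp, "cr_length"] <<- rep_$cr_length
      report[report$species == sp, "cr_repeats"] <<-
        paste(sprintf("(%s)%g", rep_$repeats$motif, rep_$repeats$copies),
              collapse = ";")
      report[report$species == sp, "csb1_hits"] <<- nrow(rep_$motif_hits)
    }
  })

  if ("kaks" %in% stages && sum(have_seq) >= 2) run_stage("kaks", function() {
    tab <- suppressWarnings(
      kaks_table(genomes[have_seq], reference = reference))
    artifacts <<- c(artifacts,
                    write_tsv(tab, file.path(out_dir, "kaks_pairs.tsv")),
                    write_tsv(summarize_kaks(tab),
                              file.path(out_dir, "kaks_by_gene.tsv")))
  })

  if ("tree" %in% stages && sum(have_seq) >= 3) run_stage("tree", function() {
    recs <- genomes[have_seq]
    genes <- Reduce(intersect, lapply(recs, function(r)
      r$features$name[r$features$category == "PCG"]))
    aligns <- list()
    for (g in genes) {
      seqs <- vapply(recs, function(r) extract_feature_sequence(r, g),
                     character(1))
      if (length(unique(nchar(seqs))) > 1) {
        logf("tree: gene ", g, " skipped (unequal lengths)")
        next
      }
      aligns[[g]] <- seqs
    }
    if (length(aligns) == 0) stop("no equal-length genes to concatenate")
    concat <- concatenate_pcgs(aligns)
    m <- k2p_matrix(concat$supermatrix)
    tree <- nj_tree(m)
    p1 <- file.path(out_dir, "distances_k2p.tsv")
    utils::write.table(m, p1, sep = "\t", quote = FALSE, col.names = NA)
    p2 <- file.path(out_dir, "tree_nj.nwk")
    ape::write.tree(tree, p2)
    artifacts <<- c(artifacts, p1, p2)
  })

  manifest <- list(species = species, stages = stages,
                   artifacts = basename(artifacts),
                   errors = if (length(errors)) errors else NULL)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  artifacts <- c(artifacts, file.path(out_dir, "manifest.json"))
  report_path <- write_tsv(report, file.path(out_dir, "report.tsv"))
  invisible(list(report = report, artifacts = c(artifacts, report_path),
                 out_dir = out_dir, errors = errors))
}
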