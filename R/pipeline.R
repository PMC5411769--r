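# End-to-end orchestration: overlap -> chimera filter -> repeat annotation ->
# contagion on maximal reads -> hinge-aided layout -> loop resolution ->
# consensus. Every stage drops a plain-text artifact into the output
# directory so intermediate results can be inspected and asserted on.

#' Default pipeline configuration
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of parameters (class `pipeline_config`).
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    k = 15,                    # minimizer k-mer size
    window = 5,                # minimizer window
    min_block = 1000,          # minimum alignment block (bp)
    max_divergence = 0.3,      # maximum alignment divergence
    end_tolerance = 250,       # read-end slack for match classification (bp)
    min_coverage = 3,          # chimera: minimum pile depth
    continuity_window = 200,   # chimera: continuity window (bp)
    continuity_fraction = 0.15,# chimera: fraction of piles that must continue
    min_keep = 2000,           # chimera: minimum retained read length (bp)
    gradient_window = 100,     # annotation: endpoint clustering window (bp)
    gradient_min = NA,         # annotation: endpoint count (NA = auto)
    end_exempt = 250,          # annotation: ignored margin at read ends (bp); kept equal to end_tolerance so no read falls between "annotatable" and "chainable"
    pairing_fraction = 0.9,    # bridging: confinement fraction for annotation pairs
    position_tolerance = 300,  # contagion: annotation matching tolerance (bp)
    min_size = NA,             # contagion: component size floor (NA = auto)
    hinge_tol = 300,           # layout: hinge/poison matching tolerance (bp)
    hinge_pref = 300,          # layout: hinge preference margin (bp)
    tip_clip = 3,              # layout: remove tips shorter than this
    max_plasmid_length = 500000, # resolution: loop-length gate (bp)
    max_loop_edges = 12,       # resolution: enumeration ceiling
    consensus_rounds = 3,      # polishing rounds
    threads = 1)
  ov <- list(...)
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config parameter(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  structure(cfg, class = "pipeline_config")
}

#' Write / read a flat key=value configuration file
#'
#' @param cfg A `pipeline_config`.
#' @param path File path.
#' @return `path` invisibly / the parsed `pipeline_config`.
#' @export
write_config <- function(cfg, path) {
  writeLines(sprintf("%s=%s", names(cfg),
                     vapply(cfg, function(x) format(x, scientific = FALSE), "")),
             path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- grep("=", readLines(path), fixed = TRUE, value = TRUE)
  kv <- strsplit(lines, "=", fixed = TRUE)
  vals <- lapply(kv, function(p) {
    v <- suppressWarnings(as.numeric(p[2]))
    if (is.na(v) && p[2] != "NA") p[2] else v
  })
  do.call(pipeline_config, setNames(vals, vapply(kv, `[[`, "", 1)))
}

#' Run the full assembly pipeline
#'
#' @param reads Named character vector of read sequences, or the path of a
#'   FASTA file.
#' @param out_dir Output directory for contigs, GFA and stage artifacts.
#' @param config A [pipeline_config()].
#' @param paf Optional path of a precomputed all-vs-all PAF; when given the
#'   internal overlapper is skipped.
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with the principal stage results: `records`,
#'   `reports`, `annotations`, `maximal`, `contagion`, `hinges`, `poisoned`,
#'   `layout`, `resolved`, `loops`, `paths`, `contigs`, `files`.
#' @export
run_pipeline <- function(reads, out_dir, config = pipeline_config(),
                         paf = NULL, quiet = FALSE) {
  t_all <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           " (artifacts in ", out_dir, ")", call. = FALSE)
    })
    say("[%s] done in %.1fs", name, as.numeric(Sys.time() - t0, units = "secs"))
    res
  }
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    reads <- read_fasta(reads)
  }
  if (!is.character(reads) || is.null(names(reads)) || length(reads) == 0) {
    stop("reads must be a non-empty named character vector or a FASTA path")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- config
  say("pipeline: %d reads, %.1f Mb; config: %s", length(reads),
      sum(nchar(reads)) / 1e6,
      paste(names(cfg), unlist(cfg), sep = "=", collapse = " "))

  records <- stage("overlap", {
    if (!is.null(paf)) {
      filter_records(read_paf(paf), cfg$min_block, cfg$max_divergence)
    } else {
      find_all_overlaps(reads, k = cfg$k, window = cfg$window,
                        min_block = cfg$min_block,
                        max_divergence = cfg$max_divergence,
                        threads = cfg$threads)
    }
  })
  write_paf(records, file.path(out_dir, "overlaps.paf"))
  rl <- setNames(nchar(reads), names(reads))

  trimmed <- stage("chimera-filter", {
    piles <- build_pileograms(records, rl)
    reports <- detect_chimeras(piles, rl, min_coverage = cfg$min_coverage,
                               continuity_window = cfg$continuity_window,
                               continuity_fraction = cfg$continuity_fraction,
                               min_keep = cfg$min_keep)
    data.table::fwrite(reports, file.path(out_dir, "chimera_report.tsv"),
                       sep = "\t")
    c(apply_trim(reads, reports, records, min_block = cfg$min_block),
      list(reports = reports))
  })
  reads2 <- trimmed$reads
  rl2 <- setNames(nchar(reads2), names(reads2))
  say("  %d/%d reads survive the chimera filter", length(reads2), length(reads))

  ann_all <- stage("annotate", {
    rec2 <- classify_matches(trimmed$records, cfg$end_tolerance)
    piles2 <- build_pileograms(rec2, rl2)
    # the endpoint-count threshold scales with the genome-wide coverage:
    # a per-read depth would be inflated inside collapsed repeats and
    # suppress exactly the deep-crossing annotations the hinge needs
    gm <- if (is.na(cfg$gradient_min)) {
      if (nrow(piles2) == 0) 5 else {
        per_read <- piles2[, list(d = sum(end - start) / length[1]),
                           by = "read_id"]
        max(5, ceiling(0.4 * median(per_read$d)))
      }
    } else cfg$gradient_min
    ann <- annotate_reads(piles2, rl2, gradient_min = gm,
                          window = cfg$gradient_window,
                          end_exempt = cfg$end_exempt,
                          pairing_fraction = cfg$pairing_fraction)
    data.table::fwrite(ann, file.path(out_dir, "annotations.tsv"), sep = "\t")
    list(ann = ann, rec = rec2, piles = piles2)
  })

  maximal <- stage("maximal-reads", {
    filter_contained_reads(ann_all$rec, rl2)
  })
  say("  %d maximal reads, %d annotations (%d locally bridged)",
      length(maximal), nrow(ann_all$ann), sum(ann_all$ann$bridged))

  ctg <- stage("contagion", {
    annm <- ann_all$ann[ann_all$ann$read_id %in% maximal, ]
    recm <- ann_all$rec[ann_all$rec$qname %in% maximal &
                          ann_all$rec$tname %in% maximal, ]
    med_depth <- if (nrow(ann_all$piles)) {
      # median over reads of the mean pile depth on the read
      per_read <- ann_all$piles[
        , list(d = sum(end - start) / length[1]), by = "read_id"]
      median(per_read$d)
    } else 0
    ms <- if (is.na(cfg$min_size)) max(2, ceiling(0.2 * med_depth)) else
      cfg$min_size
    res <- run_contagion(annm, recm, rl2,
                         position_tolerance = cfg$position_tolerance,
                         min_size = ms)
    data.table::fwrite(res$hinges, file.path(out_dir, "hinges.tsv"), sep = "\t")
    data.table::fwrite(res$poisoned, file.path(out_dir, "poisoned.tsv"),
                       sep = "\t")
    write_contagion_dot(res$graph, file.path(out_dir, "contagion.dot"))
    c(res, list(records = recm))
  })
  say("  %d hinges (%d in, %d out), %d poison marks",
      nrow(ctg$hinges), sum(ctg$hinges$direction == "in_hinge"),
      sum(ctg$hinges$direction == "out_hinge"), nrow(ctg$poisoned))

  lay <- stage("layout", {
    g <- build_layout_graph(rl2[maximal], ctg$records, ctg$hinges,
                            ctg$poisoned, end_tolerance = cfg$end_tolerance,
                            hinge_tol = cfg$hinge_tol,
                            hinge_pref = cfg$hinge_pref)
    if (cfg$tip_clip > 0) g <- clip_tips(g, cfg$tip_clip)
    write_layout_dot(g, file.path(out_dir, "layout.dot"))
    g
  })
  say("  layout: %d oriented nodes, %d edges", length(lay$nodes),
      nrow(lay$edges))

  resolved <- stage("resolve", {
    loops_before <- loop_report(lay, cfg$max_loop_edges)
    g <- resolve_unique_loops(lay, cfg$max_plasmid_length, cfg$max_loop_edges)
    loops_after <- loop_report(g, cfg$max_loop_edges)
    jsonlite::write_json(list(before = loops_before, after = loops_after),
                         file.path(out_dir, "loops.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    list(g = g, loops_before = loops_before, loops_after = loops_after)
  })

  cons <- stage("consensus", {
    paths <- extract_unbranched_paths(resolved$g)
    if (length(paths) == 0) {
      list(paths = paths, contigs = character(0))
    } else {
      drafts <- setNames(
        vapply(paths, build_draft, "", reads = reads2),
        sprintf("contig_%03d", seq_along(paths)))
      polished <- polish_contigs(drafts, reads2, rounds = cfg$consensus_rounds)
      list(paths = paths, contigs = polished)
    }
  })
  files <- write_outputs(resolved$g, cons$contigs, cons$paths, out_dir,
                         loop_info = resolved$loops_after)
  say("assembly complete: %d contig(s) in %.1fs", length(cons$contigs),
      as.numeric(Sys.time() - t_all, units = "secs"))
  invisible(list(records = records, reports = trimmed$reports,
                 annotations = ann_all$ann, maximal = maximal,
                 contagion = ctg$graph, hinges = ctg$hinges,
                 poisoned = ctg$poisoned, layout = lay,
                 resolved = resolved$g, loops = resolved$loops_after,
                 paths = cons$paths, contigs = cons$contigs, files = files))
}

#' Canonical repeat-motif fixtures
#'
#' Returns the genome specification and read-sampling arguments for the five
#' canonical repeat motifs: a bridged two-copy repeat (`bridged_pair`), an
#' unbridged two-copy repeat (`unbridged_pair`), an unbridged inverted
#' repeat (`inverted_pair`), an unbridged all-forward triple repeat
#' (`triple`), and a triple repeat with exactly one bridged copy
#' (`single_bridged_triple`).
#'
#' @param motif One of the motif names (`inverted_triple`, an unbridged
#'   triple repeat with one reverse-complemented copy, is available in
#'   addition to the five canonical ones).
#' @return List with `spec` (a [genome_spec()]) and `sample_args`.
#' @export
motif_zoo_spec <- function(motif = c("bridged_pair", "unbridged_pair",
                                     "inverted_pair", "triple",
                                     "single_bridged_triple",
                                     "inverted_triple")) {
  motif <- match.arg(motif)
  base_args <- list(coverage = 30, mean_length = 10000, length_sd = 500,
                    error_rate = 0.1)
  two <- function(orient2) genome_spec(
    c(90000, 90000),
    repeats = list(list(id = "R", length = 20000,
                        placements = list(list(after = 1, orient = "fwd"),
                                          list(after = 2, orient = orient2)))))
  three <- function(len, orient3 = "fwd") genome_spec(
    c(70000, 70000, 70000),
    repeats = list(list(id = "R", length = len,
                        placements = list(list(after = 1, orient = "fwd"),
                                          list(after = 2, orient = "fwd"),
                                          list(after = 3, orient = orient3)))))
  switch(motif,
    bridged_pair = list(
      # reads much longer than the repeat: every copy is bridged many times
      # over, and partners crossing one boundary usually cross the other, so
      # the local bridging test fires
      spec = two("fwd"),
      sample_args = list(coverage = 30, mean_length = 30000,
                         length_sd = 1500, error_rate = 0.1)),
    unbridged_pair = list(
      spec = two("fwd"),
      sample_args = c(base_args, list(forbid_bridge = "R"))),
    inverted_pair = list(
      spec = two("rev"),
      sample_args = c(base_args, list(forbid_bridge = "R"))),
    triple = list(
      spec = three(20000),
      sample_args = c(base_args, list(forbid_bridge = "R"))),
    single_bridged_triple = list(
      # the repeat is longer than the reads (so the entry population is
      # well spread and no read can span a copy by chance) and copy 3 is
      # bridged by one injected long read with ample flanks
      spec = three(12000),
      sample_args = c(base_args, list(
        forbid_bridge = c("R:1", "R:2"),
        force_bridge = list(list(repeat_id = "R", copy = 3,
                                 margin = 2000))))),
    inverted_triple = list(
      spec = three(20000, "rev"),
      sample_args = c(base_args, list(forbid_bridge = "R")))
  )
}

#' Generate the five canonical motif fixtures
#'
#' @param out_dir Directory; one subdirectory per motif is created.
#' @param seed Integer seed (each motif uses `seed + offset`).
#' @return Named character vector of the fixture directories.
#' @export
make_motif_zoo <- function(out_dir, seed = 1L) {
  motifs <- c("bridged_pair", "unbridged_pair", "inverted_pair", "triple",
              "single_bridged_triple")
  dirs <- character(0)
  for (i in seq_along(motifs)) {
    mz <- motif_zoo_spec(motifs[i])
    tr <- make_genome(mz$spec, seed = seed + 101L * i)
    sim <- do.call(sample_reads,
                   c(list(truth = tr, seed = seed + 101L * i + 1L),
                     mz$sample_args))
    d <- file.path(out_dir, motifs[i])
    write_fixture(sim, tr, d)
    dirs[motifs[i]] <- d
  }
  dirs
}

#' Summary statistics of an assembly output directory
#'
#' @param out_dir A [run_pipeline()] output directory.
#' @return A named list (contig count and lengths, hinge and poison counts,
#'   loop traversal counts).
#' @export
assembly_stats <- function(out_dir) {
  js <- file.path(out_dir, "summary.json")
  if (!file.exists(js)) stop("no summary.json under ", out_dir)
  summary <- jsonlite::read_json(js)
  hinges <- tryCatch(
    data.table::fread(file.path(out_dir, "hinges.tsv")),
    error = function(e) data.table::data.table(), warning = function(w) data.table::data.table())
  list(n_contigs = summary$n_contigs,
       contig_lengths = unlist(summary$lengths),
       circular = unlist(summary$circular),
       n_hinges = nrow(hinges),
       loops = summary$loops)
}
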