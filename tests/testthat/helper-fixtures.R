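# Shared fixtures, built once per test run and cached in-process. Pipelines
# at motif scale are expensive, so the structural (acceptance) tests and the
# property suites reuse the same runs.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

# Full pipeline run on one canonical repeat motif.
motif_run <- function(motif, seed = 1L, consensus_rounds = 0, ...) {
  key <- paste("motif", motif, seed, consensus_rounds)
  cached(key, {
    mz <- motif_zoo_spec(motif)
    truth <- make_genome(mz$spec, seed = seed * 101L)
    sim <- do.call(sample_reads,
                   c(list(truth = truth, seed = seed * 101L + 1L),
                     mz$sample_args))
    res <- run_pipeline(sim$reads,
                        out_dir = file.path(tempdir(), paste0(motif, "_", seed)),
                        config = pipeline_config(
                          consensus_rounds = consensus_rounds, ...),
                        quiet = TRUE)
    list(truth = truth, sim = sim, res = res)
  })
}

# The unbridged two-copy repeat genome at the scale used for the hinge-count
# checks: ~300 kb circular, one 20 kb two-copy repeat, 30x, 10 kb reads,
# 10% error.
hinge_count_run <- function(seed) {
  cached(paste("hc", seed), {
    spec <- genome_spec(c(140000, 140000),
      repeats = list(list(id = "R", length = 20000,
        placements = list(list(after = 1, orient = "fwd"),
                          list(after = 2, orient = "fwd")))))
    truth <- make_genome(spec, seed = 1000L + seed)
    sim <- sample_reads(truth, coverage = 30, mean_length = 10000,
                        length_sd = 1000, error_rate = 0.1,
                        seed = 2000L + seed, forbid_bridge = "R")
    res <- run_pipeline(sim$reads,
                        out_dir = file.path(tempdir(), paste0("hc", seed)),
                        config = pipeline_config(consensus_rounds = 0),
                        quiet = TRUE)
    list(truth = truth, sim = sim, res = res)
  })
}

# Repeat-free genome assembled end to end at 30x / 15% error.
repeat_free_run <- function(size = 50000, seed = 7L) {
  cached(paste("rf", size, seed), {
    truth <- make_genome(genome_spec(size), seed = seed)
    sim <- sample_reads(truth, coverage = 30, mean_length = 8000,
                        length_sd = 800, error_rate = 0.15, seed = seed + 1L)
    res <- run_pipeline(sim$reads,
                        out_dir = file.path(tempdir(), paste0("rf", seed)),
                        config = pipeline_config(k = 13, consensus_rounds = 3),
                        quiet = TRUE)
    list(truth = truth, sim = sim, res = res)
  })
}

# Tiny zero-error fixture for fast unit tests.
micro_run <- function(seed = 3L) {
  cached(paste("micro", seed), {
    truth <- make_genome(genome_spec(30000), seed = seed)
    sim <- sample_reads(truth, coverage = 12, mean_length = 3000,
                        length_sd = 300, error_rate = 0, seed = seed + 1L,
                        min_length = 1000)
    list(truth = truth, sim = sim)
  })
}

# Genome positions and genome-oriented directions of placed hinges.
hinge_truth <- function(res, sim, genome_len) {
  h <- merge(res$hinges, sim$origins[sim$origins$segment == 1L, ],
             by = "read_id")
  h$gpos <- ifelse(h$strand == "+", (h$start + h$pos) %% genome_len,
                   (h$start + h$length - h$pos) %% genome_len)
  h$gdir <- ifelse((h$direction == "in_hinge") == (h$strand == "+"),
                   "genome_in", "genome_out")
  h
}

# Distance from genome position to the nearest value in a set, on a circle.
circ_dist <- function(pos, targets, L) {
  vapply(pos, function(p) {
    d <- abs(outer(p, targets, "-")) %% L
    min(pmin(d, L - d))
  }, 0)
}

# Circular genome intervals of two reads overlap by at least `min_bp`.
true_overlap <- function(o1, o2, L, min_bp = 1) {
  # intervals may wrap; compare on the doubled line
  s1 <- o1$start; e1 <- s1 + o1$length
  s2 <- o2$start; e2 <- s2 + o2$length
  for (shift in c(-L, 0, L)) {
    if (min(e1, e2 + shift) - max(s1, s2 + shift) >= min_bp) return(TRUE)
  }
  FALSE
}

# Check the no-misassembly property: within every contracted segment that is
# not a collapsed-repeat candidate, consecutive reads must have genuinely
# overlapping true genome intervals.
check_no_misassembly <- function(res, sim, genome_len) {
  ct <- contract_layout(res$layout)
  loops <- vapply(find_loops(ct), `[[`, "", "seg")
  o <- sim$origins[sim$origins$segment == 1L, ]
  bad <- 0L
  for (s in setdiff(names(ct$segs), loops)) {
    chain <- ct$segs[[s]]
    if (length(chain) < 2) next
    ids <- vapply(chain, function(n)
      sub("\\.[0-9]+$", "", substr(n, 1, nchar(n) - 1L)), "")
    for (j in 2:length(ids)) {
      o1 <- o[o$read_id == ids[j - 1], ][1, ]
      o2 <- o[o$read_id == ids[j], ][1, ]
      if (!true_overlap(o1, o2, genome_len)) bad <- bad + 1L
    }
  }
  bad
}

# Percent identity of a contig against the (circular) truth sequence,
# measured by mapping against the doubled genome so any rotation aligns.
identity_to_truth <- function(contig, truth_seq) {
  ref <- setNames(paste0(truth_seq, truth_seq), "ref2x")
  mm <- map_reads(setNames(contig, "contig"), ref)
  if (nrow(mm) == 0) return(0)
  sum(mm$nmatch) / sum(mm$blen)
}

# Zero-error micro fixture assembled end to end (cached).
micro_assembly <- function(seed = 3L) {
  cached(paste("microasm", seed), {
    mr <- micro_run(seed)
    res <- run_pipeline(mr$sim$reads,
                        out_dir = file.path(tempdir(), paste0("microasm", seed)),
                        config = pipeline_config(min_block = 500),
                        quiet = TRUE)
    c(mr, list(res = res))
  })
}

# Build an idealized layout graph from a list of oriented junctions
# (c(from, to) node names); every read is 10 kb and every junction joins a
# 4 kb suffix of `from` to a 4 kb prefix of `to`, plus the strand mirror.
ideal_graph <- function(junctions) {
  lens <- setNames(rep(10000L, 0), character(0))
  rows <- list()
  rc <- function(n) paste0(substr(n, 1, nchar(n) - 1),
                           ifelse(substr(n, nchar(n), nchar(n)) == "+", "-", "+"))
  for (j in junctions) {
    for (n in j) lens[sub(".$", "", n)] <- 10000L
    rows[[length(rows) + 1L]] <- data.table::data.table(
      from = j[1], to = j[2], us = 6000L, ue = 10000L, vs = 0L, ve = 4000L,
      via_hinge = FALSE)
    rows[[length(rows) + 1L]] <- data.table::data.table(
      from = rc(j[2]), to = rc(j[1]), us = 6000L, ue = 10000L,
      vs = 0L, ve = 4000L, via_hinge = FALSE)
  }
  edges <- unique(data.table::rbindlist(rows))
  nodes <- sort(unique(c(edges$from, edges$to)))
  structure(list(nodes = nodes, edges = edges, read_lengths = lens),
            class = "layout_graph")
}
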