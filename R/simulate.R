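# Simulation of circular genomes with controlled repeat structure and of
# error-prone long reads with full ground truth. Every downstream stage of the
# assembler is exercised against these fixtures, so the generator records exact
# coordinates for every repeat copy and every read.

#' Specify a synthetic genome
#'
#' A genome is a circular arrangement of unique segments with repeat copies
#' inserted between them, plus optional plasmids. Repeat copies are placed at
#' "insertion slots": slot `i` lies after unique segment `i` (slot 0 precedes
#' the first segment). Two copies may not share a slot (they would abut and
#' form a single longer repeat).
#'
#' @param unique_lengths Integer vector of unique-segment lengths (bp), all > 0.
#' @param repeats List of repeat descriptions, each a list with elements
#'   `id` (character), `length` (bp), `placements` (list of
#'   `list(after = slot, orient = "fwd"|"rev")`), and optional
#'   `divergence` (per-copy substitution fraction in `[0, 0.05]`, default 0).
#' @param circular Logical; the chromosome is circular (default TRUE).
#' @param plasmids List of `list(length = bp, shared_repeat_id = NULL|id)`.
#'   A shared repeat id embeds one forward copy of that repeat into the
#'   plasmid backbone, so the plasmid and the chromosome share sequence.
#' @return An object of class `genome_spec`.
#' @export
genome_spec <- function(unique_lengths, repeats = list(), circular = TRUE,
                        plasmids = list()) {
  stopifnot(length(unique_lengths) >= 1, all(unique_lengths > 0))
  n_slots <- length(unique_lengths)
  used_slots <- integer(0)
  for (r in repeats) {
    stopifnot(is.character(r$id), r$length > 0)
    div <- r$divergence %||% 0
    if (div < 0 || div > 0.05) stop("repeat divergence must lie in [0, 0.05]")
    for (p in r$placements) {
      if (!p$after %in% 0:n_slots) {
        stop("placement slot ", p$after, " outside 0..", n_slots)
      }
      if (p$after %in% used_slots) {
        stop("overlapping repeat placements: slot ", p$after, " used twice")
      }
      used_slots <- c(used_slots, p$after)
      stopifnot(p$orient %in% c("fwd", "rev"))
    }
  }
  for (p in plasmids) {
    stopifnot(p$length > 0)
    if (!is.null(p$shared_repeat_id) &&
        !p$shared_repeat_id %in% vapply(repeats, `[[`, "", "id")) {
      stop("plasmid references unknown repeat id: ", p$shared_repeat_id)
    }
  }
  structure(list(unique_lengths = as.integer(unique_lengths),
                 repeats = repeats, circular = isTRUE(circular),
                 plasmids = plasmids),
            class = "genome_spec")
}

#' Generate a genome with ground truth from a specification
#'
#' @param spec A [genome_spec()].
#' @param seed Integer seed; identical `(spec, seed)` gives identical output.
#' @return An object of class `genome_truth`: a list with `seqs` (named
#'   character vector of replicon sequences; the chromosome is named
#'   `"chromosome"`, plasmids `"plasmid_1"`, ...), `repeat_copies` (a
#'   data.table with columns `repeat_id`, `replicon`, `start`, `end`,
#'   `orient`; 0-based half-open coordinates on the replicon's forward
#'   strand), `circular` (named logical per replicon), and `spec`.
#' @export
make_genome <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "genome_spec"))
  local_seed(seed)

  rep_ids <- vapply(spec$repeats, `[[`, "", "id")
  rep_base <- setNames(
    lapply(spec$repeats, function(r) random_dna(r$length)), rep_ids)

  n_seg <- length(spec$unique_lengths)
  segs <- lapply(spec$unique_lengths, random_dna)

  pieces <- character(0)
  copies <- list()
  pos <- 0L
  emit_copy <- function(r, p, replicon, pos) {
    seqr <- rep_base[[r$id]]
    div <- r$divergence %||% 0
    if (div > 0) seqr <- substitute_bases(seqr, div)
    if (p$orient == "rev") seqr <- revcomp(seqr)
    list(seq = seqr,
         row = data.table::data.table(repeat_id = r$id, replicon = replicon,
                                      start = pos, end = pos + nchar(seqr),
                                      orient = p$orient))
  }
  for (slot in 0:n_seg) {
    if (slot > 0) {
      pieces <- c(pieces, segs[[slot]])
      pos <- pos + nchar(segs[[slot]])
    }
    for (r in spec$repeats) {
      for (p in r$placements) {
        if (p$after == slot) {
          ec <- emit_copy(r, p, "chromosome", pos)
          pieces <- c(pieces, ec$seq)
          copies <- c(copies, list(ec$row))
          pos <- pos + nchar(ec$seq)
        }
      }
    }
  }
  seqs <- c(chromosome = paste(pieces, collapse = ""))
  circ <- c(chromosome = spec$circular)

  for (i in seq_along(spec$plasmids)) {
    p <- spec$plasmids[[i]]
    nm <- paste0("plasmid_", i)
    backbone <- random_dna(p$length)
    if (is.null(p$shared_repeat_id)) {
      seqs[nm] <- backbone
    } else {
      half <- nchar(backbone) %/% 2L
      rseq <- rep_base[[p$shared_repeat_id]]
      seqs[nm] <- paste0(substr(backbone, 1, half), rseq,
                         substr(backbone, half + 1, nchar(backbone)))
      copies <- c(copies, list(data.table::data.table(
        repeat_id = p$shared_repeat_id, replicon = nm,
        start = half, end = half + nchar(rseq), orient = "fwd")))
    }
    circ[nm] <- TRUE
  }

  repeat_copies <- if (length(copies)) data.table::rbindlist(copies) else
    data.table::data.table(repeat_id = character(), replicon = character(),
                           start = integer(), end = integer(),
                           orient = character())
  structure(list(seqs = seqs, repeat_copies = repeat_copies,
                 circular = circ, spec = spec),
            class = "genome_truth")
}

# Substitute a deterministic count of bases (floor(rate * length)), so the
# realized divergence never exceeds the requested one.
substitute_bases <- function(seq, rate) {
  n <- nchar(seq)
  k <- floor(rate * n)
  if (k == 0) return(seq)
  idx <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  chars[idx] <- vapply(chars[idx],
                       function(b) sample(setdiff(DNA_BASES, b), 1), "")
  paste(chars, collapse = "")
}

#' Sample error-prone long reads from a genome
#'
#' Read start positions are uniform on each (circular) replicon and wrap the
#' origin; strands are uniform; lengths follow a truncated normal with a hard
#' floor. Errors are i.i.d. substitutions, insertions and deletions in equal
#' proportion (each at `error_rate / 3`). Chimeric reads concatenate two
#' independently drawn segments.
#'
#' @param truth A [make_genome()] result.
#' @param coverage Fold coverage per replicon (> 0).
#' @param mean_length,length_sd Read length distribution (bp).
#' @param error_rate Total per-base error fraction in `[0, 0.2]`.
#' @param chimera_rate Fraction of reads that are chimeric.
#' @param seed Integer seed.
#' @param min_length Hard floor on read length (bp).
#' @param forbid_bridge Character vector of repeat ids; no sampled read may
#'   fully contain any copy of these repeats (reads are re-drawn, or
#'   truncated as a last resort), guaranteeing the repeat stays unbridged.
#' @param force_bridge List of `list(repeat_id =, copy =, margin =)`; for each
#'   entry one extra read is emitted that spans the given copy (copies are
#'   numbered by genomic start within a repeat id) plus `margin` bp of flank
#'   on each side, guaranteeing the copy is bridged.
#' @return An object of class `sim_reads`: list with `reads` (named character
#'   vector) and `origins` (data.table, one row per true segment: `read_id`,
#'   `segment`, `replicon`, `start`, `length`, `strand`, `junction`,
#'   `read_length`, `is_chimeric`). `start`/`length` are 0-based on the
#'   replicon forward strand; `junction` is the 0-based position on the final
#'   read where segment 2 begins (NA for non-chimeric reads).
#' @export
sample_reads <- function(truth, coverage = 30, mean_length = 10000,
                         length_sd = 1000, error_rate = 0.1,
                         chimera_rate = 0, seed = 1L, min_length = 1000,
                         forbid_bridge = NULL, force_bridge = NULL) {
  stopifnot(inherits(truth, "genome_truth"), coverage > 0)
  if (error_rate < 0 || error_rate > 0.2) stop("error_rate must lie in [0, 0.2]")
  if (any(mean_length > nchar(truth$seqs))) {
    stop("mean_length (", mean_length, ") exceeds a replicon length")
  }
  local_seed(seed)

  # forbid_bridge entries are either a repeat id ("R": all copies) or a
  # specific copy "R:2" (copies numbered by genomic start within the id)
  forbid <- local({
    rc <- truth$repeat_copies
    if (is.null(forbid_bridge) || nrow(rc) == 0) return(rc[0, ])
    rc <- rc[order(rc$repeat_id, rc$start), ]
    rc[, "copy" := seq_len(.N), by = "repeat_id"]
    keys <- paste0(rc$repeat_id, ":", rc$copy)
    rc[rc$repeat_id %in% forbid_bridge | keys %in% forbid_bridge, ]
  })
  margin <- 0L  # reject reads that contain a forbidden copy exactly

  reads <- character(0)
  rows <- list()
  idx <- 0L

  draw_segment <- function(replicon, len) {
    L <- nchar(truth$seqs[[replicon]])
    len <- min(len, L)
    for (try in 1:200) {
      s <- sample.int(L, 1L) - 1L
      ok <- TRUE
      fb <- forbid[forbid$replicon == replicon, ]
      if (nrow(fb)) {
        span <- (fb$end - fb$start) + 2L * margin
        off <- ((fb$start - margin - s) %% L + L) %% L
        if (any(off + span <= len)) ok <- FALSE
      }
      if (ok) return(list(start = s, len = len))
    }
    # fall back: truncate below the smallest forbidden span
    list(start = s, len = min(len, min(span) - 1L))
  }

  for (replicon in names(truth$seqs)) {
    L <- nchar(truth$seqs[[replicon]])
    n <- max(1L, round(coverage * L / mean_length))
    lens <- pmin(L, pmax(min_length, round(rnorm(n, mean_length, length_sd))))
    for (i in seq_len(n)) {
      idx <- idx + 1L
      rid <- sprintf("read_%05d", idx)
      chim <- runif(1) < chimera_rate
      if (!chim) {
        sg <- draw_segment(replicon, lens[i])
        strand <- sample(c("+", "-"), 1)
        raw <- circ_substr(truth$seqs[[replicon]], sg$start, sg$len,
                           truth$circular[[replicon]])
        if (strand == "-") raw <- revcomp(raw)
        seq <- mutate_read(raw, error_rate)
        reads[rid] <- seq
        rows[[length(rows) + 1L]] <- data.table::data.table(
          read_id = rid, segment = 1L, replicon = replicon,
          start = sg$start, length = sg$len, strand = strand,
          junction = NA_integer_, read_length = nchar(seq),
          is_chimeric = FALSE)
      } else {
        u <- runif(1, 0.3, 0.7)
        l1 <- max(200L, round(lens[i] * u)); l2 <- max(200L, lens[i] - l1)
        sg1 <- draw_segment(replicon, l1); sg2 <- draw_segment(replicon, l2)
        st1 <- sample(c("+", "-"), 1); st2 <- sample(c("+", "-"), 1)
        raw1 <- circ_substr(truth$seqs[[replicon]], sg1$start, sg1$len,
                            truth$circular[[replicon]])
        raw2 <- circ_substr(truth$seqs[[replicon]], sg2$start, sg2$len,
                            truth$circular[[replicon]])
        if (st1 == "-") raw1 <- revcomp(raw1)
        if (st2 == "-") raw2 <- revcomp(raw2)
        p1 <- mutate_read(raw1, error_rate); p2 <- mutate_read(raw2, error_rate)
        seq <- paste0(p1, p2)
        reads[rid] <- seq
        rows[[length(rows) + 1L]] <- data.table::data.table(
          read_id = rid, segment = 1:2, replicon = replicon,
          start = c(sg1$start, sg2$start), length = c(sg1$len, sg2$len),
          strand = c(st1, st2), junction = c(NA_integer_, nchar(p1)),
          read_length = nchar(seq), is_chimeric = TRUE)
      }
    }
  }

  for (fb in force_bridge %||% list()) {
    cp <- truth$repeat_copies[truth$repeat_copies$repeat_id == fb$repeat_id, ]
    cp <- cp[order(cp$start), ][fb$copy, ]
    if (nrow(cp) != 1 || is.na(cp$start)) {
      stop("force_bridge: no copy ", fb$copy, " of repeat ", fb$repeat_id)
    }
    m <- as.integer(fb$margin %||% 2000L)
    L <- nchar(truth$seqs[[cp$replicon]])
    s <- ((cp$start - m) %% L + L) %% L
    len <- min(L, (cp$end - cp$start) + 2L * m)
    idx <- idx + 1L
    rid <- sprintf("bridge_%s_%d", fb$repeat_id, fb$copy)
    raw <- circ_substr(truth$seqs[[cp$replicon]], s, len,
                       truth$circular[[cp$replicon]])
    seq <- mutate_read(raw, error_rate)
    reads[rid] <- seq
    rows[[length(rows) + 1L]] <- data.table::data.table(
      read_id = rid, segment = 1L, replicon = cp$replicon,
      start = s, length = len, strand = "+", junction = NA_integer_,
      read_length = nchar(seq), is_chimeric = FALSE)
  }

  origins <- data.table::rbindlist(rows)
  structure(list(reads = reads, origins = origins), class = "sim_reads")
}

# Apply i.i.d. substitution/insertion/deletion errors (1:1:1) to one sequence.
mutate_read <- function(seq, rate) {
  if (rate == 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  u <- runif(n)
  third <- rate / 3
  sub_i <- which(u < third)
  del_i <- which(u >= third & u < 2 * third)
  ins_i <- which(u >= 2 * third & u < rate)
  if (length(sub_i)) {
    chars[sub_i] <- DNA_BASES[
      (match(chars[sub_i], DNA_BASES) - 1L + sample.int(3, length(sub_i), replace = TRUE)) %% 4L + 1L]
  }
  if (length(ins_i)) {
    chars[ins_i] <- paste0(chars[ins_i],
                           sample(DNA_BASES, length(ins_i), replace = TRUE))
  }
  if (length(del_i)) chars[del_i] <- ""
  paste(chars, collapse = "")
}

#' Write a simulated read set and its ground truth to disk
#'
#' Emits `reads.fasta`, `origins.tsv`, `repeat_copies.tsv`, `replicons.tsv`
#' and `genome.fasta` under `out_dir`. The tables round-trip losslessly
#' through [read_fixture()].
#'
#' @param sim A [sample_reads()] result.
#' @param truth The matching [make_genome()] result.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(sim, truth, out_dir) {
  stopifnot(inherits(sim, "sim_reads"), inherits(truth, "genome_truth"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wr <- function(x, f) {
    path <- file.path(out_dir, f)
    tryCatch(data.table::fwrite(x, path, sep = "\t"),
             error = function(e) stop("writing ", path, ": ", conditionMessage(e)))
  }
  write_fasta(sim$reads, file.path(out_dir, "reads.fasta"))
  write_fasta(truth$seqs, file.path(out_dir, "genome.fasta"))
  wr(sim$origins, "origins.tsv")
  wr(truth$repeat_copies, "repeat_copies.tsv")
  wr(data.table::data.table(replicon = names(truth$seqs),
                            length = nchar(truth$seqs),
                            circular = truth$circular[names(truth$seqs)]),
     "replicons.tsv")
  invisible(out_dir)
}

#' Read back a fixture written by [write_fixture()]
#'
#' @param dir Fixture directory.
#' @return List with `reads`, `origins`, `repeat_copies`, `replicons`, `seqs`.
#' @export
read_fixture <- function(dir) {
  rd <- function(f, ...) data.table::fread(file.path(dir, f), sep = "\t", ...)
  list(reads = read_fasta(file.path(dir, "reads.fasta")),
       seqs = read_fasta(file.path(dir, "genome.fasta")),
       origins = rd("origins.tsv",
                    colClasses = list(integer = "junction")),
       repeat_copies = rd("repeat_copies.tsv"),
       replicons = rd("replicons.tsv"))
}

# Seed the RNG for the duration of the calling function, restoring the
# caller's RNG state on exit.
local_seed <- function(seed, env = parent.frame()) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  expr <- if (is.null(old)) {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = env)
  set.seed(as.integer(seed))
  invisible(NULL)
}
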