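# Pairwise alignment records. One record is a PAF-style match between two
# reads: query coordinates on the query's forward strand, target coordinates
# on the target's forward strand, strand "+" (same) or "-" (opposite).

PAF_COLS <- c("qname", "qlen", "qstart", "qend", "strand",
              "tname", "tlen", "tstart", "tend", "nmatch", "blen", "mapq")

MATCH_CLASSES <- c("suffix_prefix_overlap", "prefix_suffix_overlap",
                   "a_contained_in_b", "b_contained_in_a", "internal_match")

empty_records <- function() {
  data.table::data.table(qname = character(), qlen = integer(),
                         qstart = integer(), qend = integer(),
                         strand = character(), tname = character(),
                         tlen = integer(), tstart = integer(),
                         tend = integer(), nmatch = integer(),
                         blen = integer(), mapq = integer(),
                         cg = character(), dv = numeric())
}

#' Read pairwise alignments from a PAF file
#'
#' Parses the 12 mandatory PAF columns and, when present, the `cg:Z:` CIGAR
#' tag. Strand `"+"` means the match is on the same strand, `"-"` opposite.
#'
#' @param path PAF file path.
#' @return A data.table of alignment records with columns
#'   `qname, qlen, qstart, qend, strand, tname, tlen, tstart, tend, nmatch,
#'   blen, mapq, cg`.
#' @export
read_paf <- function(path) {
  if (!file.exists(path)) stop("PAF not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_records())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12)) {
    stop("malformed PAF line ", which(nf < 12)[1], " in ", path,
         ": expected >= 12 fields, got ", nf[which(nf < 12)[1]])
  }
  f <- function(i) vapply(parts, `[[`, "", i)
  ints <- function(i) {
    v <- suppressWarnings(as.integer(f(i)))
    if (anyNA(v)) stop("malformed PAF line ", which(is.na(v))[1], " in ",
                       path, ": non-integer field ", i)
    v
  }
  cg <- vapply(parts, function(p) {
    hit <- grep("^cg:Z:", p, value = TRUE)
    if (length(hit)) sub("^cg:Z:", "", hit[1]) else NA_character_
  }, "")
  dv <- vapply(parts, function(p) {
    hit <- grep("^(dv|de):f:", p, value = TRUE)
    if (length(hit)) as.numeric(sub("^..:f:", "", hit[1])) else NA_real_
  }, 0)
  st <- f(5)
  if (!all(st %in% c("+", "-"))) {
    stop("malformed PAF line ", which(!st %in% c("+", "-"))[1],
         " in ", path, ": bad strand")
  }
  data.table::data.table(
    qname = f(1), qlen = ints(2), qstart = ints(3), qend = ints(4),
    strand = st, tname = f(6), tlen = ints(7), tstart = ints(8),
    tend = ints(9), nmatch = ints(10), blen = ints(11), mapq = ints(12),
    cg = cg, dv = dv)
}

#' Write alignment records to a PAF file
#'
#' @param records Alignment records as produced by [read_paf()] or
#'   [find_all_overlaps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_paf <- function(records, path) {
  rec <- data.table::as.data.table(records)
  body <- rec[, PAF_COLS, with = FALSE]
  lines <- do.call(paste, c(as.list(body), sep = "\t"))
  if ("dv" %in% names(rec)) {
    has <- !is.na(rec$dv)
    lines[has] <- paste0(lines[has], "\tdv:f:", formatC(rec$dv[has], format = "g"))
  }
  if ("cg" %in% names(rec)) {
    has <- !is.na(rec$cg)
    lines[has] <- paste0(lines[has], "\tcg:Z:", rec$cg[has])
  }
  writeLines(lines, path)
  invisible(path)
}

#' Mirror alignment records
#'
#' Swaps the roles of query and target; the strand and (forward-strand)
#' coordinates are unchanged. The mirrored record describes the same match.
#'
#' @param records Alignment records.
#' @return The mirrored records.
#' @export
mirror_records <- function(records) {
  rec <- data.table::as.data.table(records)
  out <- data.table::copy(rec)
  data.table::setnames(out,
    c("qname", "qlen", "qstart", "qend", "tname", "tlen", "tstart", "tend"),
    c("tname", "tlen", "tstart", "tend", "qname", "qlen", "qstart", "qend"))
  data.table::setcolorder(out, names(rec))
  if ("cg" %in% names(out)) out[, "cg" := NA_character_]
  out
}

#' Compute all-vs-all overlaps between reads
#'
#' Runs minimap2 in all-vs-all mode (minimizer seeding and chaining) and
#' filters the resulting matches. Self-matches are removed; each match is
#' returned once, canonicalized so that `qname < tname`; the mirrored record
#' is derivable with [mirror_records()].
#'
#' @param reads Named character vector of read sequences.
#' @param k Minimizer k-mer size (>= 11).
#' @param window Minimizer window size.
#' @param min_block Minimum match block length (bp) to keep.
#' @param max_divergence Maximum `1 - nmatch/blen` to keep.
#' @param threads minimap2 thread count.
#' @return Alignment records (data.table), possibly empty.
#' @export
find_all_overlaps <- function(reads, k = 15, window = 5, min_block = 1000,
                              max_divergence = 0.3, threads = 1) {
  stopifnot(length(reads) > 0, k >= 11)
  fa <- tempfile(fileext = ".fasta")
  on.exit(unlink(fa), add = TRUE)
  write_fasta(reads, fa)
  paf <- tempfile(fileext = ".paf")
  on.exit(unlink(paf), add = TRUE)
  args <- c("-x", "ava-ont", "-c", "--eqx", "-k", k, "-w", window,
            "-t", threads, "-m", max(100, min_block %/% 10), fa, fa)
  status <- system2(minimap2_path(), args, stdout = paf, stderr = FALSE)
  if (status != 0) stop("minimap2 all-vs-all failed with status ", status)
  rec <- read_paf(paf)
  filter_records(rec, min_block, max_divergence)
}

# Canonicalize (qname < tname), drop self matches, apply block/divergence
# filters and collapse duplicate reportings of the same match.
filter_records <- function(rec, min_block, max_divergence) {
  # minimap2 reports an estimated divergence tag; fall back to the gap-
  # compressed identity from columns 10/11 (only meaningful with -c)
  div <- ifelse(is.na(rec$dv), 1 - rec$nmatch / rec$blen, rec$dv)
  rec <- rec[rec$qname != rec$tname &
             rec$blen >= min_block &
             div <= max_divergence, ]
  if (nrow(rec) == 0) return(empty_records())
  swap <- rec$qname > rec$tname
  if (any(swap)) {
    rec <- data.table::rbindlist(list(rec[!swap], mirror_records(rec[swap])),
                                 use.names = TRUE)
  }
  # two reportings of the same pair/strand whose query intervals overlap are
  # the same match seen from both sides; keep the larger block
  rec <- rec[order(rec$qname, rec$tname, rec$strand, -rec$blen)]
  keep <- rep(TRUE, nrow(rec))
  grp <- paste(rec$qname, rec$tname, rec$strand)
  dup <- duplicated(grp)
  if (any(dup)) {
    for (g in unique(grp[dup])) {
      i <- which(grp == g)
      chosen <- integer(0)
      for (j in i) {
        ov <- FALSE
        for (ch in chosen) {
          if (rec$qstart[j] < rec$qend[ch] && rec$qend[j] > rec$qstart[ch] &&
              rec$tstart[j] < rec$tend[ch] && rec$tend[j] > rec$tstart[ch]) {
            ov <- TRUE; break
          }
        }
        if (ov) keep[j] <- FALSE else chosen <- c(chosen, j)
      }
    }
  }
  rec[keep]
}

#' Classify pairwise matches
#'
#' A match is a proper overlap when it joins the suffix of one read to the
#' prefix of the other (after orienting the target by strand), a containment
#' when it spans one read's whole length within `end_tolerance`, and an
#' internal match otherwise. Mutual (near-equal) containments break to
#' `a_contained_in_b` for the lexicographically smaller query id.
#'
#' @param records Alignment records.
#' @param end_tolerance Slack (bp) at read ends.
#' @return The records with an added `class` column (one of
#'   `r paste(MATCH_CLASSES, collapse = ", ")`).
#' @export
classify_matches <- function(records, end_tolerance = 100) {
  stopifnot(end_tolerance >= 0)
  rec <- data.table::as.data.table(records)
  if (nrow(rec) == 0) { rec[, "class" := character()]; return(rec) }
  with(rec, {
    if (any(qstart < 0 | qend > qlen | tstart < 0 | tend > tlen |
            qstart >= qend | tstart >= tend)) {
      stop("alignment coordinates outside read bounds")
    }
  })
  tol <- end_tolerance
  ts2 <- ifelse(rec$strand == "+", rec$tstart, rec$tlen - rec$tend)
  te2 <- ifelse(rec$strand == "+", rec$tend, rec$tlen - rec$tstart)
  a_full <- rec$qstart <= tol & rec$qend >= rec$qlen - tol
  b_full <- ts2 <= tol & te2 >= rec$tlen - tol
  cls <- rep("internal_match", nrow(rec))
  sp <- rec$qend >= rec$qlen - tol & ts2 <= tol
  ps <- rec$qstart <= tol & te2 >= rec$tlen - tol
  cls[sp] <- "suffix_prefix_overlap"
  cls[ps] <- "prefix_suffix_overlap"
  cls[a_full & !b_full] <- "a_contained_in_b"
  cls[b_full & !a_full] <- "b_contained_in_a"
  both <- a_full & b_full
  cls[both] <- ifelse(rec$qname[both] <= rec$tname[both],
                      "a_contained_in_b", "b_contained_in_a")
  rec[, "class" := cls]
  rec
}

#' Map reads onto reference sequences
#'
#' Mapping-mode wrapper (reads vs. draft contigs) returning base-level CIGAR
#' strings in the `cg` column; used by the consensus stage and by identity
#' checks.
#'
#' @param query Named character vector of query sequences.
#' @param target Named character vector of target sequences.
#' @param preset minimap2 preset (default `"map-ont"`).
#' @param threads Thread count.
#' @return Alignment records with CIGARs (query = reads, target = reference).
#' @export
map_reads <- function(query, target, preset = "map-ont", threads = 1) {
  qf <- tempfile(fileext = ".fasta"); tf <- tempfile(fileext = ".fasta")
  paf <- tempfile(fileext = ".paf")
  on.exit(unlink(c(qf, tf, paf)), add = TRUE)
  write_fasta(query, qf)
  write_fasta(target, tf)
  status <- system2(minimap2_path(),
                    c("-x", preset, "-c", "--eqx", "-t", threads, tf, qf),
                    stdout = paf, stderr = FALSE)
  if (status != 0) stop("minimap2 mapping failed with status ", status)
  read_paf(paf)
}
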