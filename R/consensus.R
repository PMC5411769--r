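# Consensus: draft contigs are concatenations of read segments along
# unbranched paths of the (resolved) layout graph; the draft is then polished
# by per-column majority vote over the alignments of all original reads onto
# it. Insertions relative to the draft are applied when a majority of the
# covering reads supports one; deletions win a column like any other symbol.

#' Extract unbranched paths (contigs-to-be) from a layout graph
#'
#' Maximal unbranched paths and full cycles are returned once per
#' strand-overlaid pair. For every node the interval of the read actually
#' used in the contig is recorded: the full read for the first node, and the
#' unduplicated tail `[ve, len)` for every subsequent node (for circular
#' paths the closing edge trims the first node's head as well).
#'
#' @param g A `layout_graph` (typically after [resolve_unique_loops()]).
#' @return List of `contig_path` objects: `nodes`, `used` (data.table
#'   `node, start, end`), `circular`.
#' @export
extract_unbranched_paths <- function(g) {
  if (length(g$nodes) == 0) return(list())
  ct <- contract_layout(g)
  lens <- g$read_lengths
  out <- list()
  for (s in names(ct$segs)) {
    rc <- ct$seg_rc[[s]]
    if (!is.na(rc) && rc < s) next  # keep one strand representative
    chain <- ct$segs[[s]]
    touching <- ct$edges[ct$edges$from == s | ct$edges$to == s, ]
    self_edge <- touching[touching$from == s & touching$to == s, ]
    circular <- nrow(self_edge) > 0 && nrow(touching) == nrow(self_edge)
    used <- data.table::data.table(
      node = chain, start = 0L,
      end = vapply(chain, function(n) lens[[onode_read(n)]], 0L))
    if (length(chain) > 1) {
      e <- g$edges
      for (j in 2:length(chain)) {
        row <- e[e$from == chain[j - 1] & e$to == chain[j], ][1, ]
        used$start[j] <- row$ve
      }
    }
    if (circular) used$start[1] <- g$edges[self_edge$eidx[1], ]$ve
    out[[length(out) + 1L]] <- structure(
      list(nodes = chain, used = used, circular = circular),
      class = "contig_path")
  }
  out
}

#' Build the draft sequence of one contig path
#'
#' Concatenates the used interval of every node, reverse-complementing
#' reverse-oriented reads.
#'
#' @param path A `contig_path`.
#' @param reads Named character vector of read sequences.
#' @return Character scalar (the draft sequence).
#' @export
build_draft <- function(path, reads) {
  pieces <- vapply(seq_len(nrow(path$used)), function(i) {
    n <- path$used$node[i]
    seq <- reads[[onode_read(n)]]
    if (is.null(seq)) stop("read ", onode_read(n), " missing for contig node ", n)
    if (onode_orient(n) == "-") seq <- revcomp(seq)
    s <- path$used$start[i]; e <- path$used$end[i]
    if (s < 0 || e > nchar(seq) || s >= e) {
      stop("inconsistent junction coordinates on node ", n,
           " [", s, ", ", e, ") of read length ", nchar(seq))
    }
    substr(seq, s + 1L, e)
  }, "")
  paste(pieces, collapse = "")
}

# Parse one CIGAR string into op letters and lengths.
parse_cigar <- function(cg) {
  m <- gregexpr("[0-9]+[MIDNSHP=X]", cg)[[1]]
  toks <- regmatches(cg, list(m))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", toks))
  op <- sub("^[0-9]+", "", toks)
  list(n = n, op = op)
}

# Accumulate votes of one alignment record against its target contig.
# Returns list(pos = 0-based target positions, base = codes 1..5 (ACGT-),
# ins_pos, ins_seq).
alignment_votes <- function(rec_row, qseq) {
  cg <- rec_row$cg
  if (is.na(cg)) return(NULL)
  if (rec_row$strand == "-") {
    qseq <- revcomp(qseq)
    qpos <- rec_row$qlen - rec_row$qend
  } else {
    qpos <- rec_row$qstart
  }
  ci <- parse_cigar(cg)
  qadv <- ifelse(ci$op %in% c("M", "=", "X", "I"), ci$n, 0L)
  tadv <- ifelse(ci$op %in% c("M", "=", "X", "D"), ci$n, 0L)
  qoff <- qpos + c(0L, cumsum(qadv))[seq_along(ci$n)]
  toff <- rec_row$tstart + c(0L, cumsum(tadv))[seq_along(ci$n)]

  qchars <- strsplit(qseq, "", fixed = TRUE)[[1]]
  is_m <- ci$op %in% c("M", "=", "X")
  pos <- base <- integer(0)
  if (any(is_m)) {
    nm <- ci$n[is_m]
    pos <- sequence(nm, from = toff[is_m])
    qidx <- sequence(nm, from = qoff[is_m] + 1L)
    base <- match(qchars[qidx], DNA_BASES)
    keep <- !is.na(base)  # skip ambiguous bases
    pos <- pos[keep]; base <- base[keep]
  }
  is_d <- ci$op == "D"
  if (any(is_d)) {
    nd <- ci$n[is_d]
    pos <- c(pos, sequence(nd, from = toff[is_d]))
    base <- c(base, rep(5L, sum(nd)))
  }
  ins_pos <- integer(0); ins_seq <- character(0)
  is_i <- which(ci$op == "I")
  if (length(is_i)) {
    ins_pos <- toff[is_i]
    ins_seq <- vapply(is_i, function(k)
      paste(qchars[(qoff[k] + 1L):(qoff[k] + ci$n[k])], collapse = ""), "")
  }
  list(pos = pos, base = base, ins_pos = ins_pos, ins_seq = ins_seq)
}

#' Majority-vote polish of a draft sequence
#'
#' Per draft column the majority symbol among the aligned read bases (A, C,
#' G, T or deletion) is emitted, with ties broken in the fixed order
#' A < C < G < T < deletion. An insertion is applied between two columns when
#' more than half of the reads covering the junction vote for one, taking
#' the modal inserted sequence. Columns covered by no read keep the draft
#' base (with a warning).
#'
#' @param draft Character scalar (draft contig sequence).
#' @param reads Named character vector of the original reads.
#' @param realignments Alignment records of `reads` against the draft
#'   (`tname == contig`); when NULL they are computed with [map_reads()].
#' @param contig_name Name used for the draft when realigning.
#' @return Polished sequence (character scalar).
#' @export
majority_consensus <- function(draft, reads, realignments = NULL,
                               contig_name = "contig") {
  if (is.null(realignments)) {
    realignments <- map_reads(reads, setNames(draft, contig_name))
  }
  rec <- data.table::as.data.table(realignments)
  rec <- rec[rec$tname == contig_name & !is.na(rec$cg), ]
  L <- nchar(draft)
  if (nrow(rec) == 0 || L == 0) return(draft)

  votes <- lapply(seq_len(nrow(rec)), function(i) {
    alignment_votes(rec[i, ], reads[[rec$qname[i]]])
  })
  pos <- unlist(lapply(votes, `[[`, "pos"))
  base <- unlist(lapply(votes, `[[`, "base"))
  counts <- matrix(tabulate(pos * 5L + base, nbins = 5L * L), nrow = 5L)
  depth <- colSums(counts)
  winner <- max.col(t(counts), ties.method = "first")
  draft_chars <- strsplit(draft, "", fixed = TRUE)[[1]]
  out <- ifelse(winner == 5L, "", DNA_BASES[pmin(winner, 4L)])
  uncovered <- depth == 0L
  if (any(uncovered)) {
    out[uncovered] <- draft_chars[uncovered]
    warning(sum(uncovered), " draft column(s) with zero coverage retained as-is")
  }

  ins_pos <- unlist(lapply(votes, `[[`, "ins_pos"))
  ins_seq <- unlist(lapply(votes, `[[`, "ins_seq"))
  if (length(ins_pos)) {
    dt <- data.table::data.table(pos = ins_pos, seq = ins_seq)
    byp <- dt[, list(n = .N,
                     modal = names(sort(table(seq), decreasing = TRUE))[1]),
              by = "pos"]
    span_depth <- depth[pmin(pmax(byp$pos, 1L), L)]
    # alignment jitter spreads the votes for one true insertion over a
    # couple of adjacent columns, so the per-column threshold sits below a
    # strict majority (spurious insertion votes run near error_rate/3)
    apply_ins <- byp[byp$n > 0.4 * span_depth & byp$pos >= 1L & byp$pos <= L, ]
    if (nrow(apply_ins)) {
      out[apply_ins$pos] <- paste0(out[apply_ins$pos], apply_ins$modal)
    }
  }
  paste(out, collapse = "")
}

#' Polish all contigs of an assembly
#'
#' @param drafts Named character vector of draft contigs.
#' @param reads Named character vector of original reads.
#' @param rounds Number of map-and-vote rounds.
#' @return Named character vector of polished contigs.
#' @export
polish_contigs <- function(drafts, reads, rounds = 2) {
  for (r in seq_len(rounds)) {
    aln <- map_reads(reads, drafts)
    drafts <- vapply(names(drafts), function(nm) {
      majority_consensus(drafts[[nm]], reads,
                         realignments = aln[aln$tname == nm, ],
                         contig_name = nm)
    }, "")
  }
  drafts
}

#' Write assembly outputs: GFA, FASTA and a JSON summary
#'
#' The GFA 1.0 file carries one S-line per contig (polished sequence) and
#' L-lines mirroring the contracted layout graph, including the closing
#' L-line of circular contigs.
#'
#' @param g The final `layout_graph`.
#' @param contigs Named character vector of polished contig sequences.
#' @param paths The `contig_path` list the contigs were built from.
#' @param out_dir Output directory.
#' @param loop_info Optional [loop_report()] result for the JSON summary.
#' @return Invisibly, the paths of the files written.
#' @export
write_outputs <- function(g, contigs, paths, out_dir, loop_info = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  gfa <- file.path(out_dir, "assembly.gfa")
  fa <- file.path(out_dir, "contigs.fasta")
  js <- file.path(out_dir, "summary.json")

  ct <- contract_layout(g)
  # map every oriented segment to (contig name, orientation)
  seg_contig <- list()
  for (i in seq_along(paths)) {
    nm <- names(contigs)[i]
    s <- ct$node2seg[[paths[[i]]$nodes[1]]]
    seg_contig[[s]] <- c(nm, "+")
    rc <- ct$seg_rc[[s]]
    if (!is.na(rc) && is.null(seg_contig[[rc]])) seg_contig[[rc]] <- c(nm, "-")
  }
  lines <- c("H\tVN:Z:1.0",
             sprintf("S\t%s\t%s", names(contigs), contigs))
  ed <- ct$edges
  seen <- character(0)
  for (i in seq_len(nrow(ed))) {
    a <- seg_contig[[ed$from[i]]]; b <- seg_contig[[ed$to[i]]]
    if (is.null(a) || is.null(b)) next
    fwd_key <- paste(a[1], a[2], b[1], b[2])
    rco <- function(o) if (o == "+") "-" else "+"
    rev_key <- paste(b[1], rco(b[2]), a[1], rco(a[2]))
    if (fwd_key %in% seen || rev_key %in% seen) next
    seen <- c(seen, fwd_key)
    lines <- c(lines, sprintf("L\t%s\t%s\t%s\t%s\t0M",
                              a[1], a[2], b[1], b[2]))
  }
  tryCatch(writeLines(lines, gfa),
           error = function(e) stop("writing ", gfa, ": ", conditionMessage(e)))
  write_fasta(contigs, fa)
  summary <- list(
    n_contigs = length(contigs),
    lengths = as.list(setNames(nchar(contigs), names(contigs))),
    circular = as.list(setNames(
      vapply(paths, `[[`, TRUE, "circular"), names(contigs))),
    loops = loop_info %||% list())
  jsonlite::write_json(summary, js, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(gfa = gfa, fasta = fa, json = js))
}
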