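# Hinge-aided greedy layout. Every read contributes two oriented nodes
# ("<id>+" and "<id>-") and picks, on each side, its longest extension among
# proper overlaps plus internal matches that start on a hinge of the correct
# direction. Poison marks block extensions that would cross into a bridged
# repeat copy. The graph is symmetric: (u -> v) exists iff (rc(v) -> rc(u))
# does, which we get by construction, computing predecessor choices as
# mirrored successor choices of the reverse-complement node.

#' Build per-read candidate tables for the layout stage
#'
#' @param records Classified alignment records among maximal reads.
#' @return A list keyed by read id; each element has the records with that
#'   read as query (mirrored where needed).
#' @keywords internal
candidate_views <- function(records) {
  rec <- data.table::as.data.table(records)
  cols <- c("qname", "qlen", "qstart", "qend", "strand",
            "tname", "tlen", "tstart", "tend", "nmatch", "blen", "class")
  both <- data.table::rbindlist(list(
    rec[, cols, with = FALSE],
    mirror_records(rec)[, cols, with = FALSE]))
  # mirroring preserves the class up to swapping the contained side
  n <- nrow(rec)
  if (n) {
    mcls <- rec$class
    mcls[rec$class == "a_contained_in_b"] <- "b_contained_in_a"
    mcls[rec$class == "b_contained_in_a"] <- "a_contained_in_b"
    both$class[(n + 1):(2 * n)] <- mcls
  }
  split(both, both$qname)
}

# Oriented in-hinge and start-poison positions per oriented node.
oriented_marks <- function(marks, kinds, read_lengths) {
  # marks: data.table(read_id, pos, key) where key is direction or kind;
  # returns list keyed by oriented node of integer positions that act as
  # in-hinges (resp. start-poisons) in that node's frame
  out <- list()
  if (nrow(marks) == 0) return(out)
  for (i in seq_len(nrow(marks))) {
    rid <- marks$read_id[i]; p <- marks$pos[i]; k <- marks[[3]][i]
    if (!rid %in% names(read_lengths)) next  # mark on a non-maximal read
    L <- read_lengths[[rid]]
    if (k == kinds[1]) {  # forward-frame mark
      out[[onode(rid, "+")]] <- c(out[[onode(rid, "+")]], p)
    } else {              # reverse-frame mark
      out[[onode(rid, "-")]] <- c(out[[onode(rid, "-")]], L - p)
    }
  }
  out
}

#' Choose the best extension of an oriented read on one side
#'
#' Candidates are proper overlaps on the required side plus internal matches
#' whose start coincides (within `hinge_tol`) with an in-hinge on the
#' partner, oriented appropriately. Candidates whose match on the partner
#' starts at or after a poisoned start-repeat mark, or ends at or before a
#' poisoned end-repeat mark (both in the partner's oriented frame), are
#' skipped. The longest match on the choosing read wins; ties go to more
#' matching bases, then to the lexicographically smaller partner.
#'
#' @param node Oriented node name (`"<read_id>+"` or `"<read_id>-"`).
#' @param views Output of [candidate_views()].
#' @param in_hinges,start_poisons Oriented mark lists ([oriented_marks()]).
#' @param side `"successor"` (3' extension) or `"predecessor"`.
#' @param read_lengths Named integer vector.
#' @param end_tolerance Read-end slack (bp).
#' @param hinge_tol Hinge/poison matching tolerance (bp).
#' @param end_poisons Oriented end-poison list (the strand mirror of
#'   `start_poisons`).
#' @param hinge_pref Hinge preference margin (bp): a hinge candidate within
#'   this much of the longest match wins. A proper overlap can only beat a
#'   hinge match by the partner's anchored flank, and flanks below the
#'   annotation end-exemption scale can never carry an annotation, so
#'   length advantages below that scale do not distinguish a genuine unique
#'   continuation from a repeat-interior thread.
#' @return A one-row data.table (`target, us, ue, vs, ve, via_hinge`) or NULL.
#' @export
best_extension <- function(node, views, in_hinges, start_poisons, side,
                           read_lengths, end_tolerance = 250,
                           hinge_tol = 300, end_poisons = list(),
                           hinge_pref = 300) {
  if (side == "predecessor") {
    # the predecessor of n is the mirror of the successor of rc(n)
    ch <- best_extension(onode_rc(node), views, in_hinges, start_poisons,
                         "successor", read_lengths, end_tolerance, hinge_tol,
                         end_poisons, hinge_pref)
    if (is.null(ch)) return(NULL)
    L_n <- read_lengths[[onode_read(node)]]
    L_t <- read_lengths[[onode_read(ch$target)]]
    return(data.table::data.table(
      target = onode_rc(ch$target),
      us = L_n - ch$ue, ue = L_n - ch$us,
      vs = L_t - ch$ve, ve = L_t - ch$vs,
      via_hinge = ch$via_hinge))
  }
  v <- valid_extensions(node, views, in_hinges, start_poisons, end_poisons,
                        read_lengths, end_tolerance, hinge_tol)
  if (is.null(v) || nrow(v) == 0) return(NULL)
  blk <- v$blk
  # repeat entries must funnel at the hinge: a hinge candidate within
  # hinge_pref of the longest match wins, so that neither a read whose end
  # straggles past the repeat boundary nor a deep crossing read too close
  # to its own end to be annotated can capture the entries
  hidx <- which(v$via_hinge)
  idx <- seq_len(nrow(v))
  if (length(hidx) && max(blk[hidx]) >= max(blk) - hinge_pref) {
    idx <- hidx
  }
  ordk <- order(-blk[idx], -v$nmatch[idx], v$target[idx])
  v[idx[ordk[1]], c("target", "us", "ue", "vs", "ve", "via_hinge"),
    with = FALSE]
}

# All valid successor candidates of an oriented node: proper overlaps plus
# hinge-anchored internal matches, minus poisoned joins. Columns: target,
# us, ue, vs, ve (oriented frames), via_hinge, blk, nmatch.
valid_extensions <- function(node, views, in_hinges, start_poisons,
                             end_poisons, read_lengths, end_tolerance = 250,
                             hinge_tol = 300) {
  rid <- onode_read(node); o <- onode_orient(node)
  cand <- views[[rid]]
  if (is.null(cand) || nrow(cand) == 0) return(NULL)
  qlen <- cand$qlen
  if (o == "+") {
    qs <- cand$qstart; qe <- cand$qend
    po <- cand$strand
  } else {
    qs <- qlen - cand$qend; qe <- qlen - cand$qstart
    po <- ifelse(cand$strand == "+", "-", "+")
  }
  ts <- ifelse(po == "+", cand$tstart, cand$tlen - cand$tend)
  te <- ifelse(po == "+", cand$tend, cand$tlen - cand$tstart)
  tnode <- onode(cand$tname, po)

  reaches_end <- qe >= qlen - end_tolerance
  proper <- ts <= end_tolerance
  at_hinge <- vapply(seq_len(nrow(cand)), function(i) {
    h <- in_hinges[[tnode[i]]]
    !is.null(h) && any(abs(ts[i] - h) <= hinge_tol)
  }, TRUE)
  # a hinge may be joined even by a read extending a whisker deeper than
  # the hinged read (annotation jitter): the chain progresses through the
  # hinged read's own successor, so no extension is lost beyond the slack
  extends <- (cand$tlen - te) > (qlen - qe) - ifelse(at_hinge, hinge_tol, 0L)
  poisoned <- vapply(seq_len(nrow(cand)), function(i) {
    p <- start_poisons[[tnode[i]]]
    q <- end_poisons[[tnode[i]]]
    (!is.null(p) && any(ts[i] > p - 100)) ||
      (!is.null(q) && any(te[i] < q + 100))
  }, TRUE)

  ok <- reaches_end & extends & (proper | at_hinge) & !poisoned
  if (!any(ok)) return(NULL)
  idx <- which(ok)
  data.table::data.table(target = tnode[idx], us = qs[idx], ue = qe[idx],
                         vs = ts[idx], ve = te[idx],
                         via_hinge = !proper[idx] & at_hinge[idx],
                         blk = qe[idx] - qs[idx], nmatch = cand$nmatch[idx])
}

#' Build the hinge-aided greedy layout graph
#'
#' Every oriented read proposes its valid extensions (ranked by match
#' length, with hinge-anchored internal matches boosted by `hinge_pref`);
#' proposals are then reconciled globally, longest first. Accepting a
#' proposal fills the chooser's extension slot and, for a plain overlap,
#' the target's opposite-end slot, so each physical read end joins at most
#' one plain overlap while hinge sites accept any number of incoming
#' matches -- the bifurcations of collapsed repeats. A proposal whose
#' target slot is already taken simply falls through to the chooser's next
#' candidate, which keeps the chains intact when two reads rank each other
#' differently. Every accepted edge is inserted together with its
#' reverse-complement mirror, so the edge set is symmetric under strand
#' reversal.
#'
#' @param read_lengths Named integer vector of maximal read lengths.
#' @param records Classified alignment records among maximal reads.
#' @param hinges Hinge table from [place_hinges()].
#' @param poisoned Poison table from [place_hinges()].
#' @param end_tolerance,hinge_tol,hinge_pref See [best_extension()].
#' @return An object of class `layout_graph`: list with `nodes` (oriented
#'   node names) and `edges` (data.table `from, to, us, ue, vs, ve,
#'   via_hinge`; `us/ue` on the source in its frame, `vs/ve` on the target
#'   in its frame).
#' @export
build_layout_graph <- function(read_lengths, records, hinges, poisoned,
                               end_tolerance = 250, hinge_tol = 300,
                               hinge_pref = 300) {
  views <- candidate_views(records)
  ih <- oriented_marks(hinges[hinges$direction %in%
                                c("in_hinge", "out_hinge"), ],
                       c("in_hinge", "out_hinge"), read_lengths)
  sp <- oriented_marks(poisoned, c("start_repeat", "end_repeat"),
                       read_lengths)
  # a forward end-poison acts as a start-poison in the reverse frame and
  # vice versa; swapping the kind order yields the oriented end-poisons
  ep <- oriented_marks(poisoned, c("end_repeat", "start_repeat"),
                       read_lengths)
  ids <- sort(names(read_lengths))
  nodes <- c(onode(ids, "+"), onode(ids, "-"))

  props <- list()
  for (n in nodes) {
    v <- valid_extensions(n, views, ih, sp, ep, read_lengths,
                          end_tolerance, hinge_tol)
    if (is.null(v) || nrow(v) == 0) next
    v <- data.table::copy(v)
    v[, "from" := n]
    props[[length(props) + 1L]] <- v
  }
  empty <- data.table::data.table(from = character(), to = character(),
                                  us = integer(), ue = integer(),
                                  vs = integer(), ve = integer(),
                                  via_hinge = logical())
  g <- structure(list(nodes = nodes, edges = empty,
                      read_lengths = read_lengths),
                 class = "layout_graph")
  if (length(props) == 0) return(g)
  props <- data.table::rbindlist(props)
  # hinge proposals process ahead of plain overlaps within the preference
  # margin; remaining order is by match length with fixed tie-breaks
  props[, "key" := props$blk + ifelse(props$via_hinge, hinge_pref, 0L)]
  data.table::setorderv(props, c("key", "nmatch", "from", "target"),
                        order = c(-1L, -1L, 1L, 1L))

  # physical slot of an oriented node's extension side: successor of (r,+)
  # extends r's tail, successor of (r,-) extends r's head; the target of a
  # plain overlap is entered at its own 5' side
  succ_slot <- function(n) paste0(onode_read(n), "/",
                                  ifelse(onode_orient(n) == "+", "T", "H"))
  pred_slot <- function(n) paste0(onode_read(n), "/",
                                  ifelse(onode_orient(n) == "+", "H", "T"))
  taken <- new.env(parent = emptyenv())
  rows <- list()
  for (i in seq_len(nrow(props))) {
    n <- props$from[i]; t <- props$target[i]
    s_n <- succ_slot(n)
    if (isTRUE(taken[[s_n]])) next
    if (!props$via_hinge[i]) {
      p_t <- pred_slot(t)
      if (isTRUE(taken[[p_t]])) next
      taken[[p_t]] <- TRUE
    }
    taken[[s_n]] <- TRUE
    L_n <- read_lengths[[onode_read(n)]]
    L_t <- read_lengths[[onode_read(t)]]
    rows[[length(rows) + 1L]] <- data.table::data.table(
      from = n, to = t, us = props$us[i], ue = props$ue[i],
      vs = props$vs[i], ve = props$ve[i], via_hinge = props$via_hinge[i])
    # strand-symmetric mirror: rc(target) -> rc(n); it realizes the
    # mirrored node's choice, so its slots are the same physical ones
    rows[[length(rows) + 1L]] <- data.table::data.table(
      from = onode_rc(t), to = onode_rc(n),
      us = L_t - props$ve[i], ue = L_t - props$vs[i],
      vs = L_n - props$ue[i], ve = L_n - props$us[i],
      via_hinge = props$via_hinge[i])
  }
  edges <- unique(data.table::rbindlist(rows))
  edges <- edges[!duplicated(edges[, c("from", "to"), with = FALSE]), ]
  g$edges <- edges
  g
}

#' Check strand symmetry of a layout graph
#'
#' @param g A `layout_graph`.
#' @return TRUE iff the map `(u -> v) |-> (rc(v) -> rc(u))` is an
#'   automorphism of the edge set.
#' @export
is_strand_symmetric <- function(g) {
  e <- g$edges
  key <- paste(e$from, e$to)
  mkey <- paste(vapply(e$to, onode_rc, ""), vapply(e$from, onode_rc, ""))
  setequal(key, mkey)
}

#' Clip short tips from a layout graph
#'
#' A tip is a maximal chain of nodes ending at a node with no outgoing edge
#' (or starting at one with no incoming edge) that attaches to the rest of
#' the graph at a branch. Tips of fewer than `max_tip` nodes are removed,
#' symmetrically on both strands.
#'
#' @param g A `layout_graph`.
#' @param max_tip Remove tips shorter than this many nodes.
#' @return The clipped `layout_graph`.
#' @export
clip_tips <- function(g, max_tip = 3) {
  repeat {
    e <- g$edges
    outdeg <- table(factor(e$from, levels = g$nodes))
    indeg <- table(factor(e$to, levels = g$nodes))
    drop <- character(0)
    for (n in g$nodes) {
      if (outdeg[[n]] == 0 && indeg[[n]] > 0) {
        # walk backwards while the chain is unbranched
        chain <- n; cur <- n
        repeat {
          prev <- e$from[e$to == cur]
          if (length(prev) != 1) break
          if (sum(e$from == prev) != 1) break
          chain <- c(chain, prev); cur <- prev
          if (length(chain) >= max_tip) break
        }
        if (length(chain) < max_tip) drop <- c(drop, chain)
      }
    }
    if (length(drop) == 0) break
    drop <- unique(c(drop, vapply(drop, onode_rc, "")))
    g$nodes <- setdiff(g$nodes, drop)
    g$edges <- g$edges[!(g$edges$from %in% drop | g$edges$to %in% drop), ]
  }
  # tiny weak components (isolated or near-isolated reads that nothing
  # chose and that chose nothing) are junk at assembly scale
  if (length(g$nodes)) {
    ig <- igraph::graph_from_data_frame(
      g$edges[, c("from", "to"), with = FALSE], directed = FALSE,
      vertices = data.frame(name = g$nodes))
    comp <- igraph::components(ig)
    small <- names(comp$membership)[
      comp$csize[comp$membership] < max_tip]
    if (length(small) && length(small) < length(g$nodes)) {
      g$nodes <- setdiff(g$nodes, small)
      g$edges <- g$edges[!(g$edges$from %in% small | g$edges$to %in% small), ]
    }
  }
  g
}

#' Overlay the two strands of a layout graph for visualization
#'
#' Each node and its reverse complement are merged; every mirror pair of
#' directed edges becomes one undirected edge.
#'
#' @param g A symmetric `layout_graph`.
#' @return An undirected igraph whose vertices are read ids.
#' @export
overlay_strands <- function(g) {
  if (!is_strand_symmetric(g)) stop("layout graph is not strand-symmetric")
  ids <- sort(unique(vapply(g$nodes, onode_read, "")))
  if (nrow(g$edges) == 0) {
    return(igraph::make_empty_graph(n = length(ids), directed = FALSE))
  }
  e <- g$edges
  mf <- vapply(e$to, onode_rc, ""); mt <- vapply(e$from, onode_rc, "")
  # keep one representative per mirror pair (self-mirrors kept once)
  keep <- e$from < mf | (e$from == mf & e$to <= mt)
  half <- data.frame(a = vapply(e$from[keep], onode_read, ""),
                     b = vapply(e$to[keep], onode_read, ""))
  igraph::graph_from_data_frame(half, directed = FALSE,
                                vertices = data.frame(name = ids))
}

#' Export a layout graph as GFA 1.0
#'
#' Segments are reads (sequence included when `reads` is given, `*`
#' otherwise); links are the chosen edges, one per strand-mirror pair, with
#' the overlap length on the source read recorded as a plain match.
#'
#' @param g A `layout_graph`.
#' @param path Output path.
#' @param reads Optional named character vector of read sequences.
#' @return `path`, invisibly.
#' @export
write_layout_gfa <- function(g, path, reads = NULL) {
  ids <- sort(unique(vapply(g$nodes, onode_read, "")))
  s_lines <- vapply(ids, function(rid) {
    seq <- if (!is.null(reads) && rid %in% names(reads)) reads[[rid]] else "*"
    sprintf("S\t%s\t%s", rid, seq)
  }, "")
  e <- g$edges
  lines <- c("H\tVN:Z:1.0", s_lines)
  if (nrow(e)) {
    mf <- vapply(e$to, onode_rc, ""); mt <- vapply(e$from, onode_rc, "")
    keep <- e$from < mf | (e$from == mf & e$to <= mt)
    ek <- e[keep, ]
    lines <- c(lines, sprintf("L\t%s\t%s\t%s\t%s\t%dM",
                              vapply(ek$from, onode_read, ""),
                              vapply(ek$from, onode_orient, ""),
                              vapply(ek$to, onode_read, ""),
                              vapply(ek$to, onode_orient, ""),
                              as.integer(ek$ue - ek$us)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Export a layout graph in DOT format
#'
#' @param g A `layout_graph`.
#' @param path Output path.
#' @param colors Optional named vector of node colors (by read id).
#' @return `path`, invisibly.
#' @export
write_layout_dot <- function(g, path, colors = NULL) {
  e <- g$edges
  lines <- c("digraph layout {",
             sprintf("  \"%s\";", g$nodes),
             sprintf("  \"%s\" -> \"%s\"%s;", e$from, e$to,
                     ifelse(e$via_hinge, " [color=red]", "")),
             "}")
  writeLines(lines, path)
  invisible(path)
}
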