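# Loop resolution. The layout graph is contracted (unbranched chains of
# oriented reads become segments); collapsed repeat segments show up as
# segments whose endpoints branch. A component that admits exactly one
# circular traversal can be untangled into that traversal -- unless the loop
# is short enough to be a plasmid, in which case the ambiguity is kept.

#' Contract unbranched chains of a layout graph
#'
#' An edge `u -> v` is internal when `u` has out-degree 1 and `v` in-degree
#' 1; maximal chains of internal edges collapse into segments. Pure cycles
#' become one segment plus a self-edge.
#'
#' @param g A `layout_graph`.
#' @return An object of class `contracted_graph`: list with `segs` (named
#'   list of oriented node vectors), `seg_len` (bp estimates), `edges`
#'   (data.table `from, to, eidx` into `g$edges`), `node2seg`, `seg_rc`
#'   (mirror segment map), and `g` (the underlying layout graph).
#' @export
contract_layout <- function(g) {
  e <- g$edges
  nodes <- g$nodes
  outdeg <- table(factor(e$from, levels = nodes))
  indeg <- table(factor(e$to, levels = nodes))
  internal <- outdeg[e$from] == 1 & indeg[e$to] == 1
  nxt <- setNames(e$to[internal], e$from[internal])        # unique by const.
  has_int_in <- unique(e$to[internal])

  segs <- list()
  closing <- list()  # seg id -> eidx of the internal edge closing a cycle
  visited <- character(0)
  starts <- setdiff(nodes, has_int_in)
  walk_from <- function(s) {
    chain <- s
    repeat {
      nx <- unname(nxt[match(chain[length(chain)], names(nxt))])
      if (is.na(nx) || nx == chain[1]) break
      chain <- c(chain, nx)
    }
    chain
  }
  for (s in starts) {
    segs[[length(segs) + 1L]] <- walk_from(s)
    visited <- c(visited, segs[[length(segs)]])
  }
  # remaining nodes sit on pure internal cycles
  left <- setdiff(nodes, visited)
  while (length(left)) {
    s <- min(left)
    chain <- walk_from(s)
    segs[[length(segs) + 1L]] <- chain
    ei <- which(internal & e$from == chain[length(chain)] & e$to == chain[1])
    closing[[length(segs)]] <- ei[1]
    visited <- c(visited, chain)
    left <- setdiff(left, chain)
  }
  names(segs) <- paste0("s", seq_along(segs))
  node2seg <- setNames(rep(names(segs), lengths(segs)), unlist(segs))

  lens <- g$read_lengths
  seg_len <- vapply(seq_along(segs), function(i) {
    chain <- segs[[i]]
    total <- lens[[onode_read(chain[1])]]
    if (length(chain) > 1) {
      for (j in 2:length(chain)) {
        row <- e[internal & e$from == chain[j - 1] & e$to == chain[j], ][1, ]
        total <- total + (lens[[onode_read(chain[j])]] - row$ve)
      }
    }
    if (!is.null(closing[i][[1]]) && length(closing) >= i &&
        !is.null(closing[[i]])) {
      row <- e[closing[[i]], ]
      total <- total - row$ve  # the head of the first node is duplicated
    }
    as.numeric(total)
  }, 0)
  names(seg_len) <- names(segs)

  ce_rows <- which(!internal)
  ce <- data.table::data.table(
    from = node2seg[e$from[ce_rows]], to = node2seg[e$to[ce_rows]],
    eidx = ce_rows)
  for (i in seq_along(closing)) {
    if (!is.null(closing[[i]])) {
      ce <- rbind(ce, data.table::data.table(
        from = names(segs)[i], to = names(segs)[i], eidx = closing[[i]]))
    }
  }

  seg_rc <- vapply(segs, function(chain) {
    rc_first <- onode_rc(chain[length(chain)])
    unname(node2seg[rc_first])
  }, "")

  structure(list(segs = segs, seg_len = seg_len, edges = ce,
                 node2seg = node2seg, seg_rc = seg_rc, g = g),
            class = "contracted_graph")
}

#' Find collapsed-repeat loop candidates
#'
#' Every segment whose endpoints branch (more than one contracted in-edge or
#' out-edge) is returned with its entry and exit edges and a length estimate.
#'
#' @param g A `layout_graph` or `contracted_graph`.
#' @return A list of `loop_candidate`s: `seg`, `entries`, `exits` (rows of
#'   the contracted edge table), `length` (bp).
#' @export
find_loops <- function(g) {
  ct <- if (inherits(g, "contracted_graph")) g else contract_layout(g)
  out <- list()
  for (s in names(ct$segs)) {
    ent <- ct$edges[ct$edges$to == s & ct$edges$from != s, ]
    ext <- ct$edges[ct$edges$from == s & ct$edges$to != s, ]
    if (nrow(ent) > 1 || nrow(ext) > 1) {
      out[[length(out) + 1L]] <- structure(
        list(seg = s, entries = ent, exits = ext,
             length = ct$seg_len[[s]]),
        class = "loop_candidate")
    }
  }
  out
}

# Weakly connected components of the contracted graph (isolated segments
# included as their own components).
contracted_components <- function(ct) {
  ig <- igraph::graph_from_data_frame(
    ct$edges[, c("from", "to"), with = FALSE], directed = FALSE,
    vertices = data.frame(name = names(ct$segs)))
  comp <- igraph::components(ig)$membership
  split(names(comp), comp)
}

# Canonical form of a circular oriented-label sequence under rotation and
# reverse complement.
canonical_cycle <- function(labels, rc_map) {
  rots <- function(v) {
    n <- length(v)
    vapply(seq_len(n), function(i)
      paste(v[c(i:n, seq_len(i - 1L))], collapse = " "), "")
  }
  rc <- rev(unname(rc_map[labels]))
  min(c(rots(labels), rots(rc)))
}

#' Count the distinct traversals of a contracted component
#'
#' Enumerates all circular walks that use every junction edge of the
#' component exactly once (one orientation of every strand-mirrored edge
#' pair), then deduplicates the induced circular segment-label sequences up
#' to rotation and reverse complement. Components with more than `max_edges`
#' edge pairs are refused.
#'
#' @param ct A `contracted_graph`.
#' @param comp Character vector of segment ids forming one weak component;
#'   default: the whole graph must be one component.
#' @param max_edges Brute-force ceiling on the number of edge pairs.
#' @return A list of class `traversal_enumeration`: `count`, `sequences`
#'   (canonical label cycles), `n_pairs`.
#' @export
count_traversals <- function(ct, comp = NULL, max_edges = 12) {
  comp <- comp %||% names(ct$segs)
  ed <- ct$edges[ct$edges$from %in% comp | ct$edges$to %in% comp, ]
  if (nrow(ed) == 0) {
    # an isolated segment (a finished cycle was contracted to a self-edge
    # elsewhere; with no edges at all there is nothing to traverse)
    return(structure(list(count = 1L, sequences = comp[1], n_pairs = 0L),
                     class = "traversal_enumeration"))
  }
  self_mirrored <- any(ct$seg_rc[comp] %in% comp)

  ed <- data.table::as.data.table(ed)
  ed[, "row" := seq_len(nrow(ed))]
  if (self_mirrored) {
    # pair each edge with its strand mirror inside the component
    ed[, "mfrom" := ct$seg_rc[ed$to]]
    ed[, "mto" := ct$seg_rc[ed$from]]
    key <- paste(ed$from, ed$to)
    pair_id <- integer(nrow(ed))
    nextp <- 0L
    for (i in seq_len(nrow(ed))) {
      if (pair_id[i] > 0L) next
      nextp <- nextp + 1L
      pair_id[i] <- nextp
      js <- which(pair_id == 0L & ed$from == ed$mfrom[i] & ed$to == ed$mto[i])
      if (length(js)) pair_id[js[1]] <- nextp
    }
    ed[, "pair" := pair_id]
  } else {
    ed[, "pair" := seq_len(nrow(ed))]
  }
  n_pairs <- max(ed$pair)
  if (n_pairs > max_edges) {
    stop("component with ", n_pairs,
         " junction edges exceeds the enumeration limit (", max_edges, ")")
  }

  ord <- order(ed$from, ed$to, ed$eidx)
  start <- ed[ord[1], ]
  seqs <- character(0)
  walk <- function(cur, used, labels) {
    if (all(used)) {
      if (cur == start$from) {
        seqs[[length(seqs) + 1L]] <<- canonical_cycle(labels, ct$seg_rc)
      }
      return(invisible(NULL))
    }
    nxt <- ed[ed$from == cur & !used[ed$pair], ]
    for (i in seq_len(nrow(nxt))) {
      u2 <- used; u2[nxt$pair[i]] <- TRUE
      walk(nxt$to[i], u2, c(labels, nxt$to[i]))
    }
  }
  used0 <- rep(FALSE, n_pairs); used0[start$pair] <- TRUE
  walk(start$to, used0, start$to)
  seqs <- unique(seqs)
  structure(list(count = length(seqs), sequences = seqs, n_pairs = n_pairs),
            class = "traversal_enumeration")
}

#' Untangle uniquely traversable loops
#'
#' Every weak component whose traversal enumeration has exactly one sequence
#' and whose collapsed loop candidates are all longer than
#' `max_plasmid_length` is rewritten into its unique circular traversal
#' (collapsed segments are duplicated once per passage). Components at or
#' under the gate, or with several traversals, are left intact. Applied
#' iteratively until no component changes.
#'
#' @param g A `layout_graph`.
#' @param max_plasmid_length Loop-length gate (bp).
#' @param max_edges Enumeration ceiling per component.
#' @return The resolved `layout_graph`.
#' @export
resolve_unique_loops <- function(g, max_plasmid_length = 500000,
                                 max_edges = 12) {
  repeat {
    ct <- contract_layout(g)
    comps <- contracted_components(ct)
    changed <- FALSE
    for (comp in comps) {
      cands <- Filter(function(l) l$seg %in% comp, find_loops(ct))
      if (length(cands) == 0) next
      if (any(vapply(cands, `[[`, 0, "length") <= max_plasmid_length)) next
      if (any(ct$seg_rc[comp] %in% comp)) next  # see methods vignette
      tv <- tryCatch(count_traversals(ct, comp, max_edges),
                     error = function(e) NULL)
      if (is.null(tv) || tv$count != 1) next
      g <- rewrite_component(g, ct, comp)
      changed <- TRUE
      break  # graph changed; re-contract before touching other components
    }
    if (!changed) break
  }
  g
}

# Rewrite one component of the layout graph into its unique traversal. The
# traversal is recomputed as an explicit edge walk, collapsed segments are
# instantiated once per passage (nodes suffixed ".2", ".3", ...), and the
# mirror strand is rebuilt symmetrically.
rewrite_component <- function(g, ct, comp) {
  ed <- ct$edges[ct$edges$from %in% comp, ]
  ed <- data.table::as.data.table(ed)
  ord <- order(ed$from, ed$to, ed$eidx)
  start <- ed[ord[1], ]
  n_edges <- nrow(ed)
  found <- NULL
  walk <- function(cur, used, path) {
    if (!is.null(found)) return(invisible(NULL))
    if (all(used)) {
      if (cur == start$from) found <<- path
      return(invisible(NULL))
    }
    nxt <- which(ed$from == cur & !used)
    for (i in nxt) {
      u2 <- used; u2[i] <- TRUE
      walk(ed$to[i], u2, c(path, i))
    }
  }
  used0 <- rep(FALSE, n_edges); used0[1] <- FALSE
  si <- which(ed$from == start$from & ed$to == start$to &
                ed$eidx == start$eidx)[1]
  used0[si] <- TRUE
  walk(start$to, used0, si)
  if (is.null(found)) return(g)  # should not happen for count-1 components

  lens <- g$read_lengths
  occ <- new.env()
  new_edges <- list()
  add_edge <- function(from, to, row) {
    new_edges[[length(new_edges) + 1L]] <<- data.table::data.table(
      from = from, to = to, us = row$us, ue = row$ue,
      vs = row$vs, ve = row$ve, via_hinge = row$via_hinge)
  }
  # walk the traversal, instantiating segment node chains
  seg_seq <- ed$to[found]                      # segments entered, in order
  inst_chains <- vector("list", length(seg_seq))
  for (k in seq_along(seg_seq)) {
    chain <- ct$segs[[seg_seq[k]]]
    for (nd in chain) {
      rid_o <- onode_read(nd)
      assign(rid_o, (get0(rid_o, occ) %||% 0L) + 1L, occ)
    }
    kth <- vapply(chain, function(nd) {
      rid_o <- onode_read(nd)
      k2 <- get(rid_o, occ)
      if (k2 == 1L) nd else onode(paste0(rid_o, ".", k2), onode_orient(nd))
    }, "")
    inst_chains[[k]] <- kth
    # internal edges of the segment instance
    if (length(chain) > 1) {
      for (j in 2:length(chain)) {
        row <- g$edges[g$edges$from == chain[j - 1] &
                         g$edges$to == chain[j], ][1, ]
        add_edge(kth[j - 1], kth[j], row)
      }
    }
  }
  # junction edges between consecutive instances (and the closing one)
  for (k in seq_along(found)) {
    row <- g$edges[ed$eidx[found[k]], ]
    prev_chain <- inst_chains[[if (k == 1) length(found) else k - 1L]]
    this_chain <- inst_chains[[k]]
    add_edge(prev_chain[length(prev_chain)], this_chain[1], row)
  }
  fwd <- data.table::rbindlist(new_edges)
  # mirror strand
  flip_node <- function(n) onode_rc(n)
  base_len <- function(n) lens[[onode_read(n)]]
  rev_edges <- data.table::data.table(
    from = vapply(fwd$to, flip_node, ""),
    to = vapply(fwd$from, flip_node, ""),
    us = vapply(fwd$to, base_len, 0) - fwd$ve,
    ue = vapply(fwd$to, base_len, 0) - fwd$vs,
    vs = vapply(fwd$from, base_len, 0) - fwd$ue,
    ve = vapply(fwd$from, base_len, 0) - fwd$us,
    via_hinge = fwd$via_hinge)

  old_nodes <- unlist(ct$segs[c(comp, unname(ct$seg_rc[comp]))])
  g$nodes <- c(setdiff(g$nodes, old_nodes),
               unique(c(unlist(inst_chains),
                        vapply(unlist(inst_chains), flip_node, ""))))
  g$edges <- rbind(
    g$edges[!(g$edges$from %in% old_nodes | g$edges$to %in% old_nodes), ],
    fwd, rev_edges)
  g
}

#' Report loops and their traversal counts
#'
#' @param g A `layout_graph`.
#' @param max_edges Enumeration ceiling per component.
#' @return A list (one element per weak component that contains loops):
#'   `segments`, `loop_lengths`, `traversals` (count or NA when refused).
#' @export
loop_report <- function(g, max_edges = 12) {
  ct <- contract_layout(g)
  comps <- contracted_components(ct)
  out <- list()
  for (comp in comps) {
    cands <- Filter(function(l) l$seg %in% comp, find_loops(ct))
    if (length(cands) == 0) next
    tv <- tryCatch(count_traversals(ct, comp, max_edges),
                   error = function(e) NULL)
    out[[length(out) + 1L]] <- list(
      segments = comp,
      loop_lengths = vapply(cands, `[[`, 0, "length"),
      traversals = if (is.null(tv)) NA_integer_ else tv$count)
  }
  out
}
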