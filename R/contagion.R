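# The Contagion stage spreads the bridging condition globally across repeat
# annotations, kills redundant annotations so that each unbridged repeat is
# left with exactly one start and one end annotation, poisons reads whose
# annotations were killed by a bridged repeat, and finally converts the
# survivors into in-hinges and out-hinges.
#
# Annotation kinds live on each read's forward strand: a start_repeat has the
# repeat to its right (3'), an end_repeat to its left. Across an opposite-
# strand alignment the kind therefore flips: the same genomic repeat boundary
# appears as a start on one read and as an end on the reverse-complemented
# partner. "Extension into the repeat" is the distance from the annotation to
# the read end on the repeat side.

ann_extension <- function(ann) {
  ifelse(ann$kind == "start_repeat", ann$len - ann$pos, ann$pos)
}

#' Build the Contagion graph
#'
#' Nodes are repeat annotations on maximal reads. Two annotations are
#' connected when an alignment between their reads maps one annotation
#' position to within `position_tolerance` of the other (flipping the
#' annotation kind across opposite-strand alignments) and the matched segment
#' extends at least `position_tolerance` into the repeat side of both
#' annotations. The edge points toward the annotation whose read extends the
#' farthest into the repeat (ties to the lexicographically smaller read id).
#'
#' @param ann Annotation table ([annotate_reads()]) restricted to maximal
#'   reads.
#' @param records Classified alignment records among maximal reads.
#' @param read_lengths Named integer vector.
#' @param position_tolerance Matching tolerance (bp).
#' @return An object of class `contagion`: list with `ann` (annotations plus
#'   `len` and `component` columns), `edges` (`from`, `to` annotation ids,
#'   `class` of the supporting match), and `tol`.
#' @export
build_contagion_graph <- function(ann, records, read_lengths,
                                  position_tolerance = 300) {
  ann <- data.table::as.data.table(ann)
  ann[, "len" := as.integer(read_lengths[ann$read_id])]
  rec <- data.table::as.data.table(records)
  tol <- position_tolerance

  edges <- data.table::data.table(from = integer(), to = integer(),
                                  class = character())
  if (nrow(ann) > 0 && nrow(rec) > 0) {
    rec <- rec[, c("qname", "qstart", "qend", "strand",
                   "tname", "tstart", "tend", "class"), with = FALSE]
    rec[, "rec_i" := seq_len(nrow(rec))]
    # annotations on the query side of each record, with projected target pos
    a <- merge(rec, ann[, c("ann_id", "read_id", "pos", "kind"), with = FALSE],
               by.x = "qname", by.y = "read_id", allow.cartesian = TRUE)
    a <- a[a$pos >= a$qstart - tol & a$pos <= a$qend + tol, ]
    if (nrow(a)) {
      # repeat-side extension of the match on the query read
      ext_ok <- ifelse(a$kind == "start_repeat",
                       a$qend - a$pos >= tol, a$pos - a$qstart >= tol)
      a <- a[ext_ok, ]
    }
    if (nrow(a)) {
      a[, "proj" := ifelse(a$strand == "+",
                           a$tstart + (a$pos - a$qstart),
                           a$tend - (a$pos - a$qstart))]
      a[, "kind_b" := ifelse(a$strand == "+", a$kind,
                             ifelse(a$kind == "start_repeat",
                                    "end_repeat", "start_repeat"))]
      b <- ann[, c("ann_id", "read_id", "pos", "kind"), with = FALSE]
      data.table::setnames(b, c("ann_id_b", "read_id", "pos_b", "kind_b"))
      a[, c("lo", "hi") := list(a$proj - tol, a$proj + tol)]
      m <- b[a, on = c("read_id" = "tname", "kind_b" = "kind_b",
                       "pos_b >= lo", "pos_b <= hi"),
             nomatch = NULL,
             .(ann_id_a = i.ann_id, ann_id_b = x.ann_id_b,
               class = i.class, kind_b = i.kind_b,
               tstart = i.tstart, tend = i.tend, pos_b = x.pos_b)]
      if (nrow(m)) {
        ext_ok_b <- ifelse(m$kind_b == "start_repeat",
                           m$tend - m$pos_b >= tol, m$pos_b - m$tstart >= tol)
        m <- m[ext_ok_b, ]
      }
      if (nrow(m)) {
        ea <- ann_extension(ann[match(m$ann_id_a, ann$ann_id), ])
        eb <- ann_extension(ann[match(m$ann_id_b, ann$ann_id), ])
        ra <- ann$read_id[match(m$ann_id_a, ann$ann_id)]
        rb <- ann$read_id[match(m$ann_id_b, ann$ann_id)]
        # direction: lesser extender -> greater; ties survive on smaller id
        a_wins <- ea > eb | (ea == eb & ra <= rb)
        edges <- data.table::data.table(
          from = ifelse(a_wins, m$ann_id_b, m$ann_id_a),
          to = ifelse(a_wins, m$ann_id_a, m$ann_id_b),
          class = m$class)
        edges <- unique(edges)
      }
    }
  }

  g <- structure(list(ann = ann, edges = edges, tol = tol),
                 class = "contagion")
  assign_components(g)
}

# Weakly connected component labels over the annotation nodes.
assign_components <- function(g) {
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("from", "to"), with = FALSE],
    directed = FALSE,
    vertices = data.frame(name = g$ann$ann_id))
  comp <- igraph::components(ig)$membership
  g$ann[, "component" := as.integer(comp[as.character(g$ann$ann_id)])]
  g
}

#' Prune small Contagion components
#'
#' Annotations whose weakly connected component has fewer than `min_size`
#' members are killed; they are typically the product of imprecise annotation
#' placement and would otherwise seed spurious extra hinges.
#'
#' @param g A `contagion` object.
#' @param min_size Minimum component size.
#' @return The updated `contagion` object.
#' @export
prune_small_components <- function(g, min_size = 2) {
  sizes <- table(g$ann$component)
  small <- as.integer(names(sizes)[sizes < min_size])
  g$ann[g$ann$component %in% small & g$ann$status == "active",
        "status" := "killed"]
  g
}

#' Kill pass over overlapping reads, with poisoning
#'
#' For every Contagion edge whose supporting match is a proper overlap, the
#' annotation extending the least into the repeat is killed. A victim whose
#' killer is bridged — or was itself poisoned — is marked poisoned instead of
#' plainly killed: its read keeps a poison mark that the layout stage uses to
#' avoid collapsing bridged repeats.
#'
#' @param g A `contagion` object (after pruning).
#' @return The updated `contagion` object.
#' @export
kill_by_overlap <- function(g) {
  ov <- g$edges[g$edges$class %in%
                  c("suffix_prefix_overlap", "prefix_suffix_overlap"), ]
  if (nrow(ov) == 0) return(g)
  alive <- g$ann$status != "killed"  # pruned annotations take no part
  ok <- alive[match(ov$from, g$ann$ann_id)] & alive[match(ov$to, g$ann$ann_id)]
  ov <- ov[ok, ]
  if (nrow(ov) == 0) return(g)

  victim <- match(ov$from, g$ann$ann_id)
  killer <- match(ov$to, g$ann$ann_id)
  g$ann$status[victim] <- "killed"
  # poison propagation: a victim of a bridged or poisoned killer is poisoned
  repeat {
    poisoned <- g$ann$status == "poisoned"
    hot <- g$ann$bridged[killer] | poisoned[killer]
    newly <- victim[hot] [g$ann$status[victim[hot]] != "poisoned"]
    if (length(newly) == 0) break
    g$ann$status[newly] <- "poisoned"
  }
  g
}

#' Kill pass over internal matches
#'
#' Among annotations that are neither poisoned nor bridged (and whose reads
#' carry no poison mark of the same kind), every Contagion edge supported by
#' an internal match kills the annotation extending the least into the
#' repeat. After this pass each unbridged repeat retains exactly one start
#' and one end annotation across all of its copies.
#'
#' @param g A `contagion` object (after [kill_by_overlap()]).
#' @return The updated `contagion` object.
#' @export
kill_by_internal_match <- function(g) {
  im <- g$edges[g$edges$class == "internal_match", ]
  if (nrow(im) == 0) return(g)
  idx_f <- match(im$from, g$ann$ann_id)
  idx_t <- match(im$to, g$ann$ann_id)
  poisoned_reads <- unique(g$ann$read_id[g$ann$status == "poisoned"])
  # both endpoints must be on nonpoisoned reads and not bridged; the victim
  # must still be active
  ok <- !(g$ann$read_id[idx_f] %in% poisoned_reads) &
    !(g$ann$read_id[idx_t] %in% poisoned_reads) &
    !g$ann$bridged[idx_f] & !g$ann$bridged[idx_t] &
    g$ann$status[idx_t] != "killed"
  g$ann$status[idx_f[ok & g$ann$status[idx_f] == "active"]] <- "killed"
  g
}

#' Place hinges from the surviving annotations
#'
#' Surviving active, non-bridged start annotations become in-hinges and end
#' annotations become out-hinges. Bridged annotations never yield hinges
#' (their repeat copy is separable without one), and poisoned annotations are
#' reported as poison marks for the layout stage.
#'
#' @param g A `contagion` object after both kill passes.
#' @return List with `hinges` (data.table `read_id, pos, direction`) and
#'   `poisoned` (data.table `read_id, pos, kind`).
#' @export
place_hinges <- function(g) {
  surv <- g$ann[g$ann$status == "active" & !g$ann$bridged, ]
  hinges <- data.table::data.table(
    read_id = surv$read_id, pos = surv$pos,
    direction = ifelse(surv$kind == "start_repeat", "in_hinge", "out_hinge"))
  pois <- g$ann[g$ann$status == "poisoned", ]
  poisoned <- data.table::data.table(read_id = pois$read_id, pos = pois$pos,
                                     kind = pois$kind)
  list(hinges = hinges, poisoned = poisoned)
}

#' Run the full Contagion algorithm
#'
#' Convenience wrapper: build the graph, prune small components, run the
#' overlap and internal-match kill passes, and place hinges.
#'
#' @inheritParams build_contagion_graph
#' @param min_size Minimum component size for [prune_small_components()].
#' @return List with `graph` (the final `contagion` object), `hinges`, and
#'   `poisoned`.
#' @export
run_contagion <- function(ann, records, read_lengths, position_tolerance = 300,
                          min_size = 2) {
  g <- build_contagion_graph(ann, records, read_lengths, position_tolerance)
  g <- prune_small_components(g, min_size)
  g <- kill_by_overlap(g)
  g <- kill_by_internal_match(g)
  c(list(graph = g), place_hinges(g))
}

#' Export the Contagion graph in DOT format
#'
#' Nodes are colored by status (active, killed, poisoned) with bridged
#' annotations in red, mirroring the usual visualization of the graph.
#'
#' @param g A `contagion` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contagion_dot <- function(g, path) {
  col <- ifelse(g$ann$bridged, "red",
                ifelse(g$ann$status == "poisoned", "purple",
                       ifelse(g$ann$status == "killed", "gray", "black")))
  lines <- c("digraph contagion {",
             sprintf("  a%d [label=\"%s:%d:%s\", color=%s];",
                     g$ann$ann_id, g$ann$read_id, g$ann$pos,
                     sub("_repeat", "", g$ann$kind), col),
             sprintf("  a%d -> a%d;", g$edges$from, g$edges$to),
             "}")
  writeLines(lines, path)
  invisible(path)
}
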