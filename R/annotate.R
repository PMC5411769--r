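# Repeat annotation: sharp gradients in the number of alignments on a read
# mark the beginning or end of a repeat. Relying on gradients of the pile
# count, rather than the count itself, keeps the caller immune to smooth
# coverage fluctuations.

ANN_COLS <- function() {
  data.table::data.table(read_id = character(), pos = integer(),
                         kind = character(), support = integer(),
                         status = character(), bridged = logical())
}

#' Detect repeat annotations on one read
#'
#' A `start_repeat` annotation is emitted where at least `gradient_min` piles
#' begin within one window; an `end_repeat` where that many piles end within
#' one window. The annotation position is the modal endpoint of the cluster.
#' Positions within one window of either read end are exempt (piles
#' necessarily start and end there). `start_repeat` marks the first repeat
#' base; `end_repeat` marks one past the last repeat base.
#'
#' @param p Pile-o-gram of one chimera-filtered read.
#' @param read_length Read length; taken from `p` when omitted.
#' @param gradient_min Minimum number of co-located pile endpoints. Default
#'   `max(5, ceiling(0.4 * median pile depth))` of this read.
#' @param window Clustering window (bp).
#' @param end_exempt Margin (bp) at both read ends inside which endpoints are
#'   ignored: every partner's pile necessarily stops near the read end, and
#'   with errors the alignment ends straggle a few hundred bp short of it,
#'   so endpoint clusters inside this margin carry no repeat signal.
#' @return A data.table with columns `read_id, pos, kind, support, status,
#'   bridged` (`status = "active"`, `bridged = FALSE`).
#' @export
detect_repeat_annotations <- function(p, read_length = NULL,
                                      gradient_min = NULL, window = 100,
                                      end_exempt = 250) {
  if (nrow(p) == 0) return(ANN_COLS())
  len <- as.integer(read_length %||% p$length[1])
  rid <- p$read_id[1]
  if (is.null(gradient_min)) {
    steps <- pile_depth_steps(p$start, p$end, len)
    widths <- diff(c(steps$pos, len))
    med <- median(rep(steps$depth, widths))
    gradient_min <- max(5, ceiling(0.4 * med))
  }

  cluster_endpoints <- function(pos, kind) {
    pos <- sort(pos[pos >= end_exempt & pos <= len - end_exempt])
    if (length(pos) == 0) return(ANN_COLS())
    # windowed counts around each distinct endpoint
    upos <- unique(pos)
    cnt <- vapply(upos, function(x)
      sum(pos >= x - window & pos <= x + window), 0L)
    hits <- upos[cnt >= gradient_min]
    if (length(hits) == 0) return(ANN_COLS())
    grp <- cumsum(c(1L, diff(hits) > window))
    rows <- lapply(split(hits, grp), function(h) {
      members <- pos[pos >= min(h) - window & pos <= max(h) + window]
      tab <- table(members)
      modal <- as.integer(names(tab)[tab == max(tab)])
      data.table::data.table(read_id = rid,
                             pos = as.integer(round(median(modal))),
                             kind = kind,
                             support = length(members),
                             status = "active", bridged = FALSE)
    })
    data.table::rbindlist(rows)
  }

  out <- data.table::rbindlist(list(
    cluster_endpoints(p$start, "start_repeat"),
    cluster_endpoints(p$end, "end_repeat")))
  if (nrow(out)) data.table::setorderv(out, c("pos", "kind"))
  out
}

#' Decide the local bridging condition of annotation pairs on one read
#'
#' A read that carries both a start-of-repeat and an end-of-repeat
#' annotation spans a whole repeat copy -- provided the two annotations
#' delimit the same repeat. That is verified by confinement: matches from
#' other copies cannot extend past the repeat, so at least
#' `pairing_fraction` of the piles starting on the start annotation must end
#' at or before the end annotation, and symmetrically at least that
#' fraction of the piles ending on the end annotation must start at or
#' after the start annotation. Pairs that pass are marked bridged. (A pair
#' of annotations belonging to two different repeats with interleaved
#' matches, e.g. a repeat inside a longer repeat whose copies extend
#' beyond, fails the confinement test.)
#'
#' @param ann Annotations on one read ([detect_repeat_annotations()]).
#' @param p The read's pile-o-gram.
#' @param pairing_fraction Fraction of annotation-anchored piles that must
#'   be confined by the paired annotation.
#' @param window Matching window (bp) around the annotation positions.
#' @return `ann` with the `bridged` column updated.
#' @export
mark_bridged <- function(ann, p, pairing_fraction = 0.9, window = 100) {
  if (nrow(ann) < 2) return(ann)
  starts <- which(ann$kind == "start_repeat")
  ends <- which(ann$kind == "end_repeat")
  for (i in starts) {
    for (j in ends) {
      if (ann$pos[j] <= ann$pos[i] + 2 * window) next
      at_s <- p$start >= ann$pos[i] - window & p$start <= ann$pos[i] + window
      at_e <- p$end >= ann$pos[j] - window & p$end <= ann$pos[j] + window
      if (!any(at_s) || !any(at_e)) next
      conf_s <- mean(p$end[at_s] <= ann$pos[j] + window)
      conf_e <- mean(p$start[at_e] >= ann$pos[i] - window)
      if (conf_s >= pairing_fraction && conf_e >= pairing_fraction) {
        ann$bridged[c(i, j)] <- TRUE
      }
    }
  }
  ann
}

#' Annotate all reads and decide local bridging
#'
#' @param piles Output of [build_pileograms()].
#' @param read_lengths Named integer vector.
#' @param gradient_min,window,end_exempt See [detect_repeat_annotations()].
#' @param pairing_fraction See [mark_bridged()].
#' @return Combined annotation table with a unique `ann_id` column.
#' @export
annotate_reads <- function(piles, read_lengths, gradient_min = NULL,
                           window = 100, end_exempt = 250,
                           pairing_fraction = 0.9) {
  out <- lapply(split(piles, piles$read_id), function(p) {
    ann <- detect_repeat_annotations(p, gradient_min = gradient_min,
                                     window = window,
                                     end_exempt = end_exempt)
    if (nrow(ann)) mark_bridged(ann, p, pairing_fraction, window) else ann
  })
  ann <- data.table::rbindlist(out)
  if (nrow(ann) == 0) { a <- ANN_COLS(); a[, "ann_id" := integer()]; return(a) }
  ann[, "ann_id" := seq_len(nrow(ann))]
  ann
}

#' Keep only maximal (non-contained) reads
#'
#' A read survives iff no alignment record classifies it as contained in a
#' surviving read. Reads are processed from longest to shortest (ties by
#' lexicographic id), so containment chains always leave at least one
#' survivor per chain and near-equal mutual containments keep exactly one.
#'
#' @param records Classified alignment records ([classify_matches()]).
#' @param read_lengths Named integer vector of all read lengths.
#' @param end_tolerance Same slack as used for classification; mutual
#'   (near-equal) containments are expanded to both directions here so that
#'   exactly one read of such a pair survives.
#' @return Character vector of surviving (maximal) read ids.
#' @export
filter_contained_reads <- function(records, read_lengths,
                                   end_tolerance = 250) {
  rec <- data.table::as.data.table(records)
  cont <- rec[rec$class %in% c("a_contained_in_b", "b_contained_in_a"), ]
  tol <- end_tolerance
  ts2 <- ifelse(cont$strand == "+", cont$tstart, cont$tlen - cont$tend)
  te2 <- ifelse(cont$strand == "+", cont$tend, cont$tlen - cont$tstart)
  a_full <- cont$qstart <= tol & cont$qend >= cont$qlen - tol
  b_full <- ts2 <= tol & te2 >= cont$tlen - tol
  inner <- c(cont$qname[a_full], cont$tname[b_full])
  outer <- c(cont$tname[a_full], cont$qname[b_full])
  ids <- names(read_lengths)[order(-read_lengths, names(read_lengths))]
  surviving <- character(0)
  gone <- character(0)
  for (rid in ids) {
    containers <- outer[inner == rid]
    if (any(containers %in% surviving)) gone <- c(gone, rid)
    else surviving <- c(surviving, rid)
  }
  sort(surviving)
}
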