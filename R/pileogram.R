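# Pile-o-grams: for each read, the stack of aligned intervals contributed by
# all its partners. Chimeric reads betray themselves here as positions where
# the set of aligned partners changes abruptly, or where the pile depth drops
# below a floor.

#' Build pile-o-grams for all reads
#'
#' Each alignment record contributes one pile to each of its two reads: the
#' matched interval on that read, with the partner id and relative strand.
#'
#' @param records Canonical alignment records (see [find_all_overlaps()]).
#' @param read_lengths Named integer vector of read lengths.
#' @return A data.table with columns `read_id, length, start, end, partner,
#'   partner_strand`, sorted by read and start.
#' @export
build_pileograms <- function(records, read_lengths) {
  rec <- data.table::as.data.table(records)
  if (nrow(rec) == 0) {
    return(data.table::data.table(read_id = character(), length = integer(),
                                  start = integer(), end = integer(),
                                  partner = character(),
                                  partner_strand = character()))
  }
  piles <- data.table::rbindlist(list(
    data.table::data.table(read_id = rec$qname, start = rec$qstart,
                           end = rec$qend, partner = rec$tname,
                           partner_strand = rec$strand),
    data.table::data.table(read_id = rec$tname, start = rec$tstart,
                           end = rec$tend, partner = rec$qname,
                           partner_strand = rec$strand)))
  piles[, "length" := as.integer(read_lengths[piles$read_id])]
  data.table::setcolorder(piles, c("read_id", "length", "start", "end",
                                   "partner", "partner_strand"))
  data.table::setorderv(piles, c("read_id", "start", "end"))
  piles[]
}

#' Build the pile-o-gram of a single read
#'
#' @param read_id Read identifier.
#' @param records Alignment records; every record must involve `read_id`.
#' @param read_length Length of the read (bp).
#' @return A data.table of piles for this read (possibly empty).
#' @export
build_pileogram <- function(read_id, records, read_length) {
  rid <- read_id
  rec <- data.table::as.data.table(records)
  if (nrow(rec) > 0 && !all(rec$qname == rid | rec$tname == rid)) {
    stop("records not involving read ", rid, " passed to build_pileogram")
  }
  p <- build_pileograms(rec, setNames(read_length, rid))
  p[p[["read_id"]] == rid, ]
}

# Pile depth of one read's pileogram, evaluated at integer positions 0..len-1,
# returned as a step function over breakpoints (data.table pos, depth: depth
# holds on [pos, next_pos)).
pile_depth_steps <- function(starts, ends, len) {
  ev <- data.table::data.table(pos = c(0L, starts, ends),
                               d = c(0L, rep(1L, length(starts)),
                                     rep(-1L, length(ends))))
  ev <- ev[ev$pos < len, ]
  ev <- ev[, list(d = sum(d)), by = "pos"]
  data.table::setorderv(ev, "pos")
  ev[, "depth" := cumsum(ev$d)]
  ev[, c("pos", "depth"), with = FALSE]
}

#' Detect chimeric segments on one read
#'
#' A breakpoint is called at position `x` when fewer than
#' `continuity_fraction` of the piles covering `[x - window, x)` continue
#' through `[x, x + window)`. A segment is additionally marked chimeric when
#' the pile depth falls below `min_coverage`. Read ends are exempt within one
#' window (piles necessarily end there). The longest clean segment is
#' retained; reads whose longest clean segment is shorter than `min_keep`
#' are discarded.
#'
#' @param p Pile-o-gram of one read ([build_pileogram()]).
#' @param read_length Read length; taken from `p` when omitted.
#' @param min_coverage Minimum pile depth (piles).
#' @param continuity_window Window (bp) for the continuity test.
#' @param continuity_fraction Minimum fraction of piles that must continue.
#' @param min_keep Minimum retained length (bp).
#' @return A list of class `chimera_report`: `read_id`, `breakpoints`
#'   (integer vector), `retained` (c(start, end) or NULL), `discard` flag.
#' @export
detect_chimera <- function(p, read_length = NULL, min_coverage = 3,
                           continuity_window = 200,
                           continuity_fraction = 0.15, min_keep = 2000) {
  len <- as.integer(read_length %||% p$length[1])
  rid <- if (nrow(p)) p$read_id[1] else NA_character_
  w <- as.integer(continuity_window)

  report <- function(bp, retained, discard) {
    structure(list(read_id = rid, breakpoints = bp,
                   retained = retained, discard = discard),
              class = "chimera_report")
  }
  if (nrow(p) == 0) return(report(integer(0), NULL, TRUE))

  # continuity breakpoints at interior pile end positions
  cand <- sort(unique(p$end[p$end >= w & p$end <= len - w]))
  bp <- integer(0)
  for (x in cand) {
    covering <- p$start <= x - w & p$end >= x
    n_cov <- sum(covering)
    if (n_cov == 0) next
    n_cont <- sum(covering & p$end >= x + w)
    if (n_cont / n_cov < continuity_fraction) bp <- c(bp, x)
  }
  if (length(bp)) {  # merge clusters within one window to their median
    grp <- cumsum(c(1L, diff(bp) > w))
    bp <- as.integer(tapply(bp, grp, function(v) round(median(v))))
  }

  # low-depth chimeric intervals (interior only)
  steps <- pile_depth_steps(p$start, p$end, len)
  low <- steps$depth < min_coverage
  ivs <- list()
  pos <- c(steps$pos, len)
  for (i in which(low)) {
    s <- max(pos[i], w); e <- min(pos[i + 1L], len - w)
    if (s < e) ivs[[length(ivs) + 1L]] <- c(s, e)
  }

  # clean segments: cut [0, len) at breakpoints, remove low-depth intervals
  cuts <- sort(unique(c(0L, bp, len,
                        unlist(lapply(ivs, function(v) c(v[1], v[2]))))))
  segs <- data.table::data.table(s = head(cuts, -1L), e = tail(cuts, -1L))
  if (length(ivs)) {
    bad <- vapply(seq_len(nrow(segs)), function(i) {
      any(vapply(ivs, function(v)
        segs$s[i] < v[2] && segs$e[i] > v[1], TRUE))
    }, TRUE)
    segs <- segs[!bad, ]
  }
  if (nrow(segs) == 0) return(report(bp, NULL, TRUE))
  best <- segs[which.max(segs$e - segs$s), ]
  if (best$e - best$s < min_keep) return(report(bp, NULL, TRUE))
  report(bp, c(best$s, best$e), FALSE)
}

#' Run the chimera filter over all reads
#'
#' @param piles Output of [build_pileograms()].
#' @param read_lengths Named integer vector (covers reads with no piles too).
#' @param ... Passed to [detect_chimera()].
#' @return A data.table with one row per read: `read_id, discard, keep_start,
#'   keep_end, n_breakpoints`.
#' @export
detect_chimeras <- function(piles, read_lengths, ...) {
  split_p <- split(piles, piles$read_id)
  rows <- lapply(names(read_lengths), function(rid) {
    p <- split_p[[rid]]
    if (is.null(p)) p <- piles[0, ]
    rep <- detect_chimera(p, read_length = read_lengths[[rid]], ...)
    data.table::data.table(
      read_id = rid, discard = rep$discard,
      keep_start = if (rep$discard) NA_integer_ else rep$retained[1],
      keep_end = if (rep$discard) NA_integer_ else rep$retained[2],
      n_breakpoints = length(rep$breakpoints))
  })
  data.table::rbindlist(rows)
}

#' Apply chimera reports: trim reads and re-offset alignment records
#'
#' Discarded reads are removed from the read set and from all records.
#' Trimmed reads keep their retained interval; matched intervals in the
#' records are clipped to the retained interval and shifted to the new
#' coordinate system, with the partner side of each record clipped by the
#' same amounts (respecting strand).
#'
#' @param reads Named character vector of read sequences.
#' @param reports Output of [detect_chimeras()].
#' @param records Alignment records.
#' @param min_block Drop records whose clipped block is shorter than this.
#' @return List with `reads` (trimmed) and `records` (re-offset).
#' @export
apply_trim <- function(reads, reports, records, min_block = 1000) {
  rep <- data.table::as.data.table(reports)
  keep <- rep[!rep$discard, ]
  reads <- reads[keep$read_id]
  ks <- setNames(keep$keep_start, keep$read_id)
  ke <- setNames(keep$keep_end, keep$read_id)
  reads <- vapply(names(reads), function(rid) {
    substr(reads[[rid]], ks[[rid]] + 1L, ke[[rid]])
  }, "")

  rec <- data.table::as.data.table(records)
  rec <- rec[rec$qname %in% keep$read_id & rec$tname %in% keep$read_id, ]
  if (nrow(rec) == 0) return(list(reads = reads, records = empty_records()))

  clip_side <- function(rec, side) {
    rid <- rec[[paste0(side, "name")]]
    s <- ks[rid]; e <- ke[rid]
    st <- rec[[paste0(side, "start")]]; en <- rec[[paste0(side, "end")]]
    dl <- pmax(0L, s - st); dr <- pmax(0L, en - e)
    other <- if (side == "q") "t" else "q"
    ost <- rec[[paste0(other, "start")]]; oen <- rec[[paste0(other, "end")]]
    plus <- rec$strand == "+"
    rec[[paste0(side, "start")]] <- pmax(st, s) - s
    rec[[paste0(side, "end")]] <- pmin(en, e) - s
    rec[[paste0(side, "len")]] <- as.integer(e - s)
    rec[[paste0(other, "start")]] <- ost + ifelse(plus, dl, dr)
    rec[[paste0(other, "end")]] <- oen - ifelse(plus, dr, dl)
    rec
  }
  rec <- clip_side(rec, "q")
  rec <- clip_side(rec, "t")
  ok <- rec$qstart < rec$qend & rec$tstart < rec$tend
  rec <- rec[ok, ]
  shrink <- pmax(rec$qend - rec$qstart, rec$tend - rec$tstart) / rec$blen
  rec$nmatch <- as.integer(round(rec$nmatch * pmin(1, shrink)))
  rec$blen <- as.integer(pmax(rec$qend - rec$qstart, rec$tend - rec$tstart))
  rec <- rec[rec$blen >= min_block, ]
  list(reads = reads, records = rec)
}
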