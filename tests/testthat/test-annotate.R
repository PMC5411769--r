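make_piles <- function(read_id, len, starts, ends) {
  data.table::data.table(read_id = read_id, length = as.integer(len),
                         start = as.integer(starts), end = as.integer(ends),
                         partner = sprintf("p%03d", seq_along(starts)),
                         partner_strand = "+")
}

test_that("a pile-start cluster yields one annotation at its modal position", {
  set.seed(17)
  # background: 25 piles with scattered endpoints; signal: 20 piles starting
  # within +-40 bp of 4000
  bg_s <- sample(600:3500, 25); bg_e <- pmin(9000, bg_s + 5000)
  sig_s <- 4000 + sample(-40:40, 20, replace = TRUE)
  sig_e <- pmin(9200, sig_s + sample(3000:5000, 20, replace = TRUE))
  p <- make_piles("r", 10000, c(bg_s, sig_s), c(bg_e, sig_e))
  ann <- detect_repeat_annotations(p, gradient_min = 12, window = 100)
  st <- ann[ann$kind == "start_repeat", ]
  expect_equal(nrow(st), 1)
  expect_lte(abs(st$pos - 4000), 100)
  expect_gte(st$support, 12)

  # uniform pileogram: nothing
  pu <- make_piles("r", 10000, rep(0, 20), rep(10000, 20))
  expect_equal(nrow(detect_repeat_annotations(pu, gradient_min = 8)), 0)
})

test_that("smooth coverage fluctuations produce no annotations", {
  # depth drifting between ~20x and ~40x with endpoints spread uniformly:
  # gradients of the pile count stay shallow everywhere
  set.seed(23)
  for (trial in 1:5) {
    len <- 10000
    density <- function(x) 20 + 20 * sin(x / len * pi)  # slow drift
    starts <- sort(sample(0:(len - 2000), 60, replace = TRUE,
                          prob = density(0:(len - 2000))))
    ends <- pmin(len, starts + sample(2500:5000, 60, replace = TRUE))
    p <- make_piles("r", len, starts, ends)
    ann <- detect_repeat_annotations(p, window = 100)  # auto gradient_min
    expect_equal(nrow(ann), 0)
  }
})

test_that("bridging is decided by annotation-pair confinement", {
  # a read spanning a whole short repeat: cross-copy piles start at 3000 and
  # end at 6000, never extending past either side
  set.seed(31)
  sp_s <- 3000 + sample(-30:30, 18, replace = TRUE)
  sp_e <- 6000 + sample(-30:30, 18, replace = TRUE)
  own_s <- sample(500:2500, 10); own_e <- pmin(10000, own_s + 6000)
  p <- make_piles("r", 10000, c(sp_s, own_s), c(sp_e, own_e))
  ann <- detect_repeat_annotations(p, gradient_min = 10)
  expect_setequal(ann$kind, c("start_repeat", "end_repeat"))
  ann2 <- mark_bridged(ann, p)
  expect_true(all(ann2$bridged))

  # enter-only read: piles start at the boundary but end wherever their
  # partner happens to end; a single start annotation is never bridged
  pe <- make_piles("r", 10000, c(sp_s, own_s),
                   pmin(10000, c(sp_s, own_s) +
                          sample(2000:4800, 28, replace = TRUE)))
  anne <- detect_repeat_annotations(pe, gradient_min = 10)
  anne2 <- mark_bridged(anne, pe)
  expect_false(any(anne2$bridged))

  # repeat within a longer repeat: piles start at the outer annotation but
  # most extend past the would-be end annotation -> confinement fails
  out_s <- 2000 + sample(-30:30, 15, replace = TRUE)
  out_e <- pmin(10000, out_s + sample(5500:7500, 15, replace = TRUE))
  inner_e <- 5000 + sample(-30:30, 15, replace = TRUE)
  inner_s <- pmax(0, inner_e - sample(2000:4000, 15, replace = TRUE))
  pn <- make_piles("r", 10000, c(out_s, inner_s), c(out_e, inner_e))
  annn <- detect_repeat_annotations(pn, gradient_min = 10)
  annn2 <- mark_bridged(annn, pn)
  expect_false(any(annn2$bridged[annn2$kind == "start_repeat" &
                                   abs(annn2$pos - 2000) < 200]))
})

test_that("containment filtering keeps exactly the maximal reads", {
  lens <- c(a = 10000L, b = 6000L, c = 9500L, d = 7000L)
  rec <- data.table::data.table(
    qname = c("b", "x"), qlen = c(6000L, 1L),
    qstart = c(0L, 0L), qend = c(6000L, 1L), strand = "+",
    tname = c("a", "y"), tlen = c(10000L, 1L),
    tstart = c(2000L, 0L), tend = c(8000L, 1L),
    nmatch = 1L, blen = 1L, mapq = 60L, cg = NA_character_, dv = NA_real_)
  rec <- classify_matches(rec[1, ], 100)
  # b inside a -> b removed, everyone else untouched
  expect_setequal(filter_contained_reads(rec, lens), c("a", "c", "d"))

  # no containments -> all survive
  rec2 <- data.table::copy(rec); rec2$class <- "suffix_prefix_overlap"
  expect_setequal(filter_contained_reads(rec2, lens), names(lens))

  # near-equal mutual containment: exactly one of the pair survives
  recm <- data.table::data.table(
    qname = "a", qlen = 10000L, qstart = 30L, qend = 9990L, strand = "+",
    tname = "c", tlen = 9500L, tstart = 0L, tend = 9460L,
    nmatch = 9000L, blen = 9960L, mapq = 60L, cg = NA_character_,
    dv = NA_real_)
  recm <- classify_matches(recm, 100)
  surv <- filter_contained_reads(recm, lens)
  expect_equal(sum(c("a", "c") %in% surv), 1)
  expect_true("a" %in% surv)  # the longer read wins

  # containment chain c in a, b in c (no direct b-a record): c is removed
  # because its container a survives; b then survives by the rule "removed
  # only if contained in a SURVIVING read" -- at least one read per chain
  # always remains
  chain <- data.table::rbindlist(list(
    data.table::data.table(qname = "c", qlen = 9500L, qstart = 0L,
                           qend = 9500L, strand = "+", tname = "a",
                           tlen = 10000L, tstart = 200L, tend = 9800L,
                           nmatch = 9000L, blen = 9600L, mapq = 60L,
                           cg = NA_character_, dv = NA_real_),
    data.table::data.table(qname = "b", qlen = 6000L, qstart = 0L,
                           qend = 6000L, strand = "+", tname = "c",
                           tlen = 9500L, tstart = 1000L, tend = 7100L,
                           nmatch = 5500L, blen = 6100L, mapq = 60L,
                           cg = NA_character_, dv = NA_real_)))
  chain <- classify_matches(chain, 100)
  expect_setequal(filter_contained_reads(chain, lens), c("a", "b", "d"))
})

test_that("annotations land on true repeat boundaries in simulation", {
  run <- motif_run("unbridged_pair", seed = 1)
  truth <- run$truth; sim <- run$sim; res <- run$res
  L <- nchar(truth$seqs[[1]])
  cp <- truth$repeat_copies
  boundaries <- c(cp$start, cp$end)
  ann <- res$annotations
  o <- sim$origins[sim$origins$segment == 1L, ]
  a <- merge(ann, o, by = "read_id")
  gpos <- ifelse(a$strand == "+", (a$start + a$pos) %% L,
                 (a$start + a$length - a$pos) %% L)
  d <- circ_dist(gpos, boundaries, L)
  # well-supported annotations sit on true boundaries
  expect_gte(mean(d[a$support >= 10] <= 300), 0.95)
  expect_gt(sum(a$support >= 10), 20)
})
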