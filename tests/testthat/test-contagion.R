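# Micro-scenarios with hand-laid annotations and alignment records: three
# reads covering the start of a repeat from two copies (the overlap kill and
# the internal-match kill), a bridging read that poisons its victims, and
# the strand-flip of annotation kinds across opposite-strand alignments.

ann_row <- function(read_id, pos, kind, bridged = FALSE, ann_id) {
  data.table::data.table(read_id = read_id, pos = as.integer(pos),
                         kind = kind, support = 20L, status = "active",
                         bridged = bridged, ann_id = as.integer(ann_id))
}

rec_row <- function(q, qlen, qs, qe, t, tlen, ts, te, strand = "+") {
  r <- data.table::data.table(
    qname = q, qlen = as.integer(qlen), qstart = as.integer(qs),
    qend = as.integer(qe), strand = strand, tname = t,
    tlen = as.integer(tlen), tstart = as.integer(ts), tend = as.integer(te),
    nmatch = as.integer(0.9 * (qe - qs)), blen = as.integer(qe - qs),
    mapq = 60L, cg = NA_character_, dv = NA_real_)
  classify_matches(r, 100)
}

# Reads around one repeat-start boundary B:
#   u1 covers [B-1000, B+9000)  -> start annotation at 1000, deepest
#   u2 covers [B-3000, B+7000)  -> start annotation at 3000, overlaps u1
#   u3 covers [B'-5000, B'+5000) on the OTHER copy -> annotation at 5000,
#      shares only repeat sequence with u1/u2 (internal matches)
start_scenario <- function() {
  lens <- c(u1 = 10000L, u2 = 10000L, u3 = 10000L)
  ann <- data.table::rbindlist(list(
    ann_row("u1", 1000, "start_repeat", ann_id = 1),
    ann_row("u2", 3000, "start_repeat", ann_id = 2),
    ann_row("u3", 5000, "start_repeat", ann_id = 3)))
  rec <- data.table::rbindlist(list(
    rec_row("u1", 10000, 0, 8000, "u2", 10000, 2000, 10000),
    rec_row("u1", 10000, 1000, 6000, "u3", 10000, 5000, 10000),
    rec_row("u2", 10000, 3000, 8000, "u3", 10000, 5000, 10000)))
  list(lens = lens, ann = ann, rec = rec)
}

test_that("the contagion graph connects same-boundary annotations, oriented by extension", {
  sc <- start_scenario()
  g <- build_contagion_graph(sc$ann, sc$rec, sc$lens, 300)
  # one component of three annotations
  expect_equal(length(unique(g$ann$component)), 1)
  # edges point from lesser to greater extension: u2->u1, u3->u1, u3->u2
  e <- g$edges[order(g$edges$from, g$edges$to), ]
  expect_equal(nrow(e), 3)
  expect_equal(e$from, c(2L, 3L, 3L))
  expect_equal(e$to, c(1L, 1L, 2L))

  # a single annotated read has no edges
  g1 <- build_contagion_graph(sc$ann[1, ], sc$rec, sc$lens, 300)
  expect_equal(nrow(g1$edges), 0)
})

test_that("the kill passes leave one survivor which becomes the hinge", {
  sc <- start_scenario()
  g <- build_contagion_graph(sc$ann, sc$rec, sc$lens, 300)
  g <- prune_small_components(g, 3)
  expect_true(all(g$ann$status == "active"))  # component large enough

  g <- kill_by_overlap(g)
  expect_equal(g$ann$status[g$ann$ann_id == 2], "killed")  # overlap kill
  expect_equal(g$ann$status[g$ann$ann_id == 1], "active")

  g <- kill_by_internal_match(g)
  expect_equal(g$ann$status[g$ann$ann_id == 3], "killed")  # internal kill

  out <- place_hinges(g)
  expect_equal(nrow(out$hinges), 1)
  expect_equal(out$hinges$read_id, "u1")
  expect_equal(out$hinges$direction, "in_hinge")
  expect_equal(nrow(out$poisoned), 0)
})

test_that("small components are pruned", {
  sc <- start_scenario()
  # a stray annotation with no matching partner forms a singleton component
  ann <- rbind(sc$ann, ann_row("u1", 8000, "end_repeat", ann_id = 4))
  g <- build_contagion_graph(ann, sc$rec, sc$lens, 300)
  g3 <- prune_small_components(g, 3)
  expect_equal(g3$ann$status[g3$ann$ann_id == 4], "killed")
  # min_size = 1 is a no-op
  g1 <- prune_small_components(build_contagion_graph(ann, sc$rec, sc$lens, 300), 1)
  expect_true(all(g1$ann$status == "active"))
})

test_that("victims of a bridged killer are poisoned, and poisoning spreads down kill chains", {
  # w bridges the repeat: its start annotation is (locally) bridged and it
  # extends deepest; u1 enters the same copy and overlaps w
  lens <- c(u1 = 10000L, u2 = 10000L, w = 12000L)
  ann <- data.table::rbindlist(list(
    ann_row("u1", 4000, "start_repeat", ann_id = 1),
    ann_row("u2", 6000, "start_repeat", ann_id = 2),
    ann_row("w", 2000, "start_repeat", bridged = TRUE, ann_id = 3)))
  rec <- data.table::rbindlist(list(
    rec_row("u1", 10000, 2000, 10000, "w", 12000, 0, 8000),
    rec_row("u1", 10000, 0, 8000, "u2", 10000, 2000, 10000)))
  g <- build_contagion_graph(ann, rec, lens, 300)
  g <- kill_by_overlap(g)
  expect_equal(g$ann$status[g$ann$ann_id == 1], "poisoned")  # killed by w
  expect_equal(g$ann$status[g$ann$ann_id == 2], "poisoned")  # killed by u1
  out <- place_hinges(g)
  expect_equal(nrow(out$hinges), 0)  # w is bridged, victims poisoned
  expect_setequal(out$poisoned$read_id, c("u1", "u2"))

  # internal-match kills skip poisoned reads entirely
  g2 <- kill_by_internal_match(g)
  expect_identical(g2$ann$status, g$ann$status)
})

test_that("annotation kinds flip across opposite-strand alignments", {
  lens <- c(a = 10000L, b = 10000L)
  ann <- data.table::rbindlist(list(
    ann_row("a", 2000, "start_repeat", ann_id = 1),
    ann_row("b", 8000, "end_repeat", ann_id = 2)))
  rec <- rec_row("a", 10000, 2000, 9000, "b", 10000, 1000, 8000,
                 strand = "-")
  g <- build_contagion_graph(ann, rec, lens, 300)
  expect_equal(nrow(g$edges), 1)
  # same-kind pairing on the same strand would NOT connect them
  ann_same <- data.table::rbindlist(list(
    ann_row("a", 2000, "start_repeat", ann_id = 1),
    ann_row("b", 8000, "end_repeat", ann_id = 2)))
  rec_plus <- rec_row("a", 10000, 2000, 9000, "b", 10000, 1000, 8000, "+")
  g2 <- build_contagion_graph(ann_same, rec_plus, lens, 300)
  expect_equal(nrow(g2$edges), 0)
})

test_that("contagion results do not depend on row order", {
  sc <- start_scenario()
  run <- function(ann, rec) {
    r <- run_contagion(ann, rec, sc$lens, 300, 2)
    r$graph$ann[order(r$graph$ann$ann_id),
                c("ann_id", "status"), with = FALSE]
  }
  ref <- run(sc$ann, sc$rec)
  set.seed(77)
  for (i in 1:5) {
    ann_p <- sc$ann[sample(nrow(sc$ann)), ]
    rec_p <- sc$rec[sample(nrow(sc$rec)), ]
    expect_equal(as.data.frame(run(ann_p, rec_p)), as.data.frame(ref))
  }
})

test_that("kill passes never resurrect annotations", {
  sc <- start_scenario()
  g <- build_contagion_graph(sc$ann, sc$rec, sc$lens, 300)
  g <- prune_small_components(g, 2)
  a1 <- sum(g$ann$status == "active")
  g <- kill_by_overlap(g)
  a2 <- sum(g$ann$status == "active")
  g <- kill_by_internal_match(g)
  a3 <- sum(g$ann$status == "active")
  expect_true(a1 >= a2 && a2 >= a3)
})
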