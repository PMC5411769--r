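make_rec <- function(qname = "a", qlen = 10000L, qstart, qend, strand = "+",
                     tname = "b", tlen = 10000L, tstart, tend) {
  data.table::data.table(qname = qname, qlen = as.integer(qlen),
                         qstart = as.integer(qstart), qend = as.integer(qend),
                         strand = strand, tname = tname,
                         tlen = as.integer(tlen), tstart = as.integer(tstart),
                         tend = as.integer(tend),
                         nmatch = as.integer(qend - qstart),
                         blen = as.integer(qend - qstart), mapq = 60L,
                         cg = NA_character_, dv = NA_real_)
}

test_that("matches classify into overlaps, containments and internal", {
  r1 <- make_rec(qstart = 5000, qend = 10000, tstart = 0, tend = 5000)
  expect_equal(classify_matches(r1, 0)$class, "suffix_prefix_overlap")

  r2 <- make_rec(qstart = 2000, qend = 8000, tlen = 6000, tstart = 0,
                 tend = 6000)
  expect_equal(classify_matches(r2, 0)$class, "b_contained_in_a")

  r3 <- make_rec(qstart = 3000, qend = 6000, tstart = 3000, tend = 6000)
  expect_equal(classify_matches(r3, 0)$class, "internal_match")

  # opposite strand: target coordinates are oriented before the end test
  r4 <- make_rec(qstart = 5000, qend = 10000, strand = "-",
                 tstart = 5000, tend = 10000)
  expect_equal(classify_matches(r4, 0)$class, "suffix_prefix_overlap")

  # mutual containment ties break to a_contained_in_b on the smaller id
  r5 <- make_rec(qstart = 0, qend = 10000, tstart = 0, tend = 10000)
  expect_equal(classify_matches(r5, 0)$class, "a_contained_in_b")

  # out-of-bounds coordinates rejected
  r6 <- make_rec(qstart = 0, qend = 10001, tstart = 0, tend = 5000)
  expect_error(classify_matches(r6, 0), "bounds")
})

test_that("classification commutes with mirroring", {
  set.seed(42)
  mirror_class <- c(suffix_prefix_overlap = "prefix_suffix_overlap",
                    prefix_suffix_overlap = "suffix_prefix_overlap",
                    a_contained_in_b = "b_contained_in_a",
                    b_contained_in_a = "a_contained_in_b",
                    internal_match = "internal_match")
  for (i in 1:50) {
    qlen <- sample(2000:12000, 1); tlen <- sample(2000:12000, 1)
    qs <- sample(0:(qlen - 500), 1); qe <- sample((qs + 400):qlen, 1)
    ts <- sample(0:(tlen - 400), 1); te <- min(tlen, ts + (qe - qs))
    rec <- make_rec(qlen = qlen, qstart = qs, qend = qe,
                    strand = sample(c("+", "-"), 1),
                    tlen = tlen, tstart = ts, tend = te)
    cls <- classify_matches(rec, 100)$class
    mcls <- classify_matches(mirror_records(rec), 100)$class
    expect_identical(mcls, unname(mirror_class[cls]))
  }
})

test_that("PAF files round-trip and malformed input is reported", {
  rec <- data.table::rbindlist(list(
    make_rec(qstart = 100, qend = 900, tstart = 0, tend = 800),
    make_rec(qname = "c", qstart = 0, qend = 500, strand = "-",
             tstart = 200, tend = 700)))
  rec$dv <- c(0.125, NA)
  p <- tempfile(fileext = ".paf")
  write_paf(rec, p)
  back <- read_paf(p)
  expect_equal(as.data.frame(back[, names(rec), with = FALSE]),
               as.data.frame(rec), tolerance = 1e-6)

  # single line
  writeLines("q\t100\t0\t50\t+\tt\t200\t10\t60\t40\t50\t0", p)
  one <- read_paf(p)
  expect_equal(nrow(one), 1)
  expect_equal(one$tstart, 10)

  # empty file
  writeLines(character(0), p)
  expect_equal(nrow(read_paf(p)), 0)

  # malformed line number reported
  writeLines(c("q\t100\t0\t50\t+\tt\t200\t10\t60\t40\t50\t0",
               "garbage\tline"), p)
  expect_error(read_paf(p), "line 2")
})

test_that("trivial overlap cases are found", {
  set.seed(9)
  base <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                collapse = "")
  reads <- c(r1 = base, r2 = base)
  rec <- find_all_overlaps(reads, min_block = 1000)
  expect_gte(nrow(rec), 1)
  expect_true(all(rec$strand == "+"))
  expect_true(any(rec$qend - rec$qstart > 9500))

  reads_rc <- c(r1 = base, r2 = revcomp(base))
  rec_rc <- find_all_overlaps(reads_rc, min_block = 1000)
  expect_gte(nrow(rec_rc), 1)
  expect_true(all(rec_rc$strand == "-"))
})

test_that("overlapper agrees with a brute-force DP aligner at small scale", {
  # 18 zero-error reads of ~1.5-2 kb from a 10 kb circular genome: the truth
  # defines which pairs overlap; the overlapper must find every pair whose
  # true overlap is comfortably above min_block, and every reported pair
  # must be confirmed by Biostrings local alignment
  truth <- make_genome(genome_spec(10000), seed = 31)
  sim <- sample_reads(truth, coverage = 3, mean_length = 1800,
                      length_sd = 150, error_rate = 0.02, seed = 32,
                      min_length = 1400)
  reads <- sim$reads
  o <- sim$origins
  L <- 10000
  rec <- find_all_overlaps(reads, min_block = 400)
  found <- unique(paste(pmin(rec$qname, rec$tname),
                        pmax(rec$qname, rec$tname)))

  ids <- names(reads)
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1)) {
      o1 <- o[o$read_id == ids[i], ][1, ]; o2 <- o[o$read_id == ids[j], ][1, ]
      tov <- 0
      for (shift in c(-L, 0, L)) {
        tov <- max(tov, min(o1$start + o1$length, o2$start + o2$length + shift) -
                     max(o1$start, o2$start + shift))
      }
      key <- paste(min(ids[i], ids[j]), max(ids[i], ids[j]))
      if (tov >= 700) {
        expect_true(key %in% found,
                    label = sprintf("pair %s with true overlap %d found", key, tov))
      }
      if (key %in% found) {
        # confirm with an independent local DP alignment (either strand)
        sc <- function(a, b) Biostrings::pairwiseAlignment(
          a, b, type = "local",
          substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = 1, mismatch = -2),
          gapOpening = 2, gapExtension = 1, scoreOnly = TRUE)
        best <- max(sc(reads[[ids[i]]], reads[[ids[j]]]),
                    sc(reads[[ids[i]]], revcomp(reads[[ids[j]]])))
        expect_gt(best, 300)
      }
    }
  }
})
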