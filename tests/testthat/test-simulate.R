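test_that("genomes honour their specification", {
  # no repeats: plain circular sequence
  tr0 <- make_genome(genome_spec(50000), seed = 1)
  expect_equal(nchar(tr0$seqs[["chromosome"]]), 50000)
  expect_equal(nrow(tr0$repeat_copies), 0)

  # exact two-copy forward repeat: both copies identical
  sp <- genome_spec(c(30000, 30000),
    repeats = list(list(id = "R1", length = 5000,
      placements = list(list(after = 1, orient = "fwd"),
                        list(after = 2, orient = "fwd")))))
  tr <- make_genome(sp, seed = 2)
  expect_equal(nchar(tr$seqs[["chromosome"]]), 70000)
  cp <- tr$repeat_copies
  s1 <- substr(tr$seqs[[1]], cp$start[1] + 1, cp$end[1])
  s2 <- substr(tr$seqs[[1]], cp$start[2] + 1, cp$end[2])
  expect_identical(s1, s2)

  # inverted copy extracts as the reverse complement of the first
  spi <- genome_spec(c(30000, 30000),
    repeats = list(list(id = "R1", length = 5000,
      placements = list(list(after = 1, orient = "fwd"),
                        list(after = 2, orient = "rev")))))
  tri <- make_genome(spi, seed = 2)
  cpi <- tri$repeat_copies
  f <- substr(tri$seqs[[1]], cpi$start[1] + 1, cpi$end[1])
  r <- substr(tri$seqs[[1]], cpi$start[2] + 1, cpi$end[2])
  # independent reverse-complement route
  oracle_rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", f), "")[[1]]),
                     collapse = "")
  expect_identical(r, oracle_rc)

  # divergence bound: copies differ by at most divergence * length
  spd <- genome_spec(c(30000, 30000),
    repeats = list(list(id = "R1", length = 5000, divergence = 0.02,
      placements = list(list(after = 1, orient = "fwd"),
                        list(after = 2, orient = "fwd")))))
  trd <- make_genome(spd, seed = 3)
  cpd <- trd$repeat_copies
  c1 <- strsplit(substr(trd$seqs[[1]], cpd$start[1] + 1, cpd$end[1]), "")[[1]]
  c2 <- strsplit(substr(trd$seqs[[1]], cpd$start[2] + 1, cpd$end[2]), "")[[1]]
  expect_lte(sum(c1 != c2), 2 * floor(0.02 * 5000))
  expect_gt(sum(c1 != c2), 0)

  # invalid specs rejected
  expect_error(genome_spec(c(1000), repeats = list(list(id = "R", length = 10,
    placements = list(list(after = 0, orient = "fwd"),
                      list(after = 0, orient = "fwd"))))), "overlapping")
  expect_error(genome_spec(c(1000), repeats = list(list(id = "R", length = 10,
    divergence = 0.2, placements = list(list(after = 1, orient = "fwd"))))),
    "divergence")
})

test_that("plasmids can share a repeat with the chromosome", {
  sp <- genome_spec(c(40000),
    repeats = list(list(id = "R", length = 4000,
      placements = list(list(after = 1, orient = "fwd")))),
    plasmids = list(list(length = 10000, shared_repeat_id = "R")))
  tr <- make_genome(sp, seed = 4)
  expect_true("plasmid_1" %in% names(tr$seqs))
  cp <- tr$repeat_copies
  expect_setequal(unique(cp$replicon), c("chromosome", "plasmid_1"))
  chr_copy <- substr(tr$seqs[["chromosome"]],
                     cp$start[cp$replicon == "chromosome"] + 1,
                     cp$end[cp$replicon == "chromosome"])
  pl_copy <- substr(tr$seqs[["plasmid_1"]],
                    cp$start[cp$replicon == "plasmid_1"] + 1,
                    cp$end[cp$replicon == "plasmid_1"])
  expect_identical(chr_copy, pl_copy)
})

test_that("read sampling matches the requested conditions", {
  tr <- make_genome(genome_spec(c(100000, 100000)), seed = 5)

  # zero error: every read is an exact (possibly reverse-complemented)
  # substring of the circular genome
  sim0 <- sample_reads(tr, coverage = 3, mean_length = 6000, length_sd = 500,
                       error_rate = 0, seed = 6)
  doubled <- paste0(tr$seqs[[1]], tr$seqs[[1]])
  for (rid in head(names(sim0$reads), 20)) {
    o <- sim0$origins[sim0$origins$read_id == rid, ]
    seq <- sim0$reads[[rid]]
    if (o$strand == "-") seq <- revcomp(seq)
    expect_identical(seq, substr(doubled, o$start + 1, o$start + o$length))
  }

  # coverage conservation at 30x over 200 kb: total bases within 5%
  sim30 <- sample_reads(tr, coverage = 30, mean_length = 10000,
                        length_sd = 1000, error_rate = 0.1, seed = 7)
  expect_gte(sum(nchar(sim30$reads)), 5.7e6)
  expect_lte(sum(nchar(sim30$reads)), 6.3e6)

  # chimera count within 3 sigma of Binomial(n, 0.05)
  simc <- sample_reads(tr, coverage = 50, mean_length = 10000,
                       length_sd = 500, error_rate = 0, chimera_rate = 0.05,
                       seed = 8)
  n <- length(simc$reads)
  k <- sum(unique(simc$origins[, c("read_id", "is_chimeric")])$is_chimeric)
  expect_gt(k, 0.05 * n - 3 * sqrt(n * 0.05 * 0.95))
  expect_lt(k, 0.05 * n + 3 * sqrt(n * 0.05 * 0.95))

  # overlong mean rejected
  expect_error(sample_reads(tr, coverage = 1, mean_length = 5e6, seed = 1),
               "exceeds")
})

test_that("same seed gives byte-identical output, different seed differs", {
  sp <- genome_spec(c(20000),
    repeats = list(list(id = "R", length = 2000,
      placements = list(list(after = 1, orient = "fwd")))))
  t1 <- make_genome(sp, seed = 11); t2 <- make_genome(sp, seed = 11)
  expect_identical(t1$seqs, t2$seqs)
  s1 <- sample_reads(t1, coverage = 5, mean_length = 2000, seed = 12)
  s2 <- sample_reads(t2, coverage = 5, mean_length = 2000, seed = 12)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$origins, s2$origins)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(s1$reads, f1); write_fasta(s2$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  s3 <- sample_reads(t1, coverage = 5, mean_length = 2000, seed = 13)
  expect_false(identical(s1$reads, s3$reads))
})

test_that("bridging control forces and forbids spanning reads", {
  sp <- genome_spec(c(60000, 60000),
    repeats = list(list(id = "R", length = 8000,
      placements = list(list(after = 1, orient = "fwd"),
                        list(after = 2, orient = "fwd")))))
  tr <- make_genome(sp, seed = 20)
  L <- nchar(tr$seqs[[1]])
  cp <- tr$repeat_copies[order(tr$repeat_copies$start), ]
  contains_copy <- function(o, k) {
    off <- ((cp$start[k] - o$start) %% L + L) %% L
    off + (cp$end[k] - cp$start[k]) <= o$length
  }
  # forbidden: no sampled read fully contains any copy
  simf <- sample_reads(tr, coverage = 20, mean_length = 10000,
                       length_sd = 1000, error_rate = 0, seed = 21,
                       forbid_bridge = "R")
  o <- simf$origins[simf$origins$segment == 1L, ]
  for (k in 1:2) {
    expect_equal(sum(vapply(seq_len(nrow(o)), function(i)
      contains_copy(o[i, ], k), TRUE)), 0)
  }
  # forced: the extra read spans its copy
  simb <- sample_reads(tr, coverage = 5, mean_length = 6000,
                       length_sd = 500, error_rate = 0, seed = 22,
                       force_bridge = list(list(repeat_id = "R", copy = 2,
                                                margin = 1500)))
  ob <- simb$origins[grepl("^bridge_", simb$origins$read_id), ]
  expect_equal(nrow(ob), 1)
  expect_true(contains_copy(ob[1, ], 2))
  # per-copy forbid leaves the other copy free to be bridged
  simp <- sample_reads(tr, coverage = 25, mean_length = 12000,
                       length_sd = 500, error_rate = 0, seed = 23,
                       forbid_bridge = "R:1")
  op <- simp$origins
  n1 <- sum(vapply(seq_len(nrow(op)), function(i) contains_copy(op[i, ], 1), TRUE))
  n2 <- sum(vapply(seq_len(nrow(op)), function(i) contains_copy(op[i, ], 2), TRUE))
  expect_equal(n1, 0)
  expect_gt(n2, 0)
})

test_that("fixtures round-trip losslessly through disk", {
  mr <- micro_run()
  d <- file.path(tempdir(), "fixture_rt")
  write_fixture(mr$sim, mr$truth, d)
  back <- read_fixture(d)
  expect_identical(back$reads, mr$sim$reads)
  expect_identical(back$seqs, mr$truth$seqs)
  expect_equal(as.data.frame(back$origins), as.data.frame(mr$sim$origins))
  expect_equal(nrow(back$repeat_copies), nrow(mr$truth$repeat_copies))
  expect_equal(back$replicons$length, unname(nchar(mr$truth$seqs)))
})
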