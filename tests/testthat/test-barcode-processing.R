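flanks <- default_flanks()
bc_ok <- strrep("TG", 15)    # conforms to (WS) x 15
bc_ok2 <- strrep("AC", 15)

test_that("weak/strong pattern matching checks every position and length", {
  expect_true(matches_ws_pattern(bc_ok))
  expect_true(matches_ws_pattern("AGTCAGTCAGTCAGTCAGTCAGTCAGTCAG"))
  bad <- bc_ok
  substr(bad, 2, 2) <- "A"   # A at an S position
  expect_false(matches_ws_pattern(bad))
  expect_false(matches_ws_pattern(substr(bc_ok, 1, 29)))  # 29-mer
  expect_equal(matches_ws_pattern(c(bc_ok, bad)), c(TRUE, FALSE))
  expect_error(matches_ws_pattern(bc_ok, "WX"), "W/S")
})

test_that("quality filter is strict and extraction requires both flanks", {
  read_of <- function(bc) paste0("CCCC", flanks$fwd, bc, flanks$rev, "AAAA")
  L <- nchar(read_of(bc_ok))
  fq <- tempfile(fileext = ".fastq")
  on.exit(unlink(fq))
  q30 <- phred33(30, L)
  q20_at_5 <- q30; substr(q20_at_5, 5, 5) <- phred33(20, 1)
  q21_at_5 <- q30; substr(q21_at_5, 5, 5) <- phred33(21, 1)
  no_rev <- paste0("CCCC", flanks$fwd, bc_ok, "TTTTTTTTTTTT", "AAAA")
  write_fastq_lines(fq,
                    c(read_of(bc_ok), read_of(bc_ok2), read_of(bc_ok),
                      no_rev),
                    c(q30, q20_at_5, q21_at_5, q30))
  counts <- read_and_filter_fastq(fq, flank_fwd = flanks$fwd,
                                  flank_rev = flanks$rev)
  # Q=20 base fails the strictly-greater filter; Q=21 passes; the read
  # without the reverse flank is never counted
  expect_identical(counts, setNames(2L, bc_ok))
  expect_error(suppressWarnings(
    read_and_filter_fastq(tempfile(fileext = ".fastq"))), "FASTQ")
})

test_that("Hamming merging conserves counts and honours the tie-break", {
  err1 <- bc_ok; substr(err1, 3, 3) <- "C"  # 1 mismatch from bc_ok
  counts <- setNames(c(100, 5), c(bc_ok, err1))
  merged <- merge_barcodes(counts)
  expect_identical(as.integer(merged[bc_ok]), 105L)
  expect_length(attr(merged, "unmerged"), 0)
  expect_equal(sum(merged), sum(counts))
  # idempotence on an already-merged census
  again <- merge_barcodes(c(merged))
  expect_equal(c(again), c(merged))
  # distant conforming barcodes are never merged into each other
  both <- setNames(c(10, 3), c(bc_ok, bc_ok2))
  expect_equal(c(merge_barcodes(both)), both[order(names(both))])
  # conforming barcodes beyond max_hamming stay separate even when close
  near3 <- bc_ok
  for (p in c(1, 3, 5)) substr(near3, p, p) <- "A"  # valid, distance 3
  sep <- merge_barcodes(setNames(c(100, 4), c(bc_ok, near3)),
                        max_hamming = 2)
  expect_length(sep, 2)
  # a low-count conforming error merges into its abundant neighbour
  near1 <- bc_ok; substr(near1, 1, 1) <- "A"  # valid, distance 1
  m1 <- merge_barcodes(setNames(c(100, 3), c(bc_ok, near1)))
  expect_identical(as.integer(m1[bc_ok]), 103L)
  # equidistant error merges into the highest-priority representative
  a <- strrep("TG", 15)
  b <- a; substr(b, 1, 1) <- "A"; substr(b, 3, 3) <- "A"  # valid, d(a,b)=2
  err <- a; substr(err, 1, 1) <- "A"; substr(err, 2, 2) <- "A"  # invalid
  # err is at distance 2 from both a and b; equal counts, so the
  # lexicographically first representative (b) wins the tie
  two <- setNames(c(50, 50, 4), c(a, b, err))
  m2 <- merge_barcodes(two)
  expect_identical(as.integer(m2[a]), 50L)
  expect_identical(as.integer(m2[b]), 54L)
  # out-of-range errors survive as flagged singletons
  far <- strrep("CA", 15)  # non-conforming, far from everything
  m3 <- merge_barcodes(setNames(c(20, 2), c(bc_ok, far)), max_hamming = 2)
  expect_identical(attr(m3, "unmerged"), far)
  expect_equal(sum(m3), 22)
})

test_that("count conservation holds on random error clouds", {
  set.seed(77)
  for (rep in 1:5) {
    true_bc <- random_barcodes(20)
    counts <- setNames(rpois(20, 200) + 1, true_bc)
    # sprinkle 1-2 base errors
    for (i in 1:30) {
      b <- sample(true_bc, 1)
      for (k in seq_len(sample(2, 1))) {
        p <- sample(30, 1)
        substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(b, p, p)), 1)
      }
      counts[b] <- sum(counts[b], sample(5, 1), na.rm = TRUE)
    }
    merged <- merge_barcodes(counts)
    expect_equal(sum(merged), sum(counts))
  }
})

test_that("frequencies normalise and round-trip through reads and merging", {
  expect_equal(census_to_frequencies(setNames(c(3, 1), c("b1", "b2"))),
               setNames(c(0.75, 0.25), c("b1", "b2")))
  expect_error(census_to_frequencies(setNames(numeric(0), character(0))),
               "empty")
  single <- barcode_census(setNames(7, bc_ok), "s", "POT")
  expect_equal(unname(single$frequencies), 1)

  # generator -> FASTQ -> filter -> merge recovers the census
  set.seed(91)
  bcs <- random_barcodes(40)
  cen <- barcode_census(setNames(rpois(40, 400) + 50, bcs), "s", "POT")
  fq <- tempfile(fileext = ".fastq")
  on.exit(unlink(fq))
  emit_barcode_reads(cen, fq, depth = 50000, error_rate = 0.003,
                     fail_q_fraction = 0.01, seed = 92)
  merged <- merge_barcodes(read_and_filter_fastq(fq))
  # >= 99% of read mass lands on true barcodes after merging
  expect_gt(sum(merged[names(merged) %in% bcs]) / sum(merged), 0.99)
  f_in <- cen$frequencies[order(names(cen$frequencies))]
  f_out <- census_to_frequencies(merged[names(merged) %in% bcs])
  f_out <- f_out[order(names(f_out))]
  expect_equal(unname(f_out), unname(f_in[names(f_out)]), tolerance = 0.05)
})
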