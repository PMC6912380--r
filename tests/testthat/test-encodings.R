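POLY_A <- strrep("A", 41)  # bypasses the centered-C rule on purpose: the
                           # per-sequence encoders are pure functions of the
                           # string, validation lives in encode_matrix()

test_that("every encoding has its documented dimension on valid windows", {
  s <- random_windows(3, seed = 1)$seq
  dims <- c(Kmer = 1364, BPF = 164, EIIP = 64, M6AMRFS = 200, RFHC = 164,
            DPCP = 240, TPCP = 704)
  for (seq in s) {
    expect_length(encode_kmer(seq), dims[["Kmer"]])
    expect_length(encode_bpf(seq), dims[["BPF"]])
    expect_length(encode_eiip(seq), dims[["EIIP"]])
    expect_length(encode_m6amrfs(seq), dims[["M6AMRFS"]])
    expect_length(encode_rfhc(seq), dims[["RFHC"]])
    expect_length(encode_dpcp(seq), dims[["DPCP"]])
    expect_length(encode_tpcp(seq), dims[["TPCP"]])
    expect_length(encode_dpe(seq), 160)
    expect_length(encode_lpdf(seq), 40)
  }
})

test_that("k-mer blocks are frequencies: each k-block sums to one", {
  v <- encode_kmer(random_windows(1, seed = 2)$seq)
  offsets <- cumsum(c(0, 4, 16, 64, 256))
  sizes <- c(4, 16, 64, 256, 1024)
  for (i in 1:5) {
    expect_equal(sum(v[(offsets[i] + 1):(offsets[i] + sizes[i])]), 1)
  }
})

test_that("k-mer encoding of a single-symbol sequence concentrates on A-runs", {
  v <- encode_kmer(POLY_A)
  expect_equal(unname(v["A"]), 1)
  expect_equal(unname(v["AA"]), 1)
  expect_equal(unname(v["AAAAA"]), 1)
  expect_equal(sum(v != 0), 5)
})

test_that("k-mer, EIIP, DPCP and TPCP match brute-force counting oracles", {
  dt <- random_table(2, 15, seed = 21)
  tt <- random_table(3, 11, seed = 22)
  for (seq in random_windows(8, seed = 3)$seq) {
    expect_equal(unname(encode_kmer(seq)), unname(oracle_kmer(seq)),
                 tolerance = 1e-12)
    expect_equal(unname(encode_eiip(seq)), unname(oracle_eiip(seq)),
                 tolerance = 1e-12)
    expect_equal(unname(encode_dpcp(seq, dt)), unname(oracle_pcp(seq, dt, 2)),
                 tolerance = 1e-12)
    expect_equal(unname(encode_tpcp(seq, tt)), unname(oracle_pcp(seq, tt, 3)),
                 tolerance = 1e-12)
  }
})

test_that("EIIP frequencies normalize: entries divided by their weights sum to 1", {
  seq <- random_windows(1, seed = 4)$seq
  v <- encode_eiip(seq)
  e <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)
  tri <- names(v)
  w <- e[substr(tri, 1, 1)] + e[substr(tri, 2, 2)] + e[substr(tri, 3, 3)]
  expect_equal(sum(v / w), 1, tolerance = 1e-12)
  expect_equal(unname(encode_eiip(POLY_A)["AAA"]), 3 * 0.1260,
               tolerance = 1e-12)
  expect_equal(sum(encode_eiip(POLY_A) != 0), 1)
})

test_that("binary profile is one-hot in A,T,G,C order with 41 ones", {
  seq <- random_windows(1, seed = 5)$seq
  v <- encode_bpf(seq)
  expect_equal(sum(v), 41)
  expect_true(all(v %in% c(0, 1)))
  a_first <- paste0("A", substr(seq, 2, 41))
  expect_equal(unname(encode_bpf(a_first)[1:4]), c(1, 0, 0, 0))
  c_first <- paste0("C", substr(seq, 2, 41))
  expect_equal(unname(encode_bpf(c_first)[1:4]), c(0, 0, 0, 1))
  g_first <- paste0("G", substr(seq, 2, 41))
  expect_equal(unname(encode_bpf(g_first)[1:4]), c(0, 0, 1, 0))
})

test_that("dinucleotide binary code reproduces the four reference tuples", {
  # AT->(0,0,0,1), AA->(0,0,0,0), GG->(1,1,1,1), AC->(0,0,1,0): these pin
  # down the per-base 2-bit code; assert them before trusting anything else.
  first4 <- function(seq) unname(encode_dpe(seq)[1:4])
  pad <- substr(random_windows(1, seed = 6)$seq, 3, 41)
  expect_equal(first4(paste0("AT", pad)), c(0, 0, 0, 1))
  expect_equal(first4(paste0("AA", pad)), c(0, 0, 0, 0))
  expect_equal(first4(paste0("GG", pad)), c(1, 1, 1, 1))
  expect_equal(first4(paste0("AC", pad)), c(0, 0, 1, 0))
  # derived from the inferred per-base code C=(1,0), T=(0,1)
  expect_equal(first4(paste0("CT", pad)), c(1, 0, 0, 1))
})

test_that("local dinucleotide frequencies follow their prefix-count definition", {
  expect_equal(unname(encode_lpdf(POLY_A)), (1:40) / (2:41), tolerance = 1e-12)
  seq <- random_windows(1, seed = 7)$seq
  ac_start <- paste0("AC", substr(seq, 3, 41))
  expect_equal(unname(encode_lpdf(ac_start)[1]), 1 / 2)
  for (s in random_windows(4, seed = 8)$seq) {
    v <- encode_lpdf(s)
    expect_equal(unname(v), oracle_lpdf(s), tolerance = 1e-12)
    expect_true(all(v > 0 & v <= 0.5))
  }
})

test_that("combined encoding concatenates its two parts in order", {
  seq <- random_windows(1, seed = 9)$seq
  v <- encode_m6amrfs(seq)
  expect_equal(v[1:160], encode_dpe(seq))
  expect_equal(unname(v[161:200]), unname(encode_lpdf(seq)))
})

test_that("chemical-class triples and cumulative densities are correct", {
  pad <- substr(random_windows(1, seed = 10)$seq, 3, 41)
  v <- encode_rfhc(paste0("AC", pad))
  expect_equal(unname(v[1:4]), c(1, 1, 1, 1))       # A triple, d_1 = 1
  expect_equal(unname(v[5:8]), c(0, 0, 1, 0.5))     # C triple, one C in 2
  expect_true(all(encode_rfhc(POLY_A)[seq(4, 164, 4)] == 1))
  for (s in random_windows(4, seed = 11)$seq) {
    expect_equal(unname(encode_rfhc(s)), oracle_rfhc(s), tolerance = 1e-12)
  }
})

test_that("property-table structure drives DPCP/TPCP as documented", {
  seq <- random_windows(1, seed = 12)$seq
  # identity table: the 15 entries per dinucleotide all equal its frequency
  v <- encode_dpcp(seq, identity_table(2, 15))
  freq <- matrix(v, nrow = 15)
  expect_true(all(abs(freq - rep(colMeans(freq), each = 15)) < 1e-12))
  expect_equal(sum(colMeans(freq)), 1, tolerance = 1e-12)
  # zero table annihilates
  zt <- identity_table(3, 11) * 0
  expect_true(all(encode_tpcp(seq, zt) == 0))
  # malformed tables are configuration errors
  expect_error(encode_dpcp(seq, identity_table(2, 14)), "property table")
  expect_error(encode_tpcp(seq, identity_table(3, 11) * 2), "\\[0, 1\\]")
})

test_that("encodings are pure and position-aware where documented", {
  seq <- random_windows(1, seed = 13)$seq
  expect_identical(encode_kmer(seq), encode_kmer(seq))
  set.seed(14)
  for (i in 1:5) {
    perm <- paste(sample(strsplit(seq, "")[[1]]), collapse = "")
    expect_equal(encode_kmer(perm)[1:4], encode_kmer(seq)[1:4])  # composition
    expect_false(identical(encode_bpf(perm), encode_bpf(seq)))
  }
})

test_that("encode_matrix validates windows, orders rows, and labels columns", {
  samples <- random_windows(4, seed = 15)
  m <- encode_matrix(samples, "kmer")
  expect_equal(rownames(m), samples$id)
  expect_equal(attr(m, "encoding"), "Kmer")
  expect_equal(colnames(m)[1], "Kmer.1")
  bad <- samples
  bad$seq[2] <- strrep("A", 41)
  expect_error(encode_matrix(bad, "Kmer"), "w002")
  expect_error(encode_matrix(samples, "nope"), "unknown encoding")
})

test_that("bundled property tables satisfy the shape and range invariants", {
  dt <- default_dinuc_table()
  tt <- default_trinuc_table()
  expect_equal(dim(dt), c(16, 15))
  expect_equal(dim(tt), c(64, 11))
  expect_true(all(dt >= 0 & dt <= 1))
  expect_true(all(tt >= 0 & tt <= 1))
  expect_equal(rownames(dt), all_oligos(2))
  expect_equal(rownames(tt), all_oligos(3))
})
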