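# Shared fixtures and independent brute-force oracles. The oracles share no
# code with the package implementation: plain loops over explicit windows.

random_windows <- function(n, seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i) {
    chars <- sample(c("A", "C", "G", "T"), 41, replace = TRUE)
    chars[21] <- "C"
    paste(chars, collapse = "")
  }, character(1))
  dna_samples(sprintf("w%03d", seq_len(n)), seqs)
}

all_oligos <- function(k) {
  sort(do.call(paste0,
               expand.grid(rep(list(c("A", "C", "G", "T")), k),
                           stringsAsFactors = FALSE)))
}

# Count of `word` among the overlapping substrings of `seq`.
oracle_count <- function(seq, word) {
  k <- nchar(word)
  hits <- 0L
  for (i in seq_len(nchar(seq) - k + 1)) {
    if (substr(seq, i, i + k - 1) == word) hits <- hits + 1L
  }
  hits
}

oracle_kmer <- function(seq) {
  unlist(lapply(1:5, function(k) {
    vapply(all_oligos(k), function(w) {
      oracle_count(seq, w) / (nchar(seq) - k + 1)
    }, numeric(1))
  }))
}

oracle_eiip <- function(seq) {
  e <- c(A = 0.1260, C = 0.1340, G = 0.0806, T = 0.1335)
  vapply(all_oligos(3), function(w) {
    b <- strsplit(w, "")[[1]]
    (e[b[1]] + e[b[2]] + e[b[3]]) * oracle_count(seq, w) / 39
  }, numeric(1))
}

oracle_pcp <- function(seq, table, k) {
  nwin <- nchar(seq) - k + 1
  out <- numeric(0)
  for (w in all_oligos(k)) {
    out <- c(out, table[w, ] * oracle_count(seq, w) / nwin)
  }
  out
}

oracle_bpf <- function(seq) {
  code <- list(A = c(1, 0, 0, 0), T = c(0, 1, 0, 0), G = c(0, 0, 1, 0),
               C = c(0, 0, 0, 1))
  out <- numeric(0)
  for (j in seq_len(nchar(seq))) out <- c(out, code[[substr(seq, j, j)]])
  out
}

oracle_dpe <- function(seq) {
  bit2 <- list(A = c(0, 0), C = c(1, 0), G = c(1, 1), T = c(0, 1))
  out <- numeric(0)
  for (j in seq_len(nchar(seq) - 1)) {
    out <- c(out, bit2[[substr(seq, j, j)]], bit2[[substr(seq, j + 1, j + 1)]])
  }
  out
}

oracle_lpdf <- function(seq) {
  vapply(2:nchar(seq), function(j) {
    di <- substr(seq, j - 1, j)
    hits <- 0L
    for (i in 2:j) if (substr(seq, i - 1, i) == di) hits <- hits + 1L
    hits / j
  }, numeric(1))
}

oracle_rfhc <- function(seq) {
  code <- list(A = c(1, 1, 1), T = c(0, 1, 0), G = c(1, 0, 0), C = c(0, 0, 1))
  out <- numeric(0)
  for (j in seq_len(nchar(seq))) {
    b <- substr(seq, j, j)
    d <- oracle_count_prefix(seq, j)
    out <- c(out, code[[b]], d / j)
  }
  out
}

oracle_count_prefix <- function(seq, j) {
  b <- substr(seq, j, j)
  sum(strsplit(substr(seq, 1, j), "")[[1]] == b)
}

# Synthetic property tables with known structure for encoding tests.
identity_table <- function(k, nprop) {
  m <- matrix(1, 4^k, nprop, dimnames = list(all_oligos(k), NULL))
  colnames(m) <- sprintf("p%02d", seq_len(nprop))
  m
}

random_table <- function(k, nprop, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(4^k * nprop), 4^k, nprop,
              dimnames = list(all_oligos(k), sprintf("p%02d", seq_len(nprop))))
  m
}

# Cheap deterministic builder for crossval tests: scores by the C-content
# difference from the training-set class means.
centroid_builder <- function(train, seed) {
  cfrac <- function(s) {
    vapply(s$seq, function(x) mean(strsplit(x, "")[[1]] == "C"), numeric(1))
  }
  mu_pos <- mean(cfrac(train[train$label == "pos", ]))
  mu_neg <- mean(cfrac(train[train$label == "neg", ]))
  function(test) {
    f <- cfrac(test)
    stats::plogis(50 * (f - (mu_pos + mu_neg) / 2) * sign(mu_pos - mu_neg))
  }
}

random_builder <- function(train, seed) {
  function(test) {
    set.seed(seed + nrow(test))
    stats::runif(nrow(test))
  }
}
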