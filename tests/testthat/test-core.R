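toy_dms_dag <- function() {
  src <- from_seq("AAAA")
  mutagenize(src, "single", prefix = "mut")
}

test_that("enumerating a pool yields size-many distinct Hamming-1 variants", {
  p <- toy_dms_dag()
  expect_equal(pool_size(p), 12)
  res <- lapply(0:11, function(s) generate(p, s))
  seqs <- vapply(res, function(r) seq_chars(r$seq), character(1))
  nms <- vapply(res, function(r) r$name, character(1))
  expect_equal(length(unique(seqs)), 12L)
  expect_equal(anyDuplicated(nms), 0L)
  hamming <- vapply(seqs, function(x) {
    sum(strsplit(x, "")[[1]] != strsplit("AAAA", "")[[1]])
  }, numeric(1))
  expect_true(all(hamming == 1))
  # brute-force oracle: all single-nucleotide variants of AAAA
  brute <- unlist(lapply(1:4, function(i) {
    vapply(c("C", "G", "T"), function(b) {
      x <- strsplit("AAAA", "")[[1]]; x[i] <- b; paste(x, collapse = "")
    }, character(1))
  }))
  expect_setequal(seqs, brute)
})

test_that("generate is pure: order-independent, restart-independent", {
  p <- stack_pools(wt = repeat_pool(from_seq("ACGTACGT"), 3, prefix = "rep"),
                   mut = mutagenize(from_seq("ACGTACGT"), "random",
                                    rate = 0.4, n = 5, prefix = "mut"))
  all_states <- 0:(pool_size(p) - 1)
  pass1 <- lapply(all_states, function(s) generate(p, s, master_seed = 7))
  set.seed(99)  # perturb global RNG between passes
  shuffled <- sample(all_states)
  pass2 <- lapply(shuffled, function(s) generate(p, s, master_seed = 7))
  for (i in seq_along(shuffled)) {
    expect_equal(pass2[[i]], pass1[[shuffled[i] + 1]])
  }
  # caller RNG is preserved across generate()
  set.seed(1); before <- .Random.seed
  invisible(generate(p, 5, master_seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("pool_size is purely algebraic (no construction)", {
  p <- stack_pools(a = repeat_pool(from_seq("ACGT"), 10),
                   b = mutagenize(from_seq("ACGT"), "single"))
  n0 <- oligopool:::generation_count()
  expect_equal(pool_size(p), 22)
  expect_equal(oligopool:::generation_count(), n0)
  invisible(generate(p, 0))
  expect_gt(oligopool:::generation_count(), n0)
})

test_that("master seed changes random-mode output only", {
  src <- from_seq("ACGTACGTACGT")
  rnd <- mutagenize(src, "random", rate = 0.5, n = 4)
  seq_a <- seq_chars(generate(rnd, 1, master_seed = 1)$seq)
  seqs_b <- vapply(2:50, function(seed) {
    seq_chars(generate(rnd, 1, master_seed = seed)$seq)
  }, character(1))
  expect_true(any(seqs_b != seq_a))  # random mode responds to the seed

  fixed <- join_pools(from_seq("AC"), from_seq("GT"))
  seqd <- mutagenize(src, "single")
  for (seed in c(0, 1, 42)) {
    expect_equal(seq_chars(generate(fixed, 0, seed)$seq), "ACGT")
    expect_equal(seq_chars(generate(seqd, 7, seed)$seq),
                 seq_chars(generate(seqd, 7, 0)$seq))
  }
})

test_that("print_dag is deterministic, leaves-first, and counts nodes", {
  p <- toy_dms_dag()
  out1 <- capture.output(print_dag(p))
  out2 <- capture.output(print_dag(p))
  expect_identical(out1, out2)

  single <- capture.output(print_dag(from_seq("ACGT")))
  expect_length(single[nzchar(single)], 1L)
  expect_match(single[1], "size=1")

  gb1 <- build_gb1()
  lines <- capture.output(print_dag(gb1))
  lines <- lines[nzchar(lines)]
  expect_length(lines, 6L)  # 1 source + 4 branch operations + 1 stack
  expect_match(lines[1], "from_seqs")
  expect_match(lines[6], "root")
})

test_that("sample_library is seeded, bounded, and warns when n > size", {
  p <- mutagenize(from_seq("ACGTAC"), "single", prefix = "m")
  s1 <- sample_library(p, 5, master_seed = 3)
  s2 <- sample_library(p, 5, master_seed = 3)
  expect_equal(s1, s2)
  states <- vapply(s1, function(r) r$state, numeric(1))
  expect_true(all(states >= 0 & states < pool_size(p)))
  expect_equal(anyDuplicated(states), 0L)

  full <- sample_library(p, pool_size(p))
  expect_equal(vapply(full, function(r) r$state, numeric(1)),
               0:(pool_size(p) - 1))
  expect_warning(sample_library(p, pool_size(p) + 5), "exceeds pool size")
})

test_that("errors carry node and state context", {
  p <- toy_dms_dag()
  expect_error(generate(p, 12), "out of range")
  expect_error(generate(p, -1), "non-negative")
})

test_that("a pool consumed by two downstream operations is well-defined", {
  src <- from_seq("ACGTAC")
  a <- mutagenize(src, "single", prefix = "m1")
  p <- join_pools(a, mutagenize(src, "single", prefix = "m2"))
  expect_equal(pool_size(p), 18 * 18)
  r <- generate(p, 100)
  expect_equal(nchar(seq_chars(r$seq)), 12)
  expect_equal(r$name, generate(p, 100)$name)
})

test_that("random small DAGs enumerate exactly size results, names distinct", {
  ops <- list(
    function(p) repeat_pool(p, sample(2:3, 1), prefix = "rep"),
    function(p) mutagenize(p, "single", prefix = "mut"),
    function(p) flip(p, prefix = "o")
  )
  set.seed(31)
  for (trial in 1:8) {
    src <- from_seqs(vapply(1:sample(1:2, 1), function(i) {
      paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE), collapse = "")
    }, character(1)), prefix = "src")
    depth <- sample(1:2, 1)
    pools <- list(src)
    for (f in ops[sample(length(ops), depth)]) {
      pools[[length(pools) + 1]] <- f(pools[[length(pools)]])
    }
    root <- if (trial %% 2 == 0) {
      stack_pools(a = pools[[length(pools)]], b = src)
    } else {
      pools[[length(pools)]]
    }
    n <- pool_size(root)
    expect_lte(n, 10000)
    res <- lapply(0:(n - 1), function(s) generate(root, s, master_seed = 2))
    nms <- vapply(res, function(r) r$name, character(1))
    expect_length(res, n)
    expect_equal(anyDuplicated(nms), 0L)
  }
})
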