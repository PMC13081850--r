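test_that("sequence sources enumerate and style their members", {
  p1 <- from_seq("ACGT")
  expect_equal(pool_size(p1), 1)
  expect_equal(seq_chars(generate(p1, 0)$seq), "ACGT")

  p3 <- from_seqs(c("AAAA", "CCCC", "GGGG"), style = list(fg = "blue"))
  expect_equal(pool_size(p3), 3)
  r <- generate(p3, 1)
  expect_equal(seq_chars(r$seq), "CCCC")
  expect_true(all(oligopool:::resolve_styles(r$seq)$fg == "blue"))
})

test_that("IUPAC motifs expand mixed-radix, leftmost fastest", {
  expect_equal(pool_size(from_iupac("ACGT")), 1)
  nn <- from_iupac("NN")
  expect_equal(pool_size(nn), 16)
  dimers <- vapply(0:15, function(s) seq_chars(generate(nn, s)$seq),
                   character(1))
  expect_setequal(dimers, as.vector(outer(c("A", "C", "G", "T"),
                                          c("A", "C", "G", "T"), paste0)))
  expect_equal(anyDuplicated(dimers), 0L)

  ay <- from_iupac("AY")
  expect_setequal(vapply(0:1, function(s) seq_chars(generate(ay, s)$seq),
                         character(1)), c("AC", "AT"))
  expect_error(from_iupac("AXGT"), "non-IUPAC")
})

test_that("PWM sources honor column probabilities", {
  onehot <- diag(4)[c(1, 4, 3), ]  # consensus ATG
  p <- from_pwm(onehot, n = 5)
  for (s in 0:4) expect_equal(seq_chars(generate(p, s)$seq), "ATG")

  pwm <- matrix(c(0.7, 0.1, 0.1, 0.1,
                  0.25, 0.25, 0.25, 0.25), 2, 4, byrow = TRUE)
  p2 <- from_pwm(pwm, n = 4000)
  draws <- vapply(0:3999, function(s) {
    seq_chars(generate(p2, s, master_seed = 1)$seq)
  }, character(1))
  first <- substr(draws, 1, 1)
  phat <- mean(first == "A")
  se <- sqrt(0.7 * 0.3 / 4000)
  expect_lt(abs(phat - 0.7), 3 * se)
  # identical keyed draws regardless of call order
  expect_equal(seq_chars(generate(p2, 17, master_seed = 1)$seq), draws[18])
  expect_error(from_pwm(matrix(1, 2, 4), 5), "sum to 1")
})

test_that("random k-mers are seeded and roughly uniform", {
  p <- random_kmers(2, 3000)
  a <- vapply(0:99, function(s) seq_chars(generate(p, s, 5)$seq),
              character(1))
  b <- vapply(0:99, function(s) seq_chars(generate(p, s, 5)$seq),
              character(1))
  expect_identical(a, b)
  draws <- vapply(0:2999, function(s) seq_chars(generate(p, s, 5)$seq),
                  character(1))
  bases <- unlist(strsplit(draws, ""))
  chi <- stats::chisq.test(table(factor(bases, c("A", "C", "G", "T"))))
  expect_gt(chi$p.value, 1e-4)
})

test_that("barcode permutation yields pairwise-distinct covering barcodes", {
  parent <- random_kmers(6, 100)
  tmpl <- join_pools(parent, from_seq("<bc>NNNN</bc>"))
  bcp <- get_barcodes(tmpl, region = "bc", length = 4)
  expect_equal(pool_size(bcp), 100)
  bcs <- vapply(0:99, function(s) {
    generate(bcp, s, master_seed = 3)$card[["bc.barcode"]]
  }, character(1))
  expect_equal(length(unique(bcs)), 100L)
  expect_true(all(nchar(bcs) == 4))

  # minimal length: 4^2 = 16 barcodes for 16 parents is a full permutation
  p16 <- join_pools(from_iupac("NN"), from_seq("<bc>NN</bc>"))
  bcp2 <- get_barcodes(p16, region = "bc", length = 2)
  bcs2 <- vapply(0:15, function(s) {
    generate(bcp2, s, master_seed = 7)$card[["bc.barcode"]]
  }, character(1))
  expect_setequal(bcs2, as.vector(outer(c("A", "C", "G", "T"),
                                        c("A", "C", "G", "T"), paste0)))

  expect_error(get_barcodes(p16, region = "bc", length = 1),
               "cannot cover")
})

test_that("nucleotide mutagenesis respects regions and rates", {
  tpl <- from_seq("AAA<tag>CCCGGG</tag>TTT")
  m <- mutagenize(tpl, "single", region = "tag")
  expect_equal(pool_size(m), 18)
  for (s in 0:17) {
    r <- generate(m, s)
    x <- seq_chars(r$seq)
    expect_equal(substr(x, 1, 3), "AAA")
    expect_equal(substr(x, 10, 12), "TTT")
    expect_true(r$card[["mutagenize.pos"]] >= 3 &&
                  r$card[["mutagenize.pos"]] < 9)
  }
  r0 <- mutagenize(tpl, "random", rate = 0, n = 5)
  for (s in 0:4) {
    expect_equal(seq_chars(generate(r0, s, 9)$seq), "AAACCCGGGTTT")
  }
})

test_that("codon-aware mutagenesis counts and policy are exact", {
  # 3-codon ORF, start excluded: P = 2 eligible residues
  orf <- from_seq("<orf>ATGGGTACC</orf>")
  single <- mutagenize_orf(orf, "single", region = "orf")
  expect_equal(pool_size(single), 38)
  pairwise <- mutagenize_orf(orf, "pairwise", region = "orf")
  expect_equal(pool_size(pairwise), 361)

  # brute-force oracle: translated variants of the single scheme cover
  # every (position, substitute) pair exactly once and never the wild type
  wt <- c("M", "G", "T")
  got <- vapply(0:37, function(s) {
    translate_dna(substr(seq_chars(generate(single, s)$seq), 1, 9))
  }, character(1))
  aa20 <- oligopool:::.AA20
  want <- c(vapply(setdiff(aa20, "G"), function(a) {
    paste0("M", a, "T")
  }, character(1)),
  vapply(setdiff(aa20, "T"), function(a) paste0("MG", a), character(1)))
  expect_setequal(got, want)
  expect_equal(anyDuplicated(got), 0L)

  # policy check on a 10-codon toy ORF: emitted codons translate to the
  # intended substitute, never to the wild type
  pep <- "MKLVNQWERS"
  toy <- from_seq(paste0("<orf>", encode_peptide(pep), "</orf>"))
  ms <- mutagenize_orf(toy, "single", region = "orf")
  expect_equal(pool_size(ms), 9 * 19)
  for (s in seq(0, 9 * 19 - 1)) {
    r <- generate(ms, s)
    aa <- translate_dna(seq_chars(r$seq))
    pos <- r$card[["mutagenize_orf.positions"]]
    expect_equal(substr(aa, pos, pos), r$card[["mutagenize_orf.sub"]])
    expect_false(substr(aa, pos, pos) ==
                   substr(pep, pos, pos))
    # only that codon changed
    expect_equal(sum(strsplit(aa, "")[[1]] != strsplit(pep, "")[[1]]), 1)
  }

  # random scheme marginals: per-position mutation rate near the target
  mr <- mutagenize_orf(toy, "random", region = "orf", rate = 0.3, n = 800)
  nmut <- vapply(0:799, function(s) {
    length(generate(mr, s, 2)$card[["mutagenize_orf.positions"]])
  }, numeric(1))
  expect_lt(abs(mean(nmut) - 9 * 0.3), 3 * sqrt(9 * 0.3 * 0.7 / 800))
})

test_that("deletion scanning slides a window through the region", {
  tpl <- from_seq("AAA<tag>CCCGGG</tag>TTT")
  d <- delete_scan(tpl, "tag", window = 3)
  expect_equal(pool_size(d), 4)
  for (s in 0:3) {
    r <- generate(d, s)
    expect_equal(nchar(seq_chars(r$seq)), 12 - 3)
    rg <- seq_regions(r$seq)
    expect_equal(rg$end - rg$start, 3)
  }
  full <- delete_scan(tpl, "tag", window = 6)
  expect_equal(pool_size(full), 1)
  rg <- seq_regions(generate(full, 0)$seq)
  expect_equal(rg$start, rg$end)  # region collapsed to an anchor
  expect_equal(seq_chars(generate(full, 0)$seq), "AAATTT")
})

test_that("insertion composes pools and shifts coordinates by the delta rule", {
  host <- from_seq("AAAA<site/>CC<down>GG</down>")
  pay <- from_seqs(c("", "TT", "TTTT"))
  p <- insert_at(host, pay, region = "site")
  expect_equal(pool_size(p), 3)
  for (s in 0:2) {
    r <- generate(p, s)
    ins <- c("", "TT", "TTTT")[s + 1]
    expect_equal(seq_chars(r$seq), paste0("AAAA", ins, "CCGG"))
    rg <- seq_regions(r$seq)
    down <- rg[rg$name == "down", ]
    expect_equal(down$start, 6 + nchar(ins))  # delta-shift oracle
    site <- rg[rg$name == "site", ]
    expect_equal(c(site$start, site$end), c(4, 4 + nchar(ins)))
  }
  # sizes multiply with host cardinality
  hosts <- from_seqs(c("AA<a/>", "CC<a/>"))
  p2 <- insert_at(hosts, pay, region = "a")
  expect_equal(pool_size(p2), 6)
})

test_that("shuffle conserves the character multiset within the region", {
  tpl <- from_seq("AC<r>GTTACA</r>GG")
  sh <- shuffle_region(tpl, n = 10, region = "r")
  expect_equal(pool_size(sh), 10)
  for (s in 0:9) {
    x <- seq_chars(generate(sh, s, 4)$seq)
    expect_equal(substr(x, 1, 2), "AC")
    expect_equal(substr(x, 9, 10), "GG")
    expect_equal(sort(strsplit(substr(x, 3, 8), "")[[1]]),
                 sort(strsplit("GTTACA", "")[[1]]))
  }
  expect_identical(seq_chars(generate(sh, 3, 4)$seq),
                   seq_chars(generate(sh, 3, 4)$seq))
  one <- shuffle_region(from_seq("A<r>C</r>G"), n = 3, region = "r")
  for (s in 0:2) expect_equal(seq_chars(generate(one, s)$seq), "ACG")
})

test_that("recombination alternates segments of equal-length parents", {
  a <- from_seq("AAAAAAAA")
  b <- from_seq("CCCCCCCC")
  r0 <- recombine(a, b, n_crossovers = 0, n = 3)
  expect_equal(pool_size(r0), 3)
  for (s in 0:2) expect_equal(seq_chars(generate(r0, s, 1)$seq), "AAAAAAAA")
  r2 <- recombine(a, b, n_crossovers = 2, n = 20)
  for (s in 0:19) {
    res <- generate(r2, s, 1)
    ch <- strsplit(seq_chars(res$seq), "")[[1]]
    expect_true(all(ch %in% c("A", "C")))
    expect_equal(ch[1], "A")  # segments start from parent A
    pts <- res$card[["recombine.crossovers"]]
    expect_equal(length(pts), 2)
  }
  expect_error(generate(recombine(from_seq("AAA"), from_seq("CC"), 1, 2), 0),
               "equal-length")
})

test_that("flip doubles a pool with orientation parity in the state", {
  site <- from_seq("AACG")
  f <- flip(site)
  expect_equal(pool_size(f), 2)
  expect_equal(seq_chars(generate(f, 0)$seq), "AACG")
  expect_equal(seq_chars(generate(f, 1)$seq), "CGTT")

  # parity under the documented digit order, on a size-2 parent
  two <- flip(from_seqs(c("AAAC", "GGGT")))
  got <- vapply(0:3, function(s) seq_chars(generate(two, s)$seq),
                character(1))
  expect_equal(got, c("AAAC", "GTTT", "GGGT", "ACCC"))

  pal <- flip(from_seq("ACGT"))
  r0 <- generate(pal, 0); r1 <- generate(pal, 1)
  expect_equal(seq_chars(r0$seq), seq_chars(r1$seq))
  expect_false(r0$name == r1$name)
})

test_that("join concatenates with shifted regions; stack unions branches", {
  j <- join_pools(from_seq("A<x>C</x>"), from_seq("<y>GT</y>"))
  r <- generate(j, 0)
  expect_equal(seq_chars(r$seq), "ACGT")
  rg <- seq_regions(r$seq)
  expect_equal(rg[rg$name == "y", ]$start, 2)  # offset by left length

  st <- stack_pools(a = from_seqs(c("AA", "AC")), b = from_seq("GG"))
  expect_equal(pool_size(st), 3)
  comps <- vapply(0:2, function(s) {
    generate(st, s)$card[["stack.component"]]
  }, character(1))
  expect_equal(comps, c("a", "a", "b"))
  single <- stack_pools(only = from_seq("ACGT"))
  expect_equal(seq_chars(generate(single, 0)$seq), "ACGT")
})

test_that("multiscan placements are disjoint, in-region, and feasible", {
  tmpl <- from_seq(paste0("TT<cre>", strrep("A", 40), "</cre>TT"))
  sites <- list(m1 = from_seq("CCCCCCCC"), m2 = flip(from_seq("GGGGGTTT")))
  sc <- insert_multiscan(tmpl, sites, region = "cre", n = 60)
  expect_equal(pool_size(sc), 60)
  for (s in 0:59) {
    r <- generate(sc, s, master_seed = 6)
    expect_equal(nchar(seq_chars(r$seq)), 44)  # placements preserve length
    o1 <- r$card[["insert_multiscan.m1_offset"]]
    o2 <- r$card[["insert_multiscan.m2_offset"]]
    expect_true(o1 >= 0 && o1 + 8 <= 40)
    expect_true(o2 >= 0 && o2 + 8 <= 40)
    expect_true(o1 + 8 <= o2 || o2 + 8 <= o1)  # pairwise disjoint
    expect_true(r$card[["insert_multiscan.m2_orient"]] %in% c("fwd", "rev"))
  }
  # a site exactly filling the region is always placed at offset 0
  snug <- insert_multiscan(from_seq("<r>AAAA</r>"),
                           list(s1 = from_seq("CGCG")), region = "r", n = 5)
  for (s in 0:4) {
    expect_equal(generate(snug, s)$card[["insert_multiscan.s1_offset"]], 0)
  }
})

test_that("select, reorder, and filter remap parent states", {
  p <- from_seqs(c("AA", "CC", "GG"))
  sel <- select_states(p, c(2, 0))
  expect_equal(pool_size(sel), 2)
  expect_equal(vapply(0:1, function(s) seq_chars(generate(sel, s)$seq),
                      character(1)), c("GG", "AA"))
  expect_error(select_states(p, 3), "out of range")

  ro <- reorder_states(p, c(1, 2, 0))
  expect_equal(vapply(0:2, function(s) seq_chars(generate(ro, s)$seq),
                      character(1)), c("CC", "GG", "AA"))
  expect_error(reorder_states(p, c(0, 0, 2)), "bijection")

  ident <- filter_pool(p, function(chars) nchar(chars) > 0)
  expect_equal(pool_size(ident), 3)

  # homopolymer screen on all 256 4-mers, vs direct enumeration
  all4 <- from_iupac("NNNN")
  keep <- function(chars) !grepl("AAAA|CCCC|GGGG|TTTT", chars)
  f <- filter_pool(all4, keep)
  brute <- sum(vapply(0:255, function(s) {
    keep(seq_chars(generate(all4, s)$seq))
  }, logical(1)))
  expect_equal(brute, 252)  # 256 minus the four homopolymers
  expect_equal(pool_size(f), brute)
  kept <- vapply(0:(pool_size(f) - 1), function(s) {
    seq_chars(generate(f, s)$seq)
  }, character(1))
  expect_true(all(keep(kept)))
  expect_equal(anyDuplicated(kept), 0L)
})

test_that("stylize and fixed edits change styling or content only", {
  tpl <- from_seq("AAA<tag>CCC</tag>TTT")
  st <- stylize(tpl, region = "tag", bg = "gray")
  r <- generate(st, 0)
  expect_equal(seq_chars(r$seq), "AAACCCTTT")
  expect_match(render_ansi(r$seq), "\033\\[")
  # composes with later mutation styling
  m <- mutagenize(st, "single", region = "tag",
                  style = list(underline = TRUE))
  res <- oligopool:::resolve_styles(generate(m, 0)$seq)
  expect_equal(res$bg[4], "gray")
  expect_true(res$underline[4])

  ed <- edit_seq(tpl, 0, 3, "GGG")
  expect_equal(seq_chars(generate(ed, 0)$seq), "GGGCCCTTT")
})

test_that("repeat replicates members with distinct names", {
  p <- repeat_pool(from_seq("ACGT"), 100, prefix = "rep")
  expect_equal(pool_size(p), 100)
  res <- lapply(0:99, function(s) generate(p, s))
  expect_true(all(vapply(res, function(r) seq_chars(r$seq), character(1))
                  == "ACGT"))
  expect_equal(anyDuplicated(vapply(res, function(r) r$name,
                                    character(1))), 0L)
  one <- repeat_pool(from_seq("ACGT"), 1)
  expect_equal(pool_size(one), 1)
  expect_equal(pool_size(repeat_pool(from_pwm(diag(4)[1:2, ], 10000), 3)),
               30000)
})
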