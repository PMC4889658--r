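test_that("trimming removes the biased flanks exactly", {
  intr <- paste0(strrep("G", 6), "ACGT", strrep("C", 40))  # 50 nt
  expect_equal(trim_interior(intr, "intron"), "ACGT")
  expect_equal(trim_interior(strrep("A", 6), "exon"), "")
  expect_equal(trim_interior(strrep("A", 46), "intron"), "")
  expect_equal(trim_interior("AAATTTAAA", "exon"), "TTT")
  # motifs planted wholly within flanks contribute nothing
  flank_only <- paste0("AATAAA", strrep("C", 20),
                       strrep("G", 34), "AATAAA")
  cnt <- count_motif(trim_interior(flank_only, "intron"), "AATAAA")
  expect_equal(cnt$Ns + cnt$Na, 0L)
})

test_that("motif counting is overlap-inclusive and two-stranded", {
  expect_equal(count_motif("AATAAATAAA", "AATAAA")$Ns, 2L)
  c2 <- count_motif("TTTATTAATAAA", "AATAAA")
  expect_equal(c(c2$Ns, c2$Na), c(1L, 1L))  # revcomp is TTTATT
  expect_equal(unlist(count_motif("CCCCCC", "AATAAA")), c(Ns = 0L, Na = 0L))
  expect_equal(count_motif("AANAAA", "AATAAA")$Ns, 0L)
  expect_equal(count_motif("", "AATAAA")$Ns, 0L)
  expect_error(count_motif("ACGT", ""), "motif")
  expect_error(count_motif("ACGT", "AXT"), "motif")
})

test_that("the asymmetry score follows its closed form and bounds", {
  expect_equal(dsa(6, 4), 0.2)
  expect_equal(dsa(5, 5), 0)
  expect_equal(dsa(7, 0), 1)
  expect_equal(dsa(0, 7), -1)
  expect_true(is.na(dsa(0, 0)))
  expect_equal(dsa(c(6, 5, 7), c(4, 5, 0)), c(0.2, 0, 1))
})

test_that("S is antisymmetric under reverse complement, exactly", {
  set.seed(41)
  regions <- tibble(
    sequence = random_windows(60, 400, prob = c(0.35, 0.2, 0.15, 0.3)),
    kind = "intron", pos_class = sample(c("first", "internal", "last"),
                                        60, replace = TRUE))
  for (m in c("AATAAA", "GGTAAG", "ACG")) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(m)))
    p1 <- dsa_profile(regions, motifs = m)
    p2 <- dsa_profile(regions, motifs = rc)
    expect_equal(p1$S, -p2$S)
    expect_equal(p1$Ns, p2$Na)
    expect_true(all(abs(p1$S) <= 1, na.rm = TRUE))
  }
})

test_that("profiles recover planted asymmetries and symmetric nulls", {
  # sense-only planting on a match-free background
  sense_only <- tibble(
    sequence = vapply(1:30, function(i) {
      paste0(strrep("C", 50), "AATAAA", strrep("C", 50), "AATAAA",
             strrep("C", 50))
    }, ""),
    kind = "intron", pos_class = "internal")
  prof <- dsa_profile(sense_only, motifs = "AATAAA")
  expect_equal(prof$S, 1)
  expect_equal(prof$n_regions, 30L)
  expect_equal(prof$Ns, 60L)

  # strand-symmetric i.i.d. background: S within Monte-Carlo CI of 0
  set.seed(42)
  sym <- tibble(sequence = random_windows(400, 600),
                kind = "intron", pos_class = "internal")
  p0 <- dsa_profile(sym, motifs = "AATAAA")
  expect_lt(abs(p0$S), 3 / sqrt(p0$Ns + p0$Na))

  # anagram controls are reported side by side on the same regions
  multi <- dsa_profile(sym, motifs = c("AATAAA", "TAAAAA", "AAAAAT"))
  expect_equal(nrow(multi), 3L)
  expect_setequal(multi$motif, c("AATAAA", "TAAAAA", "AAAAAT"))

  # empty group: undefined S flagged as NA
  empty <- dsa_profile(tibble(sequence = "CCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCCC",
                              kind = "intron", pos_class = "first"),
                       motifs = "AATAAA")
  expect_true(is.na(empty$S))
})

test_that("planted sense:antisense ratio 3 converges to S = 0.5", {
  set.seed(43)
  seqs <- vapply(1:80, function(i) {
    res <- plant_motif_asymmetry(strrep("C", 3000), "AATAAA",
                                 sense_rate = 3, antisense_rate = 1)
    res$sequence
  }, "")
  cnt <- count_motif(seqs, "AATAAA")
  s_hat <- dsa(sum(cnt$Ns), sum(cnt$Na))
  expect_lt(abs(s_hat - 0.5), 3 / sqrt(sum(cnt$Ns) + sum(cnt$Na)) + 0.02)
})

test_that("co-occurrence by size matches hand counts", {
  # 8 hand-built introns; trimming removes 6 nt / 40 nt, so place
  # motifs in the interior explicitly
  mk <- function(len, motifs_at = list()) {
    s <- paste0("GT", strrep("C", len - 4), "AG")
    for (m in motifs_at) substr(s, m[[2]], m[[2]] + nchar(m[[1]]) - 1) <- m[[1]]
    s
  }
  introns <- tibble(
    sequence = c(
      mk(600, list(list("GGTAAG", 100), list("AATAAA", 300))),  # large, both
      mk(700, list(list("GGTAAG", 100), list("AATAAA", 200))),  # large, both
      mk(800, list(list("GGTAAG", 100))),                       # large, A only
      mk(900, list()),                                          # large, none
      mk(300, list(list("GGTAAG", 100), list("AATAAA", 200))),  # small, both
      mk(200, list(list("AATAAA", 100))),                       # small, B only
      mk(250, list()),                                          # small, none
      mk(100, list())),                                         # small, none
    length = c(600L, 700L, 800L, 900L, 300L, 200L, 250L, 100L))
  res <- cooccurrence_by_size(introns, size_cut = 500)
  expect_equal(as.vector(res$table),
               c(3L, 2L, 1L, 2L))  # small/not_both, large/not_both, ...
  expect_false(res$degenerate)
  expect_equal(glance(res)$df, 1L)

  # independence gives a zero statistic
  expect_equal(chi_square_independence(matrix(10, 2, 2))$statistic, 0)

  # all introns lacking motif A: degenerate, statistic undefined
  none <- introns |> mutate(sequence = gsub("GGTAAG", "CCCCCC", sequence))
  res0 <- cooccurrence_by_size(none, size_cut = 500)
  expect_true(res0$degenerate)
  expect_true(is.na(res0$statistic))
})

test_that("positional classification splits at the boundary", {
  mk1000 <- function(pos_b) {
    s <- paste0("GT", strrep("C", 996), "AG")
    substr(s, 100, 105) <- "GGTAAG"
    substr(s, pos_b, pos_b + 5) <- "AATAAA"
    s
  }
  within_i <- tibble(sequence = mk1000(100 + 50), length = 1000L)
  # offsets measured from the intron 5' end
  res_w <- positional_cooccurrence(tibble(sequence = mk1000(150),
                                          length = 1000L),
                                   length_band = c(900, 1100))
  expect_equal(unname(res_w$table["within"]), 1L)
  res_d <- positional_cooccurrence(tibble(sequence = mk1000(700),
                                          length = 1000L),
                                   length_band = c(900, 1100))
  expect_equal(unname(res_d$table["downstream"]), 1L)
  expect_error(positional_cooccurrence(tibble(sequence = "GTAG",
                                              length = 4L),
                                       length_band = c(900, 1100)),
               "length band")

  # uniformly planted positions match the length-proportional expectation
  set.seed(44)
  seqs <- vapply(1:300, function(i) {
    s <- paste0("GT", strrep("C", 996), "AG")
    substr(s, 100, 105) <- "GGTAAG"
    p <- sample(107:950, 1)
    substr(s, p, p + 5) <- "AATAAA"
    s
  }, "")
  unif <- positional_cooccurrence(tibble(sequence = seqs,
                                         length = rep(1000L, 300)),
                                  length_band = c(900, 1100))
  expect_gt(unif$p, 0.01)
})

test_that("motif ordering counts closest pairs against a 50:50 null", {
  mk <- function(pa, pb) {
    s <- paste0("GT", strrep("C", 996), "AG")
    substr(s, pa, pa + 5) <- "GGTAAG"
    substr(s, pb, pb + 5) <- "AATAAA"
    s
  }
  one <- motif_ordering(tibble(sequence = mk(10 + 6, 100 + 6),
                               length = 1000L))
  expect_equal(unname(one$table["downstream"]), 1L)

  # 60 downstream vs 40 upstream gives chi-square 4.0
  seqs <- c(vapply(1:60, function(i) mk(100, 500), ""),
            vapply(1:40, function(i) mk(500, 100), ""))
  res <- motif_ordering(tibble(sequence = seqs, length = 1000L))
  expect_equal(unname(res$table), c(60L, 40L))
  expect_equal(res$statistic, 4)
  expect_equal(res$df, 1L)

  # symmetric planting stays within the null
  set.seed(45)
  sym <- vapply(1:200, function(i) {
    ps <- sample(c(100, 600), 2)
    mk(ps[1], ps[2])
  }, "")
  res_sym <- motif_ordering(tibble(sequence = sym, length = 1000L))
  expect_gt(res_sym$p, 0.01)
})
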