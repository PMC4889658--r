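# Exhaustive enumeration of all 4^k windows, in the model's outcome order
# (position 1 = least significant base-4 digit, A=0).
all_windows <- function(k) {
  bases <- c("A", "C", "G", "T")
  idx <- 0:(4^k - 1)
  out <- rep("", length(idx))
  for (p in seq_len(k)) {
    out <- paste0(out, bases[(idx %/% 4^(p - 1)) %% 4 + 1])
  }
  out
}

test_that("a fully constrained fit equals the pseudocounted empirical law", {
  set.seed(21)
  w <- random_windows(300, 3, prob = c(0.4, 0.3, 0.2, 0.1))
  fit <- train_maxent(w, maxent_constraints(3, "full"), pseudocount = 1)
  counts <- table(factor(w, levels = all_windows(3))) + 1
  expect_equal(fit$prob, as.numeric(counts / sum(counts)),
               tolerance = 1e-12)
  expect_equal(sum(fit$prob), 1, tolerance = 1e-9)
})

test_that("singleton constraints give the product of empirical marginals", {
  set.seed(22)
  w <- random_windows(200, 2, prob = c(0.5, 0.2, 0.2, 0.1))
  fit <- train_maxent(w, maxent_constraints(2, "singletons"),
                      pseudocount = 0)
  p1 <- as.numeric(table(factor(substr(w, 1, 1),
                                levels = c("A", "C", "G", "T")))) / 200
  p2 <- as.numeric(table(factor(substr(w, 2, 2),
                                levels = c("A", "C", "G", "T")))) / 200
  expect_equal(fit$prob, as.numeric(outer(p1, p2)), tolerance = 1e-9)
  expect_equal(sum(fit$prob), 1, tolerance = 1e-9)
})

test_that("pairwise-coupled data is matched on its pair marginals", {
  # windows from a distribution with first-neighbour coupling
  set.seed(23)
  n <- 600
  x1 <- sample(0:3, n, replace = TRUE, prob = c(0.4, 0.3, 0.2, 0.1))
  x2 <- (x1 + sample(0:1, n, replace = TRUE)) %% 4  # coupled to x1
  x3 <- sample(0:3, n, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  w <- paste0(bases[x1 + 1], bases[x2 + 1], bases[x3 + 1])

  fit <- suppressWarnings(
    train_maxent(w, maxent_constraints(3, "pairs"), pseudocount = 0,
                 tol = 1e-6))
  expect_true(fit$converged)
  expect_equal(sum(fit$prob), 1, tolerance = 1e-9)

  # brute-force oracle: enumerate all 64 outcomes and marginalize by hand
  probs <- setNames(fit$prob, all_windows(3))
  for (pair in list(c(1, 2), c(2, 3))) {
    emp <- table(factor(substr(w, pair[1], pair[1]), levels = bases),
                 factor(substr(w, pair[2], pair[2]), levels = bases)) / n
    fitted <- matrix(0, 4, 4, dimnames = list(bases, bases))
    for (win in names(probs)) {
      a <- substr(win, pair[1], pair[1])
      b <- substr(win, pair[2], pair[2])
      fitted[a, b] <- fitted[a, b] + probs[[win]]
    }
    expect_equal(fitted, unclass(unname(emp)), tolerance = 1e-5,
                 ignore_attr = TRUE)
  }
})

test_that("fitting diagnostics behave: monotone likelihood, invariances", {
  set.seed(24)
  w <- random_windows(250, 4)
  fit <- train_maxent(w, maxent_constraints(4, "pairs"), pseudocount = 1)
  expect_true(all(diff(fit$loglik_trace) > -1e-9))

  # training-set order must not matter
  fit2 <- train_maxent(sample(w), maxent_constraints(4, "pairs"),
                       pseudocount = 1)
  expect_equal(fit$prob, fit2$prob, tolerance = 1e-12)

  # duplicating every window c times leaves the distribution unchanged
  # (pseudocount 0 so the prior mass does not rescale)
  f1 <- train_maxent(w, maxent_constraints(4, "singletons"),
                     pseudocount = 0)
  f3 <- train_maxent(rep(w, 3), maxent_constraints(4, "singletons"),
                     pseudocount = 0)
  expect_equal(f1$prob, f3$prob, tolerance = 1e-12)
})

test_that("invalid training inputs are rejected", {
  expect_error(train_maxent(character(0)), "empty")
  expect_error(train_maxent(c("ACG", "AC")), "inconsistent widths")
  expect_error(train_maxent(c("ACN")), "only A, C, G, T")
  expect_warning(train_maxent(c("AAA", "AAA"),
                              maxent_constraints(3, "full"),
                              pseudocount = 0),
                 "zero empirical marginal")
})

test_that("factorized fits agree with dense fits where both apply", {
  set.seed(25)
  w <- random_windows(300, 6)
  # degenerate layout: one fragment covering everything == dense
  fd <- train_factorized(w, list(1:6), pseudocount = 1)
  dd <- train_maxent(w, maxent_constraints(6, "full"), pseudocount = 1)
  expect_equal(maxent_prob(fd, w[1:20]), maxent_prob(dd, w[1:20]),
               tolerance = 1e-12)

  # independent halves, disjoint fragments == dense fit constrained on
  # the two blocks
  w2 <- paste0(random_windows(400, 3), random_windows(400, 3))
  f2 <- train_factorized(w2, list(1:3, 4:6), pseudocount = 0)
  d2 <- train_maxent(w2, list(1:3, 4:6), pseudocount = 0)
  expect_equal(maxent_prob(f2, w2[1:20]), maxent_prob(d2, w2[1:20]),
               tolerance = 1e-9)

  # chain with overlap normalizes exactly over exhaustive enumeration
  f3 <- train_factorized(random_windows(500, 6), list(1:4, 3:6),
                         pseudocount = 1)
  expect_equal(sum(maxent_prob(f3, all_windows(6))), 1, tolerance = 1e-6)

  # finite log-probabilities for all training windows given pseudocount
  expect_true(all(is.finite(log(maxent_prob(f3, random_windows(50, 6))))))

  expect_error(train_factorized(w, list(1:3, 5:6)), "uncovered")
})

test_that("scores are log2 odds in bits", {
  set.seed(26)
  w <- random_windows(100, 3)
  fit <- train_maxent(w, maxent_constraints(3, "full"), pseudocount = 1)
  same <- splice_site_model(fit, fit, "donor")
  expect_equal(score_windows(same, w[1:10]), rep(0, 10))

  # single-position closed form: P_sig(A)=0.75 vs P_bg(A)=0.25
  sig <- suppressWarnings(
    train_maxent(c("A", "A", "A", "C"), list(1L), pseudocount = 0))
  bg <- suppressWarnings(
    train_maxent(c("A", "C", "C", "C"), list(1L), pseudocount = 0))
  m <- splice_site_model(sig, bg, "donor")
  expect_equal(score_windows(m, "A"), log2(3), tolerance = 1e-12)
  expect_equal(score_windows(m, "C"), log2(1 / 3), tolerance = 1e-12)

  # exhaustive k=3 oracle: scores match hand-computed log ratios
  w_bg <- random_windows(150, 3, prob = c(0.1, 0.2, 0.3, 0.4))
  bg3 <- train_maxent(w_bg, maxent_constraints(3, "full"), pseudocount = 1)
  m3 <- splice_site_model(fit, bg3, "donor")
  aw <- all_windows(3)
  counts_s <- table(factor(w, levels = aw)) + 1
  counts_b <- table(factor(w_bg, levels = aw)) + 1
  hand <- log2(as.numeric(counts_s / sum(counts_s)) /
                 as.numeric(counts_b / sum(counts_b)))
  expect_equal(score_windows(m3, aw), hand, tolerance = 1e-12)

  # N or missing windows score NA; width mismatch errors
  expect_true(is.na(score_windows(m3, "ANA")))
  expect_true(is.na(score_windows(m3, NA_character_)))
  expect_error(score_windows(m3, "ACGT"), "width")
})

test_that("window collection respects availability and the 32-nt floor", {
  arch <- cached_arch()
  sur <- filter_surveyed(arch$introns, gene_spans(cached_sim()$annotation))
  dw <- collect_training_windows(sur, "donor")
  aw <- collect_training_windows(sur, "acceptor")
  expect_true(all(nchar(dw) == 9))
  expect_true(all(nchar(aw) == 23))
  expect_true(all(substr(dw, 4, 5) == "GT"))
  expect_true(all(substr(aw, 19, 20) == "AG"))
  expect_false(any(grepl("N", c(dw, aw))))
  # donor (6 intronic) and acceptor (20 intronic) windows cannot overlap
  # inside a >= 32-nt intron: 6 + 20 <= 32
  expect_true(all(sur$length >= 26))
})

test_that("decoy background windows carry the obligate dinucleotide only", {
  sim <- cached_sim()
  sel <- select_isoforms(sim$annotation, 1)
  arch <- cached_arch()
  bw <- collect_background_windows(sel, sim$genome, arch$introns, "donor",
                                   n_max = 500, seed = 9)
  expect_true(all(nchar(bw) == 9))
  expect_true(all(substr(bw, 4, 5) == "GT"))
  # annotated donors excluded: decoys never reproduce a real site window
  # at its genomic position, so the overwhelming majority must differ
  expect_lte(length(bw), 500)
  bw2 <- collect_background_windows(sel, sim$genome, arch$introns, "donor",
                                    n_max = 500, seed = 9)
  expect_identical(bw, bw2)
})

test_that("strength quartiles use type-7 percentiles with lower-tie rule", {
  q <- strength_quartiles(1:8)
  expect_equal(q$cuts, c(2.75, 4.5, 6.25))
  cls <- classify_strength(q, 1:8)
  expect_equal(as.integer(table(cls)), rep(2L, 4))
  # boundary score goes to the lower class
  expect_equal(as.character(classify_strength(q, 2.75)), "weak")
  expect_equal(as.character(classify_strength(q, 2.7500001)),
               "moderately weak")
  expect_true(strength_quartiles(c(1, 1, 1, 1, 2))$degenerate)
  expect_error(strength_quartiles(c(1, 2, 3)), "at least 4")
})

test_that("planted donor strength differences are recovered in scores", {
  strong_spec <- synthetic_genome_spec(n_genes = 40,
                                       donor_strength = c(0.85, 0.95),
                                       seed = 31)
  weak_spec <- synthetic_genome_spec(n_genes = 40,
                                     donor_strength = c(0.05, 0.15),
                                     seed = 31)
  get_scores <- function(spec) {
    sim <- generate_genome(spec)
    sel <- select_isoforms(sim$annotation, 1)
    arch <- extract_architecture(sel, sim$genome)
    sur <- filter_surveyed(arch$introns, gene_spans(sim$annotation))
    model <- train_splice_model(sur, site = "donor", background = "mono")
    score_windows(model, sur$donor_window)
  }
  s_strong <- get_scores(strong_spec)
  s_weak <- get_scores(weak_spec)
  expect_gt(mean(s_strong, na.rm = TRUE), mean(s_weak, na.rm = TRUE))
})

test_that("model serialization round-trips byte-identically", {
  arch <- cached_arch()
  sur <- filter_surveyed(arch$introns, gene_spans(cached_sim()$annotation))
  don <- train_splice_model(sur, site = "donor", background = "mono",
                            max_iter = 500)
  acc <- train_splice_model(sur, site = "acceptor", background = "mono",
                            max_iter = 500)
  for (model in list(don, acc)) {
    f1 <- withr::local_tempfile(fileext = ".txt")
    f2 <- withr::local_tempfile(fileext = ".txt")
    write_splice_model(model, f1)
    back <- read_splice_model(f1)
    win <- if (model$site_kind == "donor") {
      sur$donor_window[1:20]
    } else {
      sur$acceptor_window[1:20]
    }
    expect_equal(score_windows(back, win), score_windows(model, win),
                 tolerance = 1e-12)
    write_splice_model(back, f2)
    expect_identical(readLines(f1), readLines(f2))
  }
})
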