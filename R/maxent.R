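#' @section Maximum-entropy splice-site models:
#' Splice-site strength is scored as the log2 odds (bits) of a site's
#' fixed-width window under a signal versus a background maximum-entropy
#' distribution. The signal distribution is the maximum-entropy distribution
#' over all 4^k windows whose marginals on a chosen family of position
#' subsets match the (pseudocounted) empirical marginals of annotated sites;
#' the background is fitted the same way on decoy windows carrying the
#' obligate GT/AG dinucleotide at the correct offset but not annotated as
#' splice sites.
#' @name maxent-models
NULL

BASES <- c("A", "C", "G", "T")

# Encode ACGT windows as an n x k integer matrix with values 0..3.
encode_windows <- function(windows) {
  if (length(windows) == 0) abort("empty training set")
  k <- unique(nchar(windows))
  if (length(k) != 1) abort("windows have inconsistent widths")
  m <- matrix(match(strsplit(paste(windows, collapse = ""), "")[[1]],
                    BASES) - 1L,
              ncol = k, byrow = TRUE)
  if (anyNA(m)) abort("windows must contain only A, C, G, T")
  m
}

# Outcome index (1-based) of each row of `enc` restricted to `positions`.
subset_index <- function(enc, positions) {
  idx <- rep(1L, nrow(enc))
  mult <- 1L
  for (p in positions) {
    idx <- idx + enc[, p] * mult
    mult <- mult * 4L
  }
  idx
}

# Outcome index over `positions` for every cell of the dense 4^k grid.
grid_index <- function(k, positions) {
  cells <- 0:(4^k - 1)
  idx <- rep(1, length(cells))
  mult <- 1
  for (p in positions) {
    idx <- idx + ((cells %/% 4^(p - 1)) %% 4) * mult
    mult <- mult * 4
  }
  as.integer(idx)
}

# Map outcomes of superset `sup` to outcomes of subset `sub` (positions).
sub_of_sup_index <- function(sup, sub) {
  cells <- 0:(4^length(sup) - 1)
  idx <- rep(1, length(cells))
  mult <- 1
  for (p in sub) {
    j <- match(p, sup)
    idx <- idx + ((cells %/% 4^(j - 1)) %% 4) * mult
    mult <- mult * 4
  }
  as.integer(idx)
}

#' Standard constraint families for maximum-entropy fitting
#'
#' @param k Window width.
#' @param scheme `"pairs"` gives all singleton positions plus adjacent
#'   pairs (the default donor layout), `"singletons"` position-wise
#'   independence, `"full"` the single full-order constraint (the fitted
#'   model is then the pseudocounted empirical distribution).
#' @return A list of integer position vectors.
#' @export
maxent_constraints <- function(k, scheme = c("pairs", "singletons", "full")) {
  scheme <- match.arg(scheme)
  singles <- as.list(seq_len(k))
  switch(scheme,
    singletons = singles,
    full = list(seq_len(k)),
    pairs = c(singles, lapply(seq_len(k - 1), function(i) c(i, i + 1L)))
  )
}

#' Fit a dense maximum-entropy sequence distribution
#'
#' Fits, by iterative proportional fitting (a sequential variant of
#' generalized iterative scaling), the maximum-entropy distribution over all
#' 4^k windows subject to matching the empirical marginals of the training
#' windows on each constraint subset. Pseudocounts are applied to the
#' marginal tables of the *maximal* constraint subsets; the targets of
#' subsets contained in a maximal one are derived by marginalization, so the
#' full target family is always self-consistent and the fit converges.
#'
#' @param windows Character vector of equal-width ACGT windows (duplicates
#'   retained).
#' @param constraints List of integer position vectors whose joint marginals
#'   are constrained; every position must appear in at least one subset.
#'   Defaults to singletons plus adjacent pairs.
#' @param pseudocount Added to every cell of each maximal marginal table.
#' @param tol Convergence tolerance on the maximum absolute deviation
#'   between fitted and target marginals.
#' @param max_iter Maximum number of IPF sweeps; exceeding it flags the fit
#'   as non-converged.
#' @return An object of class `"maxent_fit"`: the dense probability vector
#'   (`prob`, length 4^k, base-4 little-endian outcome order with A=0), the
#'   constraint layout, and fit diagnostics (`iterations`, `max_dev`,
#'   `converged`, `loglik_trace` in log2 units).
#' @export
train_maxent <- function(windows, constraints = NULL, pseudocount = 1,
                         tol = 1e-4, max_iter = 10000L) {
  enc <- encode_windows(windows)
  k <- ncol(enc)
  if (k > 12) abort("window too wide for a dense fit; use train_factorized()")
  if (is.null(constraints)) constraints <- maxent_constraints(k, "pairs")
  constraints <- lapply(constraints, as.integer)
  if (anyDuplicated(vapply(constraints, paste, "", collapse = ","))) {
    abort("duplicate constraint subsets")
  }
  covered <- sort(unique(unlist(constraints)))
  if (!identical(covered, seq_len(k)) && !all(seq_len(k) %in% covered)) {
    abort("every position must appear in at least one constraint subset")
  }

  n <- nrow(enc)
  is_maximal <- vapply(seq_along(constraints), function(i) {
    !any(vapply(seq_along(constraints), function(j) {
      j != i && all(constraints[[i]] %in% constraints[[j]]) &&
        length(constraints[[j]]) > length(constraints[[i]])
    }, logical(1)))
  }, logical(1))

  targets <- vector("list", length(constraints))
  denom <- NULL
  for (i in which(is_maximal)) {
    cpos <- constraints[[i]]
    counts <- tabulate(subset_index(enc, cpos), nbins = 4^length(cpos)) +
      pseudocount
    if (pseudocount == 0 && any(counts == 0)) {
      warn(paste0("zero empirical marginal cell with pseudocount 0: ",
                  "fitted probabilities will contain zeros"))
    }
    targets[[i]] <- counts / sum(counts)
  }
  for (i in which(!is_maximal)) {
    sup <- which(is_maximal &
                   vapply(constraints,
                          function(M) all(constraints[[i]] %in% M),
                          logical(1)))[1]
    map <- sub_of_sup_index(constraints[[sup]], constraints[[i]])
    targets[[i]] <- as.vector(rowsum(targets[[sup]], map))
  }

  gidx <- lapply(constraints, function(cpos) grid_index(k, cpos))
  data_idx <- subset_index(enc, seq_len(k))

  p <- rep(1 / 4^k, 4^k)
  loglik <- numeric(0)
  max_dev <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (i in seq_along(constraints)) {
      marg <- as.vector(rowsum(p, gidx[[i]]))
      ratio <- targets[[i]] / marg
      ratio[!is.finite(ratio)] <- 1
      p <- p * ratio[gidx[[i]]]
    }
    p <- p / sum(p)
    max_dev <- max(vapply(seq_along(constraints), function(i) {
      max(abs(as.vector(rowsum(p, gidx[[i]])) - targets[[i]]))
    }, numeric(1)))
    loglik <- c(loglik, sum(log2(pmax(p[data_idx], .Machine$double.xmin))))
    if (max_dev < tol) break
  }

  structure(list(
    k = k, prob = p, constraints = constraints, pseudocount = pseudocount,
    n_train = n, iterations = iter, max_dev = max_dev,
    converged = max_dev < tol, loglik_trace = loglik
  ), class = "maxent_fit")
}

#' Fit a factorized maximum-entropy distribution for wide windows
#'
#' For windows too wide to enumerate densely, the distribution is factorized
#' junction-tree style along a chain of overlapping position fragments:
#' P(x) = P1(x_f1) * prod_i Pi(x_fi) / Pi(x_overlap_i), where each fragment
#' distribution is a dense [train_maxent()] fit and each overlap marginal is
#' obtained from the fragment that introduces it. Written this way the
#' product telescopes into a chain of conditionals and is exactly
#' normalized.
#'
#' @param windows Character vector of equal-width ACGT windows.
#' @param fragment_layout List of integer position vectors, in chain order;
#'   their union must cover every position. Consecutive fragments may
#'   overlap.
#' @param constraints_fn Function of a fragment width returning the
#'   constraint list for that fragment; default constrains the full
#'   fragment joint (the pseudocounted empirical fragment distribution).
#' @inheritParams train_maxent
#' @return An object of class `"maxent_factorized"` holding the per-fragment
#'   fits and overlap layouts.
#' @export
train_factorized <- function(windows, fragment_layout,
                             constraints_fn = NULL, pseudocount = 1,
                             tol = 1e-4, max_iter = 10000L) {
  enc <- encode_windows(windows)
  k <- ncol(enc)
  covered <- sort(unique(unlist(fragment_layout)))
  if (!all(seq_len(k) %in% covered)) {
    abort("fragment layout leaves window positions uncovered")
  }
  if (is.null(constraints_fn)) {
    constraints_fn <- function(m) list(seq_len(m))
  }
  frags <- vector("list", length(fragment_layout))
  for (i in seq_along(fragment_layout)) {
    pos <- as.integer(fragment_layout[[i]])
    sub <- if (all(diff(pos) == 1L)) {
      substr(windows, pos[1], pos[length(pos)])
    } else {
      apply(enc[, pos, drop = FALSE], 1, function(r) {
        paste(BASES[r + 1L], collapse = "")
      })
    }
    fit <- train_maxent(sub, constraints = constraints_fn(length(pos)),
                        pseudocount = pseudocount, tol = tol,
                        max_iter = max_iter)
    overlap <- if (i == 1) integer(0) else {
      intersect(pos, fragment_layout[[i - 1]])
    }
    ov_prob <- if (length(overlap) > 0) {
      as.vector(rowsum(fit$prob, sub_of_sup_index(pos, overlap)))
    } else {
      numeric(0)
    }
    frags[[i]] <- list(positions = pos, fit = fit, overlap = overlap,
                       overlap_prob = ov_prob)
  }
  structure(list(k = k, fragments = frags,
                 n_train = nrow(enc), pseudocount = pseudocount),
            class = "maxent_factorized")
}

#' A zero-order (mononucleotide) background distribution
#'
#' @param sequences Character vector whose pooled base composition defines
#'   the model.
#' @param k Window width the model will score.
#' @return An object of class `"maxent_mono"`.
#' @export
mono_background <- function(sequences, k) {
  tab <- table(factor(strsplit(paste(sequences, collapse = ""), "")[[1]],
                      levels = BASES))
  p <- (as.numeric(tab) + 1) / (sum(tab) + 4)
  structure(list(k = k, base_probs = setNames(p, BASES)),
            class = "maxent_mono")
}

# log2 probability of encoded windows under any fitted model.
model_log2p <- function(model, enc) {
  if (inherits(model, "maxent_fit")) {
    log2(model$prob[subset_index(enc, seq_len(model$k))])
  } else if (inherits(model, "maxent_factorized")) {
    lp <- rep(0, nrow(enc))
    for (fr in model$fragments) {
      lp <- lp + log2(fr$fit$prob[subset_index(enc, fr$positions)])
      if (length(fr$overlap) > 0) {
        lp <- lp - log2(fr$overlap_prob[subset_index(enc, fr$overlap)])
      }
    }
    lp
  } else if (inherits(model, "maxent_mono")) {
    lpb <- log2(model$base_probs)
    rowSums(matrix(lpb[enc + 1L], nrow = nrow(enc)))
  } else {
    abort("unknown model class")
  }
}

#' Probability of windows under a fitted maximum-entropy model
#'
#' @param model A `maxent_fit`, `maxent_factorized`, or `maxent_mono`.
#' @param windows Character vector of windows of the model's width.
#' @return Numeric probabilities.
#' @export
maxent_prob <- function(model, windows) {
  2^model_log2p(model, encode_windows(windows))
}

#' Pair signal and background fits into a splice-site scorer
#'
#' @param signal,background Fitted models sharing the same window width.
#' @param site_kind `"donor"` or `"acceptor"`.
#' @return An object of class `"splice_model"`.
#' @export
splice_site_model <- function(signal, background,
                              site_kind = c("donor", "acceptor")) {
  site_kind <- match.arg(site_kind)
  if (signal$k != background$k) {
    abort("signal and background models have different window widths")
  }
  structure(list(signal = signal, background = background,
                 site_kind = site_kind, k = signal$k),
            class = "splice_model")
}

#' Score splice-site windows in bits
#'
#' Scores each window as log2(P_signal / P_background). Windows containing
#' N (or unavailable, `NA`) get an `NA` score and are dropped from
#' downstream analyses.
#'
#' @param model A [splice_site_model()].
#' @param windows Character vector of windows.
#' @return Numeric vector of scores in bits.
#' @export
score_windows <- function(model, windows) {
  out <- rep(NA_real_, length(windows))
  ok <- !is.na(windows) & !grepl("[^ACGT]", windows)
  if (!any(ok)) return(out)
  w <- windows[ok]
  if (any(nchar(w) != model$k)) abort("window width does not match model")
  enc <- encode_windows(w)
  out[ok] <- model_log2p(model$signal, enc) -
    model_log2p(model$background, enc)
  out
}

#' @export
print.splice_model <- function(x, ...) {
  cat(sprintf("<splice_model> %s, k = %d, signal n = %d, background n = %s\n",
              x$site_kind, x$k, x$signal$n_train %||% NA,
              format(x$background$n_train %||% NA)))
  invisible(x)
}

#' Collect training windows for a splice-site model
#'
#' @param introns Intron tibble from [extract_architecture()] (usually after
#'   [filter_surveyed()]).
#' @param site `"donor"` (9-mers: 3 exonic + 6 intronic nt) or `"acceptor"`
#'   (23-mers: 20 intronic + 3 exonic nt).
#' @return Character vector of available windows (duplicates retained;
#'   windows with N or overhanging a short flanking exon are excluded).
#' @export
collect_training_windows <- function(introns, site = c("donor", "acceptor")) {
  site <- match.arg(site)
  w <- if (site == "donor") {
    introns$donor_window[introns$donor_ok]
  } else {
    introns$acceptor_window[introns$acceptor_ok]
  }
  if (length(w) == 0) abort("empty training set")
  w
}

#' Collect decoy background windows from pre-mRNA sequences
#'
#' Scans the unspliced (pre-mRNA) sequence of every transcript for positions
#' carrying the obligate dinucleotide at the splice-site offset (GT at
#' intronic +1/+2 for donors, AG at -2/-1 for acceptors), excludes the
#' annotated sites themselves and windows containing N, and returns up to
#' `n_max` windows sampled reproducibly.
#'
#' @param transcripts Exon tibble of the selected isoforms.
#' @param genome Genome from [read_genome()].
#' @param introns Intron tibble (annotated sites to exclude).
#' @param site `"donor"` or `"acceptor"`.
#' @param n_max Maximum number of decoys to return (`NULL` = all).
#' @param seed Seed for the decoy subsample.
#' @return Character vector of decoy windows.
#' @export
collect_background_windows <- function(transcripts, genome, introns,
                                       site = c("donor", "acceptor"),
                                       n_max = NULL, seed = 1L) {
  site <- match.arg(site)
  width <- if (site == "donor") 9L else 23L
  dinuc <- if (site == "donor") "GT" else "AG"
  # offset of the obligate dinucleotide's first base within the window
  d_off <- if (site == "donor") 3L else 18L

  spans <- transcripts |>
    group_by(.data$transcript_id) |>
    summarise(chrom = first(.data$chrom), strand = first(.data$strand),
              start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  chrom_str <- setNames(as.character(genome[unique(spans$chrom)]),
                        unique(spans$chrom))

  decoys <- character(0)
  for (i in seq_len(nrow(spans))) {
    tx <- spans$transcript_id[i]
    pre <- substring(chrom_str[spans$chrom[i]], spans$start[i], spans$end[i])
    if (spans$strand[i] == "-") pre <- revcomp(pre)
    L <- nchar(pre)
    if (L < width) next
    hits <- Biostrings::start(
      Biostrings::matchPattern(dinuc, Biostrings::DNAString(pre))
    )
    starts <- hits - d_off
    starts <- starts[starts >= 1 & starts + width - 1 <= L]
    if (length(starts) == 0) next
    # pre-mRNA coordinate of annotated site windows for this transcript
    ints <- introns[introns$transcript_id == tx, , drop = FALSE]
    if (nrow(ints) > 0) {
      if (spans$strand[i] == "+") {
        site_pos <- if (site == "donor") {
          ints$start - spans$start[i] + 1L - 3L
        } else {
          ints$end - spans$start[i] + 1L - 19L
        }
      } else {
        site_pos <- if (site == "donor") {
          spans$end[i] - ints$end + 1L - 3L
        } else {
          spans$end[i] - ints$start + 1L - 19L
        }
      }
      starts <- setdiff(starts, site_pos)
    }
    if (length(starts) == 0) next
    w <- substring(pre, starts, starts + width - 1L)
    decoys <- c(decoys, w[!grepl("[^ACGT]", w)])
  }
  if (length(decoys) == 0) abort("no background windows found")
  if (!is.null(n_max) && length(decoys) > n_max) {
    decoys <- with_seed(seed, sample(decoys, n_max))
  }
  decoys
}

#' Default acceptor fragment layout
#'
#' A chain of three 9-position fragments with 2-position overlaps tiling the
#' 23-mer acceptor window. The obligate AG (window positions 19-20) carries
#' no score because signal and background both fix it.
#'
#' @return List of integer position vectors.
#' @export
acceptor_fragment_layout <- function() {
  list(1:9, 8:16, 15:23)
}

#' Train a full splice-site strength model from surveyed introns
#'
#' Convenience wrapper: collects signal windows, collects (or falls back to
#' a mononucleotide) background, fits the site-appropriate model (dense
#' singleton+adjacent-pair maximum entropy for the 9-mer donor, chain
#' factorization for the 23-mer acceptor), and returns the paired scorer.
#'
#' @inheritParams collect_background_windows
#' @param background `"decoy"` (default) or `"mono"`.
#' @param pseudocount,tol,max_iter Passed to the fitters.
#' @return A [splice_site_model()].
#' @export
train_splice_model <- function(introns, transcripts = NULL, genome = NULL,
                               site = c("donor", "acceptor"),
                               background = c("decoy", "mono"),
                               n_max = NULL, seed = 1L, pseudocount = 1,
                               tol = 1e-4, max_iter = 10000L) {
  site <- match.arg(site)
  background <- match.arg(background)
  sig_win <- collect_training_windows(introns, site)
  fit_one <- function(w) {
    if (site == "donor") {
      train_maxent(w, maxent_constraints(9L, "pairs"),
                   pseudocount = pseudocount, tol = tol,
                   max_iter = max_iter)
    } else {
      train_factorized(w, acceptor_fragment_layout(),
                       pseudocount = pseudocount, tol = tol,
                       max_iter = max_iter)
    }
  }
  signal <- fit_one(sig_win)
  bg <- if (background == "decoy") {
    if (is.null(transcripts) || is.null(genome)) {
      abort("decoy background needs `transcripts` and `genome`")
    }
    bw <- collect_background_windows(transcripts, genome, introns, site,
                                     n_max = n_max, seed = seed)
    fit_one(bw)
  } else {
    mono_background(sig_win, if (site == "donor") 9L else 23L)
  }
  splice_site_model(signal, bg, site)
}

#' Empirical strength quartiles
#'
#' Cut points at the empirical 25/50/75 percentiles of a score vector.
#' Boundary scores belong to the lower class (a score equal to the first
#' cut is "weak").
#'
#' @param scores Numeric scores (at least 4 non-missing values).
#' @return Object of class `"strength_quartiles"`: `cuts` (3 values) and
#'   `labels`; `degenerate` is `TRUE` when the cuts are not strictly
#'   increasing.
#' @export
strength_quartiles <- function(scores) {
  s <- scores[!is.na(scores)]
  if (length(s) < 4) abort("need at least 4 scores")
  cuts <- unname(quantile(s, c(0.25, 0.5, 0.75), type = 7))
  structure(list(cuts = cuts,
                 labels = c("weak", "moderately weak", "moderately strong",
                            "strong"),
                 degenerate = any(diff(cuts) <= 0)),
            class = "strength_quartiles")
}

#' @rdname strength_quartiles
#' @param q A `strength_quartiles` object.
#' @param scores Scores to classify.
#' @return `classify_strength()`: an ordered factor.
#' @export
classify_strength <- function(q, scores) {
  if (q$degenerate) warn("degenerate quartiles: cut points not increasing")
  cut(scores, breaks = c(-Inf, q$cuts, Inf), labels = q$labels,
      right = TRUE, ordered_result = TRUE)
}

#' Serialize a splice-site model to versioned flat text
#'
#' The format is deterministic: re-serializing a round-tripped model is
#' byte-identical.
#'
#' @param model A [splice_site_model()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_splice_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# genarch splice model v1",
               paste0("site\t", model$site_kind),
               paste0("k\t", model$k)), con)
  for (part in c("signal", "background")) {
    write_component(model[[part]], part, con)
  }
  invisible(path)
}

write_component <- function(m, label, con) {
  if (inherits(m, "maxent_fit")) {
    writeLines(c(paste0("component\t", label, "\tdense"),
                 paste0("k\t", m$k),
                 paste0("pseudocount\t", format(m$pseudocount)),
                 paste0("constraints\t",
                        paste(vapply(m$constraints, paste, "",
                                     collapse = ","), collapse = ";")),
                 paste0("prob\t", m$k, "\t", length(m$prob))), con)
    writeLines(sprintf("%.17g", m$prob), con)
  } else if (inherits(m, "maxent_factorized")) {
    writeLines(c(paste0("component\t", label, "\tfactorized"),
                 paste0("k\t", m$k),
                 paste0("n_fragments\t", length(m$fragments))), con)
    for (fr in m$fragments) {
      writeLines(paste0("fragment\t",
                        paste(fr$positions, collapse = ",")), con)
      writeLines(sprintf("%.17g", fr$fit$prob), con)
    }
  } else if (inherits(m, "maxent_mono")) {
    writeLines(c(paste0("component\t", label, "\tmono"),
                 paste0("k\t", m$k),
                 paste0("base_probs\t",
                        paste(sprintf("%.17g", m$base_probs),
                              collapse = ","))), con)
  }
}

#' @rdname write_splice_model
#' @export
read_splice_model <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# genarch splice model")) {
    abort("not a genarch splice model file")
  }
  site <- strsplit(lines[2], "\t")[[1]][2]
  parts <- list()
  i <- 4L
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], "\t")[[1]]
    stopifnot(hdr[1] == "component")
    label <- hdr[2]
    kind <- hdr[3]
    k <- as.integer(strsplit(lines[i + 1L], "\t")[[1]][2])
    if (kind == "dense") {
      pc <- as.numeric(strsplit(lines[i + 2L], "\t")[[1]][2])
      cons <- lapply(strsplit(strsplit(lines[i + 3L], "\t")[[1]][2],
                              ";")[[1]],
                     function(s) as.integer(strsplit(s, ",")[[1]]))
      np <- as.integer(strsplit(lines[i + 4L], "\t")[[1]][3])
      prob <- as.numeric(lines[(i + 5L):(i + 4L + np)])
      parts[[label]] <- structure(
        list(k = k, prob = prob, constraints = cons, pseudocount = pc,
             n_train = NA_integer_, iterations = NA_integer_,
             max_dev = NA_real_, converged = NA, loglik_trace = numeric(0)),
        class = "maxent_fit")
      i <- i + 5L + np
    } else if (kind == "factorized") {
      nf <- as.integer(strsplit(lines[i + 2L], "\t")[[1]][2])
      i <- i + 3L
      frags <- vector("list", nf)
      prev_pos <- integer(0)
      for (f in seq_len(nf)) {
        pos <- as.integer(strsplit(strsplit(lines[i], "\t")[[1]][2],
                                   ",")[[1]])
        np <- 4^length(pos)
        prob <- as.numeric(lines[(i + 1L):(i + np)])
        fit <- structure(
          list(k = length(pos), prob = prob,
               constraints = list(seq_along(pos)), pseudocount = NA_real_,
               n_train = NA_integer_, iterations = NA_integer_,
               max_dev = NA_real_, converged = NA,
               loglik_trace = numeric(0)),
          class = "maxent_fit")
        overlap <- intersect(pos, prev_pos)
        ov_prob <- if (length(overlap) > 0) {
          as.vector(rowsum(prob, sub_of_sup_index(pos, overlap)))
        } else {
          numeric(0)
        }
        frags[[f]] <- list(positions = pos, fit = fit, overlap = overlap,
                           overlap_prob = ov_prob)
        prev_pos <- pos
        i <- i + 1L + np
      }
      parts[[label]] <- structure(
        list(k = k, fragments = frags, n_train = NA_integer_,
             pseudocount = NA_real_),
        class = "maxent_factorized")
    } else if (kind == "mono") {
      bp <- as.numeric(strsplit(strsplit(lines[i + 2L], "\t")[[1]][2],
                                ",")[[1]])
      parts[[label]] <- structure(
        list(k = k, base_probs = setNames(bp, BASES)),
        class = "maxent_mono")
      i <- i + 3L
    } else {
      abort(paste0("unknown component kind: ", kind))
    }
  }
  splice_site_model(parts$signal, parts$background, site)
}
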