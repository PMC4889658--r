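#' Default interior trimming rules for strand-asymmetry counts
#'
#' Nucleotides near feature boundaries are biased by splicing signals, so
#' motif counting is restricted to trimmed interiors: exons lose 3 nt at
#' each end; introns lose 6 nt at the 5' end (donor signal) and 40 nt at
#' the 3' end (polypyrimidine tract and branch site).
#'
#' @return Named list mapping region kind to `c(trim5, trim3)` in nt.
#' @export
default_trim_rules <- function() {
  list(exon = c(3L, 3L), intron = c(6L, 40L))
}

#' Trim a feature sequence to its interior
#'
#' @param sequence Character vector of sequences in transcript orientation.
#' @param kind `"exon"` or `"intron"` (vectorized).
#' @param rules Trim rules, see [default_trim_rules()].
#' @return Character vector of interiors; `""` when the sequence is not
#'   longer than the summed trims.
#' @export
trim_interior <- function(sequence, kind, rules = default_trim_rules()) {
  t5 <- vapply(kind, function(k) rules[[k]][1], integer(1))
  t3 <- vapply(kind, function(k) rules[[k]][2], integer(1))
  len <- nchar(sequence)
  out <- substring(sequence, t5 + 1L, len - t3)
  out[len <= t5 + t3] <- ""
  unname(out)
}

#' Count a motif on both strands of a sequence
#'
#' Overlap-inclusive counts of `motif` (sense strand, Ns) and of its
#' reverse complement (i.e. the motif on the antisense strand, Na) in each
#' sequence. Windows containing N never match.
#'
#' @param sequence Character vector of sequences.
#' @param motif A single ACGT motif.
#' @return A tibble with columns `Ns` and `Na`, one row per sequence.
#' @export
count_motif <- function(sequence, motif) {
  if (!is.character(motif) || length(motif) != 1 || nchar(motif) == 0 ||
      grepl("[^ACGT]", motif)) {
    abort("motif must be a non-empty ACGT string")
  }
  seqs <- Biostrings::DNAStringSet(ifelse(nchar(sequence) == 0, "N",
                                          sequence))
  tibble(
    Ns = Biostrings::vcountPattern(motif, seqs, fixed = TRUE),
    Na = Biostrings::vcountPattern(revcomp(motif), seqs, fixed = TRUE)
  )
}

#' DNA strand asymmetry score
#'
#' S = (Ns - Na) / (Ns + Na): the normalized excess of a motif on the sense
#' strand over the antisense strand. Undefined (`NA`) when both counts are
#' zero.
#'
#' @param Ns,Na Non-negative counts (vectorized).
#' @return Numeric S in \[-1, 1\], `NA` when Ns + Na == 0.
#' @export
dsa <- function(Ns, Na) {
  tot <- Ns + Na
  ifelse(tot == 0, NA_real_, (Ns - Na) / tot)
}

#' Motif set studied by default
#'
#' The canonical polyadenylation hexamer, three weaker variants, the
#' donor-site-like hexamer, and two AATAAA anagram controls.
#'
#' @return Character vector of hexamers.
#' @export
default_motifs <- function() {
  c("AATAAA", "ATTAAA", "AATATA", "TATAAA", "GGTAAG", "TAAAAA", "AAAAAT")
}

#' Strand-asymmetry profile over region classes
#'
#' Counts each motif in the trimmed interior of every region, pools counts
#' within each (motif x region class x optional extra grouping) cell, and
#' reports the pooled-count S together with the secondary mean of
#' per-region S values.
#'
#' @param regions Tibble with columns `sequence`, `kind` (`"exon"` or
#'   `"intron"`), `pos_class`, plus any grouping columns.
#' @param motifs Character vector of motifs.
#' @param group_vars Extra grouping column names (e.g. a strength-quartile
#'   column), or `NULL`.
#' @param rules Trim rules; set to `NULL` to count on untrimmed sequences.
#' @return A tibble: `motif`, `kind`, `pos_class`, grouping columns,
#'   `n_regions`, `Ns`, `Na`, `S` (pooled), `S_mean_region` (mean of
#'   per-region S, regions with zero counts excluded).
#' @export
dsa_profile <- function(regions, motifs = default_motifs(),
                        group_vars = NULL, rules = default_trim_rules()) {
  interior <- if (is.null(rules)) {
    regions$sequence
  } else {
    trim_interior(regions$sequence, regions$kind, rules)
  }
  keys <- c("kind", "pos_class", group_vars)
  purrr::map(motifs, function(m) {
    cnt <- count_motif(interior, m)
    regions |>
      select(dplyr::all_of(keys)) |>
      mutate(Ns = cnt$Ns, Na = cnt$Na, s_region = dsa(cnt$Ns, cnt$Na)) |>
      group_by(dplyr::across(dplyr::all_of(keys))) |>
      summarise(n_regions = n(), Ns = sum(.data$Ns), Na = sum(.data$Na),
                S_mean_region = mean(.data$s_region, na.rm = TRUE),
                .groups = "drop") |>
      mutate(motif = m, S = dsa(.data$Ns, .data$Na))
  }) |>
    purrr::list_rbind() |>
    select("motif", dplyr::all_of(keys), "n_regions", "Ns", "Na", "S",
           "S_mean_region")
}

new_cooccurrence <- function(table, statistic, df, p, method,
                             degenerate = FALSE) {
  structure(list(table = table, statistic = statistic, df = df, p = p,
                 method = method, degenerate = degenerate),
            class = "cooccurrence_table")
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  cat(sprintf("<cooccurrence_table> %s\n", x$method))
  print(x$table)
  if (x$degenerate) {
    cat("statistic undefined (degenerate table)\n")
  } else {
    cat(sprintf("chi-square = %.4g, df = %d, p = %.3g\n",
                x$statistic, x$df, x$p))
  }
  invisible(x)
}

#' Motif co-occurrence by intron size class
#'
#' Classifies every intron by whether both motifs occur in its (trimmed)
#' interior and whether it is longer than `size_cut` nt, and tests
#' independence of co-occurrence and size class with an uncorrected Pearson
#' chi-square.
#'
#' @param introns Intron tibble with `sequence` and `length`.
#' @param motif_a,motif_b The two motifs.
#' @param size_cut Size threshold in nt (classes `> size_cut` vs
#'   `<= size_cut`).
#' @param rules Trim rules (`NULL` = untrimmed).
#' @return A `cooccurrence_table`: 2x2 counts, chi-square, df, p. The
#'   statistic is flagged degenerate when a margin is zero.
#' @export
cooccurrence_by_size <- function(introns, motif_a = "GGTAAG",
                                 motif_b = "AATAAA", size_cut = 500L,
                                 rules = default_trim_rules()) {
  interior <- if (is.null(rules)) {
    introns$sequence
  } else {
    trim_interior(introns$sequence, rep("intron", nrow(introns)), rules)
  }
  has_a <- count_motif(interior, motif_a)$Ns > 0
  has_b <- count_motif(interior, motif_b)$Ns > 0
  both <- factor(has_a & has_b, levels = c(FALSE, TRUE),
                 labels = c("not_both", "both"))
  size_class <- factor(introns$length > size_cut, levels = c(FALSE, TRUE),
                       labels = c("small", "large"))
  tab <- table(size_class, both)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(new_cooccurrence(tab, NA_real_, NA_integer_, NA_real_,
                            "co-occurrence vs size class", TRUE))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  new_cooccurrence(tab, unname(ct$statistic), unname(ct$parameter),
                   ct$p.value, "co-occurrence vs size class")
}

#' Positional distribution of a motif within co-occurring introns
#'
#' Within introns of a given length band that contain both motifs, each
#' occurrence of `motif_b` is classified by whether it starts within the
#' first `boundary` nt of the intron or downstream of it. The observed
#' split is tested (goodness-of-fit chi-square, no correction) against the
#' expectation proportional to the searchable interior length on either
#' side of the boundary.
#'
#' @param introns Intron tibble with `sequence` and `length`.
#' @param motif_a,motif_b Co-occurrence pair; positions are recorded for
#'   `motif_b`.
#' @param length_band Length band `c(lo, hi)` in nt (inclusive).
#' @param boundary Position threshold in nt from the intron 5' end.
#' @param rules Trim rules; motif positions are reported in intron
#'   coordinates regardless.
#' @return A `cooccurrence_table` with observed within/downstream counts.
#' @export
positional_cooccurrence <- function(introns, motif_a = "GGTAAG",
                                    motif_b = "AATAAA",
                                    length_band = c(900L, 1100L),
                                    boundary = 500L,
                                    rules = default_trim_rules()) {
  band <- introns |>
    filter(.data$length >= length_band[1], .data$length <= length_band[2])
  if (nrow(band) == 0) abort("no introns in the requested length band")
  t5 <- if (is.null(rules)) 0L else rules$intron[1]
  t3 <- if (is.null(rules)) 0L else rules$intron[2]
  interior <- if (is.null(rules)) {
    band$sequence
  } else {
    trim_interior(band$sequence, rep("intron", nrow(band)), rules)
  }
  has_a <- count_motif(interior, motif_a)$Ns > 0
  has_b <- count_motif(interior, motif_b)$Ns > 0
  cooc <- which(has_a & has_b)
  n_within <- 0L
  n_down <- 0L
  exp_within <- 0
  exp_down <- 0
  mlen <- nchar(motif_b)
  for (i in cooc) {
    pos <- Biostrings::start(
      Biostrings::matchPattern(motif_b,
                               Biostrings::DNAString(interior[i]),
                               fixed = TRUE)
    ) + t5  # intron coordinates
    n_within <- n_within + sum(pos <= boundary)
    n_down <- n_down + sum(pos > boundary)
    # searchable start positions on either side of the boundary
    lo <- t5 + 1L
    hi <- band$length[i] - t3 - mlen + 1L
    if (hi < lo) next
    exp_within <- exp_within + max(0L, min(boundary, hi) - lo + 1L)
    exp_down <- exp_down + max(0L, hi - max(boundary + 1L, lo) + 1L)
  }
  obs <- c(within = n_within, downstream = n_down)
  if (sum(obs) == 0 || exp_within <= 0 || exp_down <= 0) {
    return(new_cooccurrence(obs, NA_real_, NA_integer_, NA_real_,
                            "motif position vs boundary", TRUE))
  }
  expected <- sum(obs) * c(exp_within, exp_down) / (exp_within + exp_down)
  stat <- sum((obs - expected)^2 / expected)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  new_cooccurrence(obs, stat, 1L, p, "motif position vs boundary")
}

#' Relative ordering of two motifs within introns
#'
#' For every intron containing at least one occurrence of each motif, finds
#' the closest pair (ties broken by the 5'-most start of `motif_a`, then of
#' `motif_b`) and classifies whether `motif_b` lies downstream of
#' `motif_a`. The downstream/upstream split is tested against 50:50 with an
#' uncorrected goodness-of-fit chi-square.
#'
#' @inheritParams cooccurrence_by_size
#' @return A `cooccurrence_table` with downstream/upstream counts.
#' @export
motif_ordering <- function(introns, motif_a = "GGTAAG",
                           motif_b = "AATAAA",
                           rules = default_trim_rules()) {
  interior <- if (is.null(rules)) {
    introns$sequence
  } else {
    trim_interior(introns$sequence, rep("intron", nrow(introns)), rules)
  }
  n_down <- 0L
  n_up <- 0L
  for (s in interior) {
    if (nchar(s) == 0) next
    d <- Biostrings::DNAString(s)
    pa <- Biostrings::start(Biostrings::matchPattern(motif_a, d,
                                                     fixed = TRUE))
    pb <- Biostrings::start(Biostrings::matchPattern(motif_b, d,
                                                     fixed = TRUE))
    if (length(pa) == 0 || length(pb) == 0) next
    grid <- expand.grid(a = pa, b = pb)
    grid$dist <- abs(grid$b - grid$a)
    grid <- grid[order(grid$dist, grid$a, grid$b), , drop = FALSE]
    best <- grid[1, ]
    if (best$b > best$a) n_down <- n_down + 1L else n_up <- n_up + 1L
  }
  obs <- c(downstream = n_down, upstream = n_up)
  if (sum(obs) == 0) {
    return(new_cooccurrence(obs, NA_real_, NA_integer_, NA_real_,
                            "motif ordering vs 50:50", TRUE))
  }
  expected <- rep(sum(obs) / 2, 2)
  stat <- sum((obs - expected)^2 / expected)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  new_cooccurrence(obs, stat, 1L, p, "motif ordering vs 50:50")
}
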