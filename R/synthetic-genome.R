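#' Specification for a synthetic genome with planted structure
#'
#' Describes a genome of multi-exon protein-coding genes whose structural
#' statistics are known by construction, so that every pipeline stage can
#' be validated by parameter recovery. Defaults emulate the surveyed fly
#' architecture: per-class median intron lengths of 145 / 69 / 65 nt
#' (first / internal / last), log-normal length distributions with
#' realistic mean-to-median ratios, AT-rich (60%) background, canonical
#' GT..AG introns with donor windows drawn from a position probability
#' model whose sharpness ("strength") is a per-intron dial, and hexamer
#' motifs planted at controlled sense/antisense rates to realize target
#' strand asymmetries.
#'
#' @param n_genes Number of genes.
#' @param exons_per_gene Integer vector of exon counts sampled uniformly
#'   (>= 3, so every gene has >= 2 introns).
#' @param intron_len Named list (`first`, `internal`, `last`) of
#'   `c(meanlog, sdlog)` for log-normal intron lengths.
#' @param intron_len_range Clamp range for intron lengths, nt.
#' @param exon_len Named list (`first`, `second`, `internal`, `last`) of
#'   `c(meanlog, sdlog)` for exon lengths.
#' @param exon_len_range Clamp range for exon lengths, nt.
#' @param donor_strength Range `c(lo, hi)` of the per-intron donor
#'   sharpness dial in \[0, 1\].
#' @param acceptor_strength Scalar sharpness of the acceptor signal.
#' @param strength_size_rho Latent Gaussian correlation coupling a gene's
#'   intron lengths with its donor sharpness (see
#'   [couple_strength_and_size()]).
#' @param motif_plan Tibble with columns `motif`, `region` (`"intron"` or
#'   `"exon"`), `sense_rate`, `antisense_rate` (insertions per kb of
#'   plantable interior).
#' @param base_probs Background base composition (named, A/C/G/T).
#' @param strand_p Probability that a gene is placed on the minus strand.
#' @param spacer_range Intergenic spacer length range, nt.
#' @param nested_frac Fraction of genes whose largest intron hosts a small
#'   nested two-exon gene (exercises the nested-gene filter).
#' @param chrom_name Chromosome name for the emitted FASTA/GTF.
#' @param seed RNG seed; generation is byte-reproducible given the spec.
#' @return An object of class `"synthetic_genome_spec"`.
#' @export
synthetic_genome_spec <- function(
    n_genes = 200L,
    exons_per_gene = 3:7,
    intron_len = list(first = c(meanlog = log(145), sdlog = 2.18),
                      internal = c(meanlog = log(69), sdlog = 2.35),
                      last = c(meanlog = log(65), sdlog = 1.90)),
    intron_len_range = c(32L, 50000L),
    exon_len = list(first = c(meanlog = log(230), sdlog = 0.90),
                    second = c(meanlog = log(233), sdlog = 0.87),
                    internal = c(meanlog = log(212), sdlog = 1.09),
                    last = c(meanlog = log(596), sdlog = 0.84)),
    exon_len_range = c(10L, 20000L),
    donor_strength = c(0.3, 0.95),
    acceptor_strength = 0.7,
    strength_size_rho = 0,
    motif_plan = tibble(
      motif = c("AATAAA", "GGTAAG"),
      region = c("intron", "intron"),
      sense_rate = c(1.5, 0.4),
      antisense_rate = c(0.5, 0.4)
    ),
    base_probs = c(A = 0.3, C = 0.2, G = 0.2, T = 0.3),
    strand_p = 0.5,
    spacer_range = c(300L, 1000L),
    nested_frac = 0,
    chrom_name = "chrS1",
    seed = 1L) {
  stopifnot(min(exons_per_gene) >= 3,
            all(motif_plan$sense_rate >= 0),
            all(motif_plan$antisense_rate >= 0),
            abs(strength_size_rho) < 1,
            abs(sum(base_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "synthetic_genome_spec")
}

#' Couple intron size and donor strength in a synthetic spec
#'
#' Sets the latent Gaussian correlation `rho` shared between an intron's
#' length quantile and its donor sharpness dial. Because both observables
#' are monotone transforms of the latents, the Kendall tau between intron
#' length and the *latent* sharpness is exactly `2 / pi * asin(rho)`
#' ([expected_latent_tau()]); the tau recovered through maximum-entropy
#' *scores* is attenuated by scoring noise but keeps the sign.
#'
#' @param spec A [synthetic_genome_spec()].
#' @param rho_target Latent correlation, |rho| < 1.
#' @return The modified spec.
#' @export
couple_strength_and_size <- function(spec, rho_target) {
  stopifnot(abs(rho_target) < 1)
  spec$strength_size_rho <- rho_target
  spec
}

#' @rdname couple_strength_and_size
#' @param rho Latent correlation value(s).
#' @export
expected_latent_tau <- function(rho) 2 / pi * asin(rho)

# Donor position probability model: 9 positions (3 exonic + 6 intronic),
# GT fixed at intronic +1/+2. Rows A, C, G, T.
donor_consensus <- function() {
  m <- matrix(c(
    0.45, 0.35, 0.15, 0.05,  # -3
    0.60, 0.10, 0.15, 0.15,  # -2
    0.10, 0.05, 0.80, 0.05,  # -1
    0.00, 0.00, 1.00, 0.00,  # +1 G
    0.00, 0.00, 0.00, 1.00,  # +2 T
    0.60, 0.05, 0.30, 0.05,  # +3
    0.70, 0.05, 0.15, 0.10,  # +4
    0.05, 0.05, 0.80, 0.10,  # +5
    0.20, 0.15, 0.15, 0.50   # +6
  ), nrow = 9, byrow = TRUE, dimnames = list(NULL, BASES))
  m
}

# Acceptor position probability model: 23 positions (20 intronic + 3
# exonic), AG fixed at window positions 19-20.
acceptor_consensus <- function() {
  ppt <- c(0.15, 0.30, 0.10, 0.45)  # pyrimidine-rich tract
  m <- matrix(rep(ppt, 18), nrow = 18, byrow = TRUE)
  m <- rbind(m,
             c(1, 0, 0, 0),          # -2 A
             c(0, 0, 1, 0),          # -1 G
             c(0.25, 0.15, 0.45, 0.15),  # +1
             c(0.30, 0.20, 0.20, 0.30),
             c(0.30, 0.20, 0.20, 0.30))
  colnames(m) <- BASES
  m
}

# Interpolate a consensus model toward background with sharpness w,
# keeping the obligate positions fixed.
dial_pwm <- function(cons, w, base_probs, fixed_rows) {
  out <- (1 - w) * matrix(base_probs, nrow(cons), 4, byrow = TRUE) +
    w * cons
  out[fixed_rows, ] <- cons[fixed_rows, ]
  out
}

sample_pwm <- function(pwm) {
  paste(vapply(seq_len(nrow(pwm)), function(i) {
    sample(BASES, 1L, prob = pwm[i, ])
  }, ""), collapse = "")
}

sample_range <- function(range) {
  range[1] + sample.int(range[2] - range[1] + 1L, 1L) - 1L
}

random_seq <- function(n, base_probs) {
  if (n <= 0) return("")
  paste(sample(BASES, n, replace = TRUE, prob = base_probs), collapse = "")
}

rlnorm_clamped <- function(n, pars, range, q = NULL) {
  x <- if (is.null(q)) {
    rlnorm(n, pars[1], pars[2])
  } else {
    qlnorm(q, pars[1], pars[2])
  }
  as.integer(pmin(pmax(round(x), range[1]), range[2]))
}

#' Plant a motif with controlled strand asymmetry into a sequence
#'
#' Inserts (overwrites in place) Poisson-distributed numbers of sense and
#' antisense copies of `motif` at uniform positions within
#' `allowed_range`, avoiding previously planted copies and any `avoid`
#' intervals. Uses the current RNG state; wrap in a seeded context for
#' reproducibility. With rates `rs` and `ra` per kb the expected strand
#' asymmetry of the planted region set is (rs - ra) / (rs + ra).
#'
#' @param sequence A single character sequence.
#' @param motif ACGT motif.
#' @param sense_rate,antisense_rate Insertions per kb of allowed interior.
#' @param allowed_range `c(lo, hi)`: allowed start positions (1-based;
#'   insertions must also end inside `hi + nchar(motif) - 1`...`hi` rule:
#'   a start at `hi` is allowed only if the motif still fits the range).
#' @param avoid Optional list of `c(lo, hi)` intervals insertions must not
#'   touch.
#' @param max_tries Rejection-sampling cap per insertion.
#' @return List with `sequence` (modified) and `placements` (tibble
#'   `pos`, `strand`).
#' @export
plant_motif_asymmetry <- function(sequence, motif, sense_rate,
                                  antisense_rate,
                                  allowed_range = NULL, avoid = list(),
                                  max_tries = 50L) {
  L <- nchar(sequence)
  mlen <- nchar(motif)
  if (is.null(allowed_range)) allowed_range <- c(1L, L - mlen + 1L)
  lo <- allowed_range[1]
  hi <- min(allowed_range[2], L - mlen + 1L)
  if (hi < lo) {
    return(list(sequence = sequence,
                placements = tibble(pos = integer(0), strand = character(0))))
  }
  span_kb <- (hi - lo + mlen) / 1000
  n_s <- rpois(1, sense_rate * span_kb)
  n_a <- rpois(1, antisense_rate * span_kb)
  strands <- c(rep("sense", n_s), rep("antisense", n_a))
  if (length(strands) > 1) strands <- sample(strands)
  taken <- lapply(avoid, function(iv) iv)
  pos_out <- integer(0)
  str_out <- character(0)
  for (s in strands) {
    ins <- if (s == "sense") motif else revcomp(motif)
    for (try in seq_len(max_tries)) {
      p <- lo + sample.int(hi - lo + 1L, 1L) - 1L
      clash <- any(vapply(taken, function(iv) {
        p <= iv[2] && (p + mlen - 1L) >= iv[1]
      }, logical(1)))
      if (!clash) {
        substr(sequence, p, p + mlen - 1L) <- ins
        taken <- c(taken, list(c(p, p + mlen - 1L)))
        pos_out <- c(pos_out, p)
        str_out <- c(str_out, s)
        break
      }
    }
  }
  list(sequence = sequence,
       placements = tibble(pos = pos_out, strand = str_out))
}

#' Generate a synthetic genome, annotation, and ground truth
#'
#' Builds the genome described by a [synthetic_genome_spec()]: genes are
#' laid out without overlap (except requested nested genes), every intron
#' carries GT..AG termini, donor/acceptor windows are drawn from the
#' spec's signal models, and motifs are planted per the motif plan. The
#' result round-trips through the extraction pipeline to exactly the
#' recorded ground truth.
#'
#' @param spec A [synthetic_genome_spec()].
#' @return An object of class `"synthetic_genome"`: `genome` (a
#'   [Biostrings::DNAStringSet]), `annotation` (exon tibble as returned by
#'   [read_annotation()]), `gtf` (full feature tibble), and `truth` (list
#'   of tibbles `genes`, `exons`, `introns`, `motifs`).
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_genome_spec"))
  with_seed(spec$seed, generate_genome_impl(spec))
}

generate_genome_impl <- function(spec) {
  don_cons <- donor_consensus()
  acc_cons <- acceptor_consensus()
  acc_pwm <- dial_pwm(acc_cons, spec$acceptor_strength, spec$base_probs,
                      fixed_rows = c(19L, 20L))
  n_nested <- round(spec$nested_frac * spec$n_genes)
  nested_hosts <- if (n_nested > 0) {
    sample(spec$n_genes, n_nested)
  } else {
    integer(0)
  }

  segs <- character(0)
  cursor <- 0L  # bases already emitted on the chromosome
  gtf_rows <- list()
  truth_genes <- list()
  truth_exons <- list()
  truth_introns <- list()
  truth_motifs <- list()
  extra_id <- 0L

  for (g in seq_len(spec$n_genes)) {
    gid <- sprintf("SYNG%05d", g)
    tid <- sprintf("SYNT%05d", g)
    n_ex <- if (length(spec$exons_per_gene) == 1) {
      spec$exons_per_gene
    } else {
      sample(spec$exons_per_gene, 1L)
    }
    n_in <- n_ex - 1L
    in_class <- intron_pos_class(seq_len(n_in), n_in)
    ex_class <- exon_pos_class(seq_len(n_ex), n_ex)

    # latent coupling: shared Gaussian drives length quantile + sharpness
    rho <- spec$strength_size_rho
    z_len <- rnorm(n_in)
    z_w <- rho * z_len + sqrt(1 - rho^2) * rnorm(n_in)
    in_len <- vapply(seq_len(n_in), function(i) {
      rlnorm_clamped(1L, spec$intron_len[[in_class[i]]],
                     spec$intron_len_range, q = pnorm(z_len[i]))
    }, integer(1))
    w <- spec$donor_strength[1] +
      diff(spec$donor_strength) * pnorm(z_w)
    ex_len <- unname(vapply(ex_class, function(cl) {
      rlnorm_clamped(1L, spec$exon_len[[cl]], spec$exon_len_range)
    }, integer(1)))

    ex_seq <- vapply(ex_len, random_seq, "",
                     base_probs = spec$base_probs)
    in_seq <- character(n_in)
    reserved <- vector("list", n_in)  # intervals motifs must avoid
    nested_here <- g %in% nested_hosts

    for (i in seq_len(n_in)) {
      don_pwm <- dial_pwm(don_cons, w[i], spec$base_probs,
                          fixed_rows = c(4L, 5L))
      don9 <- sample_pwm(don_pwm)
      acc23 <- sample_pwm(acc_pwm)
      substr(ex_seq[i], ex_len[i] - 2L, ex_len[i]) <- substr(don9, 1, 3)
      substr(ex_seq[i + 1L], 1L, 3L) <- substr(acc23, 21, 23)
      mid <- random_seq(in_len[i] - 26L, spec$base_probs)
      in_seq[i] <- paste0(substr(don9, 4, 9), mid, substr(acc23, 1, 20))
      reserved[[i]] <- list()
    }

    # nested mini-gene inside the largest intron with enough interior
    nested_info <- NULL
    if (nested_here) {
      cand <- which(in_len >= 180L)
      if (length(cand) > 0) {
        host <- cand[which.max(in_len[cand])]
        extra_id <- extra_id + 1L
        mini <- build_mini_gene(spec, acc_pwm, don_cons)
        at <- 30L  # offset inside host intron, clear of splice windows
        substr(in_seq[host], at, at + nchar(mini$seq) - 1L) <- mini$seq
        reserved[[host]] <- c(reserved[[host]],
                              list(c(at, at + nchar(mini$seq) - 1L)))
        nested_info <- list(host = host, at = at, mini = mini,
                            id = extra_id)
      }
    }

    # plant motifs
    for (r in seq_len(nrow(spec$motif_plan))) {
      plan <- spec$motif_plan[r, ]
      if (plan$region == "intron") {
        for (i in seq_len(n_in)) {
          res <- plant_motif_asymmetry(
            in_seq[i], plan$motif, plan$sense_rate, plan$antisense_rate,
            allowed_range = c(7L, in_len[i] - 20L - nchar(plan$motif) + 1L),
            avoid = reserved[[i]])
          in_seq[i] <- res$sequence
          reserved[[i]] <- c(reserved[[i]],
                             lapply(res$placements$pos, function(p) {
                               c(p, p + nchar(plan$motif) - 1L)
                             }))
          if (nrow(res$placements) > 0) {
            truth_motifs[[length(truth_motifs) + 1L]] <-
              res$placements |>
              mutate(gene_id = gid, region = "intron", ordinal = i,
                     motif = plan$motif)
          }
        }
      } else {
        for (i in seq_len(n_ex)) {
          lo <- if (i == 1L) 1L else 4L
          hi <- ex_len[i] - (if (i == n_ex) 0L else 3L) -
            nchar(plan$motif) + 1L
          res <- plant_motif_asymmetry(
            ex_seq[i], plan$motif, plan$sense_rate, plan$antisense_rate,
            allowed_range = c(lo, hi))
          ex_seq[i] <- res$sequence
          if (nrow(res$placements) > 0) {
            truth_motifs[[length(truth_motifs) + 1L]] <-
              res$placements |>
              mutate(gene_id = gid, region = "exon", ordinal = i,
                     motif = plan$motif)
          }
        }
      }
    }

    # assemble and place
    gene_seq <- paste0(paste0(ex_seq[-n_ex], in_seq, collapse = ""),
                       ex_seq[n_ex])
    L <- nchar(gene_seq)
    strand <- if (runif(1) < spec$strand_p) "-" else "+"
    spacer <- sample_range(spec$spacer_range)
    segs <- c(segs, random_seq(spacer, spec$base_probs))
    cursor <- cursor + spacer
    gene_start <- cursor + 1L
    segs <- c(segs, if (strand == "-") revcomp(gene_seq) else gene_seq)
    cursor <- cursor + L

    # local (transcript-orientation) exon offsets
    loc_start <- cumsum(c(1L, head(ex_len + c(in_len, 0L), -1L)))
    loc_end <- loc_start + ex_len - 1L
    gen_start <- if (strand == "+") {
      gene_start + loc_start - 1L
    } else {
      gene_start + L - loc_end
    }
    gen_end <- if (strand == "+") {
      gene_start + loc_end - 1L
    } else {
      gene_start + L - loc_start
    }

    gtf_rows[[length(gtf_rows) + 1L]] <- tibble(
      gene_id = gid, transcript_id = tid, strand = strand,
      feature = "exon", start = gen_start, end = gen_end,
      exon_number = seq_len(n_ex)
    )
    truth_genes[[length(truth_genes) + 1L]] <- tibble(
      gene_id = gid, chrom = spec$chrom_name, strand = strand,
      start = gene_start, end = gene_start + L - 1L, n_exons = n_ex)
    truth_exons[[length(truth_exons) + 1L]] <- tibble(
      gene_id = gid, transcript_id = tid, ordinal = seq_len(n_ex),
      pos_class = ex_class, length = ex_len)
    truth_introns[[length(truth_introns) + 1L]] <- tibble(
      gene_id = gid, transcript_id = tid, ordinal = seq_len(n_in),
      pos_class = in_class, length = in_len, donor_w = w,
      next_exon_length = ex_len[-1L])

    # nested gene annotation (placed relative to host intron)
    if (!is.null(nested_info)) {
      ni <- nested_info
      host <- ni$host
      # local offset of host intron within the gene
      in_loc_start <- loc_end[host] + 1L
      n_lo <- in_loc_start + ni$at - 1L
      mini <- ni$mini
      ngid <- sprintf("SYNGN%04d", ni$id)
      ntid <- sprintf("SYNTN%04d", ni$id)
      nested_strand <- strand  # transcript orientation follows host here
      ex_lo <- n_lo + mini$exon_loc_start - 1L
      ex_hi <- n_lo + mini$exon_loc_end - 1L
      ngen_start <- if (strand == "+") {
        gene_start + ex_lo - 1L
      } else {
        gene_start + L - ex_hi
      }
      ngen_end <- if (strand == "+") {
        gene_start + ex_hi - 1L
      } else {
        gene_start + L - ex_lo
      }
      gtf_rows[[length(gtf_rows) + 1L]] <- tibble(
        gene_id = ngid, transcript_id = ntid, strand = nested_strand,
        feature = "exon", start = ngen_start, end = ngen_end,
        exon_number = seq_along(ngen_start))
    }
  }
  segs <- c(segs, random_seq(sample_range(spec$spacer_range),
                             spec$base_probs))

  chrom <- paste(segs, collapse = "")
  genome <- Biostrings::DNAStringSet(setNames(chrom, spec$chrom_name))
  gtf <- purrr::list_rbind(gtf_rows) |>
    mutate(chrom = spec$chrom_name, biotype = "protein_coding")
  annotation <- gtf |>
    transmute(.data$chrom, .data$start, .data$end, .data$strand,
              .data$gene_id, .data$transcript_id, .data$biotype) |>
    arrange(.data$chrom, .data$start, .data$transcript_id)
  truth <- list(
    genes = purrr::list_rbind(truth_genes),
    exons = purrr::list_rbind(truth_exons),
    introns = purrr::list_rbind(truth_introns),
    motifs = if (length(truth_motifs) > 0) {
      purrr::list_rbind(truth_motifs) |>
        select("gene_id", "region", "ordinal", "motif", "strand", "pos")
    } else {
      tibble(gene_id = character(0), region = character(0),
             ordinal = integer(0), motif = character(0),
             strand = character(0), pos = integer(0))
    }
  )
  structure(list(genome = genome, annotation = annotation, gtf = gtf,
                 truth = truth, spec = spec),
            class = "synthetic_genome")
}

# A minimal 2-exon gene (GT..AG intron) used as a nested-gene payload.
build_mini_gene <- function(spec, acc_pwm, don_cons) {
  e1 <- 24L
  e2 <- 24L
  il <- 40L
  don_pwm <- dial_pwm(don_cons, 0.9, spec$base_probs, fixed_rows = c(4L, 5L))
  don9 <- sample_pwm(don_pwm)
  acc23 <- sample_pwm(acc_pwm)
  ex1 <- random_seq(e1, spec$base_probs)
  ex2 <- random_seq(e2, spec$base_probs)
  substr(ex1, e1 - 2L, e1) <- substr(don9, 1, 3)
  substr(ex2, 1L, 3L) <- substr(acc23, 21, 23)
  intr <- paste0(substr(don9, 4, 9),
                 random_seq(il - 26L, spec$base_probs),
                 substr(acc23, 1, 20))
  list(seq = paste0(ex1, intr, ex2),
       exon_loc_start = c(1L, e1 + il + 1L),
       exon_loc_end = c(e1, e1 + il + e2))
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat(sprintf(
    "<synthetic_genome> %d genes, %d introns, chromosome %s (%d nt)\n",
    nrow(x$truth$genes), nrow(x$truth$introns),
    names(x$genome)[1], Biostrings::width(x$genome)[1]))
  invisible(x)
}

#' Write a synthetic genome as FASTA + Ensembl-style GTF
#'
#' @param sim A [generate_genome()] result.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Named character vector with paths `fasta` and `gtf`.
#' @export
write_synthetic_genome <- function(sim, dir, prefix = "synthetic") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, paste0(prefix, ".fa"))
  gtf <- file.path(dir, paste0(prefix, ".gtf"))
  Biostrings::writeXStringSet(sim$genome, fasta)
  rows <- sim$gtf |>
    mutate(
      attr = sprintf(
        paste0('gene_id "%s"; transcript_id "%s"; exon_number "%d"; ',
               'gene_biotype "protein_coding";'),
        .data$gene_id, .data$transcript_id, .data$exon_number),
      line = sprintf("%s\tgenarch\t%s\t%d\t%d\t.\t%s\t.\t%s",
                     .data$chrom, .data$feature, .data$start, .data$end,
                     .data$strand, .data$attr)
    )
  writeLines(c("#!genome-build synthetic", rows$line), gtf)
  c(fasta = fasta, gtf = gtf)
}
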