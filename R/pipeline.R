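#' Configuration for an end-to-end pipeline run
#'
#' Collects every tunable parameter of the analysis with its survey
#' default: minimum intron size 32 nt, cap-proximal boundary 250 nt,
#' co-occurrence size cut 500 nt, positional co-occurrence band
#' 900-1100 nt, sliding window of 2000 observations, 100,000 randomization
#' replicates at alpha 0.05.
#'
#' @param fasta,gtf Input paths.
#' @param out_dir Optional output directory for the report bundle.
#' @param seed Master seed, fanned out to named substreams (isoform
#'   lottery, decoy sampling, randomization test).
#' @param min_intron Minimum surveyed intron size, nt.
#' @param nested Nested-gene filter mode (`"contained"` or `"overlap"`).
#' @param cap_boundary First-exon length boundary for cap-proximal units,
#'   nt.
#' @param size_cut Intron size cut for motif co-occurrence, nt.
#' @param length_band Intron length band for positional co-occurrence, nt.
#' @param motifs Motif list for strand-asymmetry profiling.
#' @param background Splice-model background (`"decoy"` or `"mono"`).
#' @param bg_n_max Decoy subsample cap (`NULL` = all decoys).
#' @param pseudocount,tol,max_iter Maximum-entropy fitting controls.
#' @param window,step Sliding-window width and step, observations.
#' @param n_sim,alpha Randomization-test replicates and per-test threshold.
#' @return A list of class `"run_config"`.
#' @export
run_config <- function(fasta, gtf, out_dir = NULL, seed = 1L,
                       min_intron = 32L, nested = "contained",
                       cap_boundary = 250L, size_cut = 500L,
                       length_band = c(900L, 1100L),
                       motifs = default_motifs(),
                       background = "decoy", bg_n_max = 20000L,
                       pseudocount = 1, tol = 1e-4, max_iter = 10000L,
                       window = 2000L, step = 1L,
                       n_sim = 100000L, alpha = 0.05) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full gene-architecture pipeline
#'
#' Executes extraction, splice-model training and scoring, IpE unit
#' statistics, strand-asymmetry profiling, the randomization test, and the
#' co-occurrence analyses, returning (and optionally writing) the report
#' bundle.
#'
#' @param config A [run_config()].
#' @return A list of class `"genarch_report"` with elements `surveyed`
#'   (scored intron tibble), `exons`, `ipe_units`, `models`, `quartiles`,
#'   `table1`, `ipe_by_quartile`, `sliding`, `dsa`, `dsa_by_strength`,
#'   `randomization`, `cooccurrence`, `correlations`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  genome <- stage("read_genome", read_genome(config$fasta))
  annot <- stage("read_annotation", read_annotation(config$gtf))
  sel <- stage("select_isoforms",
               select_isoforms(annot, substream_seed(config$seed,
                                                     "isoform")))
  arch <- stage("extract_architecture", extract_architecture(sel, genome))
  spans <- gene_spans(annot)
  surveyed <- stage("filter_surveyed",
                    filter_surveyed(arch$introns, spans,
                                    min_size = config$min_intron,
                                    nested = config$nested))
  exons <- arch$exons |>
    semi_join(distinct(surveyed, .data$transcript_id),
              by = "transcript_id")

  models <- stage("train_models", list(
    donor = train_splice_model(
      surveyed, sel, genome, "donor", background = config$background,
      n_max = config$bg_n_max,
      seed = substream_seed(config$seed, "background"),
      pseudocount = config$pseudocount, tol = config$tol,
      max_iter = config$max_iter),
    acceptor = train_splice_model(
      surveyed, sel, genome, "acceptor", background = config$background,
      n_max = config$bg_n_max,
      seed = substream_seed(config$seed, "background"),
      pseudocount = config$pseudocount, tol = config$tol,
      max_iter = config$max_iter)
  ))
  surveyed <- surveyed |>
    mutate(donor_score = score_windows(models$donor, .data$donor_window),
           acceptor_score = score_windows(models$acceptor,
                                          .data$acceptor_window))

  quart <- stage("quartiles", strength_quartiles(surveyed$donor_score))
  surveyed <- surveyed |>
    mutate(strength_class = classify_strength(quart, .data$donor_score))

  ipe <- stage("ipe_units",
               build_ipe_units(surveyed, exons,
                               cap_boundary = config$cap_boundary)) |>
    left_join(surveyed |>
                select("transcript_id", intron_ordinal = "ordinal",
                       "strength_class"),
              by = c("transcript_id", "intron_ordinal"))

  table1 <- stage("table1", table1_summary(surveyed, exons))

  ipe_by_quartile <- ipe |>
    filter(!is.na(.data$strength_class)) |>
    group_by(.data$pos_class, .data$strength_class) |>
    summarise(n = n(), median_size = median(.data$size),
              mean_size = mean(.data$size), .groups = "drop")

  sliding <- list()
  first_units <- surveyed |>
    filter(.data$pos_class == "first", !is.na(.data$donor_score)) |>
    left_join(exons |> filter(.data$ordinal == 1L) |>
                select("transcript_id", first_exon_len = "length"),
              by = "transcript_id")
  if (nrow(first_units) >= config$window) {
    sliding$first_exon <- sliding_window_median(
      first_units, "first_exon_len", c("length", "donor_score"),
      window = config$window, step = config$step)
  } else {
    warn(sprintf(
      "sliding-window stage skipped: %d first introns < window of %d",
      nrow(first_units), config$window))
  }
  for (cl in c("internal", "last")) {
    dat <- ipe |> filter(.data$pos_class == cl)
    if (nrow(dat) >= config$window) {
      sliding[[cl]] <- sliding_window_median(
        dat, "next_exon_length", "intron_length",
        window = config$window, step = config$step)
    }
  }

  regions <- bind_rows(
    surveyed |>
      transmute(kind = "intron", .data$pos_class, .data$sequence,
                .data$strength_class),
    exons |>
      transmute(kind = "exon", .data$pos_class, .data$sequence,
                strength_class =
                  classify_strength(quart, NA_real_))
  )
  dsa_tbl <- stage("dsa", dsa_profile(regions, motifs = config$motifs))
  dsa_by_strength <- dsa_profile(
    regions |> filter(.data$kind == "intron",
                      !is.na(.data$strength_class)),
    motifs = intersect(c("AATAAA", "GGTAAG"), config$motifs),
    group_vars = "strength_class")

  rand <- stage("randomization", {
    internal <- ipe |> filter(.data$pos_class == "internal")
    ipe_randomization_test(
      internal$size, internal$intron_length, internal$next_exon_length,
      n_sim = config$n_sim, alpha = config$alpha,
      seed = substream_seed(config$seed, "randomization"))
  })

  cooc <- stage("cooccurrence", list(
    by_size = cooccurrence_by_size(surveyed, size_cut = config$size_cut),
    positional = tryCatch(
      positional_cooccurrence(surveyed, length_band = config$length_band),
      error = function(e) NULL),
    ordering = motif_ordering(surveyed)
  ))

  scored <- surveyed |> filter(!is.na(.data$donor_score))
  correlations <- bind_rows(
    kendall_tau_b(scored$length, scored$donor_score) |>
      mutate(comparison = "intron size vs 5'ss strength, all introns"),
    kendall_tau_b(scored$length[!is.na(scored$acceptor_score)],
                  scored$acceptor_score[!is.na(scored$acceptor_score)]) |>
      mutate(comparison = "intron size vs 3'ss strength, all introns")
  )

  manifest <- c(
    list(seed = config$seed, n_genes_annotated =
           length(unique(annot$gene_id)),
         n_genes_surveyed = length(unique(surveyed$gene_id)),
         n_introns_surveyed = nrow(surveyed)),
    config[c("fasta", "gtf", "min_intron", "nested", "cap_boundary",
             "size_cut", "window", "n_sim", "alpha", "background")]
  )

  report <- structure(
    list(surveyed = surveyed, exons = exons, ipe_units = ipe,
         models = models, quartiles = quart, table1 = table1,
         ipe_by_quartile = ipe_by_quartile, sliding = sliding,
         dsa = dsa_tbl, dsa_by_strength = dsa_by_strength,
         randomization = rand, cooccurrence = cooc,
         correlations = correlations, manifest = manifest,
         isoform_log = isoform_log(sel)),
    class = "genarch_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' Per-class summary of the surveyed introns
#'
#' One row per intron positional class with the counts and the mean and
#' median intron size, next-exon size, and donor/acceptor strengths.
#'
#' @param introns Scored surveyed intron tibble (columns `donor_score` and
#'   `acceptor_score` optional).
#' @param exons Exon tibble of the same transcripts.
#' @return A tibble with one row per class (`first`, `internal`, `last`).
#' @export
table1_summary <- function(introns, exons) {
  nxt <- exons |>
    select("transcript_id", next_ordinal = "ordinal",
           next_exon_length = "length")
  dat <- introns |>
    mutate(next_ordinal = .data$ordinal + 1L) |>
    left_join(nxt, by = c("transcript_id", "next_ordinal"))
  if (!"donor_score" %in% names(dat)) dat$donor_score <- NA_real_
  if (!"acceptor_score" %in% names(dat)) dat$acceptor_score <- NA_real_
  tibble(pos_class = c("first", "internal", "last")) |>
    left_join(
      dat |>
        group_by(.data$pos_class) |>
        summarise(
          n = n(),
          mean_intron_size = mean(.data$length),
          median_intron_size = median(.data$length),
          mean_exon_size = mean(.data$next_exon_length, na.rm = TRUE),
          median_exon_size = median(.data$next_exon_length, na.rm = TRUE),
          mean_5ss = mean(.data$donor_score, na.rm = TRUE),
          median_5ss = median(.data$donor_score, na.rm = TRUE),
          mean_3ss = mean(.data$acceptor_score, na.rm = TRUE),
          median_3ss = median(.data$acceptor_score, na.rm = TRUE),
          .groups = "drop"),
      by = "pos_class") |>
    mutate(n = tidyr::replace_na(.data$n, 0L))
}

#' @export
print.genarch_report <- function(x, ...) {
  cat(sprintf(
    "<genarch_report> %d surveyed introns in %d genes\n",
    x$manifest$n_introns_surveyed, x$manifest$n_genes_surveyed))
  cat("per-class summary:\n")
  print(as.data.frame(x$table1), digits = 3)
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(df, name) {
    write.table(df, file.path(out_dir, paste0(name, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  tsv(report$surveyed |> select(-"sequence"), "surveyed_introns")
  tsv(report$exons |> select(-"sequence"), "exons")
  tsv(report$ipe_units, "ipe_units")
  tsv(report$table1, "table1_summary")
  tsv(report$ipe_by_quartile, "ipe_by_quartile")
  tsv(report$dsa, "dsa")
  tsv(report$dsa_by_strength, "dsa_by_strength")
  tsv(report$correlations, "correlations")
  tsv(report$isoform_log, "isoform_selection")
  for (nm in names(report$sliding)) {
    write.table(as.data.frame(report$sliding[[nm]]),
                file.path(out_dir, paste0("sliding_", nm, ".csv")),
                sep = ",", quote = FALSE, row.names = FALSE)
  }
  tsv(glance(report$randomization), "randomization")
  man <- report$manifest
  writeLines(paste0(names(man), "=",
                    vapply(man, function(v) paste(format(v), collapse = ","),
                           "")),
             file.path(out_dir, "manifest.txt"))
  export_introns_bed(report$surveyed, file.path(out_dir,
                                                "surveyed_introns.bed"))
  invisible(out_dir)
}
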