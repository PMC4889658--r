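#' Read a genome FASTA into an uppercase DNA string set
#'
#' Loads all records of a (optionally gzip-compressed) FASTA file, uppercases
#' the sequences, and maps every IUPAC ambiguity code other than A/C/G/T to N,
#' so downstream motif counts and model training see a clean 5-letter
#' alphabet.
#'
#' @param fasta_path Path to a FASTA file, possibly `.gz`.
#' @return A named [Biostrings::DNAStringSet], one element per record.
#' @export
read_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    abort(paste0("FASTA file not found: ", fasta_path))
  }
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome))) {
    abort("duplicate record names in FASTA")
  }
  genome <- Biostrings::DNAStringSet(toupper(genome))
  Biostrings::replaceAmbiguities(genome, new = "N")
}

#' Extract a genomic subsequence with bounds checking
#'
#' @param genome A [Biostrings::DNAStringSet] from [read_genome()].
#' @param chrom Chromosome name.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` returns the forward sequence, `"-"` its reverse
#'   complement.
#' @return A character scalar.
#' @export
genome_seq <- function(genome, chrom, start, end, strand = "+") {
  if (!chrom %in% names(genome)) {
    abort(paste0("chromosome not in genome: ", chrom))
  }
  len <- Biostrings::width(genome[chrom])
  if (start < 1 || end > len || start > end) {
    abort(sprintf("coordinates [%d, %d] outside %s (length %d)",
                  start, end, chrom, len))
  }
  s <- as.character(Biostrings::subseq(genome[[chrom]], start, end))
  if (strand == "-") revcomp(s) else s
}

#' Read exon annotation from an Ensembl-style GTF
#'
#' Imports the GTF through \pkg{rtracklayer} and returns a tibble of exon
#' rows. The biotype is taken from `gene_biotype` when present, falling back
#' to `transcript_biotype`.
#'
#' @param gtf_path Path to a GTF file, possibly `.gz`.
#' @return A tibble with columns `chrom`, `start`, `end` (1-based inclusive),
#'   `strand`, `gene_id`, `transcript_id`, `biotype`.
#' @export
read_annotation <- function(gtf_path) {
  if (!file.exists(gtf_path)) {
    abort(paste0("GTF file not found: ", gtf_path))
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  md <- S4Vectors::mcols(gr)
  biotype <- if ("gene_biotype" %in% names(md)) {
    as.character(md$gene_biotype)
  } else if ("transcript_biotype" %in% names(md)) {
    as.character(md$transcript_biotype)
  } else {
    rep(NA_character_, length(gr))
  }
  tibble(
    chrom = as.character(GenomeInfoDb::seqnames(gr)),
    start = BiocGenerics::start(gr),
    end = BiocGenerics::end(gr),
    strand = as.character(BiocGenerics::strand(gr)),
    gene_id = as.character(md$gene_id),
    transcript_id = as.character(md$transcript_id),
    biotype = biotype
  ) |>
    arrange(.data$chrom, .data$start, .data$transcript_id)
}

#' Genomic span of every gene in an annotation
#'
#' @param annotation Exon tibble as returned by [read_annotation()].
#' @return A tibble with one row per gene: `gene_id`, `chrom`, `start`,
#'   `end`, `strand`.
#' @export
gene_spans <- function(annotation) {
  annotation |>
    group_by(.data$gene_id) |>
    summarise(chrom = first(.data$chrom),
              start = min(.data$start),
              end = max(.data$end),
              strand = first(.data$strand),
              .groups = "drop")
}

#' Select one isoform per protein-coding gene
#'
#' Chooses, for every gene with at least one protein-coding transcript, one
#' transcript uniformly at random. The draw is deterministic for a given
#' seed; genes without protein-coding transcripts are dropped (and recorded
#' in the selection log).
#'
#' @param annotation Exon tibble (see [read_annotation()]).
#' @param seed Integer seed for the isoform lottery.
#' @return The exon rows of the selected transcripts. The selection log (one
#'   row per gene: `gene_id`, `transcript_id`, `n_isoforms`) is attached as
#'   attribute `"isoform_log"` and via [isoform_log()].
#' @export
select_isoforms <- function(annotation, seed = 1L) {
  pc <- annotation |>
    filter(.data$biotype == "protein_coding")
  excluded <- setdiff(unique(annotation$gene_id), unique(pc$gene_id))
  tx <- pc |>
    distinct(.data$gene_id, .data$transcript_id) |>
    arrange(.data$gene_id, .data$transcript_id)
  picks <- with_seed(seed, {
    tx |>
      group_by(.data$gene_id) |>
      summarise(transcript_id = .data$transcript_id[sample.int(n(), 1L)],
                n_isoforms = n(), .groups = "drop")
  })
  out <- pc |> semi_join(picks, by = c("gene_id", "transcript_id"))
  log <- bind_rows(
    picks,
    tibble(gene_id = excluded, transcript_id = NA_character_,
           n_isoforms = 0L)
  ) |> arrange(.data$gene_id)
  attr(out, "isoform_log") <- log
  out
}

#' @rdname select_isoforms
#' @param x Result of [select_isoforms()].
#' @export
isoform_log <- function(x) attr(x, "isoform_log")

# Positional class of exons given transcript-orientation ordinal and count.
exon_pos_class <- function(ordinal, n) {
  dplyr::case_when(
    ordinal == 1L ~ "first",
    ordinal == n ~ "last",
    ordinal == 2L ~ "second",
    TRUE ~ "internal"
  )
}

intron_pos_class <- function(ordinal, n) {
  dplyr::case_when(
    ordinal == 1L ~ "first",
    ordinal == n ~ "last",
    TRUE ~ "internal"
  )
}

#' Extract exon and intron records from selected transcripts
#'
#' Computes, for every transcript, the ordered exons and the introns between
#' them. All sequences are reported in transcript orientation (reverse
#' complemented for minus-strand genes); ordinals count 5' to 3' along the
#' transcript. Donor windows are 9-mers (last 3 exonic nt + first 6 intronic
#' nt), acceptor windows 23-mers (last 20 intronic nt + first 3 exonic nt); a
#' window overhanging a too-short flanking exon, or containing N, is flagged
#' unavailable for training and scoring.
#'
#' @param transcripts Exon tibble of the selected isoforms
#'   (see [select_isoforms()]).
#' @param genome Genome from [read_genome()].
#' @return A list of class `"gene_architecture"` with tibbles `exons` and
#'   `introns`.
#' @export
extract_architecture <- function(transcripts, genome) {
  chroms <- unique(transcripts$chrom)
  missing <- setdiff(chroms, names(genome))
  if (length(missing) > 0) {
    abort(paste0("annotation references chromosomes absent from the genome: ",
                 paste(missing, collapse = ", ")))
  }
  chrom_str <- setNames(as.character(genome[chroms]), chroms)
  chrom_len <- setNames(nchar(chrom_str), chroms)

  ex <- transcripts |>
    arrange(.data$transcript_id, .data$start) |>
    group_by(.data$transcript_id) |>
    mutate(
      n_exons = n(),
      g_idx = row_number(),
      ordinal = if_else(.data$strand == "+", .data$g_idx,
                        .data$n_exons - .data$g_idx + 1L)
    ) |>
    ungroup()
  if (any(ex$start < 1L) || any(ex$end > chrom_len[ex$chrom])) {
    abort("exon interval outside chromosome bounds")
  }
  overlap <- ex |>
    group_by(.data$transcript_id) |>
    mutate(bad = .data$g_idx > 1L & .data$start <= lag(.data$end)) |>
    ungroup()
  if (any(overlap$bad, na.rm = TRUE)) {
    abort("overlapping exons within a transcript")
  }

  fwd <- substring(chrom_str[ex$chrom], ex$start, ex$end)
  ex_seq <- ifelse(ex$strand == "-", revcomp(fwd), fwd)

  exons <- ex |>
    mutate(length = .data$end - .data$start + 1L,
           sequence = ex_seq,
           pos_class = exon_pos_class(.data$ordinal, .data$n_exons)) |>
    select("gene_id", "transcript_id", "chrom", "strand", "ordinal",
           "n_exons", "pos_class", "start", "end", "length", "sequence") |>
    arrange(.data$transcript_id, .data$ordinal)

  # Introns: genomic gaps between consecutive exons of a transcript.
  gaps <- ex |>
    group_by(.data$transcript_id) |>
    arrange(.data$g_idx, .by_group = TRUE) |>
    mutate(gap_start = lag(.data$end) + 1L, gap_end = .data$start - 1L) |>
    filter(.data$g_idx > 1L) |>
    ungroup()
  if (nrow(gaps) > 0 && any(gaps$gap_end < gaps$gap_start)) {
    abort("zero-length intron between adjacent exons")
  }
  introns <- gaps |>
    group_by(.data$transcript_id) |>
    mutate(
      n_introns = n(),
      ordinal = if_else(.data$strand == "+", row_number(),
                        .data$n_introns - row_number() + 1L)
    ) |>
    ungroup() |>
    mutate(start = .data$gap_start, end = .data$gap_end,
           length = .data$end - .data$start + 1L)

  i_fwd <- substring(chrom_str[introns$chrom], introns$start, introns$end)
  i_seq <- ifelse(introns$strand == "-", revcomp(i_fwd), i_fwd)

  # Window coordinates in genomic space; orientation fixed afterwards.
  plus <- introns$strand == "+"
  d_start <- ifelse(plus, introns$start - 3L, introns$end - 5L)
  d_end <- ifelse(plus, introns$start + 5L, introns$end + 3L)
  a_start <- ifelse(plus, introns$end - 19L, introns$start - 3L)
  a_end <- ifelse(plus, introns$end + 3L, introns$start + 19L)

  up_exon_len <- exon_len_lookup(ex, introns, offset_upstream = TRUE)
  dn_exon_len <- exon_len_lookup(ex, introns, offset_upstream = FALSE)

  d_avail <- up_exon_len >= 3L & introns$length >= 6L
  a_avail <- dn_exon_len >= 3L & introns$length >= 20L

  d_win <- rep(NA_character_, nrow(introns))
  a_win <- rep(NA_character_, nrow(introns))
  if (any(d_avail)) {
    w <- substring(chrom_str[introns$chrom[d_avail]],
                   d_start[d_avail], d_end[d_avail])
    d_win[d_avail] <- ifelse(plus[d_avail], w, revcomp(w))
  }
  if (any(a_avail)) {
    w <- substring(chrom_str[introns$chrom[a_avail]],
                   a_start[a_avail], a_end[a_avail])
    a_win[a_avail] <- ifelse(plus[a_avail], w, revcomp(w))
  }

  introns <- introns |>
    mutate(
      sequence = i_seq,
      pos_class = intron_pos_class(.data$ordinal, .data$n_introns),
      donor_dinuc = substr(.data$sequence, 1L, 2L),
      acceptor_dinuc = substr(.data$sequence, .data$length - 1L,
                              .data$length),
      donor_window = d_win,
      acceptor_window = a_win,
      donor_ok = d_avail & !is.na(d_win) & !grepl("N", d_win, fixed = TRUE),
      acceptor_ok = a_avail & !is.na(a_win) &
        !grepl("N", a_win, fixed = TRUE)
    ) |>
    select("gene_id", "transcript_id", "chrom", "strand", "ordinal",
           "n_introns", "pos_class", "start", "end", "length", "sequence",
           "donor_dinuc", "acceptor_dinuc", "donor_window",
           "acceptor_window", "donor_ok", "acceptor_ok") |>
    arrange(.data$transcript_id, .data$ordinal)

  structure(list(exons = exons, introns = introns),
            class = "gene_architecture")
}

# Length of the exon flanking a gap on its transcript-upstream or
# -downstream side. `introns` rows carry g_idx of the exon ending the gap.
exon_len_lookup <- function(ex, introns, offset_upstream) {
  key_ex <- paste(ex$transcript_id, ex$g_idx)
  # gap g_idx corresponds to the downstream (genomic) exon index
  g_idx_up <- ifelse(introns$strand == "+", introns$g_idx - 1L,
                     introns$g_idx)
  g_idx_dn <- ifelse(introns$strand == "+", introns$g_idx,
                     introns$g_idx - 1L)
  idx <- if (offset_upstream) g_idx_up else g_idx_dn
  lens <- (ex$end - ex$start + 1L)[match(paste(introns$transcript_id, idx),
                                         key_ex)]
  lens
}

#' @export
print.gene_architecture <- function(x, ...) {
  cat(sprintf("<gene_architecture> %d transcripts, %d exons, %d introns\n",
              length(unique(x$exons$transcript_id)),
              nrow(x$exons), nrow(x$introns)))
  invisible(x)
}

#' Apply the survey filters to extracted introns
#'
#' Retains introns that are at least `min_size` nt long, carry canonical
#' GT/AG termini, and host no nested gene; genes left with fewer than two
#' retained introns are then dropped entirely. The nested-gene test flags an
#' intron when another gene's genomic span is fully contained within it
#' (`nested = "contained"`, the default) or overlaps it by at least one
#' nucleotide (`nested = "overlap"`).
#'
#' @param introns Intron tibble from [extract_architecture()].
#' @param spans Gene spans from [gene_spans()] (all genes, both strands).
#' @param min_size Minimum intron length in nt.
#' @param nested Nested-gene test mode.
#' @return The surveyed intron tibble, with logical flag columns
#'   `min_size_ok`, `canonical`, `nested_gene_overlap` retained for audit.
#' @export
filter_surveyed <- function(introns, spans, min_size = 32L,
                            nested = c("contained", "overlap")) {
  nested <- match.arg(nested)
  flagged <- introns |>
    mutate(
      min_size_ok = .data$length >= min_size,
      canonical = .data$donor_dinuc == "GT" & .data$acceptor_dinuc == "AG",
      nested_gene_overlap = nested_gene_flag(introns, spans, nested)
    )
  kept <- flagged |>
    filter(.data$min_size_ok, .data$canonical, !.data$nested_gene_overlap) |>
    group_by(.data$gene_id) |>
    filter(n() >= 2L) |>
    ungroup()
  kept
}

nested_gene_flag <- function(introns, spans, mode) {
  if (nrow(introns) == 0) return(logical(0))
  flag <- logical(nrow(introns))
  for (chr in unique(introns$chrom)) {
    ii <- which(introns$chrom == chr)
    si <- which(spans$chrom == chr)
    if (length(si) == 0) next
    ir <- IRanges::IRanges(introns$start[ii], introns$end[ii])
    sr <- IRanges::IRanges(spans$start[si], spans$end[si])
    type <- if (mode == "contained") "within" else "any"
    hits <- IRanges::findOverlaps(sr, ir, type = type)
    if (length(hits) == 0) next
    other <- spans$gene_id[si][S4Vectors::queryHits(hits)] !=
      introns$gene_id[ii][S4Vectors::subjectHits(hits)]
    flag[ii[unique(S4Vectors::subjectHits(hits)[other])]] <- TRUE
  }
  flag
}

#' Assemble intron-plus-next-exon (IpE) units
#'
#' Pairs every intron with the exon that immediately follows it in
#' transcript orientation. The unit size is the intron length plus the next
#' exon length, i.e. the distance between two consecutive donor splice
#' sites. First units are split by the distance of their donor site from the
#' transcript cap, approximated by first-exon length: `first_cap_proximal`
#' when the first exon is at most `cap_boundary` nt, `first_cap_distal`
#' otherwise.
#'
#' @param introns Intron tibble (usually surveyed; see [filter_surveyed()]).
#' @param exons Exon tibble from [extract_architecture()].
#' @param cap_boundary Cap-proximal boundary on first-exon length, nt
#'   (inclusive).
#' @return A tibble with one row per unit: identifiers, `intron_ordinal`,
#'   `intron_length`, `next_exon_length`, `size`, `pos_class`,
#'   `first_exon_len`, and `upstream_5ss_score` (carried over from a
#'   `donor_score` column on `introns` when present, `NA` otherwise).
#' @export
build_ipe_units <- function(introns, exons, cap_boundary = 250L) {
  first_len <- exons |>
    filter(.data$ordinal == 1L) |>
    select("transcript_id", first_exon_len = "length")
  nxt <- exons |>
    select("transcript_id", next_ordinal = "ordinal",
           next_exon_length = "length")
  score <- if ("donor_score" %in% names(introns)) {
    introns$donor_score
  } else {
    rep(NA_real_, nrow(introns))
  }
  introns |>
    mutate(upstream_5ss_score = score,
           next_ordinal = .data$ordinal + 1L) |>
    inner_join(nxt, by = c("transcript_id", "next_ordinal")) |>
    left_join(first_len, by = "transcript_id") |>
    mutate(
      size = .data$length + .data$next_exon_length,
      pos_class = dplyr::case_when(
        .data$pos_class == "first" &
          .data$first_exon_len <= cap_boundary ~ "first_cap_proximal",
        .data$pos_class == "first" ~ "first_cap_distal",
        TRUE ~ .data$pos_class
      )
    ) |>
    select("gene_id", "transcript_id", intron_ordinal = "ordinal",
           intron_length = "length", "next_exon_length", "size",
           "pos_class", "first_exon_len", "upstream_5ss_score")
}

#' Export surveyed introns as BED6
#'
#' Writes 0-based half-open intervals with the gene and ordinal as the
#' feature name.
#'
#' @param introns Intron tibble.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
export_introns_bed <- function(introns, path) {
  bed <- introns |>
    transmute(.data$chrom, start = .data$start - 1L, end = .data$end,
              name = paste0(.data$gene_id, ":", .data$ordinal),
              score = 0L, .data$strand) |>
    arrange(.data$chrom, .data$start)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
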