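# Shared fixtures and independent oracles, all built in code.

suppressPackageStartupMessages({
  library(dplyr)
  library(tibble)
})

# ---- brute-force Kendall tau-b oracle (all-pairs count) --------------------
tau_b_brute <- function(x, y) {
  n <- length(x)
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  up <- upper.tri(dx)
  nc_nd <- sum(dx[up] * dy[up])
  n0 <- n * (n - 1) / 2
  tx <- sum(dx[up] == 0)
  ty <- sum(dy[up] == 0)
  nc_nd / sqrt((n0 - tx) * (n0 - ty))
}

# ---- brute-force two-sample KS distance ------------------------------------
ks_d_brute <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(vapply(pts, function(t) mean(a <= t) - mean(b <= t), numeric(1))))
}

# ---- hand-built transcripts ------------------------------------------------
# Build a plus-orientation gene from explicit exon and intron sequences;
# returns the local sequence and local (1-based) exon coordinates.
make_toy_gene <- function(exon_seqs, intron_seqs) {
  stopifnot(length(exon_seqs) == length(intron_seqs) + 1)
  s <- ""
  starts <- ends <- integer(length(exon_seqs))
  for (i in seq_along(exon_seqs)) {
    starts[i] <- nchar(s) + 1L
    s <- paste0(s, exon_seqs[i])
    ends[i] <- nchar(s)
    if (i <= length(intron_seqs)) s <- paste0(s, intron_seqs[i])
  }
  list(seq = s, exon_start = starts, exon_end = ends)
}

# Place toy genes on one chromosome. `genes` is a list of
# list(id, strand, gene = make_toy_gene(...)); returns genome + annotation.
assemble_toy <- function(genes, chrom = "chrT", spacer = 60L) {
  spacer_seq <- strrep("C", spacer)
  chrom_seq <- ""
  rows <- list()
  for (g in genes) {
    chrom_seq <- paste0(chrom_seq, spacer_seq)
    offset <- nchar(chrom_seq)
    L <- nchar(g$gene$seq)
    placed <- if (g$strand == "-") {
      as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(g$gene$seq)))
    } else {
      g$gene$seq
    }
    chrom_seq <- paste0(chrom_seq, placed)
    gs <- if (g$strand == "+") {
      offset + g$gene$exon_start
    } else {
      offset + L - g$gene$exon_end + 1L
    }
    ge <- if (g$strand == "+") {
      offset + g$gene$exon_end
    } else {
      offset + L - g$gene$exon_start + 1L
    }
    rows[[length(rows) + 1L]] <- tibble(
      chrom = chrom, start = gs, end = ge, strand = g$strand,
      gene_id = g$id, transcript_id = paste0(g$id, ".t1"),
      biotype = g$biotype %||% "protein_coding")
  }
  chrom_seq <- paste0(chrom_seq, spacer_seq)
  list(genome = Biostrings::DNAStringSet(setNames(chrom_seq, chrom)),
       annotation = bind_rows(rows) |> arrange(start))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical intron of a given total length (>= 30): GT + filler + AG.
canon_intron <- function(len, filler = "A") {
  paste0("GT", strrep(filler, len - 4L), "AG")
}

good_exon <- function(len = 12L) {
  paste0(strrep("C", len - 6L), "AGTCAG")  # ends with plausible donor tail
}

# ---- the 10-gene filter-cascade fixture ------------------------------------
# Hand-enumerated survivors: G1 (3 introns), G7 (3 of 4), G8 (2, minus
# strand), G9 (2 x 32-nt). Dropped: G2 (31-nt intron), G3 (GC donor),
# G4 (nested G5 in intron 1), G5 (single intron), G6 (AT acceptor),
# G10 (GT..AA acceptor).
toy_survey_fixture <- function() {
  ex <- function(n = 3) rep(good_exon(), n)
  genes <- list(
    list(id = "G1", strand = "+",
         gene = make_toy_gene(ex(4), c(canon_intron(40), canon_intron(35),
                                       canon_intron(50)))),
    list(id = "G2", strand = "+",
         gene = make_toy_gene(ex(3), c(canon_intron(31), canon_intron(40)))),
    list(id = "G3", strand = "+",
         gene = make_toy_gene(ex(3), c(
           paste0("GC", strrep("A", 36), "AG"), canon_intron(40)))),
    # G4 intron 1 is long; G5 will be annotated inside it
    list(id = "G4", strand = "+",
         gene = make_toy_gene(ex(3), c(canon_intron(120), canon_intron(40)))),
    list(id = "G6", strand = "+",
         gene = make_toy_gene(ex(3), c(
           paste0("GT", strrep("A", 36), "AT"), canon_intron(40)))),
    list(id = "G7", strand = "+",
         gene = make_toy_gene(ex(5), c(canon_intron(40), canon_intron(31),
                                       canon_intron(33), canon_intron(44)))),
    list(id = "G8", strand = "-",
         gene = make_toy_gene(ex(3), c(canon_intron(38), canon_intron(42)))),
    list(id = "G9", strand = "+",
         gene = make_toy_gene(ex(3), c(canon_intron(32), canon_intron(32)))),
    list(id = "G10", strand = "+",
         gene = make_toy_gene(ex(3), c(
           paste0("GT", strrep("A", 36), "AA"), canon_intron(40))))
  )
  toy <- assemble_toy(genes)
  # annotate nested gene G5 inside G4's first intron (two 10-nt exons)
  g4 <- toy$annotation |> filter(gene_id == "G4")
  i1_start <- g4$end[1] + 1L  # genomic start of G4 intron 1
  g5 <- tibble(
    chrom = "chrT",
    start = c(i1_start + 10L, i1_start + 40L),
    end = c(i1_start + 19L, i1_start + 49L),
    strand = "+", gene_id = "G5", transcript_id = "G5.t1",
    biotype = "protein_coding")
  toy$annotation <- bind_rows(toy$annotation, g5) |> arrange(start)
  toy$expected_survivors <- c(G1 = 3L, G7 = 3L, G8 = 2L, G9 = 2L)
  toy
}

# ---- cached small synthetic genome -----------------------------------------
.sim_cache <- new.env(parent = emptyenv())
cached_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    spec <- synthetic_genome_spec(n_genes = 60L, seed = 101L)
    .sim_cache$sim <- generate_genome(spec)
  }
  .sim_cache$sim
}

cached_arch <- function() {
  if (is.null(.sim_cache$arch)) {
    sim <- cached_sim()
    sel <- select_isoforms(sim$annotation, seed = 1L)
    .sim_cache$arch <- extract_architecture(sel, sim$genome)
  }
  .sim_cache$arch
}

random_windows <- function(n, k, prob = rep(0.25, 4)) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE, prob = prob),
          collapse = "")
  }, "")
}
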