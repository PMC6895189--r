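#' Simulation configuration
#'
#' The defaults state the standard test world: a 100 kb genome over two
#' scaffolds at 42% GC with 20 multi-exon genes, per-individual coverage
#' Poisson(60), 1% per-base sequencing error, and 500 injected assembly
#' errors placed only at positions eligible under the default correction
#' thresholds.  The independent individual differs from the truth genome at
#' `snp_rate` per base; `indel_site_rate` of positions carry indel-supporting
#' reads (at ~25% of depth, so they trip the 10% indel filter as real
#' indel/repeat regions would).
#'
#' @param seed Integer RNG seed; every derived fixture is deterministic in it.
#' @param genome_length Total bases across scaffolds.
#' @param n_scaffolds Number of scaffolds.
#' @param gc_fraction GC content of the background sequence.
#' @param n_genes Number of non-overlapping single-transcript genes.
#' @param mean_exons_per_gene Mean CDS segment count per gene (>= 1).
#' @param coverage_mean Poisson mean per-site read depth per individual.
#' @param sequencing_error_rate Symmetric per-base read error rate.
#' @param n_injected_errors Assembly errors to inject.
#' @param fraction_errors_in_cds Fraction of injected errors placed in CDS.
#' @param snp_rate Per-base SNP rate of the independent individual.
#' @param indel_site_rate Fraction of positions designated indel sites.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, genome_length = 100000L, n_scaffolds = 2L,
                       gc_fraction = 0.42, n_genes = 20L,
                       mean_exons_per_gene = 3, coverage_mean = 60,
                       sequencing_error_rate = 0.01,
                       n_injected_errors = 500L,
                       fraction_errors_in_cds = 0.3,
                       snp_rate = 0.001, indel_site_rate = 0.001) {
  cfg <- list(
    seed = as.integer(seed), genome_length = as.integer(genome_length),
    n_scaffolds = as.integer(n_scaffolds), gc_fraction = gc_fraction,
    n_genes = as.integer(n_genes),
    mean_exons_per_gene = mean_exons_per_gene,
    coverage_mean = coverage_mean,
    sequencing_error_rate = sequencing_error_rate,
    n_injected_errors = as.integer(n_injected_errors),
    fraction_errors_in_cds = fraction_errors_in_cds,
    snp_rate = snp_rate, indel_site_rate = indel_site_rate
  )
  rates <- c("gc_fraction", "sequencing_error_rate", "fraction_errors_in_cds",
             "snp_rate", "indel_site_rate")
  for (r in rates) {
    if (!is.numeric(cfg[[r]]) || is.na(cfg[[r]]) || cfg[[r]] < 0 ||
        cfg[[r]] > 1) {
      stop(r, " must lie in [0, 1]")
    }
  }
  stopifnot(cfg$genome_length >= 1L, cfg$n_scaffolds >= 1L,
            cfg$n_genes >= 0L, cfg$mean_exons_per_gene >= 1,
            cfg$coverage_mean > 0,
            cfg$n_injected_errors <= cfg$genome_length)
  structure(cfg, class = "sim_config")
}

#' Simulate a truth genome, gene models and injected assembly errors
#'
#' Deterministic given `config$seed`.  Genes are non-overlapping, on both
#' strands, with CDS length divisible by 3 (ATG start, clean stop, no
#' premature stops).  Injected errors avoid designated indel sites, so with
#' the default coverage they land only at positions eligible under default
#' correction thresholds; `fraction_errors_in_cds` of them fall inside CDS.
#' SNP sites of the independent individual are disjoint from error sites.
#' Ground-truth codon effect classes for CDS errors are computed from the
#' simulator's own gene bookkeeping (ref = corrupted codon, corrected =
#' truth codon), independent of the projection module.
#'
#' @param config [sim_config()].
#' @return A `seqbug_sim` object: `true_genome` and `corrupted_genome`
#'   (named character), `gtf` (character lines), `genes` (CDS segment
#'   table), `error_sites`, `coding_effects`, `snp_sites`, `indel_sites`,
#'   and the `config`.
#' @export
simulate_truth <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  base_probs <- c((1 - config$gc_fraction) / 2, config$gc_fraction / 2,
                  config$gc_fraction / 2, (1 - config$gc_fraction) / 2)

  per <- config$genome_length %/% config$n_scaffolds
  lens <- rep(per, config$n_scaffolds)
  lens[1L] <- lens[1L] + config$genome_length %% config$n_scaffolds
  scaf_ids <- sprintf("scaf%d", seq_len(config$n_scaffolds))
  genome <- lapply(lens, function(L) {
    paste(sample(BASES, L, replace = TRUE, prob = base_probs), collapse = "")
  })
  names(genome) <- scaf_ids

  # gene placement: sequential with intergenic gaps, proportional per scaffold
  genes_per_scaf <- diff(round(cumsum(c(0, lens / sum(lens))) * config$n_genes))
  seg_list <- list()
  coding_list <- list()
  gi <- 0L
  stop_codons <- c("TAA", "TAG", "TGA")
  codon_pool <- setdiff(
    apply(expand.grid(BASES, BASES, BASES), 1L, paste, collapse = ""),
    stop_codons
  )
  for (si in seq_len(config$n_scaffolds)) {
    cursor <- 1L
    placed <- 0L
    while (placed < genes_per_scaf[si]) {
      gap <- sample(100:300, 1L)
      n_ex <- max(1L, 1L + rpois(1L, max(0, config$mean_exons_per_gene - 1)))
      ex_len <- sample(60:240, n_ex, replace = TRUE)
      ex_len[n_ex] <- ex_len[n_ex] - sum(ex_len) %% 3L
      in_len <- if (n_ex > 1L) sample(40:150, n_ex - 1L, replace = TRUE) else
        integer()
      span <- sum(ex_len) + sum(in_len)
      if (cursor + gap + span - 1L > lens[si]) {
        stop("gene placement exceeds scaffold ", scaf_ids[si],
             ": genes exceed genome for this config")
      }
      gi <- gi + 1L
      g_start <- cursor + gap
      starts <- g_start + cumsum(c(0L, head(ex_len, -1L) + in_len))
      ends <- starts + ex_len - 1L
      strand <- sample(c("+", "-"), 1L)
      L <- sum(ex_len)
      coding <- paste0(
        "ATG",
        paste(sample(codon_pool, L / 3L - 2L, replace = TRUE), collapse = ""),
        sample(stop_codons, 1L)
      )
      # transcript-orientation exon order; genomic content per exon
      ord <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      offs <- cumsum(c(0L, ex_len[ord][-n_ex]))
      s <- genome[[si]]
      for (j in seq_len(n_ex)) {
        e <- ord[j]
        piece <- substr(coding, offs[j] + 1L, offs[j] + ex_len[e])
        if (strand == "-") piece <- revcomp(piece)
        s <- paste0(substr(s, 1L, starts[e] - 1L), piece,
                    substring(s, ends[e] + 1L))
      }
      genome[[si]] <- s
      frames <- (3L - (cumsum(c(0L, ex_len[ord][-n_ex])) %% 3L)) %% 3L
      seg_list[[gi]] <- data.table(
        seq_id = scaf_ids[si], start = starts[ord], end = ends[ord],
        strand = strand, frame = frames,
        gene_id = sprintf("simg%04d", gi),
        transcript_id = sprintf("simt%04d", gi),
        seg_idx = seq_len(n_ex)
      )
      coding_list[[gi]] <- data.table(
        gene_id = sprintf("simg%04d", gi),
        transcript_id = sprintf("simt%04d", gi),
        cds_len = L
      )
      cursor <- g_start + span
      placed <- placed + 1L
    }
  }
  if (gi < config$n_genes) stop("genes exceed genome for this config")
  segs <- rbindlist(seg_list)

  # positional bookkeeping over the whole genome
  glob <- data.table(
    seq_id = rep(scaf_ids, lens),
    pos = unlist(lapply(lens, seq_len))
  )
  cds_key <- segs[, .(pos = seq.int(start, end)), by = .(seq_id, start, end)
                  ][, .(seq_id, pos)]
  glob[, in_cds := FALSE]
  glob[cds_key, in_cds := TRUE, on = .(seq_id, pos)]

  n_indel <- round(config$indel_site_rate * config$genome_length)
  indel_idx <- sort(sample.int(nrow(glob), n_indel))
  indel_sites <- glob[indel_idx, .(seq_id, pos)]

  avail <- setdiff(seq_len(nrow(glob)), indel_idx)
  cds_avail <- intersect(avail, which(glob$in_cds))
  non_avail <- setdiff(avail, which(glob$in_cds))
  n_cds_err <- round(config$n_injected_errors * config$fraction_errors_in_cds)
  n_cds_err <- min(n_cds_err, length(cds_avail))
  n_non_err <- config$n_injected_errors - n_cds_err
  err_idx <- sort(c(sample(cds_avail, n_cds_err),
                    sample(non_avail, n_non_err)))
  error_sites <- glob[err_idx, .(seq_id, pos, in_cds)]
  if (nrow(error_sites)) {
    error_sites[, true_base := substring(genome[[.BY$seq_id]], pos, pos),
                by = .(seq_id)]
    error_sites[, corrupted_base := vapply(true_base, function(b) {
      sample(setdiff(BASES, b), 1L)
    }, "")]
  } else {
    error_sites[, `:=`(true_base = character(), corrupted_base = character())]
  }

  n_snp <- round(config$snp_rate * config$genome_length)
  snp_pool <- setdiff(avail, err_idx)
  snp_idx <- sort(sample(snp_pool, min(n_snp, length(snp_pool))))
  snp_sites <- glob[snp_idx, .(seq_id, pos)]
  if (nrow(snp_sites)) {
    snp_sites[, true_base := substring(genome[[.BY$seq_id]], pos, pos),
              by = .(seq_id)]
    snp_sites[, snp_base := vapply(true_base, function(b) {
      sample(setdiff(BASES, b), 1L)
    }, "")]
  } else {
    snp_sites[, `:=`(true_base = character(), snp_base = character())]
  }

  corrupted <- genome
  for (sid in unique(error_sites$seq_id)) {
    sub <- error_sites[seq_id == sid]
    ch <- strsplit(corrupted[[sid]], "", fixed = TRUE)[[1L]]
    ch[sub$pos] <- sub$corrupted_base
    corrupted[[sid]] <- paste(ch, collapse = "")
  }

  sim <- structure(list(
    config = config,
    true_genome = unlist(genome),
    corrupted_genome = unlist(corrupted),
    genes = segs[],
    gtf = sim_gtf_lines(segs),
    error_sites = error_sites[],
    snp_sites = snp_sites[],
    indel_sites = indel_sites[]
  ), class = "seqbug_sim")
  sim$coding_effects <- sim_coding_effects(sim)
  sim
}

#' @noRd
sim_gtf_lines <- function(segs) {
  g <- segs[, .(
    start = min(start), end = max(end), strand = strand[1L],
    seq_id = seq_id[1L], transcript_id = transcript_id[1L]
  ), by = gene_id]
  gene_lines <- sprintf(
    '%s\tseqbug_sim\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    g$seq_id, g$start, g$end, g$strand, g$gene_id
  )
  tx_lines <- sprintf(
    '%s\tseqbug_sim\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    g$seq_id, g$start, g$end, g$strand, g$gene_id, g$transcript_id
  )
  s <- copy(segs)
  setorder(s, seq_id, start)
  cds_lines <- sprintf(
    '%s\tseqbug_sim\tCDS\t%d\t%d\t.\t%s\t%d\tgene_id "%s"; transcript_id "%s";',
    s$seq_id, s$start, s$end, s$strand, s$frame, s$gene_id, s$transcript_id
  )
  c("#!genome-build seqbug-sim", gene_lines, tx_lines, cds_lines)
}

#' @noRd
sim_extract_cds <- function(segs_one_tx, genome) {
  s <- copy(segs_one_tx)
  setorder(s, seg_idx)
  raw <- substring(genome[[s$seq_id[1L]]], s$start, s$end)
  if (s$strand[1L] == "-") raw <- revcomp(raw)
  paste(raw, collapse = "")
}

#' @noRd
sim_coding_effects <- function(sim) {
  errs <- sim$error_sites[in_cds == TRUE]
  empty <- data.table(gene_id = character(), transcript_id = character(),
                      codon_index = integer(), ref_codon = character(),
                      corrected_codon = character(), ref_aa = character(),
                      corrected_aa = character(), effect = character())
  if (nrow(errs) == 0L) return(empty)
  segs <- sim$genes
  hit <- segs[errs, on = .(seq_id, start <= pos, end >= pos), nomatch = NULL,
              .(gene_id, transcript_id, seq_id, strand, seg_idx,
                seg_start = x.start, seg_end = x.end, pos = i.pos)]
  seg_off <- segs[order(seg_idx),
                  .(seg_idx, offset = cumsum(shift(end - start + 1L,
                                                   fill = 0L))),
                  by = transcript_id]
  hit <- seg_off[hit, on = c("transcript_id", "seg_idx")]
  hit[, cds_pos := offset + fifelse(strand == "+", pos - seg_start + 1L,
                                    seg_end - pos + 1L)]
  hit[, codon_index := (cds_pos - 1L) %/% 3L + 1L]
  out <- hit[, {
    tx_segs <- segs[transcript_id == .BY$transcript_id]
    ref <- sim_extract_cds(tx_segs, as.list(sim$corrupted_genome))
    tru <- sim_extract_cds(tx_segs, as.list(sim$true_genome))
    ci <- unique(codon_index)
    rc <- substring(ref, (ci - 1L) * 3L + 1L, ci * 3L)
    cc <- substring(tru, (ci - 1L) * 3L + 1L, ci * 3L)
    .(gene_id = gene_id[1L], codon_index = ci, ref_codon = rc,
      corrected_codon = cc)
  }, by = .(transcript_id)]
  out[, ref_aa := translate_codons(ref_codon)]
  out[, corrected_aa := translate_codons(corrected_codon)]
  # local effect call (kept separate from the projection module's)
  out[, effect := ifelse(corrected_aa == "*" & ref_aa != "*", "stop_gain",
                  ifelse(ref_aa == "*" & corrected_aa != "*", "stop_loss",
                  ifelse(codon_index == 1L & ref_aa == "M" &
                           corrected_aa != "M", "start_loss",
                  ifelse(ref_aa == corrected_aa, "synonymous",
                         "nonsynonymous"))))]
  setorder(out, transcript_id, codon_index)
  out[]
}

#' Simulate a per-base pileup for one individual
#'
#' Count-level simulation (no reads, no mapping): per-site depth is
#' Poisson(`coverage_mean`); at designated indel sites ~25% of reads support
#' an indel; remaining reads draw the individual's true base with symmetric
#' per-base error `sequencing_error_rate` (errors split multinomially over
#' the other three bases).  The `ref_base` column comes from the corrupted
#' assembly, as a readcount run against the draft assembly would report.
#' The `independent` individual reads from the truth genome with its SNPs
#' applied; `same` reads from the truth genome directly.
#'
#' @param sim [simulate_truth()] result.
#' @param individual `"same"` (assembly individual) or `"independent"`.
#' @param planted_snp_sites Optional `data.table(seq_id, pos)` of extra SNP
#'   sites for the independent individual (validation stress tests plant
#'   these at corrected sites); the SNP base is chosen deterministically as
#'   the next base cyclically after the truth base.
#' @return Pileup `data.table` in [read_pileup()] layout, one row per
#'   genome position.
#' @export
simulate_pileup <- function(sim, individual = c("same", "independent"),
                            planted_snp_sites = NULL) {
  stopifnot(inherits(sim, "seqbug_sim"))
  individual <- match.arg(individual)
  config <- sim$config
  set.seed(config$seed + match(individual, c("same", "independent")))

  source_genome <- sim$true_genome
  if (individual == "independent") {
    apply_sub <- function(genome, sites, base_col) {
      for (sid in unique(sites$seq_id)) {
        sub <- sites[seq_id == sid]
        ch <- strsplit(genome[[sid]], "", fixed = TRUE)[[1L]]
        ch[sub$pos] <- sub[[base_col]]
        genome[[sid]] <- paste(ch, collapse = "")
      }
      genome
    }
    if (nrow(sim$snp_sites)) {
      source_genome <- apply_sub(as.list(source_genome), sim$snp_sites,
                                 "snp_base")
      source_genome <- unlist(source_genome)
    }
    if (!is.null(planted_snp_sites) && nrow(planted_snp_sites)) {
      pl <- as.data.table(planted_snp_sites)[, .(seq_id, pos)]
      pl[, true_base := substring(sim$true_genome[[.BY$seq_id]], pos, pos),
         by = .(seq_id)]
      pl[, snp_base := BASES[match(true_base, BASES) %% 4L + 1L]]
      source_genome <- unlist(apply_sub(as.list(source_genome), pl,
                                        "snp_base"))
    }
  }

  lens <- nchar(sim$true_genome)
  dt <- data.table(
    seq_id = rep(names(lens), lens),
    pos = unlist(lapply(unname(lens), seq_len))
  )
  n <- nrow(dt)
  true_chars <- unlist(strsplit(unname(source_genome[names(lens)]), "",
                                fixed = TRUE), use.names = FALSE)
  ref_chars <- unlist(strsplit(unname(sim$corrupted_genome[names(lens)]), "",
                               fixed = TRUE), use.names = FALSE)
  tb <- match(true_chars, BASES)

  depth <- rpois(n, config$coverage_mean)
  indel_reads <- integer(n)
  if (nrow(sim$indel_sites)) {
    ii <- dt[sim$indel_sites, on = .(seq_id, pos), which = TRUE]
    indel_reads[ii] <- rbinom(length(ii), depth[ii], 0.25)
  }
  base_depth <- depth - indel_reads

  e <- config$sequencing_error_rate
  n_err <- rbinom(n, base_depth, e)
  e1 <- rbinom(n, n_err, 1 / 3)
  e2 <- rbinom(n, n_err - e1, 1 / 2)
  e3 <- n_err - e1 - e2
  counts <- matrix(0L, nrow = n, ncol = 4L, dimnames = list(NULL, BASES))
  for (b in 1:4) {
    idx <- which(tb == b)
    counts[idx, b] <- base_depth[idx] - n_err[idx]
    others <- setdiff(1:4, b)
    counts[idx, others[1L]] <- e1[idx]
    counts[idx, others[2L]] <- e2[idx]
    counts[idx, others[3L]] <- e3[idx]
  }
  dt[, `:=`(
    ref_base = ref_chars, depth = depth,
    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
    T = counts[, "T"], N = 0L,
    indel_fraction = fifelse(depth > 0L, indel_reads / depth, 0)
  )]
  setorder(dt, seq_id, pos)
  dt[]
}

#' Simulate alignment, tree and signal-table fixtures with planted truth
#'
#' Protein alignments start from a per-column consensus shared by all
#' species; gap columns put a gap in one background species, and planted
#' unique-substitution columns (placed more than `gap_flank` columns from
#' any gap) give the focal species a divergent residue -- by construction
#' these are exactly the columns a correct scanner recovers.  Trees are
#' random rooted topologies whose focal terminal branch is extended so the
#' focal root-to-tip distance is strictly maximal.  The signal table draws
#' the five adaptation signals independently at `signal_prob`.
#'
#' @param config [sim_config()] (only the seed is used).
#' @param n_alignments,n_species,aln_length Alignment fixture dimensions.
#' @param n_unique_per_aln Planted unique substitutions per alignment.
#' @param n_gap_cols Gap-carrying columns per alignment.
#' @param gap_flank Exclusion radius the planting respects (default 5).
#' @param n_signal_genes,signal_prob Signal-table dimensions.
#' @param focal Focal species name.
#' @return List: `alignments`, `planted_substitutions`, `trees`,
#'   `signal_table`, `focal`.
#' @export
simulate_signal_fixtures <- function(config = sim_config(),
                                     n_alignments = 10L, n_species = 6L,
                                     aln_length = 300L,
                                     n_unique_per_aln = 5L, n_gap_cols = 2L,
                                     gap_flank = 5L,
                                     n_signal_genes = 1000L,
                                     signal_prob = 0.5, focal = "tiger") {
  stopifnot(inherits(config, "sim_config"), n_species >= 3L)
  set.seed(config$seed + 7L)
  species <- c(focal, sprintf("sp%02d", seq_len(n_species - 1L)))
  aa20 <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], character())

  alignments <- list()
  planted <- list()
  for (a in seq_len(n_alignments)) {
    cons <- sample(aa20, aln_length, replace = TRUE)
    mat <- matrix(rep(cons, each = n_species), nrow = n_species,
                  dimnames = list(species, NULL))
    gap_cols <- if (n_gap_cols > 0L) {
      sort(sample(aln_length, n_gap_cols))
    } else integer()
    for (g in gap_cols) {
      mat[sample(species[-1L], 1L), g] <- "-"
    }
    near <- rep(FALSE, aln_length)
    for (g in gap_cols) {
      near[max(1L, g - gap_flank):min(aln_length, g + gap_flank)] <- TRUE
    }
    pool <- which(!near)
    ucols <- sort(sample(pool, min(n_unique_per_aln, length(pool))))
    for (u in ucols) {
      mat[focal, u] <- sample(setdiff(aa20, cons[u]), 1L)
    }
    alignments[[a]] <- apply(mat, 1L, paste, collapse = "")
    planted[[a]] <- data.table(
      aln_id = a, column = ucols,
      background_aa = cons[ucols],
      focal_aa = mat[focal, ucols]
    )
  }

  trees <- lapply(seq_len(n_alignments), function(a) {
    tr <- ape::rtree(n_species, tip.label = sample(species))
    d <- ape::node.depth.edgelength(tr)[seq_len(n_species)]
    fi <- match(focal, tr$tip.label)
    fe <- which(tr$edge[, 2L] == fi)
    tr$edge.length[fe] <- tr$edge.length[fe] +
      max(d[-fi]) - d[fi] + 0.5
    tr
  })

  signal_table <- data.table(
    gene_id = sprintf("sig%05d", seq_len(n_signal_genes))
  )
  for (s in MSA_SIGNALS) {
    signal_table[, (s) := as.logical(rbinom(n_signal_genes, 1L, signal_prob))]
  }

  list(alignments = alignments,
       planted_substitutions = rbindlist(planted),
       trees = trees, signal_table = signal_table[], focal = focal)
}
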