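# 12 bp scaffold, CDS 1-6 + 10-12: ATG AAA | intron CCC | TAA
TOY_SEQ <- c(scaf1 = "ATGAAACCCTAA")
toy_gtf_lines <- function(strand = "+", frames = c(0L, 0L)) {
  # frames given in genomic row order
  c("#!genome-build toy",
    sprintf('scaf1\ttoy\tCDS\t1\t6\t.\t%s\t%d\tgene_id "g1"; transcript_id "t1";',
            strand, frames[1]),
    sprintf('scaf1\ttoy\tCDS\t10\t12\t.\t%s\t%d\tgene_id "g1"; transcript_id "t1";',
            strand, frames[2]))
}

test_that("load_gtf assembles plus- and minus-strand models", {
  m <- load_gtf(toy_gtf(toy_gtf_lines("+")))
  expect_equal(nrow(m$transcripts), 1L)
  expect_equal(m$transcripts$cds_len, 9L)
  expect_false(m$transcripts$partial)
  expect_equal(extract_cds(m, TOY_SEQ)[["t1"]], "ATGAAATAA")

  # same coordinates minus strand: reverse complement, segment order reversed
  mm <- load_gtf(toy_gtf(toy_gtf_lines("-", frames = c(0L, 0L))))
  expect_equal(mm$segments$start, c(10L, 1L))  # transcript orientation
  expect_equal(extract_cds(mm, TOY_SEQ)[["t1"]], "TTATTTCAT")
  expect_equal(
    extract_cds(mm, TOY_SEQ)[["t1"]],
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAString("ATGAAATAA")))
  )
})

test_that("load_gtf flags frame problems and skips orphan CDS", {
  # phase chain 0 -> 0 is wrong for a 6 bp first exon (expected 0 -> 0 ok);
  # force inconsistency with a 6+3 layout claiming phase 1 on exon 2
  bad <- load_gtf(toy_gtf(toy_gtf_lines("+", frames = c(0L, 1L))))
  expect_true(bad$transcripts$partial)

  orphan <- c("#!genome-build toy",
              'scaf1\ttoy\tCDS\t1\t6\t.\t+\t0\tgene_id "g1";',
              'scaf1\ttoy\tCDS\t10\t12\t.\t+\t0\tgene_id "g1"; transcript_id "t1";')
  expect_warning(m <- load_gtf(toy_gtf(orphan)), "transcript_id")
  expect_equal(nrow(m$segments), 1L)

  # a non-zero first phase is honoured by trimming, not flagged partial
  part <- c("#!genome-build toy",
            'scaf1\ttoy\tCDS\t1\t7\t.\t+\t1\tgene_id "g1"; transcript_id "t1";')
  mp <- load_gtf(toy_gtf(part))
  expect_false(mp$transcripts$partial)
  expect_equal(extract_cds(mp, TOY_SEQ)[["t1"]], "TGAAAC")
})

decision_row <- function(seq_id, pos, ref, alt) {
  data.table::data.table(seq_id = seq_id, pos = as.integer(pos),
                         ref_base = ref, max_base = alt, ref_count = 2L,
                         max_count = 50L, status = "corrected")
}

test_that("project_corrections classifies effects across strands", {
  m <- load_gtf(toy_gtf(toy_gtf_lines("+")))
  # third base of codon 1: G -> A, ATG(M) -> ATA(I): nonsynonymous
  p1 <- project_corrections(m, decision_row("scaf1", 3, "G", "A"), TOY_SEQ)
  expect_equal(p1$codon_corrections$ref_codon, "ATG")
  expect_equal(p1$codon_corrections$corrected_codon, "ATA")
  expect_equal(p1$codon_corrections$effect, "start_loss")  # codon 1 ATG lost
  expect_equal(p1$cds_corrected[["t1"]], "ATAAAATAA")

  # synonymous third-position change: AAA(K) -> AAG(K)
  p2 <- project_corrections(m, decision_row("scaf1", 6, "A", "G"), TOY_SEQ)
  expect_equal(p2$codon_corrections$effect, "synonymous")

  # stop codon lost: TAA -> CAA via site 10 on the second exon
  p3 <- project_corrections(m, decision_row("scaf1", 10, "T", "C"), TOY_SEQ)
  expect_equal(p3$codon_corrections$codon_index, 3L)
  expect_equal(p3$codon_corrections$effect, "stop_loss")

  # minus strand: genomic G at pos 3 is C in transcript space
  mm <- load_gtf(toy_gtf(toy_gtf_lines("-")))
  pm <- project_corrections(mm, decision_row("scaf1", 3, "G", "A"), TOY_SEQ)
  expect_equal(pm$codon_corrections$ref_codon, "CAT")
  expect_equal(pm$codon_corrections$corrected_codon, "TAT")  # complemented alt
  expect_equal(pm$codon_corrections$effect, "nonsynonymous")
})

test_that("two corrected sites in one codon merge into one record", {
  m <- load_gtf(toy_gtf(toy_gtf_lines("+")))
  dec <- rbind(decision_row("scaf1", 4, "A", "G"),
               decision_row("scaf1", 6, "A", "G"))
  p <- project_corrections(m, dec, TOY_SEQ)
  expect_equal(nrow(p$codon_corrections), 1L)
  expect_equal(p$codon_corrections$ref_codon, "AAA")
  expect_equal(p$codon_corrections$corrected_codon, "GAG")
  expect_equal(p$codon_corrections$genomic_sites[[1]], c(4L, 6L))
  # agrees with translate-and-diff on the whole CDS
  oracle <- oracle_codon_diff(extract_cds(m, TOY_SEQ)[["t1"]],
                              p$cds_corrected[["t1"]])
  expect_equal(p$codon_corrections$effect, oracle$effect)
  expect_equal(p$codon_corrections$codon_index, oracle$codon_index)
})

test_that("sites in partial transcripts are reported unprojectable", {
  bad <- load_gtf(toy_gtf(toy_gtf_lines("+", frames = c(0L, 1L))))
  p <- project_corrections(bad, decision_row("scaf1", 3, "G", "A"), TOY_SEQ)
  expect_equal(nrow(p$codon_corrections), 0L)
  expect_equal(p$unprojectable$reason, "partial_transcript")
  expect_equal(p$unprojectable$pos, 3L)
})

test_that("projection matches simulator ground truth and the translation oracle", {
  sim <- simulate_truth(sim_config(seed = 31, genome_length = 40000,
                                   n_genes = 12, n_injected_errors = 250,
                                   fraction_errors_in_cds = 0.6))
  models <- load_gtf(toy_gtf(sim$gtf))
  dec <- classify_positions(simulate_pileup(sim, "same"))
  proj <- project_corrections(models, dec, sim$corrupted_genome)
  cc <- proj$codon_corrections

  truth <- sim$coding_effects
  m <- merge(cc, truth, by = c("transcript_id", "codon_index"))
  expect_equal(nrow(m), nrow(truth))
  expect_equal(nrow(cc), nrow(truth))
  expect_equal(m$ref_codon.x, m$ref_codon.y)
  expect_equal(m$corrected_codon.x, m$corrected_codon.y)
  expect_equal(m$effect.x, m$effect.y)

  # translation oracle per transcript
  cds_orig <- extract_cds(models, sim$corrupted_genome)
  for (tid in unique(cc$transcript_id)) {
    oracle <- oracle_codon_diff(cds_orig[[tid]], proj$cds_corrected[[tid]])
    got <- cc[transcript_id == tid][order(codon_index)]
    expect_equal(got$codon_index, oracle$codon_index)
    expect_equal(got$effect, oracle$effect)
  }

  # conservation: per-gene codon totals equal distinct (transcript, codon)
  g <- summarize_gene_effects(cc)
  expect_equal(sum(g$n_codons_corrected),
               nrow(unique(cc[, .(transcript_id, codon_index)])))
})

test_that("strand symmetry: flipping the scaffold preserves effect classes", {
  sim <- simulate_truth(sim_config(seed = 33, genome_length = 15000,
                                   n_scaffolds = 1, n_genes = 5,
                                   n_injected_errors = 120,
                                   fraction_errors_in_cds = 0.7))
  models <- load_gtf(toy_gtf(sim$gtf))
  dec <- classify_positions(simulate_pileup(sim, "same"))
  fwd <- project_corrections(models, dec, sim$corrupted_genome)

  L <- nchar(sim$corrupted_genome[["scaf1"]])
  comp <- function(b) chartr("ACGT", "TGCA", b)
  flip_strand <- c("+" = "-", "-" = "+")
  segs <- sim$genes
  gtf_flip <- c("#!genome-build toy", sprintf(
    'scaf1\ttoy\tCDS\t%d\t%d\t.\t%s\t%d\tgene_id "%s"; transcript_id "%s";',
    L - segs$end + 1L, L - segs$start + 1L, flip_strand[segs$strand],
    segs$frame, segs$gene_id, segs$transcript_id
  ))
  models_flip <- load_gtf(toy_gtf(gtf_flip))
  genome_flip <- c(scaf1 = as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(sim$corrupted_genome[["scaf1"]]))))
  dec_flip <- data.table::copy(dec[status == "corrected"])
  dec_flip[, `:=`(pos = L - pos + 1L, ref_base = comp(ref_base),
                  max_base = comp(max_base))]
  rev_ <- project_corrections(models_flip, dec_flip, genome_flip)

  a <- fwd$codon_corrections[order(transcript_id, codon_index),
                             .(transcript_id, codon_index, effect)]
  b <- rev_$codon_corrections[order(transcript_id, codon_index),
                              .(transcript_id, codon_index, effect)]
  expect_equal(a, b)
})

test_that("summarize_gene_effects counts overlapping classes", {
  cc <- data.table::data.table(
    gene_id = c("g1", "g1", "g2"),
    transcript_id = c("t1", "t1", "t2"),
    seq_id = "s", codon_index = c(1L, 2L, 1L),
    ref_codon = c("AAA", "GGA", "TTA"),
    corrected_codon = c("AAG", "GGG", "TCA"),
    ref_aa = c("K", "G", "L"), corrected_aa = c("K", "G", "S"),
    effect = c("synonymous", "synonymous", "nonsynonymous"),
    genomic_sites = list(1L, 2L, 3L)
  )
  g <- summarize_gene_effects(cc)
  expect_equal(g[gene_id == "g1", .(has_synonymous, has_nonsynonymous)],
               data.table::data.table(has_synonymous = TRUE,
                                      has_nonsynonymous = FALSE))
  expect_equal(g[gene_id == "g2"]$has_nonsynonymous, TRUE)
  expect_equal(nrow(summarize_gene_effects(cc[0])), 0L)
})
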