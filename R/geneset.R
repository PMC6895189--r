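#' Load CDS gene models from an Ensembl-dialect GTF
#'
#' Only `CDS` features are used.  Segments are ordered 5'->3' in transcript
#' orientation (reverse genomic order on the minus strand) and the GTF frame
#' (phase) column is honoured: a non-zero first phase marks a 5'-partial CDS
#' whose leading bases are trimmed before codon numbering.  Transcripts whose
#' phase chain is internally inconsistent, or whose effective CDS length is
#' not a multiple of 3, are flagged `partial` and excluded from codon calls.
#'
#' @param path GTF file; `#!` header lines are ignored.
#' @return A `transcript_models` object: list with `segments` (one row per
#'   CDS segment with transcript-orientation `offset`) and `transcripts`
#'   (per-transcript strand, CDS length, first phase, `partial` flag).
#' @export
load_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0L) stop("no CDS features in ", path)
  tid <- cds$transcript_id
  if (anyNA(tid)) {
    warning(sum(is.na(tid)), " CDS feature(s) without transcript_id skipped")
    cds <- cds[!is.na(tid)]
  }
  segs <- data.table(
    seq_id = as.character(GenomeInfoDb::seqnames(cds)),
    start = BiocGenerics::start(cds),
    end = BiocGenerics::end(cds),
    strand = as.character(BiocGenerics::strand(cds)),
    frame = cds$phase,
    gene_id = cds$gene_id,
    transcript_id = cds$transcript_id
  )
  if (any(!segs$strand %in% c("+", "-"))) {
    stop("CDS feature with undefined strand")
  }
  if (anyNA(segs$frame)) {
    warning("CDS feature(s) with missing frame treated as frame 0")
    segs[is.na(frame), frame := 0L]
  }
  build_transcript_models(segs)
}

#' @noRd
build_transcript_models <- function(segs) {
  segs <- copy(segs)
  # transcript orientation: plus by ascending start, minus by descending
  segs[, seg_len := end - start + 1L]
  setorder(segs, transcript_id, start)
  segs[strand == "-", `:=`(
    start = rev(start), end = rev(end), frame = rev(frame),
    seg_len = rev(seg_len)
  ), by = transcript_id]
  segs[, seg_idx := seq_len(.N), by = transcript_id]
  segs[, offset := cumsum(shift(seg_len, fill = 0L)), by = transcript_id]

  tx <- segs[, {
    # GFF phase chain: phase[i+1] == (3 - (len[i] - phase[i]) %% 3) %% 3
    expected <- c(frame[1L],
                  (3L - (cumsum(seg_len) - frame[1L]) %% 3L) %% 3L)[seq_len(.N)]
    chain_ok <- all(frame == expected)
    eff_len <- sum(seg_len) - frame[1L]
    .(gene_id = gene_id[1L], seq_id = seq_id[1L], strand = strand[1L],
      cds_len = sum(seg_len), phase1 = frame[1L],
      partial = !chain_ok || eff_len %% 3L != 0L)
  }, by = transcript_id]

  structure(list(segments = segs[], transcripts = tx[]),
            class = "transcript_models")
}

#' @export
print.transcript_models <- function(x, ...) {
  cat("transcript_models:", nrow(x$transcripts), "transcripts (",
      sum(x$transcripts$partial), "partial ),",
      nrow(x$segments), "CDS segments\n")
  invisible(x)
}

#' Extract CDS sequences for every transcript
#'
#' Concatenates CDS segments in transcript orientation (reverse-complemented
#' on the minus strand), trims leading bases indicated by the first phase,
#' and uppercases.
#'
#' @param models [load_gtf()] result.
#' @param assembly Named character vector or FASTA path.
#' @return Named character vector keyed by transcript_id.
#' @export
extract_cds <- function(models, assembly) {
  seqs <- as_assembly(assembly)
  segs <- models$segments
  missing_seq <- setdiff(unique(segs$seq_id), names(seqs))
  if (length(missing_seq)) {
    stop("GTF scaffold absent from assembly: ", missing_seq[1L])
  }
  pieces <- segs[, {
    raw <- substring(seqs[[seq_id[1L]]], start, end)
    if (strand[1L] == "-") raw <- revcomp(raw)
    .(cds = paste(raw, collapse = ""))
  }, by = transcript_id]
  out <- toupper(pieces$cds)
  names(out) <- pieces$transcript_id
  p1 <- models$transcripts$phase1[match(names(out),
                                        models$transcripts$transcript_id)]
  trim <- p1 > 0L
  out[trim] <- substring(out[trim], p1[trim] + 1L)
  out
}

#' Project corrected sites into codons and classify effects
#'
#' Every corrected genomic site overlapping the CDS of k transcripts yields
#' k codon records; multiple corrected sites in one codon merge into a
#' single record listing all contributing genomic positions.  Minus-strand
#' replacement bases are complemented before substitution.  Effects follow
#' the standard nuclear genetic code: `synonymous`, `nonsynonymous`,
#' `stop_gain`, `stop_loss`, and `start_loss` (first codon ATG lost).
#' Corrected sites landing in `partial`-flagged transcripts, or upstream of
#' the frame-trimmed CDS start, are returned as `unprojectable` rather than
#' silently dropped.
#'
#' @param models [load_gtf()] result.
#' @param decisions Decision table or ledger; only `status == "corrected"`
#'   rows are projected.
#' @param assembly The ORIGINAL (pre-correction) assembly, so reference
#'   codons are reconstructable.
#' @return List with `codon_corrections` (one row per transcript x codon;
#'   `genomic_sites` is a list column), `cds_corrected` (full corrected CDS
#'   set, every transcript), and `unprojectable`.
#' @export
project_corrections <- function(models, decisions, assembly) {
  seqs <- as_assembly(assembly)
  decisions <- as.data.table(decisions)
  corr <- decisions[status == "corrected",
                    .(seq_id, pos, ref_base, max_base)]

  # corrected CDS set: apply the genomic patches, re-extract every transcript
  patched <- correct_assembly(seqs, decisions)$sequences
  cds_corrected <- extract_cds(models, patched)

  empty_cc <- data.table(
    gene_id = character(), transcript_id = character(), seq_id = character(),
    codon_index = integer(), ref_codon = character(),
    corrected_codon = character(), ref_aa = character(),
    corrected_aa = character(), effect = character(),
    genomic_sites = list()
  )
  empty_un <- data.table(transcript_id = character(), seq_id = character(),
                         pos = integer(), reason = character())
  if (nrow(corr) == 0L) {
    return(list(codon_corrections = empty_cc, cds_corrected = cds_corrected,
                unprojectable = empty_un))
  }

  segs <- models$segments
  hits <- segs[corr, on = .(seq_id, start <= pos, end >= pos), nomatch = NULL,
               .(transcript_id, gene_id, seq_id, strand,
                 seg_start = x.start, seg_end = x.end, offset,
                 pos = i.pos, ref_base = i.ref_base, max_base = i.max_base)]
  if (nrow(hits) == 0L) {
    return(list(codon_corrections = empty_cc, cds_corrected = cds_corrected,
                unprojectable = empty_un))
  }
  tx <- models$transcripts
  hits <- tx[, .(transcript_id, phase1, partial)][hits, on = "transcript_id"]

  unprojectable <- hits[partial == TRUE,
                        .(transcript_id, seq_id, pos,
                          reason = "partial_transcript")]
  hits <- hits[partial == FALSE]

  hits[, within := fifelse(strand == "+", pos - seg_start + 1L,
                           seg_end - pos + 1L)]
  hits[, cds_pos := offset + within - phase1]
  up <- hits[cds_pos < 1L,
             .(transcript_id, seq_id, pos, reason = "upstream_of_frame")]
  unprojectable <- rbindlist(list(unprojectable, up))
  hits <- hits[cds_pos >= 1L]
  if (nrow(hits) == 0L) {
    return(list(codon_corrections = empty_cc, cds_corrected = cds_corrected,
                unprojectable = unprojectable[]))
  }

  hits[, codon_index := (cds_pos - 1L) %/% 3L + 1L]
  hits[, pos_in_codon := (cds_pos - 1L) %% 3L + 1L]
  hits[, new_base := fifelse(strand == "+", toupper(max_base),
                             complement_base(toupper(max_base)))]

  cds_orig <- extract_cds(models, seqs)
  cc <- hits[, {
    cds <- cds_orig[[transcript_id[1L]]]
    rc <- substr(cds, (codon_index[1L] - 1L) * 3L + 1L, codon_index[1L] * 3L)
    # sanity: the oriented assembly base must sit where the ledger says
    ori_ref <- fifelse(strand == "+", toupper(ref_base),
                       complement_base(toupper(ref_base)))
    got <- substring(rc, pos_in_codon, pos_in_codon)
    if (!all(got == ori_ref)) {
      stop("assembly/annotation skew at ", seq_id[1L], ":", pos[1L],
           " (transcript ", transcript_id[1L], ")")
    }
    nc <- strsplit(rc, "", fixed = TRUE)[[1L]]
    nc[pos_in_codon] <- new_base
    .(gene_id = gene_id[1L], seq_id = seq_id[1L],
      ref_codon = rc, corrected_codon = paste(nc, collapse = ""),
      genomic_sites = list(sort(pos)))
  }, by = .(transcript_id, codon_index)]

  cc[, ref_aa := translate_codons(ref_codon)]
  cc[, corrected_aa := translate_codons(corrected_codon)]
  cc[, effect := classify_effect(ref_aa, corrected_aa, codon_index)]
  setorderv(cc, c("transcript_id", "codon_index"))
  list(
    codon_corrections = cc[, .(gene_id, transcript_id, seq_id, codon_index,
                               ref_codon, corrected_codon, ref_aa,
                               corrected_aa, effect, genomic_sites)],
    cds_corrected = cds_corrected,
    unprojectable = unprojectable[]
  )
}

#' @noRd
classify_effect <- function(ref_aa, corrected_aa, codon_index) {
  fifelse(corrected_aa == "*" & ref_aa != "*", "stop_gain",
  fifelse(ref_aa == "*" & corrected_aa != "*", "stop_loss",
  fifelse(codon_index == 1L & ref_aa == "M" & corrected_aa != "M",
          "start_loss",
  fifelse(ref_aa == corrected_aa, "synonymous", "nonsynonymous"))))
}

#' Per-gene summary of codon corrections
#'
#' A gene counts as non-synonymous if any of its corrected codons is
#' `nonsynonymous`, `stop_gain`, `stop_loss` or `start_loss`, and as
#' synonymous if any is `synonymous`; a gene can appear in both classes.
#' `n_codons_corrected` counts distinct (transcript, codon) pairs, so gene
#' totals conserve the codon-record count.
#'
#' @param codon_corrections From [project_corrections()].
#' @return Per-gene `data.table`.
#' @export
summarize_gene_effects <- function(codon_corrections) {
  cc <- as.data.table(codon_corrections)
  if (nrow(cc) == 0L) {
    return(data.table(gene_id = character(), n_codons_corrected = integer(),
                      n_synonymous = integer(), n_nonsynonymous = integer(),
                      has_synonymous = logical(), has_nonsynonymous = logical()))
  }
  nonsyn <- c("nonsynonymous", "stop_gain", "stop_loss", "start_loss")
  out <- cc[, .(
    n_codons_corrected = uniqueN(paste(transcript_id, codon_index)),
    n_synonymous = sum(effect == "synonymous"),
    n_nonsynonymous = sum(effect %in% nonsyn),
    has_synonymous = any(effect == "synonymous"),
    has_nonsynonymous = any(effect %in% nonsyn)
  ), by = gene_id]
  setorder(out, gene_id)
  out[]
}
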