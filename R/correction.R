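#' Correction rule parameters
#'
#' The published defaults: positions with coverage below 10x or above 200x,
#' or with more than 10% of reads supporting an indel, are ineligible; among
#' eligible positions the assembly base is replaced by the most frequent read
#' base when its own count is at most one fifth (`1/ratio_denominator`) of
#' the most frequent base's count.
#'
#' @param min_cov Minimum eligible coverage (default 10).
#' @param max_cov Maximum eligible coverage (default 200).
#' @param max_indel_fraction Maximum eligible indel read fraction (default 0.10).
#' @param ratio_denominator Replacement stringency: correct when
#'   `ref_count * ratio_denominator <= max_count` (default 5).
#' @param correct_N_reference Allow replacing an assembly `N` (default FALSE;
#'   gap filling is a different problem).
#' @return A `correction_params` list.
#' @export
correction_params <- function(min_cov = 10L, max_cov = 200L,
                              max_indel_fraction = 0.10,
                              ratio_denominator = 5L,
                              correct_N_reference = FALSE) {
  min_cov <- as.integer(min_cov)
  max_cov <- as.integer(max_cov)
  ratio_denominator <- as.integer(ratio_denominator)
  if (is.na(min_cov) || min_cov < 1L) stop("min_cov must be >= 1")
  if (is.na(max_cov) || max_cov <= min_cov) stop("max_cov must exceed min_cov")
  if (!is.numeric(max_indel_fraction) || is.na(max_indel_fraction) ||
      max_indel_fraction <= 0 || max_indel_fraction >= 1) {
    stop("max_indel_fraction must lie in (0, 1)")
  }
  if (is.na(ratio_denominator) || ratio_denominator < 1L) {
    stop("ratio_denominator must be >= 1")
  }
  structure(
    list(min_cov = min_cov, max_cov = max_cov,
         max_indel_fraction = max_indel_fraction,
         ratio_denominator = ratio_denominator,
         correct_N_reference = isTRUE(correct_N_reference)),
    class = "correction_params"
  )
}

CORRECTION_STATUSES <- c(
  "corrected", "kept", "ineligible_low_cov", "ineligible_high_cov",
  "ineligible_indel", "ineligible_ref_N", "ambiguous_tie"
)

#' Classify every pileup position under the correction rule
#'
#' Eligibility filters are applied in order low coverage, high coverage,
#' indel fraction, reference N.  Among eligible positions the most frequent
#' base (`max_base`) is the argmax over A/C/G/T counts -- N is never a
#' replacement allele.  A position is `corrected` when `max_base` differs
#' from the assembly base and `ref_count * ratio_denominator <= max_count`
#' (inclusive one-fifth rule, integer cross-multiplication so there is no
#' floating-point boundary).  When two or more non-reference bases tie for
#' the maximum and the rule would otherwise fire, the position is reported
#' `ambiguous_tie` and left uncorrected.  IUPAC ambiguity codes other than N
#' in the reference column are treated as N.
#'
#' @param pileup Pileup table ([read_pileup()]).
#' @param params [correction_params()].
#' @return `data.table` with one decision per position: `seq_id`, `pos`,
#'   `ref_base`, `max_base` (NA when ineligible), `ref_count`, `max_count`,
#'   `status`.
#' @export
classify_positions <- function(pileup, params = correction_params()) {
  stopifnot(inherits(params, "correction_params"))
  pileup <- as.data.table(pileup)
  n <- nrow(pileup)
  if (n == 0L) {
    return(data.table(seq_id = character(), pos = integer(),
                      ref_base = character(), max_base = character(),
                      ref_count = integer(), max_count = integer(),
                      status = character()))
  }
  counts <- as.matrix(pileup[, .(A, C, G, T)])
  storage.mode(counts) <- "integer"
  ref <- toupper(pileup$ref_base)
  ref[!ref %in% BASES_N] <- "N"

  ref_idx <- match(ref, BASES)                      # NA for N
  ref_count <- integer(n)
  has_ref <- !is.na(ref_idx)
  ref_count[has_ref] <- counts[cbind(which(has_ref), ref_idx[has_ref])]

  max_count <- do.call(pmax.int, as.data.frame(counts))
  n_at_max <- rowSums(counts == max_count)
  max_base <- BASES[max.col(counts, ties.method = "first")]
  ref_at_max <- has_ref & ref_count == max_count

  denom <- params$ratio_denominator
  would_fire <- max_count > 0L &
    as.numeric(ref_count) * denom <= as.numeric(max_count)

  status <- rep("kept", n)
  status[would_fire & !ref_at_max & n_at_max == 1L] <- "corrected"
  status[would_fire & !ref_at_max & n_at_max >= 2L] <- "ambiguous_tie"
  if (!params$correct_N_reference) status[ref == "N"] <- "ineligible_ref_N"
  status[pileup$indel_fraction > params$max_indel_fraction] <- "ineligible_indel"
  status[pileup$depth > params$max_cov] <- "ineligible_high_cov"
  status[pileup$depth < params$min_cov] <- "ineligible_low_cov"

  ineligible <- startsWith(status, "ineligible")
  max_base[ineligible | n_at_max >= 2L] <- NA_character_

  data.table(
    seq_id = pileup$seq_id, pos = pileup$pos, ref_base = ref,
    max_base = max_base, ref_count = ref_count, max_count = max_count,
    status = status
  )
}

#' Apply corrections to an assembly
#'
#' Patches every `status == "corrected"` site.  The assembly base must equal
#' the decision's `ref_base` (case-insensitively) -- a mismatch aborts with
#' the offending site, guarding against assembly/pileup version skew.
#' Soft-masked (lowercase) bases stay lowercase after replacement; nothing
#' else in the sequences changes.
#'
#' @param assembly Named character vector of sequences, or a FASTA path.
#' @param decisions Decision table from [classify_positions()].
#' @return List with `sequences` (corrected, named character) and `report`:
#'   per-status counts, per-scaffold corrected counts, and totals with
#'   genome-size denominators both including and excluding assembly N runs.
#' @export
correct_assembly <- function(assembly, decisions) {
  seqs <- as_assembly(assembly)
  decisions <- as.data.table(decisions)
  corr <- decisions[status == "corrected"]
  if (nrow(corr)) {
    missing_seq <- setdiff(unique(corr$seq_id), names(seqs))
    if (length(missing_seq)) {
      stop("corrected site on unknown scaffold: ", missing_seq[1L])
    }
    for (sid in unique(corr$seq_id)) {
      s <- seqs[[sid]]
      sub <- corr[seq_id == sid]
      if (any(sub$pos > nchar(s))) {
        bad <- sub[pos > nchar(s)][1L]
        stop("corrected site ", sid, ":", bad$pos, " beyond scaffold end")
      }
      old <- substring(s, sub$pos, sub$pos)
      if (!all(toupper(old) == toupper(sub$ref_base))) {
        i <- which(toupper(old) != toupper(sub$ref_base))[1L]
        stop("assembly base '", old[i], "' at ", sid, ":", sub$pos[i],
             " does not match ledger ref_base '", sub$ref_base[i],
             "' -- assembly/pileup version skew?")
      }
      lower <- old != toupper(old)
      repl <- ifelse(lower, tolower(sub$max_base), toupper(sub$max_base))
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      ch[sub$pos] <- repl
      seqs[[sid]] <- paste(ch, collapse = "")
    }
  }
  genome_size <- sum(nchar(seqs))
  n_count <- sum(vapply(
    seqs, function(s) lengths(regmatches(s, gregexpr("[Nn]", s))), 0L
  ))
  per_status <- as.list(table(factor(decisions$status,
                                     levels = CORRECTION_STATUSES)))
  per_scaffold <- if (nrow(corr)) corr[, .(corrected = .N), by = seq_id] else
    data.table(seq_id = character(), corrected = integer())
  report <- list(
    total_positions = nrow(decisions),
    eligible = sum(!startsWith(decisions$status, "ineligible")),
    corrected = nrow(corr),
    per_status = per_status,
    per_scaffold = per_scaffold,
    genome_size = genome_size,
    genome_size_non_N = genome_size - n_count,
    corrected_fraction = if (genome_size) nrow(corr) / genome_size else 0,
    corrected_fraction_non_N =
      if (genome_size > n_count) nrow(corr) / (genome_size - n_count) else 0
  )
  list(sequences = seqs, report = report)
}

#' @noRd
as_assembly <- function(assembly) {
  if (is.character(assembly) && length(assembly) == 1L &&
      is.null(names(assembly)) && file.exists(assembly)) {
    return(read_fasta(assembly))
  }
  stopifnot(is.character(assembly), !is.null(names(assembly)))
  assembly
}

#' Write the correction ledger (VCF + TSV)
#'
#' The VCF (v4.2) carries one record per corrected site with `REF` the
#' assembly base, `ALT` the replacement, and `INFO` fields `RC` (ref_base
#' count), `MC` (max_base count) and `ST` (status).  The TSV mirrors the
#' decision table; with `emit_all = FALSE` (default) only corrected sites
#' are written, with `emit_all = TRUE` every status including the ineligible
#' and ambiguous classes.
#'
#' @param decisions Decision table from [classify_positions()].
#' @param vcf_path Output VCF path (NULL to skip).
#' @param tsv_path Output TSV path (NULL to skip).
#' @param emit_all Include non-corrected statuses in the TSV.
#' @export
write_correction_ledger <- function(decisions, vcf_path = NULL,
                                    tsv_path = NULL, emit_all = FALSE) {
  decisions <- as.data.table(decisions)
  corr <- decisions[status == "corrected"]
  setorder(corr, seq_id, pos)
  if (!is.null(vcf_path)) {
    hdr <- c(
      "##fileformat=VCFv4.2",
      "##source=seqbug",
      '##INFO=<ID=RC,Number=1,Type=Integer,Description="Read count supporting the assembly (reference) base">',
      '##INFO=<ID=MC,Number=1,Type=Integer,Description="Read count supporting the most frequent base">',
      '##INFO=<ID=ST,Number=1,Type=String,Description="Correction status">',
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"
    )
    rec <- if (nrow(corr)) paste(
      corr$seq_id, corr$pos, ".", corr$ref_base, corr$max_base, ".", "PASS",
      paste0("RC=", corr$ref_count, ";MC=", corr$max_count, ";ST=corrected"),
      sep = "\t"
    ) else character()
    writeLines(c(hdr, rec), vcf_path)
  }
  if (!is.null(tsv_path)) {
    out <- if (emit_all) decisions else corr
    fwrite(out, tsv_path, sep = "\t")
  }
  invisible(list(vcf = vcf_path, tsv = tsv_path, n_corrected = nrow(corr)))
}

#' Read a correction ledger VCF back into a decision table
#'
#' @param vcf_path Ledger written by [write_correction_ledger()].
#' @return Decision table (all rows `status == "corrected"`).
#' @export
read_correction_ledger <- function(vcf_path) {
  lines <- readLines(vcf_path)
  lines <- lines[!startsWith(lines, "#")]
  if (!length(lines)) {
    return(data.table(seq_id = character(), pos = integer(),
                      ref_base = character(), max_base = character(),
                      ref_count = integer(), max_count = integer(),
                      status = character()))
  }
  f <- strsplit(lines, "\t", fixed = TRUE)
  info <- vapply(f, `[[`, "", 8L)
  grab <- function(key) {
    m <- regmatches(info, regexpr(paste0("(?<=", key, "=)[^;]+"), info,
                                  perl = TRUE))
    suppressWarnings(as.integer(m))
  }
  dt <- data.table(
    seq_id = vapply(f, `[[`, "", 1L),
    pos = as.integer(vapply(f, `[[`, "", 2L)),
    ref_base = vapply(f, `[[`, "", 4L),
    max_base = vapply(f, `[[`, "", 5L),
    ref_count = grab("RC"),
    max_count = grab("MC"),
    status = "corrected"
  )
  setorder(dt, seq_id, pos)
  dt[]
}
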