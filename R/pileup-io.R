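#' Read a bam-readcount style per-base pileup
#'
#' Parses the tab-separated per-position metrics emitted by bam-readcount:
#' `seq_id  pos  ref_base  depth  allele:count[:...]  allele:count[:...] ...`
#' Each allele block is colon-delimited with the allele symbol first and its
#' read count second; trailing per-allele statistics are ignored.  Counts are
#' assumed to be restricted upstream to reads with mapping quality >= 25 and
#' base quality >= 25 (the filters are applied by the readcount step, not
#' here).  Insertion/deletion alleles (leading `+`/`-`) are collapsed into a
#' single per-position `indel_fraction`; allele symbols other than A/C/G/T
#' (e.g. `=`) are folded into N.
#'
#' @param path Pileup TSV, plain or gzip-compressed.
#' @param region Optional scaffold name; only rows for that `seq_id` are kept.
#' @return A `data.table` with one row per position, ordered by
#'   `(seq_id, pos)`: columns `seq_id`, `pos` (1-based), `ref_base`, `depth`,
#'   `A`, `C`, `G`, `T`, `N`, `indel_fraction`.  If the depth field disagrees
#'   with the summed allele counts a warning is raised and the recomputed
#'   depth is kept.
#' @export
read_pileup <- function(path, region = NULL) {
  stopifnot(file.exists(path))
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_pileup())

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 4L)
  if (length(bad)) {
    stop("malformed pileup row at line ", bad[1L], ": fewer than 4 fields")
  }

  seq_id <- vapply(fields, `[[`, "", 1L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  ref <- toupper(vapply(fields, `[[`, "", 3L))
  file_depth <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
  bad <- which(is.na(pos) | pos < 1L | is.na(file_depth))
  if (length(bad)) {
    stop("malformed pileup row at line ", bad[1L],
         ": position/depth not a valid integer")
  }
  ref[!ref %in% BASES_N] <- "N"

  n <- length(lines)
  counts <- matrix(0L, nrow = n, ncol = 5L, dimnames = list(NULL, BASES_N))
  indel_reads <- integer(n)
  for (i in seq_len(n)) {
    blocks <- fields[[i]][-(1:4)]
    if (!length(blocks)) next
    parts <- strsplit(blocks, ":", fixed = TRUE)
    for (p in parts) {
      if (length(p) < 2L) {
        stop("malformed pileup row at line ", i, ": allele block '",
             paste(p, collapse = ":"), "' lacks a count")
      }
      cnt <- suppressWarnings(as.integer(p[[2L]]))
      if (is.na(cnt) || cnt < 0L) {
        stop("malformed pileup row at line ", i,
             ": allele count '", p[[2L]], "' is not a non-negative integer")
      }
      allele <- toupper(p[[1L]])
      first <- substr(allele, 1L, 1L)
      if (first %in% c("+", "-")) {
        indel_reads[i] <- indel_reads[i] + cnt
      } else if (allele %in% BASES) {
        counts[i, allele] <- counts[i, allele] + cnt
      } else {
        counts[i, "N"] <- counts[i, "N"] + cnt
      }
    }
  }

  total <- as.integer(rowSums(counts)) + indel_reads
  mismatch <- which(file_depth != total)
  depth <- file_depth
  if (length(mismatch)) {
    warning(length(mismatch), " row(s) with depth field disagreeing with ",
            "summed allele counts (first at line ", mismatch[1L],
            "); recomputed depth kept")
    depth[mismatch] <- total[mismatch]
  }

  dt <- data.table(
    seq_id = seq_id, pos = pos, ref_base = ref, depth = depth,
    A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
    T = counts[, "T"], N = counts[, "N"],
    indel_fraction = fifelse(depth > 0L, indel_reads / depth, 0)
  )
  if (!is.null(region)) dt <- dt[seq_id == region]
  setorder(dt, seq_id, pos)
  dt[]
}

#' @noRd
empty_pileup <- function() {
  data.table(
    seq_id = character(), pos = integer(), ref_base = character(),
    depth = integer(), A = integer(), C = integer(), G = integer(),
    T = integer(), N = integer(), indel_fraction = numeric()
  )
}

#' Write a pileup table in the bam-readcount TSV dialect
#'
#' Indel support is re-expanded into a single `+N:<count>` allele block with
#' `count = round(indel_fraction * depth)`, so a read/write round trip
#' reproduces every field exactly for tables whose indel fraction is a
#' multiple of `1/depth` (always true for parsed or simulated pileups).
#'
#' @param pileup Table as returned by [read_pileup()].
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @export
write_pileup <- function(pileup, path) {
  pileup <- as.data.table(pileup)
  indel_reads <- as.integer(round(pileup$indel_fraction * pileup$depth))
  blocks <- paste0(
    "A:", pileup$A, "\tC:", pileup$C, "\tG:", pileup$G,
    "\tT:", pileup$T, "\tN:", pileup$N
  )
  lines <- paste0(
    pileup$seq_id, "\t", pileup$pos, "\t", pileup$ref_base, "\t",
    pileup$depth, "\t", blocks,
    fifelse(indel_reads > 0L, paste0("\t+N:", indel_reads), "")
  )
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Histogram of per-position coverage
#'
#' Bins are left-closed, right-open intervals `[k*bin_width, (k+1)*bin_width)`.
#' Every input position is counted exactly once, so bin counts sum to the
#' number of rows.
#'
#' @param pileup Pileup table ([read_pileup()]).
#' @param bin_width Positive integer bin width (default 10).
#' @return `data.table` with `bin_start`, `bin_end` (exclusive), `count`,
#'   one row per non-empty bin, ascending.
#' @export
coverage_histogram <- function(pileup, bin_width = 10L) {
  stopifnot(is.numeric(bin_width), length(bin_width) == 1L, bin_width >= 1)
  bin_width <- as.integer(bin_width)
  pileup <- as.data.table(pileup)
  if (nrow(pileup) == 0L) {
    return(data.table(bin_start = integer(), bin_end = integer(),
                      count = integer()))
  }
  bin <- (pileup$depth %/% bin_width) * bin_width
  tab <- as.data.table(table(bin))
  out <- data.table(
    bin_start = as.integer(as.character(tab$bin)),
    count = as.integer(tab$N)
  )
  out[, bin_end := bin_start + bin_width]
  setorder(out, bin_start)
  out[, .(bin_start, bin_end, count)]
}
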