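#' Scan a protein alignment for focal-lineage unique substitutions
#'
#' A column qualifies when every non-focal (background) species carries the
#' same residue, the focal species carries a different one, no sequence has
#' a gap or `X` in the column, and the column lies more than `gap_flank`
#' alignment columns away from every column containing a gap in any
#' sequence.  The flank is measured in alignment columns (the scan operates
#' on the alignment, not on ungapped residues).
#'
#' @param aln Named character vector of equal-length aligned protein
#'   sequences (or an `AAStringSet`, or a FASTA path).
#' @param focal Name of the focal species; at least 2 background species
#'   are required for background identity to be defined.
#' @param gap_flank Gap exclusion radius in columns (default 5).
#' @return `data.table` with `column` (1-based), `background_aa`, `focal_aa`.
#' @export
find_unique_substitutions <- function(aln, focal, gap_flank = 5L) {
  if (is.character(aln) && length(aln) == 1L && is.null(names(aln)) &&
      file.exists(aln)) {
    aln <- read_fasta(aln)
  }
  if (methods::is(aln, "XStringSet")) {
    aln <- stats::setNames(as.character(aln), names(aln))
  }
  stopifnot(is.character(aln), !is.null(names(aln)))
  gap_flank <- as.integer(gap_flank)
  stopifnot(gap_flank >= 0L)
  if (!focal %in% names(aln)) stop("focal species '", focal, "' not in alignment")
  if (length(aln) - 1L < 2L) {
    stop("need at least 2 non-focal species for a defined background")
  }
  if (length(unique(nchar(aln))) != 1L) {
    stop("aligned sequences must all have equal length")
  }
  mat <- toupper(do.call(rbind, strsplit(unname(aln), "", fixed = TRUE)))
  rownames(mat) <- names(aln)
  L <- ncol(mat)
  empty <- data.table(column = integer(), background_aa = character(),
                      focal_aa = character())
  if (L == 0L) return(empty)

  gap_cols <- which(colSums(mat == "-") > 0L)
  near_gap <- rep(FALSE, L)
  if (length(gap_cols) && gap_flank > 0L) {
    for (g in gap_cols) {
      lo <- max(1L, g - gap_flank)
      hi <- min(L, g + gap_flank)
      near_gap[lo:hi] <- TRUE
    }
  }
  near_gap[gap_cols] <- TRUE

  bg <- mat[setdiff(rownames(mat), focal), , drop = FALSE]
  fo <- mat[focal, ]
  clean <- colSums(mat == "-" | mat == "X") == 0L
  bg_same <- colSums(bg != rep(bg[1L, ], each = nrow(bg))) == 0L
  hit <- which(clean & !near_gap & bg_same & fo != bg[1L, ])
  if (!length(hit)) return(empty)
  data.table(column = hit, background_aa = unname(bg[1L, hit]),
             focal_aa = unname(fo[hit]))
}

#' Root-to-tip branch-length distances
#'
#' Sums branch lengths along the unique root-to-leaf path for every tip of
#' a rooted tree.  Optionally reports whether a designated focal tip's
#' distance strictly exceeds every other tip's (the strict-maximum reading
#' of "higher nucleotide divergence"; formal significance testing is left
#' to the caller).
#'
#' @param tree `phylo` object, Newick string, or Newick file path.
#' @param focal Optional focal tip label.
#' @return List with `distances` (named numeric, one per tip), `focal`, and
#'   `focal_strictly_max` (NA when no focal tip given).
#' @export
root_to_tip_distances <- function(tree, focal = NULL) {
  if (is.character(tree) && length(tree) == 1L) {
    tree <- if (file.exists(tree)) ape::read.tree(tree) else
      ape::read.tree(text = tree)
  }
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) {
    stop("tree is unrooted; root it first (e.g. ape::root) before calling")
  }
  if (is.null(tree$edge.length) ||
      length(tree$edge.length) != nrow(tree$edge)) {
    stop("tree is missing branch lengths")
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    stop("branch lengths must all be present and >= 0")
  }
  d <- ape::node.depth.edgelength(tree)
  dist <- d[seq_along(tree$tip.label)]
  names(dist) <- tree$tip.label
  fmax <- NA
  if (!is.null(focal)) {
    if (!focal %in% tree$tip.label) stop("focal tip '", focal, "' not in tree")
    fmax <- dist[[focal]] > max(dist[names(dist) != focal])
  }
  list(distances = dist, focal = focal, focal_strictly_max = fmax)
}

MSA_SIGNALS <- c("HBW", "RTT", "PSG", "USF", "PSS")

#' Aggregate the five adaptation signals per gene
#'
#' The five boolean signals are HBW (higher branch dN/dS), RTT (higher
#' root-to-tip branch length), PSG (positively selected gene, branch-site
#' model), USF (unique substitution with functional impact) and PSS
#' (positively selected sites).  A gene shows multiple signs of adaptation
#' (MSA) when at least `threshold` signals are true.  Also emitted: the
#' gene-wide flag (all of HBW, RTT, PSG) and site-specific flag (both USF
#' and PSS), plus the full 2^5 intersection census (upset-plot input).
#' The signal values themselves come from upstream tools and are consumed
#' as precomputed columns; missing columns or NA cells are treated as FALSE
#' with a message.
#'
#' @param signals `data.frame`/`data.table` with `gene_id` and logical (or
#'   0/1) columns named after the signals, or a TSV path.
#' @param threshold Minimum number of true signals for MSA (default 3).
#' @return List with `genes` (per-gene flags), `census` (32-row pattern
#'   table whose counts sum to the gene count), `n_msa` and `msa_fraction`.
#' @export
aggregate_msa <- function(signals, threshold = 3L) {
  if (is.character(signals) && length(signals) == 1L) {
    signals <- fread(signals)
  }
  signals <- as.data.table(signals)
  stopifnot("gene_id" %in% names(signals))
  threshold <- as.integer(threshold)
  stopifnot(threshold >= 1L, threshold <= 5L)
  sig <- copy(signals)
  for (s in MSA_SIGNALS) {
    if (!s %in% names(sig)) {
      message("signal column '", s, "' missing; treated as FALSE")
      sig[, (s) := FALSE]
    }
    v <- as.logical(sig[[s]])
    if (anyNA(v)) {
      message(sum(is.na(v)), " NA cell(s) in '", s, "' treated as FALSE")
      v[is.na(v)] <- FALSE
    }
    sig[, (s) := v]
  }
  m <- as.matrix(sig[, MSA_SIGNALS, with = FALSE])
  genes <- data.table(
    gene_id = sig$gene_id,
    sig[, MSA_SIGNALS, with = FALSE],
    n_signals = as.integer(rowSums(m)),
    msa = rowSums(m) >= threshold,
    gene_wide_all3 = m[, "HBW"] & m[, "RTT"] & m[, "PSG"],
    site_specific_both = m[, "USF"] & m[, "PSS"]
  )
  pattern <- apply(m, 1L, function(r) {
    on <- MSA_SIGNALS[as.logical(r)]
    if (length(on)) paste(on, collapse = "+") else "(none)"
  })
  all_patterns <- vapply(0:31, function(k) {
    on <- MSA_SIGNALS[bitwAnd(k, 2^(0:4)) > 0]
    if (length(on)) paste(on, collapse = "+") else "(none)"
  }, "")
  census <- data.table(
    pattern = all_patterns,
    n_signals = vapply(0:31, function(k) sum(bitwAnd(k, 2^(0:4)) > 0), 0L),
    count = as.integer(table(factor(pattern, levels = all_patterns)))
  )
  setorder(census, -n_signals, pattern)
  list(genes = genes[], census = census[],
       n_msa = sum(genes$msa),
       msa_fraction = if (nrow(genes)) mean(genes$msa) else NA_real_)
}
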