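# Brute-force oracles, deliberately written as plain scalar loops so they
# stay independent of the vectorized implementation paths they check.

oracle_classify_one <- function(row, params) {
  bases <- c("A", "C", "G", "T")
  if (row$depth < params$min_cov) return("ineligible_low_cov")
  if (row$depth > params$max_cov) return("ineligible_high_cov")
  if (row$indel_fraction > params$max_indel_fraction) {
    return("ineligible_indel")
  }
  ref <- toupper(row$ref_base)
  if (!ref %in% bases) {
    if (!params$correct_N_reference) return("ineligible_ref_N")
  }
  counts <- c(A = row$A, C = row$C, G = row$G, T = row$T)
  mx <- -1L
  argmax <- character()
  for (b in bases) {
    if (counts[[b]] > mx) {
      mx <- counts[[b]]
      argmax <- b
    } else if (counts[[b]] == mx) {
      argmax <- c(argmax, b)
    }
  }
  ref_count <- if (ref %in% bases) counts[[ref]] else 0L
  fires <- mx > 0L && ref_count * params$ratio_denominator <= mx
  if (!fires) return("kept")
  if (ref %in% argmax) return("kept")
  if (length(argmax) >= 2L) return("ambiguous_tie")
  "corrected"
}

# translate-and-diff: compare two CDS strings codon by codon
oracle_codon_diff <- function(cds_ref, cds_new) {
  gc <- Biostrings::GENETIC_CODE
  stopifnot(nchar(cds_ref) == nchar(cds_new), nchar(cds_ref) %% 3 == 0)
  out <- list()
  for (ci in seq_len(nchar(cds_ref) %/% 3)) {
    a <- substr(cds_ref, (ci - 1) * 3 + 1, ci * 3)
    b <- substr(cds_new, (ci - 1) * 3 + 1, ci * 3)
    if (a == b) next
    aa_a <- gc[[a]] %||% "X"
    aa_b <- gc[[b]] %||% "X"
    eff <- if (aa_b == "*" && aa_a != "*") "stop_gain"
      else if (aa_a == "*" && aa_b != "*") "stop_loss"
      else if (ci == 1 && aa_a == "M" && aa_b != "M") "start_loss"
      else if (aa_a == aa_b) "synonymous"
      else "nonsynonymous"
    out[[length(out) + 1L]] <- data.frame(
      codon_index = ci, ref_codon = a, corrected_codon = b,
      ref_aa = aa_a, corrected_aa = aa_b, effect = eff,
      stringsAsFactors = FALSE
    )
  }
  if (!length(out)) {
    return(data.frame(codon_index = integer(), ref_codon = character(),
                      corrected_codon = character(), ref_aa = character(),
                      corrected_aa = character(), effect = character()))
  }
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

oracle_unique_subs <- function(aln, focal, gap_flank = 5) {
  mat <- do.call(rbind, strsplit(toupper(unname(aln)), ""))
  rownames(mat) <- names(aln)
  L <- ncol(mat)
  bg_names <- setdiff(names(aln), focal)
  hits <- integer()
  for (col in seq_len(L)) {
    if (any(mat[, col] %in% c("-", "X"))) next
    near <- FALSE
    for (g in seq_len(L)) {
      if (any(mat[, g] == "-") && abs(g - col) <= gap_flank) near <- TRUE
    }
    if (near) next
    bg <- mat[bg_names, col]
    if (length(unique(bg)) != 1L) next
    if (mat[focal, col] == bg[[1L]]) next
    hits <- c(hits, col)
  }
  hits
}

# root-to-tip by explicit parent walking
oracle_rtt <- function(tree) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  out <- numeric(ntip)
  for (tip in seq_len(ntip)) {
    d <- 0
    node <- tip
    while (node != root) {
      e <- which(tree$edge[, 2L] == node)
      d <- d + tree$edge.length[e]
      node <- tree$edge[e, 1L]
    }
    out[tip] <- d
  }
  names(out) <- tree$tip.label
  out
}

# one-row pileup builder for rule tests
pile_row <- function(ref = "C", A = 0, C = 0, G = 0, T = 0, N = 0,
                     indel_fraction = 0, depth = NULL, seq_id = "s",
                     pos = 1L) {
  depth <- depth %||% (A + C + G + T + N)
  data.table::data.table(
    seq_id = seq_id, pos = as.integer(pos), ref_base = ref,
    depth = as.integer(depth), A = as.integer(A), C = as.integer(C),
    G = as.integer(G), T = as.integer(T), N = as.integer(N),
    indel_fraction = indel_fraction
  )
}

toy_gtf <- function(lines, path = tempfile(fileext = ".gtf")) {
  writeLines(lines, path)
  path
}
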