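#' Inferred haplotyping against heterozygous J anchors
#'
#' VDJ recombination happens in cis: a V allele recombines only with J (or
#' D) alleles on its own chromosome. When an individual is heterozygous at
#' an anchor gene (classically IGHJ6), each V allele can therefore be
#' assigned to a chromosome by which anchor allele it co-occurs with
#' inside the same rearrangement. A V allele present on both chromosomes
#' (homozygous gene) pairs with both anchors at similar rates.
#'
#' Co-occurrence is computed from exact core matches within each record,
#' so the module needs no upstream caller; `use_calls = TRUE` trusts the
#' table's `v_call`/`j_call` columns instead.
#'
#' @name haplotyper
NULL

call_matches <- function(calls, allele) {
  !is.na(calls) & vapply(strsplit(calls, ","), function(p)
    allele %in% trimws(p), logical(1))
}

#' Assign V alleles to haplotypes via a heterozygous anchor gene
#'
#' @param records a `rearrangements` data frame.
#' @param v_cores a V `core_db` (ignored when `use_calls = TRUE`, where
#'   the union of `v_call` values is used instead).
#' @param j_cores the anchor-segment `core_db` (typically J).
#' @param anchor_gene gene whose two expressed alleles anchor the two
#'   haplotypes (e.g. `"IGHJ6"`).
#' @param threshold assignment cutoff in (0.5, 1] (default 0.9): haplotype
#'   1 when the fraction of co-occurrences toward anchor 1 is >=
#'   `threshold`, haplotype 2 when <= 1 - `threshold`, otherwise `"both"`.
#'   Alleles with no anchor co-occurrence are `"unassigned"`.
#' @param gene_order optional character vector of gene names giving the
#'   display order (e.g. genomic order).
#' @param use_calls use `v_call`/`j_call` columns instead of core matches.
#' @return A `haplotype_matrix` data frame: `allele`, `gene`, `c_anchor1`,
#'   `c_anchor2`, `fraction` (toward anchor 1), `assignment`; attributes
#'   `anchors`, `anchor_gene`, `threshold`.
#' @export
infer_haplotype <- function(records, v_cores, j_cores, anchor_gene,
                            threshold = 0.9, gene_order = NULL,
                            use_calls = FALSE) {
  stopifnot(threshold > 0.5, threshold <= 1)
  if (use_calls) {
    j_alleles <- sort(unique(unlist(strsplit(
      records$j_call[!is.na(records$j_call)], ","))))
    j_alleles <- trimws(j_alleles[gene_of(trimws(j_alleles)) == anchor_gene])
    anchor_hits <- lapply(j_alleles, function(a)
      call_matches(records$j_call, a))
    names(anchor_hits) <- j_alleles
  } else {
    stopifnot(inherits(j_cores, "core_db"))
    anchor_cores <- j_cores$cores[core_gene(names(j_cores$cores)) ==
                                    anchor_gene]
    subject <- Biostrings::DNAStringSet(records$sequence)
    anchor_hits <- lapply(anchor_cores, function(cc)
      Biostrings::vcountPattern(cc, subject) > 0L)
  }
  nonzero <- vapply(anchor_hits, any, logical(1))
  anchor_hits <- anchor_hits[nonzero]
  if (length(anchor_hits) < 2L)
    stop("no heterozygous anchor: fewer than two alleles of ", anchor_gene,
         " observed")
  if (length(anchor_hits) > 2L)
    stop("more than two alleles of ", anchor_gene,
         " observed; cannot anchor two haplotypes")
  anchors <- sort(names(anchor_hits))
  h1 <- anchor_hits[[anchors[[1L]]]]
  h2 <- anchor_hits[[anchors[[2L]]]]
  if (use_calls) {
    v_alleles <- sort(unique(trimws(unlist(strsplit(
      records$v_call[!is.na(records$v_call)], ",")))))
    v_hits <- lapply(v_alleles, function(a) call_matches(records$v_call, a))
    names(v_hits) <- v_alleles
  } else {
    stopifnot(inherits(v_cores, "core_db"))
    v_hits <- lapply(v_cores$cores, function(cc)
      Biostrings::vcountPattern(cc, subject) > 0L)
  }
  c1 <- vapply(v_hits, function(v) sum(v & h1), 0L)
  c2 <- vapply(v_hits, function(v) sum(v & h2), 0L)
  tot <- c1 + c2
  frac <- ifelse(tot > 0, c1 / tot, NA_real_)
  assignment <- rep("unassigned", length(tot))
  assignment[tot > 0 & frac >= threshold] <- "1"
  assignment[tot > 0 & frac <= 1 - threshold] <- "2"
  assignment[tot > 0 & frac < threshold & frac > 1 - threshold] <- "both"
  out <- data.frame(allele = names(v_hits),
                    gene = core_gene(names(v_hits)),
                    c_anchor1 = c1, c_anchor2 = c2, fraction = frac,
                    assignment = assignment, stringsAsFactors = FALSE)
  if (!is.null(gene_order)) {
    key <- match(out$gene, gene_order)
    out <- out[order(key, out$allele), , drop = FALSE]
  }
  rownames(out) <- NULL
  attr(out, "anchors") <- anchors
  attr(out, "anchor_gene") <- anchor_gene
  attr(out, "threshold") <- threshold
  class(out) <- c("haplotype_matrix", "data.frame")
  out
}

#' Write a haplotype matrix as TSV
#'
#' @param hap a `haplotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_haplotype <- function(hap, path) {
  stopifnot(inherits(hap, "haplotype_matrix"))
  utils::write.table(hap, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  a <- attr(x, "anchors")
  cat(sprintf("<haplotype_matrix> anchors %s (hap 1) / %s (hap 2), threshold %.2f\n",
              a[[1L]], a[[2L]], attr(x, "threshold")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
plot.haplotype_matrix <- function(x, ...) {
  a <- attr(x, "anchors")
  col <- c(`1` = "firebrick", `2` = "navy", both = "purple",
           unassigned = "grey70")[x$assignment]
  op <- graphics::par(mar = c(4, 8, 2, 1))
  on.exit(graphics::par(op))
  graphics::barplot(rev(x$fraction), horiz = TRUE, names.arg = rev(x$allele),
                    las = 1, col = rev(col), border = NA, xlim = c(0, 1),
                    cex.names = 0.6,
                    xlab = sprintf("fraction of co-occurrences toward %s",
                                   a[[1L]]), ...)
  graphics::abline(v = c(1 - attr(x, "threshold"), attr(x, "threshold")),
                   lty = 2)
  invisible(x)
}
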