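#' Ground-truthed VDJ library simulation
#'
#' The simulator emulates the statistical structure that core-based
#' genotyping assumes in an IgM repertoire library: a diploid genotype,
#' heavily skewed gene usage (expressed V genes span roughly three orders
#' of magnitude in frequency), recombination trimming at the
#' recombination-proximal ends (3' of V, 5' of J, both ends of D),
#' untemplated N additions at the two junctions, UMI tagging with PCR
#' duplication, and per-base sequencing error. Every read carries a full
#' provenance record, so tests can compare any measured quantity against
#' exact ground truth.
#'
#' It is not a biologically calibrated repertoire simulator: there is no
#' selection, no clonal lineage structure (beyond [inject_clone()]), no
#' P-nucleotides -- recombination "loss or replacement" is modelled as
#' pure loss plus junctional N insertion.
#'
#' @name simulator
NULL

#' Simulation configuration
#'
#' @param n_reads number of reads to emit.
#' @param usage optional list of named numeric usage weights per segment
#'   (`v`, `d`, `j`); genes absent from the vector get weight 0. `NULL`
#'   draws log-uniform weights spanning `usage_span_log10` orders.
#' @param usage_span_log10 per-segment log10 span of the default usage
#'   draw. V genes span 3 orders (repertoires show >1000-fold V usage
#'   spreads); D usage is less extreme (1 order) and J usage is
#'   concentrated on a few high-frequency genes (0.5 orders).
#' @param trim_prob geometric trimming parameter per end (`v3`, `j5`,
#'   `d5`, `d3`), default 0.5 each.
#' @param trim_cap maximum trimmed nucleotides per end (default 8).
#' @param n_insert_mean Poisson mean of the N-insertion length at each of
#'   the two junctions (default 4).
#' @param umi_length UMI length in nucleotides (default 12).
#' @param per_base_error per-base substitution error rate applied per read
#'   (default 0.003, Illumina MiSeq scale).
#' @param shm_rate per-base somatic hypermutation rate applied per
#'   molecule (default 0: IgM naive repertoires are essentially
#'   unmutated; the knob exists to probe robustness).
#' @param prefix_range range of the random 5' pad length (primer/UTR
#'   stand-in), default 10-30 nt.
#' @param reads_per_umi_mean mean reads per UMI (zero-truncated Poisson,
#'   default 1.5).
#' @param constant_region_length length of the fixed 3' constant-region
#'   stub appended to every read (default 20 nt).
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_reads = 10000L, usage = NULL,
                       usage_span_log10 = c(v = 3, d = 1, j = 0.5),
                       trim_prob = c(v3 = 0.5, j5 = 0.5, d5 = 0.5, d3 = 0.5),
                       trim_cap = 8L, n_insert_mean = 4,
                       umi_length = 12L, per_base_error = 0.003,
                       shm_rate = 0, prefix_range = c(10L, 30L),
                       reads_per_umi_mean = 1.5,
                       constant_region_length = 20L) {
  stopifnot(n_reads > 0, per_base_error >= 0, per_base_error <= 1,
            shm_rate >= 0, shm_rate <= 1, all(trim_prob > 0),
            all(trim_prob <= 1), reads_per_umi_mean >= 1)
  structure(list(n_reads = as.integer(n_reads), usage = usage,
                 usage_span_log10 = usage_span_log10,
                 trim_prob = trim_prob, trim_cap = as.integer(trim_cap),
                 n_insert_mean = n_insert_mean,
                 umi_length = as.integer(umi_length),
                 per_base_error = per_base_error, shm_rate = shm_rate,
                 prefix_range = as.integer(prefix_range),
                 reads_per_umi_mean = reads_per_umi_mean,
                 constant_region_length = as.integer(constant_region_length)),
            class = "sim_config")
}

#' Generate a synthetic germline allele database
#'
#' Random gene base sequences with allelic variants differing at one to
#' `max_variant_positions` random positions. Names follow the
#' `GENE*ALLELE` convention under a synthetic prefix (e.g. `SYNV3*02`), so
#' all naming semantics of real databases apply.
#'
#' @param n_genes number of genes.
#' @param alleles_per_gene integer vector recycled over genes (e.g.
#'   `c(1, 2)`), or a single integer.
#' @param seq_length length range `c(min, max)` of the gene sequences;
#'   defaults per segment: V 65-75, D 16-26, J 45-55.
#' @param segment `"V"`, `"D"` or `"J"`.
#' @param seed RNG seed.
#' @param max_variant_positions maximum differing positions per extra
#'   allele (default 2).
#' @return An `allele_db`.
#' @export
simulate_germline_db <- function(n_genes, alleles_per_gene = c(1L, 2L),
                                 seq_length = NULL,
                                 segment = c("V", "D", "J"), seed = 1L,
                                 max_variant_positions = 2L) {
  segment <- match.arg(segment)
  if (is.null(seq_length))
    seq_length <- switch(segment, V = c(65L, 75L), D = c(16L, 26L),
                         J = c(45L, 55L))
  k <- rep_len(as.integer(alleles_per_gene), n_genes)
  with_seed(seed, {
    names_out <- character(0)
    seqs_out <- character(0)
    for (g in seq_len(n_genes)) {
      L <- sample(seq_length[[1L]]:seq_length[[2L]], 1L)
      base <- random_dna(L)
      gene <- sprintf("SYN%s%d", segment, g)
      alleles <- base
      tries <- 0L
      while (length(alleles) < k[[g]] && tries < 100L) {
        tries <- tries + 1L
        v <- base
        npos <- sample(max_variant_positions, 1L)
        pos <- sample(L, npos)
        for (p in pos) {
          old <- substr(v, p, p)
          substr(v, p, p) <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
        }
        if (!v %in% alleles) alleles <- c(alleles, v)
      }
      names_out <- c(names_out,
                     sprintf("%s*%02d", gene, seq_along(alleles)))
      seqs_out <- c(seqs_out, alleles)
    }
    new_allele_db(names_out, seqs_out, segment)
  })
}

#' Sample a diploid genotype from an allele database
#'
#' Per gene and haplotype, the gene is present with probability
#' `presence`; a present haplotype carries one allele drawn uniformly from
#' the gene's database alleles. Different draws on the two haplotypes make
#' the gene heterozygous.
#'
#' @param db an `allele_db`.
#' @param seed RNG seed.
#' @param presence per-haplotype gene presence probability (default 0.95).
#' @return A `sim_genotype` data frame: `gene`, `hap1`, `hap2` (allele
#'   names, `NA` when absent from that haplotype).
#' @export
simulate_genotype <- function(db, seed = 1L, presence = 0.95) {
  stopifnot(inherits(db, "allele_db"), presence > 0, presence <= 1)
  genes <- unique(db$gene)
  with_seed(seed, {
    pick <- function(g) {
      alleles <- db$name[db$gene == g]
      vapply(1:2, function(h) {
        if (stats::runif(1) <= presence)
          alleles[sample.int(length(alleles), 1L)]
        else NA_character_
      }, character(1))
    }
    haps <- vapply(genes, pick, character(2))
    out <- data.frame(gene = genes, hap1 = haps[1L, ], hap2 = haps[2L, ],
                      stringsAsFactors = FALSE)
    rownames(out) <- NULL
    class(out) <- c("sim_genotype", "data.frame")
    out
  })
}

#' Alleles truly present in a simulated genotype
#'
#' @param genotype a `sim_genotype`.
#' @return Sorted unique allele names over both haplotypes.
#' @export
true_alleles <- function(genotype) {
  sort(unique(stats::na.omit(c(genotype$hap1, genotype$hap2))))
}

geom_trim <- function(n, p, cap) pmin(stats::rgeom(n, p), cap)

draw_usage <- function(config, segment_key, genes) {
  u <- config$usage[[segment_key]]
  if (!is.null(u)) {
    w <- rep(0, length(genes))
    names(w) <- genes
    w[intersect(names(u), genes)] <- u[intersect(names(u), genes)]
    return(w)
  }
  span <- config$usage_span_log10
  span <- if (length(span) > 1L) span[[segment_key]] else span
  stats::setNames(10 ^ stats::runif(length(genes), 0, span), genes)
}

inject_errors <- function(seqs, rate) {
  if (rate <= 0) return(seqs)
  lens <- nchar(seqs)
  nerr <- stats::rbinom(length(seqs), lens, rate)
  for (i in which(nerr > 0L)) {
    pos <- sample(lens[[i]], nerr[[i]])
    for (p in pos) {
      old <- substr(seqs[[i]], p, p)
      substr(seqs[[i]], p, p) <-
        sample(setdiff(c("A", "C", "G", "T"), old), 1L)
    }
  }
  seqs
}

#' Simulate an AIRR repertoire library with ground truth
#'
#' Each cDNA molecule draws a haplotype uniformly, then V, D and J genes
#' from that haplotype by the usage weights, trims each
#' recombination-proximal end geometrically (capped), inserts random N
#' nucleotides at both junctions, prepends a random 5' pad and appends a
#' fixed constant-region stub. Molecules receive a random UMI and a
#' zero-truncated Poisson number of reads (PCR duplicates); sequencing
#' errors are injected per read, SHM (if enabled) per molecule. The
#' junction (CDR3 stand-in) is taken from provenance: the last 6 retained
#' V nucleotides through the first 6 retained J nucleotides.
#'
#' @param genotype list with `sim_genotype` elements `v`, `d`, `j`.
#' @param dbs list with `allele_db` elements `v`, `d`, `j`.
#' @param config a [sim_config()].
#' @param seed RNG seed; fixed seed gives a byte-identical library.
#' @return A `sim_library` list: `records` (a `rearrangements` data frame
#'   with truth-derived `v_call`/`d_call`/`j_call`), `truth` (per-read
#'   provenance: alleles, trims, insert lengths, haplotype, junction,
#'   UMI, pre-error assembly fields), `genotype`, `usage`, `config`.
#' @export
simulate_library <- function(genotype, dbs, config = sim_config(),
                             seed = 1L) {
  stopifnot(all(c("v", "d", "j") %in% names(genotype)),
            all(c("v", "d", "j") %in% names(dbs)))
  with_seed(seed, {
    usage <- list(v = draw_usage(config, "v", genotype$v$gene),
                  d = draw_usage(config, "d", genotype$d$gene),
                  j = draw_usage(config, "j", genotype$j$gene))
    # Molecules: zero-truncated Poisson read multiplicities.
    mean_sz <- config$reads_per_umi_mean
    n_guess <- ceiling(config$n_reads / mean_sz * 1.3) + 50L
    sizes <- stats::rpois(n_guess, mean_sz - 1) + 1L
    while (sum(sizes) < config$n_reads)
      sizes <- c(sizes, stats::rpois(n_guess, mean_sz - 1) + 1L)
    n_mol <- which(cumsum(sizes) >= config$n_reads)[[1L]]
    sizes <- sizes[seq_len(n_mol)]
    sizes[[n_mol]] <- sizes[[n_mol]] - (sum(sizes) - config$n_reads)
    hap <- sample(1:2, n_mol, replace = TRUE)
    pick_gene <- function(gt, w, hap) {
      out <- character(n_mol)
      for (h in 1:2) {
        avail <- gt$gene[!is.na(gt[[paste0("hap", h)]])]
        idx <- which(hap == h)
        out[idx] <- sample(avail, length(idx), replace = TRUE,
                           prob = w[avail])
      }
      out
    }
    vg <- pick_gene(genotype$v, usage$v, hap)
    dg <- pick_gene(genotype$d, usage$d, hap)
    jg <- pick_gene(genotype$j, usage$j, hap)
    allele_of <- function(gt, gene, hap) {
      m <- match(gene, gt$gene)
      ifelse(hap == 1L, gt$hap1[m], gt$hap2[m])
    }
    va <- allele_of(genotype$v, vg, hap)
    da <- allele_of(genotype$d, dg, hap)
    ja <- allele_of(genotype$j, jg, hap)
    seq_of <- function(db, allele) db$seq[match(allele, db$name)]
    vseq <- seq_of(dbs$v, va)
    dseq <- seq_of(dbs$d, da)
    jseq <- seq_of(dbs$j, ja)
    tp <- config$trim_prob
    v_trim3 <- geom_trim(n_mol, tp[["v3"]], config$trim_cap)
    j_trim5 <- geom_trim(n_mol, tp[["j5"]], config$trim_cap)
    d_trim5 <- geom_trim(n_mol, tp[["d5"]], config$trim_cap)
    d_trim3 <- geom_trim(n_mol, tp[["d3"]], config$trim_cap)
    v_trim3 <- pmin(v_trim3, nchar(vseq) - 1L)
    j_trim5 <- pmin(j_trim5, nchar(jseq) - 1L)
    vprime <- substr(vseq, 1L, nchar(vseq) - v_trim3)
    dprime <- substr(dseq, d_trim5 + 1L, nchar(dseq) - d_trim3)
    jprime <- substr(jseq, j_trim5 + 1L, nchar(jseq))
    n1_len <- stats::rpois(n_mol, config$n_insert_mean)
    n2_len <- stats::rpois(n_mol, config$n_insert_mean)
    n1 <- random_dna(n1_len)
    n2 <- random_dna(n2_len)
    pre_len <- sample(config$prefix_range[[1L]]:config$prefix_range[[2L]],
                      n_mol, replace = TRUE)
    prefix <- random_dna(pre_len)
    constant <- random_dna(config$constant_region_length)
    junction <- paste0(
      substr(vprime, pmax(1L, nchar(vprime) - 5L), nchar(vprime)),
      n1, dprime, n2, substr(jprime, 1L, 6L))
    mol_seq <- paste0(prefix, vprime, n1, dprime, n2, jprime, constant)
    mol_seq <- inject_errors(mol_seq, config$shm_rate)
    umi <- random_dna(rep(config$umi_length, n_mol))
    # Expand molecules into reads.
    ridx <- rep(seq_len(n_mol), sizes)
    reads <- inject_errors(mol_seq[ridx], config$per_base_error)
    records <- as_rearrangements(data.frame(
      sequence = reads, umi = umi[ridx], cdr3 = junction[ridx],
      v_call = va[ridx], d_call = da[ridx], j_call = ja[ridx],
      stringsAsFactors = FALSE))
    truth <- data.frame(
      read_id = seq_along(ridx), molecule = ridx, haplotype = hap[ridx],
      v_allele = va[ridx], d_allele = da[ridx], j_allele = ja[ridx],
      v_trim3 = v_trim3[ridx], d_trim5 = d_trim5[ridx],
      d_trim3 = d_trim3[ridx], j_trim5 = j_trim5[ridx],
      n1_len = n1_len[ridx], n2_len = n2_len[ridx],
      n1 = n1[ridx], n2 = n2[ridx], prefix = prefix[ridx],
      junction = junction[ridx], umi = umi[ridx],
      stringsAsFactors = FALSE)
    obj <- list(records = records, truth = truth, genotype = genotype,
                usage = usage, constant_region = constant,
                config = config, seed = seed)
    class(obj) <- "sim_library"
    obj
  })
}

#' @export
print.sim_library <- function(x, ...) {
  cat(sprintf("<sim_library> %d reads, %d molecules, seed %d\n",
              nrow(x$records), max(x$truth$molecule), x$seed))
  cat(sprintf("  true genotype: %d V / %d D / %d J alleles\n",
              length(true_alleles(x$genotype$v)),
              length(true_alleles(x$genotype$d)),
              length(true_alleles(x$genotype$j))))
  invisible(x)
}

#' Append a clonal-expansion fixture
#'
#' Appends `n_copies` of one fixed VDJ sequence containing `core` -- a
#' single junction repeated verbatim, each copy under its own UMI (an
#' expanded clone spans many cells, so UMI deduplication does not remove
#' it). Such a fixture must be caught by the CDR3 diversity filters, not
#' by the count-based ones.
#'
#' @param records a `rearrangements` data frame.
#' @param core the search string the clone carries (typically an allele's
#'   core sequence).
#' @param n_copies number of copies to append (>= 1; 0 returns the input
#'   unchanged).
#' @param seed RNG seed for the fixed pads/junction/UMIs.
#' @param umi_length UMI length (default 12).
#' @return The records with the clone rows appended (row ids renumbered).
#' @export
inject_clone <- function(records, core, n_copies, seed = 1L,
                         umi_length = 12L) {
  stopifnot(n_copies >= 0)
  if (n_copies == 0L) return(records)
  with_seed(seed, {
    pad1 <- random_dna(20L)
    pad2 <- random_dna(20L)
    junction <- random_dna(21L)
    umis <- random_dna(rep(umi_length, n_copies))
    clone <- data.frame(
      sequence = rep(paste0(pad1, core, pad2), n_copies),
      umi = umis, cdr3 = rep(junction, n_copies),
      v_call = NA_character_, d_call = NA_character_,
      j_call = NA_character_, stringsAsFactors = FALSE)
    out <- rbind(as.data.frame(records)[, c("sequence", "umi", "cdr3",
                                            "v_call", "d_call", "j_call")],
                 clone)
    as_rearrangements(out)
  })
}
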