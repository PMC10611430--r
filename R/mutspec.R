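# Drift-vs-selection test on mutation-class spectra: simulate random SNPs
# on an annotated genome, classify each as missense, nonsense, synonymous
# or upstream/intergenic, and bootstrap-compare observed class counts to
# this neutral null.

SNP_EFFECTS <- c("missense", "nonsense", "synonymous", "upstream",
                 "intergenic")
SNP_CLASSES <- c("missense", "nonsense", "synonymous",
                 "upstream_intergenic")

# position-level lookup tables for one genome: per-contig character
# vectors, the covering gene (0 = none) and an upstream-window flag
genome_index <- function(genome) {
  stopifnot(inherits(genome, "annotated_genome"))
  chars <- lapply(as.character(genome$contigs),
                  function(s) strsplit(s, "", fixed = TRUE)[[1]])
  g <- genome$genes
  w <- genome$upstream_window
  gene_at <- lapply(chars, function(x) integer(length(x)))
  upstream <- lapply(chars, function(x) logical(length(x)))
  if (nrow(g) > 0) {
    for (j in seq_len(nrow(g))) {
      ctg <- g$contig[j]
      L <- length(chars[[ctg]])
      if (g$start[j] < 1 || g$end[j] > L)
        stop("gene interval outside contig bounds", call. = FALSE)
      gene_at[[ctg]][g$start[j]:g$end[j]] <- j
      win <- if (g$strand[j] == "+")
        seq.int(max(1, g$start[j] - w), g$start[j] - 1) else
        seq.int(g$end[j] + 1, min(L, g$end[j] + w))
      if (w > 0 && length(win) > 0 && win[1] <= win[length(win)])
        upstream[[ctg]][win] <- TRUE
    }
    for (ctg in names(upstream))
      upstream[[ctg]] <- upstream[[ctg]] & gene_at[[ctg]] == 0L
  }
  list(chars = chars, gene_at = gene_at, upstream = upstream, genes = g)
}

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# vectorized effect classification against a prebuilt index
classify_positions <- function(idx, contig, position, alt) {
  n <- length(position)
  effect <- rep("intergenic", n)
  gene_j <- integer(n)
  for (ctg in unique(contig)) {
    sel <- contig == ctg
    gene_j[sel] <- idx$gene_at[[ctg]][position[sel]]
    effect[sel][idx$upstream[[ctg]][position[sel]]] <- "upstream"
  }
  in_cds <- gene_j > 0
  if (any(in_cds)) {
    j <- gene_j[in_cds]
    pos <- position[in_cds]
    a <- alt[in_cds]
    ctg <- contig[in_cds]
    g <- idx$genes
    plus <- g$strand[j] == "+"
    off <- ifelse(plus, pos - g$start[j], g$end[j] - pos)
    ci <- off %/% 3
    within <- off %% 3
    # genomic coordinates of the codon's three bases, in coding order
    p1 <- ifelse(plus, g$start[j] + 3 * ci, g$end[j] - 3 * ci)
    step <- ifelse(plus, 1L, -1L)
    base_at <- function(p) {
      out <- character(length(p))
      for (cc in unique(ctg)) {
        s <- ctg == cc
        out[s] <- idx$chars[[cc]][p[s]]
      }
      out
    }
    b1 <- base_at(p1)
    b2 <- base_at(p1 + step)
    b3 <- base_at(p1 + 2 * step)
    flip <- !plus
    b1[flip] <- COMPLEMENT[b1[flip]]
    b2[flip] <- COMPLEMENT[b2[flip]]
    b3[flip] <- COMPLEMENT[b3[flip]]
    codon_old <- matrix(c(b1, b2, b3), ncol = 3)
    codon_new <- codon_old
    a_coding <- ifelse(plus, a, COMPLEMENT[a])
    codon_new[cbind(seq_along(j), within + 1)] <- a_coding
    code <- Biostrings::GENETIC_CODE
    aa_old <- code[apply(codon_old, 1, paste, collapse = "")]
    aa_new <- code[apply(codon_new, 1, paste, collapse = "")]
    cls <- ifelse(aa_old == aa_new, "synonymous",
                  ifelse(aa_new == "*", "nonsense", "missense"))
    effect[in_cds] <- cls
  }
  factor(effect, levels = SNP_EFFECTS)
}

#' Classify the effect of a single-nucleotide variant
#'
#' Inside a CDS the affected codon is translated (reverse-complemented
#' first on minus-strand genes) before and after the substitution:
#' unchanged amino acid gives \code{"synonymous"}, a gained stop gives
#' \code{"nonsense"}, any other amino-acid change (including a lost stop)
#' gives \code{"missense"}. Outside all CDS, a position within the
#' genome's \code{upstream_window} of a gene start (strand-aware) is
#' \code{"upstream"}; everything else is \code{"intergenic"}. Upstream and
#' intergenic are reported jointly as the fourth class in the bootstrap
#' test.
#'
#' @param genome an \code{"annotated_genome"}.
#' @param contig,position,alt vectors (recycled to a common length) of
#'   contig name, 1-based position and alternate base.
#' @param ref optional expected reference base(s); an error is raised on
#'   mismatch with the genome.
#' @return A factor with levels \code{missense, nonsense, synonymous,
#'   upstream, intergenic}.
#' @examples
#' g <- gen_annotated_genome(n_contigs = 1, contig_length = 2000,
#'                           n_genes = 2, gene_length = 300,
#'                           upstream_window = 100, seed = 1)
#' classify_snp(g, "contig_01", g$genes$start[1] + 3, "A")
#' @export
classify_snp <- function(genome, contig, position, alt, ref = NULL) {
  idx <- genome_index(genome)
  n <- max(length(contig), length(position), length(alt))
  contig <- rep_len(as.character(contig), n)
  position <- rep_len(as.integer(position), n)
  alt <- rep_len(toupper(as.character(alt)), n)
  if (!all(contig %in% names(idx$chars)))
    stop("unknown contig name", call. = FALSE)
  lens <- lengths(idx$chars)[contig]
  if (any(position < 1 | position > lens))
    stop("`position` outside contig bounds", call. = FALSE)
  if (!all(alt %in% names(COMPLEMENT)))
    stop("`alt` must be one of A, C, G, T", call. = FALSE)
  genome_ref <- vapply(seq_len(n),
                       function(i) idx$chars[[contig[i]]][position[i]],
                       character(1))
  if (!is.null(ref) && any(toupper(rep_len(ref, n)) != genome_ref))
    stop("supplied `ref` does not match the genome sequence",
         call. = FALSE)
  if (any(alt == genome_ref))
    stop("`alt` must differ from the reference base", call. = FALSE)
  classify_positions(idx, contig, position, alt)
}

#' Simulate a neutral null distribution of SNPs
#'
#' Draws \code{n} substitutions uniformly over every genome position, with
#' the alternate base uniform over the three non-reference bases, and
#' classifies each one. This is the mutation spectrum expected under pure
#' drift: deviations of observed class counts from it are the signature of
#' selection.
#'
#' @param genome an \code{"annotated_genome"}.
#' @param n number of SNPs to simulate (>= 1); large null sets
#'   (e.g. 100000) give a smooth reference spectrum.
#' @param seed optional integer seed.
#' @return A data.frame with columns \code{contig}, \code{position},
#'   \code{ref}, \code{alt} and \code{effect} (factor over the five
#'   internal effect levels).
#' @seealso [bootstrap_class_test()], [snp_class_counts()]
#' @export
simulate_snps <- function(genome, n, seed = NULL) {
  stopifnot(inherits(genome, "annotated_genome"))
  check_count(n, "n", minimum = 1)
  idx <- genome_index(genome)
  widths <- lengths(idx$chars)
  total <- sum(widths)
  if (total == 0) stop("empty genome", call. = FALSE)
  with_seed(seed, {
    loc <- sample.int(total, n, replace = TRUE)
    bounds <- cumsum(widths)
    ci <- findInterval(loc - 1, bounds) + 1
    contig <- names(widths)[ci]
    position <- loc - c(0, bounds)[ci]
    ref <- character(n)
    for (cc in unique(contig)) {
      s <- contig == cc
      ref[s] <- idx$chars[[cc]][position[s]]
    }
    bases <- names(COMPLEMENT)
    shift <- sample.int(3, n, replace = TRUE)
    alt <- bases[(match(ref, bases) - 1 + shift) %% 4 + 1]
    data.frame(contig = contig, position = position, ref = ref, alt = alt,
               effect = classify_positions(idx, contig, position, alt),
               stringsAsFactors = FALSE)
  })
}

#' Collapse SNP effects to the four reported mutation classes
#'
#' @param snps a data.frame from [simulate_snps()], or a factor/character
#'   vector of effects.
#' @return Named integer vector of counts over \code{missense, nonsense,
#'   synonymous, upstream_intergenic}.
#' @export
snp_class_counts <- function(snps) {
  eff <- if (is.data.frame(snps)) snps$effect else snps
  eff <- as.character(eff)
  if (!all(eff %in% SNP_EFFECTS))
    stop("unknown effect label", call. = FALSE)
  cls <- ifelse(eff %in% c("upstream", "intergenic"),
                "upstream_intergenic", eff)
  counts <- table(factor(cls, levels = SNP_CLASSES))
  setNames(as.integer(counts), SNP_CLASSES)
}

#' Bootstrap test of observed mutation-class counts against a neutral null
#'
#' Each of \code{n_boot} bootstrap replicates draws, with replacement, a
#' subsample of size \code{sum(observed_counts)} from the null SNP set and
#' tallies the four mutation classes (equivalently, a multinomial draw at
#' the null class proportions). For every class the tail proportions
#' \eqn{P(\mathrm{sim} \ge \mathrm{obs})} and
#' \eqn{P(\mathrm{sim} \le \mathrm{obs})} are reported; ties count in both
#' tails ("at least as extreme"). Small tail proportions flag classes
#' over- or under-represented relative to drift.
#'
#' @param null_snps a data.frame from [simulate_snps()] (or an effect
#'   factor/character vector) defining the null spectrum.
#' @param observed_counts named vector of observed counts; names must be
#'   among \code{missense, nonsense, synonymous, upstream, intergenic,
#'   upstream_intergenic} (upstream and intergenic are pooled).
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed optional integer seed.
#' @return A \code{"bootstrap_result"}: list with \code{table} (per class:
#'   observed, null mean, \code{p_ge}, \code{p_le}), \code{sim_counts}
#'   (classes x n_boot matrix), \code{n_boot}, \code{subsample_size} and
#'   \code{seed}.
#' @export
bootstrap_class_test <- function(null_snps, observed_counts, n_boot = 1000,
                                 seed = NULL) {
  check_count(n_boot, "n_boot", minimum = 1)
  null_counts <- snp_class_counts(null_snps)
  if (sum(null_counts) == 0)
    stop("`null_snps` is empty", call. = FALSE)
  obs <- normalize_observed(observed_counts)
  size <- sum(obs)
  if (size < 1)
    stop("`observed_counts` must sum to at least 1", call. = FALSE)
  prob <- null_counts / sum(null_counts)
  sims <- with_seed(seed, rmultinom(n_boot, size, prob))
  rownames(sims) <- SNP_CLASSES
  tab <- data.frame(
    class = SNP_CLASSES,
    observed = obs[SNP_CLASSES],
    null_mean = size * prob[SNP_CLASSES],
    p_ge = vapply(SNP_CLASSES, function(k) mean(sims[k, ] >= obs[k]),
                  numeric(1)),
    p_le = vapply(SNP_CLASSES, function(k) mean(sims[k, ] <= obs[k]),
                  numeric(1)),
    row.names = NULL)
  structure(list(table = tab, sim_counts = sims, n_boot = n_boot,
                 subsample_size = size, seed = seed),
            class = "bootstrap_result")
}

normalize_observed <- function(x) {
  if (is.null(names(x)) || any(!is.finite(x)) || any(x < 0))
    stop("`observed_counts` must be a named vector of non-negative counts",
         call. = FALSE)
  out <- setNames(numeric(length(SNP_CLASSES)), SNP_CLASSES)
  for (nm in names(x)) {
    key <- if (nm %in% c("upstream", "intergenic")) "upstream_intergenic"
      else nm
    if (!key %in% SNP_CLASSES)
      stop(sprintf("unknown mutation class `%s`", nm), call. = FALSE)
    out[key] <- out[key] + x[[nm]]
  }
  out
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Mutation-class bootstrap: %d resamples of %d SNPs\n",
              x$n_boot, x$subsample_size))
  print(transform(x$table, null_mean = round(null_mean, 2)),
        row.names = FALSE)
  invisible(x)
}

#' Write SNP records as a minimal VCF
#'
#' Plain-text VCF 4.2 with CHROM, POS, REF, ALT and the effect class in
#' INFO (\code{EFF=}), sufficient for inspection in standard tooling.
#'
#' @param snps a data.frame from [simulate_snps()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_snps_vcf <- function(snps, path) {
  stopifnot(is.data.frame(snps),
            all(c("contig", "position", "ref", "alt", "effect") %in%
                  names(snps)))
  lines <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Mutation effect class\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tEFF=%s",
            snps$contig, snps$position, snps$ref, snps$alt,
            as.character(snps$effect)))
  writeLines(lines, path)
  invisible(path)
}
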