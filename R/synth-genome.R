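# Synthetic annotated genomes: random contigs carrying compact single-CDS
# protein-coding genes. These act as the substrate for the mutation-class
# null model; they make no attempt to mimic real yeast genome composition.

#' Generate a synthetic annotated genome
#'
#' Builds \code{n_contigs} random nucleotide contigs at a chosen GC content
#' and packs \code{n_genes} non-overlapping single-CDS gene models into
#' them. Every gene starts with ATG, ends with a stop codon, and contains
#' no internal stop codons; each gene is flanked by at least
#' \code{upstream_window} bp free of other genes, so its promoter-proximal
#' window never overlaps a neighbouring CDS.
#'
#' Genes are placed on the forward strand by default;
#' \code{strand_mode = "random"} assigns each gene a random strand (the CDS
#' is then written into the contig as its reverse complement), exercising
#' strand-aware classification downstream.
#'
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig (bp).
#' @param n_genes number of gene models to place.
#' @param gene_length CDS length in bp; must be a multiple of 3 and >= 6.
#' @param upstream_window bp upstream of a start codon classified as
#'   "upstream" rather than intergenic (default 1000, configurable).
#' @param gc_content GC fraction of the intergenic background, in (0, 1).
#' @param strand_mode \code{"forward"} or \code{"random"}.
#' @param seed optional integer seed.
#' @return An object of class \code{"annotated_genome"}: a list with
#'   \code{contigs} (a [Biostrings::DNAStringSet]), \code{genes} (a
#'   data.frame with \code{gene_id}, \code{contig}, \code{start},
#'   \code{end}, \code{strand}; 1-based inclusive coordinates) and
#'   \code{upstream_window}.
#' @seealso [write_genome()], [simulate_snps()], [classify_snp()]
#' @examples
#' g <- gen_annotated_genome(n_contigs = 1, contig_length = 3000,
#'                           n_genes = 4, gene_length = 300, seed = 1)
#' g$genes
#' @export
gen_annotated_genome <- function(n_contigs = 2, contig_length = 5000,
                                 n_genes = 10, gene_length = 300,
                                 upstream_window = 1000, gc_content = 0.4,
                                 strand_mode = c("forward", "random"),
                                 seed = NULL) {
  strand_mode <- match.arg(strand_mode)
  check_count(n_contigs, "n_contigs", minimum = 1)
  check_count(contig_length, "contig_length", minimum = 1)
  check_count(n_genes, "n_genes", minimum = 0)
  check_count(gene_length, "gene_length", minimum = 6)
  if (gene_length %% 3 != 0)
    stop("`gene_length` must be divisible by 3", call. = FALSE)
  check_count(upstream_window, "upstream_window", minimum = 0)
  check_number(gc_content, "gc_content", lower = 0, upper = 1,
               allow_boundary = FALSE)

  slot <- gene_length + 2 * upstream_window
  if (n_genes * slot > n_contigs * contig_length)
    stop(sprintf(paste0("cannot pack %d genes of %d bp (plus %d bp flanks) ",
                        "into %d contig(s) of %d bp"),
                 n_genes, gene_length, upstream_window, n_contigs,
                 contig_length),
         call. = FALSE)
  per_contig <- contig_length %/% slot
  if (n_genes > 0 && per_contig * n_contigs < n_genes)
    stop("infeasible packing: genes do not fit contig-by-contig with their ",
         "upstream flanks", call. = FALSE)

  with_seed(seed, {
    base_probs <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
                    G = gc_content / 2, T = (1 - gc_content) / 2)
    contig_names <- sprintf("contig_%02d", seq_len(n_contigs))
    contig_chars <- lapply(seq_len(n_contigs), function(i)
      sample(names(base_probs), contig_length, replace = TRUE,
             prob = base_probs))
    names(contig_chars) <- contig_names

    genes <- NULL
    if (n_genes > 0) {
      stops <- c("TAA", "TAG", "TGA")
      codons <- as.vector(outer(outer(c("T", "C", "A", "G"),
                                      c("T", "C", "A", "G"), paste0),
                                c("T", "C", "A", "G"), paste0))
      sense <- setdiff(codons, stops)
      contig_of <- rep(contig_names, each = per_contig)[seq_len(n_genes)]
      rank_in_contig <- stats::ave(seq_len(n_genes), contig_of,
                                   FUN = seq_along)
      start <- (rank_in_contig - 1) * slot + upstream_window + 1
      end <- start + gene_length - 1
      strand <- if (strand_mode == "random")
        sample(c("+", "-"), n_genes, replace = TRUE) else rep("+", n_genes)
      genes <- data.frame(
        gene_id = sprintf("gene_%03d", seq_len(n_genes)),
        contig = contig_of, start = start, end = end, strand = strand,
        stringsAsFactors = FALSE)
      n_internal <- gene_length / 3 - 2
      for (j in seq_len(n_genes)) {
        cds <- c("ATG",
                 sample(sense, n_internal, replace = TRUE),
                 sample(stops, 1))
        cds_chars <- strsplit(paste(cds, collapse = ""), "", fixed = TRUE)[[1]]
        # a "-" strand gene is stored in the contig as the reverse
        # complement of its coding sequence
        if (strand[j] == "-") cds_chars <- revcomp_chars(cds_chars)
        contig_chars[[contig_of[j]]][start[j]:end[j]] <- cds_chars
      }
    } else {
      genes <- data.frame(gene_id = character(), contig = character(),
                          start = integer(), end = integer(),
                          strand = character(), stringsAsFactors = FALSE)
    }

    contigs <- Biostrings::DNAStringSet(
      vapply(contig_chars, paste, character(1), collapse = ""))
    annotated_genome(contigs, genes, upstream_window)
  })
}

#' Assemble an annotated genome from sequences and gene models
#'
#' @param contigs a named [Biostrings::DNAStringSet] or named character
#'   vector of contig sequences.
#' @param genes data.frame with columns \code{contig}, \code{start},
#'   \code{end}, \code{strand} (\code{+}/\code{-}; 1-based inclusive
#'   coordinates) and optionally \code{gene_id}; single-CDS gene models
#'   whose length must be divisible by 3.
#' @param upstream_window bp upstream of a start codon classified as
#'   "upstream" by [classify_snp()].
#' @return An \code{"annotated_genome"} object.
#' @export
annotated_genome <- function(contigs, genes = NULL, upstream_window = 1000) {
  if (!methods::is(contigs, "DNAStringSet"))
    contigs <- Biostrings::DNAStringSet(contigs)
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)))
    stop("contigs must have unique names", call. = FALSE)
  check_count(upstream_window, "upstream_window", minimum = 0)
  if (is.null(genes) || nrow(genes) == 0) {
    genes <- data.frame(gene_id = character(), contig = character(),
                        start = integer(), end = integer(),
                        strand = character(), stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("contig", "start", "end", "strand") %in% names(genes)))
    if (!"gene_id" %in% names(genes))
      genes$gene_id <- sprintf("gene_%03d", seq_len(nrow(genes)))
    genes <- genes[, c("gene_id", "contig", "start", "end", "strand")]
    if (any(!genes$contig %in% names(contigs)))
      stop("gene on unknown contig", call. = FALSE)
    lens <- Biostrings::width(contigs)[match(genes$contig, names(contigs))]
    if (any(genes$start < 1) || any(genes$end > lens) ||
        any(genes$end < genes$start))
      stop("gene interval outside contig bounds", call. = FALSE)
    if (any((genes$end - genes$start + 1) %% 3 != 0))
      stop("CDS length must be divisible by 3", call. = FALSE)
    if (any(!genes$strand %in% c("+", "-")))
      stop("gene strands must be '+' or '-'", call. = FALSE)
  }
  structure(list(contigs = contigs, genes = genes,
                 upstream_window = as.integer(upstream_window)),
            class = "annotated_genome")
}

# reverse complement of a character vector of bases (genomic orientation)
revcomp_chars <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rev(unname(comp[x]))
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("Annotated genome: %d contig(s), %s bp total, %d gene(s), upstream window %d bp\n",
              length(x$contigs),
              format(sum(Biostrings::width(x$contigs)), big.mark = ","),
              nrow(x$genes), x$upstream_window))
  invisible(x)
}

#' Write a genome to FASTA and GFF3
#'
#' Sequences go to FASTA via [Biostrings::writeXStringSet()]; gene models
#' go to GFF3 (gene + CDS features, 1-based inclusive coordinates) via
#' [rtracklayer::export()].
#'
#' @param genome an [gen_annotated_genome()] result.
#' @param fasta,gff output file paths.
#' @return Invisibly, the genome.
#' @export
write_genome <- function(genome, fasta, gff) {
  stopifnot(inherits(genome, "annotated_genome"))
  Biostrings::writeXStringSet(genome$contigs, filepath = fasta)
  g <- genome$genes
  if (nrow(g) > 0) {
    gene_gr <- GenomicRanges::GRanges(
      seqnames = g$contig,
      ranges = IRanges::IRanges(start = g$start, end = g$end),
      strand = g$strand, type = "gene", ID = g$gene_id)
    cds_gr <- GenomicRanges::GRanges(
      seqnames = g$contig,
      ranges = IRanges::IRanges(start = g$start, end = g$end),
      strand = g$strand, type = "CDS", phase = 0L,
      ID = paste0(g$gene_id, ".cds"), Parent = g$gene_id)
    gr <- c(gene_gr, cds_gr)
  } else {
    gr <- GenomicRanges::GRanges()
  }
  rtracklayer::export(gr, gff, format = "gff3")
  invisible(genome)
}

#' Read a genome from FASTA and GFF3
#'
#' Inverse of [write_genome()]; only \code{CDS} (or, failing that,
#' \code{gene}) features are used as gene models.
#'
#' @param fasta,gff input file paths.
#' @param upstream_window bp upstream of a start codon treated as
#'   "upstream" by [classify_snp()].
#' @return An \code{"annotated_genome"} object.
#' @export
read_genome <- function(fasta, gff, upstream_window = 1000) {
  contigs <- Biostrings::readDNAStringSet(fasta)
  names(contigs) <- sub("\\s.*$", "", names(contigs))
  gr <- rtracklayer::import(gff, format = "gff3")
  keep <- if (any(gr$type == "CDS")) gr[gr$type == "CDS"] else
    gr[gr$type == "gene"]
  genes <- data.frame(
    gene_id = if (!is.null(keep$ID)) sub("\\.cds$", "", keep$ID) else
      sprintf("gene_%03d", seq_along(keep)),
    contig = as.character(GenomicRanges::seqnames(keep)),
    start = GenomicRanges::start(keep),
    end = GenomicRanges::end(keep),
    strand = as.character(GenomicRanges::strand(keep)),
    stringsAsFactors = FALSE)
  if (nrow(genes) > 0 && any(!genes$strand %in% c("+", "-")))
    stop("gene models must have explicit +/- strands", call. = FALSE)
  annotated_genome(contigs, genes, upstream_window)
}
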