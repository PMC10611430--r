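# Independent oracles used across tests. These deliberately use different
# algorithms (enumeration, closed forms, Biostrings translation) from the
# package implementations they check.

# extinction probability by literal subset enumeration: fraction of all
# `draws`-subsets of 1:N avoiding the first k groups
enumerate_extinction <- function(N, k, draws) {
  subsets <- utils::combn(N, draws)
  mean(apply(subsets, 2, function(s) all(s > k)))
}

# extinction probability via the closed-form ratio of binomial coefficients
choose_extinction <- function(N, k, draws) {
  if (draws > N - k) return(0)
  exp(lchoose(N - k, draws) - lchoose(N, draws))
}

# mutant count after growth by plain bisection on the two-exponential
# carrying-capacity equation
bisect_growth_mutants <- function(I, m, lambda, s_c, fold,
                                  tol = 1e-12) {
  f <- function(t) (I - m) * exp(lambda * t) +
    m * exp(lambda * (1 + s_c) * t) - fold * I
  lo <- 0
  hi <- log(fold) / lambda
  while (f(hi) < 0) hi <- hi * 2
  while (hi - lo > tol * max(1, hi)) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  m * exp(lambda * (1 + s_c) * (lo + hi) / 2)
}

# SNP effect by whole-protein translation with Biostrings (strand-aware),
# independent of the package's codon-index arithmetic
translate_oracle <- function(genome, contig, pos, alt) {
  gr <- genome$genes
  hit <- which(gr$contig == contig & gr$start <= pos & gr$end >= pos)
  if (length(hit) == 1) {
    row <- gr[hit, ]
    mut <- Biostrings::replaceLetterAt(genome$contigs[[contig]], pos, alt)
    seq0 <- Biostrings::subseq(genome$contigs[[contig]], row$start, row$end)
    seq1 <- Biostrings::subseq(mut, row$start, row$end)
    if (row$strand == "-") {
      seq0 <- Biostrings::reverseComplement(seq0)
      seq1 <- Biostrings::reverseComplement(seq1)
    }
    p0 <- strsplit(as.character(
      Biostrings::translate(seq0, no.init.codon = TRUE)), "")[[1]]
    p1 <- strsplit(as.character(suppressWarnings(
      Biostrings::translate(seq1, if.fuzzy.codon = "X",
                            no.init.codon = TRUE))), "")[[1]]
    i <- which(p0 != p1)
    if (length(i) == 0) return("synonymous")
    if (p1[i] == "*") return("nonsense")
    return("missense")
  }
  w <- genome$upstream_window
  up <- any((gr$contig == contig & gr$strand == "+" &
               pos >= gr$start - w & pos < gr$start) |
            (gr$contig == contig & gr$strand == "-" &
               pos > gr$end & pos <= gr$end + w))
  if (up) "upstream" else "intergenic"
}

# exhaustive per-site enumeration of all 3L possible SNPs on a genome.
# CDS variants are classified by translating the complete mutant protein
# (batched per gene); non-CDS positions by interval arithmetic. Both are
# independent of the package's codon-index computation.
enumerate_all_snps <- function(genome) {
  bases <- c("A", "C", "G", "T")
  gr <- genome$genes
  w <- genome$upstream_window
  out <- list()
  for (ctg in names(genome$contigs)) {
    chars <- strsplit(as.character(genome$contigs[[ctg]]), "")[[1]]
    L <- length(chars)
    pos <- rep(seq_len(L), each = 3)
    ref <- chars[pos]
    alt <- vapply(seq_along(pos), function(i)
      setdiff(bases, ref[i])[(i - 1) %% 3 + 1], character(1))
    effect <- rep(NA_character_, length(pos))

    gg <- gr[gr$contig == ctg, , drop = FALSE]
    in_cds <- rep(FALSE, L)
    for (j in seq_len(nrow(gg))) in_cds[gg$start[j]:gg$end[j]] <- TRUE
    up <- rep(FALSE, L)
    for (j in seq_len(nrow(gg))) {
      win <- if (gg$strand[j] == "+")
        seq.int(max(1, gg$start[j] - w), gg$start[j] - 1) else
        seq.int(gg$end[j] + 1, min(L, gg$end[j] + w))
      if (w > 0 && length(win) > 0 && win[1] <= win[length(win)])
        up[win] <- TRUE
    }
    up <- up & !in_cds
    effect[!in_cds[pos]] <- ifelse(up[pos[!in_cds[pos]]], "upstream",
                                   "intergenic")

    for (j in seq_len(nrow(gg))) {
      span <- gg$start[j]:gg$end[j]
      cds_chars <- chars[span]
      variants <- character(3 * length(span))
      vpos <- integer(3 * length(span))
      valt <- character(3 * length(span))
      vi <- 0
      for (p_rel in seq_along(span)) {
        for (a in setdiff(bases, cds_chars[p_rel])) {
          vi <- vi + 1
          mutant <- cds_chars
          mutant[p_rel] <- a
          variants[vi] <- paste(mutant, collapse = "")
          vpos[vi] <- span[p_rel]
          valt[vi] <- a
        }
      }
      vs <- Biostrings::DNAStringSet(c(paste(cds_chars, collapse = ""),
                                       variants))
      if (gg$strand[j] == "-") vs <- Biostrings::reverseComplement(vs)
      # no.init.codon: read the first codon with the plain codon table, so
      # a damaged start codon registers as an amino-acid change rather
      # than an alternative initiator silently translated as Met
      prots <- as.character(suppressWarnings(
        Biostrings::translate(vs, if.fuzzy.codon = "X",
                              no.init.codon = TRUE)))
      p0 <- strsplit(prots[1], "")[[1]]
      cls <- vapply(prots[-1], function(p1s) {
        p1 <- strsplit(p1s, "")[[1]]
        i <- which(p0 != p1)
        if (length(i) == 0) return("synonymous")
        if (p1[i[1]] == "*") return("nonsense")
        "missense"
      }, character(1), USE.NAMES = FALSE)
      effect[match(paste(vpos, valt), paste(pos, alt))] <- cls
    }
    out[[ctg]] <- data.frame(contig = ctg, position = pos, ref = ref,
                             alt = alt, effect = effect,
                             stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# small genome with a hand-chosen gene, for codon-level classification
# examples worked out by hand in the tests
hand_genome <- function(cds_plus, pad = "AAAAAAAAAA", strand = "+",
                        upstream_window = 4) {
  insert <- if (strand == "+") cds_plus else
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(cds_plus)))
  seq <- paste0(pad, insert, pad)
  genes <- data.frame(contig = "c1", start = nchar(pad) + 1,
                      end = nchar(pad) + nchar(cds_plus), strand = strand)
  annotated_genome(c(c1 = seq), genes, upstream_window = upstream_window)
}
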