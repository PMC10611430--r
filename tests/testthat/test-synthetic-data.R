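# Synthetic-data generators: group sizes, genomes, settling videos,
# competition counts

test_that("group-size generator honours family, mean and seed", {
  fixed <- gen_group_sizes(size_spec("fixed", mean_size = 50), 200)
  expect_length(fixed, 200)
  expect_true(all(fixed == 50))

  spec <- size_spec("lognormal", mean_size = 50, dispersion = 0.5)
  s <- gen_group_sizes(spec, 10000, seed = 101)
  expect_length(s, 10000)
  expect_true(all(s >= 1 & s == round(s)))
  # lognormal parameterization targets E[X] = mean_size; 3 SE window
  expect_gt(mean(s), 48)
  expect_lt(mean(s), 52)

  expect_identical(gen_group_sizes(spec, 100, seed = 7),
                   gen_group_sizes(spec, 100, seed = 7))

  emp <- size_spec("empirical", sizes = c(10, 20, 30))
  drawn <- gen_group_sizes(emp, 500, seed = 1)
  expect_true(all(drawn %in% c(10, 20, 30)))

  expect_error(size_spec("lognormal", mean_size = -5), "outside")
  expect_error(gen_group_sizes(spec, 0), "outside")
  expect_error(size_spec("empirical"), "non-empty")
})

test_that("synthetic genomes have clean gene models on both strands", {
  g <- gen_annotated_genome(n_contigs = 2, contig_length = 3000,
                            n_genes = 10, gene_length = 300,
                            upstream_window = 100,
                            strand_mode = "random", seed = 5)
  expect_equal(nrow(g$genes), 10)
  expect_true(all(g$genes$end - g$genes$start + 1 == 300))
  # no overlap within contigs
  for (ctg in unique(g$genes$contig)) {
    gg <- g$genes[g$genes$contig == ctg, ]
    gg <- gg[order(gg$start), ]
    if (nrow(gg) > 1)
      expect_true(all(gg$start[-1] > gg$end[-nrow(gg)]))
  }
  # every CDS starts with ATG, ends with a stop, and has no internal stop
  for (j in seq_len(nrow(g$genes))) {
    row <- g$genes[j, ]
    cds <- Biostrings::subseq(g$contigs[[row$contig]], row$start, row$end)
    if (row$strand == "-") cds <- Biostrings::reverseComplement(cds)
    prot <- as.character(Biostrings::translate(cds))
    expect_identical(substr(as.character(cds), 1, 3), "ATG")
    expect_identical(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
  }
  # determinism
  g2 <- gen_annotated_genome(n_contigs = 2, contig_length = 3000,
                             n_genes = 10, gene_length = 300,
                             upstream_window = 100,
                             strand_mode = "random", seed = 5)
  expect_identical(as.character(g$contigs), as.character(g2$contigs))
  expect_identical(g$genes, g2$genes)
})

test_that("gene-free genomes and infeasible packings behave as specified", {
  g0 <- gen_annotated_genome(n_contigs = 1, contig_length = 500,
                             n_genes = 0, seed = 1, upstream_window = 50)
  expect_equal(nrow(g0$genes), 0)
  snps <- simulate_snps(g0, 300, seed = 2)
  expect_true(all(snps$effect == "intergenic"))

  expect_error(gen_annotated_genome(n_contigs = 1, contig_length = 1000,
                                    n_genes = 5, gene_length = 300,
                                    upstream_window = 100),
               "pack")
  expect_error(gen_annotated_genome(gene_length = 301), "divisible")
})

test_that("genomes round-trip through FASTA + GFF3", {
  g <- gen_annotated_genome(n_contigs = 2, contig_length = 2000,
                            n_genes = 4, gene_length = 150,
                            upstream_window = 200,
                            strand_mode = "random", seed = 9)
  fa <- tempfile(fileext = ".fa")
  gff <- tempfile(fileext = ".gff3")
  write_genome(g, fa, gff)
  g2 <- read_genome(fa, gff, upstream_window = 200)
  expect_identical(as.character(g$contigs), as.character(g2$contigs))
  expect_equal(g$genes[order(g$genes$start), c("contig", "start", "end", "strand")],
               g2$genes[order(g2$genes$start), c("contig", "start", "end", "strand")],
               ignore_attr = TRUE)
  unlink(c(fa, gff))
})

test_that("settling videos move a conserved biomass band at the programmed speed", {
  still <- gen_settling_video(height = 50, width = 6, n_frames = 5,
                              front_speed = 0, noise_sd = 0)
  expect_true(all(still$frames[, , 1] == still$frames[, , 5]))

  v <- gen_settling_video(height = 150, width = 6, n_frames = 50,
                          front_speed = 2, band_frac = 0.3, noise_sd = 0)
  centroid <- function(f) sum(seq_len(nrow(f)) * rowSums(f)) / sum(f)
  expect_equal(centroid(v$frames[, , 50]) - centroid(v$frames[, , 1]),
               98, tolerance = 1e-9)  # 2 px/frame * 49 frames
  # biomass conservation frame to frame (noise-free: exact)
  mass <- apply(v$frames, 3, sum)
  expect_equal(max(mass) - min(mass), 0, tolerance = 1e-9)

  vn <- gen_settling_video(height = 400, width = 20, n_frames = 100,
                           front_speed = 2, band_frac = 0.4,
                           noise_sd = 0.05, seed = 31)
  expect_equal(settling_rate(vn), 2, tolerance = 0.05)

  expect_error(gen_settling_video(height = 60, n_frames = 50,
                                  front_speed = 2),
               "exit")
  expect_identical(
    gen_settling_video(height = 80, width = 5, n_frames = 10,
                       front_speed = 1, noise_sd = 0.1, seed = 3)$frames,
    gen_settling_video(height = 80, width = 5, n_frames = 10,
                       front_speed = 1, noise_sd = 0.1, seed = 3)$frames)
})

test_that("video stacks round-trip through multi-page TIFF", {
  v <- gen_settling_video(height = 40, width = 8, n_frames = 6,
                          front_speed = 2, noise_sd = 0.02, seed = 12)
  path <- tempfile(fileext = ".tif")
  write_video(v, path)
  v2 <- read_video(path, frame_interval = v$frame_interval)
  expect_equal(dim(v2$frames), dim(v$frames))
  # 16-bit quantization on write
  expect_equal(v2$frames, v$frames, tolerance = 1e-2)
  unlink(path)
})

test_that("competition fixtures encode their programmed fitness", {
  cc <- gen_competition_counts(true_fitness = 1, generations_ancestor = 4)
  expect_equal(malthusian_fitness(cc), 1)

  cc2 <- gen_competition_counts(initial_count_evolved = 100,
                                initial_count_ancestor = 100,
                                true_fitness = 2, generations_ancestor = 1)
  expect_equal(cc2$ancestor_final, 200)
  expect_equal(cc2$evolved_final, 400)
  expect_equal(malthusian_fitness(cc2), 2)

  # Poisson counting noise: unbiased recovery on average (Monte Carlo)
  w_hat <- vapply(seq_len(1000), function(i)
    malthusian_fitness(gen_competition_counts(
      initial_count_evolved = 500, initial_count_ancestor = 500,
      true_fitness = 1.5, generations_ancestor = 5,
      count_noise = "poisson", seed = 5000 + i)),
    numeric(1))
  expect_equal(mean(w_hat), 1.5, tolerance = 0.02)
})
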