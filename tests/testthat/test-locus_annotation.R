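# Scaffold filtering, pseudogene detection, linkage-window clustering,
# locus typing and activity calls.

mk_genes <- function(...) {
  rows <- list(...)
  do.call(gene_records, as.list(do.call(rbind.data.frame, rows)))
}

gene_row <- function(id, scaffold, start, end, class, strand = "+",
                     pseudo = NA) {
  data.frame(gene_id = id, scaffold = scaffold, start = start, end = end,
             strand = strand, gene_class = class, pseudo = pseudo,
             stringsAsFactors = FALSE)
}

test_that("scaffold filter is boundary-inclusive at 1 Mb", {
  g <- mk_genes(gene_row("a", "s1", 100, 2000, "T2_RNASE_III"),
                gene_row("b", "s2", 100, 2000, "FBX_SLF"),
                gene_row("c", "s3", 100, 2000, "FBX_SLF"))
  lens <- c(s1 = 8e5, s2 = 1e6, s3 = 5e6)
  kept <- filter_scaffolds(g, lens)
  expect_setequal(kept$gene_id, c("b", "c"))  # exactly 1 Mb retained
  expect_equal(as.vector(attr(kept, "removed")["s1"]), 1)
  expect_equal(nrow(filter_scaffolds(g[0, ], lens)), 0)
  expect_error(filter_scaffolds(g, lens[-1]), "s1")
})

test_that("pseudogene detection finds in-frame premature stops only", {
  expect_true(detect_pseudogene("ATGTAAGGGCCC"))    # TAA at codon 2
  expect_false(detect_pseudogene("ATGGGGCCCTAA"))   # terminal stop only
  expect_false(detect_pseudogene("ATGTNAGGGCCC"))   # N-codon never a stop
  expect_true(detect_pseudogene("ATGTGACCC"))
  expect_false(detect_pseudogene("ATG"))
  expect_warning(out <- detect_pseudogene("ATGTAAGG"), "multiple of 3")
  expect_false(out)  # after truncation TAA is the (excluded) final codon
  expect_error(detect_pseudogene("AT"), "at least one codon")
  expect_error(detect_pseudogene("ATGXAA"), "alphabet")
})

test_that("linkage uses span gaps, boundary-inclusive, same scaffold only", {
  anchor <- mk_genes(gene_row("rn", "s1", 1e6, 1.002e6, "T2_RNASE_III"))
  cands <- mk_genes(
    gene_row("near", "s1", 1.002e6 + 2.9e6, 1.002e6 + 2.903e6, "FBX_SLF"),
    gene_row("edge", "s1", 1.002e6 + 3.0e6, 1.002e6 + 3.003e6, "FBX_SLF"),
    gene_row("far", "s1", 1.002e6 + 3.1e6, 1.002e6 + 3.103e6, "FBX_SLF"),
    gene_row("othersc", "s2", 1.1e6, 1.103e6, "FBX_SLF"),
    gene_row("overlap", "s1", 1.001e6, 1.004e6, "FBX_SLF"),
    gene_row("upstream", "s1", 1e5, 1.03e5, "FBX_SLF"))
  hit <- link_genes(anchor, cands)
  expect_setequal(hit$gene_id, c("near", "edge", "overlap", "upstream"))
  expect_error(link_genes(mk_genes(gene_row("f", "s1", 1, 10, "FBX_SLF")),
                          cands), "RNase")
})

test_that("locus calling clusters, types and scores activity", {
  g <- mk_genes(
    gene_row("rnase1", "s1", 1e6, 1.002e6, "T2_RNASE_III", pseudo = FALSE),
    gene_row("slf1", "s1", 1.01e6, 1.013e6, "FBX_SLF", pseudo = FALSE),
    gene_row("slf2", "s1", 1.02e6, 1.023e6, "FBX_SLF", pseudo = FALSE),
    # a second locus beyond the window
    gene_row("rnase2", "s1", 6e6, 6.002e6, "T2_RNASE_III", pseudo = FALSE),
    gene_row("slf3", "s1", 6.01e6, 6.013e6, "FBX_SLF", pseudo = TRUE),
    # class I/II locus on another scaffold
    gene_row("rnI", "s2", 2e6, 2.002e6, "T2_RNASE_I", pseudo = FALSE),
    gene_row("fbk", "s2", 2.01e6, 2.013e6, "FBX_OTHER", pseudo = FALSE),
    # orphan class III
    gene_row("lone", "s3", 2e6, 2.002e6, "T2_RNASE_III", pseudo = FALSE))
  loci <- call_loci(g)
  types <- vapply(loci, `[[`, character(1), "locus_type")
  act <- vapply(loci, `[[`, character(1), "activity")
  expect_equal(sort(types), sort(c("TYPE1_S_LIKE", "TYPE1_S_LIKE",
                                   "CLASSI_II_LINKED", "ORPHAN_RNASE")))
  t1 <- which(types == "TYPE1_S_LIKE")
  expect_setequal(act[t1], c("ACTIVE", "INACTIVE"))  # pseudo-SLF kills one
  expect_equal(act[types == "ORPHAN_RNASE"], "INACTIVE")
  # every input RNase in exactly one locus; F-boxes never duplicated
  members <- unlist(lapply(loci, function(l) c(l$rnases$gene_id,
                                               l$fboxes$gene_id)))
  expect_false(anyDuplicated(members) > 0)
  expect_true(all(c("rnase1", "rnase2", "rnI", "lone") %in% members))
})

test_that("anchors sharing a linked F-box merge into one locus", {
  g <- mk_genes(
    gene_row("rnA", "s1", 1e6, 1.002e6, "T2_RNASE_III", pseudo = FALSE),
    gene_row("shared", "s1", 2.5e6, 2.503e6, "FBX_SLF", pseudo = FALSE),
    gene_row("rnB", "s1", 4e6, 4.002e6, "T2_RNASE_III", pseudo = FALSE))
  loci <- call_loci(g)
  expect_length(loci, 1)
  expect_equal(nrow(loci[[1]]$rnases), 2)
})

test_that("annotation is invariant to gene order and strand flips", {
  sim <- gen_genome(genome_sim_config(), seed = 99)
  genes <- flag_pseudogenes(sim$genes, sim$cds)
  base <- loci_table(call_loci(genes))
  perm <- genes[rev(seq_len(nrow(genes))), ]
  expect_equal(loci_table(call_loci(perm)), base)
  flipped <- genes
  flipped$strand <- ifelse(flipped$strand == "+", "-", "+")
  expect_equal(loci_table(call_loci(flipped)), base)
})

test_that("low expression downgrades activity and is flagged", {
  g <- mk_genes(
    gene_row("rn", "s1", 1e6, 1.002e6, "T2_RNASE_III", pseudo = FALSE),
    gene_row("psi", "s1", 1.01e6, 1.013e6, "FBX_SLF", pseudo = TRUE),
    gene_row("lowslf", "s1", 1.02e6, 1.023e6, "FBX_SLF", pseudo = FALSE))
  expr <- data.frame(gene_id = c("lowslf", "rn"),
                     tissue = c("stamen", "style"),
                     tpm = c(0.2, 30))
  loci <- call_loci(g, expression = expr)
  expect_equal(loci[[1]]$activity, "INACTIVE")
  expect_equal(loci[[1]]$n_low_expressed, 1)
  # without expression data the intact SLF keeps the locus active
  expect_equal(call_loci(g)[[1]]$activity, "ACTIVE")
})

test_that("genome summaries promote the strongest locus to the S-locus", {
  g <- mk_genes(
    gene_row("rn1", "s1", 1e6, 1.002e6, "T2_RNASE_III", pseudo = FALSE),
    gene_row("s1a", "s1", 1.01e6, 1.013e6, "FBX_SLF", pseudo = FALSE),
    gene_row("s1b", "s1", 1.02e6, 1.023e6, "FBX_SLF", pseudo = FALSE),
    gene_row("rn2", "s2", 1e6, 1.002e6, "T2_RNASE_III", pseudo = FALSE),
    gene_row("s2a", "s2", 1.01e6, 1.013e6, "FBX_SLF", pseudo = TRUE))
  prof <- summarize_genome(call_loci(g), "toy", "TYPE1_SI", wgd_events = 1)
  types <- vapply(prof$loci, `[[`, character(1), "locus_type")
  promoted <- prof$loci[[which(types == "TYPE1_S")]]
  expect_equal(promoted$scaffold, "s1")  # two intact SLFs beat one pseudo
  expect_equal(prof$n_type1_active, 1)
  expect_equal(prof$n_type1_inactive, 1)
  expect_equal(prof$s_rnase_status, "intact")

  empty <- summarize_genome(list(), "none", "SC")
  expect_equal(empty$n_type1, 0)
  expect_error(summarize_genome(list(), "x", "WEIRD"), "phenotype")
})

test_that("GFF3 round trip preserves coordinates and classes", {
  sim <- gen_genome(genome_sim_config(n_type1_loci = 2, n_other_genes = 0),
                    seed = 5)
  path <- file.path(tempdir(), "genes_roundtrip.gff3")
  write_gene_gff(sim$genes, path, sim$scaffold_lengths)
  back <- read_gene_gff(path)
  ord <- order(back$gene_id)
  ord0 <- order(sim$genes$gene_id)
  expect_equal(back$start[ord], sim$genes$start[ord0])
  expect_equal(back$end[ord], sim$genes$end[ord0])
  expect_equal(back$gene_class[ord], sim$genes$gene_class[ord0])
  expect_equal(back$scaffold[ord], sim$genes$scaffold[ord0])
})
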