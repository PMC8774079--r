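# Generators for synthetic inputs with the statistical structure the
# analysis assumes: genomes with planted RNase/F-box loci, Bernoulli
# detoxification matrices, multinomially sampled progeny counts, and trait
# histories evolved forward under the F81 kernel. Every generator is a pure
# function of (config, seed), and ground truth is returned alongside the
# data so recovery tests can score the pipeline exactly.

SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1L, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

random_cds <- function(len_range, pseudo = FALSE) {
  n_codons <- round(stats::runif(1, len_range[1], len_range[2]) / 3)
  n_codons <- max(n_codons, 10L)
  body <- sample(SENSE_CODONS, n_codons - 2L, replace = TRUE)
  if (pseudo) {  # in-frame premature stop, away from both ends
    pos <- sample(seq.int(2L, length(body) - 1L), 1L)
    body[pos] <- sample(c("TAA", "TAG", "TGA"), 1L)
  }
  paste(c("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L)), collapse = "")
}

#' Configuration for the synthetic genome generator
#'
#' Defaults emulate the canonical type-1 S-locus architecture (an S-RNase
#' flanked by a cluster of SLF genes) at a scale the linkage-window rules
#' can be scored against: a handful of multi-megabase scaffolds, planted
#' type-1 and Class I/II loci separated by more than the linkage window,
#' decoy F-box clusters beyond the window from any RNase, and orphan
#' RNases beyond the window from any F-box.
#'
#' @param n_scaffolds Number of scaffolds (default 3).
#' @param n_type1_loci Planted type-1 loci (default 4).
#' @param n_class12_loci Planted Class I/II RNase + F-box loci (default 1).
#' @param n_orphan_rnases Planted unlinked Class III RNases (default 1).
#' @param n_decoy_fbox_clusters Decoy F-box clusters unlinked to any RNase
#'   (default 2).
#' @param n_other_genes Unclassified filler genes (default 6).
#' @param slfs_per_locus Range of SLF genes per type-1 locus (default
#'   3--10; the real clusters carry 9--37 genes, but the locus span must
#'   stay well below the inter-locus separation, and every annotation rule
#'   is insensitive to cluster size beyond one).
#' @param pseudogene_rate Per-gene probability of an injected in-frame
#'   premature stop (default 0.15).
#' @param gene_len Range of CDS lengths in bp (default 900--3000, typical
#'   for RNase/F-box CDS).
#' @param intergenic Range of within-locus intergenic gaps in bp.
#' @param window Linkage window the layout must defeat (default 3e6).
#' @return List of class `genome_sim_config`.
#' @export
genome_sim_config <- function(n_scaffolds = 3, n_type1_loci = 4,
                              n_class12_loci = 1, n_orphan_rnases = 1,
                              n_decoy_fbox_clusters = 2, n_other_genes = 6,
                              slfs_per_locus = c(3, 10),
                              pseudogene_rate = 0.15,
                              gene_len = c(900, 3000),
                              intergenic = c(2e3, 1e4),
                              window = 3e6) {
  stopifnot(n_scaffolds >= 1, n_type1_loci >= 0,
            slfs_per_locus[1] >= 1, pseudogene_rate >= 0,
            pseudogene_rate <= 1)
  structure(as.list(environment()), class = "genome_sim_config")
}

# One cluster of genes laid out left-to-right; returns a data.frame of
# relative coordinates plus CDS strings and pseudo truth flags.
build_block <- function(kind, config, block_id) {
  genes <- switch(kind,
    type1 = {
      n_slf <- sample(seq(config$slfs_per_locus[1],
                          config$slfs_per_locus[2]), 1L)
      cls <- c("T2_RNASE_III", rep("FBX_SLF", n_slf))
      cls[sample(seq_along(cls))]  # RNase at a random position in cluster
    },
    class12 = {
      n_fb <- sample(1:3, 1L)
      cls <- c(sample(c("T2_RNASE_I", "T2_RNASE_II"), 1L),
               rep("FBX_OTHER", n_fb))
      cls[sample(seq_along(cls))]
    },
    orphan = "T2_RNASE_III",
    decoy_fbox = rep(sample(c("FBX_SLF", "FBX_OTHER"), 1L),
                     sample(1:3, 1L)),
    other = rep("OTHER", 1L))
  pseudo <- stats::runif(length(genes)) < config$pseudogene_rate
  cds <- vapply(pseudo, function(p) random_cds(config$gene_len, p),
                character(1))
  len <- nchar(cds)
  gap <- round(stats::runif(length(genes), config$intergenic[1],
                            config$intergenic[2]))
  start <- cumsum(c(0, (len + gap)[-length(len)]))
  data.frame(
    gene_id = sprintf("%s_g%d", block_id, seq_along(genes)),
    offset = start, len = len,
    strand = sample(c("+", "-"), length(genes), replace = TRUE),
    gene_class = genes, pseudo = pseudo, cds = cds,
    stringsAsFactors = FALSE)
}

#' Generate a synthetic genome with planted S-/S-like loci
#'
#' Lays out planted loci, orphan RNases and decoy F-box clusters on
#' scaffolds so that distinct blocks are always separated by more than the
#' linkage window, injects in-frame premature stops at the configured
#' pseudogene rate, and returns everything the annotation pipeline needs
#' plus the ground truth.
#'
#' @param config [genome_sim_config()].
#' @param seed Integer seed; output is a pure function of (config, seed).
#' @return List with `genes` ([gene_records()], `pseudo = NA`: detection is
#'   the pipeline's job), `cds` (named character vector), `scaffold_lengths`
#'   (named numeric), and `truth` (planted loci with member ids, type and
#'   activity; planted pseudogene ids; the config and seed).
#' @export
gen_genome <- function(config = genome_sim_config(), seed = 1) {
  with_seed(child_seed(seed, 1), {
    blocks <- c(rep("type1", config$n_type1_loci),
                rep("class12", config$n_class12_loci),
                rep("orphan", config$n_orphan_rnases),
                rep("decoy_fbox", config$n_decoy_fbox_clusters))
    built <- lapply(seq_along(blocks), function(i) {
      list(kind = blocks[i],
           genes = build_block(blocks[i], config, sprintf("b%02d", i)))
    })
    scaffold <- rep(seq_len(config$n_scaffolds),
                    length.out = length(built))

    rows <- list(); truth_loci <- list(); lengths <- numeric(0)
    for (sc in seq_len(config$n_scaffolds)) {
      mine <- built[scaffold == sc]
      pos <- 5e4  # leading margin
      for (b in mine) {
        g <- b$genes
        g$scaffold <- sprintf("scf%02d", sc)
        g$start <- pos + g$offset
        g$end <- g$start + g$len
        rows[[length(rows) + 1L]] <- g
        if (b$kind %in% c("type1", "class12", "orphan")) {
          truth_loci[[length(truth_loci) + 1L]] <- list(
            members = g$gene_id,
            scaffold = g$scaffold[1],
            locus_type = switch(b$kind,
              type1 = "TYPE1_S_LIKE",
              class12 = "CLASSI_II_LINKED",
              orphan = "ORPHAN_RNASE"),
            activity = if (b$kind == "type1" &&
                           any(!g$pseudo[g$gene_class == "T2_RNASE_III"]) &&
                           any(!g$pseudo[g$gene_class == "FBX_SLF"])) {
              "ACTIVE"
            } else if (b$kind == "class12" &&
                       any(!g$pseudo[grepl("RNASE", g$gene_class)]) &&
                       any(!g$pseudo[g$gene_class == "FBX_OTHER"])) {
              "ACTIVE"
            } else "INACTIVE")
        }
        pos <- max(g$end) + config$window + 1e4  # > window separation
      }
      lengths[sprintf("scf%02d", sc)] <- max(pos, 1.2e6)
    }

    genes <- do.call(rbind, rows)
    # filler genes in the wide inter-block gaps (class OTHER: inert)
    if (config$n_other_genes > 0) {
      for (i in seq_len(config$n_other_genes)) {
        b <- build_block("other", config, sprintf("oth%02d", i))
        sc <- sample(names(lengths), 1L)
        on_sc <- genes[genes$scaffold == sc, ]
        anchor <- max(on_sc$end) + 2e4 + (i - 1) * 6e3
        b$scaffold <- sc; b$start <- anchor; b$end <- anchor + b$len
        genes <- rbind(genes, b)
        lengths[sc] <- max(lengths[sc], max(b$end) + 5e4)
      }
    }

    cds <- stats::setNames(genes$cds, genes$gene_id)
    truth <- list(loci = truth_loci,
                  pseudogenes = genes$gene_id[genes$pseudo],
                  config = config, seed = seed)
    gr <- gene_records(genes$gene_id, genes$scaffold, genes$start,
                       genes$end, genes$strand, genes$gene_class,
                       pseudo = NA)
    list(genes = gr, cds = cds, scaffold_lengths = lengths, truth = truth)
  })
}

#' Write a synthetic genome to disk
#'
#' Writes `genes.gff3`, `cds.fa`, `scaffold_lengths.tsv` and `truth.json`
#' into `dir`.
#'
#' @param sim Output of [gen_genome()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_genome <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_gene_gff(sim$genes, file.path(dir, "genes.gff3"),
                 scaffold_lengths = sim$scaffold_lengths)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sim$cds),
                              file.path(dir, "cds.fa"))
  utils::write.table(
    data.frame(scaffold = names(sim$scaffold_lengths),
               length = unname(sim$scaffold_lengths)),
    file.path(dir, "scaffold_lengths.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Random haplotype-by-RNase detoxification matrix
#'
#' Independent Bernoulli(p_r) off-diagonal entries; the diagonal is FALSE
#' (an SLF repertoire never detoxifies its own S-RNase).
#'
#' @param n_haplotypes At least 3.
#' @param p_r Per-pair detoxification probability.
#' @param seed Integer seed.
#' @return Logical matrix with haplotype names `H1..Hn`.
#' @export
gen_detox_matrix <- function(n_haplotypes, p_r, seed = 1) {
  if (n_haplotypes < 3) stop_input("need at least 3 haplotypes")
  if (p_r < 0 || p_r > 1) stop_input("p_r must be in [0, 1]")
  with_seed(child_seed(seed, 2), {
    m <- matrix(stats::runif(n_haplotypes^2) < p_r, n_haplotypes)
    diag(m) <- FALSE
    dimnames(m) <- rep(list(paste0("H", seq_len(n_haplotypes))), 2)
    m
  })
}

#' Sample progeny genotype counts for a transgenic self-cross
#'
#' Multinomial draw of `n_offspring` from [predict_progeny()].
#'
#' @inheritParams predict_progeny
#' @param n_offspring Number of genotyped progeny.
#' @param seed Integer seed.
#' @return Named integer vector of genotype counts.
#' @export
gen_progeny <- function(parent_alleles, transgene, n_offspring, seed = 1,
                        transgene_zygosity = "hemizygous") {
  pred <- predict_progeny(parent_alleles, transgene,
                          transgene_zygosity = transgene_zygosity)
  if (n_offspring == 0) {
    return(stats::setNames(integer(length(pred)), names(pred)))
  }
  with_seed(child_seed(seed, 3), {
    stats::setNames(as.integer(stats::rmultinom(1, n_offspring, pred)),
                    names(pred))
  })
}

#' Evolve a discrete trait history forward along a tree
#'
#' Draws the root state from pi and propagates states tipward through the
#' F81 transition kernel of each branch.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param params [f81_params()].
#' @param seed Integer seed.
#' @return List with `tip_states` (named by tip label) and `node_states`
#'   (all nodes, named as in [marginal_posteriors()] rows).
#' @export
gen_trait_history <- function(tree, params, seed = 1) {
  tree <- check_tree(tree)
  tr <- stats::reorder(tree, "postorder")
  n_tip <- length(tr$tip.label)
  n_node <- n_tip + tr$Nnode
  states <- params$states
  with_seed(child_seed(seed, 4), {
    x <- character(n_node)
    x[n_tip + 1L] <- sample(states, 1L, prob = params$pi)
    for (e in rev(seq_len(nrow(tr$edge)))) {  # parents before children
      parent <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      P <- f81_matrix(tr$edge.length[e], params)
      x[child] <- sample(states, 1L, prob = P[x[parent], ])
    }
    names(x) <- c(tr$tip.label, paste0("node", (n_tip + 1L):n_node))
    list(tip_states = x[seq_len(n_tip)],
         node_states = x)
  })
}
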