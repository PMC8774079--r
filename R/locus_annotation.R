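# Type-1 S-/S-like locus annotation from a classified gene table.
#
# Inputs are genes already classified (T2 RNase Class I/II/III, SLF-family
# F-box, other F-box, other) on scaffolds; homology search and domain
# scanning are upstream of this package. Annotation proceeds by scaffold
# quality filtering (>= 1 Mb), pseudogene detection from CDS (in-frame
# premature stop), linkage-window clustering (F-box genes within 3 Mb of a
# T2 RNase anchor), locus typing, and activity calls.

RNASE_CLASSES <- c("T2_RNASE_I", "T2_RNASE_II", "T2_RNASE_III")
FBOX_CLASSES <- c("FBX_SLF", "FBX_OTHER")
GENE_CLASSES <- c(RNASE_CLASSES, FBOX_CLASSES, "OTHER")
LOCUS_TYPES <- c("TYPE1_S", "TYPE1_S_LIKE", "CLASSI_II_LINKED",
                 "ORPHAN_RNASE")

#' Build a gene-record table
#'
#' Validates and normalizes a table of classified gene features. Coordinates
#' are 0-based half-open internally; [read_gene_gff()] converts from GFF3's
#' 1-based inclusive convention.
#'
#' @param gene_id,scaffold Character vectors.
#' @param start,end Numeric coordinates, `start < end` (0-based half-open).
#' @param strand `"+"` or `"-"`.
#' @param gene_class One of `r paste(GENE_CLASSES, collapse = ", ")`.
#' @param pseudo Optional logical flag (NA = unknown until CDS is scanned).
#' @return data.frame of class `gene_records`.
#' @export
gene_records <- function(gene_id, scaffold, start, end, strand = "+",
                         gene_class, pseudo = NA) {
  df <- data.frame(gene_id = as.character(gene_id),
                   scaffold = as.character(scaffold),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = strand, gene_class = as.character(gene_class),
                   pseudo = pseudo, stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) stop_input("duplicate gene_id")
  if (any(df$start >= df$end)) stop_input("need start < end for every gene")
  bad <- setdiff(unique(df$gene_class), GENE_CLASSES)
  if (length(bad)) {
    stop_input("unknown gene_class: ", paste(bad, collapse = ", "))
  }
  if (any(!df$strand %in% c("+", "-"))) stop_input("strand must be + or -")
  class(df) <- c("gene_records", "data.frame")
  df
}

#' Read classified genes from GFF3
#'
#' Gene-class labels are taken from a `gene_class` attribute; an optional
#' `pseudo` attribute ("true"/"false") is honored. GFF3 1-based inclusive
#' coordinates are converted to the package's 0-based half-open convention.
#'
#' @param path GFF3 file.
#' @return `gene_records` table.
#' @export
read_gene_gff <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type %in% c("gene", "pseudogene")]
  meta <- S4Vectors::mcols(gr)
  id <- if ("ID" %in% names(meta)) as.character(meta$ID)
        else as.character(meta$Name)
  cls <- as.character(meta$gene_class)
  pseudo <- if ("pseudo" %in% names(meta)) {
    tolower(as.character(meta$pseudo)) == "true"
  } else {
    as.character(gr$type) == "pseudogene"
  }
  gene_records(gene_id = id,
               scaffold = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               strand = ifelse(as.character(GenomicRanges::strand(gr)) == "-",
                               "-", "+"),
               gene_class = cls, pseudo = pseudo)
}

#' Write classified genes to GFF3
#'
#' Inverse of [read_gene_gff()].
#'
#' @param genes `gene_records` table.
#' @param path Output file.
#' @param scaffold_lengths Optional named vector recorded as sequence
#'   lengths.
#' @return `path`, invisibly.
#' @export
write_gene_gff <- function(genes, path, scaffold_lengths = NULL) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$scaffold,
    ranges = IRanges::IRanges(start = genes$start + 1L, end = genes$end),
    strand = genes$strand)
  gr$type <- "gene"
  gr$source <- "slocusevo"
  gr$ID <- genes$gene_id
  gr$gene_class <- genes$gene_class
  gr$pseudo <- ifelse(is.na(genes$pseudo), "false",
                      tolower(as.character(genes$pseudo)))
  if (!is.null(scaffold_lengths)) {
    GenomeInfoDb_ok <- requireNamespace("GenomeInfoDb", quietly = TRUE)
    if (GenomeInfoDb_ok) {
      GenomeInfoDb::seqlengths(gr) <-
        scaffold_lengths[GenomeInfoDb::seqlevels(gr)]
    }
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Drop genes on scaffolds below the assembly-quality threshold
#'
#' Loci can only be resolved on scaffolds long enough to span a linkage
#' region; genes on scaffolds shorter than `min_len` (default 1 Mb,
#' boundary-inclusive) are removed. The number removed per scaffold is
#' attached as attribute `"removed"`.
#'
#' @param genes `gene_records` table.
#' @param scaffold_lengths Named numeric vector (bp) or data.frame with
#'   columns `scaffold`, `length`.
#' @param min_len Minimum scaffold length in bp (default 1e6).
#' @return Filtered `gene_records`.
#' @export
filter_scaffolds <- function(genes, scaffold_lengths, min_len = 1e6) {
  if (is.data.frame(scaffold_lengths)) {
    scaffold_lengths <- stats::setNames(scaffold_lengths$length,
                                        scaffold_lengths$scaffold)
  }
  missing <- setdiff(unique(genes$scaffold), names(scaffold_lengths))
  if (length(missing)) {
    stop_input("no declared length for scaffold(s): ",
               paste(missing, collapse = ", "))
  }
  keep <- scaffold_lengths[genes$scaffold] >= min_len
  removed <- table(genes$scaffold[!keep])
  out <- genes[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Detect a pseudogene from its CDS
#'
#' TRUE iff an in-frame stop codon (standard code) occurs strictly before
#' the final codon, reading frame 0 of the provided CDS. Codons containing
#' N are never counted as stops. A length not divisible by 3 drops the
#' trailing remainder with a warning.
#'
#' @param cds Character string or `Biostrings::DNAString` (alphabet ACGTN).
#' @return Logical flag.
#' @examples
#' detect_pseudogene("ATGTAAGGGCCC")  # TRUE: TAA at codon 2
#' detect_pseudogene("ATGGGGCCCTAA")  # FALSE: terminal stop only
#' @export
detect_pseudogene <- function(cds) {
  s <- toupper(as.character(cds))
  if (nchar(s) < 3) stop_input("CDS must be at least one codon long")
  if (grepl("[^ACGTN]", s)) stop_input("CDS alphabet must be ACGTN")
  n <- nchar(s)
  if (n %% 3 != 0) {
    warning("CDS length not a multiple of 3; truncating trailing remainder")
    n <- n - n %% 3
  }
  if (n < 6L) return(FALSE)  # a single codon cannot hold a premature stop
  starts <- seq.int(1L, n - 3L, by = 3L)  # exclude final codon
  codons <- substring(s, starts, starts + 2L)
  any(codons %in% STOP_CODONS)
}

#' Flag pseudogenes across a gene table from a CDS set
#'
#' @param genes `gene_records` table.
#' @param cds Named character vector or `DNAStringSet` keyed by `gene_id`.
#' @return `genes` with the `pseudo` column filled for genes with a CDS.
#' @export
flag_pseudogenes <- function(genes, cds) {
  cds <- stats::setNames(as.character(cds), names(cds))
  have <- genes$gene_id %in% names(cds)
  genes$pseudo[have] <- vapply(cds[genes$gene_id[have]], detect_pseudogene,
                               logical(1))
  genes
}

span_gap <- function(s1, e1, s2, e2) {
  pmax(0, pmax(s1, s2) - pmin(e1, e2))
}

#' F-box genes linked to an RNase anchor
#'
#' Candidates on the anchor's scaffold whose gap between gene spans
#' (0 when overlapping) is at most `window` (default 3 Mb, inclusive);
#' strand is ignored.
#'
#' @param anchor Single-row `gene_records` (an RNase-class gene).
#' @param candidates `gene_records` table.
#' @param window Linkage window in bp.
#' @return Subset of `candidates`.
#' @export
link_genes <- function(anchor, candidates, window = 3e6) {
  stopifnot(nrow(anchor) == 1)
  if (!anchor$gene_class %in% RNASE_CLASSES) {
    stop_input("anchor must be an RNase-class gene")
  }
  same <- candidates$scaffold == anchor$scaffold
  gap <- span_gap(anchor$start, anchor$end,
                  candidates$start, candidates$end)
  candidates[same & gap <= window & candidates$gene_id != anchor$gene_id, ,
             drop = FALSE]
}

gene_functional <- function(genes, expression = NULL, tpm_threshold = 1.0) {
  ok <- !isTRUE_vec(genes$pseudo)
  low <- rep(FALSE, nrow(genes))
  if (!is.null(expression)) {
    tissue <- ifelse(genes$gene_class %in% FBOX_CLASSES, "stamen", "style")
    tpm <- mapply(function(g, ti) {
      v <- expression$tpm[expression$gene_id == g & expression$tissue == ti]
      if (length(v)) v[1] else NA_real_
    }, genes$gene_id, tissue)
    low <- !is.na(tpm) & tpm < tpm_threshold
  }
  list(functional = ok & !low, low_expressed = low)
}

isTRUE_vec <- function(x) !is.na(x) & x

#' Cluster classified genes into candidate S-/S-like loci
#'
#' Every RNase-class gene anchors a candidate locus containing the F-box
#' genes within the linkage window ([link_genes()]); anchors that share at
#' least one linked F-box gene are merged into a single locus. Loci are
#' typed: a Class III T2 RNase with at least one linked SLF-family F-box is
#' a type-1 S-like locus (one per genome is promoted to the functional
#' S-locus by [summarize_genome()] when the species shows type-1 SI); a
#' Class I/II RNase with a linked F-box is a Class I/II linked locus; an
#' RNase without linked F-box genes (or a Class III RNase whose only linked
#' F-boxes fall outside the SLF subfamily) is an orphan RNase. A locus is
#' ACTIVE iff it has at least one functional (non-pseudogene, and not
#' low-expressed when expression data are given: TPM below `tpm_threshold`
#' in stamen for F-box genes, style for RNases) RNase and one functional
#' SLF.
#'
#' @param genes `gene_records` table (pre-filtered and classified; `pseudo`
#'   filled where known).
#' @param window Linkage window in bp (default 3e6).
#' @param expression Optional data.frame `gene_id`, `tissue`, `tpm`.
#' @param tpm_threshold Low-expression cutoff in TPM (default 1.0).
#' @return List of `locus` objects (each a list with `locus_id`,
#'   `scaffold`, `span`, `rnases`, `fboxes`, `locus_type`, `activity`,
#'   `n_low_expressed`), ordered by scaffold then span start.
#' @export
call_loci <- function(genes, window = 3e6, expression = NULL,
                      tpm_threshold = 1.0) {
  genes <- genes[order(genes$scaffold, genes$start, genes$gene_id), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  anchors <- which(genes$gene_class %in% RNASE_CLASSES)
  fbx <- genes[genes$gene_class %in% FBOX_CLASSES, , drop = FALSE]
  if (!length(anchors)) return(list())

  linked <- lapply(anchors, function(i) {
    link_genes(genes[i, , drop = FALSE], fbx, window = window)$gene_id
  })

  # merge anchors sharing any linked F-box (connected components)
  comp <- seq_along(anchors)
  repeat {
    changed <- FALSE
    for (i in seq_along(anchors)) {
      for (j in seq_along(anchors)) {
        if (comp[i] != comp[j] &&
            length(intersect(linked[[i]], linked[[j]]))) {
          comp[comp == max(comp[i], comp[j])] <- min(comp[i], comp[j])
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }

  fun <- gene_functional(genes, expression, tpm_threshold)
  loci <- lapply(unique(comp), function(cc) {
    idx <- anchors[comp == cc]
    rn <- genes[idx, , drop = FALSE]
    fb_ids <- unique(unlist(linked[comp == cc]))
    fb <- fbx[fbx$gene_id %in% fb_ids, , drop = FALSE]
    members <- rbind(rn, fb)
    has_slf <- any(fb$gene_class == "FBX_SLF")
    type <- if (nrow(fb) == 0L) {
      "ORPHAN_RNASE"
    } else if (any(rn$gene_class == "T2_RNASE_III") && has_slf) {
      "TYPE1_S_LIKE"
    } else if (has_slf || any(fb$gene_class == "FBX_OTHER")) {
      if (any(rn$gene_class == "T2_RNASE_III")) "ORPHAN_RNASE"
      else "CLASSI_II_LINKED"
    }
    rn_fun <- fun$functional[match(rn$gene_id, genes$gene_id)]
    slf <- fb[fb$gene_class == "FBX_SLF", , drop = FALSE]
    slf_fun <- fun$functional[match(slf$gene_id, genes$gene_id)]
    fb_any_fun <- fun$functional[match(fb$gene_id, genes$gene_id)]
    active <- switch(type,
      TYPE1_S_LIKE = any(rn_fun) && any(slf_fun),
      CLASSI_II_LINKED = any(rn_fun) && any(fb_any_fun),
      ORPHAN_RNASE = FALSE)
    low <- sum(fun$low_expressed[match(members$gene_id, genes$gene_id)])
    structure(list(
      locus_id = NA_character_,
      scaffold = rn$scaffold[1],
      span = c(min(members$start), max(members$end)),
      rnases = rn, fboxes = fb,
      locus_type = type,
      activity = if (active) "ACTIVE" else "INACTIVE",
      n_low_expressed = low,
      n_intact_slfs = sum(slf_fun)
    ), class = "locus")
  })

  ord <- order(vapply(loci, `[[`, character(1), "scaffold"),
               vapply(loci, function(l) l$span[1], numeric(1)))
  loci <- loci[ord]
  for (i in seq_along(loci)) {
    loci[[i]]$locus_id <- sprintf("locus_%03d", i)
  }
  loci
}

#' @export
print.locus <- function(x, ...) {
  cat("<locus> ", x$locus_id, " ", x$scaffold, ":",
      format(x$span[1], big.mark = ","), "-",
      format(x$span[2], big.mark = ","), " ", x$locus_type, " ",
      x$activity, " (", nrow(x$rnases), " RNase, ", nrow(x$fboxes),
      " F-box)\n", sep = "")
  invisible(x)
}

#' Summarize a genome's loci into a species profile
#'
#' Tallies loci per type and activity and, for a type-1 SI species,
#' promotes one type-1 locus to the functional S-locus: the one with the
#' most intact SLFs, ties broken by larger span then scaffold name.
#'
#' @param loci List from [call_loci()].
#' @param species Species name.
#' @param phenotype One of `TYPE1_SI, TYPE2_SI, TYPE3_SI, TYPE4_SI,
#'   GSI_OTHER, SSI_OTHER, SC, DIOECIOUS`.
#' @param wgd_events Number of known whole-genome duplication/triplication
#'   events (an input from the literature, not inferred here).
#' @param s_rnase_status Optional status of the S-locus S-RNase
#'   (`"intact"`, `"pseudogene"`, `"deleted"`); defaults to a value derived
#'   from the loci (a deletion cannot be observed from RNase-anchored loci
#'   and must be supplied explicitly).
#' @return List of class `species_profile` with the per-type/per-activity
#'   counts consumed by [infer_routes()].
#' @export
summarize_genome <- function(loci, species, phenotype, wgd_events = 0,
                             s_rnase_status = NULL) {
  phen <- c("TYPE1_SI", "TYPE2_SI", "TYPE3_SI", "TYPE4_SI", "GSI_OTHER",
            "SSI_OTHER", "SC", "DIOECIOUS")
  if (!phenotype %in% phen) {
    stop_input("phenotype must be one of: ", paste(phen, collapse = ", "))
  }
  types <- vapply(loci, `[[`, character(1), "locus_type")
  t1 <- which(types == "TYPE1_S_LIKE")
  if (phenotype == "TYPE1_SI" && length(t1)) {
    n_slf <- vapply(loci[t1], `[[`, numeric(1), "n_intact_slfs")
    spans <- vapply(loci[t1], function(l) diff(l$span), numeric(1))
    scafs <- vapply(loci[t1], `[[`, character(1), "scaffold")
    best <- t1[order(-n_slf, -spans, scafs)[1L]]
    loci[[best]]$locus_type <- "TYPE1_S"
    types[best] <- "TYPE1_S"
  }
  act <- vapply(loci, `[[`, character(1), "activity")
  is_t1 <- types %in% c("TYPE1_S", "TYPE1_S_LIKE")
  lowexp <- vapply(loci, function(l) l$n_low_expressed > 0, logical(1))

  if (is.null(s_rnase_status)) {
    s_rnase_status <- if (!any(is_t1)) {
      NA_character_
    } else if (any(vapply(loci[is_t1], function(l) any(!isTRUE_vec(l$rnases$pseudo)),
                          logical(1)))) {
      "intact"
    } else {
      "pseudogene"
    }
  }

  counts <- table(factor(types, LOCUS_TYPES),
                  factor(act, c("ACTIVE", "INACTIVE")))
  structure(list(
    species = species, si_phenotype = phenotype,
    wgd_events = as.integer(wgd_events),
    loci = loci,
    counts = counts,
    n_type1 = sum(is_t1),
    n_type1_active = sum(is_t1 & act == "ACTIVE"),
    n_type1_inactive = sum(is_t1 & act == "INACTIVE"),
    n_type1_lowexpr = sum(is_t1 & lowexp),
    s_rnase_status = s_rnase_status
  ), class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat("<species_profile> ", x$species, " [", x$si_phenotype, "], ",
      x$wgd_events, " WGD; type-1 loci: ", x$n_type1_active, " active / ",
      x$n_type1_inactive, " inactive\n", sep = "")
  invisible(x)
}

#' Export a locus list as a flat table
#'
#' @param loci List from [call_loci()].
#' @return data.frame with one row per locus (member gene ids
#'   comma-separated).
#' @export
loci_table <- function(loci) {
  if (!length(loci)) {
    return(data.frame(locus_id = character(), scaffold = character(),
                      start = numeric(), end = numeric(),
                      locus_type = character(), activity = character(),
                      rnases = character(), fboxes = character()))
  }
  do.call(rbind, lapply(loci, function(l) {
    data.frame(locus_id = l$locus_id, scaffold = l$scaffold,
               start = l$span[1], end = l$span[2],
               locus_type = l$locus_type, activity = l$activity,
               rnases = paste(l$rnases$gene_id, collapse = ","),
               fboxes = paste(l$fboxes$gene_id, collapse = ","))
  }))
}
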