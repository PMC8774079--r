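# Detoxification specificity: which S-RNases a given SLF (or transgene
# expressing one) can target for degradation.

#' Construct a detoxification specificity
#'
#' A `detox_spec` records, for one SLF or transgene, the set of S-RNase
#' alleles it detoxifies. Under collaborative non-self recognition an
#' endogenous haplotype's SLF repertoire never detoxifies its own S-RNase;
#' that invariant is enforced when `own_allele` is supplied.
#'
#' @param source_id Identifier of the SLF or transgene (e.g. `"ShS5-SLF5"`).
#' @param targets Character vector of detoxified S-RNase allele names
#'   (possibly empty).
#' @param universe Optional character vector of all allele names in play;
#'   when given, `targets` must be a subset.
#' @param own_allele Optional allele name of the haplotype carrying this
#'   repertoire; must not appear in `targets`.
#' @return An object of class `detox_spec`.
#' @examples
#' detox_spec("ShS5-SLF5", targets = "S3L", universe = c("S3", "S3L"))
#' @export
detox_spec <- function(source_id, targets = character(), universe = NULL,
                       own_allele = NULL) {
  targets <- unique(as.character(targets))
  if (anyNA(targets) || any(!nzchar(targets))) {
    stop_input("detox targets must be non-empty allele names")
  }
  if (!is.null(universe) && length(setdiff(targets, universe))) {
    stop_input("unknown allele(s) in targets: ",
               paste(setdiff(targets, universe), collapse = ", "))
  }
  if (!is.null(own_allele) && own_allele %in% targets) {
    stop_input("an endogenous repertoire cannot detoxify its own allele (",
               own_allele, ")")
  }
  structure(
    list(source_id = as.character(source_id),
         targets = sort(targets)),
    class = "detox_spec"
  )
}

#' @export
print.detox_spec <- function(x, ...) {
  cat("<detox_spec> ", x$source_id, ": detoxifies {",
      paste(x$targets, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' @export
format.detox_spec <- function(x, ...) {
  paste0(x$source_id, " -> {", paste(x$targets, collapse = ","), "}")
}

#' Read transgene specificities from a TSV file
#'
#' Expected columns: `transgene_id`, `source_species`, `targets`
#' (comma-separated allele names; empty for a transgene with no
#' detoxification activity).
#'
#' @param path Path to the TSV file.
#' @param universe Optional allele universe for validation.
#' @return A list of [detox_spec()] objects, one per row.
#' @export
read_detox_specs <- function(path, universe = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("transgene_id", "targets")
  if (length(setdiff(need, names(tab)))) {
    stop_input("spec table must have columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(tab)), function(i) {
    tg <- strsplit(tab$targets[i], ",", fixed = TRUE)[[1]]
    tg <- trimws(tg[nzchar(trimws(tg))])
    sp <- detox_spec(tab$transgene_id[i], tg, universe = universe)
    sp$source_species <- tab$source_species[i] %||% NA_character_
    sp
  })
}
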