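# SI loss/regain route classification.
#
# Loss routes: R1 duplication of the S-locus (competitive interaction
# between the two resident haplotypes breaks SI), R2 deletion/inactivation
# of the S-RNase, R3 deletion of the whole S-locus. Regain routes:
# (a) inactivation or reduced expression of the duplicate copies,
# (b) deletion of the duplicates, (c) reactivation of the S-RNase,
# (d) evolution of a new SI system (type-2/3/4). A species' call is read
# off its genomic type-1 locus inventory plus its SI phenotype by an
# ordered decision table; the first matching rule wins.

ROUTE_PHENOTYPES <- c("TYPE1_SI", "TYPE2_SI", "TYPE3_SI", "TYPE4_SI",
                      "GSI_OTHER", "SSI_OTHER", "SC", "DIOECIOUS")

route_call <- function(species, loss, regain, rationale,
                       alternatives = list(), provisional = FALSE) {
  structure(list(species = species, loss_route = loss,
                 regain_route = regain,
                 ambiguous_alternatives = alternatives,
                 rationale = rationale, provisional = provisional),
            class = "route_call")
}

#' @export
print.route_call <- function(x, ...) {
  cat("<route_call> ", x$species, ": loss ", x$loss_route, ", regain ",
      x$regain_route,
      if (length(x$ambiguous_alternatives)) " (ambiguous)" else "",
      "\n  ", x$rationale, "\n", sep = "")
  invisible(x)
}

profile_fields <- function(profile) {
  if (inherits(profile, "species_profile")) {
    list(species = profile$species, phenotype = profile$si_phenotype,
         wgd = profile$wgd_events,
         active = profile$n_type1_active,
         inactive = profile$n_type1_inactive,
         lowexpr = profile$n_type1_lowexpr,
         s_rnase = profile$s_rnase_status %||% NA_character_)
  } else {
    list(species = profile$species, phenotype = profile$phenotype,
         wgd = as.integer(profile$wgd_events),
         active = as.integer(profile$n_type1_active),
         inactive = as.integer(profile$n_type1_inactive),
         lowexpr = as.integer(profile$n_type1_lowexpr),
         s_rnase = as.character(profile$s_rnase_status %||% NA))
  }
}

#' Classify a species' SI loss/regain history
#'
#' Applies an ordered decision table to the species' SI phenotype and
#' type-1 locus inventory; the first matching rule wins. Rules, in order:
#'
#' 1. Type-1 SI, at least one WGD, exactly one type-1 locus: loss by
#'    duplication (R1), SI regained by deletion of the duplicates (b).
#' 2. Type-1 SI, two or more type-1 loci with all but one inactive or
#'    low-expressed: R1, regained by inactivation/reduced expression of
#'    the duplicates (a).
#' 3. Self-compatible, one type-1 locus whose S-RNase is deleted or
#'    pseudogenized with SLFs intact: S-RNase loss (R2), no regain.
#' 4. Self-compatible with two or more active type-1 loci: loss by
#'    retained duplication (R1), no regain.
#' 5. Type-2 or type-4 SI with no type-1 locus: whole-locus deletion (R3)
#'    then a new SI system (d).
#' 6. Type-3 SI with two or more type-1 (S-like) loci: R1 then d.
#' 7. Other GSI with exactly two type-1 loci: ambiguous, R1 regained via
#'    a or d.
#' 8. Other SSI with no type-1 locus: R3 then d.
#' 9. Self-compatible with no type-1 locus: R3, no regain.
#' 10. Anything else: UNCLASSIFIED with a rationale.
#'
#' Route c (S-RNase reactivation) is representable in the output vocabulary
#' but never emitted by the table; no analyzed species requires it.
#'
#' @param profile A [summarize_genome()] `species_profile`, or a list/row
#'   with fields `species`, `phenotype`, `wgd_events`, `n_type1_active`,
#'   `n_type1_inactive`, `n_type1_lowexpr`, `s_rnase_status`.
#' @return A `route_call`: `loss_route` in `R1/R2/R3/NONE/UNCLASSIFIED`,
#'   `regain_route` in `a/b/c/d/NONE`, possible `ambiguous_alternatives`,
#'   and a textual `rationale`.
#' @export
infer_routes <- function(profile) {
  f <- profile_fields(profile)
  if (!f$phenotype %in% ROUTE_PHENOTYPES) {
    stop_input("unknown phenotype: ", f$phenotype)
  }
  if (anyNA(c(f$active, f$inactive)) || f$active < 0 || f$inactive < 0) {
    stop_input("inconsistent profile counts for ", f$species)
  }
  total <- f$active + f$inactive
  lost_rnase <- !is.na(f$s_rnase) && f$s_rnase %in% c("deleted", "pseudogene")

  if (f$phenotype == "TYPE1_SI" && f$wgd >= 1 && total == 1) {
    return(route_call(f$species, "R1", "b",
      "single type-1 S-locus despite WGD: duplicate loci deleted"))
  }
  if (f$phenotype == "TYPE1_SI" && total >= 2 &&
      f$active <= 1 && (f$inactive + f$lowexpr) >= total - 1) {
    return(route_call(f$species, "R1", "a",
      "duplicate type-1 loci, all but one inactive or low-expressed"))
  }
  if (f$phenotype == "SC" && total == 1 && lost_rnase) {
    return(route_call(f$species, "R2", "NONE",
      paste0("S-RNase ", f$s_rnase, " with SLFs retained")))
  }
  if (f$phenotype == "SC" && total >= 2 && f$active == total) {
    return(route_call(f$species, "R1", "NONE",
      "retained duplicate active type-1 S-loci (competitive interaction)"))
  }
  if (f$phenotype %in% c("TYPE2_SI", "TYPE4_SI") && total == 0) {
    return(route_call(f$species, "R3", "d",
      "no type-1 locus; SI regained through a new system"))
  }
  if (f$phenotype == "TYPE3_SI" && total >= 2) {
    return(route_call(f$species, "R1", "d",
      "duplicate type-1 S-like loci; SI regained through a new system"))
  }
  if (f$phenotype == "GSI_OTHER" && total == 2) {
    return(route_call(f$species, "R1", "a",
      "two type-1 loci in a GSI species: regain via a or d indistinguishable",
      alternatives = list(c("R1", "a"), c("R1", "d"))))
  }
  if (f$phenotype == "SSI_OTHER" && total == 0) {
    return(route_call(f$species, "R3", "d",
      "no type-1 locus in an SSI species; regain through a new system"))
  }
  if (f$phenotype == "SC" && total == 0) {
    return(route_call(f$species, "R3", "NONE",
      "no type-1 locus; only whole-locus deletion explains absence"))
  }
  route_call(f$species, "UNCLASSIFIED", "NONE",
    sprintf("no rule for phenotype %s with %d active / %d inactive loci",
            f$phenotype, f$active, f$inactive))
}

#' Classify a table of species profiles
#'
#' One [infer_routes()] call per row, plus a tally of species per
#' (loss, regain) route.
#'
#' @param profiles data.frame with the columns listed in [infer_routes()]
#'   (see [read_species_profiles()]).
#' @return List with `calls` (data.frame: species, loss_route,
#'   regain_route, ambiguous, rationale) and `tally` (counts per route
#'   combination).
#' @export
batch_infer <- function(profiles) {
  if (!nrow(profiles)) {
    return(list(calls = data.frame(species = character(),
                                   loss_route = character(),
                                   regain_route = character(),
                                   ambiguous = logical(),
                                   rationale = character()),
                tally = table(character())))
  }
  if (anyDuplicated(profiles$species)) {
    stop_input("duplicate species names in profile table")
  }
  calls <- lapply(seq_len(nrow(profiles)), function(i) {
    infer_routes(as.list(profiles[i, , drop = FALSE]))
  })
  df <- do.call(rbind, lapply(calls, function(cl) {
    data.frame(species = cl$species, loss_route = cl$loss_route,
               regain_route = cl$regain_route,
               ambiguous = length(cl$ambiguous_alternatives) > 0,
               rationale = cl$rationale)
  }))
  rownames(df) <- NULL
  routes <- paste0(df$loss_route,
                   ifelse(df$regain_route == "NONE", "",
                          paste0("+", df$regain_route)))
  list(calls = df, tally = table(routes))
}

#' Read a species-profile table
#'
#' Expected columns: `species`, `phenotype`, `wgd_events`,
#' `n_type1_active`, `n_type1_inactive`, `n_type1_lowexpr`,
#' `s_rnase_status`; extra columns are preserved. The packaged fixture
#' `fig8b_profiles.tsv` transcribes the 22-species inventory, including
#' the literature route labels where stated (`literature_route_label`; rows
#' whose inventory was not printed are marked `status = "inferred"`, and
#' tentative degeneration calls `provisional = TRUE`).
#'
#' @param path TSV path; defaults to the packaged fixture.
#' @return data.frame.
#' @export
read_species_profiles <- function(path = system.file("extdata",
                                                     "fig8b_profiles.tsv",
                                                     package = "slocusevo")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("species", "phenotype", "wgd_events", "n_type1_active",
            "n_type1_inactive", "n_type1_lowexpr", "s_rnase_status")
  if (length(setdiff(need, names(tab)))) {
    stop_input("profile table must have columns: ",
               paste(need, collapse = ", "))
  }
  tab
}
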