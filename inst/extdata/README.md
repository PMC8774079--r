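# Packaged data files

- `transgene_specs.tsv` — per-transgene detoxification specificity calls
  (which of the two Petunia hybrida S-RNases, S3 and S3L, each introduced
  SLF/SFB/SFBB transgene inactivates), aggregating to 22 detoxified pairs
  out of 26 tested.
- `progeny_counts.tsv` — self-progeny S-genotype counts for transgenic
  PhS3S3L lines. Rows with `source = reported` transcribe published
  counts; rows with `source = synthetic` are Mendelian-consistent
  stand-ins for lines whose counts appear only in supplementary tables
  not distributed here, matching the published per-line specificity
  conclusion.
- `fig8b_profiles.tsv` — per-species SI phenotype, WGD count and type-1
  S-/S-like locus inventory for 22 eudicot species, with the literature
  route label where one was stated (`literature_route_label`). Rows flagged
  `status = inferred` fill in exemplar species whose inventories were not
  printed; `provisional = TRUE` marks tentative degeneration calls.
- `synthetic_family_tree.nwk`, `synthetic_family_traits.tsv` — a
  synthetic stand-in family-level dated tree (branch lengths in Myr) and
  8-state SI trait coding used for demonstration and determinism tests;
  the topology and dates are plausible but not a published tree.
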