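# Shared fixtures, all built in code at test time.

# Six-term diamond ontology:
#   root -> A -> C -> E
#   root -> B -> C        (C has two parents)
#   root -> B -> D
toy_ontology <- function() {
  make_ontology(
    terms = c("HP:0000001", "HP:0000002", "HP:0000003", "HP:0000004",
              "HP:0000005", "HP:0000006"),
    parents = list(
      "HP:0000001" = character(0),
      "HP:0000002" = "HP:0000001",
      "HP:0000003" = "HP:0000001",
      "HP:0000004" = c("HP:0000002", "HP:0000003"),
      "HP:0000005" = "HP:0000003",
      "HP:0000006" = "HP:0000004"))
}

# Hand-assigned ICs (root 0; deeper = more informative).
toy_ic <- function() {
  c("HP:0000001" = 0, "HP:0000002" = 1, "HP:0000003" = 1.2,
    "HP:0000004" = 2.5, "HP:0000005" = 2, "HP:0000006" = 3.4)
}

toy_resources <- function() {
  phenotype_resources(
    toy_ontology(),
    gene_to_diseases = data.frame(
      gene = c("GENE1", "GENE1", "GENE2"),
      disease = c("D1", "D2", "D3")),
    disease_to_terms = data.frame(
      disease = c("D1", "D1", "D2", "D3", "D3"),
      term = c("HP:0000004", "HP:0000005", "HP:0000006",
               "HP:0000002", "HP:0000003")),
    term_ic = toy_ic())
}

# Write a VCF file from header sample names and body lines.
write_test_vcf <- function(samples, body_lines,
                           extra_header = character(0)) {
  path <- tempfile(fileext = ".vcf")
  header <- c("##fileformat=VCFv4.2",
              extra_header,
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(header, body_lines), path)
  path
}

trio_pedigree <- c(P1 = "proband", M1 = "mother", F1 = "father")

# Minimal joined variant table for filter/feature tests.
make_variant_table <- function(n = 1, ...) {
  base <- data.frame(
    chrom = rep("1", n), pos = seq_len(n) * 100L,
    ref = rep("A", n), alt = rep("T", n),
    gene = rep("GENE1", n), func = rep("nonsynonymous SNV", n),
    exon_dist = rep(0L, n), splice_z = rep(NA_real_, n),
    af_eas = rep(NA_real_, n), af_eur = rep(NA_real_, n),
    af_afr = rep(NA_real_, n),
    score_sift = rep(NA_real_, n), score_polyphen2 = rep(NA_real_, n),
    score_mutationtaster = rep(NA_real_, n),
    score_primateai = rep(NA_real_, n), score_dann = rep(NA_real_, n),
    score_cadd = rep(NA_real_, n),
    gerp = rep(NA_real_, n), clinvar = rep("absent", n),
    gt_proband = rep("0/1", n),
    stringsAsFactors = FALSE)
  override <- list(...)
  for (nm in names(override)) base[[nm]] <- override[[nm]]
  base$key <- variant_key(base$chrom, base$pos, base$ref, base$alt)
  base
}

# Small cohort shared across ranker/cli tests (built once per run).
.fixtures <- new.env()
small_cohort_bundle <- function() {
  if (is.null(.fixtures$small)) {
    spec <- cohort_spec(n_cases = 6, n_genes = 40, variants_per_case = 80,
                        seed = 7)
    cohort <- generate_cohort(spec)
    .fixtures$small <- list(
      spec = spec, cohort = cohort,
      ranks = generate_external_ranks(cohort, seed = 7),
      kb_df = generate_fixture_kb(cohort, seed = 7))
  }
  .fixtures$small
}
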