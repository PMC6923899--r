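# Writing a synthetic cohort to disk in the interchange formats every other
# module consumes (VCF + annotation TSV + HPO list per case, resource TSVs,
# OBO subset, external ranks, truth, knowledge base) and reading it back.

.write_case_vcf <- function(case, path) {
  v <- case$variants
  roles <- unname(case$pedigree)
  samples <- names(case$pedigree)
  header <- c("##fileformat=VCFv4.2",
              "##reference=hg38",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  gt_cols <- lapply(roles, function(r) {
    g <- v[[paste0("gt_", r)]]
    ifelse(is.na(g), "./.", g)
  })
  body <- do.call(paste, c(list(v$chrom, v$pos, ".", v$ref, v$alt, ".",
                                "PASS", ".", "GT"), gt_cols, sep = "\t"))
  writeLines(c(header, body), path)
  invisible(path)
}

.write_obo <- function(ontology, path) {
  out <- c("format-version: 1.2", "")
  for (t in ontology$terms) {
    out <- c(out, "[Term]", paste0("id: ", t), paste0("name: term ", t),
             paste0("is_a: ", ontology$parents[[t]]), "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Write a cohort bundle to a directory
#'
#' Emits, under `dir`: `resources/` (OBO ontology subset, gene-disease and
#' disease-term TSVs, interactome edges, OMIM list, panels), one
#' `<case>.vcf`, `<case>.annotations.tsv` and `<case>.hpo.txt` per case
#' under `cases/`, plus `external_ranks.tsv`, `truth.tsv` and `kb.tsv`.
#' All files are plain text and byte-deterministic given the cohort.
#'
#' @param cohort A [generate_cohort()] bundle.
#' @param dir Output directory (created if needed).
#' @param external_ranks,kb Optional tables to include.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, external_ranks = NULL, kb = NULL) {
  rdir <- file.path(dir, "resources")
  cdir <- file.path(dir, "cases")
  for (d in c(dir, rdir, cdir)) dir.create(d, showWarnings = FALSE,
                                           recursive = TRUE)
  res <- cohort$resources
  .write_obo(res$resources$ontology, file.path(rdir, "ontology.obo"))
  write.table(res$gene_to_diseases, file.path(rdir, "gene_to_diseases.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(res$disease_to_terms, file.path(rdir, "disease_to_terms.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(res$graph, file.path(rdir, "ppi.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  writeLines(res$omim, file.path(rdir, "omim_genes.txt"))
  for (p in names(res$panels))
    writeLines(res$panels[[p]], file.path(rdir, paste0(p, ".txt")))

  for (case in cohort$cases) {
    base <- file.path(cdir, case$case_id)
    .write_case_vcf(case, paste0(base, ".vcf"))
    ann_cols <- c("chrom", "pos", "ref", "alt", "gene", "func", "exon_dist",
                  "splice_z", af_columns(case$variants),
                  paste0("score_", PREDICTOR_TOOLS), "gerp", "clinvar")
    write.table(case$variants[, ann_cols], paste0(base, ".annotations.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    writeLines(case$hpo_terms, paste0(base, ".hpo.txt"))
    meta <- data.frame(case_id = case$case_id, sex = case$proband_sex,
                       trio = case$is_trio)
    write.table(meta, paste0(base, ".meta.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  }
  write.table(cohort$truth, file.path(dir, "truth.tsv"), sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (!is.null(external_ranks))
    write.table(external_ranks, file.path(dir, "external_ranks.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(kb))
    write.table(kb, file.path(dir, "kb.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Read gene-list files (one symbol per line, `#` comments)
#' @param path File path.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Read a cohort directory written by [write_cohort()]
#'
#' Cases are rebuilt from their VCF + annotation + HPO files through
#' [read_vcf()] and [join_annotations()], so reading a cohort exercises the
#' same path as user-supplied data.
#'
#' @param dir Cohort directory.
#' @return A cohort bundle (`resources`, `cases`, `truth`, and
#'   `external_ranks` / `kb` when present).
#' @export
read_cohort <- function(dir) {
  rdir <- file.path(dir, "resources")
  ontology <- read_obo(file.path(rdir, "ontology.obo"))
  g2d <- read.delim(file.path(rdir, "gene_to_diseases.tsv"),
                    stringsAsFactors = FALSE)
  d2t <- read.delim(file.path(rdir, "disease_to_terms.tsv"),
                    stringsAsFactors = FALSE)
  resources <- phenotype_resources(ontology, g2d, d2t)
  graph <- read.delim(file.path(rdir, "ppi.tsv"), stringsAsFactors = FALSE)
  omim <- read_gene_list(file.path(rdir, "omim_genes.txt"))
  panel_files <- list.files(rdir, pattern = "^panel.*\\.txt$",
                            full.names = TRUE)
  panels <- lapply(stats::setNames(panel_files,
                                   sub("\\.txt$", "", basename(panel_files))),
                   read_gene_list)

  vcfs <- list.files(file.path(dir, "cases"), pattern = "\\.vcf$",
                     full.names = TRUE)
  cases <- lapply(vcfs, function(vp) {
    base <- sub("\\.vcf$", "", vp)
    meta <- read.delim(paste0(base, ".meta.tsv"), stringsAsFactors = FALSE)
    pedigree <- if (meta$trio)
      c(PROBAND = "proband", MOTHER = "mother", FATHER = "father")
    else c(PROBAND = "proband")
    v <- read_vcf(vp, pedigree)
    v <- join_annotations(v, paste0(base, ".annotations.tsv"))
    list(case_id = meta$case_id, variants = v,
         hpo_terms = readLines(paste0(base, ".hpo.txt"), warn = FALSE),
         pedigree = pedigree, proband_sex = meta$sex, is_trio = meta$trio)
  })
  out <- list(resources = list(resources = resources, graph = graph,
                               omim = omim, panels = panels,
                               genes = sort(unique(g2d$gene)),
                               gene_to_diseases = g2d,
                               disease_to_terms = d2t),
              cases = cases,
              truth = read.delim(file.path(dir, "truth.tsv"),
                                 stringsAsFactors = FALSE,
                                 colClasses = c(chrom = "character",
                                                ref = "character",
                                                alt = "character")))
  er <- file.path(dir, "external_ranks.tsv")
  if (file.exists(er)) out$external_ranks <- read.delim(er,
                                                        stringsAsFactors = FALSE)
  kbf <- file.path(dir, "kb.tsv")
  if (file.exists(kbf)) out$kb <- load_relations(kbf)
  out
}
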