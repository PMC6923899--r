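# Baseline filtration and the nine configurable filter predicates, plus
# zygosity calling and trio inheritance-mode inference. Every predicate is a
# pure function of the joined variant table; apply_filters() is their
# conjunction with per-filter removal counts.

#' Filter configuration
#'
#' All knobs of the configurable filtration stage. `NULL` disables a filter.
#' Defaults: splice-region distance 10 intronic bases, splice |z-score|
#' threshold 1.8, all other filters off.
#'
#' @param chromosomes Optional chromosome label set.
#' @param variant_types Optional subset of the variant-type vocabulary
#'   (plus `"unknown"`).
#' @param zygosity Optional subset of
#'   `c("heterozygous", "compound_heterozygous", "homozygous")`.
#' @param inheritance Optional subset of the inheritance-mode vocabulary.
#' @param predictor_threshold Optional score threshold in `[0,1]`; variants
#'   are kept when the maximum selected predictor score is strictly higher.
#' @param predictor_tools Predictor subset used by the threshold filter.
#' @param maf_max Optional allele-frequency ceiling in `[0,1]` (inclusive).
#' @param populations Population subset used by the MAF filter (`NULL` = all
#'   `af_*` columns present).
#' @param require_dmvar Keep only variants with knowledge-base evidence.
#' @param clinvar_classes Optional subset of
#'   `c("pathogenic", "unknown", "benign")`; variants with no ClinVar record
#'   fail any non-`NULL` set.
#' @param require_omim Keep only genes on the OMIM list.
#' @param panel Optional gene-panel symbol set.
#' @param splice_distance Max intronic distance from the exon/intron boundary
#'   for splice-region variants (default 10).
#' @param splice_z_min Splice |z-score| that must be strictly exceeded
#'   (default 1.8).
#' @return A `filter_config` list.
#' @export
filter_config <- function(chromosomes = NULL, variant_types = NULL,
                          zygosity = NULL, inheritance = NULL,
                          predictor_threshold = NULL,
                          predictor_tools = PREDICTOR_TOOLS,
                          maf_max = NULL, populations = NULL,
                          require_dmvar = FALSE, clinvar_classes = NULL,
                          require_omim = FALSE, panel = NULL,
                          splice_distance = 10L, splice_z_min = 1.8) {
  stopifnot(splice_distance >= 1, splice_z_min > 0)
  if (!is.null(predictor_threshold))
    stopifnot(predictor_threshold >= 0, predictor_threshold <= 1)
  if (!is.null(maf_max)) stopifnot(maf_max >= 0, maf_max <= 1)
  if (!is.null(clinvar_classes))
    stopifnot(all(clinvar_classes %in% c("pathogenic", "unknown", "benign")))
  if (!is.null(inheritance))
    stopifnot(all(inheritance %in% INHERITANCE_MODES))
  structure(list(chromosomes = chromosomes, variant_types = variant_types,
                 zygosity = zygosity, inheritance = inheritance,
                 predictor_threshold = predictor_threshold,
                 predictor_tools = predictor_tools,
                 maf_max = maf_max, populations = populations,
                 require_dmvar = require_dmvar,
                 clinvar_classes = clinvar_classes,
                 require_omim = require_omim, panel = panel,
                 splice_distance = as.integer(splice_distance),
                 splice_z_min = splice_z_min),
            class = "filter_config")
}

#' Default functional-class to variant-type mapping
#'
#' The 11-type vocabulary follows the exonic-function convention of the
#' upstream annotator; classes outside the mapping become `"unknown"`. The
#' mapping ships as an editable TSV (`extdata/variant_types.tsv`).
#'
#' @return `data.frame` with columns `func` and `type`.
#' @export
default_variant_type_map <- function() {
  read.delim(system.file("extdata", "variant_types.tsv", package = "rankvar"),
             stringsAsFactors = FALSE)
}

#' Classify functional classes into the variant-type vocabulary
#'
#' @param func Character vector of functional classes.
#' @param type_map Mapping `data.frame` (`func`, `type`).
#' @return Character vector of type labels (`"unknown"` outside the map).
#' @export
classify_variant_type <- function(func, type_map = default_variant_type_map()) {
  out <- type_map$type[match(func, type_map$func)]
  out[is.na(out) | is.na(func)] <- "unknown"
  out
}

.alt_count <- function(gt) {
  ifelse(is.na(gt), NA_integer_,
         vapply(strsplit(gt, "[/|]"), function(a) sum(a == "1"), integer(1)))
}
.n_alleles <- function(gt) {
  ifelse(is.na(gt), NA_integer_,
         vapply(strsplit(gt, "[/|]"), length, integer(1)))
}

#' Pseudo-autosomal regions of the X chromosome
#' @param build `"hg38"` (default) or `"hg19"`.
#' @return `data.frame` with `start`, `end` (1-based inclusive, chromosome X).
#' @export
par_regions <- function(build = "hg38") {
  switch(build,
         hg38 = data.frame(start = c(10001, 155701383),
                           end = c(2781479, 156030895)),
         hg19 = data.frame(start = c(60001, 154931044),
                           end = c(2699520, 155260560)),
         stop("unknown build '", build, "'"))
}

.in_par <- function(pos, par) {
  out <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(par))) out <- out | (pos >= par$start[i] & pos <= par$end[i])
  out
}

#' Call per-variant zygosity and gene-level compound heterozygosity
#'
#' Proband genotypes 0/1 are heterozygous and 1/1 homozygous; on the male
#' non-pseudo-autosomal X (or Y) any alt-carrying call is hemizygous.
#' `gene_compound_het` flags every heterozygous variant in a gene carrying at
#' least two proband-heterozygous variants.
#'
#' @param variants Joined variant table with `gt_proband`.
#' @param proband_sex `"male"` or `"female"`.
#' @param par Pseudo-autosomal coordinate table, as [par_regions()].
#' @return The table with `zygosity` and `gene_compound_het` columns.
#' @export
call_zygosity <- function(variants, proband_sex,
                          par = par_regions("hg38")) {
  stopifnot(proband_sex %in% c("male", "female"))
  ac <- .alt_count(variants$gt_proband)
  nal <- .n_alleles(variants$gt_proband)
  hemi_zone <- proband_sex == "male" &
    ((variants$chrom == "X" & !.in_par(variants$pos, par)) |
       variants$chrom == "Y")
  z <- rep("missing", nrow(variants))
  has_gt <- !is.na(ac)
  z[has_gt & ac == 0] <- "reference"
  z[has_gt & ac >= 1 & hemi_zone] <- "hemizygous"
  z[has_gt & !hemi_zone & ac == 1] <- "heterozygous"
  z[has_gt & !hemi_zone & nal > 1 & ac == nal] <- "homozygous"
  z[has_gt & !hemi_zone & nal == 1 & ac == 1] <- "hemizygous"
  variants$zygosity <- z
  het_per_gene <- table(variants$gene[z == "heterozygous"])
  variants$gene_compound_het <- z == "heterozygous" &
    !is.na(variants$gene) &
    variants$gene %in% names(het_per_gene)[het_per_gene >= 2]
  variants
}

#' Infer trio inheritance modes per variant
#'
#' For trio tables (with `gt_mother` and `gt_father`) each variant receives a
#' subset of `c("de_novo", "autosomal_dominant", "autosomal_recessive",
#' "compound_het_in_trans", "x_linked")`. Singleton cases get the empty set
#' for every variant.
#'
#' @param variants Joined variant table (zygosity already called for
#'   X-linked logic; [call_zygosity()] is invoked if absent).
#' @param proband_sex `"male"` or `"female"`.
#' @param par Pseudo-autosomal coordinate table.
#' @return The table with a `modes` list-column and a `inheritance` string
#'   column (modes joined by `";"`).
#' @export
infer_inheritance <- function(variants, proband_sex,
                              par = par_regions("hg38")) {
  n <- nrow(variants)
  if (!"zygosity" %in% names(variants))
    variants <- call_zygosity(variants, proband_sex, par)
  modes <- vector("list", n)
  is_trio <- all(c("gt_mother", "gt_father") %in% names(variants))
  if (!is_trio) {
    variants$modes <- replicate(n, character(0), simplify = FALSE)
    variants$inheritance <- ""
    return(variants)
  }
  p <- .alt_count(variants$gt_proband)
  m <- .alt_count(variants$gt_mother)
  f <- .alt_count(variants$gt_father)
  on_x <- variants$chrom == "X" & !.in_par(variants$pos, par)

  maternal <- !is.na(p) & p >= 1 & !is.na(m) & m >= 1 & !is.na(f) & f == 0
  paternal <- !is.na(p) & p >= 1 & !is.na(f) & f >= 1 & !is.na(m) & m == 0
  het <- !is.na(p) & p == 1
  comp_genes <- unique(stats::na.omit(variants$gene[het]))
  comp_genes <- comp_genes[vapply(comp_genes, function(g) {
    in_g <- !is.na(variants$gene) & variants$gene == g & het
    sum(in_g) >= 2 && any(in_g & maternal) && any(in_g & paternal)
  }, logical(1))]

  for (i in seq_len(n)) {
    mo <- character(0)
    if (!is.na(p[i]) && !is.na(m[i]) && !is.na(f[i])) {
      if (p[i] >= 1 && m[i] == 0 && f[i] == 0) mo <- c(mo, "de_novo")
      if (p[i] == 1 && ((m[i] == 1 && f[i] == 0) || (m[i] == 0 && f[i] == 1)))
        mo <- c(mo, "autosomal_dominant")
      if (p[i] == 2 && m[i] == 1 && f[i] == 1)
        mo <- c(mo, "autosomal_recessive")
      if (on_x[i]) {
        if (proband_sex == "male" && p[i] >= 1 && m[i] >= 1)
          mo <- c(mo, "x_linked")
        if (proband_sex == "female" && p[i] == 2)
          mo <- c(mo, "x_linked")
      }
    }
    if (het[i] && !is.na(variants$gene[i]) &&
        variants$gene[i] %in% comp_genes && (maternal[i] || paternal[i]))
      mo <- c(mo, "compound_het_in_trans")
    modes[[i]] <- intersect(INHERITANCE_MODES, mo)
  }
  variants$modes <- modes
  variants$inheritance <- vapply(modes, paste, character(1), collapse = ";")
  variants
}

#' Splice-region keep predicate
#'
#' A splicing variant is kept iff it lies within `splice_distance` bases of
#' the exon/intron boundary and its |z-score| strictly exceeds
#' `splice_z_min`; a missing z-score is never kept.
#'
#' @param exon_dist Integer distances from the boundary (0 = exonic).
#' @param splice_z Splice z-scores (may be `NA`).
#' @param config A [filter_config()].
#' @return Logical keep vector.
#' @export
splice_region_filter <- function(exon_dist, splice_z, config = filter_config()) {
  !is.na(exon_dist) & exon_dist <= config$splice_distance &
    !is.na(splice_z) & abs(splice_z) > config$splice_z_min
}

#' Baseline filtration
#'
#' Retains coding non-synonymous and splice-region variants; synonymous,
#' non-coding and deep-intronic records are removed, and splice-region
#' records must additionally pass [splice_region_filter()].
#'
#' @param variants Joined variant table.
#' @param config A [filter_config()] (splice defaults).
#' @param type_map Variant-type mapping table.
#' @return The retained subset of `variants` with a `variant_type` column.
#' @export
baseline_filtration <- function(variants, config = filter_config(),
                                type_map = default_variant_type_map()) {
  variants$variant_type <- classify_variant_type(variants$func, type_map)
  keep <- variants$variant_type %in% CODING_TYPES |
    (variants$variant_type == "splicing" &
       splice_region_filter(variants$exon_dist, variants$splice_z, config))
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predictor-score keep predicate
#'
#' Keeps a variant iff the maximum present score among the selected tools is
#' strictly higher than the threshold; when every selected score is missing
#' the variant is kept (absent evidence never removes).
#'
#' @param variants Joined variant table.
#' @param config A [filter_config()] with non-`NULL` `predictor_threshold`.
#' @return Logical keep vector.
#' @export
predictor_filter <- function(variants, config) {
  cols <- paste0("score_", config$predictor_tools)
  cols <- intersect(cols, names(variants))
  mat <- as.matrix(variants[, cols, drop = FALSE])
  mx <- suppressWarnings(apply(mat, 1, max, na.rm = TRUE))
  ifelse(is.infinite(mx), TRUE, mx > config$predictor_threshold)
}

#' Population-frequency keep predicate
#'
#' Keeps a variant iff the maximum present allele frequency over the selected
#' populations is at most `maf_max` (inclusive ceiling); all-missing
#' frequencies are kept.
#'
#' @param variants Joined variant table.
#' @param config A [filter_config()] with non-`NULL` `maf_max`.
#' @return Logical keep vector.
#' @export
maf_filter <- function(variants, config) {
  pops <- config$populations
  have <- sub("^af_", "", af_columns(variants))
  if (is.null(pops)) pops <- have
  bad <- setdiff(pops, have)
  if (length(bad))
    stop("unknown population label(s) in config: ", paste(bad, collapse = ", "))
  mat <- as.matrix(variants[, paste0("af_", pops), drop = FALSE])
  mx <- suppressWarnings(apply(mat, 1, max, na.rm = TRUE))
  ifelse(is.infinite(mx), TRUE, mx <= config$maf_max)
}

#' Membership keep predicate (literature, ClinVar, OMIM, panel)
#'
#' Conjunction of: knowledge-base membership when `require_dmvar`; ClinVar
#' class in `clinvar_classes` (records with no ClinVar entry fail any
#' non-`NULL` set); gene on the OMIM list when `require_omim`; gene in the
#' panel when one is set.
#'
#' @param variants Joined variant table.
#' @param config A [filter_config()].
#' @param kb Optional [knowledge_base] for dmVar membership.
#' @param omim_genes Optional character vector of OMIM gene symbols.
#' @return Logical keep vector.
#' @export
membership_filters <- function(variants, config, kb = NULL, omim_genes = NULL) {
  keep <- rep(TRUE, nrow(variants))
  if (isTRUE(config$require_dmvar)) {
    if (is.null(kb)) stop("require_dmvar set but no knowledge base supplied")
    keep <- keep & kb_count(kb, variants$key) > 0
  }
  if (!is.null(config$clinvar_classes)) {
    cls <- variants$clinvar
    cls[is.na(cls) | cls == "" | cls == "absent"] <- NA
    keep <- keep & !is.na(cls) & cls %in% config$clinvar_classes
  }
  if (isTRUE(config$require_omim)) {
    if (is.null(omim_genes)) stop("require_omim set but no OMIM list supplied")
    keep <- keep & !is.na(variants$gene) & variants$gene %in% omim_genes
  }
  if (!is.null(config$panel))
    keep <- keep & !is.na(variants$gene) & variants$gene %in% config$panel
  keep
}

#' Apply all enabled filters as a pure conjunction
#'
#' Each enabled predicate is evaluated on the full input (zygosity and
#' compound-het flags are computed on the supplied, i.e. post-baseline, set)
#' and a record is kept iff every enabled predicate keeps it. Removal counts
#' are reported per filter on the full input, so filtering is
#' order-independent and idempotent.
#'
#' @param variants Joined variant table (typically post
#'   [baseline_filtration()]).
#' @param config A [filter_config()].
#' @param proband_sex `"male"` or `"female"` (needed by zygosity and
#'   inheritance filters).
#' @param kb,omim_genes Resources for the membership filters.
#' @param type_map Variant-type mapping table.
#' @return `list(variants = kept table, removed = named integer counts)`.
#' @export
apply_filters <- function(variants, config, proband_sex = "female",
                          kb = NULL, omim_genes = NULL,
                          type_map = default_variant_type_map()) {
  n <- nrow(variants)
  masks <- list()
  if (!is.null(config$chromosomes))
    masks$chromosome <- variants$chrom %in% normalize_chrom(config$chromosomes)
  if (!is.null(config$variant_types))
    masks$variant_type <-
      classify_variant_type(variants$func, type_map) %in% config$variant_types
  if (!is.null(config$zygosity) || !is.null(config$inheritance)) {
    variants <- call_zygosity(variants, proband_sex)
    if (!is.null(config$zygosity)) {
      z <- variants$zygosity
      masks$zygosity <- z %in% config$zygosity |
        (variants$gene_compound_het &
           "compound_heterozygous" %in% config$zygosity)
    }
    if (!is.null(config$inheritance)) {
      variants <- infer_inheritance(variants, proband_sex)
      masks$inheritance <- vapply(variants$modes, function(mo)
        length(intersect(mo, config$inheritance)) > 0, logical(1))
    }
  }
  if (!is.null(config$predictor_threshold))
    masks$predictor <- predictor_filter(variants, config)
  if (!is.null(config$maf_max))
    masks$maf <- maf_filter(variants, config)
  if (isTRUE(config$require_dmvar) || !is.null(config$clinvar_classes) ||
      isTRUE(config$require_omim) || !is.null(config$panel))
    masks$membership <- membership_filters(variants, config, kb, omim_genes)

  keep <- rep(TRUE, n)
  removed <- integer(0)
  for (nm in names(masks)) {
    keep <- keep & masks[[nm]]
    removed[nm] <- sum(!masks[[nm]])
  }
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(variants = out, removed = removed, n_input = n, n_kept = sum(keep))
}
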