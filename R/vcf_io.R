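# Reading VCFs into the joined per-alternate-allele variant table, annotation
# joining, and CSV export of ranked results.

CHROM_LEVELS <- c(as.character(1:22), "X", "Y", "M")

#' Normalize chromosome labels
#'
#' Strips a leading `"chr"` prefix and maps `"MT"` to `"M"` so that labels
#' from different reference naming schemes compare equal.
#'
#' @param x Character vector of chromosome labels.
#' @return Character vector of normalized labels.
#' @export
normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  x[toupper(x) == "MT"] <- "M"
  x
}

#' Build a variant key string
#'
#' The canonical `chrom:pos:ref:alt` identifier used to join annotations,
#' knowledge-base relations and truth tables.
#'
#' @param chrom,pos,ref,alt Vectors of the four key fields.
#' @return Character vector of keys.
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(normalize_chrom(chrom), as.integer(pos), toupper(ref), toupper(alt),
        sep = ":")
}

.chrom_order <- function(chrom) match(normalize_chrom(chrom), CHROM_LEVELS)

# Recode one GT string against alternate allele index j: alleles equal to j
# become 1, all others (reference or other alternates) 0; "." stays missing.
.recode_gt <- function(gt, j) {
  if (is.na(gt) || gt %in% c(".", "./.", ".|.")) return(NA_character_)
  sep <- if (grepl("|", gt, fixed = TRUE)) "|" else "/"
  alleles <- strsplit(gt, "[/|]")[[1]]
  if (any(alleles == ".")) return(NA_character_)
  paste(ifelse(alleles == as.character(j), "1", "0"), collapse = sep)
}

.validate_vcf_text <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!any(startsWith(lines, "#CHROM")))
    stop("malformed VCF header in '", path, "': no #CHROM line")
  body <- which(!startsWith(lines, "#"))
  for (i in body) {
    nf <- length(strsplit(lines[i], "\t", fixed = TRUE)[[1]])
    if (nf < 8L)
      stop("malformed VCF body at line ", i, " of '", path,
           "': expected >= 8 tab-separated fields, found ", nf)
  }
  invisible(lines[startsWith(lines, "##")])
}

#' Read a VCF into a per-alternate-allele variant table
#'
#' Each multi-allelic row is split into one record per alternate allele, with
#' every sample genotype recoded against that allele (matching allele indices
#' become 1, all others 0; missing genotypes stay missing). Records are
#' ordered by (chrom, pos, ref, alt).
#'
#' @param path Path to a VCF 4.x file (plain text).
#' @param pedigree Optional named character vector mapping sample IDs to roles
#'   (`"proband"`, `"mother"`, `"father"`). When `NULL` and the file has a
#'   single sample, that sample is bound as the proband.
#' @return A `data.frame` with columns `chrom`, `pos`, `ref`, `alt`, `key`,
#'   `site`, `n_alts` and one `gt_<role>` column per pedigree role. The
#'   number of VCF body rows is kept in attribute `n_body_rows`.
#' @export
read_vcf <- function(path, pedigree = NULL) {
  .validate_vcf_text(path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix)))                     # single-row VCF drops to vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  n_row <- nrow(fix)
  samples <- colnames(vcf@gt)[-1]
  if (is.null(pedigree)) {
    if (length(samples) == 1L) pedigree <- stats::setNames("proband", samples)
    else stop("pedigree required for multi-sample VCF '", path, "'")
  }
  missing_samples <- setdiff(names(pedigree), samples)
  if (length(missing_samples))
    stop("pedigree binding error: sample(s) ", paste(missing_samples, collapse = ", "),
         " absent from '", path, "'")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = n_row,
                                     dimnames = list(NULL, samples))

  out <- vector("list", n_row)
  for (i in seq_len(n_row)) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    rows <- lapply(seq_along(alts), function(j) {
      rec <- data.frame(chrom = normalize_chrom(fix$CHROM[i]),
                        pos = as.integer(fix$POS[i]),
                        ref = toupper(fix$REF[i]),
                        alt = toupper(alts[j]),
                        site = i, n_alts = length(alts),
                        stringsAsFactors = FALSE)
      for (s in names(pedigree))
        rec[[paste0("gt_", pedigree[[s]])]] <- .recode_gt(gt[i, s], j)
      rec
    })
    out[[i]] <- do.call(rbind, rows)
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), site = integer(), n_alts = integer(),
                      stringsAsFactors = FALSE)
    for (r in unique(pedigree)) res[[paste0("gt_", r)]] <- character()
  }
  res$key <- variant_key(res$chrom, res$pos, res$ref, res$alt)
  res <- res[order(.chrom_order(res$chrom), res$pos, res$ref, res$alt), ,
             drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_body_rows") <- n_row
  attr(res, "pedigree") <- pedigree
  res
}

#' Merge three single-sample VCFs into one trio variant table
#'
#' Per-sample VCFs are merged by variant key; genotypes for sites absent from
#' a member's file are recorded as missing. Reference-block (GVCF) semantics
#' are not implemented: joint genotyping belongs upstream.
#'
#' @param proband,mother,father Paths to the three single-sample VCFs.
#' @return A trio variant table as from [read_vcf()].
#' @export
merge_trio_vcfs <- function(proband, mother, father) {
  paths <- c(proband = proband, mother = mother, father = father)
  tabs <- lapply(names(paths), function(role) {
    v <- read_vcf(paths[[role]])
    names(v)[names(v) == "gt_proband"] <- paste0("gt_", role)
    v
  })
  keys <- unique(unlist(lapply(tabs, `[[`, "key")))
  base <- tabs[[1]][match(keys, tabs[[1]]$key),
                    c("chrom", "pos", "ref", "alt", "key")]
  for (i in 2:3) {
    miss <- is.na(base$chrom)
    idx <- match(keys[miss], tabs[[i]]$key)
    base[miss, c("chrom", "pos", "ref", "alt", "key")] <-
      tabs[[i]][idx, c("chrom", "pos", "ref", "alt", "key")]
  }
  for (i in 1:3) {
    role <- names(paths)[i]
    base[[paste0("gt_", role)]] <-
      tabs[[i]][[paste0("gt_", role)]][match(keys, tabs[[i]]$key)]
  }
  base$site <- seq_len(nrow(base))
  base$n_alts <- 1L
  base <- base[order(.chrom_order(base$chrom), base$pos, base$ref, base$alt), ]
  rownames(base) <- NULL
  attr(base, "pedigree") <- c(p = "proband", m = "mother", f = "father")
  base
}

# GRCh37/38 chromosome-1..3 lengths, used as a contig-line signature.
.BUILD_CONTIG_LENGTHS <- list(
  hg19 = c(`1` = 249250621, `2` = 243199373, `3` = 198022430),
  hg38 = c(`1` = 248956422, `2` = 242193529, `3` = 198295559)
)

#' Detect the reference build from VCF header text
#'
#' Inspects `##reference` lines for an hg19/GRCh37 or hg38/GRCh38 token, then
#' falls back to matching contig lengths for chromosomes 1-3. Returns
#' `"unknown"` when neither signature matches, in which case the caller must
#' supply the build.
#'
#' @param header_text Character vector of header lines (or one string).
#' @return `"hg19"`, `"hg38"` or `"unknown"`.
#' @export
detect_reference_build <- function(header_text) {
  lines <- unlist(strsplit(header_text, "\n", fixed = TRUE))
  ref <- grep("^##reference=", lines, value = TRUE)
  if (length(ref)) {
    if (any(grepl("hg19|GRCh37", ref, ignore.case = TRUE))) return("hg19")
    if (any(grepl("hg38|GRCh38", ref, ignore.case = TRUE))) return("hg38")
  }
  contig <- grep("^##contig=", lines, value = TRUE)
  ids <- normalize_chrom(sub(".*<ID=([^,>]+).*", "\\1", contig))
  lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", contig)))
  for (build in names(.BUILD_CONTIG_LENGTHS)) {
    sig <- .BUILD_CONTIG_LENGTHS[[build]]
    hit <- !is.na(lens) & ids %in% names(sig) & lens == sig[ids]
    if (any(hit)) return(build)
  }
  "unknown"
}

ANNOTATION_COLS <- c("gene", "func", "exon_dist", "splice_z",
                     "score_sift", "score_polyphen2", "score_mutationtaster",
                     "score_primateai", "score_dann", "score_cadd",
                     "gerp", "clinvar")

#' Join a variant table with its annotation TSV
#'
#' The annotation table stands in for upstream annotator output and is keyed
#' by `chrom`, `pos`, `ref`, `alt`. Variants with no matching annotation row
#' carry all-missing annotation fields and `annotated = FALSE`.
#'
#' @param variants Variant table from [read_vcf()].
#' @param table Path to the annotation TSV (or a `data.frame`). Expected
#'   columns: `chrom,pos,ref,alt,gene,func,exon_dist,splice_z,af_<POP>...,`
#'   `score_sift,score_polyphen2,score_mutationtaster,score_primateai,`
#'   `score_dann,score_cadd,gerp,clinvar`.
#' @return The variant table with annotation columns and an `annotated` flag.
#' @export
join_annotations <- function(variants, table) {
  ann <- if (is.character(table)) {
    read.delim(table, stringsAsFactors = FALSE,
               colClasses = c(chrom = "character", ref = "character",
                              alt = "character"))
  } else table
  ann$key <- variant_key(ann$chrom, ann$pos, ann$ref, ann$alt)
  dup <- unique(ann$key[duplicated(ann$key)])
  if (length(dup))
    stop("duplicate annotation keys: ", paste(dup, collapse = ", "))
  idx <- match(variants$key, ann$key)
  copy_cols <- setdiff(names(ann), c("chrom", "pos", "ref", "alt", "key"))
  for (col in copy_cols) variants[[col]] <- ann[[col]][idx]
  variants$annotated <- !is.na(idx)
  variants
}

#' Population allele-frequency column names in a variant table
#' @param variants Joined variant table.
#' @return Character vector of `af_*` column names.
#' @export
af_columns <- function(variants) grep("^af_", names(variants), value = TRUE)

#' Write a ranked result as CSV
#'
#' One row per mutation, grouped by gene in rank order (higher-scoring
#' mutation first within a gene). Scores round-trip at six decimal places.
#'
#' @param result A `ranked_result` from [score_case()] (or compatible
#'   `data.frame` with `gene_rank`, `gene`, `gene_score`, `key`, `score`).
#' @param path Output file path.
#' @export
write_results_csv <- function(result, path) {
  cols <- c(rank = "gene_rank", gene = "gene", gtx_score = "gene_score",
            variant = "key", zygosity = "zygosity", func = "func",
            max_maf = "max_maf",
            score_sift = "score_sift", score_polyphen2 = "score_polyphen2",
            score_mutationtaster = "score_mutationtaster",
            score_primateai = "score_primateai", score_dann = "score_dann",
            score_cadd = "score_cadd", clinvar = "clinvar",
            evidence_count = "evidence_count", mutation_score = "score")
  out <- data.frame(row.names = seq_len(nrow(result)))
  for (nm in names(cols)) {
    src <- cols[[nm]]
    out[[nm]] <- if (src %in% names(result)) result[[src]]
                 else rep(NA, nrow(result))
  }
  write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}
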