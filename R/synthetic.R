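# Self-contained synthetic cohorts: a random DAG ontology, gene-disease-term
# maps, a scale-free interactome, annotated variant tables with one planted
# causal SNV per case, noisy patient phenotypes, reference-ranker rank files
# and a fixture knowledge base. Everything is deterministic under the seed.

#' Synthetic cohort specification
#'
#' Defaults define the study conditions used throughout the test suite:
#' 50 cases over 300 genes with ~1200 variants per case (the order of
#' magnitude of genes per exome the evaluation corpus reports), causal
#' feature shift 1.5 background standard deviations, 20% phenotype noise.
#'
#' @param n_cases Number of cases.
#' @param n_genes Number of genes in the synthetic genome.
#' @param variants_per_case Poisson mean of variants per case.
#' @param causal_effect Causal feature shift in background-SD units (>= 0).
#' @param phenotype_noise Fraction of patient terms replaced by random
#'   ontology terms, in `[0, 1]`.
#' @param trio_fraction Fraction of cases simulated as trios.
#' @param seed Integer seed.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_cases = 50L, n_genes = 300L,
                        variants_per_case = 1200L, causal_effect = 1.5,
                        phenotype_noise = 0.2, trio_fraction = 0.5,
                        seed = 1L) {
  stopifnot(n_cases >= 1, n_genes >= 2, variants_per_case >= 1,
            causal_effect >= 0, phenotype_noise >= 0, phenotype_noise <= 1,
            trio_fraction >= 0, trio_fraction <= 1)
  structure(list(n_cases = as.integer(n_cases), n_genes = as.integer(n_genes),
                 variants_per_case = as.integer(variants_per_case),
                 causal_effect = causal_effect,
                 phenotype_noise = phenotype_noise,
                 trio_fraction = trio_fraction, seed = as.integer(seed)),
            class = "cohort_spec")
}

.SD_BETA25 <- sqrt(2 * 5 / ((2 + 5)^2 * (2 + 5 + 1)))  # sd of Beta(2, 5)

#' Generate the shared phenotype and network resources
#'
#' Builds a random is-a DAG of ~`n_terms` terms (chain-seeded so depth is at
#' least 4), annotates each gene with 1-3 diseases of 3-8 terms, draws a
#' scale-free interactome via preferential attachment with uniform edge
#' confidences, and samples an OMIM-style gene list plus three gene panels.
#'
#' @param spec A [cohort_spec()].
#' @param n_terms Ontology size (default 200).
#' @return List with `resources` ([phenotype_resources()]), `graph` (edge
#'   `data.frame`), `omim` (character), `panels` (named list of gene sets)
#'   and `genes`.
#' @export
generate_resources <- function(spec, n_terms = 200L) {
  set.seed(spec$seed)
  terms <- sprintf("HP:%07d", seq_len(n_terms))
  parents <- vector("list", n_terms)
  names(parents) <- terms
  parents[[1]] <- character(0)
  for (i in 2:n_terms) {
    if (i <= 5) {                      # seed chain guarantees depth >= 4
      parents[[i]] <- terms[i - 1]
    } else {
      k <- sample(1:2, 1)
      lo <- max(2, i - 40)             # attach near the frontier: deep DAG
      pool <- lo:(i - 1)
      parents[[i]] <- terms[sample(pool, min(k, length(pool)))]
    }
  }
  ontology <- make_ontology(terms, parents)

  genes <- sprintf("G%04d", seq_len(spec$n_genes))
  g2d <- list(); d2t <- list(); did <- 0
  for (g in genes) {
    nd <- sample(1:3, 1)
    for (j in seq_len(nd)) {
      did <- did + 1
      d <- sprintf("D%04d", did)
      g2d[[length(g2d) + 1]] <- data.frame(gene = g, disease = d)
      ts <- sample(terms[-1], sample(3:8, 1))
      d2t[[length(d2t) + 1]] <- data.frame(disease = d, term = ts)
    }
  }
  gene_to_diseases <- do.call(rbind, g2d)
  disease_to_terms <- do.call(rbind, d2t)
  resources <- phenotype_resources(ontology, gene_to_diseases,
                                   disease_to_terms)

  g <- igraph::sample_pa(spec$n_genes, power = 1, m = 2, directed = FALSE)
  el <- igraph::as_edgelist(g)
  graph <- data.frame(gene_a = genes[as.integer(el[, 1])],
                      gene_b = genes[as.integer(el[, 2])],
                      weight = round(stats::runif(nrow(el), 0.3, 1), 3),
                      stringsAsFactors = FALSE)
  graph <- graph[graph$gene_a != graph$gene_b, ]

  omim <- sort(sample(genes, round(0.7 * spec$n_genes)))
  panels <- lapply(stats::setNames(1:3, paste0("panel", 1:3)),
                   function(i) sort(sample(genes, min(30, spec$n_genes))))
  list(resources = resources, graph = graph, omim = omim, panels = panels,
       genes = genes,
       gene_to_diseases = gene_to_diseases,
       disease_to_terms = disease_to_terms)
}

.sample_snv_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  list(ref = ref, alt = alt)
}

.BG_FUNC <- c("nonsynonymous SNV" = 0.45, "synonymous SNV" = 0.22,
              "splicing" = 0.08, "stopgain" = 0.03,
              "frameshift insertion" = 0.02, "frameshift deletion" = 0.02,
              "nonframeshift insertion" = 0.02, "nonframeshift deletion" = 0.02,
              "ncRNA_exonic" = 0.06, "intronic" = 0.08)

#' Generate one synthetic case with a planted causal SNV
#'
#' Background variants draw predictor scores from Beta(2, 5), population
#' frequencies from a mixture with mass in 0.01-0.2 plus a rare tail,
#' conservation from N(0, 1), and ClinVar mostly absent. The causal SNV's
#' predictor scores are shifted upward by `causal_effect` background
#' standard deviations, its frequency shrunk by `exp(-2 * causal_effect)`
#' and its ClinVar class set to pathogenic with probability
#' `0.3 * min(1, causal_effect / 1.5)`; conservation is drawn from the
#' background distribution. Every shift vanishes continuously at zero
#' effect. Patient HPO terms are the causal gene's
#' disease terms with `phenotype_noise` random replacement; trio genotypes
#' follow the drawn inheritance mode.
#'
#' @param spec A [cohort_spec()].
#' @param res A [generate_resources()] bundle.
#' @param case_id Case identifier string.
#' @param causal_gene Gene symbol to plant (must have disease annotations).
#' @param seed Integer seed for this case.
#' @return List with `case` (`case_id`, `variants`, `hpo_terms`, `pedigree`,
#'   `proband_sex`, `is_trio`) and `truth` (`case_id`, `gene`, `key`,
#'   `mode`).
#' @export
generate_case <- function(spec, res, case_id, causal_gene, seed) {
  set.seed(seed)
  n_bg <- max(5L, stats::rpois(1, spec$variants_per_case))
  genes <- sample(res$genes, n_bg, replace = TRUE)

  is_trio <- stats::runif(1) < spec$trio_fraction
  mode <- if (is_trio)
    sample(c("de_novo", "autosomal_dominant", "autosomal_recessive",
             "x_linked"), 1, prob = c(0.5, 0.2, 0.2, 0.1))
  else NA_character_
  proband_sex <- if (identical(mode, "x_linked")) "male"
                 else sample(c("male", "female"), 1)

  chrom <- sample(as.character(1:22), n_bg, replace = TRUE)
  pos <- sample.int(2.4e8, n_bg)
  al <- .sample_snv_alleles(n_bg)
  func <- sample(names(.BG_FUNC), n_bg, replace = TRUE, prob = .BG_FUNC)
  exon_dist <- integer(n_bg)
  exon_dist[func == "splicing"] <- sample(1:20, sum(func == "splicing"),
                                          replace = TRUE)
  exon_dist[func == "intronic"] <- sample(100:1000, sum(func == "intronic"),
                                          replace = TRUE)
  splice_z <- rep(NA_real_, n_bg)
  splice_z[func == "splicing"] <- round(stats::rnorm(sum(func == "splicing"),
                                                     0, 2), 3)

  pred <- matrix(stats::rbeta(n_bg * 6, 2, 5), n_bg, 6,
                 dimnames = list(NULL, paste0("score_", PREDICTOR_TOOLS)))
  pred[matrix(stats::runif(n_bg * 6) < 0.1, n_bg, 6)] <- NA

  af_base <- ifelse(stats::runif(n_bg) < 0.2,
                    stats::runif(n_bg, 0, 0.001),
                    stats::runif(n_bg, 0.01, 0.2))
  afs <- sapply(1:3, function(j) pmin(1, af_base * stats::runif(n_bg, 0.5, 1.5)))
  colnames(afs) <- c("af_eas", "af_eur", "af_afr")

  gerp <- stats::rnorm(n_bg)
  gerp[stats::runif(n_bg) < 0.1] <- NA
  clinvar <- sample(c("absent", "benign", "unknown", "pathogenic"), n_bg,
                    replace = TRUE, prob = c(0.955, 0.025, 0.015, 0.005))

  # the planted causal SNV
  eff <- spec$causal_effect
  c_chrom <- if (identical(mode, "x_linked")) "X" else
    sample(as.character(1:22), 1)
  c_pos <- if (c_chrom == "X") sample(2800000:155000000, 1) else
    sample.int(2.4e8, 1)
  c_al <- .sample_snv_alleles(1)
  c_pred <- pmin(1, stats::rbeta(6, 2, 5) + eff * .SD_BETA25)
  c_af_base <- ifelse(stats::runif(1) < 0.2, stats::runif(1, 0, 0.001),
                      stats::runif(1, 0.01, 0.2)) * exp(-2 * eff)
  c_afs <- pmin(1, c_af_base * stats::runif(3, 0.5, 1.5))
  c_clinvar <- if (stats::runif(1) < 0.3 * min(1, eff / 1.5)) "pathogenic"
               else "absent"

  variants <- data.frame(
    chrom = c(chrom, c_chrom),
    pos = c(pos, c_pos),
    ref = c(al$ref, c_al$ref),
    alt = c(al$alt, c_al$alt),
    gene = c(genes, causal_gene),
    func = c(func, "nonsynonymous SNV"),
    exon_dist = c(exon_dist, 0L),
    splice_z = c(splice_z, NA_real_),
    stringsAsFactors = FALSE)
  variants <- cbind(variants,
                    rbind(afs, c_afs),
                    rbind(pred, c_pred))
  variants$gerp <- c(gerp, stats::rnorm(1))
  variants$clinvar <- c(clinvar, c_clinvar)
  n <- nrow(variants)

  # genotypes; the causal variant (last row) follows the inheritance mode
  gt_p <- sample(c("0/1", "1/1"), n, replace = TRUE, prob = c(0.85, 0.15))
  if (is_trio) {
    gt_m <- sample(c("0/0", "0/1", "1/1"), n, replace = TRUE,
                   prob = c(0.55, 0.35, 0.1))
    gt_f <- sample(c("0/0", "0/1", "1/1"), n, replace = TRUE,
                   prob = c(0.55, 0.35, 0.1))
    cz <- switch(mode,
                 de_novo = c("0/1", "0/0", "0/0"),
                 autosomal_dominant = c("0/1", "0/1", "0/0"),
                 autosomal_recessive = c("1/1", "0/1", "0/1"),
                 x_linked = c("1/1", "0/1", "0/0"))
    gt_p[n] <- cz[1]; gt_m[n] <- cz[2]; gt_f[n] <- cz[3]
    variants$gt_proband <- gt_p
    variants$gt_mother <- gt_m
    variants$gt_father <- gt_f
    pedigree <- c(PROBAND = "proband", MOTHER = "mother", FATHER = "father")
  } else {
    gt_p[n] <- "0/1"
    variants$gt_proband <- gt_p
    pedigree <- c(PROBAND = "proband")
  }

  variants$key <- variant_key(variants$chrom, variants$pos, variants$ref,
                              variants$alt)
  dup <- duplicated(variants$key)
  variants <- variants[!dup, , drop = FALSE]
  variants <- variants[order(.chrom_order(variants$chrom), variants$pos,
                             variants$ref, variants$alt), , drop = FALSE]
  variants$annotated <- TRUE
  rownames(variants) <- NULL

  # patient phenotypes from the causal gene's first disease
  diseases <- res$resources$gene_to_diseases[[causal_gene]]
  if (is.null(diseases))
    stop("causal gene '", causal_gene, "' has no disease annotation")
  dterms <- unique(res$resources$disease_to_terms[[diseases[1]]])
  noisy <- stats::runif(length(dterms)) < spec$phenotype_noise
  all_terms <- res$resources$ontology$terms
  hpo <- dterms
  hpo[noisy] <- sample(all_terms[-1], sum(noisy), replace = TRUE)
  hpo <- unique(hpo)

  c_key <- variant_key(c_chrom, c_pos, c_al$ref, c_al$alt)
  list(case = list(case_id = case_id, variants = variants, hpo_terms = hpo,
                   pedigree = pedigree, proband_sex = proband_sex,
                   is_trio = is_trio),
       truth = data.frame(case_id = case_id, gene = causal_gene,
                          chrom = c_chrom, pos = c_pos, ref = c_al$ref,
                          alt = c_al$alt, key = c_key, mode = mode,
                          stringsAsFactors = FALSE))
}

#' Generate a full synthetic cohort
#'
#' Resources, cases and ground truth under one seed; case `i` uses seed
#' `spec$seed + 1000 + i`.
#'
#' @param spec A [cohort_spec()].
#' @return List with `spec`, `resources` bundle, `cases` (list) and `truth`
#'   (`data.frame`).
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  res <- generate_resources(spec)
  set.seed(spec$seed)
  causal_genes <- sample(res$genes, spec$n_cases, replace = TRUE)
  cases <- vector("list", spec$n_cases)
  truth <- vector("list", spec$n_cases)
  for (i in seq_len(spec$n_cases)) {
    gc <- generate_case(spec, res, sprintf("case%03d", i), causal_genes[i],
                        seed = spec$seed + 1000L + i)
    cases[[i]] <- gc$case
    truth[[i]] <- gc$truth
  }
  list(spec = spec, resources = res, cases = cases,
       truth = do.call(rbind, truth))
}

#' Generate synthetic reference-ranker outputs
#'
#' Each synthetic ranker ranks the genes of a case as a permutation of
#' `1..n`: the causal gene's rank is 1 plus an Exponential displacement with
#' mean `noise` (rank units; `noise = 0` pins it at rank 1), the remaining
#' genes are randomly ordered.
#'
#' @param cohort A [generate_cohort()] bundle.
#' @param noise Mean causal-gene rank displacement (default 10, emulating
#'   reference prioritizers with top-5 accuracy near one third).
#' @param seed Integer seed.
#' @param rankers Ranker names (default two).
#' @return `data.frame`: `case_id`, `ranker_name`, `gene`, `rank`.
#' @export
generate_external_ranks <- function(cohort, noise = 10, seed = 1L,
                                    rankers = c("rankerA", "rankerB")) {
  stopifnot(noise >= 0)
  set.seed(seed)
  out <- list()
  for (case in cohort$cases) {
    causal <- cohort$truth$gene[cohort$truth$case_id == case$case_id]
    genes <- unique(stats::na.omit(case$variants$gene))
    n <- length(genes)
    for (rk in rankers) {
      disp <- if (noise == 0) 0 else floor(stats::rexp(1, rate = 1 / noise))
      causal_rank <- min(n, 1 + disp)
      others <- sample(setdiff(genes, causal))
      ranked <- append(others, causal, after = causal_rank - 1)
      out[[length(out) + 1]] <- data.frame(
        case_id = case$case_id, ranker_name = rk, gene = ranked,
        rank = seq_len(n), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.KB_TRIGGERS <- c("causes", "induces", "underlies", "associated")

#' Generate a fixture knowledge base for a cohort
#'
#' Every causal variant receives 1-10 mutation-disease relations; 5% of
#' background variants receive 1-2. Sentences are templated with the trigger
#' word embedded, so highlighting is exercised end to end.
#'
#' @param cohort A [generate_cohort()] bundle.
#' @param seed Integer seed.
#' @return Relations `data.frame` accepted by [load_relations()].
#' @export
generate_fixture_kb <- function(cohort, seed = 1L) {
  set.seed(seed)
  rows <- list()
  emit <- function(key, n_rel) {
    for (j in seq_len(n_rel)) {
      d <- sprintf("D%04d", sample.int(900, 1))
      trig <- sample(.KB_TRIGGERS, 1)
      rows[[length(rows) + 1]] <<- data.frame(
        variant_id = key, disease_id = d,
        disease_category = paste0("C", 1 + (as.integer(substr(d, 2, 5)) %% 5)),
        pmid = sample.int(3e7, 1),
        sentence = sprintf("Variant %s %s disease %s in probands.",
                           key, trig, d),
        trigger = trig, stringsAsFactors = FALSE)
    }
  }
  for (k in cohort$truth$key) emit(k, sample(1:10, 1))
  for (case in cohort$cases) {
    bg <- setdiff(case$variants$key, cohort$truth$key)
    hit <- bg[stats::runif(length(bg)) < 0.05]
    for (k in hit) emit(k, sample(1:2, 1))
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
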