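# Phenotype resources (HPO subset ontology, gene-disease-term maps,
# information content), Resnik semantic similarity, interactome propagation,
# and assembly of the per-mutation feature vector fed to the ranker.

#' Read a minimal OBO ontology subset
#'
#' Parses `[Term]` stanzas keeping `id`, `name` and `is_a` (trailing `!`
#' comments stripped). Obsolete terms are dropped.
#'
#' @param path Path to an OBO file.
#' @return An `ontology` list with `terms`, `parents` (named list) and
#'   `names` (named character).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  terms <- character(0); parents <- list(); nm <- character(0)
  cur <- NULL; cur_parents <- character(0); cur_name <- NA_character_
  obsolete <- FALSE; in_term <- FALSE
  flush <- function() {
    if (!is.null(cur) && !obsolete) {
      terms <<- c(terms, cur)
      parents[[cur]] <<- cur_parents
      nm[cur] <<- cur_name
    }
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (ln == "[Term]") {
      flush(); in_term <- TRUE
      cur <- NULL; cur_parents <- character(0)
      cur_name <- NA_character_; obsolete <- FALSE
    } else if (startsWith(ln, "[")) {
      flush(); in_term <- FALSE; cur <- NULL
    } else if (in_term) {
      if (startsWith(ln, "id:")) cur <- trimws(sub("^id:", "", ln))
      else if (startsWith(ln, "name:")) cur_name <- trimws(sub("^name:", "", ln))
      else if (startsWith(ln, "is_a:")) {
        v <- trimws(sub("!.*$", "", sub("^is_a:", "", ln)))
        cur_parents <- c(cur_parents, v)
      } else if (startsWith(ln, "is_obsolete:") && grepl("true", ln))
        obsolete <- TRUE
    }
  }
  flush()
  make_ontology(terms, parents, nm)
}

#' Construct an ontology from term and parent lists
#'
#' @param terms Character vector of term IDs.
#' @param parents Named list mapping each term to its parent IDs (is-a).
#' @param names Optional named character of term names.
#' @return An `ontology` object with precomputed ancestor closures and
#'   depths. Errors if the is-a graph is cyclic.
#' @export
make_ontology <- function(terms, parents, names = NULL) {
  parents <- lapply(stats::setNames(terms, terms), function(t) {
    p <- parents[[t]]
    intersect(if (is.null(p)) character(0) else p, terms)
  })
  anc <- stats::setNames(vector("list", length(terms)), terms)
  depth <- stats::setNames(rep(NA_real_, length(terms)), terms)
  visiting <- character(0)
  get_anc <- function(t) {
    if (!is.null(anc[[t]])) return(anc[[t]])
    if (t %in% visiting) stop("ontology is cyclic at term ", t)
    visiting <<- c(visiting, t)
    a <- t
    d <- 0
    for (p in parents[[t]]) {
      a <- union(a, get_anc(p))
      d <- max(d, depth[[p]] + 1)
    }
    visiting <<- setdiff(visiting, t)
    anc[[t]] <<- a
    depth[[t]] <<- d
    a
  }
  for (t in terms) get_anc(t)
  structure(list(terms = terms, parents = parents, names = names,
                 ancestors = anc, depth = depth),
            class = "ontology")
}

#' Bundle phenotype resources
#'
#' Combines the ontology, gene-to-disease and disease-to-term maps and
#' per-term information content (IC). When `term_ic` is `NULL`, IC is the
#' negative log annotation frequency of each term in the disease corpus with
#' annotations propagated to ancestors (so ancestors are never more
#' informative); with an empty corpus it falls back to term depth.
#'
#' @param ontology An [make_ontology()] / [read_obo()] ontology.
#' @param gene_to_diseases `data.frame` with columns `gene`, `disease`.
#' @param disease_to_terms `data.frame` with columns `disease`, `term`.
#' @param term_ic Optional named numeric of information contents.
#' @return A `phenotype_resources` object.
#' @export
phenotype_resources <- function(ontology, gene_to_diseases, disease_to_terms,
                                term_ic = NULL) {
  bad <- setdiff(unique(disease_to_terms$term), ontology$terms)
  if (length(bad))
    stop("disease terms absent from ontology: ", paste(bad, collapse = ", "))
  if (is.null(term_ic)) {
    diseases <- unique(disease_to_terms$disease)
    if (length(diseases)) {
      count <- stats::setNames(numeric(length(ontology$terms)), ontology$terms)
      for (d in diseases) {
        ts <- disease_to_terms$term[disease_to_terms$disease == d]
        prop <- unique(unlist(ontology$ancestors[ts]))
        count[prop] <- count[prop] + 1
      }
      term_ic <- -log(pmax(count, 0.5) / length(diseases))
    } else {
      term_ic <- ontology$depth
    }
  }
  d2t <- split(disease_to_terms$term, disease_to_terms$disease)
  g2d <- split(gene_to_diseases$disease, gene_to_diseases$gene)
  structure(list(ontology = ontology,
                 gene_to_diseases = g2d,
                 disease_to_terms = d2t,
                 term_ic = term_ic,
                 cache = new.env(parent = emptyenv())),
            class = "phenotype_resources")
}

# Lazily build and cache the |T| x |T| MICA-IC similarity matrix. Intended
# for desk-scale ontologies (hundreds of terms); full HPO would need the
# pairwise path instead.
.sim_matrix <- function(res) {
  if (!is.null(res$cache$sim)) return(res$cache$sim)
  ont <- res$ontology
  nT <- length(ont$terms)
  A <- matrix(FALSE, nT, nT, dimnames = list(ont$terms, ont$terms))
  for (t in ont$terms) A[t, ont$ancestors[[t]]] <- TRUE
  ic <- res$term_ic[ont$terms]
  S <- matrix(0, nT, nT, dimnames = list(ont$terms, ont$terms))
  for (a in ont$terms[order(ic, decreasing = TRUE)]) {
    if (ic[[a]] <= 0) break
    desc <- which(A[, a])
    if (length(desc)) {
      blk <- S[desc, desc, drop = FALSE]
      blk[blk == 0] <- ic[[a]]
      S[desc, desc] <- blk
    }
  }
  res$cache$sim <- S
  S
}

#' Resnik similarity of two ontology terms
#'
#' Information content of the most informative common ancestor (MICA).
#' Symmetric; `term_similarity(t, t)` equals the IC of `t`.
#'
#' @param t1,t2 Term IDs.
#' @param resources A [phenotype_resources()] object.
#' @return Non-negative similarity.
#' @export
term_similarity <- function(t1, t2, resources) {
  ont <- resources$ontology
  for (t in c(t1, t2))
    if (!t %in% ont$terms) stop("unknown ontology term: ", t)
  common <- intersect(ont$ancestors[[t1]], ont$ancestors[[t2]])
  if (!length(common)) return(0)
  max(resources$term_ic[common], 0)
}

# Best-match-average score of a patient term set against one disease term
# set, normalized by the mean of the two sets' self-similarities (mean IC).
.bma_score <- function(S, ic_p, ic_d) {
  num <- (mean(apply(S, 1, max)) + mean(apply(S, 2, max))) / 2
  norm <- (mean(ic_p) + mean(ic_d)) / 2
  if (norm <= 0) return(0)
  min(max(num / norm, 0), 1)
}

# Scores for every disease given a patient term set; returns named numeric.
.disease_scores <- function(patient_terms, resources, diseases = NULL) {
  S <- .sim_matrix(resources)
  ic <- resources$term_ic
  if (is.null(diseases)) diseases <- names(resources$disease_to_terms)
  p <- unique(patient_terms)
  vapply(stats::setNames(diseases, diseases), function(d) {
    dt <- unique(resources$disease_to_terms[[d]])
    if (!length(dt)) return(0)
    .bma_score(S[p, dt, drop = FALSE], ic[p], ic[dt])
  }, numeric(1))
}

#' Phenotype similarity between a patient and a gene
#'
#' For each disease associated with the gene, the symmetric best-match
#' average of Resnik term similarities between the patient's terms and the
#' disease's terms, normalized by the mean of the two sets' self-similarities;
#' the gene score is the maximum over its diseases, clipped to `[0, 1]`.
#' Genes with no disease annotation score 0.
#'
#' @param patient_terms Character vector of patient HPO term IDs (non-empty).
#' @param gene Gene symbol.
#' @param resources A [phenotype_resources()] object.
#' @return Similarity in `[0, 1]`.
#' @export
phenotype_similarity <- function(patient_terms, gene, resources) {
  patient_terms <- unique(patient_terms)
  if (!length(patient_terms)) stop("patient term set is empty")
  bad <- setdiff(patient_terms, resources$ontology$terms)
  if (length(bad)) stop("unknown ontology term: ", paste(bad, collapse = ", "))
  ds <- resources$gene_to_diseases[[gene]]
  if (is.null(ds) || !length(ds)) return(0)
  max(.disease_scores(patient_terms, resources, unique(ds)))
}

#' Phenotype similarity propagated through the interactome
#'
#' One-hop propagation: `damping` times the maximum over direct neighbors of
#' edge weight times the neighbor's [phenotype_similarity()]. Isolated genes
#' score 0.
#'
#' @param gene Gene symbol.
#' @param patient_terms Patient HPO term IDs.
#' @param resources A [phenotype_resources()] object.
#' @param graph Interactome edge `data.frame` (`gene_a`, `gene_b`, `weight`).
#' @param damping Attenuation factor in `(0, 1]`, default 0.5.
#' @return Similarity in `[0, 1]`.
#' @export
interactome_similarity <- function(gene, patient_terms, resources, graph,
                                   damping = 0.5) {
  stopifnot(damping > 0, damping <= 1)
  ia <- graph$gene_a == gene
  ib <- graph$gene_b == gene
  nb <- c(graph$gene_b[ia], graph$gene_a[ib])
  w <- c(graph$weight[ia], graph$weight[ib])
  if (!length(nb)) return(0)
  sims <- vapply(nb, phenotype_similarity, numeric(1),
                 patient_terms = patient_terms, resources = resources)
  min(max(damping * max(w * sims), 0), 1)
}

.clinvar_code <- function(cls) {
  out <- rep(0.5, length(cls))          # unknown and absent a priori equal
  out[!is.na(cls) & cls == "pathogenic"] <- 1
  out[!is.na(cls) & cls == "benign"] <- 0
  out
}

#' Build the feature matrix for a case
#'
#' Assembles, per mutation: direct and interactome phenotype similarity,
#' conservation (raw; standardized inside the model), ClinVar code
#' (pathogenic 1, unknown/absent 0.5, benign 0), maximum population MAF, the
#' six predictor scores, and `log1p` of the knowledge-base relation count.
#' Imputation: conservation 0, predictor scores 0.5, MAF 0; the mask records
#' every imputation.
#'
#' @param variants Joined variant table of one case.
#' @param hpo_terms Patient HPO term IDs (non-empty).
#' @param resources A [phenotype_resources()] object.
#' @param graph Interactome edge `data.frame`.
#' @param kb Optional [load_relations()] knowledge base.
#' @param damping Interactome damping factor.
#' @return `list(x = numeric matrix, mask = logical matrix)`, rows aligned
#'   with `variants`, columns `FEATURE_NAMES`.
#' @export
build_feature_matrix <- function(variants, hpo_terms, resources, graph,
                                 kb = NULL, damping = 0.5) {
  n <- nrow(variants)
  genes <- unique(stats::na.omit(variants$gene))
  dscores <- .disease_scores(unique(hpo_terms), resources)
  gene_sim <- function(g) {
    ds <- resources$gene_to_diseases[[g]]
    if (is.null(ds) || !length(ds)) 0 else max(dscores[unique(ds)])
  }
  # direct similarity for every gene that is either in the case or a
  # neighbor of a case gene (neighbors feed the interactome feature)
  nb_of <- function(g) {
    c(graph$gene_b[graph$gene_a == g], graph$gene_a[graph$gene_b == g])
  }
  neighbors <- lapply(stats::setNames(genes, genes), nb_of)
  all_genes <- union(genes, unlist(neighbors))
  sims <- vapply(stats::setNames(all_genes, all_genes), gene_sim, numeric(1))
  ppi <- vapply(stats::setNames(genes, genes), function(g) {
    nb <- neighbors[[g]]
    if (!length(nb)) return(0)
    ia <- graph$gene_a == g; ib <- graph$gene_b == g
    w <- c(graph$weight[ia], graph$weight[ib])
    min(max(damping * max(w * sims[nb]), 0), 1)
  }, numeric(1))

  x <- matrix(0, n, length(FEATURE_NAMES),
              dimnames = list(NULL, FEATURE_NAMES))
  mask <- matrix(FALSE, n, length(FEATURE_NAMES),
                 dimnames = list(NULL, FEATURE_NAMES))
  gidx <- match(variants$gene, names(sims))
  x[, "pheno_dir"] <- ifelse(is.na(gidx), 0, sims[gidx])
  pidx <- match(variants$gene, names(ppi))
  x[, "pheno_ppi"] <- ifelse(is.na(pidx), 0, ppi[pidx])

  gerp <- variants$gerp
  mask[, "gerp"] <- is.na(gerp)
  x[, "gerp"] <- ifelse(is.na(gerp), 0, gerp)

  x[, "clinvar"] <- .clinvar_code(variants$clinvar)
  mask[, "clinvar"] <- is.na(variants$clinvar) | variants$clinvar == "absent"

  afc <- af_columns(variants)
  if (length(afc)) {
    afm <- as.matrix(variants[, afc, drop = FALSE])
    mx <- suppressWarnings(apply(afm, 1, max, na.rm = TRUE))
    mask[, "max_maf"] <- is.infinite(mx)
    x[, "max_maf"] <- ifelse(is.infinite(mx), 0, mx)
  } else {
    mask[, "max_maf"] <- TRUE
  }

  for (tool in PREDICTOR_TOOLS) {
    col <- paste0("score_", tool)
    v <- if (col %in% names(variants)) variants[[col]] else rep(NA_real_, n)
    mask[, col] <- is.na(v)
    x[, col] <- ifelse(is.na(v), 0.5, v)
  }

  counts <- if (is.null(kb)) rep(0, n) else kb_count(kb, variants$key)
  x[, "lit"] <- log1p(counts)
  list(x = x, mask = mask)
}

#' Build the feature vector of a single mutation
#'
#' Single-row convenience wrapper around [build_feature_matrix()].
#'
#' @inheritParams build_feature_matrix
#' @param record One-row joined variant table.
#' @return `list(x = named numeric, mask = named logical)`.
#' @export
build_feature_vector <- function(record, hpo_terms, resources, graph,
                                 kb = NULL, damping = 0.5) {
  fm <- build_feature_matrix(record, hpo_terms, resources, graph, kb, damping)
  list(x = fm$x[1, ], mask = fm$mask[1, ])
}
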