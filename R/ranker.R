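# Rank-decay training labels, the score network, per-case scoring with
# gene-level max aggregation, popularity reordering and the leave-one-out
# evaluation protocol.

#' Label specification for rank-decay training targets
#'
#' @param gamma Decay factor in `(0, 1)`; default 0.99.
#' @param n_decoys Decoy genes selected per case; default 40.
#' @return A `label_spec` list.
#' @export
label_spec <- function(gamma = 0.99, n_decoys = 40L) {
  stopifnot(gamma > 0, gamma < 1, n_decoys >= 1)
  structure(list(gamma = gamma, n_decoys = as.integer(n_decoys)),
            class = "label_spec")
}

#' Rank-decay training label
#'
#' `gamma^(x - 1)` for average external rank `x >= 1`: the causal mutation
#' (x = 1) anchors at exactly 1 and the label decays strictly with rank.
#'
#' @param x Average external gene rank(s), each `>= 1`.
#' @param spec A [label_spec()].
#' @return Labels in `(0, 1]`.
#' @export
make_label <- function(x, spec = label_spec()) {
  if (any(is.na(x)) || any(x < 1))
    stop("rank x must be >= 1")
  spec$gamma^(x - 1)
}

#' Average external rank of a gene in one case
#'
#' Arithmetic mean over the configured reference rankers that cover the
#' gene; rankers missing the gene are excluded from the denominator.
#'
#' @param records `data.frame` of external rank records with columns
#'   `ranker_name`, `gene`, `rank` (one case).
#' @param gene Gene symbol.
#' @param rankers Character vector of configured ranker names.
#' @return Mean rank (numeric scalar).
#' @export
average_rank <- function(records, gene, rankers) {
  hit <- records$gene == gene & records$ranker_name %in% rankers
  if (!any(hit))
    stop("gene '", gene, "' is not ranked by any configured ranker")
  mean(records$rank[hit])
}

# Mean of the available predictor scores -- the annotation-only
# deleteriousness used to pick a decoy gene's representative mutation.
.preliminary_deleteriousness <- function(variants) {
  cols <- intersect(paste0("score_", PREDICTOR_TOOLS), names(variants))
  mat <- as.matrix(variants[, cols, drop = FALSE])
  rowMeans(mat, na.rm = TRUE)
}

#' Build the training set from a cohort and reference-ranker output
#'
#' Per case: one causal example labelled exactly 1, plus `spec$n_decoys`
#' decoy examples — the non-causal genes with the smallest average external
#' rank (ties by gene symbol), each represented by its most deleterious
#' mutation (highest mean available predictor score, ties by variant key),
#' labelled `gamma^(avg_rank - 1)`. Cases with fewer rankable genes use all
#' available with a warning.
#'
#' @param cohort List of cases (`case_id`, `variants`, `hpo_terms`, ...).
#' @param external_ranks `data.frame` with columns `case_id`, `ranker_name`,
#'   `gene`, `rank`.
#' @param truth `data.frame` with columns `case_id`, `gene`, `key` (the
#'   causal mutation per case).
#' @param spec A [label_spec()].
#' @param resources,graph,kb Feature resources passed to
#'   [build_feature_matrix()].
#' @param rankers Configured ranker names (default: all present).
#' @param feature_cache Optional environment; per-case feature matrices are
#'   stored there under the case ID so callers can reuse them.
#' @return `data.frame`: `case_id`, `gene`, `key`, `label`, `is_causal` and
#'   one column per feature.
#' @export
build_training_set <- function(cohort, external_ranks, truth, spec,
                               resources, graph, kb = NULL,
                               rankers = unique(external_ranks$ranker_name),
                               feature_cache = NULL) {
  out <- vector("list", length(cohort))
  for (ci in seq_along(cohort)) {
    case <- cohort[[ci]]
    v <- case$variants
    fm <- build_feature_matrix(v, case$hpo_terms, resources, graph, kb)
    if (!is.null(feature_cache)) feature_cache[[case$case_id]] <- fm
    tr <- truth[truth$case_id == case$case_id, , drop = FALSE]
    if (nrow(tr) != 1)
      stop("case '", case$case_id, "' has no unique causal truth record")
    causal_idx <- match(tr$key, v$key)
    if (is.na(causal_idx))
      stop("causal variant ", tr$key, " absent from case '", case$case_id, "'")

    er <- external_ranks[external_ranks$case_id == case$case_id &
                           external_ranks$ranker_name %in% rankers, ,
                         drop = FALSE]
    rankable <- intersect(unique(er$gene), unique(v$gene))
    rankable <- setdiff(rankable, tr$gene)
    if (!length(rankable)) {
      warning("case '", case$case_id, "' has no rankable decoy genes")
      avg <- numeric(0)
    } else {
      avg <- vapply(rankable, function(g) average_rank(er, g, rankers),
                    numeric(1))
    }
    ord <- order(avg, rankable)
    if (length(rankable) < spec$n_decoys)
      warning("case '", case$case_id, "' has only ", length(rankable),
              " rankable decoy genes (wanted ", spec$n_decoys, ")")
    take <- head(ord, spec$n_decoys)
    decoy_genes <- rankable[take]
    decoy_rank <- avg[take]

    delet <- .preliminary_deleteriousness(v)
    rep_idx <- vapply(decoy_genes, function(g) {
      idx <- which(!is.na(v$gene) & v$gene == g)
      idx[order(-delet[idx], v$key[idx])][1]
    }, integer(1))

    rows <- c(causal_idx, rep_idx)
    df <- data.frame(case_id = case$case_id,
                     gene = v$gene[rows], key = v$key[rows],
                     label = c(1, make_label(decoy_rank, spec)),
                     is_causal = c(TRUE, rep(FALSE, length(rep_idx))),
                     stringsAsFactors = FALSE)
    out[[ci]] <- cbind(df, as.data.frame(fm$x[rows, , drop = FALSE]))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Train the mutation score network
#'
#' Fits a single-hidden-layer network with logistic (bounded `[0, 1]`)
#' output by least squares on the rank-decay labels, with L2 weight decay
#' for regularization. Examples are put in a canonical order and features
#' standardized before fitting, so training is reproducible under the seed
#' and invariant to input row order; standardization constants are stored
#' with the model.
#'
#' @param examples Training `data.frame` from [build_training_set()] (needs
#'   `label` plus the feature columns).
#' @param hidden Hidden-layer size (default 16).
#' @param decay L2 weight decay (default 1e-3).
#' @param maxit Maximum optimizer iterations (default 300).
#' @param seed Integer seed for weight initialization.
#' @param gamma Decay factor recorded with the model.
#' @return A `score_model` object.
#' @export
train_ranker <- function(examples, hidden = 16L, decay = 1e-3, maxit = 300L,
                         seed = 1L, gamma = 0.99) {
  feats <- intersect(FEATURE_NAMES, names(examples))
  if (length(unique(examples$label)) < 2)
    stop("need at least two distinct labels to train")
  # canonical ordering: invariant to caller's row order
  ord <- do.call(order, c(
    examples[intersect(c("case_id", "gene", "key"), names(examples))],
    list(examples$label)))
  examples <- examples[ord, , drop = FALSE]
  x <- as.matrix(examples[, feats, drop = FALSE])
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  scale[!is.finite(scale) | scale == 0] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  if (all(apply(xs, 2, function(v) length(unique(v)) == 1)))
    warning("degenerate training input: all feature vectors identical")
  set.seed(seed)
  net <- nnet::nnet(xs, examples$label, size = hidden, decay = decay,
                    maxit = maxit, linout = FALSE, trace = FALSE)
  structure(list(net = net, center = center, scale = scale,
                 feature_names = feats, hidden = hidden, decay = decay,
                 maxit = maxit, seed = seed, gamma = gamma,
                 version = "1"),
            class = "score_model")
}

#' @export
print.score_model <- function(x, ...) {
  cat(sprintf("score model: %d features -> %d hidden -> 1 (gamma %.2f, seed %d)\n",
              length(x$feature_names), x$hidden, x$gamma, x$seed))
  invisible(x)
}

#' Predict mutation scores from a feature matrix
#' @param model A [train_ranker()] model.
#' @param x Feature matrix with the model's feature columns.
#' @return Numeric scores in `[0, 1]`.
#' @export
predict_scores <- function(model, x) {
  x <- as.matrix(x[, model$feature_names, drop = FALSE])
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  as.numeric(predict(model$net, xs))
}

#' Score a case and rank its genes
#'
#' Every mutation receives a score in `[0, 1]`; each gene is scored by the
#' maximum over its mutations; genes are sorted by descending score with
#' ties broken by gene symbol, and a gene's mutations by descending score
#' then variant key. Unannotated variants (no gene) are skipped.
#'
#' @param model A [train_ranker()] model.
#' @param case A case list (`variants`, `hpo_terms`).
#' @param resources,graph,kb Feature resources.
#' @param features Optional precomputed [build_feature_matrix()] result for
#'   this case (skips recomputation).
#' @return A `ranked_result` `data.frame`: one row per mutation with
#'   `gene_rank`, `gene`, `gene_score`, `key`, `score` plus the annotation
#'   columns of the variant table; attribute `ordering_mode = "score"`.
#' @export
score_case <- function(model, case, resources, graph, kb = NULL,
                       features = NULL) {
  v <- case$variants
  if (!nrow(v)) {
    out <- data.frame(gene_rank = integer(), gene = character(),
                      gene_score = numeric(), key = character(),
                      score = numeric(), stringsAsFactors = FALSE)
    attr(out, "ordering_mode") <- "score"
    class(out) <- c("ranked_result", class(out))
    return(out)
  }
  fm <- if (is.null(features))
    build_feature_matrix(v, case$hpo_terms, resources, graph, kb)
  else features
  v$score <- pmin(pmax(predict_scores(model, fm$x), 0), 1)
  v <- v[!is.na(v$gene), , drop = FALSE]
  gene_score <- tapply(v$score, v$gene, max)
  genes <- names(gene_score)[order(-gene_score, names(gene_score))]
  v$gene_score <- as.numeric(gene_score[v$gene])
  v$gene_rank <- match(v$gene, genes)
  v$evidence_count <- if (is.null(kb)) 0L else kb_count(kb, v$key)
  afc <- af_columns(v)
  if (length(afc) && !"max_maf" %in% names(v)) {
    mx <- suppressWarnings(apply(as.matrix(v[, afc, drop = FALSE]), 1, max,
                                 na.rm = TRUE))
    v$max_maf <- ifelse(is.infinite(mx), NA_real_, mx)
  }
  v <- v[order(v$gene_rank, -v$score, v$key), , drop = FALSE]
  rownames(v) <- NULL
  front <- c("gene_rank", "gene", "gene_score", "key", "score")
  v <- v[, c(front, setdiff(names(v), front)), drop = FALSE]
  attr(v, "ordering_mode") <- "score"
  class(v) <- c("ranked_result", class(v))
  v
}

#' Reorder a ranked result by research popularity
#'
#' Genes are reordered by descending total knowledge-base relation count
#' over their mutations, ties by gene symbol; with no knowledge-base entries
#' at all the order falls back to gene symbol. The member set is preserved
#' exactly.
#'
#' @param result A `ranked_result` from [score_case()].
#' @param kb A [load_relations()] knowledge base.
#' @return The reordered `ranked_result` (`ordering_mode = "popularity"`).
#' @export
rank_by_popularity <- function(result, kb) {
  if (!nrow(result)) return(result)
  counts <- kb_count(kb, result$key)
  gene_pop <- tapply(counts, result$gene, sum)
  genes <- names(gene_pop)[order(-gene_pop, names(gene_pop))]
  result$gene_rank <- match(result$gene, genes)
  result <- result[order(result$gene_rank, -result$score, result$key), ,
                   drop = FALSE]
  rownames(result) <- NULL
  attr(result, "ordering_mode") <- "popularity"
  result
}

#' Leave-one-out evaluation over a cohort
#'
#' For each case, trains a model on all other cases' training examples and
#' scores the held-out case unfiltered, recording the rank position of its
#' causal gene (`NA` when the causal gene receives no rank).
#'
#' @param cohort List of cases.
#' @param external_ranks,truth,spec As in [build_training_set()].
#' @param resources,graph,kb Feature resources.
#' @param seed Base seed; fold `i` trains with `seed + i`.
#' @param ... Passed to [train_ranker()] (e.g. `hidden`, `maxit`).
#' @return Integer vector of causal-gene ranks, one per case, named by
#'   case ID.
#' @export
leave_one_out_evaluate <- function(cohort, external_ranks, truth, spec,
                                   resources, graph, kb = NULL, seed = 1L,
                                   ...) {
  stopifnot(length(cohort) >= 2)
  cache <- new.env(parent = emptyenv())
  training <- build_training_set(cohort, external_ranks, truth, spec,
                                 resources, graph, kb,
                                 feature_cache = cache)
  ranks <- stats::setNames(rep(NA_integer_, length(cohort)),
                           vapply(cohort, `[[`, character(1), "case_id"))
  for (i in seq_along(cohort)) {
    case <- cohort[[i]]
    fold <- training[training$case_id != case$case_id, , drop = FALSE]
    model <- train_ranker(fold, seed = seed + i, gamma = spec$gamma, ...)
    res <- score_case(model, case, resources, graph, kb,
                      features = cache[[case$case_id]])
    causal_gene <- truth$gene[truth$case_id == case$case_id]
    r <- res$gene_rank[match(causal_gene, res$gene)]
    ranks[case$case_id] <- if (length(r) && !is.na(r)) r else NA_integer_
  }
  ranks
}

#' Save / load a score model as JSON
#'
#' Serializes the network weights, architecture, standardization constants
#' and decay factor to a versioned JSON file.
#'
#' @param model A `score_model`.
#' @param path Output path.
#' @export
save_model <- function(model, path) {
  obj <- list(version = model$version, hidden = model$hidden,
              decay = model$decay, maxit = model$maxit, seed = model$seed,
              gamma = model$gamma, feature_names = model$feature_names,
              center = as.list(model$center), scale = as.list(model$scale),
              n = model$net$n, wts = model$net$wts)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @return `load_model()` returns the restored `score_model`.
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  feats <- obj$feature_names
  # rebuild an nnet skeleton and inject the stored weights
  dummy_x <- matrix(0, max(4, obj$hidden), length(feats),
                    dimnames = list(NULL, feats))
  dummy_y <- rep(c(0, 1), length.out = nrow(dummy_x))
  set.seed(obj$seed)
  net <- nnet::nnet(dummy_x, dummy_y, size = obj$hidden, maxit = 1,
                    decay = obj$decay, linout = FALSE, trace = FALSE)
  stopifnot(length(net$wts) == length(obj$wts))
  net$wts <- as.numeric(obj$wts)
  structure(list(net = net, center = unlist(obj$center),
                 scale = unlist(obj$scale), feature_names = feats,
                 hidden = obj$hidden, decay = obj$decay, maxit = obj$maxit,
                 seed = obj$seed, gamma = obj$gamma, version = obj$version),
            class = "score_model")
}
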