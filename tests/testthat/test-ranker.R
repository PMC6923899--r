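test_that("rank-decay labels anchor at 1 and decay strictly", {
  spec <- label_spec()
  expect_identical(make_label(1, spec), 1)
  expect_identical(make_label(1, label_spec(gamma = 0.5)), 1)
  # iterative-multiplication oracle
  acc <- 1
  for (x in 2:20) {
    acc <- acc * 0.99
    expect_equal(make_label(x, spec), acc)
  }
  expect_error(make_label(0.5, spec), ">= 1")
  expect_error(label_spec(gamma = 1), "gamma")
})

test_that("average external rank uses only the configured, covering rankers", {
  rec <- data.frame(case_id = "c", ranker_name = c("A", "B", "C"),
                    gene = "G", rank = c(3L, 5L, 100L))
  expect_equal(average_rank(rec, "G", c("A", "B")), 4)
  expect_equal(average_rank(rec, "G", "C"), 100)
  rec2 <- rec[rec$ranker_name == "A", ]
  expect_equal(average_rank(rec2, "G", c("A", "B")), 3)  # B excluded
  expect_error(average_rank(rec2, "H", c("A", "B")), "not ranked")
})

test_that("training sets pair one causal with rank-selected decoy examples", {
  fx <- small_cohort_bundle()
  spec <- label_spec(n_decoys = 10)
  tr <- build_training_set(fx$cohort$cases, fx$ranks, fx$cohort$truth, spec,
                           fx$cohort$resources$resources,
                           fx$cohort$resources$graph)
  expect_equal(nrow(tr), 6 * 11)
  causal <- tr[tr$is_causal, ]
  expect_equal(nrow(causal), 6L)
  expect_true(all(causal$label == 1))
  expect_equal(causal$gene, fx$cohort$truth$gene)
  decoys <- tr[!tr$is_causal, ]
  expect_true(all(decoys$label > 0 & decoys$label <= 1))
  # a case's decoys never include its own causal gene
  for (cid in unique(decoys$case_id)) {
    own_causal <- fx$cohort$truth$gene[fx$cohort$truth$case_id == cid]
    expect_false(own_causal %in% decoys$gene[decoys$case_id == cid])
  }
  # decoy labels equal gamma^(avg_rank - 1) for their gene
  one <- decoys[decoys$case_id == "case001", ][1, ]
  er <- fx$ranks[fx$ranks$case_id == "case001", ]
  expect_equal(one$label,
               make_label(average_rank(er, one$gene, unique(er$ranker_name)),
                          spec))
})

test_that("decoy representatives are the most deleterious gene mutations", {
  fx <- small_cohort_bundle()
  spec <- label_spec(n_decoys = 5)
  tr <- build_training_set(fx$cohort$cases, fx$ranks, fx$cohort$truth, spec,
                           fx$cohort$resources$resources,
                           fx$cohort$resources$graph)
  case <- fx$cohort$cases[[1]]
  v <- case$variants
  pred_cols <- grep("^score_", names(v), value = TRUE)
  delet <- rowMeans(as.matrix(v[, pred_cols]), na.rm = TRUE)
  for (i in which(!tr$is_causal & tr$case_id == case$case_id)) {
    g <- tr$gene[i]
    idx <- which(v$gene == g)
    expect_equal(tr$key[i], v$key[idx[order(-delet[idx], v$key[idx])]][1])
  }
})

test_that("cases short of decoys warn and use what is rankable", {
  fx <- small_cohort_bundle()
  spec <- label_spec(n_decoys = 1000)
  expect_warning(
    tr <- build_training_set(fx$cohort$cases[1], fx$ranks,
                             fx$cohort$truth, spec,
                             fx$cohort$resources$resources,
                             fx$cohort$resources$graph),
    "rankable")
  n_genes_ranked <- length(intersect(
    unique(fx$ranks$gene[fx$ranks$case_id == "case001"]),
    unique(fx$cohort$cases[[1]]$variants$gene)))
  expect_equal(nrow(tr), n_genes_ranked)  # causal + all other rankable genes
})

test_that("training is seed-reproducible and row-order invariant", {
  fx <- small_cohort_bundle()
  spec <- label_spec(n_decoys = 10)
  tr <- build_training_set(fx$cohort$cases, fx$ranks, fx$cohort$truth, spec,
                           fx$cohort$resources$resources,
                           fx$cohort$resources$graph)
  m1 <- train_ranker(tr, seed = 5, maxit = 50)
  m2 <- train_ranker(tr, seed = 5, maxit = 50)
  expect_identical(m1$net$wts, m2$net$wts)
  set.seed(99)
  m3 <- train_ranker(tr[sample(nrow(tr)), ], seed = 5, maxit = 50)
  expect_identical(m1$net$wts, m3$net$wts)
  m4 <- train_ranker(tr, seed = 6, maxit = 50)
  expect_false(identical(m1$net$wts, m4$net$wts))
})

test_that("the network recovers a noiseless monotone label ordering", {
  set.seed(3)
  n <- 400
  x <- matrix(runif(n * 3), n, 3,
              dimnames = list(NULL, c("pheno_dir", "max_maf", "gerp")))
  label <- 0.1 + 0.8 * x[, "pheno_dir"]^2
  ex <- data.frame(case_id = "c", gene = paste0("g", 1:n),
                   key = sprintf("1:%d:A:T", 1:n), label = label)
  ex <- cbind(ex, as.data.frame(x))
  train_idx <- seq_len(300)
  m <- train_ranker(ex[train_idx, ], seed = 1, maxit = 400)
  held <- ex[-train_idx, ]
  pred <- predict_scores(m, held)
  rho <- cor(pred, held$label, method = "spearman")
  expect_gte(rho, 0.95)
})

test_that("degenerate all-identical training input warns but returns a model", {
  ex <- data.frame(case_id = "c", gene = paste0("g", 1:10),
                   key = sprintf("1:%d:A:T", 1:10),
                   label = rep(c(0.2, 0.8), 5),
                   pheno_dir = 1, max_maf = 0)
  expect_warning(m <- train_ranker(ex, seed = 1, maxit = 20), "degenerate")
  expect_s3_class(m, "score_model")
})

test_that("case scoring bounds scores and aggregates genes by max", {
  fx <- small_cohort_bundle()
  spec <- label_spec(n_decoys = 10)
  tr <- build_training_set(fx$cohort$cases, fx$ranks, fx$cohort$truth, spec,
                           fx$cohort$resources$resources,
                           fx$cohort$resources$graph)
  m <- train_ranker(tr, seed = 2)
  res <- score_case(m, fx$cohort$cases[[2]],
                    fx$cohort$resources$resources, fx$cohort$resources$graph)
  expect_true(all(res$score >= 0 & res$score <= 1))
  agg <- tapply(res$score, res$gene, max)
  expect_equal(res$gene_score, as.numeric(agg[res$gene]))
  # descending gene order with deterministic tie-break
  ord <- res[!duplicated(res$gene), ]
  expect_true(all(diff(ord$gene_score) <= 1e-12))
  # empty case
  empty <- list(case_id = "e", variants = fx$cohort$cases[[1]]$variants[0, ],
                hpo_terms = "HP:0000002")
  expect_equal(nrow(score_case(m, empty, fx$cohort$resources$resources,
                               fx$cohort$resources$graph)), 0L)
})

test_that("popularity ordering follows evidence counts and preserves members", {
  fx <- small_cohort_bundle()
  spec <- label_spec(n_decoys = 10)
  tr <- build_training_set(fx$cohort$cases, fx$ranks, fx$cohort$truth, spec,
                           fx$cohort$resources$resources,
                           fx$cohort$resources$graph)
  m <- train_ranker(tr, seed = 2)
  kb <- load_relations(fx$kb_df)
  res <- score_case(m, fx$cohort$cases[[1]],
                    fx$cohort$resources$resources, fx$cohort$resources$graph,
                    kb)
  pop <- rank_by_popularity(res, kb)
  expect_setequal(pop$key, res$key)
  expect_equal(attr(pop, "ordering_mode"), "popularity")
  counts <- tapply(kb_count(kb, pop$key), pop$gene, sum)
  ord <- pop[!duplicated(pop$gene), ]
  expect_true(all(diff(unname(counts[ord$gene])) <= 0))
  # empty knowledge base: alphabetical gene fallback
  kb0 <- load_relations(fx$kb_df[0, ])
  pop0 <- rank_by_popularity(res, kb0)
  ord0 <- pop0[!duplicated(pop0$gene), ]
  expect_equal(ord0$gene, sort(ord0$gene))
})

test_that("leave-one-out trains on the complement and records causal ranks", {
  fx <- small_cohort_bundle()
  two <- fx$cohort$cases[1:2]
  spec <- label_spec(n_decoys = 10)
  r1 <- leave_one_out_evaluate(two, fx$ranks, fx$cohort$truth, spec,
                               fx$cohort$resources$resources,
                               fx$cohort$resources$graph, seed = 4)
  expect_length(r1, 2L)
  expect_named(r1, c("case001", "case002"))
  expect_true(all(r1 >= 1, na.rm = TRUE))
  r2 <- leave_one_out_evaluate(two, fx$ranks, fx$cohort$truth, spec,
                               fx$cohort$resources$resources,
                               fx$cohort$resources$graph, seed = 4)
  expect_identical(r1, r2)  # deterministic under fixed seed
})

test_that("models survive a JSON save/load round trip", {
  fx <- small_cohort_bundle()
  spec <- label_spec(n_decoys = 10)
  tr <- build_training_set(fx$cohort$cases, fx$ranks, fx$cohort$truth, spec,
                           fx$cohort$resources$resources,
                           fx$cohort$resources$graph)
  m <- train_ranker(tr, seed = 2, maxit = 60)
  path <- tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  x <- tr[, m$feature_names]
  expect_equal(predict_scores(m2, x), predict_scores(m, x), tolerance = 1e-12)
})
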