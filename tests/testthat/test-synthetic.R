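test_that("cohort generation is byte-deterministic under the seed", {
  spec <- cohort_spec(n_cases = 2, n_genes = 20, variants_per_case = 25,
                      seed = 13)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  for (d in c(d1, d2)) {
    cohort <- generate_cohort(spec)
    ranks <- generate_external_ranks(cohort, seed = 13)
    kb <- generate_fixture_kb(cohort, seed = 13)
    write_cohort(cohort, d, external_ranks = ranks, kb = kb)
  }
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_equal(f1, f2)
  for (f in f1)
    expect_identical(readLines(file.path(d1, f), warn = FALSE),
                     readLines(file.path(d2, f), warn = FALSE),
                     info = f)
})

test_that("generated resources are referentially intact and deep enough", {
  res <- generate_resources(cohort_spec(n_genes = 30, seed = 3))
  ont <- res$resources$ontology
  expect_gte(max(unlist(ont$depth)), 4)     # make_ontology rejects cycles
  expect_true(all(res$disease_to_terms$term %in% ont$terms))
  expect_true(all(res$gene_to_diseases$disease %in%
                    res$disease_to_terms$disease))
  expect_true(all(res$graph$gene_a %in% res$genes))
  expect_true(all(res$graph$weight >= 0 & res$graph$weight <= 1))
  expect_false(any(res$graph$gene_a == res$graph$gene_b))
})

test_that("noiseless phenotypes are a subset of the causal disease terms", {
  spec <- cohort_spec(n_cases = 1, n_genes = 20, variants_per_case = 20,
                      phenotype_noise = 0, seed = 9)
  res <- generate_resources(spec)
  gc <- generate_case(spec, res, "c1", res$genes[1], seed = 10)
  d <- res$resources$gene_to_diseases[[res$genes[1]]][1]
  expect_true(all(gc$case$hpo_terms %in%
                    res$resources$disease_to_terms[[d]]))
  # truth points at a variant that exists in the table
  expect_true(gc$truth$key %in% gc$case$variants$key)
})

test_that("zero causal effect leaves the causal features at background", {
  spec <- cohort_spec(n_cases = 1, n_genes = 10, variants_per_case = 5,
                      causal_effect = 0, trio_fraction = 0, seed = 17)
  res <- generate_resources(spec)
  causal <- c(); background <- c()
  for (i in 1:834) {
    gc <- generate_case(spec, res, "c", res$genes[1], seed = 20000 + i)
    v <- gc$case$variants
    ci <- match(gc$truth$key, v$key)
    pred_cols <- grep("^score_", names(v), value = TRUE)
    causal <- c(causal, unlist(v[ci, pred_cols]))
    background <- c(background, unlist(v[-ci, pred_cols][1, ]))
  }
  causal <- causal[!is.na(causal)]
  background <- background[!is.na(background)]
  expect_gte(length(causal), 5000 * 0.85)
  ks <- suppressWarnings(ks.test(causal, background))
  expect_gt(ks$p.value, 0.01)
})

test_that("a positive causal effect shifts predictor scores upward", {
  spec <- cohort_spec(n_cases = 1, n_genes = 10, variants_per_case = 30,
                      causal_effect = 1.5, trio_fraction = 0, seed = 19)
  res <- generate_resources(spec)
  causal <- c(); background <- c()
  for (i in 1:50) {
    gc <- generate_case(spec, res, "c", res$genes[1], seed = 30000 + i)
    v <- gc$case$variants
    ci <- match(gc$truth$key, v$key)
    pred_cols <- grep("^score_", names(v), value = TRUE)
    causal <- c(causal, unlist(v[ci, pred_cols]))
    background <- c(background, unlist(v[-ci, pred_cols]))
  }
  expect_gt(mean(causal, na.rm = TRUE), mean(background, na.rm = TRUE) + 0.15)
})

test_that("simulated trio genotypes close the loop with inheritance calls", {
  spec <- cohort_spec(n_cases = 1, n_genes = 20, variants_per_case = 20,
                      trio_fraction = 1, seed = 23)
  res <- generate_resources(spec)
  seen <- character(0)
  for (i in 1:30) {
    gc <- generate_case(spec, res, "c", res$genes[1], seed = 40000 + i)
    v <- infer_inheritance(gc$case$variants, gc$case$proband_sex)
    ci <- match(gc$truth$key, v$key)
    expect_true(gc$truth$mode %in% v$modes[[ci]],
                info = paste("mode", gc$truth$mode))
    seen <- union(seen, gc$truth$mode)
  }
  expect_gte(length(seen), 2)  # several modes exercised
})

test_that("synthetic rankers emit permutations that degrade with noise", {
  fx <- small_cohort_bundle()
  r0 <- generate_external_ranks(fx$cohort, noise = 0, seed = 1)
  for (cid in unique(r0$case_id)) {
    for (rk in unique(r0$ranker_name)) {
      sub <- r0[r0$case_id == cid & r0$ranker_name == rk, ]
      expect_equal(sort(sub$rank), seq_len(nrow(sub)))   # a permutation
      causal <- fx$cohort$truth$gene[fx$cohort$truth$case_id == cid]
      expect_equal(sub$rank[sub$gene == causal], 1L)     # noiseless: rank 1
    }
  }
  causal_rank_mean <- function(noise, seed) {
    r <- generate_external_ranks(fx$cohort, noise = noise, seed = seed)
    r <- merge(r, fx$cohort$truth[, c("case_id", "gene")],
               by = c("case_id", "gene"))
    mean(r$rank)
  }
  lo <- vapply(1:50, function(s) causal_rank_mean(2, s), numeric(1))
  hi <- vapply(1:50, function(s) causal_rank_mean(15, s), numeric(1))
  expect_gt(mean(hi), mean(lo))  # noise degrades the causal rank on average
})

test_that("the fixture knowledge base is loadable and closes the loop", {
  fx <- small_cohort_bundle()
  expect_no_warning(kb <- load_relations(fx$kb_df))  # zero rejects
  expect_true(all(kb_count(kb, fx$cohort$truth$key) >= 1))
  # every templated sentence gets its embedded trigger highlighted
  for (i in seq_len(min(50, nrow(kb$relations)))) {
    h <- highlight_sentence(kb$relations[i, ])
    expect_match(h, "\\*\\*", info = kb$relations$sentence[i])
  }
})

test_that("cohort directories round-trip through the interchange files", {
  fx <- small_cohort_bundle()
  dir <- file.path(tempdir(), "rt")
  write_cohort(fx$cohort, dir, external_ranks = fx$ranks, kb = fx$kb_df)
  back <- read_cohort(dir)
  expect_length(back$cases, length(fx$cohort$cases))
  v0 <- fx$cohort$cases[[1]]$variants
  v1 <- back$cases[[1]]$variants
  expect_setequal(v0$key, v1$key)
  idx <- match(v0$key, v1$key)
  expect_equal(v0$gt_proband, v1$gt_proband[idx])
  expect_equal(v0$af_eur, v1$af_eur[idx], tolerance = 1e-9)
  expect_equal(v0$func, v1$func[idx])
  expect_identical(sort(back$cases[[1]]$hpo_terms),
                   sort(fx$cohort$cases[[1]]$hpo_terms))
  expect_equal(back$truth$key, fx$cohort$truth$key)
  expect_equal(nrow(back$external_ranks), nrow(fx$ranks))
})
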