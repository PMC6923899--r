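test_that("variant types map through the vocabulary with unknown fallback", {
  expect_equal(classify_variant_type("stopgain"), "stopgain")
  expect_equal(classify_variant_type("nonsynonymous SNV"), "missense")
  expect_equal(classify_variant_type("weird_class"), "unknown")
  expect_equal(classify_variant_type(""), "unknown")
  expect_equal(classify_variant_type(NA_character_), "unknown")
})

test_that("baseline filtration keeps coding/splice and drops the rest", {
  v <- make_variant_table(
    5,
    func = c("synonymous SNV", "nonsynonymous SNV", "intronic",
             "splicing", "splicing"),
    exon_dist = c(0L, 0L, 500L, 5L, 5L),
    splice_z = c(NA, NA, NA, -2.0, 0.5),
    pos = c(100L, 200L, 300L, 400L, 500L))
  out <- baseline_filtration(v)
  # synonymous removed, missense kept, deep intronic removed,
  # splice z -2.0 kept, splice z 0.5 removed
  expect_equal(out$pos, c(200L, 400L))
})

test_that("splice-region boundaries follow the default 10 / 1.8 knobs", {
  cfg <- filter_config()
  expect_true(splice_region_filter(5L, -2.0, cfg))
  expect_false(splice_region_filter(11L, 3.0, cfg))   # distance beyond 10
  expect_false(splice_region_filter(5L, 1.8, cfg))    # strict on |z|
  expect_true(splice_region_filter(10L, 1.81, cfg))   # inclusive on distance
  expect_false(splice_region_filter(5L, NA, cfg))     # missing z never kept
})

test_that("predictor filter keeps on strict max-score exceedance", {
  cfg <- filter_config(predictor_threshold = 0.5)
  v <- make_variant_table(3, score_sift = c(0.2, NA, 0.5),
                          score_cadd = c(0.9, NA, NA))
  keep <- predictor_filter(v, cfg)
  expect_equal(keep, c(TRUE, TRUE, FALSE))  # max 0.9 / all-missing / 0.5 strict
})

test_that("MAF filter is an inclusive ceiling over selected populations", {
  cfg <- filter_config(maf_max = 0.01)
  v <- make_variant_table(3,
                          af_eas = c(0.0001, NA, 0.01),
                          af_eur = c(0.02, NA, 0.005))
  expect_equal(maf_filter(v, cfg), c(FALSE, TRUE, TRUE))
  cfg_eas <- filter_config(maf_max = 0.01, populations = "eas")
  expect_equal(maf_filter(v, cfg_eas), c(TRUE, TRUE, TRUE))
  expect_error(maf_filter(v, filter_config(maf_max = 0.01,
                                           populations = "nope")),
               "unknown population")
})

test_that("zygosity calls cover het, hom, hemizygous, missing and compound het", {
  v <- make_variant_table(5,
                          chrom = c("1", "1", "X", "1", "1"),
                          pos = c(100L, 200L, 5e6L, 400L, 500L),
                          gene = c("A", "A", "B", "C", "C"),
                          gt_proband = c("0/1", "1/1", "0/1", "0/1", "./."))
  v$gt_proband[5] <- NA
  z <- call_zygosity(v, "male")
  expect_equal(z$zygosity, c("heterozygous", "homozygous", "hemizygous",
                             "heterozygous", "missing"))
  # gene A has two proband hets? no: one het + one hom -> not compound
  expect_false(any(z$gene_compound_het[z$gene == "A"]))
  v2 <- make_variant_table(2, gene = "G", gt_proband = c("0/1", "0/1"),
                           pos = c(1L, 2L))
  z2 <- call_zygosity(v2, "female")
  expect_true(all(z2$gene_compound_het))
  # PAR X in a male stays diploid
  vp <- make_variant_table(1, chrom = "X", pos = 100000L, gt_proband = "0/1")
  expect_equal(call_zygosity(vp, "male")$zygosity, "heterozygous")
})

test_that("trio inheritance matches the exhaustive 27-combination oracle", {
  gts <- c("0/0", "0/1", "1/1")
  combos <- expand.grid(p = gts, m = gts, f = gts,
                        stringsAsFactors = FALSE)
  v <- make_variant_table(nrow(combos), pos = seq_len(nrow(combos)),
                          gene = paste0("G", seq_len(nrow(combos))))
  v$gt_proband <- combos$p
  v$gt_mother <- combos$m
  v$gt_father <- combos$f
  got <- infer_inheritance(v, "female")$modes

  # independent oracle: explicit case analysis per combination
  alt <- function(g) sum(strsplit(g, "/")[[1]] == "1")
  for (i in seq_len(nrow(combos))) {
    p <- alt(combos$p[i]); m <- alt(combos$m[i]); f <- alt(combos$f[i])
    want <- character(0)
    if (p >= 1 && m == 0 && f == 0) want <- c(want, "de_novo")
    if (p == 1 && sum(c(m, f) == 1) == 1 && sum(c(m, f) == 0) == 1)
      want <- c(want, "autosomal_dominant")
    if (p == 2 && m == 1 && f == 1) want <- c(want, "autosomal_recessive")
    expect_setequal(got[[i]], want)
  }
})

test_that("male X sites match the 9-combination hemizygous oracle", {
  gts <- c("0/0", "0/1", "1/1")
  combos <- expand.grid(p = gts, m = gts, stringsAsFactors = FALSE)
  v <- make_variant_table(nrow(combos), chrom = "X",
                          pos = 5e6L + seq_len(nrow(combos)),
                          gene = paste0("G", seq_len(nrow(combos))))
  v$gt_proband <- combos$p
  v$gt_mother <- combos$m
  v$gt_father <- "0/0"
  got <- infer_inheritance(v, "male")$modes
  alt <- function(g) sum(strsplit(g, "/")[[1]] == "1")
  for (i in seq_len(nrow(combos))) {
    p <- alt(combos$p[i]); m <- alt(combos$m[i])
    expect_equal("x_linked" %in% got[[i]], p >= 1 && m >= 1,
                 info = paste(combos$p[i], combos$m[i]))
  }
})

test_that("singleton cases have no inheritance output", {
  v <- make_variant_table(3, pos = 1:3, gt_proband = c("0/1", "1/1", "0/1"))
  out <- infer_inheritance(v, "female")
  expect_true(all(vapply(out$modes, length, integer(1)) == 0L))
})

test_that("compound het in trans requires one variant from each parent", {
  v <- make_variant_table(3, gene = "G", pos = 1:3,
                          gt_proband = c("0/1", "0/1", "0/1"))
  v$gt_mother <- c("0/1", "0/0", "0/0")
  v$gt_father <- c("0/0", "0/1", "0/1")
  out <- infer_inheritance(v, "female")
  expect_true(all(vapply(out$modes[1:3], function(m)
    "compound_het_in_trans" %in% m, logical(1))))
  # both hets from the same parent: not in trans
  v2 <- v
  v2$gt_mother <- c("0/1", "0/1", "0/1")
  v2$gt_father <- "0/0"
  out2 <- infer_inheritance(v2, "female")
  expect_false(any(vapply(out2$modes, function(m)
    "compound_het_in_trans" %in% m, logical(1))))
})

test_that("membership filters act on ClinVar class, OMIM and panels", {
  v <- make_variant_table(3, gene = c("BRCA1", "RAF1", "TTN"),
                          clinvar = c("pathogenic", "absent", "benign"),
                          pos = 1:3)
  cfg <- filter_config(clinvar_classes = "pathogenic")
  expect_equal(membership_filters(v, cfg), c(TRUE, FALSE, FALSE))
  cfg2 <- filter_config(require_omim = TRUE)
  expect_equal(membership_filters(v, cfg2, omim_genes = c("BRCA1", "TTN")),
               c(TRUE, FALSE, TRUE))
  cfg3 <- filter_config(panel = "BRCA1")
  expect_equal(membership_filters(v, cfg3), c(TRUE, FALSE, FALSE))
})

test_that("apply_filters is a pure, idempotent, monotone conjunction", {
  set.seed(42)
  n <- 40
  v <- make_variant_table(n, pos = seq_len(n),
                          gene = sample(c("A", "B", "C"), n, TRUE),
                          af_eur = round(runif(n, 0, 0.1), 4),
                          score_cadd = round(runif(n), 3),
                          clinvar = sample(c("absent", "pathogenic", "benign"),
                                           n, TRUE))
  # all filters disabled -> identity
  none <- apply_filters(v, filter_config(), "female")
  expect_equal(none$variants[names(v)], v)
  expect_equal(length(none$removed), 0L)

  cfg <- filter_config(maf_max = 0.05, predictor_threshold = 0.4)
  out <- apply_filters(v, cfg, "female")
  # kept + |union removed| = input size
  union_removed <- sum(!(maf_filter(v, cfg) & predictor_filter(v, cfg)))
  expect_equal(out$n_kept + union_removed, n)
  # idempotence
  again <- apply_filters(out$variants, cfg, "female")
  expect_equal(again$variants, out$variants)
  # enabling one more filter never increases the kept set
  cfg2 <- filter_config(maf_max = 0.05, predictor_threshold = 0.4,
                        clinvar_classes = "pathogenic")
  out2 <- apply_filters(v, cfg2, "female")
  expect_true(all(out2$variants$key %in% out$variants$key))
  # a strictly tighter knob shrinks the kept set
  cfg3 <- filter_config(maf_max = 0.01, predictor_threshold = 0.4)
  out3 <- apply_filters(v, cfg3, "female")
  expect_true(all(out3$variants$key %in% out$variants$key))
})

test_that("default configuration carries the documented knob values", {
  cfg <- filter_config()
  expect_identical(cfg$splice_distance, 10L)
  expect_identical(cfg$splice_z_min, 1.8)
})
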