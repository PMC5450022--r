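mk_dataset <- function(expr, id = "d1", scale = "linear") {
  md <- data.frame(sample = colnames(expr),
                   treatment = ifelse(grepl("^c", colnames(expr)),
                                      "control", sub("_r\\d+$", "",
                                                     colnames(expr))),
                   replicate = 1L,
                   is_control = grepl("^c", colnames(expr)))
  raw_dataset(expr, md, id = id, scale = scale)
}

test_that("normalisation averages replicates then divides by control", {
  expr <- matrix(c(4, 4, 2, 2), nrow = 1,
                 dimnames = list("G1", c("t_r1", "t_r2", "c_r1", "c_r2")))
  out <- normalize_dataset(mk_dataset(expr))
  expect_equal(out["G1", "t"], 1)  # log2(4/2)

  # treatment identical to control -> all zeros
  expr2 <- matrix(c(5, 5, 5, 5), nrow = 1,
                  dimnames = list("G1", c("t_r1", "t_r2", "c_r1", "c_r2")))
  expect_equal(unname(normalize_dataset(mk_dataset(expr2))[1, 1]), 0)

  # two treatments share the single control mean
  expr3 <- matrix(c(8, 2, 4, 4), nrow = 1,
                  dimnames = list("G1", c("a_r1", "b_r1", "c_r1", "c_r2")))
  out3 <- normalize_dataset(mk_dataset(expr3))
  expect_equal(out3["G1", "a"], 1)
  expect_equal(out3["G1", "b"], -1)

  # zero control mean fails naming the gene
  expr4 <- matrix(c(4, 0), nrow = 1, dimnames = list("Gz", c("t_r1", "c_r1")))
  expect_error(normalize_dataset(mk_dataset(expr4)), "Gz")
})

test_that("normalising an already log2-vs-control dataset is a no-op", {
  expr <- matrix(c(1.5, 0.5), nrow = 1,
                 dimnames = list("G1", c("t_r1", "t_r2")))
  md <- data.frame(sample = colnames(expr), treatment = "t",
                   replicate = 1:2, is_control = FALSE)
  ds <- raw_dataset(expr, md, id = "lc", scale = "log2_change")
  expect_equal(unname(normalize_dataset(ds)[1, 1]), 1)  # mean only
  one <- matrix(0.7, 1, 1, dimnames = list("G1", "t_r1"))
  ds1 <- raw_dataset(one, md[1, ], id = "lc1", scale = "log2_change")
  expect_equal(unname(normalize_dataset(ds1)[1, 1]), 0.7)
})

test_that("symbol merging preserves missingness and applies aliases", {
  a <- matrix(c(1, 2), ncol = 1, dimnames = list(c("G1", "G2"), "t"))
  b <- matrix(c(3, 4), ncol = 1, dimnames = list(c("G1", "G3"), "t"))
  comp <- merge_by_symbol(list(dsA = a, dsB = b))
  expect_equal(dim(comp$matrix), c(3L, 2L))
  expect_true(is.na(comp$matrix["G3", "dsA.t"]))
  expect_true(is.na(comp$matrix["G2", "dsB.t"]))
  # merge conservation: non-missing cells = sum of per-dataset gene counts
  expect_equal(sum(!is.na(comp$matrix)), nrow(a) + nrow(b))

  # alias applied before merging -> one row
  c1 <- matrix(1, ncol = 1, dimnames = list("SNAI2", "t"))
  c2 <- matrix(2, ncol = 1, dimnames = list("SLUG", "t"))
  aliases <- data.frame(alias = "SNAI2", official = "SLUG")
  comp2 <- merge_by_symbol(list(x = c1, y = c2), aliases)
  expect_equal(nrow(comp2$matrix), 1L)
  expect_equal(rownames(comp2$matrix), "SLUG")

  # duplicates within a dataset collapse by mean, with a warning
  d <- matrix(c(1, 3), ncol = 1, dimnames = list(c("g1", "G1"), "t"))
  expect_warning(comp3 <- merge_by_symbol(list(z = d)), "collapsed")
  expect_equal(unname(comp3$matrix["G1", 1]), 2)

  expect_error(merge_by_symbol(list()), "no datasets")
})

test_that("up-regulation fractions respect thresholds and missing data", {
  m <- matrix(c(1, 1, 1, 1, 1, 1, 1, 1, 0.2, 0.2), nrow = 1,
              dimnames = list("G", paste0("c", 1:10)))
  comp <- structure(list(matrix = m, provenance = NULL),
                    class = "merged_compendium")
  expect_equal(upregulation_fraction(comp, "G", 1.5)$percent, 80)
  expect_equal(upregulation_fraction(comp, "G", 1)$percent, 100)
  m2 <- m; m2[1, 6:10] <- NA
  comp2 <- structure(list(matrix = m2, provenance = NULL),
                     class = "merged_compendium")
  f <- upregulation_fraction(comp2, "G", 1.5)
  expect_equal(f$percent, 100)
  expect_equal(f$basis, 5)
  expect_error(upregulation_fraction(comp, "NOPE", 1.5), "absent")
})

test_that("the synthetic compendium recovers its construction", {
  cfg <- compendium_config(n_datasets = 30L, seed = 77L)
  comp <- generate_compendium(cfg)
  expect_length(comp$datasets, 30L)
  expect_equal(nrow(comp$truth), 30L)
  # determinism
  comp2 <- generate_compendium(cfg)
  expect_identical(comp$datasets[[5]]$expr, comp2$datasets[[5]]$expr)
  expect_error(compendium_config(n_datasets = 0), "positive")

  normalized <- lapply(comp$datasets, normalize_dataset)
  merged <- merge_by_symbol(normalized, default_alias_table())
  expect_equal(ncol(merged$matrix), 30L)

  # Stat3 up-regulation fraction matches the closed-form Normal tail
  # within 3 binomial standard errors
  f <- upregulation_fraction(merged, "Stat3", 1.5)
  sd_tot <- sqrt(cfg$sigma_b^2 +
                   cfg$sigma_rep^2 * (2 / cfg$replicates))
  p <- stats::pnorm(log2(1.5), cfg$b, sd_tot, lower.tail = FALSE)
  se3 <- 3 * sqrt(p * (1 - p) / 30)
  expect_lt(abs(f$percent / 100 - p), se3)
  # the paper-level claim holds under the default effect model
  expect_gt(f$percent, 70)
})

test_that("strong-EMT stratification enriches the coupled genes only", {
  cfg <- compendium_config(n_datasets = 40L, seed = 123L)
  comp <- generate_compendium(cfg)
  merged <- merge_by_symbol(lapply(comp$datasets, normalize_dataset),
                            default_alias_table())
  strat <- stratify_by_emt(merged, cfg$signature)
  enr <- strat$enrichment
  # per-column EMT score orders with the true strength s
  s_truth <- comp$truth$s[match(sub("\\.emt1$", "", names(strat$scores)),
                                comp$truth$dataset)]
  expect_gt(stats::cor(strat$scores, s_truth, method = "spearman"), 0.9)
  # Sox2 (threshold-coupled) strictly enriched in the strong group
  expect_gt(enr$difference[enr$gene == "Sox2"], 0)
  # Stat3 (strength-independent) roughly equal: within binomial noise
  p_stat3 <- mean(merged$matrix["STAT3", ] > log2(1.5))
  se <- sqrt(p_stat3 * (1 - p_stat3) * (1 / 10 + 1 / 30)) * 3
  expect_lt(abs(enr$difference[enr$gene == "Stat3"]) / 100, se + 1e-12)
  expect_error(stratify_by_emt(
    structure(list(matrix = merged$matrix[, 1:3], provenance = NULL),
              class = "merged_compendium"), cfg$signature), "4 columns")
})
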