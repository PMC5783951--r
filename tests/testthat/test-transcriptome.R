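make_ds <- function(values, stage = NULL, line = NULL, id = "ds") {
  if (is.null(colnames(values)))
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  samples <- data.frame(sample = colnames(values))
  if (!is.null(stage)) samples$stage <- stage
  if (!is.null(line)) samples$line <- line
  expression_dataset(values, samples, id = id)
}

test_that("missing-value filtering honours the configurable markers", {
  v <- rbind(g1 = c(1, 2), g2 = c(NA, 3), g3 = c(4, 5))
  colnames(v) <- c("s1", "s2")
  ds <- make_ds(v)
  expect_message(out <- filter_missing(ds), "dropped 1 of 3")
  expect_identical(rownames(out$values), c("g1", "g3"))

  # same result whichever dialect marks the gap
  v2 <- v; v2[2, 1] <- -999
  expect_identical(
    rownames(suppressMessages(filter_missing(make_ds(v2),
                                             sentinels = -999))$values),
    c("g1", "g3"))
  v3 <- v; v3[2, 1] <- -1
  expect_identical(
    rownames(suppressMessages(filter_missing(make_ds(v3),
                                             negative_missing = TRUE))$values),
    c("g1", "g3"))

  # no missing values: identity
  clean <- make_ds(rbind(g1 = c(1, 2)))
  expect_equal(suppressMessages(filter_missing(clean))$values, clean$values)
  allbad <- make_ds(rbind(g1 = c(NA, 1)))
  expect_error(filter_missing(allbad), "no genes left")
})

test_that("mean normalization equalizes grand means without touching ratios", {
  d1 <- make_ds(rbind(g1 = c(1, 3), g2 = c(2, 2)))   # mean 2
  d2 <- make_ds(rbind(g1 = c(2, 6), g2 = c(4, 4)))   # mean 4
  out <- normalize_mean(list(d1, d2), target = 1)
  expect_equal(mean(out[[1]]$values), 1)
  expect_equal(mean(out[[2]]$values), 1)
  expect_equal(out[[1]]$values / d1$values,
               matrix(0.5, 2, 2, dimnames = dimnames(d1$values)))
  # idempotent
  again <- normalize_mean(out, target = 1)
  expect_equal(again[[1]]$values, out[[1]]$values)
  zero <- make_ds(rbind(g1 = c(0, 0)))
  expect_error(normalize_mean(list(zero)), "zero mean")
})

test_that("classification is invariant to per-dataset rescaling", {
  trips <- gen_triplets(triplet_spec(n_genes = 300, seed = 4))
  scaled <- trips
  scaled[c("L_o", "L_p", "L_a")] <- scaled[c("L_o", "L_p", "L_a")] * 7.3
  expect_identical(classify_traits(trips, theta = 0.2)$category,
                   classify_traits(scaled, theta = 0.2)$category)
})

test_that("replicate averaging takes gene-wise means per group", {
  v <- cbind(r1 = c(g1 = 2, g2 = 10), r2 = c(4, 20), r3 = c(9, 30))
  ds <- make_ds(v, stage = c("a", "a", "a"), line = c("L1", "L1", "L2"))
  expect_message(out <- average_replicates(ds, "line"), "2 groups")
  expect_equal(out$values[, "L1"], c(g1 = 3, g2 = 15))
  expect_equal(out$values[, "L2"], c(g1 = 9, g2 = 30))
  expect_identical(out$samples$stage, c("a", "a"))
  # single replicate: identity values
  one <- suppressMessages(average_replicates(make_ds(v[, 1, drop = FALSE]),
                                             "r1"))
  expect_equal(unname(one$values[, 1]), unname(v[, 1]))
  expect_error(average_replicates(ds, c("a", NA, "b")), "missing")
})

test_that("triplet building follows the case manifest", {
  v <- cbind(anc_o = c(g1 = 1, g2 = 2), anc_p = c(2, 1),
             ev1 = c(3, 3), ev2 = c(5, 7))
  ds <- make_ds(v)
  manifest <- list(
    case1 = list(o = "anc_o", p = "anc_p", a = "ev1"),
    case2 = list(o = "anc_o", p = "anc_p", a = c("ev1", "ev2")))
  out <- build_triplets(ds, manifest)
  expect_named(out, c("case1", "case2"))
  # shared ancestor: identical L_o and L_p columns
  expect_equal(out$case1$L_o, out$case2$L_o)
  expect_equal(out$case1$L_p, out$case2$L_p)
  expect_equal(out$case2$L_a, c(4, 5))      # averaged evolved lines
  expect_error(build_triplets(ds, list(c1 = list(o = "anc_o", p = "anc_p"))),
               "missing stage 'a'")
  expect_error(build_triplets(ds, list(c1 = list(o = "anc_o", p = "ghost",
                                                 a = "ev1"))),
               "not in dataset")
})

test_that("YAML manifests load into the build_triplets layout", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("cases:",
               "  caseA:",
               "    o: [s1]", "    p: [s2]", "    a: [s3, s4]"), path)
  mf <- read_case_manifest(path)
  expect_named(mf, "caseA")
  expect_identical(unlist(mf$caseA$a), c("s3", "s4"))
})

test_that("growth-rate independence means non-monotone across ordered rates", {
  m <- rbind(inc = c(1, 2, 3, 4),
             wobble = c(1, 3, 2, 4),
             dec_tie = c(4, 4, 2, 1),
             flat = c(2, 2, 2, 2))
  mask <- growth_independent_mask(m)
  expect_identical(unname(mask), c(FALSE, TRUE, FALSE, FALSE))
  # strict convention: a tie breaks monotonicity
  strict <- growth_independent_mask(m, strict = TRUE)
  expect_identical(unname(strict), c(FALSE, TRUE, TRUE, TRUE))
  expect_error(growth_independent_mask(m[, 1:2]), ">= 3")
  expect_error(growth_independent_mask(m, rates = c(0.4, 0.2, 0.1, 0.5)),
               "increasing order")
})

test_that("expression matrices round-trip through delimited text", {
  v <- cbind(s1 = c(g1 = 1.5, g2 = 0), s2 = c(2.5, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(gene = rownames(v), v), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  got <- read_expression_matrix(path)
  expect_equal(got, v)
})

test_that("the synthetic multi-case bundle reproduces its planted sign structure", {
  bundle <- gen_case_bundle(n_cases = 12, n_reversion_excess = 11,
                            n_genes = 800, seed = 21)
  res <- classify_cases(bundle$cases, theta = 0.2)
  d <- res$summaries[res$summaries$theta == 0.2, ]
  expect_identical(d$c_rv > d$c_ri, bundle$truth$planted_rv_excess)
  st <- res$sign_tests[res$sign_tests$theta == 0.2, ]
  expect_equal(st$rv_excess, 11)
  expect_equal(st$p_two_tailed, binom_two_tailed(11, 12))
})
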