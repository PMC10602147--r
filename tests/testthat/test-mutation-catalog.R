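# Filter cascade semantics and accounting, pyrimidine-strand classification,
# catalog construction and arm comparisons.

test_that("filter boundaries are inclusive per the stated thresholds", {
  keepOne <- function(v) filterVariants(v)$audit[["kept"]] == 1L
  indel <- function(len) variantRow(
    variant_type = "deletion", alt = "A", context = "AAA",
    ref = paste(rep("A", len + 1L), collapse = ""))
  expect_true(keepOne(indel(10)))   # length 10 kept
  expect_false(keepOne(indel(11)))  # greater than 10 removed
  expect_true(keepOne(variantRow(maf = 0.10)))
  expect_false(keepOne(variantRow(maf = 0.09)))
  expect_true(keepOne(variantRow(depth_tumor = 10L, depth_normal = 10L)))
  expect_false(keepOne(variantRow(depth_tumor = 9L)))
  expect_false(keepOne(variantRow(depth_normal = 9L)))  # joint coverage rule
  expect_true(keepOne(variantRow(alt_reads = 3L)))
  expect_false(keepOne(variantRow(alt_reads = 2L)))
  expect_false(keepOne(variantRow(known_polymorphism = TRUE)))
  expect_false(keepOne(variantRow(in_exome_interval = FALSE)))
})

test_that("audit counts sum to input size and the cascade is idempotent", {
  v <- randomVariants(500, seed = 11)
  f <- filterVariants(v)
  expect_equal(sum(f$audit), nrow(v))
  again <- filterVariants(f$kept)
  expect_equal(again$audit[["kept"]], nrow(f$kept))
  expect_equal(sum(again$audit) - again$audit[["kept"]], 0L)
  # attribution goes to the FIRST failing rule
  both <- variantRow(maf = 0.01, alt_reads = 0L)
  expect_equal(filterVariants(both)$audit[["low_maf"]], 1L)
  # empty input -> zero audit
  e <- filterVariants(v[0, ])
  expect_equal(sum(e$audit), 0L)
})

test_that("tightening any threshold never increases the kept count", {
  v <- randomVariants(400, seed = 12)
  base <- filterVariants(v)$audit[["kept"]]
  tighter <- list(filterConfig(maxIndelLen = 5),
                  filterConfig(minMaf = 0.2),
                  filterConfig(minDepth = 20),
                  filterConfig(minAltReads = 6))
  for (cfg in tighter) {
    k <- filterVariants(v, cfg)$audit[["kept"]]
    expect_lte(k, base)
    # brute-force oracle: re-filter with a per-record predicate
    ok <- with(v, !(variant_type != "SNV" &
                      abs(nchar(ref) - nchar(alt)) > cfg$maxIndelLen) &
                 maf >= cfg$minMaf &
                 depth_tumor >= cfg$minDepth & depth_normal >= cfg$minDepth &
                 alt_reads >= cfg$minAltReads &
                 !known_polymorphism & in_exome_interval)
    expect_equal(k, sum(ok))
  }
})

test_that("SNV classification folds to the pyrimidine strand", {
  r <- classifySNV("G", "A", "TGA")
  expect_equal(r$class, "C>T")
  expect_equal(r$label, "T[C>T]A")
  r2 <- classifySNV("C", "A", "ACG")
  expect_equal(r2$class, "C>A")
  expect_equal(r2$label, "A[C>A]G")
  # strand symmetry: a variant and its reverse complement classify equally
  withr::with_seed(3, {
    labs <- sample(contextLabels96(), 25)
  })
  ref <- substr(labs, 3, 3); alt <- substr(labs, 5, 5)
  ctx <- paste0(substr(labs, 1, 1), ref, substr(labs, 7, 7))
  fwd <- classifySNV(ref, alt, ctx)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rcx <- vapply(strsplit(ctx, ""), function(b)
    paste(rev(comp[b]), collapse = ""), "")
  rev <- classifySNV(unname(comp[ref]), unname(comp[alt]), rcx)
  expect_equal(fwd, rev)
  # exactly 96 reachable labels, 16 per class
  expect_equal(length(unique(fwd$label)), length(unique(labs)))
  all96 <- contextLabels96()
  expect_equal(length(all96), 96)
  expect_equal(as.vector(table(sub("^.\\[(.>.)\\].$", "\\1", all96))),
               rep(16L, 6))
  expect_warning(bad <- classifySNV("N", "A", "ANA"), "skipped")
  expect_true(is.na(bad$class))
})

test_that("catalogs satisfy count conservation and skip non-SNVs", {
  v <- rbind(variantRow(), variantRow(pos = 200L),
             variantRow(pos = 300L, ref = "C", alt = "A", context = "ACG"),
             variantRow(pos = 400L, variant_type = "deletion",
                        ref = "CAT", alt = "C", context = "ACA"))
  v$ref[1:2] <- "C"; v$alt[1:2] <- "T"; v$context[1:2] <- "ACG"
  cat1 <- buildCatalogs(v, data.frame(clone_id = "c1", genotype = "WT",
                                      treatment = "TMZ"))
  cc <- classCounts(cat1)
  expect_equal(unname(cc["C>T", 1]), 2)
  expect_equal(unname(cc["C>A", 1]), 1)
  expect_equal(unname(totalSNV(cat1)), 3)  # the indel is not counted
  expect_equal(sum(assay(cat1, "contexts")), 3)
  expect_equal(colSums(cc), totalSNV(cat1))
  expect_equal(unname(assay(cat1, "contexts")["A[C>T]G", 1]), 2)

  # a clone with zero SNVs keeps a valid all-zero catalog
  cat2 <- buildCatalogs(v, data.frame(clone_id = c("c1", "c9"),
                                      genotype = "WT", treatment = "TMZ"))
  expect_equal(unname(totalSNV(cat2)[["c9"]]), 0)
})

test_that("arm comparison recovers induced mutation loads", {
  mk <- function(totT, totD) {
    tot <- c(totT, totD)
    trt <- rep(c("TMZ", "DMSO"), c(length(totT), length(totD)))
    m <- matrix(0L, 96, length(tot),
                dimnames = list(contextLabels96(), NULL))
    m[1, ] <- tot
    CatalogExperiment(m, data.frame(
      clone_id = paste0(trt, seq_along(tot)), genotype = "WT",
      treatment = trt))
  }
  r <- compareArms(mk(c(10L, 12L, 14L), c(4L, 6L, 5L)), perClass = FALSE)
  expect_equal(r$induced[r$class == "total"], 7)
  expect_equal(r$pattern, NA_character_)

  r2 <- compareArms(mk(c(5L, 5L), c(5L, 5L)), perClass = FALSE)
  expect_equal(r2$induced, 0)
  expect_equal(r2$p_value, 1)

  # generator oracle: arms differing by 400 expected SNVs, 6 clones/arm
  sigs <- randomSignatures(2)
  arms <- data.frame(genotype = "WT", treatment = c("DMSO", "TMZ"),
                     n_clones = 6L)
  act <- cbind(c(50, 0), c(450, 0))
  sim <- simulateCatalogs(arms, sigs, act, seed = 14)
  r3 <- compareArms(sim$catalogs, perClass = TRUE)
  tot <- r3[r3$class == "total", ]
  se <- sqrt(450 / 6 + 50 / 6)  # Poisson SE of the mean difference
  expect_lt(abs(tot$induced - 400), 3 * se)
  expect_equal(r3$pattern[r3$class == "C>T"], "Pattern I")
  expect_true(all(r3$pattern[!r3$class %in% c("total", "C>T")] ==
                    "Pattern II"))
})
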