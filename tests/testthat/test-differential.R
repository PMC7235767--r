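test_that("BH adjustment matches hand cases and both oracles", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "digestor_domain_error")
  expect_error(bh_adjust(c(-0.1)), class = "digestor_domain_error")

  set.seed(5)
  for (m in c(3, 17, 80, 200)) {
    p <- runif(m)^2
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_equal(adj, stats::p.adjust(p, method = "BH"),
                 tolerance = 1e-12)
    expect_true(all(adj >= p))                       # never below raw
    expect_equal(order(adj[order(p)]), seq_len(m))   # monotone in ranks
  }
})

test_that("significance filtering is strict at alpha and splits by sign", {
  res <- data.frame(taxon = c("a", "b", "c"),
                    log2fc = c(2, -2, 1),
                    padj = c(0.05, 0.01, 0.049))
  s <- significant_shifts(res, alpha = 0.05)
  expect_equal(s$increased, "c")       # padj == alpha excluded
  expect_equal(s$decreased, "b")

  empty <- significant_shifts(data.frame(taxon = character(),
                                         log2fc = numeric(),
                                         padj = numeric()))
  expect_length(empty$increased, 0)
  expect_length(empty$decreased, 0)

  # constructed 20-taxon fixture: 6 planted positives
  set.seed(8)
  fix <- data.frame(taxon = sprintf("t%02d", 1:20),
                    log2fc = c(rep(3, 3), rep(-3, 3), rnorm(14, 0, 0.1)),
                    padj = c(rep(1e-4, 6), runif(14, 0.2, 1)))
  sf <- significant_shifts(fix)
  expect_setequal(sf$increased, sprintf("t%02d", 1:3))
  expect_setequal(sf$decreased, sprintf("t%02d", 4:6))
  expect_length(intersect(sf$increased, sf$decreased), 0)

  expect_error(significant_shifts(data.frame(taxon = "a", log2fc = 1)),
               class = "digestor_contract_error")
})

test_that("Venn classification assigns regions and directions", {
  mk <- function(inc, dec) structure(list(increased = inc, decreased = dec),
                                     class = "shift_sets")
  shifts <- list(nal = mk(c("x", "y"), character()),
                 gaba = mk("x", "y"),
                 phos = mk("x", character()))
  v <- venn_classify(shifts)
  ax <- v$assignments[v$assignments$taxon == "x", ]
  expect_equal(ax$region, "nal&gaba&phos")
  expect_equal(ax$direction, "increase")
  ay <- v$assignments[v$assignments$taxon == "y", ]
  expect_equal(ay$region, "nal&gaba")
  expect_equal(ay$direction, "conflict")
  expect_equal(v$total, 2L)
  expect_error(venn_classify(shifts[1:2]), class = "digestor_domain_error")
})

test_that("Venn regions match exhaustive enumeration on a random fixture", {
  set.seed(31)
  conds <- c("A", "B", "C")
  taxa <- sprintf("g%02d", 1:30)
  inc <- list(); dec <- list()
  for (cn in conds) {
    sig <- sample(taxa, 12)
    up <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    inc[[cn]] <- sig[up]; dec[[cn]] <- sig[!up]
  }
  shifts <- lapply(conds, function(cn) {
    structure(list(increased = inc[[cn]], decreased = dec[[cn]]),
              class = "shift_sets")
  })
  names(shifts) <- conds
  v <- venn_classify(shifts)
  orc <- oracle_venn(inc, dec, conds)
  got <- v$assignments[order(v$assignments$taxon), ]
  want <- orc[order(orc$taxon), ]
  expect_equal(got$region, want$region)
  expect_equal(got$direction, want$direction)
  expect_equal(v$total, nrow(want))

  # permutation invariance up to region relabelling
  perm <- venn_classify(shifts[c(2, 3, 1)])
  expect_equal(perm$total, v$total)
  expect_equal(sort(table(perm$assignments$direction)),
               sort(table(v$assignments$direction)))
  norm_region <- function(r) paste(sort(strsplit(r, "&")[[1]]),
                                   collapse = "&")
  expect_equal(
    sort(vapply(perm$assignments$region, norm_region, character(1),
                USE.NAMES = FALSE)),
    sort(vapply(v$assignments$region, norm_region, character(1),
                USE.NAMES = FALSE)))
})

test_that("fallback DA test controls the null and finds planted signal", {
  depth <- 20000
  base <- c(rep(0.05, 10), rep(0.005, 10))
  build <- function(p1, p2, seed, reps = 5) {
    set.seed(seed)
    counts <- rbind(
      t(stats::rmultinom(reps, depth, p1)),
      t(stats::rmultinom(reps, depth, p2)))
    rownames(counts) <- sprintf("s%d", 1:(2 * reps))
    colnames(counts) <- sprintf("t%02d", seq_along(p1))
    abundance_table(counts, samples = data.frame(
      sample_id = rownames(counts),
      condition = rep(c("trt", "ctl"), each = reps),
      day = 56, replicate = rep(1:reps, 2)))
  }
  # null: identical groups; family-wise false discovery rate <= 5%
  hits <- vapply(1:100, function(s) {
    res <- fallback_da_test(build(base, base, s), "trt", "ctl", 56)
    any(res$padj < 0.05)
  }, logical(1))
  expect_gte(sum(!hits), 95)

  # planted 8-fold enrichment of taxon 1
  planted <- base; planted[1] <- planted[1] * 8
  planted <- planted / sum(planted)
  res <- fallback_da_test(build(planted / 1, base, 7, reps = 5),
                          "trt", "ctl", 56)
  expect_equal(res$taxon[which.min(res$pvalue)], "t01")
  expect_gt(res$log2fc[1], 0)
  expect_equal(attr(res, "method"), "fallback-clr-welch")

  # constant-zero taxon gets p = 1 by convention
  tab <- build(base, base, 3)
  tab$counts[, "t20"] <- 0
  res0 <- fallback_da_test(tab, "trt", "ctl", 56)
  expect_equal(res0$pvalue[res0$taxon == "t20"], 1)

  two <- build(base, base, 4, reps = 2)
  keep <- two$samples$replicate == 1 | two$samples$condition == "ctl"
  small <- abundance_table(two$counts[keep, ], two$samples[keep, ])
  expect_error(fallback_da_test(small, "trt", "ctl", 56),
               class = "digestor_replication_error")
})

test_that("external DA tables honour the TSV contract", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tlog2fc\tpvalue",
               "g1\t1.5\t0.001", "g2\t-2\t0.2"), path)
  df <- read_da_results(path)
  s <- significant_shifts(df, alpha = 0.05)
  expect_equal(s$increased, "g1")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon\tfold", "g1\t2"), bad)
  expect_error(read_da_results(bad), class = "digestor_contract_error")
})
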