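test_that("relative abundance closes each sample and flags empty ones", {
  counts <- matrix(c(2, 2, 0, 0), 2, 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("t1", "t2")))
  p <- relative_abundance(abundance_table(counts))
  expect_equal(unname(p$proportions["s1", ]), c(0.5, 0.5))
  expect_true(all(is.na(p$proportions["s2", ])))
  expect_equal(unname(p$empty_samples), c(FALSE, TRUE))

  set.seed(1)
  big <- matrix(rpois(50 * 30, 5), 50, 30)
  pb <- relative_abundance(abundance_table(big))
  expect_equal(unname(rowSums(pb$proportions)), rep(1, 50),
               tolerance = 1e-9)
})

test_that("rank aggregation conserves totals and groups unresolved taxa", {
  tab <- toy_table()
  phy <- aggregate_rank(tab, "phylum")
  expect_equal(unname(rowSums(phy$counts)), unname(rowSums(tab$counts)))
  expect_equal(phy$counts[, "Firmicutes"],
               tab$counts[, "otu1"] + tab$counts[, "otu2"])
  expect_true("unclassified-Bacteria" %in% colnames(phy$counts))

  gen <- aggregate_rank(tab, "genus")
  expect_true("unclassified-Bacteroidetes" %in% colnames(gen$counts))
  expect_equal(unname(rowSums(gen$counts)), unname(rowSums(tab$counts)))

  # already at rank: aggregation is the identity on counts
  again <- aggregate_rank(phy, "phylum")
  expect_equal(sort(colnames(again$counts)), sort(colnames(phy$counts)))
  expect_equal(again$counts[, sort(colnames(again$counts))],
               phy$counts[, sort(colnames(phy$counts))])

  expect_error(aggregate_rank(tab, "species"),
               class = "digestor_domain_error")
})

test_that("top_taxa matches the exhaustive sort oracle and breaks ties", {
  set.seed(7)
  counts <- matrix(rpois(20 * 200, 3), 20, 200,
                   dimnames = list(sprintf("s%02d", 1:20),
                                   sprintf("otu%03d", 1:200)))
  p <- relative_abundance(abundance_table(counts))
  expect_equal(as.character(top_taxa(p, 25)),
               oracle_top_taxa(p$proportions, 25))

  tie <- matrix(c(3, 3, 1, 3, 3, 1), 2, 3, byrow = TRUE,
                dimnames = list(c("s1", "s2"), c("zed", "abc", "mid")))
  pt <- relative_abundance(abundance_table(tie))
  expect_equal(as.character(top_taxa(pt, 2)), c("abc", "zed"))
  expect_warning(res <- top_taxa(pt, 5), "exceeds taxon count")
  expect_length(res, 3)
})

test_that("intersect_top returns taxa in every condition's top-N", {
  mk <- function(v) {
    counts <- matrix(v, 1, length(v),
                     dimnames = list("s", sprintf("t%02d", seq_along(v))))
    relative_abundance(abundance_table(counts))
  }
  same <- list(a = mk(c(5, 4, 3, 2, 1)), b = mk(c(5, 4, 3, 2, 1)))
  expect_equal(length(intersect_top(same, n = 3)), 3)

  disjoint <- list(a = mk(c(9, 9, 1, 1)), b = mk(c(1, 1, 9, 9)))
  expect_length(intersect_top(disjoint, n = 2), 0)

  # 4 conditions engineered to share exactly 7 of their top 10
  set.seed(11)
  shared <- sprintf("shared%02d", 1:7)
  profs <- lapply(1:4, function(k) {
    own <- sprintf("own%d_%02d", k, 1:3)
    rest <- sprintf("rare%02d", 1:10)
    ids <- c(shared, own, rest)
    v <- c(runif(7, 50, 100), runif(3, 30, 45), runif(10, 1, 5))
    counts <- matrix(round(v), 1, length(v), dimnames = list("s", ids))
    relative_abundance(abundance_table(counts))
  })
  names(profs) <- paste0("cond", 1:4)
  got <- intersect_top(profs, n = 10)
  expect_setequal(got, shared)
  expect_error(intersect_top(profs[1], n = 10))
})

test_that("Bray-Curtis has the right values and metric properties", {
  counts <- matrix(c(1, 1, 0, 0,
                     1, 1, 0, 0,
                     0, 0, 1, 1,
                     2, 2, 0, 0), 4, 4, byrow = TRUE,
                   dimnames = list(paste0("s", 1:4), paste0("t", 1:4)))
  p <- relative_abundance(abundance_table(counts))
  bc <- bray_curtis(p)
  expect_equal(bc["s1", "s2"], 0)            # identical profiles
  expect_equal(bc["s1", "s3"], 1)            # disjoint supports
  expect_equal(bc["s1", "s4"], 0)            # closure removes scale
  x <- c(0.5, 0.5); y <- c(1, 0)
  expect_equal(oracle_bray_curtis(x, y), 0.5)

  set.seed(3)
  rc <- matrix(rpois(12 * 30, 4) + 1, 12, 30)
  pr <- relative_abundance(abundance_table(rc))
  b <- bray_curtis(pr)
  expect_equal(b, t(b))
  expect_equal(unname(diag(b)), rep(0, 12))
  expect_true(all(b >= 0 & b <= 1))
  # against vegan, the field-standard implementation
  vg <- as.matrix(vegan::vegdist(pr$proportions, method = "bray"))
  expect_equal(unname(b), unname(vg), tolerance = 1e-12)

  empty <- rbind(rc[1:2, ], 0)
  pe <- relative_abundance(abundance_table(empty))
  be <- bray_curtis(pe)
  expect_true(all(is.na(be[3, ])))
})

test_that("PCoA recovers configurations and reports negative eigenvalues", {
  # two samples: one axis at +/- d/2
  d2 <- matrix(c(0, 0.8, 0.8, 0), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  o2 <- ordinate(d2, k = 2)
  expect_equal(unname(sort(abs(o2$points[, 1]))), c(0.4, 0.4),
               tolerance = 1e-12)

  # Euclidean distances of known 2-D points: recovered up to rotation
  set.seed(9)
  pts <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(dist(pts))
  o <- ordinate(d, k = 2)
  pc <- scale(pts, scale = FALSE)
  oc <- scale(o$points, scale = FALSE)
  sv <- svd(t(oc) %*% pc)
  rot <- sv$u %*% t(sv$v)
  expect_lt(max(abs(oc %*% rot - pc)), 1e-8)

  # all-equal dissimilarities among 3 samples: equilateral, equal eig
  d3 <- matrix(0.6, 3, 3); diag(d3) <- 0
  o3 <- ordinate(d3, k = 2)
  expect_equal(o3$eig[1], o3$eig[2], tolerance = 1e-9)
  expect_equal(unname(dist(o3$points)[1:3]), rep(0.6, 3),
               tolerance = 1e-9)

  # Bray-Curtis is non-Euclidean: negative eigenvalues must be visible
  set.seed(13)
  cc <- matrix(rpois(10 * 8, 2), 10, 8) + 1
  bb <- bray_curtis(relative_abundance(abundance_table(cc)))
  ob <- ordinate(bb, k = 3)
  expect_true(length(ob$eig) > 3)
  expect_true(all(ob$explained >= 0))

  ns <- matrix(c(0, 1, 2, 0), 2, 2)
  expect_error(ordinate(ns), class = "digestor_domain_error")
})
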