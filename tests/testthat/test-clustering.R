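test_that("standardization centers to population z-scores and is idempotent", {
  m <- cbind(a = c(1, 2, 3), b = c(10, 0, 5))
  z <- standardize_features(m)
  expect_equal(z[, "a"], c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(standardize_features(z), z, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_warning(z2 <- standardize_features(cbind(m, const = c(4, 4, 4))),
                 "const")
  expect_equal(ncol(z2), 2)
  expect_error(suppressWarnings(standardize_features(cbind(c(1, 1, 1)))),
               "no columns")
})

test_that("three collinear points agglomerate as hand-computed under average linkage", {
  m <- matrix(c(0, 1, 10), ncol = 1, dimnames = list(c("0", "1", "10"), "x"))
  tree <- cluster_treatments(m, linkage = "average")
  expect_equal(sort(tree$hclust$height), c(1, 9.5))
  expect_equal(export_dendrogram(tree), "((0:1,1:1):8.5,10:9.5);")

  cut <- cut_tree(tree, 0.5)
  expect_equal(unname(cut[c("0", "1")]), c(1, 1))
  expect_false(cut[["10"]] == cut[["0"]])
  expect_equal(length(unique(cut_tree(tree, 1))), 1)
  expect_equal(length(unique(cut_tree(tree, 0))), 3)
  expect_error(cut_tree(tree, 1.5), "fraction")
  expect_error(cut_tree(tree, -0.1), "fraction")
})

test_that("identical treatments merge first at height zero", {
  m <- rbind(A = c(1, 2), B = c(1, 2), C = c(5, 9))
  tree <- cluster_treatments(m, linkage = "average")
  expect_equal(min(tree$hclust$height), 0)
  sides <- root_split(tree)
  expect_true(any(vapply(sides, function(s) setequal(s, c("A", "B")),
                         logical(1))))
})

test_that("Newick export round-trips labels and heights through ape", {
  set.seed(41)
  m <- matrix(rnorm(8 * 3), 8, 3,
              dimnames = list(c("a", "b", "c d", "e(f)", "g", "h", "i", "j"), NULL))
  tree <- cluster_treatments(standardize_features(m), linkage = "ward")
  ph <- ape::read.tree(text = export_dendrogram(tree))
  unquote <- function(x) gsub("''", "'", sub("^'(.*)'$", "\\1", x))
  expect_setequal(unquote(ph$tip.label), rownames(m))
  # ultrametric: every root-to-tip path equals the root merge height
  depths <- ape::node.depth.edgelength(ph)[seq_along(ph$tip.label)]
  expect_equal(depths, rep(max(tree$hclust$height), 8), tolerance = 1e-9)
})

test_that("merge heights are monotone and invariant to row permutation", {
  set.seed(42)
  for (linkage in c("ward", "average", "complete")) {
    m <- matrix(rnorm(12 * 4), 12, 4,
                dimnames = list(paste0("r", 1:12), paste0("c", 1:4)))
    tree <- cluster_treatments(m, linkage = linkage)
    expect_true(all(diff(tree$hclust$height) >= -1e-12))
    perm <- sample(12)
    tree_p <- cluster_treatments(m[perm, ], linkage = linkage)
    expect_equal(sort(tree_p$hclust$height), sort(tree$hclust$height),
                 tolerance = 1e-12)
    part <- function(tr) unname(lapply(split(names(cutree(tr$hclust, k = 3)),
                                             cutree(tr$hclust, k = 3)), sort))
    expect_setequal(part(tree_p), part(tree))
  }
})

test_that("average-linkage heights match a brute-force agglomeration", {
  set.seed(43)
  for (i in 1:5) {
    m <- matrix(rnorm(6 * 3), 6, 3)
    rownames(m) <- paste0("t", 1:6)
    tree <- cluster_treatments(m, linkage = "average")
    expect_equal(sort(tree$hclust$height), brute_average_heights(m),
                 tolerance = 1e-10)
  }
})

test_that("cophenetic distances dominate Euclidean ones under complete linkage", {
  set.seed(44)
  for (i in 1:5) {
    m <- matrix(rnorm(7 * 3), 7, 3)
    rownames(m) <- paste0("t", 1:7)
    tree <- cluster_treatments(m, linkage = "complete")
    expect_true(all(as.vector(stats::cophenetic(tree$hclust)) >=
                      as.vector(dist(m)) - 1e-12))
  }
})

test_that("a temperature-dominated table splits by temperature at the root", {
  m <- structured_treatment_matrix(temp_effect = 3, pretreat_effect = 1,
                                   seed = 45)
  tree <- cluster_treatments(standardize_features(m), linkage = "ward")
  sides <- root_split(tree)
  temps <- lapply(sides, function(s) sub(".*_", "", s))
  expect_setequal(lapply(temps, function(x) sort(unique(x))),
                  list(c("55", "60"), c("65", "70")))
})
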