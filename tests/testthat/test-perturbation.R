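# Deterministic chain fixture: X feeds A feeds B; C is isolated and ON.
chain_model <- function() {
  parse_model(c("X = X", "A = X", "B = A", "C = C"))
}
chain_config <- function(...) {
  sim_config(iterations = 20, repetitions = 1,
             update_scheme = "synchronous",
             initial_state = c(X = 1, C = 1), ...)
}

test_that("knockouts leave unreachable nodes at PI exactly 1", {
  km <- knockout_matrix(chain_model(), chain_config())
  expect_equal(km$PI["B", "A"], 1)     # B is downstream of A
  expect_equal(km$PI["B", "X"], 1)
  expect_equal(km$PI["C", "A"], 1)     # C is isolated
  expect_equal(km$PI["A", "C"], 1)
  # A KO silences B: PI collapses to the epsilon floor
  expect_equal(km$PI["A", "B"], km$epsilon / (1 + km$epsilon))
})

test_that("a knocked-out node with positive baseline scores PI at the epsilon floor", {
  km <- knockout_matrix(chain_model(), chain_config())
  on_nodes <- names(which(km$baseline$mean > 0))
  expect_equal(unname(km$PI[cbind(on_nodes, on_nodes)]),
               rep(km$epsilon / (1 + km$epsilon), length(on_nodes)))
})

test_that("the epsilon rule keeps zero-baseline ratios at exactly 1", {
  m <- parse_model(c("A = A", "B = A"))  # all-zero run: every baseline is 0
  km <- knockout_matrix(m, sim_config(iterations = 10, repetitions = 2,
                                      update_scheme = "synchronous"))
  expect_true(all(km$PI == 1))
  expect_equal(km$epsilon, 1 / (10 * 2))
})

test_that("classification bands are closed on the altered side", {
  labels <- classify_pi(matrix(c(0.5, 0.8, 0.81, 1.0, 1.249, 1.25, 1.3),
                               nrow = 1))$labels
  expect_identical(as.vector(labels),
                   c("downregulated", "downregulated", "unchanged",
                     "unchanged", "unchanged", "overexpressed",
                     "overexpressed"))
  shifted <- classify_pi(matrix(0.85), low = 0.9, high = 1.1)$labels
  expect_identical(as.vector(shifted), "downregulated")
})

test_that("average-linkage clustering merges identical profiles first and matches a hand-computed tree", {
  # three knockout profiles with known Euclidean distances:
  # d(r1,r2) = 0, d(r1,r3) = 5, so r1/r2 merge first at height 0
  PI <- rbind(r1 = c(1, 1, 1), r2 = c(1, 1, 1), r3 = c(4, 5, 1))
  ord <- cluster_order(PI)
  expect_equal(ord$row_tree$merge[1, ], c(-1, -2))
  expect_equal(ord$row_tree$height[1], 0)
  expect_equal(ord$row_tree$height[2], 5)  # average of d(r1,r3)=d(r2,r3)=5
  # hand-computed average linkage on a 3-point line: 0-3-9
  PI2 <- rbind(a = c(0, 0), b = c(3, 0), c = c(9, 0))
  t2 <- cluster_order(PI2)$row_tree
  expect_equal(t2$merge[1, ], c(-1, -2))       # closest pair (d=3)
  expect_equal(t2$height[2], mean(c(9, 6)))    # average of d(a,c), d(b,c)
})

test_that("dendrogram topology is invariant to input node order", {
  # tie-free profiles: merge structure must not depend on row order
  set.seed(31)
  PI <- matrix(runif(6 * 5), 6, 5,
               dimnames = list(paste0("k", 1:6), paste0("n", 1:5)))
  perm <- c(4, 1, 6, 3, 5, 2)
  o1 <- cluster_order(PI)
  o2 <- cluster_order(PI[perm, ])
  expect_setequal(o1$row_order, o2$row_order)
  expect_equal(sort(o1$row_tree$height), sort(o2$row_tree$height))
  labs <- o2$row_tree$labels
  expect_equal(as.matrix(stats::cophenetic(o1$row_tree))[labs, labs],
               as.matrix(stats::cophenetic(o2$row_tree)),
               ignore_attr = TRUE)
})

test_that("the PI matrix round-trips through its TSV export", {
  km <- knockout_matrix(chain_model(), chain_config())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pi_matrix(km, path)
  back <- read_pi_matrix(path)
  expect_equal(back, km$PI, ignore_attr = TRUE)
  expect_identical(rownames(back), rownames(km$PI))
})

test_that("heatmap rendering writes an image and a consistent TSV", {
  km <- knockout_matrix(chain_model(), chain_config())
  img <- withr::local_tempfile(fileext = ".pdf")
  out <- render_heatmap(km, file = img)
  expect_true(file.exists(out$image))
  expect_true(file.size(out$image) > 0)
  expect_equal(read_pi_matrix(out$tsv), km$PI, ignore_attr = TRUE)
  expect_match(tree_newick(cluster_order(km)$row_tree), "^\\(")
})
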